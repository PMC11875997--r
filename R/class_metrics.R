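#' Confusion score of a class
#'
#' Label composition of the core region. Confusion is the fraction of core
#' vertices not belonging to the reference class — 0 for a perfectly
#' separated class, approaching `1 - p` for a class of mixture proportion `p`
#' fully intermixed with others.
#'
#' @param partition A `region_partition` with `core` populated.
#' @param graph The `neighbor_graph` it was derived from.
#' @return List with `confusion` (fraction in `[0, 1]`) and
#'   `core_composition` (named fractions summing to 1).
#' @export
confusion_score <- function(partition, graph) {
  labs <- graph$labels[partition$core]
  comp <- table(labs) / length(labs)
  comp <- stats::setNames(as.numeric(comp), names(comp))
  list(confusion = 1 - unname(comp[partition$class]), core_composition = comp)
}

# kappa kernels: each maps boundary-edge lengths to a non-negative
# contribution; connectivity grows with edge count and shrinks with length.
kappa_kernel_fun <- function(kernel = c("reciprocal", "count", "exponential"),
                             lambda = NULL) {
  kernel <- match.arg(kernel)
  switch(kernel,
    reciprocal = function(d) 1 / d,
    count = function(d) rep(1, length(d)),
    exponential = function(d) exp(-d / lambda)
  )
}

#' Raw boundary connectivity of a class to its neighbors
#'
#' For each other class `X`, sums a kernel of the boundary-edge lengths over
#' the edges joining the reference class directly to `X`-labeled context
#' vertices. The default kernel is the reciprocal length, so connectivity
#' increases with the number of boundary edges and decreases with their
#' length. Classes with no boundary edge get exactly 0.
#'
#' @param partition A `region_partition` with `boundary_edges` populated.
#' @param graph The `neighbor_graph`.
#' @param kernel One of `"reciprocal"` (default), `"count"`,
#'   `"exponential"` (`exp(-d / lambda)`).
#' @param lambda Length scale for the exponential kernel; defaults to the
#'   mean edge length of the graph.
#' @return Named numeric vector of `kappa_raw` over every other class present
#'   in the graph (zeros included; the reference class is absent).
#' @export
connectivity <- function(partition, graph, kernel = "reciprocal", lambda = NULL) {
  if (is.null(partition$boundary_edges)) stop("compute context_region() first", call. = FALSE)
  if (is.null(lambda)) lambda <- mean(graph$lengths)
  kf <- kappa_kernel_fun(kernel, lambda)
  others <- setdiff(sort(unique(graph$labels)), partition$class)
  kappa <- stats::setNames(numeric(length(others)), others)
  bnd <- partition$boundary_edges
  if (length(bnd)) {
    e <- graph$edges[bnd, , drop = FALSE]
    d <- graph$lengths[bnd]
    if (any(d <= 0)) stop("zero-length boundary edge (internal error)", call. = FALSE)
    # the context-side endpoint of each boundary edge
    in_vc <- logical(graph$n); in_vc[partition$vc] <- TRUE
    ctx_end <- ifelse(in_vc[e[, 1]], e[, 2], e[, 1])
    contrib <- tapply(kf(d), graph$labels[ctx_end], sum)
    kappa[names(contrib)] <- as.numeric(contrib)
  }
  kappa
}

#' Quantile-normalize raw connectivities across all class pairs
#'
#' Raw connectivity values live on an arbitrary scale that depends on the
#' embedding's units and density. Following the empirical-distribution
#' normalization, each strictly positive `kappa_raw` is replaced by its
#' mid-rank empirical-CDF value `(rank - 0.5) / n` within the pooled set of
#' all strictly positive values across all ordered class pairs of the
#' embedding (average ranks for ties). Pairs with `kappa_raw = 0` — no
#' boundary connection at context range — score exactly 0.
#'
#' @param raw Square numeric matrix of raw connectivities: rows are reference
#'   classes, columns are neighbor classes, diagonal `NA`.
#' @return Object of class `connectivity_table`: list with `raw` and `score`
#'   matrices of identical shape; scores lie in `[0, 1)` and are a
#'   non-decreasing function of the raw values.
#' @export
quantile_scores <- function(raw) {
  stopifnot(is.matrix(raw), nrow(raw) == ncol(raw))
  score <- raw
  off <- !is.na(raw)
  vals <- raw[off]
  pos <- vals > 0
  if (!any(pos)) {
    if (length(vals)) warning("all raw connectivities are zero; all neighborhood scores are 0")
    vals[] <- 0
  } else {
    vals[pos] <- (rank(vals[pos], ties.method = "average") - 0.5) / sum(pos)
    vals[!pos] <- 0
  }
  score[off] <- vals
  structure(list(raw = raw, score = score), class = "connectivity_table")
}

#' Size (centered log-ratio) values over a class's combined region
#'
#' Counts the points of each label present in the combined region and
#' expresses them as centered log-ratios: `clr_l = ln(c_l) - mean(ln(c))`
#' over the labels of the composition. CLR is the standard scale-free
#' treatment of compositional counts — the values sum to zero and a class's
#' value measures its abundance relative to the geometric mean of its own
#' neighborhood, not to the whole embedding. The kappa-weighted variant
#' multiplies each neighbor's CLR by the reference class's neighborhood score
#' toward it (the class's own entry stays unweighted).
#'
#' @param partition A `region_partition` with `combined` populated.
#' @param graph The `neighbor_graph`.
#' @param neighborhood Named numeric vector of neighborhood scores of the
#'   reference class toward other classes (see [quantile_scores()]).
#' @return List with `size_clr` and `size_weighted`, both named over the
#'   labels present in the combined region.
#' @export
size_values <- function(partition, graph, neighborhood) {
  if (is.null(partition$combined)) stop("compute combined_region() first", call. = FALSE)
  cls <- partition$class
  counts <- table(graph$labels[partition$combined])
  counts <- stats::setNames(as.numeric(counts), names(counts))
  lc <- log(counts)
  clr <- lc - mean(lc)
  w <- clr
  others <- setdiff(names(clr), cls)
  w[others] <- clr[others] * ifelse(others %in% names(neighborhood),
                                    neighborhood[others], 0)
  list(size_clr = clr, size_weighted = w)
}

#' Compute all three class metrics for one embedding
#'
#' Runs the sequential pipeline per class — intra-class threshold, core
#' region (Confusion), context region and quantile-normalized boundary
#' connectivity (Neighborhood), combined region and CLR abundances (Size) —
#' and collects the results for every class of the embedding. The stages are
#' deliberately sequential: Neighborhood is computed on regions derived from
#' the Confusion stage's graph and threshold, and Size on Neighborhood's
#' regions, so each metric conditions the interpretation of the next.
#'
#' @param emb A [labeled_embedding()], or an already-built `neighbor_graph`.
#' @param h Hop count for the core traversal (context uses `h + 1`).
#'   Default 1.
#' @param k Threshold multiplier in `tau = mu + k * sigma`. Default 3.
#' @param kernel Connectivity kernel, see [connectivity()].
#' @param prune_intra Prune long intra-class edges too? Default `FALSE`.
#' @param jitter_scale,seed Passed to [build_graph()] when `emb` is an
#'   embedding.
#' @return Object of class `class_metric_set`: list with `name`, `classes`,
#'   `confusion` (named vector), `core_composition` (list of named vectors),
#'   `kappa_raw` and `neighborhood` (square matrices, diagonal `NA`),
#'   `size_clr` and `size_weighted` (lists of named vectors), `n_class`
#'   (named point counts), `partitions`, `graph`, `params`.
#' @examples
#' emb <- generate_layout(layout_spec(data.frame(
#'   label = c("a", "b"), n = c(60, 60), x = c(0, 6), y = c(0, 0), spread = 1
#' ), seed = 7))
#' m <- class_metrics(emb)
#' m$confusion
#' @export
class_metrics <- function(emb, h = 1L, k = 3, kernel = "reciprocal",
                          prune_intra = FALSE, jitter_scale = 1e-9, seed = 1L) {
  graph <- if (inherits(emb, "neighbor_graph")) emb
           else build_graph(emb, jitter_scale = jitter_scale, seed = seed)
  name <- if (inherits(emb, "labeled_embedding")) emb$name else "embedding"
  classes <- sort(unique(graph$labels))
  nc <- length(classes)

  partitions <- lapply(classes, function(cl)
    class_regions(graph, cl, h = h, k = k, prune_intra = prune_intra))
  names(partitions) <- classes

  conf <- lapply(partitions, confusion_score, graph = graph)
  confusion <- vapply(conf, `[[`, numeric(1), "confusion")
  core_composition <- lapply(conf, `[[`, "core_composition")

  kappa_raw <- matrix(NA_real_, nc, nc, dimnames = list(classes, classes))
  for (cl in classes) {
    kap <- connectivity(partitions[[cl]], graph, kernel = kernel)
    kappa_raw[cl, names(kap)] <- kap
  }
  ct <- quantile_scores(kappa_raw)

  sizes <- lapply(classes, function(cl)
    size_values(partitions[[cl]], graph, ct$score[cl, ]))
  names(sizes) <- classes

  structure(
    list(name = name, classes = classes, confusion = confusion,
         core_composition = core_composition,
         kappa_raw = ct$raw, neighborhood = ct$score,
         size_clr = lapply(sizes, `[[`, "size_clr"),
         size_weighted = lapply(sizes, `[[`, "size_weighted"),
         n_class = stats::setNames(as.numeric(table(graph$labels)[classes]), classes),
         partitions = partitions, graph = graph,
         params = list(h = as.integer(h), k = k, kernel = kernel,
                       prune_intra = prune_intra)),
    class = "class_metric_set"
  )
}

#' @export
print.class_metric_set <- function(x, ...) {
  cat("<class_metric_set> '", x$name, "': ", length(x$classes), " classes ",
      "(h=", x$params$h, ", k=", x$params$k, ", kernel=", x$params$kernel, ")\n",
      sep = "")
  print(round(x$confusion, 4))
  invisible(x)
}

#' Wide per-class metric table
#'
#' One row per class: `confusion`, then `neighborhood_<label>` score columns
#' and `size_clr_<label>` columns (NA where a label is absent from the
#' class's combined region).
#'
#' @param metrics A `class_metric_set`.
#' @return A `data.frame`.
#' @export
metric_table <- function(metrics) {
  cls <- metrics$classes
  nb <- metrics$neighborhood
  colnames(nb) <- paste0("neighborhood_", colnames(nb))
  sz <- matrix(NA_real_, length(cls), length(cls),
               dimnames = list(cls, paste0("size_clr_", cls)))
  for (cl in cls) {
    v <- metrics$size_clr[[cl]]
    sz[cl, paste0("size_clr_", names(v))] <- v
  }
  cbind(data.frame(class = cls, n = metrics$n_class[cls],
                   confusion = metrics$confusion[cls],
                   stringsAsFactors = FALSE),
        as.data.frame(nb), as.data.frame(sz), row.names = NULL)
}
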