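# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards (graph building must not consume the
# user's RNG stream).
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Build the Delaunay neighborhood graph of an embedding
#'
#' Computes the Delaunay triangulation of the 2D point set (via
#' \pkg{deldir}) and returns it as an undirected graph whose edge lengths are
#' Euclidean distances in embedding units. The Delaunay graph is the
#' perceptual backbone of all three metrics: it connects each point to its
#' natural planar neighbors without a free bandwidth parameter.
#'
#' Delaunay triangulation is undefined on duplicate points, so exactly
#' coincident points are first displaced by a deterministic, seeded jitter of
#' magnitude `jitter_scale` times the bounding-box diagonal. Jittered
#' positions are used both for the triangulation and for the reported edge
#' lengths; the embedding itself is never modified. If all points are
#' collinear (even after jitter) no triangulation exists and an error is
#' raised.
#'
#' @param emb A [labeled_embedding()].
#' @param jitter_scale Fraction of the bounding-box diagonal used as jitter
#'   magnitude for coincident points. Default `1e-9` — large enough to break
#'   exact ties, far below visual resolution.
#' @param seed Integer seed for the jitter; fixed seed gives a fully
#'   reproducible graph.
#' @return An object of class `neighbor_graph`: list with `n` (vertex count),
#'   `edges` (an `m x 2` integer matrix, each row an unordered pair `i < j`),
#'   `lengths` (numeric, per edge), `labels` (per vertex), `coords` (the
#'   possibly jittered coordinates used for triangulation), `jittered`
#'   (indices of displaced vertices).
#' @export
build_graph <- function(emb, jitter_scale = 1e-9, seed = 1L) {
  validate_embedding(emb)
  stopifnot(jitter_scale >= 0)
  xy <- emb$coords
  n <- nrow(xy)
  key <- paste(xy[, 1], xy[, 2], sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) && jitter_scale > 0) {
    diag_len <- sqrt(sum((apply(xy, 2, max) - apply(xy, 2, min))^2))
    if (diag_len == 0) diag_len <- 1 # all points coincident: unit-scale jitter
    mag <- jitter_scale * diag_len
    with_local_seed(seed, {
      xy[dup, 1] <- xy[dup, 1] + stats::runif(length(dup), -mag, mag)
      xy[dup, 2] <- xy[dup, 2] + stats::runif(length(dup), -mag, mag)
    })
  }
  # collinear input has no triangulation; deldir would silently chain points
  ctr <- sweep(xy, 2, colMeans(xy))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[2] <= sv[1] * 1e-12) {
    stop("all points are (near-)collinear; no Delaunay triangulation exists. ",
         "If points are coincident, increase jitter_scale.", call. = FALSE)
  }
  ds <- deldir::deldir(xy[, 1], xy[, 2])$delsgs
  edges <- cbind(pmin(ds$ind1, ds$ind2), pmax(ds$ind1, ds$ind2))
  storage.mode(edges) <- "integer"
  ord <- order(edges[, 1], edges[, 2])
  edges <- edges[ord, , drop = FALSE]
  lengths <- sqrt((xy[edges[, 1], 1] - xy[edges[, 2], 1])^2 +
                  (xy[edges[, 1], 2] - xy[edges[, 2], 2])^2)
  if (any(lengths <= 0)) {
    stop("zero-length edge after jitter; increase jitter_scale", call. = FALSE)
  }
  structure(
    list(n = n, edges = edges, lengths = lengths, labels = emb$labels,
         coords = xy, jittered = dup,
         params = list(jitter_scale = jitter_scale, seed = seed)),
    class = "neighbor_graph"
  )
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat("<neighbor_graph> ", x$n, " vertices, ", nrow(x$edges), " Delaunay edges, ",
      length(unique(x$labels)), " classes\n", sep = "")
  invisible(x)
}

#' Intra-class edge statistics and distance threshold
#'
#' Collects the lengths of all intra-class Delaunay edges of one class (both
#' endpoints carry the class label) and derives the pruning threshold
#' `tau = mu + k * sigma`. The threshold compensates for Delaunay's tendency
#' to connect distant points across empty space: inter-class edges longer
#' than `tau` are not perceptually plausible neighbors and are pruned during
#' the core traversal.
#'
#' `sigma` is the population standard deviation (divide by n), so a class
#' with a single intra-class edge gets `sigma = 0` and a finite threshold. A
#' class with no intra-class edge at all (a singleton, or a class never
#' Delaunay-adjacent to itself) falls back to the pooled statistics over all
#' intra-class edges of all classes; if the whole graph has none, over all
#' edges. The fallback route is recorded in the `pooled` field.
#'
#' @param graph A `neighbor_graph`.
#' @param class Class label present in the graph.
#' @param k Non-negative multiplier on sigma; larger `k` means a more
#'   permissive threshold and a larger core. Default 3.
#' @return Object of class `intra_class_stats`: list with `class`, `mu`,
#'   `sigma`, `tau`, `n_edges`, `k`, `pooled`.
#' @export
intra_class_stats <- function(graph, class, k = 3) {
  if (!class %in% graph$labels) stop("unknown class: ", class, call. = FALSE)
  lab <- graph$labels
  own <- lab[graph$edges[, 1]] == class & lab[graph$edges[, 2]] == class
  d <- graph$lengths[own]
  pooled <- FALSE
  if (length(d) == 0L) {
    pooled <- TRUE
    intra_all <- lab[graph$edges[, 1]] == lab[graph$edges[, 2]]
    d_pool <- graph$lengths[intra_all]
    if (length(d_pool) == 0L) d_pool <- graph$lengths
    mu <- mean(d_pool)
    sigma <- sqrt(mean((d_pool - mu)^2))
  } else {
    mu <- mean(d)
    sigma <- sqrt(mean((d - mu)^2)) # population sd: single edge -> sigma 0
  }
  structure(
    list(class = class, mu = mu, sigma = sigma, tau = mu + k * sigma,
         n_edges = length(d), k = k, pooled = pooled),
    class = "intra_class_stats"
  )
}

# Multi-source BFS over an edge subset: vertices reachable from `sources`
# using at most `hops` edges drawn from edges[keep, ]. Returns a sorted
# integer vector including the sources themselves.
bfs_reach <- function(graph, keep, sources, hops) {
  e <- graph$edges[keep, , drop = FALSE]
  visited <- logical(graph$n)
  visited[sources] <- TRUE
  frontier <- visited
  for (step in seq_len(hops)) {
    if (!any(frontier) || nrow(e) == 0L) break
    hit1 <- frontier[e[, 1]]
    hit2 <- frontier[e[, 2]]
    nxt <- unique(c(e[hit1, 2], e[hit2, 1]))
    nxt <- nxt[!visited[nxt]]
    if (!length(nxt)) break
    visited[nxt] <- TRUE
    frontier <- logical(graph$n)
    frontier[nxt] <- TRUE
  }
  which(visited)
}

#' Core region of a class
#'
#' Breadth-first traversal of the Delaunay graph from every vertex of the
#' reference class, up to `h` hops. An edge is traversable if both endpoints
#' belong to the class (intra-class edges are kept regardless of length,
#' unless `prune_intra = TRUE`) or if its length does not exceed the class
#' threshold `tau`. The union of all reached vertices — including the class's
#' own — is the core region, whose label composition measures visual
#' intermixing (Confusion).
#'
#' @param graph A `neighbor_graph`.
#' @param stats [intra_class_stats()] of the same class.
#' @param h Hop count, `>= 1`. Default 1.
#' @param prune_intra If `TRUE`, intra-class edges longer than `tau` are also
#'   pruned (the default keeps them: a class's own distant points stay in its
#'   core).
#' @return A `region_partition` with `core` and `core_labels` populated.
#' @export
core_region <- function(graph, stats, h = 1L, prune_intra = FALSE) {
  stopifnot(h >= 1L)
  cls <- stats$class
  lab <- graph$labels
  vc <- which(lab == cls)
  intra <- lab[graph$edges[, 1]] == cls & lab[graph$edges[, 2]] == cls
  short <- graph$lengths <= stats$tau
  keep <- if (prune_intra) short else (intra | short)
  core <- bfs_reach(graph, keep, vc, h)
  structure(
    list(class = cls, vc = vc, core = core, core_labels = unique(lab[core]),
         context = NULL, boundary_edges = NULL, context_labels = NULL,
         combined = NULL, h = as.integer(h), stats = stats,
         prune_intra = prune_intra),
    class = "region_partition"
  )
}

#' Context region of a class
#'
#' Vertices reachable from the class within `h + 1` hops without any distance
#' constraint, minus the core region. The context captures the class's
#' neighboring classes; the Delaunay edges joining class vertices directly to
#' context vertices are the boundary edges feeding the Neighborhood
#' connectivity.
#'
#' @param graph A `neighbor_graph`.
#' @param partition Output of [core_region()] (same class, same `h`).
#' @param h Hop count used for the core; the context uses `h + 1`.
#' @return The partition with `context`, `boundary_edges` (index vector into
#'   `graph$edges` rows) and `context_labels` populated.
#' @export
context_region <- function(graph, partition, h = partition$h) {
  stopifnot(identical(as.integer(h), partition$h))
  reach <- bfs_reach(graph, rep(TRUE, nrow(graph$edges)), partition$vc, h + 1L)
  ctx <- setdiff(reach, partition$core)
  in_vc <- logical(graph$n); in_vc[partition$vc] <- TRUE
  in_ctx <- logical(graph$n); in_ctx[ctx] <- TRUE
  e <- graph$edges
  bnd <- which((in_vc[e[, 1]] & in_ctx[e[, 2]]) | (in_vc[e[, 2]] & in_ctx[e[, 1]]))
  partition$context <- ctx
  partition$boundary_edges <- bnd
  partition$context_labels <- unique(graph$labels[ctx])
  partition
}

#' Combined region of a class
#'
#' Label-based closure of core and context: every vertex of the whole graph
#' whose label occurs in the core or context regions, wherever it sits in the
#' embedding. This is the reference composition for the Size metric, so that
#' relative abundances count whole classes rather than the accidental slice
#' that fell inside a hop radius.
#'
#' @param graph A `neighbor_graph`.
#' @param partition Output of [context_region()].
#' @return The partition with `combined` populated.
#' @export
combined_region <- function(graph, partition) {
  if (is.null(partition$context)) stop("compute context_region() first", call. = FALSE)
  labs <- union(partition$core_labels, partition$context_labels)
  partition$combined <- which(graph$labels %in% labs)
  partition
}

#' Full region partition for one class
#'
#' Convenience wrapper running [intra_class_stats()], [core_region()],
#' [context_region()] and [combined_region()] in sequence.
#'
#' @inheritParams core_region
#' @param class Reference class label.
#' @param k Threshold multiplier (see [intra_class_stats()]).
#' @return A fully populated `region_partition`.
#' @export
class_regions <- function(graph, class, h = 1L, k = 3, prune_intra = FALSE) {
  st <- intra_class_stats(graph, class, k)
  p <- core_region(graph, st, h, prune_intra)
  p <- context_region(graph, p, h)
  combined_region(graph, p)
}

#' @export
print.region_partition <- function(x, ...) {
  cat("<region_partition> class '", x$class, "': |core|=", length(x$core),
      " |context|=", length(x$context %||% integer()),
      " |combined|=", length(x$combined %||% integer()), "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Region membership table for one class
#'
#' One row per graph vertex with its label and region assignment
#' (`core`, `context`, `combined`, or `none`); `combined` marks vertices in
#' the label closure that are in neither core nor context. Useful for
#' debugging and plotting region construction.
#'
#' @param partition A fully populated `region_partition`.
#' @param graph The `neighbor_graph` it was derived from.
#' @return A `data.frame` with columns `vertex`, `label`, `region`.
#' @export
region_table <- function(partition, graph) {
  region <- rep("none", graph$n)
  if (!is.null(partition$combined)) region[partition$combined] <- "combined"
  if (!is.null(partition$context)) region[partition$context] <- "context"
  region[partition$core] <- "core"
  data.frame(vertex = seq_len(graph$n), label = graph$labels, region = region,
             stringsAsFactors = FALSE)
}
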