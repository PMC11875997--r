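#' Compare two embeddings through their class metrics
#'
#' Relates two embedding visualizations through shared class labels, without
#' any point correspondence. For each shared class `C` the result carries:
#'
#' * `confusion_delta`: `confusion_A(C) - confusion_B(C)`, signed, in
#'   `[-1, 1]`;
#' * `neighborhood_dissimilarity`: one minus the cosine similarity between
#'   the two neighborhood score vectors, restricted to shared labels
#'   excluding `C` itself (0 when both vectors are zero, 1 when exactly one
#'   is zero — "connected" versus "isolated" is maximal disagreement);
#' * `size_delta`: `size_clr_A[C] - size_clr_B[C]`, the change in the class's
#'   CLR abundance within its own combined region.
#'
#' Labels present in only one embedding are reported in `unmatched_labels`
#' and excluded from the vectors rather than zero-filled, so an absent class
#' is never conflated with a present-but-disconnected one. Embedding A is the
#' reference: deltas are A minus B.
#'
#' @param metrics_a,metrics_b `class_metric_set` objects (see
#'   [class_metrics()]), or `labeled_embedding`s — in which case metrics are
#'   computed with the parameters in `...`.
#' @param ... Passed to [class_metrics()] when embeddings are supplied.
#' @return Object of class `comparison_result`: list with `shared_labels`,
#'   `confusion_a/b/delta`, `neighborhood_dissimilarity`, `size_clr_a/b`,
#'   `size_delta`, `n_points_a/b` (all named by class), `unmatched_labels`
#'   (list by embedding name), `names` (the two embedding names).
#' @examples
#' spec <- layout_spec(data.frame(label = c("a", "b", "c"), n = 80,
#'                                x = c(0, 5, 10), y = 0, spread = 1), seed = 3)
#' m <- class_metrics(generate_layout(spec))
#' cmp <- compare_embeddings(m, m)   # self-comparison: all deltas zero
#' cmp$confusion_delta
#' @export
compare_embeddings <- function(metrics_a, metrics_b, ...) {
  if (inherits(metrics_a, "labeled_embedding")) metrics_a <- class_metrics(metrics_a, ...)
  if (inherits(metrics_b, "labeled_embedding")) metrics_b <- class_metrics(metrics_b, ...)
  stopifnot(inherits(metrics_a, "class_metric_set"),
            inherits(metrics_b, "class_metric_set"))
  shared <- intersect(metrics_a$classes, metrics_b$classes)
  if (!length(shared)) {
    stop("no shared class labels between '", metrics_a$name, "' and '",
         metrics_b$name, "'", call. = FALSE)
  }
  shared <- sort(shared)
  unmatched <- list(setdiff(metrics_a$classes, shared),
                    setdiff(metrics_b$classes, shared))
  names(unmatched) <- make.unique(c(metrics_a$name, metrics_b$name))

  conf_a <- metrics_a$confusion[shared]
  conf_b <- metrics_b$confusion[shared]

  nbd <- vapply(shared, function(cl) {
    keep <- setdiff(shared, cl)
    if (!length(keep)) return(0)
    cosine_dissimilarity(metrics_a$neighborhood[cl, keep],
                         metrics_b$neighborhood[cl, keep])
  }, numeric(1))

  size_a <- vapply(shared, function(cl) metrics_a$size_clr[[cl]][[cl]], numeric(1))
  size_b <- vapply(shared, function(cl) metrics_b$size_clr[[cl]][[cl]], numeric(1))

  structure(
    list(shared_labels = shared,
         confusion_a = conf_a, confusion_b = conf_b,
         confusion_delta = conf_a - conf_b,
         neighborhood_dissimilarity = nbd,
         size_clr_a = size_a, size_clr_b = size_b,
         size_delta = size_a - size_b,
         n_points_a = metrics_a$n_class[shared],
         n_points_b = metrics_b$n_class[shared],
         unmatched_labels = unmatched,
         names = c(metrics_a$name, metrics_b$name)),
    class = "comparison_result"
  )
}

# 1 - cosine similarity, with the degenerate zero-vector cases pinned:
# both zero -> 0 (identically disconnected), exactly one zero -> 1.
# Identical vectors return exactly 0 so that self-comparison is an identity
# rather than floating-point dust.
cosine_dissimilarity <- function(a, b) {
  if (identical(unname(a), unname(b))) return(0)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 && nb == 0) return(0)
  if (na == 0 || nb == 0) return(1)
  d <- 1 - sum(a * b) / (na * nb)
  min(max(d, 0), 1)
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result> '", x$names[1], "' vs '", x$names[2], "': ",
      length(x$shared_labels), " shared classes\n", sep = "")
  print(comparison_table(x), digits = 4)
  invisible(x)
}

#' Per-class comparison table
#'
#' @param result A `comparison_result`.
#' @return A `data.frame` with one row per shared class: confusion on both
#'   sides and its delta, neighborhood dissimilarity, size CLR on both sides
#'   and its delta, and point counts.
#' @export
comparison_table <- function(result) {
  data.frame(
    class = result$shared_labels,
    confusion_a = unname(result$confusion_a),
    confusion_b = unname(result$confusion_b),
    confusion_delta = unname(result$confusion_delta),
    neighborhood_dissimilarity = unname(result$neighborhood_dissimilarity),
    size_clr_a = unname(result$size_clr_a),
    size_clr_b = unname(result$size_clr_b),
    size_delta = unname(result$size_delta),
    n_points_a = unname(result$n_points_a),
    n_points_b = unname(result$n_points_b),
    stringsAsFactors = FALSE
  )
}

#' Project per-class comparison scores onto points
#'
#' Assigns every point of one embedding its class's comparison score for the
#' chosen metric, producing the per-point vector that drives metric-colored
#' scatter rendering. Points whose label is not shared between the two
#' embeddings get `NA` (rendered neutral gray).
#'
#' @param result A `comparison_result`.
#' @param emb The `labeled_embedding` of the requested side.
#' @param metric One of `"confusion"`, `"neighborhood"`, `"size"`.
#' @param side `"A"` or `"B"` — which embedding `emb` is. The per-class score
#'   is the same on both sides (deltas are computed once); the side only
#'   matters for label matching.
#' @return Numeric vector, one score per point.
#' @export
per_point_projection <- function(result, emb,
                                 metric = c("confusion", "neighborhood", "size"),
                                 side = c("A", "B")) {
  metric <- match.arg(metric)
  side <- match.arg(side)
  scores <- switch(metric,
    confusion = result$confusion_delta,
    neighborhood = result$neighborhood_dissimilarity,
    size = result$size_delta
  )
  out <- rep(NA_real_, n_points(emb))
  hit <- emb$labels %in% result$shared_labels
  out[hit] <- scores[emb$labels[hit]]
  out
}

#' Point-wise k-nearest-neighbor Jaccard baseline
#'
#' The conventional way to compare two embeddings of the *same* points: for
#' each point, the Jaccard index between its k-nearest-neighbor index sets in
#' the two layouts (Euclidean, self excluded). It requires a declared
#' point correspondence (row order) and collapses to near-zero on
#' independent re-layouts of identical data — the failure mode the
#' class-based metrics are designed to avoid. Provided for contrast.
#'
#' @param emb_a,emb_b `labeled_embedding`s with identical point counts and
#'   row-order correspondence.
#' @param k Neighborhood size, `1 <= k < n`. Default 7.
#' @return Numeric vector of per-point Jaccard indices in `[0, 1]`.
#' @export
neighborhood_jaccard_baseline <- function(emb_a, emb_b, k = 7L) {
  validate_embedding(emb_a); validate_embedding(emb_b)
  n <- n_points(emb_a)
  if (n_points(emb_b) != n) {
    stop("the Jaccard baseline requires point correspondence: embeddings have ",
         n, " and ", n_points(emb_b), " points", call. = FALSE)
  }
  stopifnot(k >= 1L, k < n)
  nn_a <- FNN::get.knn(emb_a$coords, k = k)$nn.index
  nn_b <- FNN::get.knn(emb_b$coords, k = k)$nn.index
  vapply(seq_len(n), function(i) {
    inter <- length(intersect(nn_a[i, ], nn_b[i, ]))
    inter / (2L * k - inter)
  }, numeric(1))
}
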