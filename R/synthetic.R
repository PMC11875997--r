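# Deterministic 31-bit sub-seed from a seed and string parts. Per-class
# seeding means adding or resizing one class never perturbs another class's
# draws, and the same (seed, label) always yields the same cluster.
subseed <- function(seed, ...) {
  s <- paste(c(format(seed), ...), collapse = "\r")
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483629
  as.integer(h)
}

#' Specify a synthetic Gaussian-mixture layout
#'
#' Describes a labeled 2D layout as one isotropic Gaussian cluster per class,
#' plus optional planted structural changes used by [generate_pair()]. The
#' generator stands in for real dimensionality-reduction outputs: it does not
#' imitate UMAP/t-SNE geometry, but it gives full, seeded control over the
#' three properties the metrics measure — inter-class overlap (cluster
#' center distance vs spread), adjacency structure (which clusters sit next
#' to which), and per-class abundance.
#'
#' @param classes A `data.frame` with columns `label`, `n` (points per class,
#'   `>= 1`), `x`, `y` (cluster center) and `spread` (isotropic standard
#'   deviation, `> 0`). Columns `n`, `x`, `y`, `spread` are recycled.
#' @param seed Integer master seed; the layout is fully reproducible given
#'   the spec.
#' @param planted_changes List of changes built with [plant_overlap()],
#'   [plant_adjacency()] or [plant_abundance()]; applied only by
#'   [generate_pair()] to the second embedding.
#' @param name Base name for generated embeddings.
#' @return An object of class `layout_spec`.
#' @export
layout_spec <- function(classes, seed = 1L, planted_changes = list(),
                        name = "synthetic") {
  classes <- as.data.frame(classes)
  need <- c("label", "n", "x", "y", "spread")
  miss <- setdiff(need, names(classes))
  if (length(miss)) stop("classes is missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  classes <- classes[need]
  classes$label <- as.character(classes$label)
  if (anyDuplicated(classes$label)) stop("duplicate class labels in spec", call. = FALSE)
  stopifnot(all(classes$n >= 1), all(classes$spread > 0))
  for (ch in planted_changes) {
    if (!inherits(ch, "planted_change")) {
      stop("planted_changes must be built with plant_overlap()/plant_adjacency()/plant_abundance()",
           call. = FALSE)
    }
  }
  structure(list(classes = classes, seed = as.integer(seed),
                 planted_changes = planted_changes, name = name),
            class = "layout_spec")
}

#' Planted structural changes for paired layouts
#'
#' Each constructor describes one controlled difference between the two
#' embeddings of a [generate_pair()] call, matched to the metric that should
#' detect it:
#'
#' * `plant_overlap(class, target)` moves `class`'s cluster center onto
#'   `target`'s, planting intermixing — detected by Confusion.
#' * `plant_adjacency(classes)` cyclically permutes the cluster centers of
#'   the listed classes, rearranging who neighbors whom — detected by
#'   Neighborhood.
#' * `plant_abundance(class, ratio)` rescales `class`'s point count by
#'   `ratio` (result rounded, minimum 1) — detected by Size.
#'
#' @param class,target,classes Class labels referenced by the change.
#' @param ratio Positive abundance ratio (B relative to A).
#' @return An object of class `planted_change`.
#' @name planted_changes
NULL

#' @rdname planted_changes
#' @export
plant_overlap <- function(class, target) {
  structure(list(kind = "overlap", class = class, target = target),
            class = "planted_change")
}

#' @rdname planted_changes
#' @export
plant_adjacency <- function(classes) {
  stopifnot(length(classes) >= 2)
  structure(list(kind = "adjacency", classes = as.character(classes)),
            class = "planted_change")
}

#' @rdname planted_changes
#' @export
plant_abundance <- function(class, ratio) {
  stopifnot(ratio > 0)
  structure(list(kind = "abundance", class = class, ratio = ratio),
            class = "planted_change")
}

# Apply planted changes to the class table of a spec.
apply_changes <- function(classes, changes) {
  rownames(classes) <- classes$label
  for (ch in changes) {
    switch(ch$kind,
      overlap = {
        check_label(classes, c(ch$class, ch$target))
        classes[ch$class, c("x", "y")] <- classes[ch$target, c("x", "y")]
      },
      adjacency = {
        check_label(classes, ch$classes)
        from <- ch$classes
        to <- c(from[-1], from[1]) # cyclic shift of centers
        classes[from, c("x", "y")] <- classes[to, c("x", "y")]
      },
      abundance = {
        check_label(classes, ch$class)
        classes[ch$class, "n"] <- max(1L, round(classes[ch$class, "n"] * ch$ratio))
      },
      stop("unknown planted change kind: ", ch$kind, call. = FALSE)
    )
  }
  classes
}

check_label <- function(classes, labels) {
  miss <- setdiff(labels, classes$label)
  if (length(miss)) stop("planted change references unknown class(es): ",
                         paste(miss, collapse = ", "), call. = FALSE)
}

#' Generate a labeled layout from a spec
#'
#' Draws each class as an isotropic Gaussian cluster at its center. Every
#' class uses its own sub-seed derived from `(seed, label)`, so the draw for
#' one class is independent of the presence, order, or size of the others.
#' Points are emitted class by class in spec order.
#'
#' @param spec A [layout_spec()].
#' @param name Override for the embedding name.
#' @return A [labeled_embedding()].
#' @export
generate_layout <- function(spec, name = spec$name) {
  stopifnot(inherits(spec, "layout_spec"))
  cls <- spec$classes
  pieces <- lapply(seq_len(nrow(cls)), function(i) {
    n <- cls$n[i]
    with_local_seed(subseed(spec$seed, cls$label[i], "xy"), {
      cbind(stats::rnorm(n, cls$x[i], cls$spread[i]),
            stats::rnorm(n, cls$y[i], cls$spread[i]))
    })
  })
  xy <- do.call(rbind, pieces)
  labeled_embedding(xy[, 1], xy[, 2], rep(cls$label, cls$n), name = name)
}

#' Generate a pair of layouts with planted differences
#'
#' Embedding A is generated from the spec as-is; embedding B from the spec
#' with `planted_changes` applied. Classes untouched by any change are drawn
#' with identical sub-seeds on both sides, so with no planted changes A and B
#' are identical, and every observed metric difference is attributable to the
#' plants.
#'
#' @param spec A [layout_spec()] whose `planted_changes` describe embedding B.
#' @return List of two [labeled_embedding()]s named `a` and `b`.
#' @export
generate_pair <- function(spec) {
  stopifnot(inherits(spec, "layout_spec"))
  a <- generate_layout(spec, name = paste0(spec$name, "_a"))
  spec_b <- spec
  spec_b$classes <- apply_changes(spec$classes, spec$planted_changes)
  b <- generate_layout(spec_b, name = paste0(spec$name, "_b"))
  list(a = a, b = b)
}
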