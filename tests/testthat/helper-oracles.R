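# Shared fixtures and independent oracles for the suite. The oracles here
# deliberately use different mechanics than the package (recursive path
# enumeration instead of frontier BFS; interp instead of deldir) so they can
# arbitrate correctness.

# Random labeled layout: uniform points, labels drawn so every class occurs.
random_layout <- function(n, n_classes, seed, name = "random") {
  set.seed(seed)
  labels <- c(paste0("c", seq_len(n_classes)),
              sample(paste0("c", seq_len(n_classes)), n - n_classes, replace = TRUE))
  labeled_embedding(runif(n) * 10, runif(n) * 10, labels, name = name)
}

# Gaussian-mixture layout helper around the package generator.
gaussian_layout <- function(centers, n = 100, spread = 1, seed = 1) {
  spec <- layout_spec(
    data.frame(label = rownames(centers), n = n,
               x = centers[, 1], y = centers[, 2], spread = spread),
    seed = seed)
  generate_layout(spec)
}

# A neighbor_graph built by hand, for unit tests with prescribed edge
# lengths (bypasses triangulation; structurally identical to build_graph()
# output minus coords).
fake_graph <- function(edges, lengths, labels) {
  edges <- matrix(as.integer(edges), ncol = 2)
  structure(list(n = length(labels),
                 edges = cbind(pmin(edges[, 1], edges[, 2]),
                               pmax(edges[, 1], edges[, 2])),
                 lengths = as.numeric(lengths), labels = as.character(labels),
                 coords = NULL, jittered = integer(),
                 params = list(jitter_scale = 0, seed = 0L)),
            class = "neighbor_graph")
}

# Exhaustive path-enumeration reachability: all vertices reachable from
# `sources` by a walk of at most `hops` kept edges (walks may revisit).
oracle_reach <- function(graph, keep, sources, hops) {
  e <- graph$edges[keep, , drop = FALSE]
  nbrs <- vector("list", graph$n)
  for (r in seq_len(nrow(e))) {
    nbrs[[e[r, 1]]] <- c(nbrs[[e[r, 1]]], e[r, 2])
    nbrs[[e[r, 2]]] <- c(nbrs[[e[r, 2]]], e[r, 1])
  }
  walk <- function(v, left) {
    out <- v
    if (left > 0L) for (u in nbrs[[v]]) out <- c(out, walk(u, left - 1L))
    out
  }
  sort(unique(unlist(lapply(sources, walk, left = hops))))
}

oracle_core <- function(graph, class, h, tau, prune_intra = FALSE) {
  lab <- graph$labels
  vc <- which(lab == class)
  intra <- lab[graph$edges[, 1]] == class & lab[graph$edges[, 2]] == class
  keep <- if (prune_intra) graph$lengths <= tau else (intra | graph$lengths <= tau)
  oracle_reach(graph, keep, vc, h)
}

oracle_context <- function(graph, class, h, core) {
  vc <- which(graph$labels == class)
  setdiff(oracle_reach(graph, rep(TRUE, nrow(graph$edges)), vc, h + 1L), core)
}

# Rigid motion + uniform scale of an embedding's coordinates.
transform_embedding <- function(emb, angle = 0, scale = 1, shift = c(0, 0)) {
  rot <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2)
  xy <- scale * (emb$coords %*% rot)
  labeled_embedding(xy[, 1] + shift[1], xy[, 2] + shift[2], emb$labels,
                    name = emb$name)
}
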