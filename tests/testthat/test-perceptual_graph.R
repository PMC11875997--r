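test_that("build_graph reproduces forced small triangulations", {
  tri <- labeled_embedding(c(0, 1, 0), c(0, 0, 1), c("a", "a", "b"))
  g <- build_graph(tri)
  expect_equal(nrow(g$edges), 3)

  quad <- labeled_embedding(c(0, 10, 11, 1), c(0, 0, 10, 9), rep("a", 4))
  g4 <- build_graph(quad)
  expect_equal(nrow(g4$edges), 5) # two triangles sharing a diagonal
  expect_true(all(g4$lengths > 0))
})

test_that("build_graph matches an independent triangulation and planarity", {
  skip_if_not_installed("interp")
  emb <- random_layout(50, 3, seed = 7)
  g <- build_graph(emb)
  expect_lte(nrow(g$edges), 3 * 50 - 6)

  tr <- interp::triangles(interp::tri.mesh(emb$coords[, 1], emb$coords[, 2]))
  e2 <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(1, 3)])
  e2 <- unique(cbind(pmin(e2[, 1], e2[, 2]), pmax(e2[, 1], e2[, 2])))
  e2 <- e2[order(e2[, 1], e2[, 2]), ]
  expect_equal(unname(g$edges), unname(e2))
})

test_that("coincident points are resolved by seeded deterministic jitter", {
  emb <- labeled_embedding(c(0, 0, 1, 0.5, 0.5), c(0, 0, 0, 1, 1),
                           c("a", "a", "b", "b", "b"))
  g1 <- build_graph(emb, seed = 3)
  g2 <- build_graph(emb, seed = 3)
  expect_identical(g1$coords, g2$coords)
  expect_identical(g1$edges, g2$edges)
  expect_equal(sort(g1$jittered), c(2, 5))
  expect_true(all(g1$lengths > 0))
  # jitter magnitude stays below visual resolution
  expect_lt(max(abs(g1$coords - emb$coords)), 1e-8)
})

test_that("collinear layouts raise a degeneracy error", {
  line <- labeled_embedding(0:4, 2 * (0:4), rep(c("a", "b"), length.out = 5))
  expect_error(build_graph(line), "collinear")
})

test_that("intra_class_stats follows the tau = mu + k*sigma contract", {
  # one intra-class edge of length 2: sigma 0, tau = mu for any k
  g <- fake_graph(rbind(c(1, 2), c(2, 3)), c(2, 5), c("a", "a", "b"))
  st <- intra_class_stats(g, "a", k = 10)
  expect_equal(st$mu, 2)
  expect_equal(st$sigma, 0)
  expect_equal(st$tau, 2)
  expect_equal(st$n_edges, 1)

  # population sd: edges {1,1,4} -> mu 2, sigma sqrt(2), tau(k=3) = 2 + 3*sqrt(2)
  g3 <- fake_graph(rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5)), c(1, 1, 4, 9),
                   c("a", "a", "a", "a", "b"))
  st3 <- intra_class_stats(g3, "a", k = 3)
  expect_equal(st3$mu, 2)
  expect_equal(st3$sigma, sqrt(2))
  expect_equal(st3$tau, 2 + 3 * sqrt(2))
  expect_equal(intra_class_stats(g3, "a", k = 0)$tau, 2) # k=0 -> tau = mu

  expect_error(intra_class_stats(g, "zz"), "unknown class")
})

test_that("classes without intra-class edges fall back to pooled statistics", {
  # 'b' is a singleton: pooled over all intra-class edges (lengths {1, 3})
  g <- fake_graph(rbind(c(1, 2), c(2, 3), c(3, 4)), c(1, 3, 2),
                  c("a", "a", "a", "b"))
  st <- intra_class_stats(g, "b", k = 1)
  expect_true(st$pooled)
  expect_equal(st$mu, 2)
  expect_equal(st$tau, 2 + 1)
  # graph with no intra-class edges anywhere: pooled over all edges
  g2 <- fake_graph(rbind(c(1, 2), c(2, 3)), c(2, 4), c("a", "b", "c"))
  expect_equal(intra_class_stats(g2, "a", k = 0)$tau, 3)
})

test_that("core region covers forced cases", {
  # path a-a-b-b with a long a->b bridge: pruned when tau small
  g <- fake_graph(rbind(c(1, 2), c(2, 3), c(3, 4)), c(1, 10, 1),
                  c("a", "a", "b", "b"))
  st <- intra_class_stats(g, "a", k = 0) # tau = 1
  expect_equal(core_region(g, st, h = 2)$core, c(1, 2)) # isolated class: V_C only
  # tau = +Inf at h = 1: V_C plus all Delaunay neighbors
  st_inf <- st; st_inf$tau <- Inf
  expect_equal(core_region(g, st_inf, h = 1)$core, c(1, 2, 3))
  # intra-class edges are traversable regardless of length
  g2 <- fake_graph(rbind(c(1, 2), c(2, 3)), c(100, 1), c("a", "a", "b"))
  st2 <- intra_class_stats(g2, "a", k = 0) # tau = 100 here, shrink it:
  st2$tau <- 0.5
  expect_equal(core_region(g2, st2, h = 1)$core, c(1, 2))
})

test_that("prune_intra cannot change the core (every class vertex is a source)", {
  # traversing an intra-class edge only moves between BFS sources, so the
  # union over sources is identical with or without long intra-class edges
  for (seed in c(31, 32)) {
    emb <- random_layout(50, 3, seed = seed)
    g <- build_graph(emb)
    for (cl in unique(g$labels)) for (h in 1:2) {
      st <- intra_class_stats(g, cl, k = 0) # tight tau maximizes pruning
      expect_identical(core_region(g, st, h)$core,
                       core_region(g, st, h, prune_intra = TRUE)$core)
    }
  }
})

test_that("context subtracts the core and collects boundary edges", {
  g <- fake_graph(rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4)), c(1, 1, 1, 5),
                  c("a", "b", "c", "d"))
  st <- intra_class_stats(g, "a", k = 0)
  p <- core_region(g, st, h = 1)
  p <- context_region(g, p)
  expect_true(length(intersect(p$core, p$context)) == 0)
  # boundary edges join V_C to context vertices only
  for (ei in p$boundary_edges) {
    e <- g$edges[ei, ]
    expect_true(any(e %in% p$vc) && any(e %in% p$context))
  }
  # a class occupying the whole graph leaves nothing to subtract
  gall <- fake_graph(rbind(c(1, 2), c(2, 3)), c(1, 1), c("a", "a", "a"))
  pall <- context_region(gall, core_region(gall, intra_class_stats(gall, "a", 0), 1))
  expect_length(pall$context, 0)
  expect_length(pall$boundary_edges, 0)
})

test_that("combined region is the label closure of core and context labels", {
  # chain: c cluster {1,2} - b chain {3,4,5} - a chain {6,7}; b vertex 8 far
  # away and disconnected from c's 2-hop reach. c's regions touch only b, so
  # combined = all c + ALL b vertices, including the distant vertex 8.
  g <- fake_graph(rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6),
                        c(6, 7), c(7, 8)),
                  c(1, 2, 1, 1, 1, 1, 1),
                  c("c", "c", "b", "b", "b", "a", "a", "b"))
  p <- class_regions(g, "c", h = 1, k = 0)
  expect_setequal(p$core, c(1, 2))
  expect_setequal(union(p$core_labels, p$context_labels), c("b", "c"))
  expect_setequal(p$combined, which(g$labels %in% c("b", "c")))
  expect_true(8 %in% p$combined)
  # saturated closure -> every vertex of the graph
  pb <- class_regions(g, "b", h = 2, k = 3)
  expect_setequal(union(pb$core_labels, pb$context_labels), c("a", "b", "c"))
  expect_equal(pb$combined, seq_len(g$n))
})

test_that("regions match the path-enumeration oracle on random layouts", {
  for (seed in c(1, 2, 3)) {
    emb <- random_layout(40, 3, seed = seed)
    g <- build_graph(emb)
    for (cl in unique(g$labels)) for (h in 1:2) {
      st <- intra_class_stats(g, cl, k = 3)
      p <- context_region(g, core_region(g, st, h), h)
      expect_identical(p$core, oracle_core(g, cl, h, st$tau))
      expect_identical(sort(p$context), oracle_context(g, cl, h, p$core))
    }
  }
})

test_that("region invariants and monotonicity hold on seeded layouts", {
  for (seed in 4:8) {
    emb <- random_layout(60, sample(2:5, 1), seed = seed)
    g <- build_graph(emb)
    for (cl in unique(g$labels)) {
      p1 <- class_regions(g, cl, h = 1, k = 1)
      p2 <- class_regions(g, cl, h = 2, k = 1)
      pk <- class_regions(g, cl, h = 1, k = 3)
      vc <- which(g$labels == cl)
      expect_true(all(vc %in% p1$core))
      expect_true(all(p1$core %in% p1$combined))
      expect_length(intersect(p1$core, p1$context), 0)
      expect_true(all(p1$core %in% pk$core))            # k-monotone core
      expect_true(all(p1$core %in% p2$core))            # h-monotone core
      expect_true(all(union(p1$core, p1$context) %in%
                      union(p2$core, p2$context)))      # h-monotone reach
    }
  }
})

test_that("regions are invariant under rigid motion and uniform scaling", {
  emb <- random_layout(80, 4, seed = 11)
  g <- build_graph(emb)
  embt <- transform_embedding(emb, angle = 0.7, scale = 3.5, shift = c(-20, 13))
  gt <- build_graph(embt)
  for (cl in unique(g$labels)) {
    p <- class_regions(g, cl)
    pt <- class_regions(gt, cl)
    expect_identical(p$core, pt$core)
    expect_identical(p$context, pt$context)
    expect_identical(p$combined, pt$combined)
  }
})

test_that("region_table labels each vertex with exactly one region", {
  emb <- random_layout(50, 3, seed = 13)
  g <- build_graph(emb)
  p <- class_regions(g, "c1")
  rt <- region_table(p, g)
  expect_equal(nrow(rt), g$n)
  expect_setequal(rt$vertex[rt$region == "core"], p$core)
  expect_setequal(rt$vertex[rt$region == "context"], p$context)
  expect_setequal(rt$vertex[rt$region %in% c("core", "context", "combined")],
                  union(p$combined, union(p$core, p$context)))
})
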