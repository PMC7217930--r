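test_that("modularity matches closed forms on the two-triangle graph", {
  tri2 <- two_triangles()
  natural <- c(a = 0, b = 0, c = 0, d = 1, e = 1, f = 1)
  expect_equal(modularity_q(tri2, natural), 0.5)
  expect_equal(modularity_q(tri2, setNames(rep(0, 6), letters[1:6])), 0)
  expect_equal(modularity_q(tri2, setNames(0:5, letters[1:6])), -1 / 6)
  expect_error(modularity_q(tri2, natural[-1]), "missing from membership")
})

test_that("modularity agrees with the igraph reference on random graphs", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      edges <- random_edges(sample(4:9, 1))
      g <- igraph::graph_from_data_frame(edges, directed = FALSE)
      mb <- sample(1:3, igraph::vcount(g), replace = TRUE)
      names(mb) <- igraph::V(g)$name
      expect_equal(
        modularity_q(edges, mb),
        igraph::modularity(g, mb[igraph::V(g)$name] + 1),
        tolerance = 1e-12
      )
    }
  })
})

test_that("brute force enumerates partitions and finds the optimum", {
  # 2-node single edge: optimum is the single community at Q = 0
  bf <- brute_force_partition(data.frame(from = "a", to = "b"))
  expect_equal(attr(bf, "modularity"), 0)
  expect_equal(length(unique(bf$community)), 1)

  # two disjoint triangles: planted partition, Q = 0.5
  bf2 <- brute_force_partition(two_triangles())
  expect_equal(attr(bf2, "modularity"), 0.5)
  expect_equal(length(unique(bf2$community)), 2)

  # path of 3 nodes: the 5 partitions are enumerated; best merges all
  # or pairs -- verify against direct enumeration
  p3 <- data.frame(from = c("a", "b"), to = c("b", "c"))
  bf3 <- brute_force_partition(p3)
  qs <- c(
    modularity_q(p3, c(a = 1, b = 1, c = 1)),
    modularity_q(p3, c(a = 1, b = 1, c = 2)),
    modularity_q(p3, c(a = 1, b = 2, c = 1)),
    modularity_q(p3, c(a = 1, b = 2, c = 2)),
    modularity_q(p3, c(a = 1, b = 2, c = 3))
  )
  expect_equal(attr(bf3, "modularity"), max(qs))

  big <- data.frame(from = paste0("v", 1:11), to = paste0("v", c(2:11, 1)))
  expect_error(brute_force_partition(big), "<= 10 nodes")
})

test_that("louvain recovers planted cliques exactly and is deterministic", {
  tri2 <- two_triangles()
  part <- louvain(tri2, seed = 5)
  expect_equal(attr(part, "modularity"), 0.5)
  expect_equal(length(unique(part$community)), 2)
  # planted communities: the two triangles
  comm <- setNames(part$community, part$node)
  expect_equal(length(unique(comm[c("a", "b", "c")])), 1)
  expect_equal(length(unique(comm[c("d", "e", "f")])), 1)

  # K4 collapses to a single community
  k4 <- as.data.frame(t(utils::combn(paste0("n", 1:4), 2)))
  names(k4) <- c("from", "to")
  pk4 <- louvain(k4, seed = 2)
  expect_equal(length(unique(pk4$community)), 1)
  bfk4 <- brute_force_partition(k4)
  expect_equal(attr(pk4, "modularity"), attr(bfk4, "modularity"))

  # determinism under a fixed seed
  p1 <- louvain(tri2, seed = 99)
  p2 <- louvain(tri2, seed = 99)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  expect_identical(attr(p1, "modularity"), attr(p2, "modularity"))

  expect_error(louvain(data.frame(from = character(0),
                                  to = character(0))), "no edges")
})

test_that("community ids are dense integers starting at zero", {
  part <- louvain(two_triangles(), seed = 1)
  expect_setequal(unique(part$community), 0:1)
  stored_q <- attr(part, "modularity")
  expect_equal(stored_q,
               modularity_q(two_triangles(),
                            setNames(part$community, part$node)),
               tolerance = 1e-12)
})

test_that("modularity never decreases across louvain levels", {
  withr::with_seed(23, {
    for (rep in 1:10) {
      edges <- random_edges(sample(6:12, 1), p_edge = 0.35)
      part <- louvain(edges, seed = rep)
      trace <- attr(part, "q_trace")
      if (length(trace) > 1) {
        expect_true(all(diff(trace) >= -1e-9))
      }
      expect_equal(trace[length(trace)], attr(part, "modularity"),
                   tolerance = 1e-9)
    }
  })
})

test_that("louvain tracks the brute-force optimum on small random graphs", {
  withr::with_seed(31, {
    ratio_ok <- TRUE
    for (rep in 1:30) {
      edges <- random_edges(sample(4:8, 1), p_edge = 0.45)
      q_opt <- attr(brute_force_partition(edges), "modularity")
      q_lv <- attr(louvain(edges, seed = rep), "modularity")
      expect_lte(q_lv, q_opt + 1e-12)  # oracle really is an upper bound
      if (q_lv < 0.95 * q_opt - 1e-12) ratio_ok <- FALSE
    }
    expect_true(ratio_ok)
  })
})

test_that("louvain matches the igraph implementation's modularity on cliques", {
  # disjoint-clique graphs: both must find the planted clique partition
  cl <- dplyr::bind_rows(lapply(0:2, function(b) {
    nodes <- paste0("c", b, "_", 1:4)
    as.data.frame(setNames(as.data.frame(t(utils::combn(nodes, 2))),
                           c("from", "to")))
  }))
  ours <- louvain(cl, seed = 3)
  g <- igraph::graph_from_data_frame(cl, directed = FALSE)
  ref <- igraph::cluster_louvain(g)
  expect_equal(attr(ours, "modularity"),
               igraph::modularity(g, igraph::membership(ref)),
               tolerance = 1e-12)
  expect_equal(length(unique(ours$community)), 3)
})
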