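test_that("chain graph edges follow the COM cutoff", {
  top <- condstat:::.homopolymer_topology(1L, 2L)
  f <- md_frame(rbind(c(1, 1, 1), c(1, 1, 4)), c(20, 20, 20))
  expect_equal(nrow(chain_graph(top, f, 4)$edges), 1L)
  f2 <- md_frame(rbind(c(1, 1, 1), c(1, 1, 6)), c(20, 20, 20))
  expect_equal(nrow(chain_graph(top, f2, 4)$edges), 0L)
})

test_that("largest_cluster equals the independent components oracle", {
  skip_if_not_installed("igraph")
  set.seed(17)
  for (k in 1:200) {
    n <- sample(2:100, 1)
    ids <- sort(sample(0:500, n))
    p <- runif(1, 0.005, 0.08)
    m <- matrix(runif(n * n) < p, n, n)
    hit <- which(upper.tri(m) & m, arr.ind = TRUE)
    graph <- structure(list(nodes = ids,
                            edges = cbind(i = ids[hit[, 1]],
                                          j = ids[hit[, 2]]),
                            cutoff = NA),
                       class = "chain_graph")
    expect_identical(largest_cluster(graph), igraph_largest(graph))
  }
})

test_that("largest_cluster handles simple cases and ties", {
  g <- structure(list(nodes = 0:2, edges = cbind(i = 0L, j = 1L)),
                 class = "chain_graph")
  expect_equal(largest_cluster(g), c(0L, 1L))
  full <- structure(list(nodes = 0:4,
                         edges = t(utils::combn(0:4, 2))),
                    class = "chain_graph")
  expect_equal(largest_cluster(full), 0:4)
  # two singleton ties -> component with the smallest chain id
  tie <- structure(list(nodes = c(3L, 7L),
                        edges = matrix(integer(0), 0, 2)),
                   class = "chain_graph")
  expect_equal(largest_cluster(tie), 3L)
  empty <- structure(list(nodes = integer(0),
                          edges = matrix(integer(0), 0, 2)),
                     class = "chain_graph")
  expect_error(largest_cluster(empty), "empty")
})

test_that("recentering puts the cluster COM at the midpoint and is idempotent", {
  tr <- condensate_fixture("UNIFORM", seed = 3, n_frames = 1, n_chains = 24,
                           recenter = FALSE)
  top <- tr$topology
  f <- tr$frames[[1]]
  r1 <- recenter_frame(top, f)
  cl <- largest_cluster(chain_graph(top, r1))
  expect_equal(condstat:::.cluster_com_z(top, r1, cl), f$box[3] / 2,
               tolerance = 1e-9)
  r2 <- recenter_frame(top, r1)
  expect_equal(r2$coords, r1$coords, tolerance = 1e-9)
  # x and y are untouched
  expect_identical(r1$coords[, 1:2], f$coords[, 1:2])
})

test_that("a slab straddling the boundary becomes contiguous", {
  tr <- condensate_fixture("UNIFORM", seed = 9, n_frames = 1, n_chains = 24,
                           recenter = FALSE)
  top <- tr$topology
  f <- tr$frames[[1]]
  Lz <- f$box[3]
  shifted <- f
  shifted$coords[, 3] <- (f$coords[, 3] + Lz / 2) %% Lz   # slab now wraps
  r <- recenter_frame(top, shifted)
  pep <- top$beads$block_label %in% c("V_BLOCK", "X_BLOCK")
  z <- r$coords[pep, 3] - Lz / 2
  # contiguous around the centre: the slab spans its width, not the box
  expect_lt(diff(range(z)), 11)
  expect_lt(abs(mean(z)), 2)
  cl <- largest_cluster(chain_graph(top, r))
  expect_equal(condstat:::.cluster_com_z(top, r, cl), Lz / 2,
               tolerance = 1e-9)
})
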