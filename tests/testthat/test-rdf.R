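test_that("a single pair lands in the bin containing its separation", {
  top <- condstat:::.homopolymer_topology(1L, 2L)
  tr <- md_trajectory(top, list(md_frame(rbind(c(1, 1, 1), c(1, 1, 2)),
                                         c(10, 10, 10))))
  r <- inter_rdf(tr, 0L, 1L, n_bins = 100)
  hit <- which(attr(r, "counts") > 0)
  expect_length(hit, 1L)
  expect_lt(abs(r$r[hit] - 1.0), diff(r$r)[1])
})

test_that("intra-chain exclusion zeroes an all-intra fixture", {
  top <- condstat:::.homopolymer_topology(10L, 1L)
  set.seed(2)
  tr <- md_trajectory(top, list(md_frame(matrix(runif(30, 0, 2), 10, 3),
                                         c(5, 5, 5))))
  ids <- 0:9
  r <- inter_rdf(tr, ids, ids, exclude_intrachain = TRUE)
  expect_equal(sum(attr(r, "counts")), 0)
  r2 <- inter_rdf(tr, ids, ids, exclude_intrachain = FALSE)
  expect_gt(sum(attr(r2, "counts")), 0)
})

test_that("RDF matches brute-force counts and ideal-gas normalisation", {
  tr <- random_gas(400, box = c(5, 5, 5), seed = 21)
  ids <- 0:399
  nb <- 50L
  r <- inter_rdf(tr, ids, ids, n_bins = nb)
  # brute force ordered pair histogram
  f <- tr$frames[[1]]
  edges <- seq(1e-5, 2, length.out = nb + 1)
  d <- condstat:::min_image_dist_matrix(f$coords, f$coords, f$box)
  dv <- d[upper.tri(d)]
  dv <- dv[dv >= edges[1] & dv <= 2]
  counts <- tabulate(findInterval(dv, edges, rightmost.closed = TRUE), nb)
  expect_equal(attr(r, "counts"), 2 * counts)   # ordered pairs
  expect_equal(attr(r, "n_pairs"), 400 * 399)
  # shell-normalised plateau: mean g over r in [0.5, 2] is 1
  sel <- r$r >= 0.5
  expect_equal(mean(r$g[sel]), 1, tolerance = 0.02)
  # integral over the box recovers the candidate pair count (+-2%)
  shell <- 4 / 3 * pi * diff(edges^3)
  expect_equal(sum(r$g * shell / prod(f$box)) * attr(r, "n_pairs"),
               sum(attr(r, "counts")), tolerance = 0.02)
})

test_that("ideal-gas g(r) stays within per-bin counting error", {
  tr <- random_gas(1500, box = c(5, 5, 5), seed = 8)
  set.seed(9)
  a <- sample(0:1499, 700)
  b <- setdiff(0:1499, a)[1:700]
  r <- inter_rdf(tr, a, b, n_bins = 50)
  sel <- r$r > 0.3
  counts <- attr(r, "counts")[sel]
  edges <- seq(1e-5, 2, length.out = 51)
  expected <- attr(r, "n_pairs") *
    (4 / 3 * pi * diff(edges^3))[sel] / prod(tr$frames[[1]]$box)
  z <- (counts - expected) / sqrt(expected)
  expect_gte(mean(abs(z) <= 3), 0.95)
  expect_true(all(abs(z) <= 5))
  expect_equal(mean(r$g[sel]), 1, tolerance = 0.02)
})

test_that("block RDF suite reproduces the microphase signature", {
  trL <- condensate_fixture("LAMELLAR", seed = 42, n_frames = 4)
  sL <- block_rdf_suite(trL, n_bins = 100)
  expect_gt(rdf_first_shell(sL$VV), rdf_first_shell(sL$VX))
  expect_gt(rdf_first_shell(sL$XX), rdf_first_shell(sL$VX))
  trG <- condensate_fixture("GYROID", seed = 42, n_frames = 2)
  sG <- block_rdf_suite(trG, n_bins = 100)
  expect_true(all(is.finite(c(sG$VV$g, sG$XX$g, sG$VX$g))))
  expect_gt(rdf_first_shell(sG$VX), 0)
})

test_that("uniform mixing makes the three block RDFs agree", {
  trU <- condensate_fixture("UNIFORM", seed = 42, n_frames = 16)
  sU <- block_rdf_suite(trU, n_bins = 100)
  wm <- vapply(sU, function(r) mean(r$g[r$r >= 0.4 & r$r <= 0.9]), numeric(1))
  expect_lt((max(wm) - min(wm)) / mean(wm), 0.12)
})

test_that("guest-environment RDF sees glycine as nearest neighbour", {
  top1 <- build_diblock_topology("A", 1, 1)
  xyz <- cbind(0.38 * (1:10), 1, 1)           # straight-line chain
  tr <- md_trajectory(top1, list(md_frame(xyz, c(20, 20, 20))))
  g <- guest_environment_rdf(tr, n_bins = 100)
  first_nonzero <- vapply(g, function(r) r$r[which(r$g > 0)[1]], numeric(1))
  expect_lt(abs(first_nonzero[["G"]] - 0.38), 0.02)
  expect_true(all(first_nonzero[["G"]] <= first_nonzero))
  # guest-free system flags explicitly
  hp <- condstat:::.homopolymer_topology(4L, 1L)
  trh <- md_trajectory(hp, list(md_frame(matrix(runif(12), 4, 3),
                                         c(5, 5, 5))))
  out <- guest_environment_rdf(trh)
  expect_length(out, 0L)
  expect_true(attr(out, "no_guest"))
})
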