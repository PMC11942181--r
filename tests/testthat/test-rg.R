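test_that("radius of gyration reproduces hand-computed moments", {
  top <- condstat:::.homopolymer_topology(2L, 1L)
  db <- md_trajectory(top, list(md_frame(rbind(c(1, 1, 1), c(1, 1, 1.38)),
                                         c(10, 10, 10))))
  expect_equal(radius_of_gyration(db)$rg, 0.19)
  sq <- condstat:::.homopolymer_topology(4L, 1L)
  a <- 1.2
  f <- md_frame(rbind(c(0, 0, 0), c(a, 0, 0), c(a, a, 0), c(0, a, 0)) + 3,
                c(10, 10, 10))
  expect_equal(radius_of_gyration(md_trajectory(sq, list(f)))$rg, a / sqrt(2))
})

test_that("Rg is invariant under rigid translation and unwraps across PBC", {
  set.seed(7)
  top <- condstat:::.homopolymer_topology(12L, 1L)
  xyz <- condstat:::unwrap_sequential(
    apply(matrix(rnorm(36, sd = 0.2), 12, 3), 2, cumsum) + 5, c(10, 10, 10))
  tr0 <- md_trajectory(top, list(md_frame(xyz %% 10, c(10, 10, 10))))
  rg0 <- radius_of_gyration(tr0)$rg
  shifted <- (xyz + matrix(c(3.7, -2.2, 4.9), 12, 3, byrow = TRUE)) %% 10
  tr1 <- md_trajectory(top, list(md_frame(shifted, c(10, 10, 10))))
  expect_equal(radius_of_gyration(tr1)$rg, rg0, tolerance = 1e-9)
})

test_that("block Rg decomposes consistently with whole-chain Rg", {
  tr <- condensate_fixture("UNIFORM", seed = 3, n_frames = 1, n_chains = 8,
                           recenter = FALSE)
  whole <- radius_of_gyration(tr, per = "chain")
  v <- radius_of_gyration(tr, per = "V_block")
  x <- radius_of_gyration(tr, per = "X_block")
  b <- tr$topology$beads
  f <- tr$frames[[1]]
  for (c in peptide_chain_ids(tr$topology)) {
    ix <- which(b$chain_id == c)
    xyz <- condstat:::unwrap_sequential(f$coords[ix, ], f$box)
    m <- b$mass[ix]
    half <- b$block_label[ix] == "V_BLOCK"
    com <- colSums(xyz * m) / sum(m)
    com_v <- colSums(xyz[half, ] * m[half]) / sum(m[half])
    com_x <- colSums(xyz[!half, ] * m[!half]) / sum(m[!half])
    wv <- sum(m[half]) / sum(m)
    # parallel-axis: Rg^2 = wv Rgv^2 + wx Rgx^2 + wv|dv|^2 + wx|dx|^2
    lhs <- whole$rg[whole$chain_id == c]^2
    rhs <- wv * v$rg[v$chain_id == c]^2 + (1 - wv) * x$rg[x$chain_id == c]^2 +
      wv * sum((com_v - com)^2) + (1 - wv) * sum((com_x - com)^2)
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("ideal-chain closed form matches hand evaluation and scaling", {
  expect_equal(ideal_chain_rg(50, 0.5, 0.38, 0.40),
               sqrt(2 * 0.40 * 0.38 / 6) * sqrt(50))
  expect_equal(ideal_chain_rg(50), 1.59, tolerance = 0.002)
  expect_equal(ideal_chain_rg(1, 0.3), sqrt(2 * 0.4 * 0.38 / (1.6 * 2.6)))
  expect_equal(ideal_chain_rg(200) / ideal_chain_rg(50), 2)
  expect_error(ideal_chain_rg(10, nu = 1.2), "nu")
  expect_error(ideal_chain_rg(0), "N")
  # monotone in N
  expect_true(all(diff(ideal_chain_rg(1:100, 0.33)) > 0))
})

test_that("broken chains that cannot be unwrapped raise a geometry error", {
  top <- condstat:::.homopolymer_topology(2L, 1L)
  tr <- md_trajectory(top, list(md_frame(rbind(c(1, 1, 1), c(1, 1, 5.9)),
                                         c(10, 10, 10))))
  expect_error(radius_of_gyration(tr), "cannot be unwrapped")
})
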