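test_that("normalisation maps extremes by declared orientation", {
  hi <- scale_table(c(A = 1, G = 3), "HIGHER_IS_HYDROPHOBIC", "hi")
  n1 <- normalize_scale(hi)
  expect_equal(unname(n1$values[c("A", "G")]), c(0, 1))
  lo <- scale_table(c(A = 1, G = 3), "LOWER_IS_HYDROPHOBIC", "lo")
  n2 <- normalize_scale(lo)
  expect_equal(unname(n2$values[c("A", "G")]), c(1, 0))
  # transfer free energies: the lowest dG residue is the most hydrophobic
  ww <- read_scale_csv(system.file("extdata",
                                   "scale_wimley_white_interface.csv",
                                   package = "condstat"))
  nw <- normalize_scale(ww)
  expect_equal(unname(nw$values[names(which.min(ww$values))]), 1)
  expect_equal(unname(nw$values[names(which.max(ww$values))]), 0)
})

test_that("normalisation is idempotent and rejects undefined cases", {
  sc <- scale_table(c(A = -2, G = 0, V = 5), "HIGHER_IS_HYDROPHOBIC", "x")
  once <- normalize_scale(sc)
  twice <- normalize_scale(once)
  expect_equal(twice$values, once$values)
  expect_equal(twice$orientation, once$orientation)
  none <- scale_table(c(A = 1, G = 2), "NONE", "tt")
  expect_error(normalize_scale(none), "orientation")
  flat <- scale_table(c(A = 1, G = 1), "HIGHER_IS_HYDROPHOBIC", "flat")
  expect_error(normalize_scale(flat), "degenerate")
})

test_that("pearson correlation matches hand evaluation and properties", {
  expect_equal(pearson_cor(1:5, 2 * (1:5) + 1), 1)
  expect_equal(pearson_cor(1:5, -(1:5)), -1)
  expect_equal(pearson_cor(c(1, 2, 3), c(1, 3, 2)), 0.5)
  set.seed(3)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(pearson_cor(3 * x + 7, y), pearson_cor(x, y))
  expect_equal(pearson_cor(-x, y), -pearson_cor(x, y))
  expect_error(pearson_cor(1:2, 1:2), "at least 3")
  expect_error(pearson_cor(rep(1, 5), 1:5), "zero variance")
  a <- scale_table(c(A = 1, G = 2, V = 3, L = 9), label = "a")
  b <- scale_table(c(A = 1, G = 3, V = 2), label = "b")
  expect_message(r <- pearson_cor(a, b), "matched 3")
  expect_equal(r, 0.5)
})

test_that("correlating with Tt recovers a planted linear model", {
  set.seed(5)
  vals <- stats::setNames(runif(20, 0, 1), condstat:::.AA1)
  sc <- scale_table(vals, "HIGHER_IS_HYDROPHOBIC", "planted")
  a_true <- 40
  tt_vals <- 90 - a_true * vals + rnorm(20, 0, 2)
  tt <- scale_table(tt_vals, "NONE", "Tt")
  rep1 <- correlate_with_tt(tt, list(sc), normalize = FALSE)
  expect_lt(rep1$rho, -0.9)
  expect_lt(correlate_with_tt(tt, list(sc), normalize = TRUE)$rho, -0.9)
  fit <- stats::lm(tt_vals ~ vals)
  ci <- stats::confint(fit)["vals", ]
  expect_gt(rep1$slope, ci[1]); expect_lt(rep1$slope, ci[2])
  expect_true(ci[1] < -a_true && -a_true < ci[2])
  # affine-transformed scale has |rho| = 1 against itself
  self <- correlate_with_tt(tt, list(scale_table(
    stats::setNames(2 * tt_vals + 5, names(tt_vals)),
    "HIGHER_IS_HYDROPHOBIC", "affine")), normalize = FALSE)
  expect_equal(abs(self$rho), 1)
  # too little key overlap errors
  tiny <- scale_table(c(A = 1, G = 2), "HIGHER_IS_HYDROPHOBIC", "tiny")
  expect_error(correlate_with_tt(tt, list(tiny)), "insufficient overlap")
})
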