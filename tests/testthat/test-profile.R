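test_that("density profile conserves mass and centres z on the midpoint", {
  tr <- condensate_fixture("UNIFORM", seed = 2, n_frames = 2, phi_p = 0.5)
  prof <- density_profile(tr, bin_width = 0.25)
  df <- as.data.frame(prof)
  box <- attr(prof, "box")
  binvol <- box[1] * box[2] * attr(prof, "bin_width")
  b <- tr$topology$beads
  for (sp in c("protein", "water")) {
    sel <- b$block_label %in% condstat:::.SPECIES_SELECTORS[[sp]]
    total <- sum(df$density[df$species == sp]) * binvol /
      condstat:::.AMU_PER_NM3_TO_G_CM3
    expect_equal(total, sum(b$mass[sel]), tolerance = 5e-3)
  }
  expect_equal(max(abs(df$z)), box[3] / 2 - attr(prof, "bin_width") / 2,
               tolerance = 1e-9)
})

test_that("uniform slab recovers the planted protein mass fraction", {
  tr <- condensate_fixture("UNIFORM", seed = 14, n_frames = 20, phi_p = 0.5)
  prof <- density_profile(tr, bin_width = 0.25)
  df <- as.data.frame(prof)
  core <- abs(df$z) < 5                      # the full slab (w/2 = 5)
  p <- sum(df$density[core & df$species == "protein"])
  tot <- sum(df$density[core & df$species %in% c("protein", "water", "ions")])
  expect_equal(p / tot, 0.5, tolerance = 0.02)
  # pure-solvent bins carry no protein
  far <- abs(df$z) > 8
  expect_equal(sum(df$density[far & df$species == "protein"]), 0)
})

test_that("coarser bins sum to the finer profile (refinement consistency)", {
  tr <- condensate_fixture("UNIFORM", seed = 4, n_frames = 1, phi_p = 1)
  fine <- as.data.frame(density_profile(tr, bin_width = 0.25))
  coarse <- as.data.frame(density_profile(tr, bin_width = 0.5))
  fp <- fine$density[fine$species == "protein"]
  cp <- coarse$density[coarse$species == "protein"]
  paired <- (fp[seq(1, length(fp), 2)] + fp[seq(2, length(fp), 2)]) / 2
  expect_equal(paired, cp, tolerance = 1e-9)
})

test_that("profiles are covariant under a z-translation", {
  tr <- condensate_fixture("UNIFORM", seed = 5, n_frames = 1, phi_p = 1,
                           recenter = FALSE)
  Lz <- tr$frames[[1]]$box[3]
  nbin <- round(Lz / 0.25)
  shift_bins <- 8L
  tr2 <- tr
  tr2$frames[[1]]$coords[, 3] <-
    (tr$frames[[1]]$coords[, 3] + shift_bins * 0.25) %% Lz
  p1 <- as.data.frame(density_profile(tr, 0.25))
  p2 <- as.data.frame(density_profile(tr2, 0.25))
  d1 <- p1$density[p1$species == "protein"]
  d2 <- p2$density[p2$species == "protein"]
  expect_equal(d2, d1[((seq_len(nbin) - 1L - shift_bins) %% nbin) + 1L],
               tolerance = 1e-9)
})

test_that("central enrichment separates lamellar blocks and stays flat for uniform", {
  trL <- condensate_fixture("LAMELLAR", seed = 12, n_frames = 8)
  eL <- central_block_enrichment(trL, central_width = 10 / 3)
  expect_gt(eL[["V_block"]], 1)
  expect_lt(eL[["X_block"]], 1)
  trU <- condensate_fixture("UNIFORM", seed = 13, n_frames = 32)
  eU <- central_block_enrichment(trU, central_width = 10 / 3)
  expect_equal(unname(eU), c(1, 1), tolerance = 0.08)
  expect_error(central_block_enrichment(trU, central_width = 99), "Lz")
})
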