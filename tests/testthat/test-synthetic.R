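test_that("generators are pure functions of their specs", {
  spec <- morphology_spec("GYROID", box = c(9, 9, 18), slab_width = 8,
                          phi_p = 1, n_chains = 12, n_repeats = 2, seed = 4)
  a <- generate_condensate(spec)
  b <- generate_condensate(spec)
  expect_identical(a$frames[[1]]$coords, b$frames[[1]]$coords)
  e1 <- generate_ideal_chain_ensemble(20, n_chains = 50, seed = 9)
  e2 <- generate_ideal_chain_ensemble(20, n_chains = 50, seed = 9)
  expect_identical(e1$frames[[1]]$coords, e2$frames[[1]]$coords)
  p1 <- generate_pressure_series(5, 20, n_rows = 100, noise_sd = 2, seed = 3)
  p2 <- generate_pressure_series(5, 20, n_rows = 100, noise_sd = 2, seed = 3)
  expect_identical(p1$pzz, p2$pzz)
})

test_that("condensate slab confines protein and walks keep bond length", {
  tr <- condensate_fixture("UNIFORM", seed = 2, n_frames = 2,
                           recenter = FALSE)
  b <- tr$topology$beads
  pep <- b$block_label %in% c("V_BLOCK", "X_BLOCK")
  for (f in tr$frames) {
    z <- f$coords[pep, 3]
    expect_true(all(abs(z - 12) <= 5 + 1e-9))        # w/2 with Lz/2 = 12
    ix <- which(b$chain_id == 0)
    d <- condstat:::min_image_delta(diff(f$coords[ix, ]), f$box)
    expect_equal(sqrt(rowSums(d * d)), rep(0.38, length(ix) - 1),
                 tolerance = 1e-9)
  }
})

test_that("LAMELLAR places X farther from the slab centre than V", {
  tr <- condensate_fixture("LAMELLAR", seed = 6, n_frames = 2,
                           recenter = FALSE)
  b <- tr$topology$beads
  f <- tr$frames[[1]]
  zv <- abs(f$coords[b$block_label == "V_BLOCK", 3] - 12)
  zx <- abs(f$coords[b$block_label == "X_BLOCK", 3] - 12)
  expect_gt(mean(zx), mean(zv))
  expect_lt(mean(abs(f$coords[b$block_label == "V_BLOCK", 3] - 12) > 2.51),
            0.01)                                     # V inside |z| < w/4
})

test_that("infeasible packing raises a packing error", {
  spec <- morphology_spec("UNIFORM", box = c(3, 3, 6), slab_width = 1,
                          phi_p = 1, n_chains = 200, n_repeats = 5, seed = 1)
  expect_error(generate_condensate(spec), "packing error")
})

test_that("planted pressure series inverts the surface-tension formula", {
  g0 <- generate_pressure_series(10, Lz = 20, n_droplets = 1, n_rows = 5,
                                 noise_sd = 0, seed = 1)
  expect_equal(g0$pzz - (g0$pxx + g0$pyy) / 2, rep(1, 5))
  iso <- generate_pressure_series(0, Lz = 20, n_droplets = 1, n_rows = 5,
                                  noise_sd = 0, seed = 1)
  expect_equal(iso$pxx, iso$pzz)
  noisy <- generate_pressure_series(10, Lz = 20, n_droplets = 2,
                                    n_rows = 10000, noise_sd = 4, seed = 2)
  st <- surface_tension(noisy, n_windows = 5)
  se <- st$sd / sqrt(st$n_windows)
  expect_lt(abs(st$tau_bar_nm - 10), 3 * se)
})

test_that("ideal-chain ensemble matches the closed form and edge cases", {
  tr <- generate_ideal_chain_ensemble(50, n_chains = 2000, seed = 3)
  rg <- radius_of_gyration(tr)
  expect_equal(sqrt(mean(rg$rg^2)), ideal_chain_rg(50), tolerance = 0.05)
  db <- generate_ideal_chain_ensemble(2, n_chains = 3, seed = 1)
  expect_equal(radius_of_gyration(db)$rg, rep(0.19, 3), tolerance = 1e-9)
})

test_that("hydrogen-bond fixtures plant geometry with stated margins", {
  tr <- generate_hb_fixture(hb_fixture_spec(4, 2, 3, 5, seed = 7))
  hb <- detect_hbonds(tr)
  # planted bonds hold the criteria with >= 0.02 nm / >= 10 degree margins
  expect_true(all(hb$distance <= 0.33 - 0.02))
  expect_true(all(hb$angle >= 145))
  expect_equal(sum(hb$class == "PW"), 4L)
  expect_equal(sum(hb$class == "PP"), 2L)
})
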