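# A minimal two-partner frame: one glycine-like donor residue and one water,
# with the water oxygen placed at a given distance/angle from the N-H donor.
planted_pair <- function(d_da, angle_deg) {
  gly <- condstat:::.residue_beads("GLY", "ATOMISTIC_LITE")
  meta <- data.frame(chain_id = 0L, residue_index = 0L, residue_name = "GLY",
                     block_label = "V_BLOCK", is_guest = FALSE)
  top <- add_solvent(condstat:::.assemble(list(gly), meta, "ATOMISTIC_LITE"),
                     n_water = 1L)
  # residue: N(5,5,5), H(5,4.9,5), CA/C/O along +x (see fixture template)
  res <- sweep(condstat:::.HB_RES_A, 2, c(5, 5, 5), "+")
  # place the acceptor so the D-A distance is d_da and the D-H-A angle
  # (at H, against H->N = +y) is exactly angle_deg
  a_rad <- angle_deg * pi / 180
  u <- c(sin(a_rad), cos(a_rad), 0)
  s <- 0.1 * cos(a_rad) + sqrt(0.01 * cos(a_rad)^2 - 0.01 + d_da^2)
  aw <- c(5, 4.9, 5) + s * u
  wat <- rbind(aw, aw + c(0.026, -0.09, 0), aw + c(-0.026, -0.09, 0))
  md_trajectory(top, list(md_frame(rbind(res, wat), c(10, 10, 10))))
}

test_that("the 0.330 nm / 135 degree criteria are inclusive", {
  expect_equal(nrow(detect_hbonds(planted_pair(0.28, 180))), 1L)
  expect_equal(nrow(detect_hbonds(planted_pair(0.28, 120))), 0L)
  at_dist <- detect_hbonds(planted_pair(0.330, 180))
  expect_equal(nrow(at_dist), 1L)                       # boundary inclusive
  at_angle <- detect_hbonds(planted_pair(0.28, 135.0))
  expect_equal(nrow(at_angle), 1L)
  expect_equal(nrow(detect_hbonds(planted_pair(0.34, 180))), 0L)
  expect_equal(nrow(detect_hbonds(planted_pair(0.28, 134.0))), 0L)
})

test_that("coarse resolutions are rejected for hydrogen-bond analysis", {
  tr <- random_diblock(n_chains = 2, n_repeats = 1, seed = 1)
  expect_error(detect_hbonds(tr), "atomistic-lite")
})

test_that("fixture counts are recovered and match exhaustive enumeration", {
  tr <- generate_hb_fixture(hb_fixture_spec(10, 3, 10, 50, seed = 4))
  hb <- detect_hbonds(tr)
  expect_equal(sum(hb$class == "PW"), 10L)
  expect_equal(sum(hb$class == "PP"), 3L)
  expect_equal(sum(hb$class == "WW"), 0L)
  # exhaustive O(D*A*H) oracle
  top <- tr$topology; f <- tr$frames[[1]]; b <- top$beads
  n_oracle <- 0L
  for (d in which(b$is_donor)) for (a in which(b$is_acceptor)) {
    if (d == a) next
    if (minimum_image_distance(f, d - 1L, a - 1L) > 0.33) next
    for (h in which(b$is_hydrogen & b$donor_id == d - 1L)) {
      u <- condstat:::min_image_delta(
        f$coords[d, , drop = FALSE] - f$coords[h, , drop = FALSE], f$box)
      v <- condstat:::min_image_delta(
        f$coords[a, , drop = FALSE] - f$coords[h, , drop = FALSE], f$box)
      ang <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
      if (ang >= 135) n_oracle <- n_oracle + 1L
    }
  }
  expect_equal(nrow(hb), n_oracle)
  # class partition covers every bond
  expect_equal(sum(table(hb$class)), nrow(hb))
})

test_that("all-far fixtures give zero bonds and zero nearby waters", {
  tr <- generate_hb_fixture(hb_fixture_spec(0, 0, 0, 20, seed = 2))
  expect_equal(nrow(detect_hbonds(tr)), 0L)
  expect_equal(nearby_waters(tr$topology, tr$frames[[1]], integer(0)), 0L)
})

test_that("nearby waters deduplicate and respect the 0.40 nm cutoff", {
  gly <- condstat:::.residue_beads("GLY", "ATOMISTIC_LITE")
  meta <- data.frame(chain_id = 0L, residue_index = 0L, residue_name = "GLY",
                     block_label = "V_BLOCK", is_guest = FALSE)
  top <- add_solvent(condstat:::.assemble(list(gly), meta, "ATOMISTIC_LITE"),
                     n_water = 1L)
  res <- sweep(condstat:::.HB_RES_A, 2, c(5, 5, 5), "+")
  place <- function(w) md_trajectory(top, list(md_frame(
    rbind(res, rbind(w, w + c(0.05, 0.08, 0), w + c(-0.05, 0.08, 0))),
    c(10, 10, 10))))
  near <- place(c(5, 5.35, 5))        # 0.35 nm from N
  expect_equal(nearby_waters(near$topology, near$frames[[1]], "all"), 1L)
  far <- place(c(5, 5.45, 5))         # 0.45 nm from every heavy atom
  expect_equal(nearby_waters(far$topology, far$frames[[1]], "all"), 0L)
  # one water near two heavy atoms still counts once
  mid <- place(c(5.21, 5.2, 5))       # near both N and CA
  expect_equal(nearby_waters(mid$topology, mid$frames[[1]], "all"), 1L)
})

test_that("water HB density recovers the planted ratio and error paths", {
  tr <- generate_hb_fixture(hb_fixture_spec(10, 3, 10, 5, seed = 6))
  w <- water_hb_density(tr, "all")
  expect_equal(w$mean, 10 / 20)
  expect_equal(w$series$pw, 10L)
  expect_equal(w$series$nearby, 20L)
  # a selection with no nearby water anywhere is undefined
  pp_only <- generate_hb_fixture(hb_fixture_spec(0, 2, 0, 0, seed = 1))
  expect_error(water_hb_density(pp_only, "all"), "undefined")
})

test_that("per-residue crediting follows the declared convention", {
  tr <- generate_hb_fixture(hb_fixture_spec(10, 1, 0, 0, seed = 3))
  st <- hbonds_per_residue(tr)
  nres <- nrow(residue_table(tr$topology)[
    residue_table(tr$topology)$block_label == "V_BLOCK", ])
  expect_equal(st$pw_per_residue, 10 / nres)
  expect_equal(st$pp_per_residue, 2 / nres)     # 1 PP bond credits both sides
  expect_equal(sum(st$per_residue$pp), 2)
  # 4-window SD vanishes on a stationary (repeated-frame) trajectory
  tr4 <- md_trajectory(tr$topology, rep(tr$frames, 4))
  st4 <- hbonds_per_residue(tr4)
  expect_equal(st4$pw_sd, 0)
  expect_equal(st4$pp_sd, 0)
  w4 <- water_hb_density(tr4, "all")
  expect_equal(w4$sd, 0)
})

test_that("adjacent glycine selection picks the guest's sequence neighbours", {
  top <- build_diblock_topology("A", 1, 1)
  sel <- adjacent_glycine_selection(top)
  rt <- residue_table(top)
  expect_length(sel, 2L)
  expect_equal(rt$residue_index[match(sel, rt$residue_id)], c(7L, 9L))
  top5 <- build_diblock_topology("L", 5, 2)
  expect_length(adjacent_glycine_selection(top5), 20L)   # 10 per chain
  # a glycine guest: neighbours are selected, the guest itself is not
  topg <- build_diblock_topology("G", 1, 1)
  selg <- adjacent_glycine_selection(topg)
  expect_length(selg, 2L)
  expect_false(any(residue_table(topg)$is_guest[
    match(selg, residue_table(topg)$residue_id)]))
  # guest-free topology flags the empty selection
  hp <- condstat:::.homopolymer_topology(5L, 1L)
  empty <- adjacent_glycine_selection(hp)
  expect_length(empty, 0L)
  expect_true(attr(empty, "no_guest"))
})

test_that("water HB density is invariant under rigid translation", {
  tr <- generate_hb_fixture(hb_fixture_spec(6, 2, 4, 3, seed = 9))
  f <- tr$frames[[1]]
  tr2 <- tr
  tr2$frames[[1]]$coords <-
    condstat:::wrap_coords(sweep(f$coords, 2, c(1.3, -0.7, 2.1), "+"), f$box)
  expect_equal(water_hb_density(tr2, "all")$mean,
               water_hb_density(tr, "all")$mean)
})
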