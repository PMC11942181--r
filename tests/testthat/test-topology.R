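test_that("diblock template expands with correct blocks and guest flags", {
  top <- build_diblock_topology("A", 5, 1)
  rt <- residue_table(top)
  expect_equal(nrow(rt), 50L)
  expect_equal(rt$block_label, rep(c("V_BLOCK", "X_BLOCK"), each = 25))
  # guest X sits at position 4 of each second-half pentamer
  expect_equal(rt$residue_index[rt$is_guest], 25L + 5L * (0:4) + 3L)
  expect_true(all(rt$residue_name[rt$is_guest] == "ALA"))
  expect_equal(sum(rt$is_guest), 5L)

  top2 <- build_diblock_topology("G", 1, 1)
  expect_equal(residue_table(top2)$residue_name,
               c("VAL", "PRO", "GLY", "VAL", "GLY",
                 "VAL", "PRO", "GLY", "GLY", "GLY"))
  expect_equal(sum(residue_table(top2)$is_guest), 1L)
})

test_that("invalid guests and repeat counts are rejected", {
  expect_error(build_diblock_topology("P", 1, 1), "proline")
  expect_error(build_diblock_topology("Z", 1, 1), "standard amino acid")
  expect_error(build_diblock_topology("A", 0, 1), "positive")
})

test_that("bead ids are contiguous and hydrogens reference in-residue donors", {
  for (res in c("CA", "CG4", "ATOMISTIC_LITE")) {
    top <- build_diblock_topology("S", 2, 2, res)
    b <- top$beads
    expect_equal(b$bead_id, seq_len(nrow(b)) - 1L)
    hs <- b[b$is_hydrogen, ]
    if (nrow(hs)) {
      don <- b[match(hs$donor_id, b$bead_id), ]
      expect_true(all(don$is_donor))
      expect_equal(don$residue_id, hs$residue_id)
    }
    if (res != "ATOMISTIC_LITE") expect_equal(nrow(hs), 0L)
  }
})

test_that("resolution bead counts follow the mapping", {
  ca <- build_diblock_topology("W", 1, 1, "CA")
  expect_equal(nrow(ca$beads), 10L)  # one bead per residue
  cg <- build_diblock_topology("W", 1, 1, "CG4")
  b <- cg$beads
  # tryptophan has 10 side-chain heavy atoms -> 3 side beads + backbone
  expect_equal(sum(b$residue_name == "TRP"), 4L)
  expect_equal(sum(b$residue_name == "GLY"), 4L)  # 4 glycines, backbone only
  al <- build_diblock_topology("N", 1, 1, "ATOMISTIC_LITE")
  roles <- hb_roles(al)
  expect_setequal(unique(roles),
                  c("DONOR_HEAVY", "ACCEPTOR_HEAVY", "HYDROGEN", "NONE"))
  # prolines contribute no backbone donor
  bb_don <- al$beads$is_donor & al$beads$name == "N"
  expect_equal(sum(bb_don), sum(residue_table(al)$residue_name != "PRO"))
})

test_that("coarse masses equal summed heavy-atom masses", {
  ca <- build_diblock_topology("F", 1, 1, "CA")
  al <- build_diblock_topology("F", 1, 1, "ATOMISTIC_LITE")
  m_ca <- sum(ca$beads$mass)
  m_heavy <- sum(al$beads$mass[al$beads$is_heavy])
  expect_equal(m_ca, m_heavy, tolerance = 1e-12)
})

test_that("solvent and ions append as single-residue chains", {
  top <- add_solvent(build_diblock_topology("A", 1, 1), 3, 2, 1)
  b <- top$beads
  expect_equal(sum(b$block_label == "SOLVENT"), 3L)
  expect_equal(sum(b$block_label == "ION"), 3L)
  expect_equal(b$bead_id, seq_len(nrow(b)) - 1L)
  expect_equal(length(peptide_chain_ids(top)), 1L)
})
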