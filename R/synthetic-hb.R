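#' Specification for a planted hydrogen-bond fixture
#'
#' Describes a frame in which every hydrogen bond (and every near-but-not
#' bonded water) is planted by construction, giving exact ground truth for
#' the hydrogen-bond detector and the water hydrogen-bond density. Planted
#' geometries satisfy (or violate) the 0.330 nm / 135 degree criterion with
#' comfortable margins (>= 0.02 nm and >= 10 degrees).
#'
#' @param n_pw Protein-water hydrogen-bonded triples to plant.
#' @param n_pp Protein-protein triples.
#' @param n_near_nonbonded Waters within 0.4 nm of protein heavy atoms but
#'   not hydrogen bonded.
#' @param n_far Waters far (> 0.4 nm) from any protein heavy atom.
#' @param seed Integer seed (controls small motif jitter).
#' @return An object of class `hb_fixture_spec`.
#' @export
hb_fixture_spec <- function(n_pw = 10L, n_pp = 3L, n_near_nonbonded = 10L,
                            n_far = 50L, seed = 1L) {
  n <- c(n_pw, n_pp, n_near_nonbonded, n_far)
  if (any(n < 0L)) stop("counts must be non-negative")
  if (sum(n) == 0L) stop("fixture must contain at least one motif")
  structure(list(n_pw = as.integer(n_pw), n_pp = as.integer(n_pp),
                 n_near_nonbonded = as.integer(n_near_nonbonded),
                 n_far = as.integer(n_far), seed = as.integer(seed)),
            class = "hb_fixture_spec")
}

# Local motif geometries (nm, relative to the motif origin). Protein
# residues are glycine-like N,H,CA,C,O groups; atom order matches the
# ATOMISTIC_LITE residue template.
.HB_RES_A <- rbind(N = c(0, 0, 0), H = c(0, -0.10, 0), CA = c(0.15, 0, 0),
                   C = c(0.30, 0, 0), O = c(0.42, 0, 0))
# acceptor-presenting partner residue of a PP motif (O points up at the
# donor of residue A; its own N-H points away, downward)
.HB_RES_B <- rbind(N = c(0, -0.70, 0), H = c(0, -0.80, 0),
                   CA = c(0, -0.55, 0), C = c(0, -0.40, 0),
                   O = c(0, -0.28, 0))
.HB_WAT_PW <- rbind(OW = c(0, -0.28, 0), HW1 = c(0.06, -0.36, 0),
                    HW2 = c(-0.06, -0.36, 0))
.HB_WAT_NEAR <- rbind(OW = c(0.15, 0.38, 0), HW1 = c(0.21, 0.46, 0),
                      HW2 = c(0.09, 0.46, 0))
.HB_WAT_FAR <- rbind(OW = c(0, 0, 0), HW1 = c(0.06, 0.08, 0),
                     HW2 = c(-0.06, 0.08, 0))

#' Generate a planted hydrogen-bond fixture
#'
#' Motifs are placed on a 2 nm grid (with small seeded jitter), which keeps
#' planted motifs more than 0.6 nm apart so no accidental hydrogen bonds or
#' nearby-water contacts arise between motifs. [detect_hbonds()] on the
#' output finds exactly `n_pw` PW and `n_pp` PP bonds, and the nearby-water
#' count of the all-residue selection equals `n_pw + n_near_nonbonded`.
#'
#' @param spec An [hb_fixture_spec].
#' @return A single-frame [md_trajectory] at ATOMISTIC_LITE resolution.
#' @export
generate_hb_fixture <- function(spec) {
  stopifnot(inherits(spec, "hb_fixture_spec"))
  set.seed(spec$seed)
  pitch <- 2.0
  n_motifs <- spec$n_pw + spec$n_pp + spec$n_near_nonbonded + spec$n_far
  k <- ceiling(n_motifs^(1 / 3) - 1e-9)
  dims <- c(k, k, ceiling(n_motifs / k^2))
  box <- dims * pitch
  cells <- as.matrix(expand.grid(x = seq_len(dims[1L]) - 0.5,
                                 y = seq_len(dims[2L]) - 0.5,
                                 z = seq_len(dims[3L]) - 0.5)) * pitch
  cells <- cells[seq_len(n_motifs), , drop = FALSE] +
    matrix(stats::runif(3L * n_motifs, -0.1, 0.1), n_motifs, 3L)

  kind <- rep(c("pw", "pp", "near", "far"),
              c(spec$n_pw, spec$n_pp, spec$n_near_nonbonded, spec$n_far))

  res_units <- list()
  res_coords <- list()
  wat_coords <- list()
  gly <- .residue_beads("GLY", "ATOMISTIC_LITE")
  for (m in seq_len(n_motifs)) {
    origin <- cells[m, ]
    shift <- function(tmpl) sweep(tmpl, 2L, origin, "+")
    switch(kind[m],
           pw = {
             res_units <- c(res_units, list(gly))
             res_coords <- c(res_coords, list(shift(.HB_RES_A)))
             wat_coords <- c(wat_coords, list(shift(.HB_WAT_PW)))
           },
           pp = {
             res_units <- c(res_units, list(gly, gly))
             res_coords <- c(res_coords,
                             list(shift(.HB_RES_A), shift(.HB_RES_B)))
           },
           near = {
             res_units <- c(res_units, list(gly))
             res_coords <- c(res_coords, list(shift(.HB_RES_A)))
             wat_coords <- c(wat_coords, list(shift(.HB_WAT_NEAR)))
           },
           far = {
             wat_coords <- c(wat_coords, list(shift(.HB_WAT_FAR)))
           })
  }
  n_res <- length(res_units)
  n_wat <- length(wat_coords)
  if (n_res > 0L) {
    meta <- data.frame(chain_id = 0L, residue_index = seq_len(n_res) - 1L,
                       residue_name = "GLY", block_label = "V_BLOCK",
                       is_guest = FALSE, stringsAsFactors = FALSE)
    top <- .assemble(res_units, meta, "ATOMISTIC_LITE")
    if (n_wat > 0L) top <- add_solvent(top, n_water = n_wat)
  } else {
    # water-only fixture (e.g. an all-far spec)
    meta <- data.frame(chain_id = seq_len(n_wat) - 1L, residue_index = 0L,
                       residue_name = "SOL", block_label = "SOLVENT",
                       is_guest = FALSE, stringsAsFactors = FALSE)
    top <- .assemble(rep(list(.water_beads("ATOMISTIC_LITE")), n_wat),
                     meta, "ATOMISTIC_LITE")
  }
  coords <- do.call(rbind, c(res_coords, wat_coords))
  coords <- wrap_coords(unname(coords), box)
  md_trajectory(top, list(md_frame(coords, box, time = 0)))
}
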