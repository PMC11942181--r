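#' Morphology specification for synthetic condensates
#'
#' Describes a condensate slab with controllable microphase morphology. The
#' generated systems emulate the study geometry: a protein-dense slab
#' spanning the x-y plane, centred on the box z-midpoint, coexisting with a
#' dilute solvent phase along z. Within the slab the V and X blocks are
#' placed by morphology:
#'
#' * `UNIFORM` - both blocks mixed at random through the slab.
#' * `LAMELLAR` - V block in an inner sub-slab (|z - Lz/2| < w/4), X block in
#'   the two outer sub-slabs.
#' * `GYROID` - blocks on the two sides of the triply periodic nodal surface
#'   g = sin(2 pi x/L) cos(2 pi y/L) + sin(2 pi y/L) cos(2 pi z/L) +
#'   sin(2 pi z/L) cos(2 pi x/L): V where g > t, X where g < -t.
#' * `MICELLE` - X block in spherical cores on a grid, V block in the
#'   coronas.
#' * `TWO_PHASE_SLAB` - as `UNIFORM`, with a fraction of chains placed in
#'   the dilute phase.
#'
#' @param kind Morphology kind (see above).
#' @param box Box edges (nm); default 15 x 15 x 30.
#' @param slab_width Slab width w along z (nm), `<= Lz`.
#' @param phi_p Protein mass fraction inside the slab, in (0, 1]. At 1 the
#'   system contains no solvent (fast, protein-only fixtures).
#' @param guest Guest amino acid (1-letter code, not P).
#' @param n_repeats Pentamer repeats per block.
#' @param n_chains Number of diblock chains.
#' @param water_fraction Fraction of solvent molecules that are water; the
#'   remainder is split into Na+/Cl- pairs.
#' @param seed Integer seed; the generator is a pure function of the spec.
#' @param n_frames Number of independent configurations to generate.
#' @param gyroid_period,gyroid_threshold Period L (nm) and threshold t of the
#'   gyroid level set.
#' @param micelle_radius,micelle_spacing Core radius and core-grid spacing
#'   (nm) for `MICELLE`.
#' @param dilute_fraction Fraction of chains placed in the dilute phase for
#'   `TWO_PHASE_SLAB`.
#' @return An object of class `morphology_spec`.
#' @export
morphology_spec <- function(kind = c("UNIFORM", "LAMELLAR", "GYROID",
                                     "MICELLE", "TWO_PHASE_SLAB"),
                            box = c(15, 15, 30), slab_width = 15,
                            phi_p = 0.5, guest = "A", n_repeats = 5L,
                            n_chains = 64L, water_fraction = 0.98,
                            seed = 1L, n_frames = 1L,
                            gyroid_period = 7.5, gyroid_threshold = 0.2,
                            micelle_radius = 2.0, micelle_spacing = 7.5,
                            dilute_fraction = 0.1) {
  kind <- match.arg(kind)
  box <- as.numeric(box)
  if (length(box) != 3L || any(box <= 0)) stop("box must be 3 positive lengths")
  if (slab_width <= 0 || slab_width > box[3L])
    stop("slab_width must lie in (0, Lz]")
  if (phi_p <= 0 || phi_p > 1) stop("phi_p must lie in (0, 1]")
  if (water_fraction < 0 || water_fraction > 1)
    stop("water_fraction must lie in [0, 1]")
  structure(list(kind = kind, box = box, slab_width = slab_width,
                 phi_p = phi_p, guest = guest,
                 n_repeats = as.integer(n_repeats),
                 n_chains = as.integer(n_chains),
                 water_fraction = water_fraction, seed = as.integer(seed),
                 n_frames = as.integer(n_frames),
                 gyroid_period = gyroid_period,
                 gyroid_threshold = gyroid_threshold,
                 micelle_radius = micelle_radius,
                 micelle_spacing = micelle_spacing,
                 dilute_fraction = dilute_fraction),
            class = "morphology_spec")
}

# Gyroid nodal approximant.
.gyroid_g <- function(p, L) {
  a <- 2 * pi / L
  sin(a * p[, 1L]) * cos(a * p[, 2L]) +
    sin(a * p[, 2L]) * cos(a * p[, 3L]) +
    sin(a * p[, 3L]) * cos(a * p[, 1L])
}

# Micelle core centres: cubic grid with given spacing, restricted to the slab.
.micelle_centres <- function(spec) {
  s <- spec$micelle_spacing
  zc <- spec$box[3L] / 2
  gx <- seq(s / 2, spec$box[1L] - 1e-9, by = s)
  gy <- seq(s / 2, spec$box[2L] - 1e-9, by = s)
  gz <- seq(zc - spec$slab_width / 2 + s / 2, zc + spec$slab_width / 2, by = s)
  as.matrix(expand.grid(x = gx, y = gy, z = gz))
}

# Region functions: inside(p) and score(p) (higher = deeper inside) for a
# block of one chain; p is an n x 3 matrix of wrapped coordinates.
.block_region <- function(spec, block, dilute = FALSE) {
  zc <- spec$box[3L] / 2
  w <- spec$slab_width
  margin <- min(0.1, w / 10)
  slab_score <- function(p) (w / 2 - margin) - abs(p[, 3L] - zc)
  if (dilute) {
    score <- function(p) abs(p[, 3L] - zc) - (w / 2 + 0.3)
    return(list(inside = function(p) score(p) >= 0, score = score))
  }
  block_score <- switch(
    spec$kind,
    UNIFORM = ,
    TWO_PHASE_SLAB = function(p) rep(1, nrow(p)),
    LAMELLAR = if (block == "V_BLOCK") {
      function(p) w / 4 - abs(p[, 3L] - zc)
    } else {
      function(p) abs(p[, 3L] - zc) - w / 4
    },
    GYROID = if (block == "V_BLOCK") {
      function(p) .gyroid_g(p, spec$gyroid_period) - spec$gyroid_threshold
    } else {
      function(p) -.gyroid_g(p, spec$gyroid_period) - spec$gyroid_threshold
    },
    MICELLE = {
      centres <- .micelle_centres(spec)
      core_d <- function(p) {
        d <- min_image_dist_matrix(p, centres, spec$box)
        apply(d, 1L, min)
      }
      if (block == "X_BLOCK") function(p) spec$micelle_radius - core_d(p)
      else function(p) core_d(p) - spec$micelle_radius
    })
  list(inside = function(p) block_score(p) >= 0 & slab_score(p) >= 0,
       score = function(p) pmin(block_score(p), slab_score(p)))
}

# Junction predicate: points inside the V region that are also close to the
# X region, so the V->X hand-off of a chain needs only a few bridging bonds.
.junction_ok <- function(spec, p) {
  zc <- spec$box[3L] / 2
  switch(spec$kind,
         UNIFORM = ,
         TWO_PHASE_SLAB = rep(TRUE, nrow(p)),
         LAMELLAR = abs(p[, 3L] - zc) >= spec$slab_width / 4 - 0.5,
         GYROID = .gyroid_g(p, spec$gyroid_period) <=
           spec$gyroid_threshold + 0.4,
         MICELLE = {
           centres <- .micelle_centres(spec)
           d <- apply(min_image_dist_matrix(p, centres, spec$box), 1L, min)
           d <= spec$micelle_radius + 0.5
         })
}

.random_unit <- function(n) {
  v <- matrix(stats::rnorm(3L * n), n, 3L)
  v / sqrt(rowSums(v * v))
}

# Sample n points satisfying pred() by rejection from the slab (or dilute
# region); errors out when the region appears unreachable.
.sample_points <- function(spec, pred, n, dilute = FALSE, max_iter = 200L) {
  zc <- spec$box[3L] / 2
  got <- matrix(0, 0L, 3L)
  for (k in seq_len(max_iter)) {
    m <- max(200L, 4L * n)
    z <- if (dilute) {
      lo <- spec$slab_width / 2 + 0.3
      span <- spec$box[3L] - spec$slab_width - 0.6
      if (span <= 0) stop("packing error: no dilute region available")
      (zc + lo + stats::runif(m, 0, span)) %% spec$box[3L]
    } else {
      stats::runif(m, zc - spec$slab_width / 2, zc + spec$slab_width / 2)
    }
    p <- cbind(stats::runif(m, 0, spec$box[1L]),
               stats::runif(m, 0, spec$box[2L]), z)
    got <- rbind(got, p[pred(p), , drop = FALSE])
    if (nrow(got) >= n) return(got[seq_len(n), , drop = FALSE])
  }
  stop("packing error: could not place chains in their assigned region")
}

# Grow constrained random walks for all chains in lockstep: `starts` is an
# nc x 3 matrix (one row per chain, not included in the output). Each step
# proposes one bond per chain; chains whose proposal leaves their region
# redraw (up to `retries`), and any still failing take the best-scoring of
# `n_prop` drift proposals, which lets a walk cross toward its region at
# the block junction. When `targets` is given, a chain whose remaining
# bonds barely cover the distance to its target marches straight toward it
# (a random bridge): the walk ends within about one bond of the target
# while its interior statistics stay those of a free constrained walk.
# Returns a list of nc x 3 matrices, one per step.
.grow_walks <- function(starts, n_steps, region, box, b = 0.38,
                        targets = NULL, retries = 8L, n_prop = 8L) {
  nc <- nrow(starts)
  prev <- starts
  steps <- vector("list", n_steps)
  for (k in seq_len(n_steps)) {
    prop <- wrap_coords(prev + b * .random_unit(nc), box)
    bad <- which(!region$inside(prop))
    tries <- 0L
    while (length(bad) && tries < retries) {
      redraw <- wrap_coords(prev[bad, , drop = FALSE] +
                              b * .random_unit(length(bad)), box)
      ok <- region$inside(redraw)
      prop[bad[ok], ] <- redraw[ok, , drop = FALSE]
      bad <- bad[!ok]
      tries <- tries + 1L
    }
    if (length(bad)) {
      # drift: best-scoring of n_prop proposals per still-failing chain
      nb <- length(bad)
      base <- prev[rep(bad, each = n_prop), , drop = FALSE]
      cand <- wrap_coords(base + b * .random_unit(nb * n_prop), box)
      sc <- matrix(region$score(cand), nb, n_prop, byrow = TRUE)
      pick <- max.col(sc, ties.method = "first")
      prop[bad, ] <- cand[(seq_len(nb) - 1L) * n_prop + pick, , drop = FALSE]
    }
    if (!is.null(targets)) {
      delta <- min_image_delta(targets - prev, box)
      dist <- sqrt(rowSums(delta * delta))
      left <- n_steps - k + 1L
      march <- which(dist > 0.85 * b * left & dist > b)
      if (length(march)) {
        step <- delta[march, , drop = FALSE] * (b / dist[march])
        prop[march, ] <- wrap_coords(prev[march, , drop = FALSE] + step, box)
      }
    }
    steps[[k]] <- prop
    prev <- prop
  }
  steps
}

#' Generate a synthetic condensate trajectory
#'
#' Builds the diblock topology (CA resolution), grows each chain as a
#' connected random walk (bond length 0.38 nm) inside its morphology-assigned
#' region, and fills the remaining slab volume and the dilute phase with
#' water (and ion) beads so that the protein mass fraction inside the slab
#' equals `phi_p`. Frames are independent configurations. The generator is
#' deterministic in the spec (seed included).
#'
#' @param spec A [morphology_spec].
#' @return An [md_trajectory]; protein beads are confined to
#'   `|z - Lz/2| < w/2`.
#' @export
generate_condensate <- function(spec) {
  stopifnot(inherits(spec, "morphology_spec"))
  set.seed(spec$seed)
  box <- spec$box
  zc <- box[3L] / 2
  w <- spec$slab_width
  nres_half <- 5L * spec$n_repeats

  top <- build_diblock_topology(spec$guest, spec$n_repeats, spec$n_chains, "CA")
  m_protein <- sum(top$beads$mass)

  # solvent bookkeeping: slab solvent mass fixes phi_p; the dilute phase gets
  # the same solvent mass density as the slab interior
  n_w_slab <- n_w_dil <- n_na <- n_cl <- 0L
  if (spec$phi_p < 1) {
    ion_mass <- (.ELEMENT_MASS[["Na"]] + .ELEMENT_MASS[["Cl"]]) / 2
    mbar <- spec$water_fraction * .WATER_MASS +
      (1 - spec$water_fraction) * ion_mass
    m_solv_slab <- m_protein * (1 - spec$phi_p) / spec$phi_p
    n_solv_slab <- max(0L, round(m_solv_slab / mbar))
    v_slab <- box[1L] * box[2L] * w
    v_dil <- box[1L] * box[2L] * (box[3L] - w)
    n_solv_dil <- round(n_solv_slab * v_dil / v_slab)
    n_w_slab <- round(spec$water_fraction * n_solv_slab)
    n_w_dil <- round(spec$water_fraction * n_solv_dil)
    n_ion <- (n_solv_slab - n_w_slab) + (n_solv_dil - n_w_dil)
    n_na <- n_ion %/% 2L
    n_cl <- n_ion - n_na
    # crude capacity check at 0.25 nm minimum spacing
    if ((nrow(top$beads) + n_solv_slab) * 0.25^3 > v_slab)
      stop("packing error: requested beads exceed slab capacity ",
           "at 0.25 nm minimum spacing")
    top <- add_solvent(top, n_w_slab + n_w_dil, n_na, n_cl)
  } else if (nrow(top$beads) * 0.25^3 > box[1L] * box[2L] * w) {
    stop("packing error: requested beads exceed slab capacity ",
         "at 0.25 nm minimum spacing")
  }

  n_dilute <- if (spec$kind == "TWO_PHASE_SLAB")
    round(spec$dilute_fraction * spec$n_chains) else 0L

  frames <- vector("list", spec$n_frames)
  n_solv <- n_w_slab + n_w_dil + n_na + n_cl
  # chains are grown in lockstep per group (slab chains, dilute chains)
  grow_group <- function(nc, dilute) {
    if (nc == 0L) return(NULL)
    reg_v <- .block_region(spec, "V_BLOCK", dilute)
    reg_x <- .block_region(spec, "X_BLOCK", dilute)
    starts <- .sample_points(spec, reg_v$inside, nc, dilute = dilute)
    # V halves start uniform in the V region and bridge to a nearby
    # interface point, so the block junction sits at the region boundary
    # without piling V mass against it; X halves continue from there
    targets <- NULL
    if (!dilute && spec$kind %in% c("LAMELLAR", "GYROID", "MICELLE")) {
      pool <- .sample_points(spec, function(p)
        reg_v$inside(p) & .junction_ok(spec, p), max(200L, nc))
      nearest <- apply(min_image_dist_matrix(starts, pool, box), 1L,
                       which.min)
      targets <- pool[nearest, , drop = FALSE]
    }
    v_steps <- .grow_walks(starts, nres_half - 1L, reg_v, box,
                           targets = targets)
    x_starts <- if (nres_half > 1L) v_steps[[nres_half - 1L]] else starts
    x_steps <- .grow_walks(x_starts, nres_half, reg_x, box)
    per_chain <- vector("list", nc)
    for (c in seq_len(nc)) {
      per_chain[[c]] <- rbind(
        starts[c, , drop = FALSE],
        do.call(rbind, lapply(v_steps, function(m) m[c, ])),
        do.call(rbind, lapply(x_steps, function(m) m[c, ])))
    }
    per_chain
  }
  for (f in seq_len(spec$n_frames)) {
    chain_xyz <- c(grow_group(n_dilute, TRUE),
                   grow_group(spec$n_chains - n_dilute, FALSE))
    coords <- do.call(rbind, chain_xyz)
    if (n_solv > 0L) {
      zs <- c(stats::runif(n_w_slab, zc - w / 2, zc + w / 2),
              if (n_w_dil > 0L)
                (zc + w / 2 + stats::runif(n_w_dil, 0, box[3L] - w)) %% box[3L])
      n_ion_tot <- n_na + n_cl
      n_i_slab <- round(n_ion_tot * n_w_slab / max(1L, n_w_slab + n_w_dil))
      zi <- c(stats::runif(n_i_slab, zc - w / 2, zc + w / 2),
              if (n_ion_tot - n_i_slab > 0L)
                (zc + w / 2 +
                   stats::runif(n_ion_tot - n_i_slab, 0, box[3L] - w)) %%
                  box[3L])
      zall <- c(zs, zi)
      solv <- cbind(stats::runif(n_solv, 0, box[1L]),
                    stats::runif(n_solv, 0, box[2L]), zall)
      coords <- rbind(coords, solv)
    }
    frames[[f]] <- md_frame(coords, box, time = f - 1)
  }
  md_trajectory(top, frames)
}

#' Generate a pressure series with a planted surface tension
#'
#' Rows satisfy `E[Pzz - (Pxx + Pyy)/2] = 2 N tau_target / Lz`, with
#' independent Gaussian noise of standard deviation `noise_sd` on each
#' tensor component, so [surface_tension()] recovers `tau_target` up to
#' sampling error.
#'
#' @param tau_target Planted surface tension (bar nm).
#' @param Lz Box height (nm).
#' @param n_droplets Number of droplets N.
#' @param n_rows Number of rows (frames).
#' @param noise_sd Noise standard deviation (bar).
#' @param seed Integer seed.
#' @param p0 Baseline lateral pressure (bar).
#' @return A [pressure_series].
#' @export
generate_pressure_series <- function(tau_target, Lz, n_droplets = 1L,
                                     n_rows = 1000L, noise_sd = 0,
                                     seed = 1L, p0 = 1.0) {
  if (n_rows < 1L) stop("n_rows must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  anis <- 2 * n_droplets * tau_target / Lz
  pxx <- p0 + stats::rnorm(n_rows, 0, noise_sd)
  pyy <- p0 + stats::rnorm(n_rows, 0, noise_sd)
  pzz <- p0 + anis + stats::rnorm(n_rows, 0, noise_sd)
  pressure_series(seq_len(n_rows) - 1, pxx, pyy, pzz, Lz = Lz,
                  n_droplets = n_droplets)
}

# Homopolymer CA topology used by the ideal-chain ensemble.
.homopolymer_topology <- function(n_residues, n_chains, res3 = "GLY") {
  unit <- .residue_beads(res3, "CA")
  meta <- data.frame(
    chain_id = rep(seq_len(n_chains) - 1L, each = n_residues),
    residue_index = rep(seq_len(n_residues) - 1L, n_chains),
    residue_name = res3, block_label = "V_BLOCK", is_guest = FALSE,
    stringsAsFactors = FALSE)
  .assemble(rep(list(unit), n_residues * n_chains), meta, "CA")
}

#' Generate an ensemble of ideal (freely jointed) chains
#'
#' Chains are freely jointed sequences of Kuhn segments of length `2 lp`;
#' beads are placed every `b` nm of arc length along the segment path, so a
#' chain of `n_residues` beads carries a contour of `(n_residues - 1) b`.
#' There is no excluded volume. The ensemble-mean radius of gyration matches
#' the ideal-chain closed form [ideal_chain_rg()] at Flory exponent 1/2 (up
#' to the finite-chain discretisation, a few percent for pentacontamers).
#'
#' @param n_residues Beads per chain (>= 2).
#' @param b Bond length (nm); 0.38 between consecutive residues.
#' @param lp Persistence length (nm); the Kuhn length is `2 lp`.
#' @param n_chains Number of chains.
#' @param seed Integer seed.
#' @return An [md_trajectory] with one frame holding all chains.
#' @export
generate_ideal_chain_ensemble <- function(n_residues, b = 0.38, lp = 0.40,
                                          n_chains = 1000L, seed = 1L) {
  if (n_residues < 2L) stop("n_residues must be >= 2")
  if (b <= 0 || lp <= 0) stop("b and lp must be positive")
  set.seed(seed)
  kuhn <- 2 * lp
  contour <- (n_residues - 1L) * b
  n_full <- floor(contour / kuhn)
  seg_len <- c(rep(kuhn, n_full), contour - n_full * kuhn)
  seg_len <- seg_len[seg_len > 1e-12]
  L <- max(2 * contour + 2, 5)
  box <- rep(L, 3L)
  centre <- box / 2
  s_beads <- (seq_len(n_residues) - 1L) * b
  s_seg0 <- cumsum(c(0, seg_len))
  coords <- matrix(0, n_residues * n_chains, 3L)
  for (c in seq_len(n_chains)) {
    dirs <- .random_unit(length(seg_len))
    verts <- rbind(centre,
                   matrix(centre, length(seg_len), 3L, byrow = TRUE) +
                     apply(dirs * seg_len, 2L, cumsum))
    seg_of <- pmin(findInterval(s_beads, s_seg0, rightmost.closed = TRUE),
                   length(seg_len))
    frac <- (s_beads - s_seg0[seg_of]) / seg_len[seg_of]
    xyz <- verts[seg_of, , drop = FALSE] +
      dirs[seg_of, , drop = FALSE] * seg_len[seg_of] * frac
    coords[((c - 1L) * n_residues + 1L):(c * n_residues), ] <- xyz
  }
  top <- .homopolymer_topology(n_residues, n_chains)
  md_trajectory(top, list(md_frame(wrap_coords(coords, box), box, time = 0)))
}
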