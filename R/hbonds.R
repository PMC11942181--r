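# Hydrogen-bond geometric criteria: donor heavy atom within 0.330 nm of an
# acceptor heavy atom AND donor-hydrogen-acceptor angle >= 135 degrees.
# Both thresholds are inclusive.
.HB_DIST <- 0.330
.HB_ANGLE <- 135.0
.NEARBY_DIST <- 0.400
# numerical slack so geometries planted exactly at a boundary stay inclusive
.HB_EPS <- 1e-9

.species_code <- function(block_label) {
  out <- rep("I", length(block_label))
  out[block_label %in% c("V_BLOCK", "X_BLOCK")] <- "P"
  out[block_label == "SOLVENT"] <- "W"
  out
}

.require_atomistic <- function(topology) {
  if (!identical(topology$resolution, "ATOMISTIC_LITE"))
    stop("hydrogen-bond analysis requires atomistic-lite frames ",
         "(resolution ", topology$resolution, " has no hydrogens)")
}

# Per-frame detection; returns a data.frame of bond records.
.detect_hbonds_frame <- function(topology, frame, frame_index = 0L) {
  b <- topology$beads
  don <- which(b$is_donor)
  acc <- which(b$is_acceptor)
  empty <- data.frame(frame = integer(0), donor = integer(0),
                      hydrogen = integer(0), acceptor = integer(0),
                      class = character(0), distance = numeric(0),
                      angle = numeric(0), stringsAsFactors = FALSE)
  if (!length(don) || !length(acc)) return(empty)
  h_of <- split(which(b$is_hydrogen), b$donor_id[b$is_hydrogen] + 1L)

  bond_key <- character(0)
  if (!is.null(topology$bonds) && nrow(topology$bonds)) {
    bond_key <- paste(pmin(topology$bonds$i, topology$bonds$j),
                      pmax(topology$bonds$i, topology$bonds$j))
  }

  d <- min_image_dist_matrix(frame$coords[don, , drop = FALSE],
                             frame$coords[acc, , drop = FALSE],
                             frame$box, frame$periodic)
  hit <- which(d <= .HB_DIST + .HB_EPS, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  di <- don[hit[, 1L]]
  ai <- acc[hit[, 2L]]
  keep <- di != ai
  if (length(bond_key)) {
    key <- paste(pmin(di, ai) - 1L, pmax(di, ai) - 1L)
    keep <- keep & !(key %in% bond_key)
  }
  di <- di[keep]; ai <- ai[keep]
  dist <- d[hit][keep]
  if (!length(di)) return(empty)

  # expand over the hydrogens of each donor and apply the angle criterion
  hl <- h_of[as.character(di)]
  nh <- lengths(hl)
  if (any(nh == 0L)) {   # donors without an explicit hydrogen cannot bond
    di <- di[nh > 0L]; ai <- ai[nh > 0L]; dist <- dist[nh > 0L]
    hl <- hl[nh > 0L]; nh <- nh[nh > 0L]
    if (!length(di)) return(empty)
  }
  di_e <- rep(di, nh)
  ai_e <- rep(ai, nh)
  dist_e <- rep(dist, nh)
  hi_e <- unlist(hl, use.names = FALSE)
  u <- min_image_delta(frame$coords[di_e, , drop = FALSE] -
                         frame$coords[hi_e, , drop = FALSE],
                       frame$box, frame$periodic)
  v <- min_image_delta(frame$coords[ai_e, , drop = FALSE] -
                         frame$coords[hi_e, , drop = FALSE],
                       frame$box, frame$periodic)
  cosang <- rowSums(u * v) /
    (sqrt(rowSums(u * u)) * sqrt(rowSums(v * v)))
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  ok <- ang >= .HB_ANGLE - .HB_EPS
  if (!any(ok)) return(empty)
  sp <- paste0(.species_code(b$block_label[di_e[ok]]),
               .species_code(b$block_label[ai_e[ok]]))
  cls <- ifelse(sp %in% c("PW", "WP"), "PW",
                ifelse(sp == "PP", "PP", ifelse(sp == "WW", "WW", "OTHER")))
  data.frame(frame = frame_index, donor = di_e[ok] - 1L,
             hydrogen = hi_e[ok] - 1L, acceptor = ai_e[ok] - 1L,
             class = cls, distance = dist_e[ok], angle = ang[ok],
             stringsAsFactors = FALSE)
}

#' Detect hydrogen bonds
#'
#' Finds all (donor heavy atom, hydrogen, acceptor heavy atom) triples with
#' donor-acceptor distance of at most 0.330 nm and donor-hydrogen-acceptor
#' angle of at least 135 degrees (both inclusive) under minimum image,
#' classified as
#' protein-protein (PP), protein-water (PW) or water-water (WW) by the
#' species of the donor and acceptor parents. Covalently bonded
#' donor-acceptor pairs are excluded. Requires ATOMISTIC_LITE resolution.
#'
#' @param trajectory An [md_trajectory].
#' @param frames Frame indices to analyse (1-based; default all).
#' @return Data frame with columns `frame` (0-based), `donor`, `hydrogen`,
#'   `acceptor` (bead ids), `class`, `distance` (nm), `angle` (degrees).
#' @export
detect_hbonds <- function(trajectory, frames = NULL) {
  .require_atomistic(trajectory$topology)
  if (is.null(frames)) frames <- seq_along(trajectory$frames)
  out <- lapply(frames, function(k)
    .detect_hbonds_frame(trajectory$topology, trajectory$frames[[k]], k - 1L))
  do.call(rbind, out)
}

# Resolve a residue selection: "all" (all protein residues), "guest",
# "adjacent_gly", or an explicit vector of residue ids.
.resolve_selection <- function(topology, selection) {
  rt <- residue_table(topology)
  if (is.numeric(selection)) return(as.integer(selection))
  selection <- match.arg(selection, c("all", "guest", "adjacent_gly"))
  switch(selection,
         all = rt$residue_id[rt$block_label %in% c("V_BLOCK", "X_BLOCK")],
         guest = rt$residue_id[rt$is_guest],
         adjacent_gly = adjacent_glycine_selection(topology))
}

#' Glycines adjacent to the guest residue
#'
#' The G residues immediately before and after each guest X in the sequence
#' (positions 3 and 5 of each X-block pentamer). The guest's role, not its
#' residue name, decides: for a glycine guest the selection still excludes
#' the guest position itself and includes its glycine neighbours.
#'
#' @param topology A `bead_topology` with diblock annotations.
#' @return Integer vector of residue ids; empty (with attribute
#'   `no_guest = TRUE`) when the topology has no guest residues.
#' @export
adjacent_glycine_selection <- function(topology) {
  rt <- residue_table(topology)
  guests <- rt[rt$is_guest, , drop = FALSE]
  if (!nrow(guests)) {
    out <- integer(0)
    attr(out, "no_guest") <- TRUE
    return(out)
  }
  key <- paste(rt$chain_id, rt$residue_index)
  nb_key <- c(paste(guests$chain_id, guests$residue_index - 1L),
              paste(guests$chain_id, guests$residue_index + 1L))
  hit <- rt[key %in% nb_key & rt$residue_name == "GLY" & !rt$is_guest,
            "residue_id"]
  sort(unique(hit))
}

#' Count water molecules near a residue selection
#'
#' Number of distinct water molecules whose oxygen lies within 0.40 nm
#' (minimum image) of any heavy atom of the selection; a water close to
#' several selection atoms is counted once.
#'
#' @param topology A `bead_topology`.
#' @param frame An [md_frame].
#' @param selection Residue selection (see [water_hb_density()]).
#' @return Integer count.
#' @export
nearby_waters <- function(topology, frame, selection = "all") {
  res_ids <- .resolve_selection(topology, selection)
  b <- topology$beads
  heavy <- which(b$residue_id %in% res_ids & b$is_heavy)
  wat_o <- which(b$block_label == "SOLVENT" & b$element == "O" & b$is_heavy)
  if (!length(heavy) || !length(wat_o)) return(0L)
  d <- min_image_dist_matrix(frame$coords[wat_o, , drop = FALSE],
                             frame$coords[heavy, , drop = FALSE],
                             frame$box, frame$periodic)
  near <- apply(d, 1L, min) <= .NEARBY_DIST
  length(unique(b$residue_id[wat_o[near]]))
}

# Split 1..n into k contiguous windows (as equal as possible).
.windows <- function(n, k) {
  if (n < k) return(NULL)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  split(seq_len(n), rep(seq_len(k), sizes))
}

#' Hydrogen bonds per residue
#'
#' Average number of protein-protein (PP) and protein-water (PW) hydrogen
#' bonds per protein residue. Each PP bond credits both participating
#' residues; each PW bond credits its protein residue. Totals are divided by
#' the protein residue count and the frame count. The SD over `n_windows`
#' contiguous time windows is reported when enough frames are available.
#'
#' @param trajectory An ATOMISTIC_LITE [md_trajectory].
#' @param n_windows Number of windows for the error estimate (default 4).
#' @return A list of class `hydration_stats`: `per_residue` (data frame of
#'   mean PP/PW credit per residue), `pp_per_residue`, `pw_per_residue`,
#'   `pp_sd`, `pw_sd`, `n_windows`, `n_frames`.
#' @export
hbonds_per_residue <- function(trajectory, n_windows = 4L) {
  .require_atomistic(trajectory$topology)
  nfr <- length(trajectory$frames)
  if (nfr < 1L) stop("trajectory has no frames")
  b <- trajectory$topology$beads
  rt <- residue_table(trajectory$topology)
  prot_res <- rt$residue_id[rt$block_label %in% c("V_BLOCK", "X_BLOCK")]
  nres <- length(prot_res)
  if (!nres) stop("no protein residues")
  hb <- detect_hbonds(trajectory)
  res_of <- b$residue_id
  credit <- function(rows) {
    pp <- rows[rows$class == "PP", , drop = FALSE]
    pw <- rows[rows$class == "PW", , drop = FALSE]
    cr <- c(res_of[pp$donor + 1L], res_of[pp$acceptor + 1L])
    # PW credits the protein residue, whichever side it is on
    pw_res <- ifelse(.species_code(b$block_label[pw$donor + 1L]) == "P",
                     res_of[pw$donor + 1L], res_of[pw$acceptor + 1L])
    list(pp = tabulate(match(cr, prot_res), nres),
         pw = tabulate(match(pw_res, prot_res), nres))
  }
  tot <- credit(hb)
  per_frame <- lapply(seq_len(nfr) - 1L, function(f)
    credit(hb[hb$frame == f, , drop = FALSE]))
  win <- .windows(nfr, n_windows)
  wsd <- function(what) {
    if (is.null(win)) return(NA_real_)
    vals <- vapply(win, function(ix)
      mean(vapply(per_frame[ix], function(x) sum(x[[what]]), numeric(1))) /
        nres, numeric(1))
    stats::sd(vals)
  }
  list_out <- list(
    per_residue = data.frame(residue_id = prot_res,
                             pp = tot$pp / nfr, pw = tot$pw / nfr),
    pp_per_residue = sum(tot$pp) / (nres * nfr),
    pw_per_residue = sum(tot$pw) / (nres * nfr),
    pp_sd = wsd("pp"), pw_sd = wsd("pw"),
    n_windows = n_windows, n_frames = nfr)
  structure(list_out, class = "hydration_stats")
}

#' Water hydrogen-bond density
#'
#' Per frame, the number of protein-water hydrogen bonds whose protein
#' residue belongs to the selection, divided by the number of water
#' molecules near that selection ([nearby_waters()]). Frames with no nearby
#' water are skipped with a warning. Reports the per-frame series plus mean
#' and SD over `n_windows` contiguous windows of the remaining frames.
#'
#' @param trajectory An ATOMISTIC_LITE [md_trajectory].
#' @param selection `"all"`, `"guest"`, `"adjacent_gly"`, or residue ids.
#' @param n_windows Windows for the error estimate (default 4).
#' @return List of class `whbd_result`: `series` (data frame frame/pw/
#'   nearby/density), `mean`, `sd`, `n_windows`.
#' @export
water_hb_density <- function(trajectory, selection = "all", n_windows = 4L) {
  .require_atomistic(trajectory$topology)
  res_ids <- .resolve_selection(trajectory$topology, selection)
  b <- trajectory$topology$beads
  hb <- detect_hbonds(trajectory)
  pw <- hb[hb$class == "PW", , drop = FALSE]
  pw_res <- ifelse(.species_code(b$block_label[pw$donor + 1L]) == "P",
                   b$residue_id[pw$donor + 1L], b$residue_id[pw$acceptor + 1L])
  nfr <- length(trajectory$frames)
  rows <- lapply(seq_len(nfr), function(k) {
    nw <- nearby_waters(trajectory$topology, trajectory$frames[[k]], res_ids)
    npw <- sum(pw$frame == k - 1L & pw_res %in% res_ids)
    data.frame(frame = k - 1L, pw = npw, nearby = nw,
               density = if (nw > 0L) npw / nw else NA_real_)
  })
  series <- do.call(rbind, rows)
  usable <- !is.na(series$density)
  if (!any(usable))
    stop("undefined statistic: no frame has water near the selection")
  if (any(!usable))
    warning(sprintf("%d frame(s) without nearby water skipped",
                    sum(!usable)))
  dens <- series$density[usable]
  win <- .windows(length(dens), n_windows)
  wsd <- if (is.null(win)) NA_real_ else
    stats::sd(vapply(win, function(ix) mean(dens[ix]), numeric(1)))
  structure(list(series = series, mean = mean(dens), sd = wsd,
                 n_windows = n_windows),
            class = "whbd_result")
}
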