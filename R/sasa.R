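# Deterministic quasi-uniform sphere quadrature (Fibonacci lattice).
.sphere_points <- function(n) {
  i <- seq_len(n) - 1L
  z <- 1 - 2 * (i + 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- pi * (3 - sqrt(5)) * i
  cbind(r * cos(th), r * sin(th), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-residue SASA by numerical quadrature: each atom's sphere is inflated
#' by the probe radius, covered with a deterministic quasi-uniform point
#' lattice, and the exposed fraction of points (not inside any neighbour's
#' inflated sphere, under minimum image) is multiplied by the inflated
#' sphere area `4 pi (r_i + probe)^2`. Residue SASA is the sum over its
#' atoms. Atom radii are the Bondi van der Waals set, overridable.
#'
#' @param topology An ATOMISTIC_LITE `bead_topology`.
#' @param frame An [md_frame].
#' @param probe_radius Probe radius in nm (default 0.14, a water-sized
#'   probe).
#' @param n_points Quadrature points per atom (default 960; about 1%
#'   accuracy on an isolated sphere).
#' @param radii Named radius set (nm) by element, defaults to Bondi.
#' @return Data frame with `residue_id`, `residue_name`, `sasa` (nm^2).
#' @export
sasa <- function(topology, frame, probe_radius = 0.14, n_points = 960L,
                 radii = .BONDI_RADIUS) {
  b <- topology$beads
  unknown <- setdiff(unique(b$element), names(radii))
  if (length(unknown))
    stop("no van der Waals radius for element: ",
         paste(unknown, collapse = ", "))
  r <- unname(radii[b$element]) + probe_radius
  n <- nrow(b)
  pts <- .sphere_points(n_points)
  # neighbour candidates within r_i + r_j (both probe-inflated spheres
  # can intersect only below that separation)
  d <- min_image_dist_matrix(frame$coords, frame$coords, frame$box,
                             frame$periodic)
  area <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d[i, ] <= r[i] + r & seq_len(n) != i)
    full <- 4 * pi * r[i]^2
    if (!length(nb)) {
      area[i] <- full
      next
    }
    p <- pts * r[i]
    delta <- min_image_delta(
      frame$coords[nb, , drop = FALSE] -
        matrix(frame$coords[i, ], length(nb), 3L, byrow = TRUE),
      frame$box, frame$periodic)
    exposed <- rep(TRUE, n_points)
    for (k in seq_along(nb)) {
      dd <- p - matrix(delta[k, ], n_points, 3L, byrow = TRUE)
      exposed <- exposed & rowSums(dd * dd) > r[nb[k]]^2
      if (!any(exposed)) break
    }
    area[i] <- full * sum(exposed) / n_points
  }
  agg <- rowsum(area, b$residue_id)
  rt <- residue_table(topology)
  data.frame(residue_id = rt$residue_id, residue_name = rt$residue_name,
             sasa = agg[match(rt$residue_id, as.integer(rownames(agg))), 1L])
}

#' Relative solvent accessibility
#'
#' SASA of the selected residues normalised by each residue type's maximum
#' possible exposure. Means are taken over all residues of a type and over
#' frames; the SD over `n_windows` contiguous time windows is reported when
#' enough frames exist. Values can exceed 1 for highly exposed
#' conformations and are reported unclamped (with a warning above 1.2).
#'
#' @param trajectory An ATOMISTIC_LITE [md_trajectory].
#' @param selection Residue selection (default `"guest"`); see
#'   [water_hb_density()].
#' @param max_table Named vector residue -> max SASA (nm^2); defaults to the
#'   bundled empirical table ([max_sasa_table()]).
#' @param probe_radius,n_points Passed to [sasa()].
#' @param n_windows Windows for the error estimate.
#' @return Data frame with `residue_name`, `rsa`, `sd`, `n_residues`.
#' @export
rsa <- function(trajectory, selection = "guest",
                max_table = max_sasa_table("empirical"),
                probe_radius = 0.14, n_points = 960L, n_windows = 4L) {
  .require_atomistic(trajectory$topology)
  res_ids <- .resolve_selection(trajectory$topology, selection)
  if (!length(res_ids)) stop("empty residue selection")
  rt <- residue_table(trajectory$topology)
  sel <- rt[rt$residue_id %in% res_ids, , drop = FALSE]
  missing <- setdiff(unique(sel$residue_name), names(max_table))
  if (length(missing))
    stop("residue type missing from the max-SASA table: ",
         paste(missing, collapse = ", "))
  nfr <- length(trajectory$frames)
  per_frame <- lapply(trajectory$frames, function(fr) {
    s <- sasa(trajectory$topology, fr, probe_radius, n_points)
    s$sasa[match(res_ids, s$residue_id)]
  })
  mat <- do.call(cbind, per_frame)            # residues x frames
  types <- sel$residue_name[match(res_ids, sel$residue_id)]
  win <- .windows(nfr, n_windows)
  out <- do.call(rbind, lapply(unique(types), function(tp) {
    rows <- which(types == tp)
    rsa_val <- mean(mat[rows, , drop = FALSE]) / max_table[[tp]]
    sdv <- if (is.null(win)) NA_real_ else
      stats::sd(vapply(win, function(ix)
        mean(mat[rows, ix, drop = FALSE]) / max_table[[tp]], numeric(1)))
    data.frame(residue_name = tp, rsa = rsa_val, sd = sdv,
               n_residues = length(rows), stringsAsFactors = FALSE)
  }))
  high <- out$rsa > 1.2
  if (any(high))
    warning("RSA above 1.2 for: ",
            paste(out$residue_name[high], collapse = ", "),
            " (reported unclamped)")
  out
}
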