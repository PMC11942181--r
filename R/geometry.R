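# Periodic-geometry primitives shared by every analysis stage.

# Wrap coordinates into [0, L) on periodic axes.
wrap_coords <- function(coords, box, periodic = c(TRUE, TRUE, TRUE)) {
  for (ax in 1:3) {
    if (periodic[ax]) coords[, ax] <- coords[, ax] %% box[ax]
  }
  coords
}

# Minimum-image displacement of a matrix of deltas (n x 3).
min_image_delta <- function(delta, box, periodic = c(TRUE, TRUE, TRUE)) {
  for (ax in 1:3) {
    if (periodic[ax]) {
      delta[, ax] <- delta[, ax] - box[ax] * round(delta[, ax] / box[ax])
    }
  }
  delta
}

#' Minimum-image distance between two beads
#'
#' Euclidean distance under the minimum-image convention of the frame's
#' periodic box. On non-periodic axes the plain separation is used.
#'
#' @param frame An [md_frame].
#' @param bead_i,bead_j Bead ids (0-based, as stored in the topology).
#' @return Distance in nm.
#' @export
minimum_image_distance <- function(frame, bead_i, bead_j) {
  n <- nrow(frame$coords)
  if (any(c(bead_i, bead_j) < 0L) || any(c(bead_i, bead_j) >= n))
    stop("bead id out of range")
  d <- frame$coords[bead_i + 1L, , drop = FALSE] -
    frame$coords[bead_j + 1L, , drop = FALSE]
  d <- min_image_delta(d, frame$box, frame$periodic)
  sqrt(sum(d * d))
}

# Pairwise minimum-image distances between two coordinate sets (na x nb).
# Kept dense; callers chunk when sets are large.
min_image_dist_matrix <- function(a, b, box, periodic = c(TRUE, TRUE, TRUE)) {
  na <- nrow(a); nb <- nrow(b)
  d2 <- matrix(0, na, nb)
  for (ax in 1:3) {
    dd <- outer(a[, ax], b[, ax], "-")
    if (periodic[ax]) dd <- dd - box[ax] * round(dd / box[ax])
    d2 <- d2 + dd * dd
  }
  sqrt(d2)
}

# Circular-mean based unwrapping: returns coordinates shifted to the
# periodic image nearest the (mass-weighted) circular mean on each axis.
unwrap_about_circular_mean <- function(coords, box, mass,
                                       periodic = c(TRUE, TRUE, TRUE)) {
  w <- mass / sum(mass)
  for (ax in 1:3) {
    if (!periodic[ax]) next
    L <- box[ax]
    theta <- coords[, ax] * (2 * pi / L)
    mtheta <- atan2(sum(w * sin(theta)), sum(w * cos(theta)))
    ref <- (mtheta / (2 * pi)) * L
    d <- coords[, ax] - ref
    coords[, ax] <- ref + (d - L * round(d / L))
  }
  coords
}

#' Centre of mass of a chain under periodic boundaries
#'
#' With `pbc_aware = TRUE` the chain is first unwrapped about the
#' mass-weighted circular mean on each periodic axis, so a chain split across
#' the boundary gets a physically sensible centre of mass; the result is then
#' wrapped back into the box.
#'
#' @param topology A [bead_topology].
#' @param frame An [md_frame].
#' @param chain_id Chain id as stored in the topology.
#' @param pbc_aware Unwrap across periodic boundaries before averaging.
#' @return Numeric length-3 centre of mass (nm), inside the box.
#' @export
chain_center_of_mass <- function(topology, frame, chain_id, pbc_aware = TRUE) {
  idx <- which(topology$beads$chain_id == chain_id)
  if (!length(idx)) stop(sprintf("no such chain: %s", chain_id))
  m <- topology$beads$mass[idx]
  if (sum(m) <= 0) stop("chain has zero total mass")
  xyz <- frame$coords[idx, , drop = FALSE]
  if (pbc_aware)
    xyz <- unwrap_about_circular_mean(xyz, frame$box, m, frame$periodic)
  com <- colSums(xyz * m) / sum(m)
  if (pbc_aware) {
    com <- ifelse(frame$periodic, com %% frame$box, com)
  }
  as.numeric(com)
}

# Unwrap a bead sequence so consecutive beads are joined by minimum-image
# displacements. Errors if a nominal bond exceeds half the box on any axis.
unwrap_sequential <- function(coords, box, periodic = c(TRUE, TRUE, TRUE)) {
  n <- nrow(coords)
  if (n < 2L) return(coords)
  d <- coords[-1L, , drop = FALSE] - coords[-n, , drop = FALSE]
  d <- min_image_delta(d, box, periodic)
  # a nominal bond comparable to the box itself cannot be disambiguated
  # under minimum image; treat it as a broken chain
  if (any(sqrt(rowSums(d * d)) > min(box) / 4))
    stop("chain cannot be unwrapped: bond longer than a quarter of the box")
  cs <- apply(d, 2L, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1L)
  rbind(coords[1L, , drop = FALSE],
        matrix(coords[1L, ], n - 1L, 3L, byrow = TRUE) + cs)
}
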