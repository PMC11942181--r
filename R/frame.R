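#' Construct a simulation frame
#'
#' A frame holds bead coordinates (nm) in an orthorhombic periodic box.
#'
#' @param coords Numeric matrix, one row per bead, columns x, y, z in nm.
#' @param box Numeric length-3 vector of box edges (Lx, Ly, Lz) in nm.
#' @param time Frame time in ps.
#' @param periodic Logical length-3; periodicity per axis. The analyses in
#'   this package assume full periodicity, the flag exists for distance
#'   computations on open fixtures.
#' @return An object of class `md_frame`.
#' @export
md_frame <- function(coords, box, time = 0, periodic = c(TRUE, TRUE, TRUE)) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L)
    stop("coords must have three columns (x, y, z)")
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  box <- as.numeric(box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop("box must be three positive finite lengths (nm)")
  if (any(!is.finite(coords)))
    stop("all coordinates must be finite")
  structure(
    list(coords = coords, box = box, time = as.numeric(time),
         periodic = as.logical(periodic)),
    class = "md_frame"
  )
}

#' Construct a trajectory
#'
#' @param topology A [bead_topology] object.
#' @param frames List of [md_frame] objects sharing the topology.
#' @return An object of class `md_trajectory`.
#' @export
md_trajectory <- function(topology, frames) {
  stopifnot(inherits(topology, "bead_topology"))
  if (!length(frames)) stop("a trajectory needs at least one frame")
  nb <- nrow(topology$beads)
  times <- vapply(frames, function(f) f$time, numeric(1))
  for (f in frames) {
    if (!inherits(f, "md_frame")) stop("all frames must be md_frame objects")
    if (nrow(f$coords) != nb)
      stop(sprintf("frame has %d beads but topology has %d",
                   nrow(f$coords), nb))
  }
  if (is.unsorted(times))
    stop("frame times must be non-decreasing")
  structure(list(topology = topology, frames = frames),
            class = "md_trajectory")
}

#' @export
print.md_frame <- function(x, ...) {
  cat(sprintf("<md_frame> %d beads, box %.3f x %.3f x %.3f nm, t = %g ps\n",
              nrow(x$coords), x$box[1], x$box[2], x$box[3], x$time))
  invisible(x)
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory> %d frame(s), %d beads, %d chain(s)\n",
              length(x$frames), nrow(x$topology$beads),
              length(unique(x$topology$beads$chain_id))))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory An `md_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(trajectory) length(trajectory$frames)
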