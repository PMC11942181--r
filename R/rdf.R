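# Histogram of minimum-image pair distances between two coordinate sets,
# chunked over rows of A. Pairs can be excluded when they share a chain id
# or when they are the same bead. Returns counts per bin plus the number of
# candidate pairs (exclusions removed), which is the normalisation base.
.pair_histogram <- function(ca, cb, box, edges, chain_a = NULL,
                            chain_b = NULL, id_a = NULL, id_b = NULL,
                            exclude_same_chain = FALSE, chunk = 256L) {
  na <- nrow(ca)
  nb <- nrow(cb)
  rmax <- edges[length(edges)]
  counts <- numeric(length(edges) - 1L)
  n_pairs <- 0
  for (s in seq(1L, na, by = chunk)) {
    e <- min(s + chunk - 1L, na)
    rows <- s:e
    d2 <- matrix(0, length(rows), nb)
    for (ax in 1:3) {
      dd <- outer(ca[rows, ax], cb[, ax], "-")
      dd <- dd - box[ax] * round(dd / box[ax])
      d2 <- d2 + dd * dd
    }
    keep <- matrix(TRUE, length(rows), nb)
    if (!is.null(id_a))
      keep <- keep & outer(id_a[rows], id_b, "!=")
    if (exclude_same_chain)
      keep <- keep & outer(chain_a[rows], chain_b, "!=")
    n_pairs <- n_pairs + sum(keep)
    d <- sqrt(d2[keep])
    d <- d[d >= edges[1L] & d <= rmax]
    if (length(d)) {
      bin <- findInterval(d, edges, rightmost.closed = TRUE)
      counts <- counts + tabulate(bin, nbins = length(counts))
    }
  }
  list(counts = counts, n_pairs = n_pairs)
}

#' Radial distribution function between two bead selections
#'
#' Standard shell-normalised pair distribution under minimum image:
#' `g(r) = count(r) / (N_pairs * V_shell(r) / V_box)`, averaged over frames.
#' Self-pairs are always excluded; with `exclude_intrachain = TRUE` (the
#' default) pairs on the same chain are skipped as well, isolating the
#' inter-chain structure. `N_pairs` counts the candidate pairs after
#' exclusions, so an ideal-gas system plateaus at 1. In a two-phase slab the
#' full-box normalisation makes the dense-phase g(r) plateau above 1.
#'
#' @param trajectory An [md_trajectory].
#' @param selection_a,selection_b Integer vectors of 0-based bead ids.
#' @param r_range Distance range in nm (default 1e-5 to 2).
#' @param n_bins Number of bins (default 200).
#' @param exclude_intrachain Skip pairs on the same chain.
#' @return An `rdf_result`: data frame with `r` (bin centre) and `g`,
#'   attributes `counts`, `n_pairs`, `r_range`, `labels`.
#' @export
inter_rdf <- function(trajectory, selection_a, selection_b,
                      r_range = c(1e-5, 2.0), n_bins = 200L,
                      exclude_intrachain = TRUE) {
  if (!length(selection_a) || !length(selection_b))
    stop("selections must be non-empty")
  top <- trajectory$topology
  b <- top$beads
  ia <- selection_a + 1L
  ib <- selection_b + 1L
  if (any(ia < 1L | ia > nrow(b)) || any(ib < 1L | ib > nrow(b)))
    stop("selection contains invalid bead ids")
  edges <- seq(r_range[1L], r_range[2L], length.out = n_bins + 1L)
  counts <- numeric(n_bins)
  n_pairs_tot <- 0
  vbox_mean <- 0
  for (fr in trajectory$frames) {
    h <- .pair_histogram(fr$coords[ia, , drop = FALSE],
                         fr$coords[ib, , drop = FALSE],
                         fr$box, edges,
                         chain_a = b$chain_id[ia], chain_b = b$chain_id[ib],
                         id_a = b$bead_id[ia], id_b = b$bead_id[ib],
                         exclude_same_chain = exclude_intrachain)
    counts <- counts + h$counts
    n_pairs_tot <- n_pairs_tot + h$n_pairs
    vbox_mean <- vbox_mean + prod(fr$box)
  }
  nfr <- length(trajectory$frames)
  vbox <- vbox_mean / nfr
  shell <- 4 / 3 * pi * diff(edges^3)
  g <- if (n_pairs_tot > 0) counts / (n_pairs_tot * shell / vbox)
    else rep(NA_real_, n_bins)
  out <- data.frame(r = (edges[-1L] + edges[-length(edges)]) / 2, g = g)
  structure(out, counts = counts, n_pairs = n_pairs_tot / nfr,
            r_range = r_range, labels = c("A", "B"),
            class = c("rdf_result", "data.frame"))
}

#' Block-resolved RDF suite
#'
#' The three inter-chain radial distribution functions between the diblock
#' halves -- V-V, X-X and V-X -- with intra-chain pairs excluded. In a
#' microphase-separated condensate the first-shell self-block values g_VV
#' and g_XX exceed the cross-block g_VX; in a well-mixed one the three
#' curves agree.
#'
#' @param trajectory An [md_trajectory] with diblock annotations.
#' @inheritParams inter_rdf
#' @return Named list of three `rdf_result`s: `VV`, `XX`, `VX`.
#' @export
block_rdf_suite <- function(trajectory, r_range = c(1e-5, 2.0),
                            n_bins = 200L) {
  v <- select_beads(trajectory$topology, block = "V_BLOCK")
  x <- select_beads(trajectory$topology, block = "X_BLOCK")
  if (!length(v) || !length(x))
    stop("annotation error: trajectory has no diblock block labels")
  list(
    VV = inter_rdf(trajectory, v, v, r_range, n_bins),
    XX = inter_rdf(trajectory, x, x, r_range, n_bins),
    VX = inter_rdf(trajectory, v, x, r_range, n_bins))
}

#' Guest-environment RDFs
#'
#' Radial distribution functions from guest beads to the beads of each
#' residue type native to the template (V, P, G), with intra-chain pairs
#' *included* -- the local chemical environment of the guest, sequence
#' neighbours and all.
#'
#' @param trajectory An [md_trajectory].
#' @inheritParams inter_rdf
#' @return Named list of `rdf_result`s (`V`, `P`, `G`); empty list with
#'   attribute `no_guest = TRUE` when the system has no guest residues.
#' @export
guest_environment_rdf <- function(trajectory, r_range = c(1e-5, 2.0),
                                  n_bins = 200L) {
  top <- trajectory$topology
  guest <- top$beads$bead_id[top$beads$is_guest]
  if (!length(guest)) {
    out <- list()
    attr(out, "no_guest") <- TRUE
    return(out)
  }
  native <- c(V = "VAL", P = "PRO", G = "GLY")
  res <- lapply(native, function(r3) {
    ids <- top$beads$bead_id[top$beads$residue_name == r3 &
                               !top$beads$is_guest &
                               top$beads$block_label %in%
                               c("V_BLOCK", "X_BLOCK")]
    inter_rdf(trajectory, guest, ids, r_range, n_bins,
              exclude_intrachain = FALSE)
  })
  res
}

#' First-shell height of an RDF
#'
#' Maximum of g(r) over a short-range window, a simple scalar summary used
#' to compare self- and cross-block structuring.
#'
#' @param rdf An `rdf_result`.
#' @param window Distance window in nm (default 0.3-0.7, around the bond
#'   length scale of the coarse chains).
#' @return Numeric first-shell g value.
#' @export
rdf_first_shell <- function(rdf, window = c(0.3, 0.7)) {
  sel <- rdf$r >= window[1L] & rdf$r <= window[2L]
  if (!any(sel)) stop("window contains no bins")
  max(rdf$g[sel])
}
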