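#' Inter-chain residue contact map
#'
#' Contact frequencies between sequence positions on *different* chains: two
#' residues are in contact when any pair of their beads lies within `cutoff`
#' under minimum image. Entry (i, j) is the fraction of frames, averaged
#' over all ordered chain pairs and then symmetrised, in which position i on
#' one chain contacts position j on another. The diagonal is meaningful
#' (same position on different chains).
#'
#' @param trajectory An [md_trajectory] with at least two peptide chains.
#' @param cutoff Contact cutoff in nm (default 0.6).
#' @return A `contact_map`: numeric matrix (positions x positions) with
#'   attributes `cutoff` and `n_chain_pairs`.
#' @export
contact_map <- function(trajectory, cutoff = 0.6) {
  top <- trajectory$topology
  chains <- peptide_chain_ids(top)
  if (length(chains) < 2L)
    stop("inter-chain contact map undefined for a single chain")
  b <- top$beads
  # per-chain bead indices and residue positions
  bead_of <- lapply(chains, function(c) which(b$chain_id == c))
  pos_of <- lapply(bead_of, function(ix) b$residue_index[ix] + 1L)
  npos <- max(unlist(pos_of))
  inc <- lapply(seq_along(chains), function(k) {
    # bead -> position incidence matrix
    M <- matrix(0, length(bead_of[[k]]), npos)
    M[cbind(seq_along(bead_of[[k]]), pos_of[[k]])] <- 1
    M
  })
  acc <- matrix(0, npos, npos)
  nfr <- length(trajectory$frames)
  pairs <- utils::combn(seq_along(chains), 2L)
  for (fr in trajectory$frames) {
    for (p in seq_len(ncol(pairs))) {
      a <- pairs[1L, p]; c2 <- pairs[2L, p]
      d <- min_image_dist_matrix(fr$coords[bead_of[[a]], , drop = FALSE],
                                 fr$coords[bead_of[[c2]], , drop = FALSE],
                                 fr$box, fr$periodic)
      hit <- (d <= cutoff) * 1
      res_hit <- (t(inc[[a]]) %*% hit %*% inc[[c2]]) > 0
      acc <- acc + res_hit + t(res_hit)
    }
  }
  n_ordered <- length(chains) * (length(chains) - 1L)
  out <- acc / (n_ordered * nfr)
  structure(out, cutoff = cutoff, n_chain_pairs = ncol(pairs),
            class = c("contact_map", "matrix"))
}
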