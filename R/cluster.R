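#' Chain contact graph from centre-of-mass distances
#'
#' Nodes are peptide chains; an undirected edge joins two chains whose
#' PBC-aware centres of mass are within `cutoff` under the minimum-image
#' convention. This is the contact matrix the largest-cluster search runs
#' on.
#'
#' @param topology A `bead_topology`.
#' @param frame An [md_frame].
#' @param cutoff Centre-of-mass distance cutoff in nm (default 4).
#' @return An object of class `chain_graph`: list with `nodes` (chain ids)
#'   and `edges` (two-column matrix of chain-id pairs, i < j).
#' @export
chain_graph <- function(topology, frame, cutoff = 4.0) {
  chains <- peptide_chain_ids(topology)
  if (!length(chains)) stop("frame has no peptide chains")
  com <- t(vapply(chains, function(c)
    chain_center_of_mass(topology, frame, c), numeric(3)))
  d <- min_image_dist_matrix(com, com, frame$box, frame$periodic)
  hit <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  edges <- cbind(chains[hit[, 1L]], chains[hit[, 2L]])
  colnames(edges) <- c("i", "j")
  structure(list(nodes = chains, edges = edges, cutoff = cutoff),
            class = "chain_graph")
}

#' Largest connected chain cluster
#'
#' Depth-first search over the chain graph; returns the maximum-cardinality
#' connected component. Size ties are broken in favour of the component
#' containing the smallest chain id.
#'
#' @param graph A [chain_graph].
#' @return Integer vector of chain ids in the largest cluster, sorted.
#' @export
largest_cluster <- function(graph) {
  nodes <- graph$nodes
  if (!length(nodes)) stop("empty chain graph")
  idx <- seq_along(nodes)
  adj <- vector("list", length(nodes))
  if (nrow(graph$edges)) {
    ei <- match(graph$edges[, 1L], nodes)
    ej <- match(graph$edges[, 2L], nodes)
    for (k in seq_along(ei)) {
      adj[[ei[k]]] <- c(adj[[ei[k]]], ej[k])
      adj[[ej[k]]] <- c(adj[[ej[k]]], ei[k])
    }
  }
  comp <- integer(length(nodes))
  cid <- 0L
  for (s in idx) {                       # nodes visited in increasing id order
    if (comp[s] != 0L) next
    cid <- cid + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- cid
      nb <- adj[[v]]
      stack <- c(stack, nb[comp[nb] == 0L])
    }
  }
  sizes <- tabulate(comp, nbins = cid)
  # which.max takes the first maximum; components are numbered in order of
  # their smallest node, which implements the tie-break
  best <- which.max(sizes)
  sort(nodes[comp == best])
}

# Mass-weighted PBC-aware COM (z only) of a set of chains.
.cluster_com_z <- function(topology, frame, chains) {
  idx <- which(topology$beads$chain_id %in% chains)
  m <- topology$beads$mass[idx]
  z <- frame$coords[idx, 3L]
  L <- frame$box[3L]
  theta <- z * (2 * pi / L)
  w <- m / sum(m)
  ref <- atan2(sum(w * sin(theta)), sum(w * cos(theta))) * L / (2 * pi)
  dz <- z - ref
  zu <- ref + (dz - L * round(dz / L))
  sum(w * zu) %% L
}

#' Re-centre a frame on its largest chain cluster
#'
#' Translates the frame along z (with wrapping) so the PBC-aware centre of
#' mass of the largest peptide cluster sits at the box z-midpoint. Profile
#' functions report z relative to that midpoint, so the condensate centre is
#' labelled z = 0. x and y are untouched. The operation is idempotent and,
#' because a slab straddling the periodic boundary is detected through the
#' circular mean, such a slab becomes contiguous around the centre.
#'
#' @param topology A `bead_topology`.
#' @param frame An [md_frame].
#' @param cutoff Chain-graph cutoff passed to [chain_graph()].
#' @return The re-centred [md_frame].
#' @export
recenter_frame <- function(topology, frame, cutoff = 4.0) {
  cl <- largest_cluster(chain_graph(topology, frame, cutoff))
  zc <- .cluster_com_z(topology, frame, cl)
  L <- frame$box[3L]
  shift <- L / 2 - zc
  out <- frame
  out$coords[, 3L] <- (frame$coords[, 3L] + shift) %% L
  out
}

#' Re-centre every frame of a trajectory
#'
#' Applies [recenter_frame()] per frame (the condensate diffuses along z, so
#' each frame is aligned independently).
#'
#' @param trajectory An [md_trajectory].
#' @param cutoff Chain-graph cutoff (nm).
#' @return The re-centred [md_trajectory].
#' @export
recenter_trajectory <- function(trajectory, cutoff = 4.0) {
  trajectory$frames <- lapply(trajectory$frames, function(f)
    recenter_frame(trajectory$topology, f, cutoff))
  trajectory
}
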