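# Shared fixture builders. Everything is generated in code; seeds are fixed
# per call site so tests are reproducible.

# n single-bead "chains" (ideal gas style) at uniform random positions.
random_gas <- function(n, box = c(5, 5, 5), seed = 1) {
  set.seed(seed)
  top <- condstat:::.homopolymer_topology(1L, n)
  f <- md_frame(cbind(runif(n, 0, box[1]), runif(n, 0, box[2]),
                      runif(n, 0, box[3])), box)
  md_trajectory(top, list(f))
}

# Small diblock system with uniformly random coordinates (for oracles).
random_diblock <- function(n_chains = 3, n_repeats = 1, box = c(3, 3, 3),
                           seed = 1, guest = "L") {
  set.seed(seed)
  top <- build_diblock_topology(guest, n_repeats, n_chains)
  n <- nrow(top$beads)
  f <- md_frame(cbind(runif(n, 0, box[1]), runif(n, 0, box[2]),
                      runif(n, 0, box[3])), box)
  md_trajectory(top, list(f))
}

# Condensate fixture helper with the geometry used across the suite.
condensate_fixture <- function(kind, seed, n_frames = 4, phi_p = 1,
                               n_chains = 48, recenter = TRUE, ...) {
  spec <- morphology_spec(kind, box = c(12, 12, 24), slab_width = 10,
                          phi_p = phi_p, n_chains = n_chains,
                          n_repeats = 5, seed = seed, n_frames = n_frames,
                          ...)
  tr <- generate_condensate(spec)
  if (recenter) tr <- recenter_trajectory(tr)
  tr
}

# Independent connected-components oracle built on igraph.
igraph_largest <- function(graph) {
  skip_if_not_installed("igraph")
  ids <- graph$nodes
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  if (nrow(graph$edges))
    g <- igraph::add_edges(g, rbind(match(graph$edges[, 1], ids),
                                    match(graph$edges[, 2], ids)))
  comp <- igraph::components(g)
  best_size <- max(comp$csize)
  cand <- which(comp$csize == best_size)
  # tie-break: component containing the smallest chain id
  first_node <- sapply(cand, function(k) min(ids[comp$membership == k]))
  best <- cand[which.min(first_node)]
  sort(ids[comp$membership == best])
}

# An ATOMISTIC_LITE diblock with arbitrary (well-separated) coordinates:
# each residue's atoms are placed in a compact cluster on a coarse grid.
atomistic_fixture <- function(guest = "A", n_repeats = 1, seed = 1) {
  set.seed(seed)
  top <- build_diblock_topology(guest, n_repeats, 1L, "ATOMISTIC_LITE")
  b <- top$beads
  nres <- length(unique(b$residue_id))
  k <- ceiling(sqrt(nres))
  centres <- cbind((seq_len(nres) - 1) %% k, (seq_len(nres) - 1) %/% k, 0) * 2 + 1
  coords <- matrix(0, nrow(b), 3)
  for (r in unique(b$residue_id)) {
    ix <- which(b$residue_id == r)
    local <- matrix(runif(length(ix) * 3, -0.2, 0.2), length(ix), 3)
    coords[ix, ] <- sweep(local, 2, centres[r + 1, ], "+")
  }
  md_trajectory(top, list(md_frame(coords, c(2 * k + 2, 2 * k + 2, 4))))
}

# Single free oxygen atoms (water beads carry the O radius).
oxygen_frame <- function(points, box = c(20, 20, 20)) {
  n <- nrow(points)
  meta <- data.frame(chain_id = seq_len(n) - 1L, residue_index = 0L,
                     residue_name = "SOL", block_label = "SOLVENT",
                     is_guest = FALSE)
  top <- condstat:::.assemble(rep(list(condstat:::.water_beads("CA")), n),
                              meta, "ATOMISTIC_LITE")
  list(top = top, frame = md_frame(points, box))
}
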