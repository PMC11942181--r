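#' Bead topologies
#'
#' A `bead_topology` describes the chemical identity of every bead in the
#' system: chain membership, residue names, diblock block labels
#' (`V_BLOCK` / `X_BLOCK` / `SOLVENT` / `ION`), guest flags, element, mass and
#' hydrogen-bond annotations. Coordinates live in [md_frame] objects; a
#' topology plus frames makes an [md_trajectory].
#'
#' Beads are numbered by a contiguous 0-based `bead_id` over the whole system
#' (row `i` of `$beads` is bead `i - 1`). Hydrogen beads reference their donor
#' heavy atom through `donor_id`.
#'
#' @name bead_topology
#' @keywords internal
NULL

.new_topology <- function(beads, bonds, resolution) {
  beads$bead_id <- seq_len(nrow(beads)) - 1L
  rownames(beads) <- NULL
  structure(list(beads = beads, bonds = bonds, resolution = resolution),
            class = "bead_topology")
}

#' @export
print.bead_topology <- function(x, ...) {
  b <- x$beads
  cat(sprintf(
    "<bead_topology> %s: %d beads, %d residues, %d chains (%d peptide)\n",
    x$resolution, nrow(b), length(unique(b$residue_id)),
    length(unique(b$chain_id)), length(peptide_chain_ids(x))))
  invisible(x)
}

# One-residue bead block (no ids yet). Returns list(beads=df, bonds=df of
# local row indices 1..n, i<j).
.residue_beads <- function(res3, resolution) {
  if (resolution == "CA") {
    beads <- data.frame(
      name = "CA", element = "C", mass = .RESIDUE_MASS[[res3]],
      is_heavy = TRUE, is_donor = FALSE, is_acceptor = FALSE,
      is_hydrogen = FALSE, donor_local = NA_integer_,
      stringsAsFactors = FALSE)
    return(list(beads = beads, bonds = NULL))
  }
  if (resolution == "CG4") {
    bb_mass <- .ELEMENT_MASS[["N"]] + 2 * .ELEMENT_MASS[["C"]] +
      .ELEMENT_MASS[["O"]]
    sc <- .AA_SIDECHAIN[[res3]]
    n_side <- if (is.null(sc)) 0L else ceiling(nrow(sc) / 4)
    nm <- c("BB", if (n_side > 0) paste0("SC", seq_len(n_side)))
    sc_mass <- if (is.null(sc)) 0 else sum(.ELEMENT_MASS[sc$element])
    mass <- c(bb_mass, rep(sc_mass / max(n_side, 1L), n_side))
    beads <- data.frame(
      name = nm, element = "C", mass = mass, is_heavy = TRUE,
      is_donor = FALSE, is_acceptor = FALSE, is_hydrogen = FALSE,
      donor_local = NA_integer_, stringsAsFactors = FALSE)
    bonds <- if (n_side > 0) data.frame(i = seq_len(n_side), j = seq_len(n_side) + 1L)
      else NULL
    return(list(beads = beads, bonds = bonds))
  }
  # ATOMISTIC_LITE: heavy atoms + polar hydrogens with ideal-geometry roles.
  n_is_donor <- res3 != "PRO"
  rows <- list(
    data.frame(name = "N", element = "N", mass = .ELEMENT_MASS[["N"]],
               is_heavy = TRUE, is_donor = n_is_donor, is_acceptor = FALSE,
               is_hydrogen = FALSE, donor_local = NA_integer_,
               stringsAsFactors = FALSE))
  bonds <- list()
  if (n_is_donor) {
    rows <- c(rows, list(
      data.frame(name = "H", element = "H", mass = .ELEMENT_MASS[["H"]],
                 is_heavy = FALSE, is_donor = FALSE, is_acceptor = FALSE,
                 is_hydrogen = TRUE, donor_local = 1L,
                 stringsAsFactors = FALSE)))
    bonds <- c(bonds, list(c(1L, 2L)))
  }
  atom <- function(name, element, don = FALSE, acc = FALSE) {
    data.frame(name = name, element = element,
               mass = .ELEMENT_MASS[[element]], is_heavy = TRUE,
               is_donor = don, is_acceptor = acc, is_hydrogen = FALSE,
               donor_local = NA_integer_, stringsAsFactors = FALSE)
  }
  i_ca <- length(rows) + 1L
  rows <- c(rows, list(atom("CA", "C"), atom("C", "C"),
                       atom("O", "O", acc = TRUE)))
  bonds <- c(bonds, list(c(1L, i_ca), c(i_ca, i_ca + 1L),
                         c(i_ca + 1L, i_ca + 2L)))
  sc <- .AA_SIDECHAIN[[res3]]
  if (!is.null(sc)) {
    prev <- i_ca  # side chain hangs off CA, recorded as a linear walk
    for (k in seq_len(nrow(sc))) {
      rows <- c(rows, list(atom(sc$name[k], sc$element[k],
                                don = sc$don[k], acc = sc$acc[k])))
      here <- length(rows)
      bonds <- c(bonds, list(c(prev, here)))
      if (sc$don[k] && sc$nh[k] > 0L) {
        for (h in seq_len(sc$nh[k])) {
          rows <- c(rows, list(
            data.frame(name = paste0("H", sc$name[k],
                                     if (sc$nh[k] > 1L) h else ""),
                       element = "H", mass = .ELEMENT_MASS[["H"]],
                       is_heavy = FALSE, is_donor = FALSE,
                       is_acceptor = FALSE, is_hydrogen = TRUE,
                       donor_local = here, stringsAsFactors = FALSE)))
          bonds <- c(bonds, list(c(here, length(rows))))
        }
      }
      prev <- here
    }
  }
  beads <- do.call(rbind, rows)
  bonds <- do.call(rbind, lapply(bonds, function(p) data.frame(i = p[1], j = p[2])))
  list(beads = beads, bonds = bonds)
}

.water_beads <- function(resolution) {
  if (resolution == "ATOMISTIC_LITE") {
    beads <- data.frame(
      name = c("OW", "HW1", "HW2"), element = c("O", "H", "H"),
      mass = c(.ELEMENT_MASS[["O"]], .ELEMENT_MASS[["H"]], .ELEMENT_MASS[["H"]]),
      is_heavy = c(TRUE, FALSE, FALSE),
      is_donor = c(TRUE, FALSE, FALSE),
      is_acceptor = c(TRUE, FALSE, FALSE),
      is_hydrogen = c(FALSE, TRUE, TRUE),
      donor_local = c(NA_integer_, 1L, 1L), stringsAsFactors = FALSE)
    bonds <- data.frame(i = c(1L, 1L), j = c(2L, 3L))
  } else {
    # single-bead water carries the whole molecular mass
    beads <- data.frame(
      name = "OW", element = "O", mass = .WATER_MASS, is_heavy = TRUE,
      is_donor = FALSE, is_acceptor = FALSE, is_hydrogen = FALSE,
      donor_local = NA_integer_, stringsAsFactors = FALSE)
    bonds <- NULL
  }
  list(beads = beads, bonds = bonds)
}

.ion_beads <- function(kind) {
  el <- if (kind == "NA") "Na" else "Cl"
  beads <- data.frame(
    name = kind, element = el, mass = .ELEMENT_MASS[[el]], is_heavy = TRUE,
    is_donor = FALSE, is_acceptor = FALSE, is_hydrogen = FALSE,
    donor_local = NA_integer_, stringsAsFactors = FALSE)
  list(beads = beads, bonds = NULL)
}

# Assemble residues (list of .residue_beads results + metadata) into the flat
# bead table. `meta` is a data.frame with one row per residue: chain_id,
# residue_index, residue_name, block_label, is_guest.
.assemble <- function(units, meta, resolution, link_backbone = FALSE) {
  counts <- vapply(units, function(u) nrow(u$beads), integer(1))
  offset <- cumsum(c(0L, counts[-length(counts)]))
  beads <- do.call(rbind, lapply(units, `[[`, "beads"))
  n <- nrow(beads)
  rep_meta <- meta[rep(seq_len(nrow(meta)), counts), , drop = FALSE]
  beads <- cbind(
    data.frame(chain_id = rep_meta$chain_id,
               residue_id = rep(seq_len(nrow(meta)) - 1L, counts),
               residue_index = rep_meta$residue_index,
               residue_name = rep_meta$residue_name,
               block_label = rep_meta$block_label,
               is_guest = rep_meta$is_guest, stringsAsFactors = FALSE),
    beads)
  # donor_local -> global donor_id (0-based)
  donor_id <- rep(NA_integer_, n)
  loc <- beads$donor_local
  has <- !is.na(loc)
  donor_id[has] <- rep(offset, counts)[has] + loc[has] - 1L
  beads$donor_id <- donor_id
  beads$donor_local <- NULL
  bonds <- lapply(seq_along(units), function(k) {
    b <- units[[k]]$bonds
    if (is.null(b)) return(NULL)
    data.frame(i = b$i - 1L + offset[k], j = b$j - 1L + offset[k])
  })
  bonds <- do.call(rbind, bonds)
  if (link_backbone) {
    # peptide bond C(i) -> N(i+1) within each chain
    extra <- list()
    for (k in seq_len(nrow(meta) - 1L)) {
      if (meta$chain_id[k] != meta$chain_id[k + 1L]) next
      if (!(meta$block_label[k] %in% c("V_BLOCK", "X_BLOCK"))) next
      ci <- which(units[[k]]$beads$name == "C")
      nj <- which(units[[k + 1L]]$beads$name == "N")
      if (length(ci) == 1L && length(nj) == 1L) {
        extra[[length(extra) + 1L]] <-
          data.frame(i = offset[k] + ci - 1L, j = offset[k + 1L] + nj - 1L)
      }
    }
    if (length(extra)) bonds <- rbind(bonds, do.call(rbind, extra))
  }
  .new_topology(beads, bonds, resolution)
}

#' Build a diblock ELP topology
#'
#' Expands the diblock template (V-P-G-V-G)n-(V-P-G-X-G)n into `n_chains`
#' identical chains. The first half of each chain is labelled `V_BLOCK`, the
#' second half `X_BLOCK`, and the X position of every second-half pentamer
#' carries `is_guest = TRUE`. The guest may be any standard amino acid except
#' proline, which the template forbids at the X position.
#'
#' Resolutions:
#' * `"CA"` - one bead per residue (coarse); bead mass is the residue's
#'   heavy-atom mass.
#' * `"CG4"` - backbone bead plus up to three side-chain beads of roughly
#'   four heavy atoms each.
#' * `"ATOMISTIC_LITE"` - heavy atoms plus polar hydrogens, annotated with
#'   hydrogen-bond roles (backbone N-H donors, backbone O and side-chain O/N
#'   acceptors); required by the hydrogen-bond and SASA analyses.
#'
#' @param guest 1-letter amino-acid code of the guest residue X.
#' @param n_repeats Number of pentamer repeats per block (the study condition
#'   is 5).
#' @param n_chains Number of chains.
#' @param resolution One of `"CA"`, `"CG4"`, `"ATOMISTIC_LITE"`.
#' @return A `bead_topology`.
#' @export
#' @examples
#' top <- build_diblock_topology("A", n_repeats = 5, n_chains = 1)
#' table(top$beads$block_label)
build_diblock_topology <- function(guest, n_repeats, n_chains = 1L,
                                   resolution = c("CA", "CG4",
                                                  "ATOMISTIC_LITE")) {
  resolution <- match.arg(resolution)
  if (!is.character(guest) || length(guest) != 1L || !(guest %in% .AA1))
    stop("guest must be a 1-letter code of a standard amino acid")
  if (guest == "P")
    stop("template violation: proline is not allowed at the guest position")
  n_repeats <- as.integer(n_repeats)
  n_chains <- as.integer(n_chains)
  if (is.na(n_repeats) || n_repeats <= 0L) stop("n_repeats must be positive")
  if (is.na(n_chains) || n_chains <= 0L) stop("n_chains must be positive")

  seq1 <- c(rep(c("V", "P", "G", "V", "G"), n_repeats),
            rep(c("V", "P", "G", guest, "G"), n_repeats))
  res3 <- unname(.AA3[seq1])
  nres <- length(seq1)
  half <- nres / 2L
  block <- rep(c("V_BLOCK", "X_BLOCK"), each = half)
  is_guest <- rep(FALSE, nres)
  is_guest[half + 5L * (seq_len(n_repeats) - 1L) + 4L] <- TRUE

  units <- vector("list", nres * n_chains)
  meta <- data.frame(
    chain_id = rep(seq_len(n_chains) - 1L, each = nres),
    residue_index = rep(seq_len(nres) - 1L, n_chains),
    residue_name = rep(res3, n_chains),
    block_label = rep(block, n_chains),
    is_guest = rep(is_guest, n_chains), stringsAsFactors = FALSE)
  proto <- lapply(unique(res3), function(r) .residue_beads(r, resolution))
  names(proto) <- unique(res3)
  for (k in seq_len(nrow(meta))) units[[k]] <- proto[[meta$residue_name[k]]]
  .assemble(units, meta, resolution,
            link_backbone = resolution == "ATOMISTIC_LITE")
}

#' Append solvent and ion molecules to a topology
#'
#' Each water molecule (single `OW` bead at coarse resolutions, O plus two
#' hydrogens at `ATOMISTIC_LITE`) and each Na+/Cl- ion becomes its own chain
#' and residue, labelled `SOLVENT` / `ION`.
#'
#' @param topology A `bead_topology`.
#' @param n_water,n_na,n_cl Numbers of waters and ions to append.
#' @return The extended `bead_topology`.
#' @export
add_solvent <- function(topology, n_water = 0L, n_na = 0L, n_cl = 0L) {
  n_new <- n_water + n_na + n_cl
  if (n_new == 0L) return(topology)
  res <- topology$resolution
  w <- .water_beads(res)
  units <- c(rep(list(w), n_water),
             rep(list(.ion_beads("NA")), n_na),
             rep(list(.ion_beads("CL")), n_cl))
  chain0 <- max(topology$beads$chain_id) + 1L
  meta <- data.frame(
    chain_id = chain0 + seq_len(n_new) - 1L,
    residue_index = 0L,
    residue_name = c(rep("SOL", n_water), rep("NA", n_na), rep("CL", n_cl)),
    block_label = c(rep("SOLVENT", n_water), rep("ION", n_na + n_cl)),
    is_guest = FALSE, stringsAsFactors = FALSE)
  extra <- .assemble(units, meta, res)
  nb0 <- nrow(topology$beads)
  eb <- extra$beads
  eb$bead_id <- eb$bead_id + nb0
  eb$residue_id <- eb$residue_id + max(topology$beads$residue_id) + 1L
  eb$donor_id <- eb$donor_id + nb0
  bonds <- extra$bonds
  if (!is.null(bonds)) bonds <- data.frame(i = bonds$i + nb0, j = bonds$j + nb0)
  beads <- rbind(topology$beads, eb)
  beads$bead_id <- seq_len(nrow(beads)) - 1L
  structure(list(beads = beads,
                 bonds = rbind(topology$bonds, bonds),
                 resolution = res),
            class = "bead_topology")
}

#' Peptide chain ids of a topology
#' @param topology A `bead_topology`.
#' @return Integer vector of chain ids whose residues belong to the diblock.
#' @export
peptide_chain_ids <- function(topology) {
  b <- topology$beads
  sort(unique(b$chain_id[b$block_label %in% c("V_BLOCK", "X_BLOCK")]))
}

#' Residue-level view of a topology
#' @param topology A `bead_topology`.
#' @return Data frame with one row per residue (residue_id, chain_id,
#'   residue_index, residue_name, block_label, is_guest).
#' @export
residue_table <- function(topology) {
  b <- topology$beads
  first <- !duplicated(b$residue_id)
  data.frame(residue_id = b$residue_id[first], chain_id = b$chain_id[first],
             residue_index = b$residue_index[first],
             residue_name = b$residue_name[first],
             block_label = b$block_label[first],
             is_guest = b$is_guest[first], stringsAsFactors = FALSE)
}

#' Select bead ids by topology attributes
#'
#' @param topology A `bead_topology`.
#' @param block Optional block label(s) to keep.
#' @param residue_name Optional residue name(s) to keep.
#' @param guest If `TRUE`, keep guest residues only.
#' @param heavy_only Keep heavy atoms only.
#' @return Integer vector of 0-based bead ids.
#' @export
select_beads <- function(topology, block = NULL, residue_name = NULL,
                         guest = FALSE, heavy_only = FALSE) {
  b <- topology$beads
  keep <- rep(TRUE, nrow(b))
  if (!is.null(block)) keep <- keep & b$block_label %in% block
  if (!is.null(residue_name)) keep <- keep & b$residue_name %in% residue_name
  if (guest) keep <- keep & b$is_guest
  if (heavy_only) keep <- keep & b$is_heavy
  b$bead_id[keep]
}

#' Hydrogen-bond role of each bead
#'
#' @param topology A `bead_topology`.
#' @return Character vector: `"DONOR_HEAVY"`, `"ACCEPTOR_HEAVY"`,
#'   `"DONOR_ACCEPTOR"` (e.g. hydroxyls, water oxygen), `"HYDROGEN"` or
#'   `"NONE"`, one per bead.
#' @export
hb_roles <- function(topology) {
  b <- topology$beads
  out <- rep("NONE", nrow(b))
  out[b$is_donor & !b$is_acceptor] <- "DONOR_HEAVY"
  out[!b$is_donor & b$is_acceptor] <- "ACCEPTOR_HEAVY"
  out[b$is_donor & b$is_acceptor] <- "DONOR_ACCEPTOR"
  out[b$is_hydrogen] <- "HYDROGEN"
  out
}
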