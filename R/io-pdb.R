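#' Read a PDB coordinate file
#'
#' Supports the CRYST1/MODEL dialect: `CRYST1` supplies the (orthorhombic)
#' periodic box and `MODEL`/`ENDMDL` pairs delimit frames. Coordinates are
#' converted from Angstrom to nm at the boundary. A missing `CRYST1` record
#' is an error, because every analysis in this package assumes a periodic
#' box.
#'
#' @param path PDB file path.
#' @param annot Optional sidecar annotation CSV (see [write_annotation()]).
#' @return An [md_trajectory].
#' @export
read_pdb <- function(path, annot = NULL) {
  lines <- readLines(path)
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cr))
    stop("PDB parse error: CRYST1 record required (analyses are periodic)")
  box <- as.numeric(c(substr(cr[1L], 7L, 15L), substr(cr[1L], 16L, 24L),
                      substr(cr[1L], 25L, 33L))) / 10
  if (any(is.na(box)) || any(box <= 0))
    stop("PDB parse error: malformed CRYST1 box")
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  if (!length(model_starts)) {
    frame_of <- rep(1L, sum(is_atom))
  } else {
    model_id <- cumsum(grepl("^MODEL", lines))
    frame_of <- model_id[is_atom]
    if (any(frame_of == 0L))
      stop("PDB parse error: ATOM record before first MODEL")
  }
  al <- lines[is_atom]
  if (!length(al)) stop("PDB parse error: no ATOM records")
  name <- trimws(substr(al, 13L, 16L))
  resname <- trimws(substr(al, 18L, 20L))
  chain <- substr(al, 22L, 22L)
  resseq <- suppressWarnings(as.integer(substr(al, 23L, 26L)))
  x <- suppressWarnings(as.numeric(substr(al, 31L, 38L))) / 10
  y <- suppressWarnings(as.numeric(substr(al, 39L, 46L))) / 10
  z <- suppressWarnings(as.numeric(substr(al, 47L, 54L))) / 10
  bad <- which(is.na(x) | is.na(y) | is.na(z) | is.na(resseq))
  if (length(bad))
    stop(sprintf("PDB parse error: malformed ATOM record (record %d)", bad[1L]))

  nfr <- max(frame_of)
  per_frame <- split(seq_along(al), frame_of)
  n0 <- length(per_frame[[1L]])
  frames <- vector("list", nfr)
  for (k in seq_len(nfr)) {
    ix <- per_frame[[k]]
    if (length(ix) != n0)
      stop(sprintf("PDB parse error: frame %d has %d atoms, frame 1 had %d",
                   k, length(ix), n0))
    frames[[k]] <- md_frame(cbind(x[ix], y[ix], z[ix]), box, time = k - 1)
  }
  ix0 <- per_frame[[1L]]
  # chain letter changes take priority; residue-number resets split solvent
  part <- .partition_atoms(resseq[ix0], resname[ix0], name[ix0])
  ch <- chain[ix0]
  brk <- c(TRUE, ch[-1L] != ch[-length(ch)] | diff(part$chain_uid) != 0L)
  chain_uid <- cumsum(brk)
  atoms0 <- data.frame(name = name[ix0], resname = resname[ix0],
                       residue_uid = part$residue_uid, chain_uid = chain_uid,
                       stringsAsFactors = FALSE)
  topology <- .topology_from_atoms(atoms0, quiet = !is.null(annot))
  if (!is.null(annot)) topology <- .apply_annotation(topology, annot)
  md_trajectory(topology, frames)
}

#' Write a PDB coordinate file
#'
#' Writes `CRYST1` from the first frame's box and one `MODEL`/`ENDMDL` block
#' per frame; coordinates are converted from nm to Angstrom. Peptide chains
#' get chain identifiers `A`, `B`, ... (cycling); solvent and ions share the
#' identifier `W`.
#'
#' @param trajectory An [md_trajectory].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(trajectory, path) {
  b <- trajectory$topology$beads
  pep <- peptide_chain_ids(trajectory$topology)
  chain_letter <- ifelse(b$chain_id %in% pep,
                         LETTERS[(match(b$chain_id, pep) - 1L) %% 26L + 1L],
                         "W")
  resnum <- integer(nrow(b))
  for (ix in split(seq_len(nrow(b)), b$chain_id)) {
    resnum[ix] <- match(b$residue_id[ix], unique(b$residue_id[ix]))
  }
  resnum <- ((resnum - 1L) %% 9999L) + 1L
  serial <- (b$bead_id %% 99999L) + 1L
  el <- toupper(b$element)
  con <- file(path, "w")
  on.exit(close(con))
  box <- trajectory$frames[[1L]]$box * 10
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     box[1L], box[2L], box[3L], 90, 90, 90), con)
  for (k in seq_along(trajectory$frames)) {
    fr <- trajectory$frames[[k]]
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      serial, substr(b$name, 1L, 4L), substr(b$residue_name, 1L, 3L),
      chain_letter, resnum,
      fr$coords[, 1L] * 10, fr$coords[, 2L] * 10, fr$coords[, 3L] * 10,
      substr(el, 1L, 2L)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
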