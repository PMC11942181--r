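#' Read a GRO coordinate file
#'
#' Reads single- or multi-frame (concatenated) GRO files. Coordinates are
#' nm, as native to the format; velocities, if present, are ignored. Chain
#' partitioning is recovered from residue-number restarts (the convention
#' used by [write_gro()]); block and guest annotations are reconstructed by
#' matching the residue sequence against the diblock template, or taken from
#' a sidecar annotation file written by [write_annotation()].
#'
#' @param path GRO file path.
#' @param annot Optional sidecar annotation CSV path.
#' @return An [md_trajectory].
#' @export
read_gro <- function(path, annot = NULL) {
  lines <- readLines(path)
  frames <- list()
  atoms0 <- NULL
  pos <- 1L
  frame_idx <- 0L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos])) && pos == length(lines)) break
    frame_idx <- frame_idx + 1L
    if (pos + 1L > length(lines))
      stop(sprintf("GRO parse error: file truncated in frame %d (line %d)",
                   frame_idx, pos))
    title <- lines[pos]
    natoms <- suppressWarnings(as.integer(trimws(lines[pos + 1L])))
    if (is.na(natoms) || natoms <= 0L)
      stop(sprintf("GRO parse error: bad atom count at line %d", pos + 1L))
    last <- pos + 1L + natoms + 1L
    if (last > length(lines))
      stop(sprintf("GRO parse error: file truncated in frame %d (expected %d atom lines after line %d)",
                   frame_idx, natoms, pos + 1L))
    al <- lines[(pos + 2L):(pos + 1L + natoms)]
    bad <- which(nchar(al) < 44L)
    if (length(bad))
      stop(sprintf("GRO parse error: short atom line %d", pos + 1L + bad[1L]))
    resnum <- as.integer(substr(al, 1L, 5L))
    resname <- trimws(substr(al, 6L, 10L))
    name <- trimws(substr(al, 11L, 15L))
    x <- as.numeric(substr(al, 21L, 28L))
    y <- as.numeric(substr(al, 29L, 36L))
    z <- as.numeric(substr(al, 37L, 44L))
    if (any(is.na(resnum)) || any(is.na(x)) || any(is.na(y)) || any(is.na(z)))
      stop(sprintf("GRO parse error: malformed atom record near line %d in frame %d",
                   pos + 1L + which(is.na(x) | is.na(y) | is.na(z) | is.na(resnum))[1L],
                   frame_idx))
    boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[last]), "\\s+")[[1L]]))
    if (length(boxv) < 3L || any(is.na(boxv[1:3])))
      stop(sprintf("GRO parse error: missing box line at line %d (frame %d)",
                   last, frame_idx))
    time <- frame_idx - 1
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    if (length(tm)) time <- as.numeric(sub("t=\\s*", "", tm))
    if (is.null(atoms0)) {
      part <- .partition_atoms(resnum, resname, name)
      atoms0 <- data.frame(name = name, resname = resname,
                           residue_uid = part$residue_uid,
                           chain_uid = part$chain_uid,
                           stringsAsFactors = FALSE)
    } else if (natoms != nrow(atoms0)) {
      stop(sprintf("GRO parse error: frame %d has %d atoms, frame 1 had %d",
                   frame_idx, natoms, nrow(atoms0)))
    }
    frames[[frame_idx]] <- md_frame(cbind(x, y, z), boxv[1:3], time = time)
    pos <- last + 1L
  }
  if (!length(frames)) stop("GRO parse error: empty file")
  topology <- .topology_from_atoms(atoms0, quiet = !is.null(annot))
  if (!is.null(annot)) topology <- .apply_annotation(topology, annot)
  md_trajectory(topology, frames)
}

#' Write a GRO coordinate file
#'
#' Multi-frame trajectories are written as concatenated GRO frames.
#' Coordinates are written at the format's 3-decimal (nm) precision; residue
#' numbering restarts at 1 for every molecule so that chain partitioning
#' round-trips through [read_gro()].
#'
#' @param trajectory An [md_trajectory].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gro <- function(trajectory, path) {
  b <- trajectory$topology$beads
  # per-molecule residue numbering (1-based within each chain)
  resnum <- integer(nrow(b))
  for (ix in split(seq_len(nrow(b)), b$chain_id)) {
    resnum[ix] <- match(b$residue_id[ix], unique(b$residue_id[ix]))
  }
  resnum <- ((resnum - 1L) %% 99999L) + 1L
  atomnum <- ((b$bead_id) %% 99999L) + 1L
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in trajectory$frames) {
    head <- sprintf("condstat frame t= %.4f", fr$time)
    body <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                    resnum, substr(b$residue_name, 1L, 5L),
                    substr(b$name, 1L, 5L), atomnum,
                    fr$coords[, 1L], fr$coords[, 2L], fr$coords[, 3L])
    writeLines(c(head, sprintf("%5d", nrow(b)), body,
                 sprintf("%10.5f%10.5f%10.5f", fr$box[1L], fr$box[2L], fr$box[3L])),
               con)
  }
  invisible(path)
}
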