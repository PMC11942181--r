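#' Pressure-tensor series
#'
#' Holds per-frame diagonal pressure-tensor components (bar) together with
#' the box height `Lz` (nm) and the number of protein droplets `N` -- the
#' quantities entering the slab-method surface tension
#' tau = Lz / (2 N) * (Pzz - (Pxx + Pyy) / 2).
#'
#' @param time Time values (ps).
#' @param pxx,pyy,pzz Diagonal pressure components (bar).
#' @param Lz Box height (nm); scalar or one value per row.
#' @param n_droplets Number of protein droplets in the box.
#' @return An object of class `pressure_series` (a data frame with
#'   attributes `Lz` and `n_droplets`).
#' @export
pressure_series <- function(time, pxx, pyy, pzz, Lz, n_droplets = 1L) {
  n <- length(time)
  if (!all(lengths(list(pxx, pyy, pzz)) == n))
    stop("time, pxx, pyy, pzz must have equal length")
  if (n < 1L) stop("a pressure series needs at least one row")
  Lz <- as.numeric(Lz)
  if (!(length(Lz) %in% c(1L, n)) || any(Lz <= 0) || any(!is.finite(Lz)))
    stop("Lz must be positive (scalar or one value per row)")
  n_droplets <- as.integer(n_droplets)
  if (is.na(n_droplets) || n_droplets < 1L) stop("n_droplets must be >= 1")
  out <- data.frame(time = as.numeric(time), pxx = as.numeric(pxx),
                    pyy = as.numeric(pyy), pzz = as.numeric(pzz))
  if (any(!is.finite(as.matrix(out)))) stop("pressure series must be finite")
  structure(out, Lz = Lz, n_droplets = n_droplets,
            class = c("pressure_series", "data.frame"))
}

#' Read a pressure series from an XVG-style table
#'
#' Whitespace-separated numeric table; lines starting with `#` or `@` are
#' comments. Column roles are declared through `columns` (1-based indices)
#' so tables with extra columns can be mapped explicitly.
#'
#' @param path File path.
#' @param Lz Box height in nm.
#' @param n_droplets Number of protein droplets.
#' @param columns Named integer vector mapping `time`, `pxx`, `pyy`, `pzz`
#'   to column indices.
#' @return A [pressure_series].
#' @export
read_pressure_xvg <- function(path, Lz, n_droplets = 1L,
                              columns = c(time = 1L, pxx = 2L, pyy = 3L,
                                          pzz = 4L)) {
  need <- c("time", "pxx", "pyy", "pzz")
  if (!all(need %in% names(columns)))
    stop("columns must name time, pxx, pyy and pzz")
  lines <- readLines(path)
  keep <- !grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  if (!length(rows)) stop(sprintf("%s: no data rows", path))
  parts <- strsplit(trimws(lines[rows]), "\\s+")
  ncol <- lengths(parts)
  if (any(ncol < max(columns[need])))
    stop(sprintf("%s: line %d has %d columns, need at least %d",
                 path, rows[which(ncol < max(columns[need]))[1L]],
                 min(ncol), max(columns[need])))
  vals <- suppressWarnings(
    vapply(parts, function(p) as.numeric(p[columns[need]]), numeric(4)))
  bad <- which(colSums(is.na(vals)) > 0L)
  if (length(bad))
    stop(sprintf("%s: non-numeric value at line %d", path, rows[bad[1L]]))
  pressure_series(vals[1L, ], vals[2L, ], vals[3L, ], vals[4L, ],
                  Lz = Lz, n_droplets = n_droplets)
}

#' Amino-acid scale table
#'
#' A named map from 1-letter amino-acid codes to values (hydrophobicity
#' scales, transition temperatures, ...) with a declared hydrophobic
#' orientation. The orientation is required before a scale can be normalised
#' onto \[0, 1\] with 1 at the hydrophobic end (see [normalize_scale()]).
#'
#' @param values Named numeric vector (names are 1-letter codes).
#' @param orientation `"HIGHER_IS_HYDROPHOBIC"`, `"LOWER_IS_HYDROPHOBIC"` or
#'   `"NONE"` (e.g. for transition temperatures).
#' @param label Free-text description.
#' @return An object of class `scale_table`.
#' @export
scale_table <- function(values, orientation = c("NONE",
                                                "HIGHER_IS_HYDROPHOBIC",
                                                "LOWER_IS_HYDROPHOBIC"),
                        label = "") {
  orientation <- match.arg(orientation)
  codes <- names(values)
  if (is.null(codes) || any(!nzchar(codes)))
    stop("values must be named by 1-letter amino-acid codes")
  if (anyDuplicated(codes))
    stop("duplicate amino-acid code: ", codes[duplicated(codes)][1L])
  unknown <- setdiff(codes, .AA1)
  if (length(unknown))
    stop("unknown amino-acid code: ", unknown[1L])
  if (length(values) > 20L) stop("at most 20 entries allowed")
  if (any(!is.finite(values))) stop("scale values must be finite")
  structure(list(values = values, orientation = orientation, label = label),
            class = "scale_table")
}

#' @export
print.scale_table <- function(x, ...) {
  cat(sprintf("<scale_table> %s (%s), %d entries\n",
              if (nzchar(x$label)) x$label else "unnamed",
              x$orientation, length(x$values)))
  invisible(x)
}

#' Look up scale values
#' @param scale A [scale_table].
#' @param aa 1-letter codes to look up.
#' @return Numeric values.
#' @export
scale_value <- function(scale, aa) {
  miss <- setdiff(aa, names(scale$values))
  if (length(miss))
    stop("amino acid missing from scale: ", paste(miss, collapse = ", "))
  unname(scale$values[aa])
}

#' Read an amino-acid scale from CSV
#'
#' The file has columns `aa,value` plus optional metadata comment lines
#' `# label: ...` and `# orientation: ...`. Arguments override file
#' metadata. Hydrophobicity scales must declare an orientation before they
#' can be normalised.
#'
#' @param path CSV path.
#' @param orientation Optional orientation override.
#' @param label Optional label override.
#' @return A [scale_table].
#' @export
read_scale_csv <- function(path, orientation = NULL, label = NULL) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    m <- grep(paste0("^#\\s*", key, "\\s*:"), meta, value = TRUE)
    if (!length(m)) return(NULL)
    trimws(sub(paste0("^#\\s*", key, "\\s*:"), "", m[1L]))
  }
  if (is.null(label)) label <- get_meta("label")
  if (is.null(label)) label <- basename(path)
  if (is.null(orientation)) orientation <- get_meta("orientation")
  if (is.null(orientation)) orientation <- "NONE"
  tab <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]),
                         stringsAsFactors = FALSE)
  if (!all(c("aa", "value") %in% names(tab)))
    stop(sprintf("%s: expected columns aa,value", path))
  if (any(is.na(tab$value)))
    stop(sprintf("%s: non-numeric value for %s", path,
                 tab$aa[which(is.na(tab$value))[1L]]))
  scale_table(stats::setNames(tab$value, tab$aa), orientation = orientation,
              label = label)
}
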