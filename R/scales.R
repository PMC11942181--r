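#' Normalise a hydrophobicity scale onto the unit interval
#'
#' Affine map with 1 at the most hydrophobic residue and 0 at the least
#' hydrophobic one, according to the scale's declared orientation (so scales
#' where lower values mean more hydrophobic, such as transfer free
#' energies, end up with 1 at their lowest value). Idempotent: a normalised
#' table maps to itself.
#'
#' @param scale A [scale_table] with a declared orientation.
#' @return A [scale_table] with values in \[0, 1\] and orientation
#'   `HIGHER_IS_HYDROPHOBIC`.
#' @export
normalize_scale <- function(scale) {
  stopifnot(inherits(scale, "scale_table"))
  if (scale$orientation == "NONE")
    stop("normalization undefined: scale has no declared hydrophobic ",
         "orientation")
  v <- scale$values
  rng <- range(v)
  if (diff(rng) == 0) stop("degenerate scale: all values equal")
  out <- if (scale$orientation == "HIGHER_IS_HYDROPHOBIC")
    (v - rng[1L]) / diff(rng) else (rng[2L] - v) / diff(rng)
  scale_table(out, orientation = "HIGHER_IS_HYDROPHOBIC",
              label = scale$label)
}

#' Pearson correlation with matched amino-acid keys
#'
#' Product-moment correlation between two numeric series, or between two
#' [scale_table]s matched on the intersection of their amino-acid codes
#' (the number of matched keys is messaged).
#'
#' @param x,y Numeric vectors of equal length (>= 3), or two `scale_table`s.
#' @return Pearson rho.
#' @export
pearson_cor <- function(x, y) {
  if (inherits(x, "scale_table") && inherits(y, "scale_table")) {
    keys <- intersect(names(x$values), names(y$values))
    message(sprintf("matched %d amino acids", length(keys)))
    x <- unname(x$values[keys])
    y <- unname(y$values[keys])
  }
  if (length(x) != length(y)) stop("series must have equal length")
  if (length(x) < 3L) stop("need at least 3 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  stats::cor(x, y)
}

#' Correlate hydrophobicity scales with transition temperatures
#'
#' For each scale, the Pearson correlation (and least-squares line) between
#' the scale values and the per-guest transition temperatures Tt, over the
#' intersection of amino-acid keys. Scales are normalised onto \[0, 1\]
#' (hydrophobic end at 1) first when `normalize = TRUE`; Tt itself is never
#' transformed (Pearson is affine invariant, so normalising Tt would not
#' change rho).
#'
#' @param tt A [scale_table] of transition temperatures.
#' @param scales A list of [scale_table]s (or one table).
#' @param normalize Normalise each scale before correlating.
#' @return A `correlation_report` data frame: `label`, `rho`, `n`, `slope`,
#'   `intercept`.
#' @export
correlate_with_tt <- function(tt, scales, normalize = TRUE) {
  stopifnot(inherits(tt, "scale_table"))
  if (inherits(scales, "scale_table")) scales <- list(scales)
  rows <- lapply(scales, function(sc) {
    if (normalize) sc <- normalize_scale(sc)
    keys <- intersect(names(sc$values), names(tt$values))
    if (length(keys) < 3L)
      stop(sprintf("insufficient overlap between Tt and scale '%s': %d keys",
                   sc$label, length(keys)))
    x <- unname(sc$values[keys])
    y <- unname(tt$values[keys])
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stop("undefined correlation: zero variance")
    fit <- stats::lm(y ~ x)
    data.frame(label = sc$label, rho = stats::cor(x, y), n = length(keys),
               slope = unname(stats::coef(fit)[2L]),
               intercept = unname(stats::coef(fit)[1L]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("correlation_report", "data.frame"))
}
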