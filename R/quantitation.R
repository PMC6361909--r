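#' Fit a marker-compound calibration curve
#'
#' Ordinary least-squares line `response = slope * conc + intercept`, with
#' the detection and quantitation limits derived from the residual standard
#' deviation: `LOD = 3.3 * s / slope`, `LOQ = 10 * s / slope`.
#'
#' @param conc strictly positive concentrations (>= 3 points, not all equal)
#' @param response detector responses, same length
#' @return object of class `calibration_curve`: list with `slope`,
#'   `intercept`, `r` (Pearson), `lod`, `loq`, `range` (min/max of `conc`)
#' @export
fit_calibration <- function(conc, response) {
  if (length(conc) != length(response) || length(conc) < 3L)
    stop("need >= 3 calibration points", call. = FALSE)
  if (any(conc <= 0)) stop("concentrations must be > 0", call. = FALSE)
  if (stats::sd(conc) == 0) stop("concentrations are constant", call. = FALSE)
  fit <- stats::lm(response ~ conc)
  slope <- unname(stats::coef(fit)[2L])
  # summary.lm warns on exactly collinear points; sigma = 0 is what we want
  s_resid <- suppressWarnings(summary(fit)$sigma)
  structure(list(
    slope = slope,
    intercept = unname(stats::coef(fit)[1L]),
    r = stats::cor(conc, response),
    lod = 3.3 * s_resid / abs(slope),
    loq = 10 * s_resid / abs(slope),
    range = range(conc)
  ), class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve: y = %.4g x + %.4g, r = %.4f, LOD %.3g, LOQ %.3g>\n",
    x$slope, x$intercept, x$r, x$lod, x$loq))
  invisible(x)
}

#' Compute marker content from a peak area
#'
#' Inverts a calibration line and converts to content per gram of sample:
#' `conc = (area - intercept)/slope`, then
#' `content = conc * extract_volume * dilution / sample_mass`. With
#' concentrations in mg/mL, volume in mL and mass in g the content is mg/g.
#' Areas below the intercept yield a negative concentration and are returned
#' as `NA` with a `"non_quantifiable"` attribute listing their positions.
#'
#' @param area peak area(s)
#' @param curve a [fit_calibration()] result
#' @param sample_mass sample mass in g (> 0)
#' @param extract_volume extraction volume in mL (> 0), default 50
#' @param dilution injection-independent dilution factor, default 1
#' @return numeric content(s), unit `conc-unit * mL / g`
#' @export
content_from_area <- function(area, curve, sample_mass, extract_volume = 50,
                              dilution = 1) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(sample_mass <= 0) || extract_volume <= 0)
    stop("mass and volume must be > 0", call. = FALSE)
  conc <- (area - curve$intercept) / curve$slope
  bad <- which(conc < 0)
  conc[bad] <- NA_real_
  out <- conc * extract_volume * dilution / sample_mass
  if (length(bad)) attr(out, "non_quantifiable") <- bad
  out
}

#' Percent-of-mean content index (P_mC)
#'
#' For a samples-by-compounds content table, each content is expressed as a
#' percentage of its compound's across-sample mean, and the percentages are
#' averaged per sample. By construction the index averages to exactly 100
#' over the samples, and it is invariant to rescaling any single compound
#' column. With six marker compounds this is the P_6C index.
#'
#' @param contents numeric matrix or data.frame, samples x compounds, with
#'   sample ids as row names
#' @return named numeric vector, one percentage per sample
#' @export
percent_of_mean_index <- function(contents) {
  m <- as.matrix(contents)
  if (nrow(m) < 2L) stop("need >= 2 samples", call. = FALSE)
  mu <- colMeans(m)
  if (any(mu <= 0)) stop("zero column mean in contents", call. = FALSE)
  rowMeans(sweep(m, 2L, mu, "/")) * 100
}

#' Per-compound summary statistics of a content table
#'
#' @param contents samples x compounds matrix or data.frame
#' @return data.frame with `compound`, `mean`, `sd` (sample, n-1 denominator),
#'   `rsd_pct` (100 * sd / mean)
#' @export
column_summary <- function(contents) {
  m <- as.matrix(contents)
  if (nrow(m) < 2L) stop("sample SD undefined for a single sample", call. = FALSE)
  mu <- colMeans(m)
  s <- apply(m, 2L, stats::sd)
  data.frame(compound = colnames(m), mean = unname(mu), sd = unname(s),
             rsd_pct = unname(100 * s / mu), row.names = NULL)
}

#' Pearson correlation of two series
#'
#' @param a,b numeric vectors of equal length >= 3, both non-constant
#' @return Pearson r in \[-1, 1\]
#' @export
correlate_series <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3L)
    stop("need equal-length series of >= 3 values", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined for a constant series", call. = FALSE)
  stats::cor(a, b)
}
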