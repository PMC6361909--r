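#' Ascorbic-acid-equivalent activity from a detector response
#'
#' Converts a DPPH-quench detector response to an ascorbic-acid-equivalent
#' (ASAE) concentration in mM via a linear calibration,
#' `ASAE = (response - intercept)/slope`. Values outside the calibration
#' range are kept, not dropped: the returned vector carries an `"oor"`
#' attribute with the indices of out-of-range values, and responses below the
#' intercept (negative ASAE) are additionally flagged `"invalid"`. Downstream
#' modeling decides what to do with flagged values.
#'
#' @param response detector response(s) (peak area)
#' @param curve a [fit_calibration()] result with positive slope
#' @param range calibration range in mM, default `c(0.030, 0.450)`
#' @return numeric ASAE value(s) in mM with optional `"oor"`/`"invalid"`
#'   index attributes
#' @export
asae_from_response <- function(response, curve, range = c(0.030, 0.450)) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope <= 0) stop("calibration slope must be > 0", call. = FALSE)
  asae <- (response - curve$intercept) / curve$slope
  tol <- sqrt(.Machine$double.eps)   # guard against float noise at the edges
  oor <- which(asae < range[1L] - tol | asae > range[2L] + tol)
  invalid <- which(asae < -tol)
  if (length(oor)) attr(asae, "oor") <- oor
  if (length(invalid)) attr(asae, "invalid") <- invalid
  asae
}

#' Range and fold-difference of measured activities
#'
#' @param asae positive ASAE values in mM (>= 1 value)
#' @return list with `min`, `max` and `fold` (= max/min, rounded to 2
#'   decimals)
#' @export
activity_range <- function(asae) {
  asae <- asae[!is.na(asae)]
  if (length(asae) < 1L || any(asae <= 0))
    stop("need >= 1 positive activity value", call. = FALSE)
  list(min = min(asae), max = max(asae),
       fold = round(max(asae) / min(asae), 2L))
}

#' Relative error of a predicted activity
#'
#' Sign convention: `100 * (predicted - measured) / measured`, positive when
#' the model over-predicts.
#'
#' @param measured,predicted numeric vectors, `measured` nonzero
#' @return relative error(s) in percent
#' @export
relative_error <- function(measured, predicted) {
  if (any(measured == 0)) stop("measured value of 0", call. = FALSE)
  100 * (predicted - measured) / measured
}
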