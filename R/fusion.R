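#' Build a multi-wavelength fusion fingerprint channel
#'
#' Concatenates the per-channel peak-area vectors of each sample into one
#' fused vector, peak identity preserved, so that no single detection
#' wavelength biases the evaluation. Each channel may be weighted; with an
#' optional per-channel normalization each channel is first divided by the
#' total reference (mean-sample) area of that channel, putting channels of
#' very different response intensity on a common footing.
#'
#' Global rescaling of all weights leaves every ALQFM statistic unchanged,
#' and fusing a channel with itself reproduces the single-channel statistics.
#'
#' @param fps a [fingerprint_set()]
#' @param channels channels to fuse, in order (default: all, >= 2 required)
#' @param weights positive per-channel weights (default 1)
#' @param name label of the added fused channel
#' @param normalize divide each channel by its total mean-sample area before
#'   weighting (off by default; raw areas are concatenated)
#' @return the input `fingerprint_set` with one fused channel appended; fused
#'   peak columns are named `<channel>_<peak>`
#' @export
fuse <- function(fps, channels = names(fps$channels), weights = NULL,
                 name = "fusion", normalize = FALSE) {
  stopifnot(inherits(fps, "fingerprint_set"))
  unknown <- setdiff(channels, names(fps$channels))
  if (length(unknown))
    stop("unknown channel(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  if (length(channels) < 2L)
    stop("fusion requires at least two channels", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(channels))
  if (length(weights) != length(channels) || any(weights <= 0))
    stop("weights must be positive, one per fused channel", call. = FALSE)
  if (name %in% names(fps$channels))
    stop(sprintf("channel '%s' already exists", name), call. = FALSE)
  blocks <- mapply(function(ch, w) {
    m <- fps$channels[[ch]]
    if (normalize) w <- w / sum(colMeans(m))
    m <- m * w
    colnames(m) <- paste(ch, colnames(m), sep = "_")
    m
  }, channels, weights, SIMPLIFY = FALSE)
  fused <- do.call(cbind, blocks)
  fps$channels[[name]] <- fused
  fps
}
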