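#' ALQFM similarity statistics
#'
#' The averagely linear quantified fingerprint method (ALQFM) scores a sample
#' fingerprint vector `x` against a reference vector `y` with five linked
#' statistics: the average linear qualitative similarity `S_L`, the
#' mass-corrected regression slope `b` (percent), the apparent content
#' similarity `R` (percent), the variation coefficient `alpha = |R/b - 1|`,
#' and the average linear quantitative similarity `P_L` (percent). `S_L`
#' judges compositional distribution only; `b`, `R` and `P_L` respond to the
#' overall content level; `alpha` measures the internal consistency of the two
#' content estimates.
#'
#' `qualitative_similarity()` is the mean of the Pearson correlation of `x`
#' and `y` and a ratio-uniformity term
#' `sum(x/y) / sqrt(n * sum((x/y)^2))`, which lies in (0, 1] and equals 1
#' exactly when all peak ratios `x_i/y_i` are equal.
#'
#' @param x numeric sample fingerprint vector (areas, >= 0)
#' @param y numeric reference fingerprint vector, strictly positive, same
#'   length as `x`
#' @param m_s,m_r sample and reference masses in grams (default 1, i.e. no
#'   mass correction)
#' @return `qualitative_similarity()`: `S_L` in \[-1, 1\]. `slope_b()`,
#'   `apparent_content()` and `quantitative_similarity()`: percentages.
#'   `variation_coefficient()`: a dimensionless value >= 0.
#' @name alqfm_statistics
NULL

check_xy <- function(x, y, ratios = FALSE) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("x and y must have equal length >= 2", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite", call. = FALSE)
  if (ratios && any(y <= 0))
    stop("all reference entries y_i must be > 0", call. = FALSE)
}

#' @rdname alqfm_statistics
#' @export
qualitative_similarity <- function(x, y) {
  check_xy(x, y, ratios = TRUE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Pearson correlation undefined for constant vectors", call. = FALSE)
  r <- stats::cor(x, y)
  ratio <- x / y
  uniformity <- sum(ratio) / sqrt(length(x) * sum(ratio^2))
  (r + uniformity) / 2
}

#' @rdname alqfm_statistics
#' @export
slope_b <- function(x, y, m_s = 1, m_r = 1) {
  check_xy(x, y)
  n <- length(x)
  den <- n * sum(y^2) - sum(y)^2
  if (den == 0)
    stop("slope undefined: reference vector is constant", call. = FALSE)
  (n * sum(x * y) - sum(x) * sum(y)) / den * (m_r / m_s) * 100
}

#' @rdname alqfm_statistics
#' @export
apparent_content <- function(x, y, m_s = 1, m_r = 1) {
  check_xy(x, y)
  if (sum(y) == 0)
    stop("apparent content undefined: sum of reference areas is zero",
         call. = FALSE)
  sum(x) / sum(y) * (m_r / m_s) * 100
}

#' @rdname alqfm_statistics
#' @param r_pct apparent content similarity `R` in percent
#' @param b_pct regression slope `b` in percent
#' @export
variation_coefficient <- function(r_pct, b_pct) {
  if (any(b_pct == 0)) stop("alpha undefined for b = 0", call. = FALSE)
  abs(r_pct / b_pct - 1)
}

#' @rdname alqfm_statistics
#' @param mode `"mass_corrected"` (default) applies the mass factor `m_r/m_s`
#'   to both terms of `P_L`, so that `P_L` is invariant to how much sample was
#'   weighed (consistent with `b` and `R`); `"verbatim"` applies it to the
#'   slope term only. The modes coincide when `m_s == m_r`.
#' @export
quantitative_similarity <- function(x, y, m_s = 1, m_r = 1,
                                    mode = c("mass_corrected", "verbatim")) {
  mode <- match.arg(mode)
  check_xy(x, y, ratios = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Pearson correlation undefined for constant vectors", call. = FALSE)
  b <- slope_b(x, y, m_s, m_r)
  content_term <- sum(x) * sum(x * y) /
    (sum(y) * sqrt(sum(x^2)) * sqrt(sum(y^2))) * 100
  if (mode == "mass_corrected") content_term <- content_term * (m_r / m_s)
  (stats::cor(x, y) * b + content_term) / 2
}

#' Quality-grade bands for ALQFM evaluation
#'
#' Banded thresholds mapping an `(S_L, P_L, alpha)` triple to an integer
#' quality grade 1 (best) to 8 (worst). Grades 1-7 each carry a minimum
#' `S_L`, an inclusive `P_L` band and a maximum `alpha`; the bands are
#' strictly nested, and grade 8 is the fallback outside all bands.
#' Samples with grade <= 5 are considered qualified, matching the
#' qualitative cut-offs `S_L > 0.70`, `alpha < 0.30` and the quantitative
#' acceptance window 70% <= `P_L` <= 130%.
#'
#' @return data.frame with columns `grade`, `s_l_min`, `p_l_low`, `p_l_high`,
#'   `alpha_max` (band endpoints inclusive)
#' @export
default_grade_table <- function() {
  data.frame(
    grade     = 1:7,
    s_l_min   = c(0.95, 0.915, 0.86, 0.82, 0.78, 0.74, 0.70),
    p_l_low   = c(95, 90, 85, 80, 70, 60, 50),
    p_l_high  = c(105, 110, 115, 120, 130, 140, 150),
    alpha_max = c(0.05, 0.10, 0.15, 0.20, 0.25, 0.35, 0.45)
  )
}

check_grade_table <- function(gt) {
  need <- c("grade", "s_l_min", "p_l_low", "p_l_high", "alpha_max")
  if (!all(need %in% names(gt)))
    stop("grade table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.unsorted(rev(gt$s_l_min)) || is.unsorted(gt$alpha_max) ||
      is.unsorted(rev(gt$p_l_low)) || is.unsorted(gt$p_l_high))
    stop("grade bands must be nested: s_l_min non-increasing, alpha_max ",
         "non-decreasing, P_L bands widening", call. = FALSE)
  gt
}

#' Assign ALQFM quality grades
#'
#' For each of the three criteria the criterion-grade is the smallest grade
#' whose band admits the value; the overall grade is the worst (maximum) of
#' the three, with grade 8 when any criterion falls outside all bands.
#'
#' @param s_l,p_l_pct,alpha numeric vectors of equal length
#' @param grades a grade table as returned by [default_grade_table()]
#' @return integer vector of grades in 1..8
#' @export
assign_grade <- function(s_l, p_l_pct, alpha, grades = default_grade_table()) {
  gt <- check_grade_table(grades)
  first_or_8 <- function(ok) {
    g <- which(ok)
    if (length(g)) min(g) else 8L
  }
  mapply(function(s, p, a) {
    if (!is.finite(s) || !is.finite(p) || !is.finite(a)) return(8L)
    max(first_or_8(s >= gt$s_l_min),
        first_or_8(p >= gt$p_l_low & p <= gt$p_l_high),
        first_or_8(a <= gt$alpha_max))
  }, s_l, p_l_pct, alpha)
}

#' Evaluate a fingerprint set against a reference fingerprint
#'
#' Computes the full ALQFM result (S_L, b, R, alpha, P_L, grade, qualified)
#' for every sample in every channel. Evaluating the reference against itself
#' yields `S_L = 1`, `P_L = 100`, `alpha = 0`, grade 1.
#'
#' @param fps a [fingerprint_set()]
#' @param rfp a [build_reference()] result whose channel/peak structure
#'   matches `fps` (defaults to the reference built from `fps` itself)
#' @param grades grade table, see [default_grade_table()]
#' @param mode see [quantitative_similarity()]
#' @param include_reference append the reference's own evaluation as a
#'   sample id `"RFP"` row per channel
#' @return data.frame with columns `sample_id`, `channel`, `S_L`, `b_pct`,
#'   `R_pct`, `alpha`, `P_L_pct`, `grade`, `qualified`
#' @export
evaluate_set <- function(fps, rfp = build_reference(fps),
                         grades = default_grade_table(),
                         mode = "mass_corrected",
                         include_reference = FALSE) {
  stopifnot(inherits(fps, "fingerprint_set"),
            inherits(rfp, "reference_fingerprint"))
  if (!identical(names(fps$channels), names(rfp$vectors)))
    stop("channel structure mismatch between set and reference", call. = FALSE)
  out <- list()
  for (ch in names(fps$channels)) {
    m <- fps$channels[[ch]]
    y <- rfp$vectors[[ch]]
    if (ncol(m) != length(y))
      stop(sprintf("peak count mismatch in channel '%s'", ch), call. = FALSE)
    ids <- rownames(m)
    xs <- lapply(ids, function(s) m[s, ])
    ms <- fps$masses
    if (include_reference) {
      ids <- c(ids, "RFP")
      xs <- c(xs, list(y))
      ms <- c(ms, RFP = rfp$mass)
    }
    res <- t(mapply(function(x, m_s) {
      s_l <- qualitative_similarity(x, y)
      b <- slope_b(x, y, m_s, rfp$mass)
      r <- apparent_content(x, y, m_s, rfp$mass)
      c(S_L = s_l, b_pct = b, R_pct = r,
        alpha = variation_coefficient(r, b),
        P_L_pct = quantitative_similarity(x, y, m_s, rfp$mass, mode = mode))
    }, xs, ms[ids]))
    out[[ch]] <- data.frame(sample_id = ids, channel = ch, res,
                            row.names = NULL)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$grade <- as.integer(assign_grade(out$S_L, out$P_L_pct, out$alpha, grades))
  out$qualified <- out$grade <= 5L
  out
}
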