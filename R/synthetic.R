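#' Simulate a multi-wavelength fingerprint dataset with known ground truth
#'
#' Generates a batch set emulating the structure of a multi-manufacturer
#' herbal-extract study: per channel `w` and peak `p`,
#' `area(s, w, p) = mu_wp * gamma_{g(s),w,p} * kappa_s * eps_swp`, with
#' peak base areas `mu` log-uniform over \[1e2, 1e4\], multiplicative
#' log-normal group (manufacturer) effects of log-SD `sigma_group`, a
#' per-sample batch content scale `kappa_s` (log-SD `sigma_batch`) and
#' log-normal measurement noise (`sigma_peak`). Group effects are normalized
#' to be content-neutral within each channel (they redistribute area across
#' peaks without changing the expected channel total), so `kappa_s` alone
#' carries the content level while group effects carry composition — the two
#' signals that the quantitative similarity and the clustering stage are
#' respectively meant to recover. Areas additionally scale with the weighed
#' sample mass (relative to the mean mass), the instrumental effect that the
#' `m_R/m_S` mass correction of the ALQFM statistics undoes.
#'
#' A designated set of active peaks in `activity_channel` drives the
#' bioactivity: a weighted sum of their areas plus Gaussian noise is mapped
#' affinely into the ASAE calibration range. Designated marker peaks yield
#' marker contents (mg/g) through true calibration slopes, the extraction
#' volume and the sample masses.
#'
#' Identical `(arguments, seed)` give bit-identical output.
#'
#' @param n_samples number of samples (default 30)
#' @param n_groups number of manufacturer groups (default 3, contiguous
#'   blocks of samples)
#' @param peaks named integer vector: peaks per channel (defaults to five
#'   wavelength channels with 39/39/44/30/19 co-possessing peaks)
#' @param sigma_batch log-SD of the per-sample content scale `kappa`
#'   (default 0.15)
#' @param sigma_group log-SD of group composition effects (default 0.5)
#' @param sigma_peak log-SD of per-peak measurement noise (default 0.1)
#' @param sigma_activity SD of additive activity noise on the raw activity
#'   score, whose typical magnitude is `n_active` (default 0.1)
#' @param n_active number of activity-driving peaks (default 5)
#' @param n_markers number of marker compounds (default 6)
#' @param activity_channel channel carrying active and marker peaks
#'   (default: `"220nm"` when present, else the first channel)
#' @param asae_range target ASAE interval (mM) for the affine rescaling
#' @param mean_mass,sd_mass sample mass distribution in grams (default
#'   0.56 +/- 0.01, the usual weighed extract portion)
#' @param extract_volume extraction volume in mL (default 50)
#' @param n_outliers samples given an extra composition distortion
#'   (log-SD 1) and excluded from the activity relation, emulating planted
#'   outliers (default 0)
#' @param seed integer seed; all randomness is derived from it
#' @return list with `fps` (a [fingerprint_set()]), `contents`
#'   (samples x markers data.frame, mg/g), `activity` (data.frame
#'   `sample_id`, `asae_mM`), and `truth` (list: `kappa`, `group`,
#'   `active_peaks`, `beta`, `marker_peaks`, `marker_slopes`, `outlier_ids`,
#'   noise SDs, and the affine activity map)
#' @export
simulate_fingerprints <- function(n_samples = 30L, n_groups = 3L,
                                  peaks = c("203nm" = 39L, "220nm" = 39L,
                                            "250nm" = 44L, "280nm" = 30L,
                                            "344nm" = 19L),
                                  sigma_batch = 0.15, sigma_group = 0.5,
                                  sigma_peak = 0.1, sigma_activity = 0.1,
                                  n_active = 5L, n_markers = 6L,
                                  activity_channel = NULL,
                                  asae_range = c(0.05, 0.40),
                                  mean_mass = 0.56, sd_mass = 0.01,
                                  extract_volume = 50, n_outliers = 0L,
                                  seed = NULL) {
  if (n_groups > n_samples)
    stop("more groups than samples", call. = FALSE)
  if (is.null(activity_channel))
    activity_channel <- if ("220nm" %in% names(peaks)) "220nm"
                        else names(peaks)[1L]
  if (!activity_channel %in% names(peaks))
    stop("activity_channel not among channels", call. = FALSE)
  if (n_active > peaks[[activity_channel]] ||
      n_markers > peaks[[activity_channel]])
    stop("more active/marker peaks than peaks in the activity channel",
         call. = FALSE)
  if (any(c(sigma_batch, sigma_group, sigma_peak, sigma_activity) < 0))
    stop("noise SDs must be >= 0", call. = FALSE)

  build <- function() {
    ids <- paste0("S", seq_len(n_samples))
    glev <- paste0("G", seq_len(n_groups))
    group <- rep(glev, each = ceiling(n_samples / n_groups))[seq_len(n_samples)]
    names(group) <- ids
    masses <- abs(stats::rnorm(n_samples, mean_mass, sd_mass))
    names(masses) <- ids
    mass_factor <- masses / mean(masses)
    kappa <- stats::rlnorm(n_samples, 0, sigma_batch)
    names(kappa) <- ids

    outlier_ids <- character(0)
    if (n_outliers > 0L)
      outlier_ids <- sample(ids, n_outliers)

    channels <- list()
    mu_store <- list()
    for (ch in names(peaks)) {
      p <- peaks[[ch]]
      mu <- 10^stats::runif(p, 2, 4)
      gamma <- matrix(stats::rlnorm(n_groups * p, 0, sigma_group),
                      n_groups, p)
      # content-neutral: preserve the expected channel total per group
      gamma <- gamma * sum(mu) / drop(gamma %*% mu)
      eps <- matrix(stats::rlnorm(n_samples * p, 0, sigma_peak),
                    n_samples, p)
      g_idx <- match(group, glev)
      area <- sweep(gamma[g_idx, , drop = FALSE], 2L, mu, "*") *
        (kappa * mass_factor) * eps
      if (length(outlier_ids)) {
        oi <- match(outlier_ids, ids)
        distort <- matrix(stats::rlnorm(length(oi) * p, 0, 1),
                          length(oi), p)
        area[oi, ] <- area[oi, , drop = FALSE] * distort
      }
      dimnames(area) <- list(ids, paste0("P", seq_len(p)))
      channels[[ch]] <- area
      mu_store[[ch]] <- mu
    }
    fps <- fingerprint_set(channels, masses = masses, groups = group)

    act_mat <- channels[[activity_channel]]
    mu_act <- mu_store[[activity_channel]]
    active <- sort(sample(ncol(act_mat), n_active))
    beta <- stats::runif(n_active, 0.5, 1.5) / mu_act[active]
    raw <- drop(act_mat[, active, drop = FALSE] %*% beta) +
      stats::rnorm(n_samples, 0, sigma_activity)
    span <- diff(range(raw))
    if (span == 0) {
      asae <- rep(mean(asae_range), n_samples)
      map <- c(offset = mean(asae_range), scale = 0)
    } else {
      sc <- diff(asae_range) / span
      map <- c(offset = asae_range[1L] - min(raw) * sc, scale = sc)
      asae <- map[["offset"]] + raw * map[["scale"]]
    }
    names(asae) <- ids

    markers <- sort(sample(ncol(act_mat), n_markers))
    target <- stats::runif(n_markers, 2, 90)      # mg/g at the mean mass
    slopes <- extract_volume * mu_act[markers] / (mean_mass * target)
    contents <- sapply(seq_len(n_markers), function(j) {
      conc <- act_mat[, markers[j]] / slopes[j]   # mg/mL
      conc * extract_volume / masses              # mg/g
    })
    dimnames(contents) <- list(ids, paste0("C", seq_len(n_markers)))

    list(
      fps = fps,
      contents = as.data.frame(contents),
      activity = data.frame(sample_id = ids, asae_mM = unname(asae)),
      truth = list(
        kappa = kappa, group = group,
        active_peaks = colnames(act_mat)[active], beta = beta,
        marker_peaks = colnames(act_mat)[markers], marker_slopes = slopes,
        outlier_ids = outlier_ids,
        sigma = c(batch = sigma_batch, group = sigma_group,
                  peak = sigma_peak, activity = sigma_activity),
        activity_channel = activity_channel, asae_map = map
      )
    )
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Recovery metrics of a pipeline run against simulation truth
#'
#' Quantifies how well each pipeline stage recovered the planted structure:
#' adjusted Rand index of cluster labels vs true groups, Pearson correlation
#' of the batch scale `kappa` with the quantitative similarity `P_L`,
#' precision of the top-k VIP peaks against the active set, and the fraction
#' of active peaks whose standardized PLS coefficient is positive.
#'
#' @param truth the `truth` element of [simulate_fingerprints()]
#' @param cluster_labels named (or truth-ordered) cluster labels, optional
#' @param p_l named `P_L` values per sample, optional
#' @param vip named VIP vector, optional
#' @param coef_std named standardized coefficients, optional
#' @param top_k how many top-VIP peaks to score (default: number of active
#'   peaks)
#' @return list with any of `ari`, `kappa_pl_r`, `vip_precision`,
#'   `coef_sign_agreement`
#' @export
truth_report <- function(truth, cluster_labels = NULL, p_l = NULL,
                         vip = NULL, coef_std = NULL,
                         top_k = length(truth$active_peaks)) {
  out <- list()
  ids <- names(truth$kappa)
  if (!is.null(cluster_labels)) {
    if (!is.null(names(cluster_labels))) {
      if (!setequal(names(cluster_labels), ids))
        stop("cluster labels name a different sample set", call. = FALSE)
      cluster_labels <- cluster_labels[ids]
    } else if (length(cluster_labels) != length(ids)) {
      stop("cluster labels length mismatch", call. = FALSE)
    }
    out$ari <- mclust::adjustedRandIndex(cluster_labels, truth$group)
  }
  if (!is.null(p_l)) {
    if (is.null(names(p_l)) || !setequal(names(p_l), ids))
      stop("p_l must be named by the simulated sample ids", call. = FALSE)
    out$kappa_pl_r <- stats::cor(truth$kappa, p_l[ids])
  }
  if (!is.null(vip)) {
    top <- names(sort(vip, decreasing = TRUE))[seq_len(top_k)]
    out$vip_precision <- mean(top %in% truth$active_peaks)
  }
  if (!is.null(coef_std)) {
    act <- intersect(truth$active_peaks, names(coef_std))
    out$coef_sign_agreement <- mean(coef_std[act] > 0)
  }
  out
}
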