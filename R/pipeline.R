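#' Run the full quality-consistency evaluation
#'
#' Orchestrates the whole strategy on one configuration: read (or simulate)
#' the multi-wavelength peak tables, build the mean reference fingerprint,
#' score every sample with ALQFM per channel, add the fusion channel and
#' score it, compute the P_mC content index and its correlation with `P_L`
#' per channel, cluster the samples, and — when activity data are present —
#' fit the spectrum-effect PLS model with outlier screening and VIP ranking.
#'
#' @param config a list. Either `simulate` (arguments forwarded to
#'   [simulate_fingerprints()]) or `peaks` (+ optional `masses`) paths for
#'   [read_peak_tables()]. Optional elements: `contents` (samples x
#'   compounds data.frame or CSV path), `activity` (data.frame `sample_id`,
#'   `asae_mM` or CSV path), `fusion` (list `channels`, `weights`,
#'   `normalize`), `grade_table`, `mode`, `hca` (list `channel`, `k`,
#'   `standardize`), `pls` (list `channel`, `q`, `max_ncomp`, `cv`,
#'   `alpha`), `seed`.
#' @return object of class `run_report`: list with `alqfm`, `grade_summary`,
#'   `p_mc`, `correlations`, `hca`, `activity`, `pls`, `truth` (simulations
#'   only) and `provenance`
#' @export
run_full_evaluation <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  seed <- config$seed
  truth <- NULL
  contents <- config$contents
  activity <- config$activity

  if (!is.null(config$simulate)) {
    sim <- stage("simulate", do.call(
      simulate_fingerprints, c(config$simulate, list(seed = seed))))
    fps <- sim$fps
    truth <- sim$truth
    if (is.null(contents)) contents <- sim$contents
    if (is.null(activity)) activity <- sim$activity
  } else if (!is.null(config$peaks)) {
    fps <- stage("read", read_peak_tables(config$peaks, config$masses))
  } else stop("config must name either `simulate` or `peaks`", call. = FALSE)

  if (is.character(contents))
    contents <- stage("read contents", {
      df <- utils::read.csv(contents)
      rownames(df) <- df$sample_id
      df[, setdiff(names(df), "sample_id"), drop = FALSE]
    })
  if (is.character(activity))
    activity <- stage("read activity", utils::read.csv(activity))

  fcfg <- config$fusion
  fps <- stage("fuse", fuse(
    fps,
    channels = fcfg$channels %||% setdiff(names(fps$channels), "fusion"),
    weights = fcfg$weights,
    normalize = isTRUE(fcfg$normalize)))
  rfp <- stage("reference", build_reference(fps))
  grades <- config$grade_table %||% default_grade_table()
  alqfm <- stage("alqfm", evaluate_set(
    fps, rfp, grades = grades, mode = config$mode %||% "mass_corrected"))

  grade_summary <- stage("grades", {
    tab <- table(channel = alqfm$channel, grade = alqfm$grade)
    data.frame(channel = rownames(tab), as.data.frame.matrix(tab),
               qualified = as.vector(tapply(alqfm$qualified, alqfm$channel,
                                            sum)[rownames(tab)]),
               row.names = NULL, check.names = FALSE)
  })

  p_mc <- correlations <- NULL
  if (!is.null(contents)) {
    p_mc <- stage("p_mc", percent_of_mean_index(contents))
    correlations <- stage("correlations", {
      sapply(unique(alqfm$channel), function(ch) {
        sub <- alqfm[alqfm$channel == ch & alqfm$sample_id != "RFP", ]
        pl <- sub$P_L_pct[match(names(p_mc), sub$sample_id)]
        correlate_series(p_mc, pl)
      })
    })
  }

  hcfg <- config$hca %||% list()
  h_channel <- hcfg$channel %||% names(fps$channels)[1L]
  h_k <- hcfg$k %||% max(2L, length(unique(fps$groups)))
  hca_res <- stage("hca", hca(fps$channels[[h_channel]], k = h_k,
                              standardize = isTRUE(hcfg$standardize)))

  pls_res <- "skipped"
  if (!is.null(activity)) {
    pcfg <- config$pls %||% list()
    p_channel <- pcfg$channel %||% h_channel
    pls_res <- stage("pls", {
      y <- activity$asae_mM
      names(y) <- activity$sample_id
      spectrum_effect_pls(
        fps$channels[[p_channel]], y,
        q = pcfg$q %||% 4L,
        max_ncomp = pcfg$max_ncomp %||% 10L,
        cv = pcfg$cv %||% "loo",
        alpha = pcfg$alpha %||% 0.05,
        seed = seed)
    })
  }

  structure(list(
    alqfm = alqfm, grade_summary = grade_summary,
    p_mc = p_mc, correlations = correlations,
    hca = hca_res, activity = activity, pls = pls_res, truth = truth,
    provenance = list(
      seed = seed, config = config,
      package_version = as.character(utils::packageVersion("qfinger")),
      n_samples = length(sample_ids(fps)),
      channels = names(fps$channels))
  ), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  pr <- x$provenance
  cat(sprintf("<run_report: %d samples, channels %s, seed %s>\n",
              pr$n_samples, paste(pr$channels, collapse = "/"),
              if (is.null(pr$seed)) "none" else pr$seed))
  cat(sprintf("  qualified per channel: %s\n",
              paste(sprintf("%s %d", x$grade_summary$channel,
                            x$grade_summary$qualified), collapse = ", ")))
  if (!is.null(x$correlations))
    cat(sprintf("  P_mC~P_L r: %s\n",
                paste(sprintf("%s %.3f", names(x$correlations),
                              x$correlations), collapse = ", ")))
  if (inherits(x$pls, "pls_summary")) print(x$pls) else cat("  pls: skipped\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
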