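#' Bundled reference tables: 30 glycyrrhiza extract batches
#'
#' Two plain-text tables from a quality-consistency study of 30 commercial
#' glycyrrhiza (licorice) extract batches from three manufacturers, used as
#' worked-example inputs and as test fixtures.
#'
#' `ge_marker_contents()` returns the marker quantitation and bioactivity
#' table: contents (mg/g) of six marker compounds — liquiritin apioside
#' (LQA), liquiritin (LQT), liquiritigenin (LQG), glycyrrhizic acid (GLA),
#' isoliquiritoside (ISS), isoliquiritigenin (ISG) — the P_6C
#' percent-of-mean content index, the measured ascorbic-acid-equivalent
#' (ASAE) antioxidant activity in mM, and, for the 28 modeled samples, the
#' PLS-predicted ASAE and its relative error. `group` is the manufacturer
#' (A/B/C) and `role` records each sample's use in the activity model
#' (`training`, `test`, or `outlier` for the two score-plot outliers, which
#' carry no prediction).
#'
#' `ge_alqfm_scores()` returns the ALQFM evaluation of the same batches:
#' `S_L`, `P_L_pct`, `alpha` and the quality `grade` for each of the five
#' wavelength channels (203/220/250/280/344 nm) and the fused channel, plus
#' the reference fingerprint's self-evaluation as sample id `"RFP"`.
#'
#' @return a data.frame (see above)
#' @name ge_reference_tables
NULL

ge_file <- function(name) {
  system.file("extdata", name, package = "qfinger", mustWork = TRUE)
}

#' @rdname ge_reference_tables
#' @export
ge_marker_contents <- function() {
  utils::read.csv(ge_file("ge_markers.csv"))
}

#' @rdname ge_reference_tables
#' @export
ge_alqfm_scores <- function() {
  utils::read.csv(ge_file("ge_alqfm.csv"))
}

#' Marker-compound columns of the bundled content table
#' @keywords internal
ge_marker_columns <- function() c("LQA", "LQT", "LQG", "GLA", "ISS", "ISG")
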