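#' Multi-wavelength fingerprint peak-area set
#'
#' A `fingerprint_set` holds, for each detection channel (wavelength), a
#' samples-by-peaks matrix of chromatographic peak areas, together with the
#' per-sample extraction masses and optional group (e.g. manufacturer) labels.
#' All channels share one ordered sample-id list; peaks are identified
#' positionally within a channel (the input tables are assumed to contain
#' already-aligned co-possessing peaks).
#'
#' @param channels named list of numeric matrices (samples x peaks). Row names
#'   are sample ids and must agree across channels; column names default to
#'   `P1, P2, ...`.
#' @param masses named numeric vector of sample masses in grams, or `NULL`
#'   in which case all masses default to 1.0 (making the mass-correction
#'   factor of the ALQFM statistics neutral).
#' @param groups optional named character vector of group labels per sample.
#' @return an object of class `fingerprint_set` with elements `channels`,
#'   `masses`, `groups`.
#' @seealso [read_peak_tables()], [build_reference()], [fuse()]
#' @export
fingerprint_set <- function(channels, masses = NULL, groups = NULL) {
  if (!is.list(channels) || length(channels) == 0L || is.null(names(channels)))
    stop("`channels` must be a non-empty named list of matrices", call. = FALSE)
  channels <- lapply(channels, as.matrix)
  ref_ids <- rownames(channels[[1L]])
  if (is.null(ref_ids))
    stop("channel matrices must carry sample ids as row names", call. = FALSE)
  for (ch in names(channels)) {
    m <- channels[[ch]]
    if (ncol(m) < 1L)
      stop(sprintf("channel '%s' has no peak columns", ch), call. = FALSE)
    if (is.null(colnames(m)))
      colnames(m) <- paste0("P", seq_len(ncol(m)))
    missing <- setdiff(ref_ids, rownames(m))
    extra <- setdiff(rownames(m), ref_ids)
    if (length(missing) || length(extra))
      stop(sprintf("sample alignment error in channel '%s': %s",
                   ch,
                   paste(c(
                     if (length(missing)) paste("missing", missing),
                     if (length(extra)) paste("unexpected", extra)
                   ), collapse = ", ")),
           call. = FALSE)
    channels[[ch]] <- m[ref_ids, , drop = FALSE]
    bad <- which(!is.finite(channels[[ch]]) | channels[[ch]] < 0, arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("invalid peak area at (%s, %s) in channel '%s'",
                   ref_ids[bad[1L, 1L]],
                   colnames(channels[[ch]])[bad[1L, 2L]], ch),
           call. = FALSE)
  }
  if (is.null(masses)) {
    masses <- rep(1.0, length(ref_ids))
    names(masses) <- ref_ids
  } else {
    if (is.null(names(masses)))
      stop("`masses` must be named by sample id", call. = FALSE)
    missing <- setdiff(ref_ids, names(masses))
    if (length(missing))
      stop(sprintf("sample alignment error in masses: missing %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    masses <- masses[ref_ids]
    if (any(!is.finite(masses) | masses <= 0))
      stop("all sample masses must be finite and > 0", call. = FALSE)
  }
  if (!is.null(groups)) {
    if (is.null(names(groups)))
      stop("`groups` must be named by sample id", call. = FALSE)
    groups <- groups[ref_ids]
  }
  structure(list(channels = channels, masses = masses, groups = groups),
            class = "fingerprint_set")
}

#' @export
print.fingerprint_set <- function(x, ...) {
  cat(sprintf("<fingerprint_set: %d samples, %d channel(s)>\n",
              length(x$masses), length(x$channels)))
  for (ch in names(x$channels))
    cat(sprintf("  %s: %d peaks\n", ch, ncol(x$channels[[ch]])))
  invisible(x)
}

#' Sample ids of a fingerprint set
#' @param fps a `fingerprint_set`
#' @return character vector of sample ids in canonical order
#' @export
sample_ids <- function(fps) names(fps$masses)

#' Read per-channel peak-area tables
#'
#' Reads one comma-separated file per channel. Each file is wide-format with a
#' `sample_id` first column and one numeric column per co-possessing peak;
#' peak order is preserved from the file column order.
#'
#' @param paths character vector of CSV paths; names give the channel labels
#'   (unnamed paths use the file base name, e.g. `"220nm.csv"` -> `"220nm"`).
#' @param masses optional path to (or data.frame of) a mass table with columns
#'   `sample_id`, `mass_g`. When absent all masses default to 1.0.
#' @return a validated [fingerprint_set()]
#' @export
read_peak_tables <- function(paths, masses = NULL) {
  if (is.null(names(paths)) || any(names(paths) == ""))
    names(paths) <- sub("\\.[^.]*$", "", basename(paths))
  channels <- lapply(paths, function(p) {
    df <- utils::read.csv(p, check.names = FALSE)
    if (names(df)[1L] != "sample_id")
      stop(sprintf("'%s': first column must be 'sample_id'", p), call. = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df$sample_id
    storage.mode(m) <- "double"
    m
  })
  if (!is.null(masses)) {
    if (is.character(masses)) masses <- utils::read.csv(masses)
    mv <- masses$mass_g
    names(mv) <- masses$sample_id
    masses <- mv
  }
  fingerprint_set(channels, masses = masses)
}

#' Write a fingerprint set as per-channel CSV tables
#'
#' Inverse of [read_peak_tables()]: emits one `<channel>.csv` per channel plus
#' `masses.csv`, with deterministic column order.
#'
#' @param fps a `fingerprint_set`
#' @param dir output directory (created if needed)
#' @return invisibly, the named vector of channel file paths
#' @export
write_peak_tables <- function(fps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(fps$channels), function(ch) {
    m <- fps$channels[[ch]]
    df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
    p <- file.path(dir, paste0(ch, ".csv"))
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    p
  }, character(1L))
  utils::write.csv(
    data.frame(sample_id = names(fps$masses), mass_g = unname(fps$masses)),
    file.path(dir, "masses.csv"), row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Build the mean reference fingerprint
#'
#' The reference fingerprint (RFP) of a batch set is, per channel, the
#' arithmetic mean of the sample peak areas per peak; its mass is the mean of
#' the sample masses. Every reference entry must be strictly positive, since
#' the qualitative similarity forms peak-wise ratios against it.
#'
#' @param fps a `fingerprint_set` with at least one sample
#' @return object of class `reference_fingerprint`: list with `vectors` (one
#'   numeric vector per channel) and `mass` (grams)
#' @export
build_reference <- function(fps) {
  stopifnot(inherits(fps, "fingerprint_set"))
  vectors <- lapply(names(fps$channels), function(ch) {
    v <- colMeans(fps$channels[[ch]])
    zero <- which(v <= 0)
    if (length(zero))
      stop(sprintf("reference peak '%s' in channel '%s' has zero mean area",
                   names(v)[zero[1L]], ch), call. = FALSE)
    v
  })
  names(vectors) <- names(fps$channels)
  structure(list(vectors = vectors, mass = mean(fps$masses)),
            class = "reference_fingerprint")
}

#' @export
print.reference_fingerprint <- function(x, ...) {
  cat(sprintf("<reference_fingerprint: %d channel(s), mass %.4g g>\n",
              length(x$vectors), x$mass))
  invisible(x)
}
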