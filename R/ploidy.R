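# Relative genome size from flow cytometry and ploidy confirmation rules.

#' Flow-cytometry sample
#'
#' @param sample_id label.
#' @param readings positive fluorescence means (instrument units).
#' @param preparation integer vector assigning each reading to a separately
#'   prepared sample (default: all one preparation).
#' @return A `flow_sample` object.
#' @export
flow_sample <- function(sample_id, readings,
                        preparation = rep(1L, length(readings))) {
  readings <- as.numeric(readings)
  if (length(readings) < 1) stop("at least one reading required")
  if (any(!is.finite(readings)) || any(readings <= 0))
    stop("all readings must be positive")
  if (length(preparation) != length(readings))
    stop("one preparation index per reading required")
  structure(list(sample_id = sample_id, readings = readings,
                 preparation = as.integer(preparation),
                 n_preparations = length(unique(preparation))),
            class = "flow_sample")
}

#' Relative genome size against a diploid standard
#'
#' Readings are averaged within each separately prepared sample first, then
#' across preparations; the relative size is the ratio of the sample's mean
#' to the standard's mean (1 unit = one diploid standard genome).
#'
#' @param sample,standard [flow_sample()] objects (the standard is the
#'   confirmed diploid reference).
#' @return Positive numeric relative genome size.
#' @export
relative_genome_size <- function(sample, standard) {
  stopifnot(inherits(sample, "flow_sample"),
            inherits(standard, "flow_sample"))
  prep_mean <- function(fs)
    mean(tapply(fs$readings, fs$preparation, mean))
  prep_mean(sample) / prep_mean(standard)
}

#' Classify a ploidy measurement against its published value
#'
#' The fold difference between the measured and the published relative
#' genome size is `max(a, b) / min(a, b) - 1` (symmetric in its arguments).
#' A sample is `confirmed` when the two sizes differ by at most 0.6-fold,
#' `excluded` when they differ by two-fold or more (such samples are removed
#' from all further analysis), and `flagged` in between.
#'
#' @param measured,published positive relative genome sizes.
#' @param sample_id optional label carried into the result.
#' @param confirm_bound fold difference at or below which the predicted
#'   ploidy is confirmed (default 0.6).
#' @param exclude_bound fold difference at or above which the sample is
#'   excluded (default 1.0, i.e. a two-fold ratio).
#' @return A `ploidy_call`: one-row data.frame with `sample_id`,
#'   `relative_size_measured`, `relative_size_published`,
#'   `fold_difference`, `status`.
#' @export
classify_ploidy <- function(measured, published, sample_id = NA_character_,
                            confirm_bound = 0.6, exclude_bound = 1.0) {
  if (!is.numeric(measured) || !is.numeric(published) ||
      measured <= 0 || published <= 0)
    stop("relative genome sizes must be positive")
  fold <- max(measured, published) / min(measured, published) - 1
  status <- if (fold >= exclude_bound) "excluded"
            else if (fold <= confirm_bound) "confirmed"
            else "flagged"
  structure(data.frame(sample_id = sample_id,
                       relative_size_measured = measured,
                       relative_size_published = published,
                       fold_difference = fold,
                       status = status,
                       stringsAsFactors = FALSE),
            class = c("ploidy_call", "data.frame"))
}

#' Ploidy calls for a table of samples
#'
#' @param samples data.frame with columns `sample_id`, `readings`
#'   (list-column or semicolon-separated string of numbers) and
#'   `published_relative_size`.
#' @param standard a [flow_sample()] for the diploid standard.
#' @return A data.frame of [classify_ploidy()] rows.
#' @export
ploidy_table <- function(samples, standard) {
  rows <- lapply(seq_len(nrow(samples)), function(i) {
    r <- samples$readings[[i]]
    if (is.character(r)) r <- as.numeric(strsplit(r, "[;,]")[[1]])
    fs <- flow_sample(samples$sample_id[i], r)
    classify_ploidy(relative_genome_size(fs, standard),
                    samples$published_relative_size[i],
                    sample_id = samples$sample_id[i])
  })
  do.call(rbind, rows)
}
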