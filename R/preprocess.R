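#' Global mean normalization
#'
#' Scales each sample (array) multiplicatively so that its arithmetic mean
#' intensity equals the grand mean of all pre-normalization per-sample
#' means. Only a single scale factor is applied per array, so the relative
#' ordering of probes within a sample — and every downstream ratio — is
#' preserved. The operation is idempotent.
#'
#' @param intensity Tibble with `probe_id` plus one positive numeric column
#'   per sample.
#' @return The normalized intensity tibble (same shape, same probe order).
#' @examples
#' m <- tibble::tibble(probe_id = c("p1", "p2"),
#'                     s1 = c(400, 600), s2 = c(800, 1200))
#' normalize_global_mean(m) # both samples rescaled to mean 750
#' @export
normalize_global_mean <- function(intensity) {
  check_intensity(intensity)
  if (nrow(intensity) == 0L) abort("Cannot normalize an empty matrix.")
  smp <- sample_columns(intensity)
  means <- vapply(intensity[smp], mean, numeric(1))
  grand <- mean(means)
  out <- intensity
  for (s in smp) out[[s]] <- out[[s]] * (grand / means[[s]])
  out
}

#' Filter probes below the intensity detection threshold
#'
#' Removes probes whose (normalized) intensity falls below a detection
#' threshold — by default 400, the conventional floor for this platform.
#' The scope of the rule is configurable:
#'
#' * `any_condition_mean` (default): retain a probe iff at least one
#'   condition's mean intensity is >= the threshold (a probe expressed in
#'   either condition survives);
#' * `all_condition_means`: retain only probes at or above threshold in
#'   every condition;
#' * `overall_mean`: threshold the mean over all samples.
#'
#' @param intensity Normalized intensity tibble.
#' @param design Sample design tibble (`sample_id`, `condition`,
#'   `replicate`).
#' @param intensity_threshold Positive detection threshold (default 400);
#'   0 disables the filter.
#' @param filter_policy One of `"any_condition_mean"`,
#'   `"all_condition_means"`, `"overall_mean"`.
#' @return A list with `intensity` (retained probes, input order preserved)
#'   and `removed` (tibble of removed probes with their per-condition mean
#'   intensities).
#' @export
filter_low_intensity <- function(intensity, design,
                                 intensity_threshold = 400,
                                 filter_policy = c("any_condition_mean",
                                                   "all_condition_means",
                                                   "overall_mean")) {
  check_intensity(intensity)
  check_design(design, intensity)
  filter_policy <- match.arg(filter_policy)
  if (intensity_threshold < 0) {
    abort("`intensity_threshold` must be non-negative.")
  }

  cm <- condition_means(intensity, design)
  cm$mean_overall <- rowMeans(as.matrix(
    intensity[match(cm$probe_id, intensity$probe_id), sample_columns(intensity)]
  ))
  keep <- switch(filter_policy,
    any_condition_mean = cm$mean_control >= intensity_threshold |
      cm$mean_treated >= intensity_threshold,
    all_condition_means = cm$mean_control >= intensity_threshold &
      cm$mean_treated >= intensity_threshold,
    overall_mean = cm$mean_overall >= intensity_threshold
  )

  kept_ids <- cm$probe_id[keep]
  removed <- cm[!keep, c("probe_id", "mean_control", "mean_treated",
                         "mean_overall")]
  if (nrow(removed) == nrow(intensity)) {
    inform("All probes fell below the intensity threshold.")
  }
  list(
    intensity = intensity %>% filter(.data$probe_id %in% kept_ids),
    removed = as_tibble(removed)
  )
}
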