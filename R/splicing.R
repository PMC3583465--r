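#' Gene-normalized probe-normalized (GNPN) values
#'
#' For each probe and condition, the probe-normalized value is the probe's
#' (globally normalized) mean intensity over that condition's replicates.
#' The GNPN value divides it by the geometric mean of the probe-normalized
#' values of all retained probes mapping to the same gene, so within each
#' gene and condition the geometric mean of GNPN values is exactly 1.
#' GNPN removes gene-level expression differences: only relative exon usage
#' remains, which is what the splicing index compares between conditions.
#'
#' Genes with fewer than `min_probes` retained probes carry no relative
#' information and are excluded (reported in the `excluded` attribute).
#'
#' @param intensity Filtered, normalized intensity tibble.
#' @param annotation Probe annotation.
#' @param design Sample design tibble.
#' @param min_probes Minimum retained probes per gene (default 2).
#' @return Tibble with `probe_id`, `gene_id`, `exon_id`, `gnpn_control`,
#'   `gnpn_treated`; attribute `excluded` lists dropped genes with reasons.
#' @export
compute_gnpn <- function(intensity, annotation, design, min_probes = 2L) {
  check_intensity(intensity)
  check_annotation(annotation)
  check_design(design, intensity)

  cm <- condition_means(intensity, design) %>%
    inner_join(annotation, by = "probe_id")

  probe_counts <- cm %>% count(.data$gene_id, name = "n_probes")
  excluded <- probe_counts %>%
    filter(.data$n_probes < min_probes) %>%
    mutate(reason = sprintf("fewer than %d retained probes", min_probes))
  if (nrow(excluded) > 0L) {
    inform(sprintf(
      "%d gene(s) excluded from splicing analysis (single/no retained probes).",
      nrow(excluded)))
  }

  out <- cm %>%
    semi_join(filter(probe_counts, .data$n_probes >= min_probes),
              by = "gene_id") %>%
    group_by(.data$gene_id) %>%
    mutate(
      gnpn_control = .data$mean_control / geometric_mean(.data$mean_control),
      gnpn_treated = .data$mean_treated / geometric_mean(.data$mean_treated)
    ) %>%
    ungroup() %>%
    select("probe_id", "gene_id", "exon_id", "gnpn_control", "gnpn_treated")
  attr(out, "excluded") <- as_tibble(excluded)
  out
}

#' Splicing index per probe
#'
#' Compares a probe's GNPN value between conditions. In `ratio` mode (the
#' default) `si = gnpn_treated / gnpn_control`, with a null value of 1; in
#' `difference` mode `si = gnpn_treated - gnpn_control`, with a null value
#' of 0. Because GNPN cancels gene-level shifts, a purely differentially
#' expressed gene has `si = 1` (ratio) on every probe; deviations mark
#' exons whose inclusion rate, relative to the gene level, differs between
#' the two groups.
#'
#' @param gnpn Output of [compute_gnpn()].
#' @param mode `"ratio"` or `"difference"`.
#' @return The input with `si` and `mode` columns added.
#' @export
splicing_index <- function(gnpn, mode = c("ratio", "difference")) {
  mode <- match.arg(mode)
  req <- c("probe_id", "gene_id", "exon_id", "gnpn_control", "gnpn_treated")
  if (!all(req %in% names(gnpn))) {
    abort("`gnpn` must be the output of compute_gnpn().")
  }
  gnpn %>%
    mutate(
      si = if (mode == "ratio") .data$gnpn_treated / .data$gnpn_control
           else .data$gnpn_treated - .data$gnpn_control,
      mode = mode
    )
}

#' Call alternative-splicing candidate exons
#'
#' Flags probes whose splicing index lies beyond the configured thresholds.
#' In ratio mode a probe is a candidate iff `si >= up_threshold` or
#' `si <= down_threshold` (defaults 2 and 1/2, by symmetry with the 2-fold
#' expression rule); in difference mode iff `|si| >= diff_threshold`.
#'
#' @param splice_table Output of [splicing_index()].
#' @param up_threshold,down_threshold Ratio-mode thresholds; must satisfy
#'   `down_threshold < 1 < up_threshold`.
#' @param diff_threshold Difference-mode threshold (default 1).
#' @return A `splice_calls` tibble: the input plus a logical `candidate`
#'   column. Per-gene candidate summaries via [as_gene_summary()]; counts
#'   via [glance()].
#' @export
call_as_candidates <- function(splice_table, up_threshold = 2,
                               down_threshold = 0.5, diff_threshold = 1) {
  if (!all(c("si", "mode") %in% names(splice_table))) {
    abort("`splice_table` must be the output of splicing_index().")
  }
  mode <- unique(splice_table$mode)
  stopifnot(length(mode) <= 1L)
  if (isTRUE(mode == "ratio")) {
    if (!(down_threshold < 1 && 1 < up_threshold)) {
      abort("Ratio-mode thresholds must satisfy down_threshold < 1 < up_threshold.")
    }
    out <- splice_table %>%
      mutate(candidate = .data$si >= up_threshold |
               .data$si <= down_threshold)
  } else {
    if (diff_threshold <= 0) abort("`diff_threshold` must be positive.")
    out <- splice_table %>%
      mutate(candidate = abs(.data$si) >= diff_threshold)
  }
  structure(out, class = c("splice_calls", class(out)),
            thresholds = list(up = up_threshold, down = down_threshold,
                              diff = diff_threshold))
}

#' Per-gene summary of alternative-splicing candidates
#'
#' @param x A `splice_calls` tibble from [call_as_candidates()].
#' @return Tibble with one row per gene holding any flagged exon:
#'   `gene_id`, `n_candidate_exons`, `candidate_exons` (comma-separated).
#' @export
as_gene_summary <- function(x) {
  stopifnot(inherits(x, "splice_calls"))
  as_tibble(x) %>%
    filter(.data$candidate) %>%
    group_by(.data$gene_id) %>%
    summarise(
      n_candidate_exons = n_distinct(.data$exon_id),
      candidate_exons = paste(sort(unique(.data$exon_id)), collapse = ","),
      .groups = "drop"
    )
}

#' @export
glance.splice_calls <- function(x, ...) {
  tibble(
    n_probes = nrow(x),
    n_genes = n_distinct(x$gene_id),
    n_candidates = sum(x$candidate),
    n_candidate_genes = n_distinct(x$gene_id[x$candidate])
  )
}

#' @export
tidy.splice_calls <- function(x, ...) {
  as_tibble(x) %>%
    select("probe_id", "gene_id", "exon_id", "si", "mode", "candidate")
}
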