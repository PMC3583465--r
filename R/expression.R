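#' Transcript-level summarization by geometric mean
#'
#' Collapses exon-level probe intensities to one transcript-level signal per
#' gene and condition: the geometric mean over all of the gene's retained
#' probes and all replicates of that condition (equivalently, the
#' antilogged mean of the log-intensities). Genes with no retained probes
#' are dropped.
#'
#' @param intensity Filtered, normalized intensity tibble.
#' @param annotation Probe annotation (`probe_id`, `gene_id`, `exon_id`).
#' @param design Sample design tibble.
#' @return Tibble with `gene_id`, `n_probes_retained`, `signal_control`,
#'   `signal_treated`.
#' @export
summarize_transcripts <- function(intensity, annotation, design) {
  check_intensity(intensity)
  check_annotation(annotation)
  check_design(design, intensity)
  unknown <- setdiff(intensity$probe_id, annotation$probe_id)
  if (length(unknown) > 0L) {
    abort(paste0("Probes missing from annotation: ",
                 paste(utils::head(unknown, 5L), collapse = ", ")))
  }
  intensity_long(intensity, design) %>%
    inner_join(annotation, by = "probe_id") %>%
    group_by(.data$gene_id, .data$condition) %>%
    summarise(
      n_probes_retained = n_distinct(.data$probe_id),
      signal = geometric_mean(.data$intensity),
      .groups = "drop"
    ) %>%
    tidyr::pivot_wider(names_from = "condition", values_from = "signal",
                       names_prefix = "signal_") %>%
    arrange(.data$gene_id)
}

#' Fold changes between treated and control signals
#'
#' Computes, per gene, the expression ratio `signal_treated /
#' signal_control` and the signed fold-change convention used throughout
#' exon-array reports: `+ratio` when the ratio is >= 1 and `-1/ratio`
#' otherwise, so the magnitude is always >= 1 (e.g. -2.23 means 2.23-fold
#' down in treated samples).
#'
#' @param signals Output of [summarize_transcripts()].
#' @return The input with `ratio` and `signed_fc` columns added.
#' @export
fold_changes <- function(signals) {
  req <- c("gene_id", "signal_control", "signal_treated")
  if (!all(req %in% names(signals))) {
    abort("`signals` must carry gene_id, signal_control and signal_treated.")
  }
  if (any(signals$signal_control <= 0 | signals$signal_treated <= 0)) {
    abort("Signals must be strictly positive.")
  }
  signals %>%
    mutate(
      ratio = .data$signal_treated / .data$signal_control,
      signed_fc = ifelse(.data$ratio >= 1, .data$ratio, -1 / .data$ratio)
    )
}

#' Call differentially expressed genes by fold change
#'
#' Flags genes whose transcript-level signal changes at least
#' `threshold`-fold between conditions (default 2-fold, in either
#' direction). No variance-based test accompanies the call: the method is a
#' pure fold-change rule on replicate-averaged signals.
#'
#' @param fc_table Output of [fold_changes()].
#' @param threshold Fold-change threshold, >= 1 (default 2).
#' @return A `de_calls` tibble: the input plus `direction` (`up`, `down`,
#'   `none`). Summary counts are available via [glance()].
#' @examples
#' sig <- tibble::tibble(gene_id = c("a", "b", "c"),
#'                       signal_control = c(100, 100, 100),
#'                       signal_treated = c(250, 150, 40))
#' call_de(fold_changes(sig))
#' @export
call_de <- function(fc_table, threshold = 2) {
  if (!all(c("gene_id", "ratio") %in% names(fc_table))) {
    abort("`fc_table` must carry gene_id and ratio (see fold_changes()).")
  }
  if (threshold < 1) abort("`threshold` must be >= 1.")
  out <- fc_table %>%
    mutate(direction = dplyr::case_when(
      .data$ratio >= threshold ~ "up",
      .data$ratio <= 1 / threshold ~ "down",
      TRUE ~ "none"
    ))
  structure(out, class = c("de_calls", class(out)),
            de_threshold = threshold)
}

#' @export
glance.de_calls <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_de = sum(x$direction != "none"),
    n_up = sum(x$direction == "up"),
    n_down = sum(x$direction == "down"),
    threshold = attr(x, "de_threshold")
  )
}

#' @export
tidy.de_calls <- function(x, ...) {
  as_tibble(x) %>%
    select("gene_id", "ratio", "signed_fc", "direction")
}
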