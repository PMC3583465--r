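#' Run the full exon-array analysis pipeline
#'
#' Orchestrates normalize -> filter -> transcript summarization -> DE call
#' -> GNPN/splicing index -> AS call -> (optional) term enrichment of the
#' DE gene set against the post-filter universe. The run is deterministic
#' given its inputs and configuration (no randomness is used); the report
#' records per-stage counts and a hash of the configuration, which is also
#' stamped into every output file header when `out_dir` is given.
#'
#' @param intensity Raw intensity tibble (`probe_id` + sample columns).
#' @param annotation Probe annotation tibble.
#' @param design Sample design tibble.
#' @param term_map Optional gene-to-term map; enables the enrichment stage.
#' @param intensity_threshold,filter_policy Passed to
#'   [filter_low_intensity()].
#' @param de_threshold Fold-change threshold for [call_de()].
#' @param si_mode,si_up,si_down,si_diff Splicing-index mode and thresholds
#'   (see [splicing_index()], [call_as_candidates()]).
#' @param min_term_size Passed to [enrich()].
#' @param out_dir Optional directory; when given, every stage output is
#'   written as a TSV with a provenance header.
#' @param seed Optional seed recorded in output headers (the pipeline
#'   itself draws no random numbers).
#' @return A `pipeline_run` list with `report` (one-row tibble of stage
#'   counts), `config`, `config_hash` and the stage outputs `normalized`,
#'   `removed`, `signals`, `de`, `gnpn`, `splice`, `as_summary`,
#'   `enrichment` (NULL without a term map).
#' @export
run_pipeline <- function(intensity, annotation, design, term_map = NULL,
                         intensity_threshold = 400,
                         filter_policy = "any_condition_mean",
                         de_threshold = 2,
                         si_mode = "ratio", si_up = 2, si_down = 0.5,
                         si_diff = 1,
                         min_term_size = 2L,
                         out_dir = NULL, seed = NULL) {
  config <- list(
    intensity_threshold = intensity_threshold,
    filter_policy = filter_policy,
    de_threshold = de_threshold,
    si_mode = si_mode, si_up = si_up, si_down = si_down, si_diff = si_diff,
    min_term_size = min_term_size
  )
  config_hash <- rlang::hash(config)

  normalized <- normalize_global_mean(intensity)
  filtered <- filter_low_intensity(normalized, design,
                                   intensity_threshold = intensity_threshold,
                                   filter_policy = filter_policy)

  signals <- summarize_transcripts(filtered$intensity, annotation, design)
  de <- call_de(fold_changes(signals), threshold = de_threshold)

  gnpn <- compute_gnpn(filtered$intensity, annotation, design)
  splice <- call_as_candidates(splicing_index(gnpn, mode = si_mode),
                               up_threshold = si_up,
                               down_threshold = si_down,
                               diff_threshold = si_diff)
  as_summary <- as_gene_summary(splice)

  enrichment <- NULL
  de_genes <- de$gene_id[de$direction != "none"]
  if (!is.null(term_map) && length(de_genes) > 0L) {
    enrichment <- enrich(de_genes, signals$gene_id, term_map,
                         min_term_size = min_term_size)
  }

  gde <- glance(de)
  report <- tibble(
    n_probes_in = nrow(intensity),
    n_probes_filtered = nrow(filtered$removed),
    n_probes_retained = nrow(filtered$intensity),
    n_genes = nrow(signals),
    n_de = gde$n_de, n_up = gde$n_up, n_down = gde$n_down,
    n_splice_probes = nrow(splice),
    n_as_candidates = sum(splice$candidate),
    n_as_genes = nrow(as_summary),
    n_enriched_terms = if (is.null(enrichment)) NA_integer_
                       else sum(enrichment$p_value < 0.05),
    config_hash = config_hash,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  )

  run <- structure(list(
    report = report, config = config, config_hash = config_hash,
    normalized = normalized, removed = filtered$removed,
    signals = signals, de = de, gnpn = gnpn, splice = splice,
    as_summary = as_summary, enrichment = enrichment
  ), class = "pipeline_run")

  if (!is.null(out_dir)) write_pipeline_outputs(run, out_dir, seed = seed)
  run
}

write_pipeline_outputs <- function(run, out_dir, seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  h <- list(seed = seed, config_hash = run$config_hash)
  out <- function(x, name) {
    write_tsv_with_header(as_tibble(x), file.path(out_dir, name),
                          seed = h$seed, config_hash = h$config_hash)
  }
  out(run$normalized, "normalized_intensity.tsv")
  out(run$removed, "removed_probes.tsv")
  out(run$signals, "gene_signals.tsv")
  out(tidy(run$de), "de_calls.tsv")
  out(run$gnpn, "gnpn.tsv")
  out(tidy(run$splice), "splice_calls.tsv")
  out(run$as_summary, "as_gene_summary.tsv")
  if (!is.null(run$enrichment)) out(tidy(run$enrichment), "enrichment.tsv")
  out(run$report, "run_report.tsv")
  invisible(out_dir)
}

#' @export
print.pipeline_run <- function(x, ...) {
  r <- x$report
  cat("Exon-array pipeline run\n")
  cat(sprintf("  probes: %d in, %d removed by filter, %d retained\n",
              r$n_probes_in, r$n_probes_filtered, r$n_probes_retained))
  cat(sprintf("  genes summarized: %d; DE: %d (%d up / %d down)\n",
              r$n_genes, r$n_de, r$n_up, r$n_down))
  cat(sprintf("  AS candidate probes: %d across %d genes\n",
              r$n_as_candidates, r$n_as_genes))
  if (!is.na(r$n_enriched_terms)) {
    cat(sprintf("  enriched terms (p < 0.05): %d\n", r$n_enriched_terms))
  }
  cat(sprintf("  config hash: %s\n", r$config_hash))
  invisible(x)
}

#' @export
glance.pipeline_run <- function(x, ...) x$report
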