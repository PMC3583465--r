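# Recovery scoring against a simulation's spiked truth.

#' Score differential-expression calls against spiked truth
#'
#' Compares the genes a run calls differentially expressed with the genes a
#' simulation actually spiked, giving sensitivity (recall of spiked genes)
#' and the false-discovery proportion among the calls.
#'
#' @param de A `de_calls` tibble from [call_de()].
#' @param truth Truth tibble from [simulate_experiment()].
#' @return One-row tibble: `n_true`, `n_called`, `tp`, `fp`, `sensitivity`,
#'   `fdp`.
#' @export
score_de_calls <- function(de, truth) {
  called <- de$gene_id[de$direction != "none"]
  spiked <- truth$gene_id[truth$is_de]
  tp <- length(intersect(called, spiked))
  fp <- length(setdiff(called, spiked))
  tibble(
    n_true = length(spiked), n_called = length(called), tp = tp, fp = fp,
    sensitivity = if (length(spiked) > 0L) tp / length(spiked) else NA_real_,
    fdp = if (length(called) > 0L) fp / length(called) else 0
  )
}

#' Score alternative-splicing candidate exons against spiked truth
#'
#' Compares flagged candidate exons with the exons a simulation actually
#' shifted. An exon counts as recovered if any of its probes is flagged.
#'
#' @param splice A `splice_calls` tibble from [call_as_candidates()].
#' @param truth Truth tibble from [simulate_experiment()].
#' @return One-row tibble: `n_true`, `n_called`, `tp`, `fp`, `sensitivity`,
#'   `fdp`.
#' @export
score_as_calls <- function(splice, truth) {
  called <- unique(splice$exon_id[splice$candidate])
  spiked <- truth$as_exon_id[!is.na(truth$as_exon_id)]
  tp <- length(intersect(called, spiked))
  fp <- length(setdiff(called, spiked))
  tibble(
    n_true = length(spiked), n_called = length(called), tp = tp, fp = fp,
    sensitivity = if (length(spiked) > 0L) tp / length(spiked) else NA_real_,
    fdp = if (length(called) > 0L) fp / length(called) else 0
  )
}
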