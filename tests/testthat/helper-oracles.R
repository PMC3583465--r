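# Independent oracles and tiny in-code fixtures shared across tests.

suppressPackageStartupMessages(library(dplyr))

# Upper-tail hypergeometric probability from binomial coefficients only
# (no distribution functions), for cross-checking the implementation.
hyper_tail_choose <- function(k, K, n, N) {
  i <- seq(k, min(K, n))
  if (k > min(K, n)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Brute-force enumeration of every size-n draw from a universe of N genes
# of which K carry the term; returns P(overlap >= k). Only for tiny N.
hyper_tail_enumerate <- function(k, K, n, N) {
  term <- seq_len(K)
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2, function(d) sum(d %in% term) >= k)
  mean(hits)
}

# Two-probe / two-condition toy matrix with explicit values.
# `values` is a named list: sample_id -> numeric vector over probes.
toy_intensity <- function(probe_ids, values) {
  out <- tibble::tibble(probe_id = probe_ids)
  for (s in names(values)) out[[s]] <- values[[s]]
  out
}

toy_design <- function(r = 2L) {
  tibble::tibble(
    sample_id = c(sprintf("control_%d", seq_len(r)),
                  sprintf("treated_%d", seq_len(r))),
    condition = rep(c("control", "treated"), each = r),
    replicate = rep(seq_len(r), 2L)
  )
}

toy_annotation <- function(probe_ids, gene_ids, exon_ids = NULL) {
  tibble::tibble(
    probe_id = probe_ids,
    gene_id = gene_ids,
    exon_id = exon_ids %||% paste0(probe_ids, "_ex")
  )
}

# Deterministic raw vector with exactly the requested mean and sample SD
# (n = 3), for checking the summary-statistic t-test against t.test().
raw_from_summary <- function(mean, sd) mean + sd * c(-1, 0, 1)

`%||%` <- rlang::`%||%`
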