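#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` where `X` counts genes annotated to a term in a draw of `n`
#' genes, without replacement, from a universe of `N` genes of which `K`
#' carry the term. Evaluated in log space via [stats::phyper()], so it is
#' numerically stable for universes well beyond 1e5 genes. Vectorized over
#' all four arguments.
#'
#' @param k Observed overlap (0 <= k <= min(K, n)).
#' @param K Term size in the universe.
#' @param n Query-set size.
#' @param N Universe size.
#' @return Upper-tail probability in (0, 1].
#' @examples
#' hypergeom_upper_tail(5, 5, 5, 10) # 1 / choose(10, 5)
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  args <- vctrs_recycle(k, K, n, N)
  k <- args[[1]]; K <- args[[2]]; n <- args[[3]]; N <- args[[4]]
  if (any(k < 0 | K < 0 | n < 0 | N < 0) ||
      any(K > N | n > N) || any(k > pmin(K, n))) {
    abort("Counts must satisfy 0 <= k <= min(K, n) and K, n <= N.")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

# recycle scalar arguments against each other
vctrs_recycle <- function(...) {
  xs <- list(...)
  len <- max(vapply(xs, length, integer(1)))
  lapply(xs, function(x) {
    if (length(x) == len) x
    else if (length(x) == 1L) rep(x, len)
    else abort("Arguments must be length 1 or a common length.")
  })
}

#' Hypergeometric term over-representation
#'
#' Tests every term of a gene-to-term map for over-representation in a
#' query gene set relative to an analysis universe, using the upper-tail
#' hypergeometric distribution, and adjusts the resulting p-values across
#' the tested term family with the Benjamini-Hochberg step-up procedure.
#' The recommended universe is the set of genes with a transcript-level
#' signal after preprocessing (conditioning on detectability), not the
#' whole genome.
#'
#' @param query_genes Character vector of query gene ids (e.g. the DE or AS
#'   gene set); must be a subset of `universe_genes`.
#' @param universe_genes Character vector of universe gene ids.
#' @param term_map Tibble with `gene_id`, `term_id` and optionally
#'   `term_name` (see [read_gene_term_map()]).
#' @param min_term_size Smallest in-universe term size tested (default 2).
#' @return An `enrich_result` tibble sorted by ascending p-value with
#'   columns `term_id`, `term_name`, `k`, `K`, `n`, `N`, `p_value`,
#'   `q_value` and `genes` (comma-separated query genes carrying the term).
#' @export
enrich <- function(query_genes, universe_genes, term_map, min_term_size = 2L) {
  if (!all(c("gene_id", "term_id") %in% names(term_map))) {
    abort("`term_map` must carry gene_id and term_id columns.")
  }
  if (nrow(term_map) == 0L) {
    abort("Empty term map: enrichment refuses to run without annotations.")
  }
  universe_genes <- unique(universe_genes)
  query_genes <- unique(query_genes)
  offenders <- setdiff(query_genes, universe_genes)
  if (length(offenders) > 0L) {
    abort(paste0("Query gene(s) absent from the universe: ",
                 paste(utils::head(offenders, 10L), collapse = ", ")))
  }
  if (!"term_name" %in% names(term_map)) term_map$term_name <- NA_character_

  tm <- term_map %>%
    filter(.data$gene_id %in% universe_genes) %>%
    distinct(.data$gene_id, .data$term_id, .keep_all = TRUE)

  N <- length(universe_genes)
  n <- length(query_genes)

  res <- tm %>%
    group_by(.data$term_id) %>%
    summarise(
      term_name = dplyr::first(.data$term_name),
      K = n(),
      k = sum(.data$gene_id %in% query_genes),
      genes = paste(sort(intersect(.data$gene_id, query_genes)),
                    collapse = ","),
      .groups = "drop"
    ) %>%
    filter(.data$K >= min_term_size) %>%
    mutate(
      n = n, N = N,
      p_value = hypergeom_upper_tail(.data$k, .data$K, n, N),
      q_value = bh_adjust(.data$p_value)
    ) %>%
    select("term_id", "term_name", "k", "K", "n", "N",
           "p_value", "q_value", "genes") %>%
    arrange(.data$p_value, .data$term_id)
  structure(res, class = c("enrich_result", class(res)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`, the false-discovery-
#' rate adjustment used for the q-values reported alongside enrichment
#' p-values.
#'
#' @param p Numeric vector of p-values.
#' @return Vector of q-values of the same length.
#' @export
bh_adjust <- function(p) {
  p.adjust(p, method = "BH")
}

#' @export
glance.enrich_result <- function(x, ...) {
  tibble(
    n_terms_tested = nrow(x),
    n_terms_p05 = sum(x$p_value < 0.05),
    n_terms_q05 = sum(x$q_value < 0.05),
    universe_size = if (nrow(x) > 0L) x$N[1L] else NA_integer_,
    query_size = if (nrow(x) > 0L) x$n[1L] else NA_integer_
  )
}

#' @export
tidy.enrich_result <- function(x, ...) as_tibble(x)
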