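#' MA-style plot of differential-expression calls
#'
#' Log2 fold-change against log2 average transcript signal, with the
#' fold-change thresholds drawn and called genes coloured by direction.
#'
#' @param object A `de_calls` tibble from [call_de()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.de_calls <- function(object, ...) {
  thr <- attr(object, "de_threshold")
  df <- as_tibble(object) %>%
    mutate(
      avg = log2(sqrt(.data$signal_control * .data$signal_treated)),
      lfc = log2(.data$ratio)
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$avg, y = .data$lfc,
                                   colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::geom_hline(yintercept = c(-log2(thr), log2(thr)),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(up = "#c0392b", down = "#2980b9", none = "grey60")) +
    ggplot2::labs(x = "log2 mean transcript signal",
                  y = "log2 fold change (treated / control)",
                  colour = "call") +
    ggplot2::theme_minimal()
}

#' Splicing-index distribution plot
#'
#' Histogram of the per-probe splicing index (log2 scale in ratio mode)
#' with candidate thresholds marked.
#'
#' @param object A `splice_calls` tibble from [call_as_candidates()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.splice_calls <- function(object, ...) {
  thr <- attr(object, "thresholds")
  mode <- unique(object$mode)
  df <- as_tibble(object)
  if (isTRUE(mode == "ratio")) {
    df$x <- log2(df$si)
    vlines <- log2(c(thr$down, thr$up))
    xlab <- "log2 splicing index (ratio mode)"
  } else {
    df$x <- df$si
    vlines <- c(-thr$diff, thr$diff)
    xlab <- "splicing index (difference mode)"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, fill = .data$candidate)) +
    ggplot2::geom_histogram(bins = 80, alpha = 0.9) +
    ggplot2::geom_vline(xintercept = vlines, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "#c0392b")) +
    ggplot2::labs(x = xlab, y = "probes", fill = "candidate") +
    ggplot2::theme_minimal()
}

#' Compare array and qPCR fold-changes per gene
#'
#' Side-by-side bars of the signed fold-change measured on the array and
#' the qPCR 2^-ddCt fold-change for the validated genes.
#'
#' @param de A `de_calls` tibble (array side).
#' @param qpcr A `ddct_result` tibble (qPCR side).
#' @return A ggplot object.
#' @export
plot_qpcr_comparison <- function(de, qpcr) {
  q <- as_tibble(qpcr) %>%
    mutate(signed_fc = ifelse(.data$fold_change >= 1, .data$fold_change,
                              -1 / .data$fold_change),
           platform = "qPCR") %>%
    select("gene_id", "signed_fc", "platform")
  a <- as_tibble(de) %>%
    filter(.data$gene_id %in% q$gene_id) %>%
    mutate(platform = "array") %>%
    select("gene_id", "signed_fc", "platform")
  df <- bind_rows(a, q)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene_id, y = .data$signed_fc,
                                   fill = .data$platform)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = c(-1, 1), linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "signed fold change", fill = NULL) +
    ggplot2::theme_minimal()
}
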