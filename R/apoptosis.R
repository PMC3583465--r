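#' Summarize quadrant-gated apoptosis percentages
#'
#' In Annexin-V/PI dual staining, cells in the lower-right (Annexin+/PI-)
#' quadrant are early apoptotic and cells in the upper-right (Annexin+/PI+)
#' quadrant late apoptotic; the extent of apoptosis per sample is the sum
#' of the two percentages. This function computes that sum per sample (if
#' not already supplied) and returns per-condition mean and sample SD.
#'
#' @param quadrants Tibble with `sample_id`, `condition` and either
#'   `pct_LR` + `pct_UR` or a precomputed `pct_apoptotic` column; all
#'   percentages in `[0, 100]`.
#' @return Tibble with one row per condition: `condition`, `n`, `mean`,
#'   `sd` (sample SD; `NA` for a single replicate).
#' @examples
#' q <- tibble::tibble(
#'   sample_id = paste0("s", 1:6),
#'   condition = rep(c("treated", "control"), each = 3),
#'   pct_LR = c(7.0, 7.2, 6.9, 3.0, 3.1, 2.8),
#'   pct_UR = c(4.5, 4.3, 4.4, 1.8, 1.7, 1.9)
#' )
#' apoptosis_fraction(q)
#' @export
apoptosis_fraction <- function(quadrants) {
  if (!all(c("sample_id", "condition") %in% names(quadrants))) {
    abort("`quadrants` must carry sample_id and condition.")
  }
  if (!"pct_apoptotic" %in% names(quadrants)) {
    if (!all(c("pct_LR", "pct_UR") %in% names(quadrants))) {
      abort("Provide pct_LR and pct_UR, or a pct_apoptotic column.")
    }
    quadrants <- quadrants %>%
      mutate(pct_apoptotic = .data$pct_LR + .data$pct_UR)
  }
  pct_cols <- intersect(c("pct_LR", "pct_UR", "pct_apoptotic"),
                        names(quadrants))
  vals <- unlist(quadrants[pct_cols])
  if (any(!is.finite(vals) | vals < 0 | vals > 100)) {
    abort("Percentages must lie within [0, 100].")
  }
  quadrants %>%
    group_by(.data$condition) %>%
    summarise(n = n(),
              mean = mean(.data$pct_apoptotic),
              sd = sd(.data$pct_apoptotic),
              .groups = "drop")
}

#' Two-sample t-test from group summary statistics
#'
#' Computes a two-sided two-sample t-test directly from per-group summary
#' statistics (n, mean, SD) — the form in which flow-cytometry results are
#' typically published. The default is the classical Student test with a
#' pooled variance estimate; `variant = "welch"` uses the Welch
#' (unequal-variance) statistic with Satterthwaite degrees of freedom.
#' `t` is computed as group 1 minus group 2 in the order given.
#'
#' @param groups Two-row tibble with columns `condition` (or any label
#'   column named `condition`), `n`, `mean`, `sd` — e.g. the output of
#'   [apoptosis_fraction()].
#' @param variant `"student"` (pooled variance, default) or `"welch"`.
#' @param alpha Significance level for the convenience flag (default 0.05).
#' @return An object of class `summary_ttest` with elements `statistic`,
#'   `df`, `p_value`, `estimate` (difference in means), `variant`,
#'   `significant`, and the input summaries. [tidy()] returns it as a
#'   one-row tibble.
#' @examples
#' g <- tibble::tibble(condition = c("treated", "control"),
#'                     n = c(3, 3), mean = c(11.47, 4.77),
#'                     sd = c(0.25, 0.40))
#' two_sample_t(g)
#' @export
two_sample_t <- function(groups, variant = c("student", "welch"),
                         alpha = 0.05) {
  variant <- match.arg(variant)
  if (!all(c("n", "mean", "sd") %in% names(groups)) || nrow(groups) != 2L) {
    abort("`groups` must be a two-row table with n, mean and sd columns.")
  }
  n1 <- groups$n[1L]; n2 <- groups$n[2L]
  m1 <- groups$mean[1L]; m2 <- groups$mean[2L]
  s1 <- groups$sd[1L]; s2 <- groups$sd[2L]
  if (n1 < 2L || n2 < 2L) abort("Each group needs n >= 2.")
  if (s1 < 0 || s2 < 0) abort("SDs must be non-negative.")

  if (s1 == 0 && s2 == 0) {
    if (m1 == m2) {
      warn("Both groups are degenerate (sd = 0) with equal means; p = 1.")
      res <- list(statistic = 0, df = n1 + n2 - 2, p_value = 1)
    } else {
      warn("Both groups have sd = 0 with distinct means; p = 0.")
      res <- list(statistic = sign(m1 - m2) * Inf, df = n1 + n2 - 2,
                  p_value = 0)
    }
  } else if (variant == "student") {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    tval <- (m1 - m2) / se
    df <- n1 + n2 - 2
    res <- list(statistic = tval, df = df,
                p_value = 2 * pt(-abs(tval), df))
  } else {
    se2 <- s1^2 / n1 + s2^2 / n2
    tval <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
    res <- list(statistic = tval, df = df,
                p_value = 2 * pt(-abs(tval), df))
  }

  labels <- if ("condition" %in% names(groups)) groups$condition
            else c("group1", "group2")
  structure(list(
    statistic = res$statistic,
    df = res$df,
    p_value = res$p_value,
    estimate = m1 - m2,
    variant = variant,
    alpha = alpha,
    significant = res$p_value < alpha,
    groups = labels,
    summaries = as_tibble(groups)
  ), class = "summary_ttest")
}

#' @export
print.summary_ttest <- function(x, ...) {
  cat(sprintf("Two-sample t-test (%s), %s vs %s\n",
              x$variant, x$groups[1L], x$groups[2L]))
  cat(sprintf("t = %.4g, df = %.4g, p = %.4g (%ssignificant at alpha = %g)\n",
              x$statistic, x$df, x$p_value,
              if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' @export
tidy.summary_ttest <- function(x, ...) {
  tibble(
    estimate = x$estimate,
    statistic = x$statistic,
    df = x$df,
    p_value = x$p_value,
    variant = x$variant,
    significant = x$significant
  )
}

#' @export
glance.summary_ttest <- function(x, ...) tidy(x)
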