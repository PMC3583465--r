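#' Relative quantification by the 2^-ddCt method
#'
#' Computes relative expression of each target gene from qPCR cycle-
#' threshold (Ct) records. Per sample, `dCt = ct_target - ct_reference`
#' normalizes the target to the reference (housekeeping) gene; the mean dCt
#' of the calibrator condition (default `control`) is subtracted from the
#' mean dCt of the other condition to give `ddCt`, and the fold-change is
#' `2^-ddCt`. Amplification efficiency is fixed at 2, as the method's name
#' implies; replicates are aggregated on the dCt (log) scale, and the
#' reported spread is the standard deviation of the test-condition dCt
#' values (the calibrator's variance is not propagated).
#'
#' @param records Tibble with columns `sample_id`, `condition`, `gene_id`,
#'   `ct_target`, `ct_reference`; Ct values must lie within `ct_limits`.
#' @param reference_condition Calibrator condition (default `"control"`).
#' @param ct_limits Admissible Ct range; default `c(0, 45)` (a 45-cycle
#'   program).
#' @return A `ddct_result` tibble with one row per gene: `gene_id`,
#'   `fold_change`, `log2_fold`, `sd_log2`, `n_replicates`.
#' @examples
#' ct <- tibble::tibble(
#'   sample_id = c("c1", "c2", "t1", "t2"),
#'   condition = c("control", "control", "treated", "treated"),
#'   gene_id = "BAX",
#'   ct_target = c(26, 26, 24, 24),
#'   ct_reference = c(20, 20, 19, 19)
#' )
#' delta_delta_ct(ct) # ddCt = -1, fold = 2
#' @export
delta_delta_ct <- function(records, reference_condition = "control",
                           ct_limits = c(0, 45)) {
  req <- c("sample_id", "condition", "gene_id", "ct_target", "ct_reference")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0L) {
    abort(paste0("`records` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  cts <- c(records$ct_target, records$ct_reference)
  if (any(!is.finite(cts) | cts < ct_limits[1L] | cts > ct_limits[2L])) {
    abort(sprintf("Ct values must lie within [%g, %g].",
                  ct_limits[1L], ct_limits[2L]))
  }
  conds <- unique(records$condition)
  if (!reference_condition %in% conds) {
    abort(sprintf("Reference condition '%s' absent from records.",
                  reference_condition))
  }
  if (length(conds) != 2L) {
    abort("Exactly two conditions (calibrator and test) are required.")
  }

  out <- records %>%
    mutate(delta_ct = .data$ct_target - .data$ct_reference,
           role = ifelse(.data$condition == reference_condition,
                         "calibrator", "test")) %>%
    group_by(.data$gene_id) %>%
    summarise(
      n_calibrator = sum(.data$role == "calibrator"),
      n_replicates = sum(.data$role == "test"),
      ddct = mean(.data$delta_ct[.data$role == "test"]) -
        mean(.data$delta_ct[.data$role == "calibrator"]),
      sd_log2 = ifelse(.data$n_replicates > 1L,
                       sd(.data$delta_ct[.data$role == "test"]), 0),
      .groups = "drop"
    )
  if (any(out$n_calibrator == 0L | out$n_replicates == 0L)) {
    bad <- out$gene_id[out$n_calibrator == 0L | out$n_replicates == 0L]
    abort(paste0("Gene(s) missing a condition: ", paste(bad, collapse = ", ")))
  }
  out <- out %>%
    mutate(fold_change = 2^(-.data$ddct), log2_fold = -.data$ddct) %>%
    select("gene_id", "fold_change", "log2_fold", "sd_log2", "n_replicates")
  structure(out, class = c("ddct_result", class(out)),
            reference_condition = reference_condition)
}

#' @export
glance.ddct_result <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_up = sum(x$fold_change > 1),
    n_down = sum(x$fold_change < 1),
    reference_condition = attr(x, "reference_condition")
  )
}

#' @export
tidy.ddct_result <- function(x, ...) as_tibble(x)
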