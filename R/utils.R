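#' Geometric mean
#'
#' Geometric mean of a positive numeric vector, computed on the log scale so
#' long vectors of large intensities do not overflow.
#'
#' @param x Positive numeric vector.
#' @param na.rm Drop `NA` values before averaging.
#' @return A single positive number; `NaN` for an empty vector.
#' @examples
#' geometric_mean(c(4, 9)) # 6
#' @export
geometric_mean <- function(x, na.rm = FALSE) {
  if (any(x <= 0, na.rm = TRUE)) {
    abort("geometric_mean() requires strictly positive values.")
  }
  exp(mean(log(x), na.rm = na.rm))
}

# Sample columns of a wide intensity tibble (everything except probe_id).
sample_columns <- function(intensity) {
  setdiff(names(intensity), "probe_id")
}

check_intensity <- function(intensity, call = rlang::caller_env()) {
  if (!is.data.frame(intensity) || !"probe_id" %in% names(intensity)) {
    abort("`intensity` must be a data frame with a `probe_id` column.",
          call = call)
  }
  smp <- sample_columns(intensity)
  if (length(smp) == 0L) {
    abort("`intensity` has no sample columns.", call = call)
  }
  vals <- as.matrix(intensity[smp])
  if (nrow(intensity) > 0L && !is.numeric(vals)) {
    abort("All sample columns of `intensity` must be numeric.", call = call)
  }
  if (nrow(intensity) > 0L && any(!is.finite(vals) | vals <= 0)) {
    bad <- which(!is.finite(vals) | vals <= 0, arr.ind = TRUE)[1L, ]
    abort(sprintf(
      "Non-positive intensity at probe '%s', sample '%s'.",
      intensity$probe_id[bad[1L]], smp[bad[2L]]
    ), call = call)
  }
  invisible(intensity)
}

check_design <- function(design, intensity = NULL,
                         call = rlang::caller_env()) {
  req <- c("sample_id", "condition", "replicate")
  missing_cols <- setdiff(req, names(design))
  if (length(missing_cols) > 0L) {
    abort(paste0("`design` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")), call = call)
  }
  bad_cond <- setdiff(unique(design$condition), c("control", "treated"))
  if (length(bad_cond) > 0L) {
    abort(paste0("`design` conditions must be 'control' or 'treated'; found: ",
                 paste(bad_cond, collapse = ", ")), call = call)
  }
  for (cond in c("control", "treated")) {
    if (!cond %in% design$condition) {
      abort(sprintf("condition missing: no '%s' samples in `design`.", cond),
            call = call)
    }
  }
  if (!is.null(intensity)) {
    smp <- sample_columns(intensity)
    if (!setequal(smp, design$sample_id)) {
      abort(paste0(
        "Sample mismatch between intensity matrix and design. ",
        "Matrix-only: ", paste(setdiff(smp, design$sample_id), collapse = ", "),
        "; design-only: ", paste(setdiff(design$sample_id, smp), collapse = ", ")
      ), call = call)
    }
  }
  invisible(design)
}

check_annotation <- function(annotation, call = rlang::caller_env()) {
  req <- c("probe_id", "gene_id", "exon_id")
  missing_cols <- setdiff(req, names(annotation))
  if (length(missing_cols) > 0L) {
    abort(paste0("`annotation` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")), call = call)
  }
  dup <- annotation$probe_id[duplicated(annotation$probe_id)]
  if (length(dup) > 0L) {
    abort(paste0("Duplicated probe_id in annotation: ",
                 paste(unique(dup), collapse = ", ")), call = call)
  }
  multi <- annotation %>%
    distinct(.data$exon_id, .data$gene_id) %>%
    count(.data$exon_id) %>%
    filter(.data$n > 1L)
  if (nrow(multi) > 0L) {
    abort(paste0("Exon(s) mapped to more than one gene: ",
                 paste(multi$exon_id, collapse = ", ")), call = call)
  }
  invisible(annotation)
}

# Long format: one row per (probe, sample) with condition attached.
intensity_long <- function(intensity, design) {
  intensity %>%
    tidyr::pivot_longer(-"probe_id",
                        names_to = "sample_id", values_to = "intensity") %>%
    inner_join(design, by = "sample_id")
}

# Per-probe arithmetic mean intensity within each condition, wide by condition.
condition_means <- function(intensity, design) {
  intensity_long(intensity, design) %>%
    group_by(.data$probe_id, .data$condition) %>%
    summarise(mean_intensity = mean(.data$intensity), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "condition",
                       values_from = "mean_intensity",
                       names_prefix = "mean_") %>%
    # restore input probe order
    arrange(match(.data$probe_id, intensity$probe_id))
}
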