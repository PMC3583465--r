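# All tables travel as TSV with a header row; decimal point, UTF-8, no
# thousands separators. Writers prepend one '#' comment line recording the
# tool version and (optionally) seed/config hash so outputs are traceable;
# readers skip '#' lines.

provenance_header <- function(seed = NULL, config_hash = NULL) {
  ver <- tryCatch(as.character(packageVersion("exondiff")),
                  error = function(e) "dev")
  parts <- c(sprintf("exondiff %s", ver))
  if (!is.null(seed)) parts <- c(parts, sprintf("seed=%s", seed))
  if (!is.null(config_hash)) parts <- c(parts, sprintf("config=%s", config_hash))
  paste0("# ", paste(parts, collapse = " | "))
}

write_tsv_with_header <- function(x, path, seed = NULL, config_hash = NULL) {
  readr::write_lines(provenance_header(seed, config_hash), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_tsv_quiet <- function(path, col_types) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  x <- readr::read_tsv(path, comment = "#", col_types = col_types,
                       progress = FALSE)
  probs <- readr::problems(x)
  if (nrow(probs) > 0L) {
    abort(paste0(
      sprintf("Malformed rows in %s: ", path),
      paste(sprintf("line %d (%s)", probs$row + 1L, probs$expected),
            collapse = "; ")
    ))
  }
  x
}

#' Read and write probe annotation tables
#'
#' A probe annotation maps every exon-level probe to its exon and gene:
#' columns `probe_id`, `gene_id`, `exon_id`. `probe_id` must be unique and
#' every exon must belong to exactly one gene.
#'
#' @param path Path to a TSV file with a header row.
#' @return `read_probe_annotation()` returns the validated annotation
#'   tibble; `write_probe_annotation()` invisibly returns `path`.
#' @export
read_probe_annotation <- function(path) {
  ann <- read_tsv_quiet(path, readr::cols(.default = readr::col_character()))
  if (nrow(ann) == 0L) abort(sprintf("Empty probe annotation: %s", path))
  missing_cols <- setdiff(c("probe_id", "gene_id", "exon_id"), names(ann))
  if (length(missing_cols) > 0L) {
    abort(paste0("Annotation file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  ann <- ann %>% select("probe_id", "gene_id", "exon_id")
  check_annotation(ann)
  ann
}

#' @rdname read_probe_annotation
#' @param annotation Annotation tibble to write.
#' @param ... Passed to the provenance header (`seed`, `config_hash`).
#' @export
write_probe_annotation <- function(annotation, path, ...) {
  check_annotation(annotation)
  write_tsv_with_header(annotation, path, ...)
}

#' Read an intensity matrix together with its sample design
#'
#' The intensity matrix is a TSV with `probe_id` plus one numeric column per
#' sample; the design TSV has `sample_id`, `condition` (`control` /
#' `treated`) and `replicate`. Sample columns must match the design's
#' `sample_id`s exactly, both conditions must be present, and every
#' intensity must be strictly positive — zeros or negatives are rejected
#' with the offending probe/sample coordinates.
#'
#' @param path Path to the intensity TSV.
#' @param design_path Path to the sample design TSV.
#' @return A list with tibbles `intensity` and `design`.
#' @export
read_intensity_matrix <- function(path, design_path) {
  design <- read_sample_design(design_path)
  intensity <- read_tsv_quiet(path, readr::cols(
    probe_id = readr::col_character(),
    .default = readr::col_double()
  ))
  if (!"probe_id" %in% names(intensity)) {
    abort(sprintf("Intensity file %s lacks a probe_id column.", path))
  }
  dup <- intensity$probe_id[duplicated(intensity$probe_id)]
  if (length(dup) > 0L) {
    abort(paste0("Duplicated probe_id in intensity matrix: ",
                 paste(unique(dup), collapse = ", ")))
  }
  check_intensity(intensity)
  check_design(design, intensity)
  list(intensity = intensity, design = design)
}

#' @rdname read_intensity_matrix
#' @export
read_sample_design <- function(design_path) {
  design <- read_tsv_quiet(design_path, readr::cols(
    sample_id = readr::col_character(),
    condition = readr::col_character(),
    replicate = readr::col_integer()
  ))
  check_design(design)
  design
}

#' @rdname read_intensity_matrix
#' @param intensity,design Tibbles to write.
#' @param ... Passed to the provenance header (`seed`, `config_hash`).
#' @export
write_intensity_matrix <- function(intensity, path, ...) {
  check_intensity(intensity)
  write_tsv_with_header(intensity, path, ...)
}

#' @rdname read_intensity_matrix
#' @export
write_sample_design <- function(design, path, ...) {
  check_design(design)
  write_tsv_with_header(design, path, ...)
}

#' Read a gene-to-GO-term membership table
#'
#' Expects a TSV with columns `gene_id`, `term_id` and optionally
#' `term_name`. Duplicated (gene, term) pairs are dropped with a warning;
#' ontology structure (GAF/OBO, graph propagation) is out of scope — only
#' flat term membership is used.
#'
#' @param path Path to the TSV file.
#' @return A tibble with `gene_id`, `term_id`, `term_name` (NA when absent).
#' @export
read_gene_term_map <- function(path) {
  tm <- read_tsv_quiet(path, readr::cols(.default = readr::col_character()))
  missing_cols <- setdiff(c("gene_id", "term_id"), names(tm))
  if (length(missing_cols) > 0L) {
    abort(paste0("Term-map file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"term_name" %in% names(tm)) tm$term_name <- NA_character_
  tm <- tm %>% select("gene_id", "term_id", "term_name")
  n0 <- nrow(tm)
  tm <- tm %>% distinct(.data$gene_id, .data$term_id, .keep_all = TRUE)
  if (nrow(tm) < n0) {
    warn(sprintf("Dropped %d duplicated gene-term pair(s) in %s.",
                 n0 - nrow(tm), path))
  }
  tm
}

#' @rdname read_gene_term_map
#' @param term_map Tibble to write.
#' @param ... Passed to the provenance header (`seed`, `config_hash`).
#' @export
write_gene_term_map <- function(term_map, path, ...) {
  stopifnot(all(c("gene_id", "term_id") %in% names(term_map)))
  write_tsv_with_header(term_map, path, ...)
}
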