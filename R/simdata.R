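#' Specify a synthetic exon-array experiment
#'
#' Builds a validated parameter set for the synthetic exon-microarray
#' generator. The generator emulates a two-condition (control vs. treated)
#' single-channel exon array: each gene carries a handful of exons, each exon
#' one or more probes, and probe intensities are log-normal with
#' multiplicative per-probe affinities and multiplicative measurement noise.
#' A chosen fraction of genes receives a gene-level expression shift
#' (differential expression, DE) and a disjoint fraction receives a shift in
#' a single exon (a cassette-exon alternative-splicing, AS, event); the
#' applied effects are recorded in a truth table.
#'
#' Defaults describe a desk-scale array: 2,000 genes with 4-12 exons each and
#' one probe per exon (the full platform the design emulates carries ~20,411
#' genes and ~174,458 probes; the generator scales to that size if asked).
#' Baseline intensities put roughly 10% of genes near or below the
#' 400-intensity detection filter, split into an expressed stratum
#' (log-mean `baseline_log_mean`) and a low-expression stratum
#' (log-mean `low_log_mean`). Spiked genes are drawn from the expressed
#' stratum so that recovery benchmarks measure the detection method rather
#' than the detection filter.
#'
#' @param n_genes Number of genes (>= 0).
#' @param exon_count_range Integer vector `c(min, max)`: exons per gene are
#'   drawn uniformly from this range.
#' @param probes_per_exon Probes tiled against each exon.
#' @param replicates_per_condition Arrays per condition (>= 1).
#' @param de_fraction Fraction of genes given a gene-level expression shift.
#' @param de_effect Fold multiplier (>= 1) for DE genes; applied up or down
#'   with equal probability.
#' @param as_fraction Fraction of genes given a single shifted exon.
#' @param as_effect Inclusion fold multiplier (>= 1) for the shifted exon;
#'   up or down with equal probability.
#' @param baseline_log_mean,baseline_log_sd Log-normal parameters of
#'   per-gene baseline intensity for the expressed stratum.
#' @param low_expression_fraction Fraction of genes drawn from the
#'   low-expression stratum (near/below the 400 filter).
#' @param low_log_mean,low_log_sd Log-normal parameters of the
#'   low-expression stratum.
#' @param probe_affinity_sd Log-scale SD of the multiplicative per-probe
#'   affinity (probe-to-probe brightness spread within a gene).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal measurement noise; 0 gives noise-free arrays.
#' @param seed Integer PRNG seed; a fixed seed gives bit-identical output.
#' @return A validated list of class `sim_spec`.
#' @seealso [build_gene_models()], [simulate_experiment()]
#' @export
sim_spec <- function(n_genes = 2000,
                     exon_count_range = c(4L, 12L),
                     probes_per_exon = 1L,
                     replicates_per_condition = 2L,
                     de_fraction = 0.025,
                     de_effect = 4,
                     as_fraction = 0.01,
                     as_effect = 4,
                     baseline_log_mean = log(3000),
                     baseline_log_sd = 1,
                     low_expression_fraction = 0.1,
                     low_log_mean = log(200),
                     low_log_sd = 0.5,
                     probe_affinity_sd = 0.25,
                     noise_cv = 0.2,
                     seed = 1L) {
  stopifnot(length(exon_count_range) == 2L)
  n_genes <- as.integer(n_genes)
  exon_count_range <- as.integer(exon_count_range)
  probes_per_exon <- as.integer(probes_per_exon)
  replicates_per_condition <- as.integer(replicates_per_condition)

  if (is.na(n_genes) || n_genes < 0L) {
    abort("`n_genes` must be a non-negative integer.")
  }
  if (anyNA(exon_count_range) || exon_count_range[1L] < 1L ||
      exon_count_range[1L] > exon_count_range[2L]) {
    abort("`exon_count_range` must be integers with 1 <= min <= max.")
  }
  if (is.na(probes_per_exon) || probes_per_exon < 1L) {
    abort("`probes_per_exon` must be a positive integer.")
  }
  if (is.na(replicates_per_condition) || replicates_per_condition < 1L) {
    abort("`replicates_per_condition` must be a positive integer.")
  }
  for (p in c(de_fraction = de_fraction, as_fraction = as_fraction,
              low_expression_fraction = low_expression_fraction)) {
    if (p < 0 || p > 1) abort("Fractions must lie in [0, 1].")
  }
  if (de_effect < 1) abort("`de_effect` must be >= 1.")
  if (as_effect < 1) abort("`as_effect` must be >= 1.")
  if (noise_cv < 0) abort("`noise_cv` must be >= 0.")
  if (baseline_log_sd < 0 || low_log_sd < 0 || probe_affinity_sd < 0) {
    abort("Log-scale spreads must be >= 0.")
  }

  structure(list(
    n_genes = n_genes,
    exon_count_range = exon_count_range,
    probes_per_exon = probes_per_exon,
    replicates_per_condition = replicates_per_condition,
    de_fraction = de_fraction,
    de_effect = de_effect,
    as_fraction = as_fraction,
    as_effect = as_effect,
    baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd,
    low_expression_fraction = low_expression_fraction,
    low_log_mean = low_log_mean,
    low_log_sd = low_log_sd,
    probe_affinity_sd = probe_affinity_sd,
    noise_cv = noise_cv,
    seed = as.integer(seed)
  ), class = "sim_spec")
}

#' Build gene/exon/probe models for a simulated array
#'
#' Draws the exon count of each gene and lays out probe identifiers, giving
#' the probe annotation that every downstream stage consumes. Deterministic
#' under the spec's seed.
#'
#' @param spec A [sim_spec()].
#' @return A list with
#'   * `models`: tibble with `gene_id`, `n_exons`, `n_probes`;
#'   * `annotation`: tibble with `probe_id`, `gene_id`, `exon_id`, one row
#'     per probe, each probe mapping to exactly one exon of one gene.
#' @export
build_gene_models <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (spec$n_genes == 0L) {
    return(list(
      models = tibble(gene_id = character(), n_exons = integer(),
                      n_probes = integer()),
      annotation = tibble(probe_id = character(), gene_id = character(),
                          exon_id = character())
    ))
  }
  rng <- spec$exon_count_range
  n_exons <- withr::with_seed(spec$seed, {
    if (rng[1L] == rng[2L]) {
      rep(rng[1L], spec$n_genes)
    } else {
      sample(seq(rng[1L], rng[2L]), spec$n_genes, replace = TRUE)
    }
  })
  gene_id <- sprintf("G%05d", seq_len(spec$n_genes))
  models <- tibble(
    gene_id = gene_id,
    n_exons = as.integer(n_exons),
    n_probes = as.integer(n_exons) * spec$probes_per_exon
  )
  annotation <- models %>%
    mutate(exon_idx = purrr::map(.data$n_exons, seq_len)) %>%
    tidyr::unnest("exon_idx") %>%
    mutate(exon_id = sprintf("%s_E%02d", .data$gene_id, .data$exon_idx)) %>%
    mutate(probe_idx = list(seq_len(spec$probes_per_exon))) %>%
    tidyr::unnest("probe_idx") %>%
    mutate(probe_id = sprintf("%s_P%d", .data$exon_id, .data$probe_idx)) %>%
    select("probe_id", "gene_id", "exon_id")
  list(models = models, annotation = annotation)
}

#' Simulate intensities for a two-condition exon-array experiment
#'
#' Generates the probe-by-sample intensity matrix
#' `intensity = baseline(gene) x affinity(probe) x condition_effect(gene) x
#' inclusion_effect(exon) x noise`, together with the sample design and the
#' spiked-truth table. All intensities are strictly positive (floored at a
#' tiny constant so geometric means stay defined).
#'
#' @param spec A [sim_spec()].
#' @param models Output of [build_gene_models()]; built from `spec` when
#'   omitted.
#' @return A list with `intensity` (tibble, `probe_id` plus one column per
#'   sample), `design` (tibble: `sample_id`, `condition`, `replicate`) and
#'   `truth` (tibble: `gene_id`, `low_expression`, `is_de`, `de_direction`,
#'   `true_ratio`, `as_exon_id`, `as_direction`, `true_inclusion_ratio`).
#' @export
simulate_experiment <- function(spec, models = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  models <- models %||% build_gene_models(spec)
  if (!is.list(models) || !all(c("models", "annotation") %in% names(models))) {
    abort("`models` must be the output of build_gene_models().")
  }
  ann <- models$annotation
  gm <- models$models
  if (nrow(ann) != sum(gm$n_probes) ||
      !setequal(unique(ann$gene_id), gm$gene_id)) {
    abort("`models` and its annotation are inconsistent.")
  }

  r <- spec$replicates_per_condition
  design <- tibble(
    sample_id = c(sprintf("control_%d", seq_len(r)),
                  sprintf("treated_%d", seq_len(r))),
    condition = rep(c("control", "treated"), each = r),
    replicate = rep(seq_len(r), 2L)
  )

  n_genes <- nrow(gm)
  if (n_genes == 0L) {
    intensity <- tibble(probe_id = character())
    for (s in design$sample_id) intensity[[s]] <- numeric()
    return(list(intensity = intensity, design = design,
                truth = empty_truth()))
  }

  withr::with_seed(spec$seed + 1L, {
    n_low <- round(spec$low_expression_fraction * n_genes)
    low_idx <- sample(n_genes, n_low)
    expressed_idx <- setdiff(seq_len(n_genes), low_idx)

    n_de <- round(spec$de_fraction * n_genes)
    n_as <- round(spec$as_fraction * n_genes)
    if (n_de + n_as > length(expressed_idx)) {
      abort("Too few expressed genes to place the requested DE and AS spikes.")
    }
    de_idx <- sample(expressed_idx, n_de)
    as_idx <- sample(setdiff(expressed_idx, de_idx), n_as)

    de_dir <- sample(c("up", "down"), n_de, replace = TRUE)
    as_dir <- sample(c("up", "down"), n_as, replace = TRUE)

    truth <- tibble(
      gene_id = gm$gene_id,
      low_expression = seq_len(n_genes) %in% low_idx,
      is_de = FALSE, de_direction = "none", true_ratio = 1,
      as_exon_id = NA_character_, as_direction = "none",
      true_inclusion_ratio = 1
    )
    truth$is_de[de_idx] <- TRUE
    truth$de_direction[de_idx] <- de_dir
    truth$true_ratio[de_idx] <-
      ifelse(de_dir == "up", spec$de_effect, 1 / spec$de_effect)

    # one shifted (cassette) exon per AS gene
    as_exon_pick <- vapply(gm$n_exons[as_idx],
                           function(k) sample.int(k, 1L), integer(1))
    truth$as_exon_id[as_idx] <-
      sprintf("%s_E%02d", gm$gene_id[as_idx], as_exon_pick)
    truth$as_direction[as_idx] <- as_dir
    truth$true_inclusion_ratio[as_idx] <-
      ifelse(as_dir == "up", spec$as_effect, 1 / spec$as_effect)

    baseline <- numeric(n_genes)
    baseline[expressed_idx] <- rlnorm(length(expressed_idx),
                                      spec$baseline_log_mean,
                                      spec$baseline_log_sd)
    if (n_low > 0L) {
      baseline[low_idx] <- rlnorm(n_low, spec$low_log_mean, spec$low_log_sd)
    }
    names(baseline) <- gm$gene_id

    n_probes <- nrow(ann)
    affinity <- rlnorm(n_probes, 0, spec$probe_affinity_sd)

    cond_effect <- setNames(truth$true_ratio, truth$gene_id)
    incl_effect <- setNames(truth$true_inclusion_ratio[!is.na(truth$as_exon_id)],
                            truth$as_exon_id[!is.na(truth$as_exon_id)])

    mu_control <- baseline[ann$gene_id] * affinity
    exon_mult <- rep(1, n_probes)
    hit <- ann$exon_id %in% names(incl_effect)
    exon_mult[hit] <- incl_effect[ann$exon_id[hit]]
    mu_treated <- mu_control * cond_effect[ann$gene_id] * exon_mult

    n_samples <- nrow(design)
    mu <- matrix(0, n_probes, n_samples)
    mu[, design$condition == "control"] <- mu_control
    mu[, design$condition == "treated"] <- mu_treated

    if (spec$noise_cv > 0) {
      sln <- sqrt(log1p(spec$noise_cv^2))
      noise <- matrix(rlnorm(n_probes * n_samples, -sln^2 / 2, sln),
                      n_probes, n_samples)
      mu <- mu * noise
    }
    mu <- pmax(mu, 1e-8)
    colnames(mu) <- design$sample_id

    intensity <- dplyr::bind_cols(tibble(probe_id = ann$probe_id),
                                  as_tibble(mu))
    list(intensity = intensity, design = design, truth = truth)
  })
}

empty_truth <- function() {
  tibble(gene_id = character(), low_expression = logical(),
         is_de = logical(), de_direction = character(),
         true_ratio = numeric(), as_exon_id = character(),
         as_direction = character(), true_inclusion_ratio = numeric())
}

#' Simulate a complete exon-array experiment in one call
#'
#' Convenience wrapper running [build_gene_models()] then
#' [simulate_experiment()].
#'
#' @param spec A [sim_spec()].
#' @return A list with `annotation`, `models`, `intensity`, `design`,
#'   `truth` and the `spec` itself.
#' @examples
#' xp <- simulate_exon_experiment(sim_spec(n_genes = 20, seed = 42))
#' dim(xp$intensity)
#' @export
simulate_exon_experiment <- function(spec = sim_spec()) {
  models <- build_gene_models(spec)
  sim <- simulate_experiment(spec, models)
  list(annotation = models$annotation, models = models$models,
       intensity = sim$intensity, design = sim$design, truth = sim$truth,
       spec = spec)
}
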