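test_that("gene models have the forced structure and probe counts", {
  spec <- sim_spec(n_genes = 3, exon_count_range = c(2, 2),
                   probes_per_exon = 1, seed = 1)
  gm <- build_gene_models(spec)
  expect_equal(nrow(gm$annotation), 6L)
  expect_equal(nrow(gm$models), 3L)
  expect_true(all(gm$models$n_exons == 2L))
  # every probe maps to exactly one (exon, gene)
  expect_equal(anyDuplicated(gm$annotation$probe_id), 0L)
  expect_equal(sum(gm$models$n_probes), nrow(gm$annotation))

  empty <- build_gene_models(sim_spec(n_genes = 0))
  expect_equal(nrow(empty$models), 0L)
  expect_equal(nrow(empty$annotation), 0L)
})

test_that("full-platform-scale model draw stays within the forced bounds", {
  spec <- sim_spec(n_genes = 20411, exon_count_range = c(4, 12),
                   probes_per_exon = 1, seed = 3)
  gm <- build_gene_models(spec)
  total <- nrow(gm$annotation)
  expect_gte(total, 20411 * 4)
  expect_lte(total, 20411 * 12)
  # mean probes per gene near the midpoint of a uniform 4..12 draw
  expect_gt(total / 20411, 7.5)
  expect_lt(total / 20411, 8.5)
})

test_that("invalid simulation parameters are rejected", {
  expect_error(sim_spec(n_genes = -1), "non-negative")
  expect_error(sim_spec(probes_per_exon = 0), "positive")
  expect_error(sim_spec(de_fraction = 1.5), "\\[0, 1\\]")
  expect_error(sim_spec(de_effect = 0.5), ">= 1")
  expect_error(sim_spec(exon_count_range = c(5, 2)), "min <= max")
  expect_error(simulate_experiment(sim_spec(), models = list(a = 1)),
               "build_gene_models")
})

test_that("a fixed seed gives bit-identical experiments", {
  spec <- sim_spec(n_genes = 50, seed = 1)
  a <- simulate_exon_experiment(spec)
  b <- simulate_exon_experiment(spec)
  expect_identical(a$intensity, b$intensity)
  expect_identical(a$truth, b$truth)
  expect_identical(a$design, b$design)
})

test_that("spike bookkeeping matches the requested counts", {
  spec <- sim_spec(n_genes = 2000, de_fraction = 0.025, as_fraction = 0.01,
                   seed = 5)
  xp <- simulate_exon_experiment(spec)
  expect_equal(sum(xp$truth$is_de), 50L)
  expect_equal(sum(!is.na(xp$truth$as_exon_id)), 20L)
  # non-spiked genes carry no effect
  unspiked <- xp$truth[!xp$truth$is_de, ]
  expect_true(all(unspiked$true_ratio == 1))
  expect_true(all(xp$truth$true_inclusion_ratio[is.na(xp$truth$as_exon_id)] == 1))
  # spiked effects have the requested magnitude in either direction
  expect_true(all(xp$truth$true_ratio[xp$truth$is_de] %in% c(4, 1 / 4)))
  expect_true(all(xp$intensity[, -1] > 0))
})

test_that("noise-free unspiked arrays are constant and null downstream", {
  spec <- sim_spec(n_genes = 40, de_fraction = 0, as_fraction = 0,
                   noise_cv = 0, replicates_per_condition = 2, seed = 9)
  xp <- simulate_exon_experiment(spec)
  expect_equal(xp$intensity$control_1, xp$intensity$control_2)
  expect_equal(xp$intensity$control_1, xp$intensity$treated_1)
  expect_equal(xp$intensity$treated_1, xp$intensity$treated_2)

  signals <- summarize_transcripts(normalize_global_mean(xp$intensity),
                                   xp$annotation, xp$design)
  fc <- fold_changes(signals)
  expect_equal(fc$ratio, rep(1, nrow(fc)))

  si <- splicing_index(
    suppressMessages(compute_gnpn(xp$intensity, xp$annotation, xp$design)),
    mode = "ratio")
  expect_equal(si$si, rep(1, nrow(si)))
})

test_that("empirical condition ratio converges to the spiked truth", {
  spec <- sim_spec(n_genes = 200, de_fraction = 0.05, de_effect = 4,
                   as_fraction = 0, noise_cv = 0.2,
                   replicates_per_condition = 20, seed = 13)
  xp <- simulate_exon_experiment(spec)
  signals <- summarize_transcripts(xp$intensity, xp$annotation, xp$design)
  fc <- fold_changes(signals) %>%
    dplyr::inner_join(xp$truth, by = "gene_id") %>%
    dplyr::filter(is_de)
  expect_equal(nrow(fc), 10L)
  # SE of the log-ratio of geometric means over P probes x r replicates
  sln <- sqrt(log1p(spec$noise_cv^2))
  n_meas <- fc$n_probes_retained * spec$replicates_per_condition
  se <- sqrt(2 * sln^2 / n_meas)
  expect_true(all(abs(log(fc$ratio) - log(fc$true_ratio)) < 3 * se))
})

test_that("an AS spike moves only its own exon beyond renormalization", {
  spec <- sim_spec(n_genes = 30, de_fraction = 0, as_fraction = 0.2,
                   as_effect = 4, noise_cv = 0,
                   replicates_per_condition = 1, seed = 17)
  xp <- simulate_exon_experiment(spec)
  si <- splicing_index(
    suppressMessages(compute_gnpn(xp$intensity, xp$annotation, xp$design)),
    mode = "ratio") %>%
    dplyr::inner_join(xp$truth, by = "gene_id") %>%
    dplyr::filter(!is.na(as_exon_id))
  target <- si[si$exon_id == si$as_exon_id, ]
  others <- si[si$exon_id != si$as_exon_id, ]
  # non-target exons move opposite (pure renormalization), never farther
  # from the null than the target exon of the same gene
  for (g in unique(target$gene_id)) {
    t_shift <- abs(log(target$si[target$gene_id == g]))
    o_shift <- abs(log(others$si[others$gene_id == g]))
    expect_true(all(o_shift < t_shift))
    expect_true(all(sign(log(others$si[others$gene_id == g])) ==
                      -sign(log(target$si[target$gene_id == g]))))
  }
})
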