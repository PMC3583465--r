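test_that("GNPN divides condition means by the gene geometric mean", {
  design <- toy_design(1)
  ann <- toy_annotation(c("p1", "p2", "p3"), rep("g", 3))
  m <- toy_intensity(c("p1", "p2", "p3"), list(
    control_1 = c(100, 200, 400), treated_1 = c(7, 7, 7)))
  gnpn <- compute_gnpn(m, ann, design)
  expect_equal(gnpn$gnpn_control, c(0.5, 1, 2))
  expect_equal(gnpn$gnpn_treated, rep(1, 3))
  # geometric mean of GNPN within the gene is 1 by construction
  expect_equal(prod(gnpn$gnpn_control), 1)
})

test_that("single-probe genes are excluded from splicing analysis", {
  design <- toy_design(1)
  ann <- toy_annotation(c("p1", "p2", "p3"), c("g1", "g1", "g2"))
  m <- toy_intensity(c("p1", "p2", "p3"), list(
    control_1 = c(100, 200, 500), treated_1 = c(150, 250, 600)))
  expect_message(gnpn <- compute_gnpn(m, ann, design), "excluded")
  expect_setequal(gnpn$gene_id, "g1")
  excluded <- attr(gnpn, "excluded")
  expect_equal(excluded$gene_id, "g2")
  expect_match(excluded$reason, "fewer than 2")
})

test_that("splicing index arithmetic matches both modes", {
  gnpn <- tibble::tibble(
    probe_id = c("p1", "p2"), gene_id = "g", exon_id = c("e1", "e2"),
    gnpn_control = c(0.5, 2.0), gnpn_treated = c(2.0, 0.5))
  r <- splicing_index(gnpn, mode = "ratio")
  d <- splicing_index(gnpn, mode = "difference")
  expect_equal(r$si, c(4, 0.25))
  expect_equal(d$si, c(1.5, -1.5))

  ident <- dplyr::mutate(gnpn, gnpn_treated = gnpn_control)
  expect_equal(splicing_index(ident, "ratio")$si, c(1, 1))
  expect_equal(splicing_index(ident, "difference")$si, c(0, 0))
})

test_that("GNPN cancels gene-level expression shifts (DE-only gene)", {
  # noise-free gene shifted 4-fold in treated on every exon: SI must be 1
  design <- toy_design(2)
  ann <- toy_annotation(sprintf("p%d", 1:4), rep("g", 4))
  base <- c(500, 800, 1200, 2000)
  m <- toy_intensity(sprintf("p%d", 1:4), list(
    control_1 = base, control_2 = base,
    treated_1 = base * 4, treated_2 = base * 4))
  si <- splicing_index(compute_gnpn(m, ann, design), mode = "ratio")
  expect_equal(si$si, rep(1, 4))

  # multiplying all probes of a gene by a constant changes no GNPN value
  m2 <- m
  for (s in c("control_1", "control_2", "treated_1", "treated_2")) {
    m2[[s]] <- m2[[s]] * 11
  }
  expect_equal(compute_gnpn(m2, ann, design)[, -1],
               compute_gnpn(m, ann, design)[, -1])
})

test_that("ratio-mode SI is anti-symmetric under condition swap", {
  xp <- simulate_exon_experiment(sim_spec(n_genes = 30, seed = 41))
  gnpn <- suppressMessages(
    compute_gnpn(xp$intensity, xp$annotation, xp$design))
  swapped_design <- xp$design
  swapped_design$condition <- ifelse(swapped_design$condition == "control",
                                     "treated", "control")
  gnpn_sw <- suppressMessages(
    compute_gnpn(xp$intensity, xp$annotation, swapped_design))
  expect_equal(splicing_index(gnpn_sw, "ratio")$si,
               1 / splicing_index(gnpn, "ratio")$si, tolerance = 1e-12)
  expect_equal(splicing_index(gnpn_sw, "difference")$si,
               -splicing_index(gnpn, "difference")$si, tolerance = 1e-12)
})

test_that("candidate calling applies the threshold rule", {
  st <- tibble::tibble(
    probe_id = c("p1", "p2", "p3"), gene_id = c("g1", "g1", "g2"),
    exon_id = c("e1", "e2", "e3"), gnpn_control = 1, gnpn_treated = 1,
    si = c(4.0, 1.1, 0.4), mode = "ratio")
  calls <- call_as_candidates(st)
  expect_equal(calls$candidate, c(TRUE, FALSE, TRUE))
  summ <- as_gene_summary(calls)
  expect_equal(summ$gene_id, c("g1", "g2"))
  expect_equal(summ$candidate_exons, c("e1", "e3"))

  # extreme thresholds flag nothing
  none <- call_as_candidates(st, up_threshold = Inf, down_threshold = 0)
  expect_equal(sum(none$candidate), 0L)

  expect_error(call_as_candidates(st, up_threshold = 0.9), "down_threshold < 1")

  dd <- dplyr::mutate(st, si = c(1.5, -0.2, -1.5), mode = "difference")
  dcalls <- call_as_candidates(dd, diff_threshold = 1)
  expect_equal(dcalls$candidate, c(TRUE, FALSE, TRUE))
})

test_that("noise-free spiked SI matches a brute-force recomputation", {
  # tiny instance: recompute GNPN/SI with explicit loops and compare, and
  # check the closed form f^((E-1)/E) for the spiked exon
  spec <- sim_spec(n_genes = 5, exon_count_range = c(3, 5),
                   probes_per_exon = 1, replicates_per_condition = 2,
                   de_fraction = 0.2, de_effect = 3,
                   as_fraction = 0.2, as_effect = 4,
                   low_expression_fraction = 0, noise_cv = 0, seed = 43)
  xp <- simulate_exon_experiment(spec)
  si <- splicing_index(
    compute_gnpn(xp$intensity, xp$annotation, xp$design), mode = "ratio")

  # brute force with base loops
  long <- as.data.frame(xp$intensity)
  brute <- numeric(nrow(si))
  for (i in seq_len(nrow(si))) {
    pid <- si$probe_id[i]
    gid <- si$gene_id[i]
    probes_g <- xp$annotation$probe_id[xp$annotation$gene_id == gid]
    gn <- function(cols, p) mean(unlist(long[long$probe_id == p, cols]))
    ctrl_cols <- xp$design$sample_id[xp$design$condition == "control"]
    trt_cols <- xp$design$sample_id[xp$design$condition == "treated"]
    pn_c <- vapply(probes_g, function(p) gn(ctrl_cols, p), numeric(1))
    pn_t <- vapply(probes_g, function(p) gn(trt_cols, p), numeric(1))
    g_c <- (pn_c[pid] / exp(mean(log(pn_c))))
    g_t <- (pn_t[pid] / exp(mean(log(pn_t))))
    brute[i] <- g_t / g_c
  }
  expect_equal(si$si, brute, tolerance = 1e-12)

  truth <- xp$truth[!is.na(xp$truth$as_exon_id), ]
  for (j in seq_len(nrow(truth))) {
    E <- xp$models$n_exons[xp$models$gene_id == truth$gene_id[j]]
    f <- truth$true_inclusion_ratio[j]
    got <- si$si[si$exon_id == truth$as_exon_id[j]]
    expect_equal(got, f^((E - 1) / E), tolerance = 1e-12)
  }
})
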