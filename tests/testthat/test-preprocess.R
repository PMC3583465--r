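test_that("global mean normalization rescales every sample to the grand mean", {
  m <- toy_intensity(c("p1", "p2"), list(s1 = c(400, 600), s2 = c(800, 1200)))
  norm <- normalize_global_mean(m)
  expect_equal(mean(norm$s1), 750)
  expect_equal(mean(norm$s2), 750)
  # scale factors 1.5 and 0.75
  expect_equal(norm$s1 / m$s1, rep(1.5, 2))
  expect_equal(norm$s2 / m$s2, rep(0.75, 2))

  # samples already sharing a mean are untouched
  same <- toy_intensity(c("p1", "p2"), list(s1 = c(100, 300), s2 = c(250, 150)))
  expect_equal(normalize_global_mean(same), same)

  expect_error(normalize_global_mean(toy_intensity(character(),
                                                   list(s1 = numeric()))),
               "empty")
})

test_that("normalization equalizes means of random matrices and is idempotent", {
  withr::with_seed(21, {
    m <- toy_intensity(sprintf("p%03d", 1:100),
                       lapply(setNames(1:4, paste0("s", 1:4)),
                              function(i) rlnorm(100, 6, 1)))
  })
  norm <- normalize_global_mean(m)
  means <- vapply(norm[-1], mean, numeric(1))
  expect_lt(max(abs(means / mean(means) - 1)), 1e-9)
  twice <- normalize_global_mean(norm)
  expect_equal(twice, norm, tolerance = 1e-12)
  # a single per-sample scale preserves within-sample ordering
  expect_equal(order(norm$s1), order(m$s1))
})

test_that("the 400 filter applies the condition-mean retention rule", {
  design <- toy_design(2)
  # probe q1: condition means (350, 450); q2: (350, 390); q3: (500, 600)
  m <- toy_intensity(c("q1", "q2", "q3"), list(
    control_1 = c(340, 360, 480), control_2 = c(360, 340, 520),
    treated_1 = c(440, 380, 580), treated_2 = c(460, 400, 620)))

  res <- filter_low_intensity(m, design, intensity_threshold = 400)
  expect_setequal(res$intensity$probe_id, c("q1", "q3"))
  expect_equal(res$removed$probe_id, "q2")
  expect_equal(res$removed$mean_control, 350)
  expect_equal(res$removed$mean_treated, 390)

  # stricter policy drops q1 too
  res_all <- filter_low_intensity(m, design, intensity_threshold = 400,
                                  filter_policy = "all_condition_means")
  expect_equal(res_all$intensity$probe_id, "q3")

  # overall-mean policy: q1 mean 400 retained at threshold 400
  res_ov <- filter_low_intensity(m, design, intensity_threshold = 400,
                                 filter_policy = "overall_mean")
  expect_setequal(res_ov$intensity$probe_id, c("q1", "q3"))

  # threshold 0 disables the filter
  res0 <- filter_low_intensity(m, design, intensity_threshold = 0)
  expect_equal(nrow(res0$removed), 0L)
  expect_equal(res0$intensity, m)
})

test_that("filtering is monotone in the threshold", {
  withr::with_seed(22, {
    m <- toy_intensity(sprintf("p%03d", 1:200),
                       lapply(setNames(1:4, c("control_1", "control_2",
                                              "treated_1", "treated_2")),
                              function(i) rlnorm(200, 6, 0.8)))
  })
  design <- toy_design(2)
  kept_prev <- NULL
  for (thr in c(0, 200, 400, 800, 1600)) {
    kept <- filter_low_intensity(m, design, intensity_threshold = thr)$intensity$probe_id
    if (!is.null(kept_prev)) expect_true(all(kept %in% kept_prev))
    kept_prev <- kept
  }
})

test_that("normalize-then-filter commutes with relabeling replicates", {
  xp <- simulate_exon_experiment(sim_spec(n_genes = 60, seed = 23))
  design_swapped <- xp$design
  design_swapped$replicate[1:2] <- c(2L, 1L) # swap control replicate labels
  a <- filter_low_intensity(normalize_global_mean(xp$intensity), xp$design)
  b <- filter_low_intensity(normalize_global_mean(xp$intensity), design_swapped)
  expect_equal(a$intensity, b$intensity)
  expect_equal(a$removed, b$removed)
})
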