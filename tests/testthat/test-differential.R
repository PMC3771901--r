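test_that("Mann-Whitney exact branch reproduces enumeration results", {
  # {1,2,3} vs {4,5,6}: U = 0, two-sided exact p = 2/20
  expect_equal(mann_whitney_p(1:3, 4:6), 0.1, tolerance = 1e-12)
  # identical lists are fully tied: p = 1
  expect_equal(mann_whitney_p(c(1, 2, 3), c(1, 2, 3)), 1)
  # exact branch vs permutation oracle on random small instances
  set.seed(41)
  for (i in 1:60) {
    na <- sample(2:6, 1)
    nb <- sample(2:6, 1)
    a <- rnorm(na)
    b <- rnorm(nb)
    expect_equal(mann_whitney_p(a, b), mw_permutation_p(a, b),
                 tolerance = 1e-12)
  }
  expect_true(is.na(mann_whitney_p(1, 2:4)))
})

test_that("ratio tests divide protein sums and test PSM-level values", {
  cfg <- sim_config(n_proteins = 15, noise_sigma = 0, replicate_sigma = 0,
                    effect_log2_range = c(1, 1), frac_differential_lof = 1,
                    frac_differential_hof = 0, frac_shared = 0,
                    decoy_fraction = 0, seed = 42)
  qs <- quant_from_sim(cfg)
  tests <- compute_ratio_tests(qs$quant, comparison_scheme("LOF"))
  joined <- dplyr::left_join(tests, qs$truth, by = "protein_id")
  expect_equal(unname(joined$ratio), 2^joined$true_log2fc_lof,
               tolerance = 1e-9)
  # global rescaling leaves ratios unchanged
  q2 <- qs$quant
  for (s in c("C1", "C2", "LOF1", "LOF2", "HOF1", "HOF2")) {
    q2[[s]] <- q2[[s]] * 7
  }
  q2$psm_intensities <- lapply(q2$psm_intensities, function(m) m * 7)
  tests2 <- compute_ratio_tests(q2, comparison_scheme("LOF"))
  expect_equal(tests2$ratio, tests$ratio, tolerance = 1e-12)
  expect_equal(tests2$p_value, tests$p_value, tolerance = 1e-12)
})

test_that("the two-criteria rule classifies the worked examples", {
  sch <- comparison_scheme("LOF")
  run1 <- classify_differential(
    make_tests(c(1.62, 1.71, 1.55, 1.41), c(0.01, 0.02, 0.03, 0.21)), sch)
  expect_equal(run1$direction, "up")
  run2 <- classify_differential(
    make_tests(c(1.8, 1.1, 0.95, 1.05), c(0.01, 0.3, 0.6, 0.5)), sch)
  expect_equal(run2$direction, "none")
  expect_false(run2$criterion2_met)
  run3 <- classify_differential(
    make_tests(c(0.60, 0.62, 0.65, 0.80), c(0.01, 0.02, 0.04, 0.03)), sch)
  expect_equal(run3$direction, "down")
  run4 <- classify_differential(make_tests(rep(1, 4), rep(1, 4)), sch)
  expect_equal(run4$direction, "none")
  # boundary is strict: ratio exactly 1.5 does not satisfy criterion 1
  run5 <- classify_differential(
    make_tests(c(1.5, 1.4, 1.3, 1.2), c(0.01, 0.01, 0.01, 0.01)), sch)
  expect_false(run5$criterion1_met)
  expect_equal(run5$direction, "none")
  # undefined ratio voids the call
  run6 <- classify_differential(
    make_tests(c(NA, 1.7, 1.8, 1.9), c(0.01, 0.01, 0.01, 0.01)), sch)
  expect_equal(run6$direction, "none")
  expect_equal(run6$flag, "undefined_ratio")
})

test_that("an up call survives inflating the ratios (monotonicity)", {
  sch <- comparison_scheme("LOF")
  base <- make_tests(c(1.62, 1.71, 1.55, 1.41), c(0.01, 0.02, 0.03, 0.04))
  expect_equal(classify_differential(base, sch)$direction, "up")
  for (c_mult in c(1, 1.5, 3, 10)) {
    scaled <- dplyr::mutate(base, ratio = ratio * c_mult)
    expect_equal(classify_differential(scaled, sch)$direction, "up")
  }
})

test_that("calls match the majority trend direction on simulated data", {
  cfg <- sim_config(n_proteins = 80, frac_differential_lof = 0.3,
                    effect_log2_range = c(1, 2), noise_sigma = 0.1,
                    psms_per_protein_min = 6, psms_per_protein_mean = 8,
                    decoy_fraction = 0, seed = 44)
  qs <- quant_from_sim(cfg)
  calls <- call_differential(qs$quant, "LOF")
  tests <- attr(calls, "tests")
  called <- calls[calls$direction != "none", ]
  for (i in seq_len(nrow(called))) {
    tr <- tests$ratio[tests$protein_id == called$protein_id[i]]
    maj <- if (sum(tr > 1) >= 3) "up" else if (sum(tr < 1) >= 3) "down" else NA
    expect_equal(called$direction[i], maj)
  }
})

test_that("contaminant exclusion resets direction and counts resets", {
  calls <- structure(
    tibble::tibble(
      protein_id = c("P1", "P2", "P3", "P4"),
      group = "LOF",
      direction = c("up", "down", "up", "none"),
      criterion1_met = TRUE, criterion2_met = TRUE,
      mean_ratio = 2, sem_ratio = 0.1, min_p = 0.01, flag = "ok"),
    class = c("diff_calls", class(tibble::tibble())))
  ann <- tibble::tibble(
    protein_id = c("P1", "P2", "P3"),
    organelle = c("nucleus", "mitochondria", "extracellular"))
  out <- exclude_contaminants(calls, ann, c("nucleus", "extracellular"))
  expect_equal(out$direction, c("none", "down", "none", "none"))
  expect_identical(attr(out, "n_excluded"), 2L)
  # empty excluded set is the identity
  out2 <- exclude_contaminants(calls, ann, character(0))
  expect_equal(out2$direction, calls$direction)
})

test_that("intersection reports mean and SEM of the four ratios", {
  sch <- comparison_scheme("LOF")
  lof <- classify_differential(
    make_tests(c(1.5, 1.6, 1.7, 1.6), c(0.01, 0.01, 0.01, 0.01)), sch)
  class(lof) <- c("diff_calls", class(lof))
  hof <- classify_differential(
    make_tests(c(0.5, 0.55, 0.6, 0.5), c(0.01, 0.01, 0.01, 0.01), "HOF"), sch)
  class(hof) <- c("diff_calls", class(hof))
  shared <- intersect_calls(lof, hof)
  expect_identical(nrow(shared), 1L)
  expect_equal(shared$mean_ratio_lof, 1.6)
  expect_equal(shared$sem_ratio_lof, sd(c(1.5, 1.6, 1.7, 1.6)) / 2,
               tolerance = 1e-12)
  expect_equal(round(shared$sem_ratio_lof, 3), 0.041)
  # disjoint sets give an empty intersection
  hof_other <- hof
  hof_other$protein_id <- "OTHER"
  expect_identical(nrow(intersect_calls(lof, hof_other)), 0L)
})

test_that("tidy and glance summarise a calls object", {
  cfg <- sim_config(n_proteins = 20, seed = 46)
  qs <- quant_from_sim(cfg)
  calls <- call_differential(qs$quant, "LOF")
  td <- tidy(calls)
  expect_true(all(c("ratio", "p_value", "direction") %in% names(td)))
  expect_identical(nrow(td), nrow(qs$quant) * 4L)
  gl <- glance(calls)
  expect_identical(gl$n_differential, sum(calls$direction != "none"))
})
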