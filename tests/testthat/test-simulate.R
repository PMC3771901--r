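test_that("differential label counts equal round(frac * n) exactly", {
  for (frac in c(0, 0.1, 0.077, 0.33)) {
    cfg <- sim_config(n_proteins = 100, frac_differential_lof = frac,
                      frac_differential_hof = 0.2, seed = 3)
    truth <- sim_ground_truth(cfg)
    expect_identical(sum(truth$is_differential_lof),
                     as.integer(round(frac * 100)))
    expect_identical(sum(truth$is_differential_hof), 20L)
    expect_true(all(truth$is_differential_lof == (truth$true_log2fc_lof != 0)))
  }
})

test_that("same config and seed give byte-identical outputs", {
  cfg <- sim_config(n_proteins = 40, seed = 17)
  s1 <- sim_psm_table(cfg)
  s2 <- sim_psm_table(cfg)
  expect_identical(s1, s2)
  expect_identical(sim_mrna_table(s1$truth, seed = 17),
                   sim_mrna_table(s2$truth, seed = 17))
  targets <- s1$truth$protein_id[1:3]
  expect_identical(sim_mrm_table(targets, s1$truth, seed = 5),
                   sim_mrm_table(targets, s1$truth, seed = 5))
  expect_identical(sim_labeled_mask(64, 48, 0.3, seed = 2),
                   sim_labeled_mask(64, 48, 0.3, seed = 2))
  # different seeds differ
  expect_false(identical(s1$psms,
                         sim_psm_table(sim_config(n_proteins = 40,
                                                  seed = 18))$psms))
})

test_that("noise-free forward model yields exact channel ratios", {
  cfg <- sim_config(n_proteins = 30, noise_sigma = 0, replicate_sigma = 0,
                    decoy_fraction = 0, seed = 4)
  sim <- sim_psm_table(cfg)
  quant <- aggregate_protein_intensities(sim$psms, design = cfg$design)
  joined <- dplyr::inner_join(quant, sim$truth, by = "protein_id")
  expect_equal(joined$LOF1 / joined$C1, 2^joined$true_log2fc_lof,
               tolerance = 1e-12)
  expect_equal(joined$HOF2 / joined$C2, 2^joined$true_log2fc_hof,
               tolerance = 1e-12)
})

test_that("every protein receives at least the configured minimum of PSMs", {
  cfg <- sim_config(n_proteins = 60, psms_per_protein_min = 3,
                    psms_per_protein_mean = 5, decoy_fraction = 0, seed = 6)
  sim <- sim_psm_table(cfg)
  counts <- table(sim$psms$protein_id)
  expect_identical(length(counts), 60L)
  expect_true(all(counts >= 3))
})

test_that("mRNA concordance probability 1 and 0 are sign-deterministic", {
  truth <- sim_ground_truth(sim_config(n_proteins = 80,
                                       frac_differential_lof = 0.5,
                                       frac_differential_hof = 0.5, seed = 8))
  all_match <- sim_mrna_table(truth, concordance_prob = 1, coverage = 1,
                              seed = 1)
  none_match <- sim_mrna_table(truth, concordance_prob = 0, coverage = 1,
                               seed = 1)
  check <- function(mrna, expect_same) {
    joined <- dplyr::inner_join(
      mrna, truth, by = c(gene_id = "protein_id"))
    fc <- ifelse(joined$group == "LOF", joined$true_log2fc_lof,
                 joined$true_log2fc_hof)
    keep <- fc != 0
    same <- sign(joined$mrna_log2fc[keep]) == sign(fc[keep])
    if (expect_same) expect_true(all(same)) else expect_true(!any(same))
  }
  check(all_match, TRUE)
  check(none_match, FALSE)
  expect_error(sim_mrna_table(truth, concordance_prob = 1.2),
               "concordance_prob")
})

test_that("mRNA coverage produces the expected number of records", {
  cfg <- sim_config(n_proteins = 115, frac_differential_lof = 1,
                    frac_differential_hof = 0, frac_shared = 0, seed = 9)
  truth <- sim_ground_truth(cfg)
  covered <- sapply(1:20, function(s) {
    m <- sim_mrna_table(truth, coverage = 0.96, seed = s)
    sum(m$group == "LOF")
  })
  # 115 differential proteins at 96% coverage -> about 110 covered
  expect_equal(mean(covered), 110.4, tolerance = 0.02)
})

test_that("MRM table has the designed replicate structure and row count", {
  truth <- sim_ground_truth(sim_config(n_proteins = 20,
                                       frac_differential_hof = 0.5, seed = 10))
  targets <- truth$protein_id[1:10]
  mrm <- sim_mrm_table(targets, truth, transitions_per_peptide = 3, seed = 2)
  # 10 targets x 3 transitions x (3 groups x 2 bio) x 3 technical
  expect_identical(nrow(mrm), 540L)
  expect_identical(
    nrow(dplyr::distinct(mrm, sample, bio_replicate, tech_replicate)), 18L)
  expect_error(sim_mrm_table(character(0), truth), "non-empty")
  expect_error(sim_mrm_table("NOT_THERE", truth), "targets")
})

test_that("noise-free MRM areas scale with the true group effect", {
  cfg <- sim_config(n_proteins = 10, frac_differential_hof = 1,
                    frac_differential_lof = 0, frac_shared = 0,
                    effect_log2_range = c(1, 1), seed = 11)
  truth <- sim_ground_truth(cfg)
  truth$true_log2fc_hof <- -1  # force a uniform 2-fold suppression
  mrm <- sim_mrm_table(truth$protein_id, truth, noise_sigma = 0,
                       frac_below_sn = 0, seed = 3)
  sums <- mrm |>
    dplyr::group_by(sample) |>
    dplyr::summarise(a = sum(area))
  expect_equal(sums$a[sums$sample == "HOF"] / sums$a[sums$sample == "C"],
               0.5, tolerance = 1e-12)
})

test_that("labelled mask hits the requested fraction and label semantics", {
  m <- sim_labeled_mask(128, 96, 0.5, seed = 12)
  expect_true(all(m %in% 0:2))
  realized <- mean(m[m != 0] == 2)
  expect_lt(abs(realized - 0.5), 0.01)
  full <- sim_labeled_mask(64, 64, 1.0, seed = 1)
  expect_true(all(full[full != 0] == 2))
  exc <- sim_labeled_mask(64, 64, 0.3, excluded_fraction = 0.2, seed = 2)
  expect_equal(mean(exc == 0), 0.2, tolerance = 0.01)
  expect_error(sim_labeled_mask(1, 64, 0.5), "degenerate")
})

test_that("config validation rejects malformed inputs", {
  expect_error(sim_config(n_proteins = 0), "positive")
  expect_error(sim_config(frac_differential_lof = 1.2), "fractions")
  expect_error(sim_config(effect_log2_range = c(0, 1)), "positive lower")
  expect_error(sim_config(category_weights = c(a = 0.5, b = 0.4)), "sum to 1")
  bad_purity <- matrix(c(0.5, 0.6, 0.6, 0.5), 2,
                       dimnames = list(c("C1", "C2"), c("C1", "C2")))
  expect_error(validate_purity(bad_purity), "dominant|sums")
})
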