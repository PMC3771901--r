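test_that("tryptic digestion cleaves after K/R except before proline", {
  expect_equal(digest_tryptic("MAGWKTTESTPEPTIDERLVCK"),
               c("MAGWK", "TTESTPEPTIDER", "LVCK"))
  # K before P is protected
  expect_equal(digest_tryptic("AAKPGGR"), "AAKPGGR")
  expect_equal(digest_tryptic("AAGTW"), "AAGTW")
  # terminal K yields no empty fragment
  expect_equal(digest_tryptic("AAK"), "AAK")
  expect_error(digest_tryptic("AAB"), "invalid")
  # round trip: fragments concatenate to the input
  seqs <- c("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRVGDGTQDNLSGAEKAVQVK",
            "RPRTAFSSEQLARLKREFNENRYLTERRRQQLSSELGLNEAQIKIWFQNKRAKIK")
  for (s in seqs) {
    expect_equal(paste(digest_tryptic(s), collapse = ""), s)
  }
})

test_that("MRM peptide selection applies all four rules", {
  seqs <- c(
    P1 = "MAGWKTTESTPEPTIDERLVCK",   # TTESTPEPTIDER is the only candidate
    P2 = "AAAWDDDKTTESTPEPTIDER",    # shares TTESTPEPTIDER with P1
    P3 = "GGGWKSSSTTTNNNQQQEEEK"     # one candidate, unique
  )
  cand <- select_mrm_peptides(seqs)
  # shared peptide rejected for both owners
  expect_false("TTESTPEPTIDER" %in% cand$peptide)
  # LVCK rejected: cysteine and too short; MAGWK too short
  expect_false(any(c("LVCK", "MAGWK") %in% cand$peptide))
  expect_true("SSSTTTNNNQQQEEEK" %in%
                cand$peptide[cand$protein_id == "P3"])
  # P2 keeps its own unique tryptic peptide; P1 has none left
  expect_true("AAAWDDDK" %in% cand$peptide[cand$protein_id == "P2"])
  expect_identical(attr(cand, "no_candidates"), "P1")
  # every selected peptide re-passes the rules independently
  all_peps <- unlist(lapply(seqs, digest_tryptic))
  for (i in seq_len(nrow(cand))) {
    p <- cand$peptide[i]
    expect_true(sum(all_peps == p) == 1)
    expect_false(grepl("[CM]", p))
    expect_true(nchar(p) >= 7 && nchar(p) <= 25)
    expect_true(p %in% digest_tryptic(seqs[[cand$protein_id[i]]]))
  }
})

test_that("abundance sums transition areas with strict S/N > 10", {
  tr <- tibble::tibble(
    protein_id = "P", sample = "C", bio_replicate = 1L, tech_replicate = 1L,
    area = c(100, 200, 300), signal_to_noise = c(12, 15, 20))
  expect_equal(mrm_quantify(tr)$abundance, 600)
  tr$signal_to_noise <- c(5, 15, 20)
  expect_equal(mrm_quantify(tr)$abundance, 500)
  # boundary: S/N exactly 10 is excluded
  tr$signal_to_noise <- c(10, 15, 20)
  expect_equal(mrm_quantify(tr)$abundance, 500)
  # all filtered: flagged NA
  tr$signal_to_noise <- c(1, 2, 3)
  q <- mrm_quantify(tr)
  expect_true(is.na(q$abundance) && q$all_filtered)
  # sum decomposition: removing one qualified transition subtracts its area
  tr$signal_to_noise <- c(12, 15, 20)
  expect_equal(mrm_quantify(tr)$abundance - mrm_quantify(tr[-1, ])$abundance,
               tr$area[1])
})

test_that("normalization and t-test behave on constructed replicates", {
  mk <- function(c_vals, h_vals) {
    tidyr::expand_grid(bio_replicate = 1:2, tech_replicate = 1:3) |>
      (\(g) dplyr::bind_rows(
        dplyr::mutate(g, protein_id = "P", sample = "C",
                      abundance = c_vals, n_transitions = 3L,
                      all_filtered = FALSE),
        dplyr::mutate(g, protein_id = "P", sample = "HOF",
                      abundance = h_vals, n_transitions = 3L,
                      all_filtered = FALSE)))()
  }
  c_vals <- c(100, 110, 90, 105, 95, 100)
  res <- mrm_normalize_test(mk(c_vals, c_vals / 2))
  hof <- res[res$sample == "HOF", ]
  expect_equal(hof$mean_ratio, 0.5, tolerance = 1e-12)
  expect_equal(hof$n, 6L)
  # identical groups: ratio 1, p = 1
  res2 <- mrm_normalize_test(mk(c_vals, c_vals))
  hof2 <- res2[res2$sample == "HOF", ]
  expect_equal(hof2$mean_ratio, 1, tolerance = 1e-12)
  expect_equal(hof2$p_value, 1, tolerance = 1e-9)
  # zero within-group variance with a real shift: degenerate flag
  res3 <- mrm_normalize_test(mk(rep(100, 6), rep(50, 6)))
  hof3 <- res3[res3$sample == "HOF", ]
  expect_true(hof3$degenerate)
  expect_lt(hof3$p_value, 1e-11)
})

test_that("the pooled-variance t statistic matches the hand formula", {
  x <- c(1.1, 0.9, 1.0)
  y <- c(0.5, 0.6, 0.4)
  g <- tibble::tibble(
    protein_id = "P",
    sample = rep(c("C", "HOF"), each = 3),
    bio_replicate = rep(1:3, 2), tech_replicate = 1L,
    abundance = c(x, y) * 100, n_transitions = 1L, all_filtered = FALSE)
  res <- mrm_normalize_test(g)
  # hand-computed pooled-variance two-sample t on the normalized ratios
  rx <- x * 100 / mean(x * 100)
  ry <- y * 100 / mean(x * 100)
  sp2 <- (2 * stats::var(rx) + 2 * stats::var(ry)) / 4
  t_stat <- (mean(rx) - mean(ry)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_hand <- 2 * stats::pt(-abs(t_stat), df = 4)
  expect_equal(res$p_value[res$sample == "HOF"], p_hand, tolerance = 1e-12)
})

test_that("simulated 2-fold suppression is recovered within 10%", {
  ratios <- sapply(1:10, function(s) {
    truth <- sim_ground_truth(sim_config(n_proteins = 12, seed = s))
    truth$true_log2fc_hof <- -1
    mrm <- sim_mrm_table(truth$protein_id[1:6], truth, noise_sigma = 0.1,
                         frac_below_sn = 0.1, seed = s)
    res <- mrm_normalize_test(mrm_quantify(mrm))
    mean(res$mean_ratio[res$sample == "HOF"])
  })
  expect_lt(abs(mean(ratios) - 0.5), 0.05)
})
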