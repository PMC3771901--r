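# Independent oracles used across test files. These deliberately re-derive
# results from first principles (enumeration, direct formulas) and share no
# code with the implementation paths they check.

# Two-sided Mann-Whitney p by full enumeration of rank assignments:
# p = P(|U' - na*nb/2| >= |u_obs - na*nb/2|) over all C(na+nb, na) splits.
mw_permutation_p <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  centre <- na * nb / 2
  combos <- utils::combn(na + nb, na)
  u_all <- apply(combos, 2, function(idx) {
    sum(r[idx]) - na * (na + 1) / 2
  })
  mean(abs(u_all - centre) >= abs(u_obs - centre) - 1e-9)
}

# Two-sided Fisher p by hypergeometric tail enumeration: sum the
# probabilities of all tables (same margins) no more probable than the
# observed one, with the conventional 1e-7 relative slack on "no more
# probable".
fisher_enum_p <- function(k_a, n_a, k_b, n_b) {
  m <- k_a + k_b           # total successes
  support <- max(0, m - n_b):min(n_a, m)
  dens <- dhyper(support, n_a, n_b, m)
  obs <- dhyper(k_a, n_a, n_b, m)
  sum(dens[dens <= obs * (1 + 1e-7)])
}

# Minimal simulated quant table: runs the generator and the quantification
# stage (no identification filters) so caller-level tests control exactly
# which PSMs are present.
quant_from_sim <- function(config) {
  sim <- sim_psm_table(config)
  psms <- dplyr::filter(sim$psms, !is_decoy)
  quant <- aggregate_protein_intensities(psms, design = config$design)
  list(quant = quant, truth = sim$truth)
}

# Hand-built ratio-test table for classifier unit tests.
make_tests <- function(ratios, ps, group = "LOF", protein_id = "P1") {
  scheme <- comparison_scheme(group)
  tibble::tibble(
    protein_id = protein_id,
    group = group,
    sample = scheme$pairs$sample,
    control = scheme$pairs$control,
    ratio = ratios,
    p_value = ps,
    n_psms = 10L
  )
}
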