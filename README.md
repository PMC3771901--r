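# oxymito

Quantitative mitochondrial proteomics of oxygen-adapted *Drosophila*:
a tested, reusable implementation of an 8-plex isobaric-tag (iTRAQ)
analysis pipeline comparing hypoxia-adapted (LOF), hyperoxia-adapted
(HOF) and room-air control flies, together with the companion analyses
that such a study runs around it — protein–mRNA concordance,
spectral-count abundance stratification, MRM confirmation, and
point-counting stereology of mitochondrial volume fraction.

The package is aimed at proteomics analysts who want the complete
quantitative chain — from a peptide-spectrum-match (PSM) report table to
differential-protein lists — as composable, pipe-friendly R functions,
with a synthetic-data generator that produces every input with known
ground truth so each stage can be validated end to end.

## The model

Six samples (C1, C2, LOF1, LOF2, HOF1, HOF2) are labelled with iTRAQ
reporters 113, 115, 116, 117, 118 and 119. After filtering PSMs
(peptide probability ≥ 80%, protein probability ≥ 90%, target-decoy
peptide FDR ≤ 0.5%, ≥ 2 tag-labelled unique peptides per protein),
reporter intensities are corrected for isotope impurities by solving
*P x = observed* per spectrum (with *P* the vendor purity matrix),
median-normalized to the control channel, and summed to protein level.

For each adapted group, four replicate-cross ratios are formed
(e.g. LOF1/C1, LOF1/C2, LOF2/C1, LOF2/C2), each with a two-sided
Mann–Whitney p-value on the protein's PSM-level intensities in the two
channels. A protein is called differential when both of:

1. at least one ratio is > 1.5 or < 0.67 with p < 0.05, and
2. at least three of the four ratios lie on the same side of 1, each
   with p < 0.05,

and the two criteria agree in direction. Confidently non-mitochondrial
proteins are then excluded as preparation contaminants.

Downstream, differential proteins are joined to expression-array mRNA
log2 fold changes and classified into Cartesian quadrants (quadrants
1/3 = concordant); proteins are stratified by spectral count
(high > 50, medium 10–50, low < 10 spectra); MRM targets are quantified
as sums of transition areas with S/N > 10 and tested against control;
and mitochondrial volume fraction is estimated from a 9×13 point grid
as 100·n_mito/(n_mito + n_cyto).

## Worked example

```r
library(oxymito)

cfg  <- sim_config(n_proteins = 200, seed = 42)
sim  <- sim_psm_table(cfg)                      # PSM report + ground truth
ann  <- sim$truth[c("protein_id", "organelle", "category", "length")]
mrna <- sim_mrna_table(sim$truth, seed = 42)

run <- run_pipeline(sim$psms, annotation = ann, mrna = mrna)
run
#> <oxymito pipeline run>
#>   PSMs: 2963 in, 1703 retained (FDR cutoff 0.424)
#>   quantifiable proteins: 132
#>   differential: 7 LOF, 12 HOF (17 unique, 2 shared)
#>   protein-mRNA concordance: 86% LOF, 100% HOF

glance(run$calls_hof)
#> # A tibble: 1 × 6
#>   group n_proteins  n_up n_down n_differential n_untestable
#>   <chr>      <int> <int>  <int>          <int>        <int>
#> 1 HOF          132     6      6             12            0

replicate_correlation(run$quant, "C1", "C2")
#> # A tibble: 1 × 6
#>   sample_a sample_b pearson_r slope n_used n_excluded
#>   <chr>    <chr>        <dbl> <dbl>  <int>      <int>
#> 1 C1       C2           1.000 0.998    132        0
```

Reading the output: of 200 simulated proteins, 132 survive the
confidence/FDR/two-unique-peptide funnel; the consensus rule calls 7
proteins differential in the hypoxia-adapted group and 12 in the
hyperoxia-adapted group, 2 of them shared; and the duplicate control
preparations correlate near-perfectly on log2 intensities, the
replicate QC that licenses the 1.5-fold call threshold.

Each stage is also exposed on its own (`filter_identifications()`,
`correct_isotope_impurity()`, `normalize_channels()`,
`call_differential()`, `match_mrna()`, `stratify_abundance()`,
`mrm_quantify()`, `volume_fraction()`, …), takes a data frame first and
returns a tibble, so stages chain with the pipe. `tidy()`/`glance()`
summarise fitted results; `plot_*()` and `autoplot()` draw the standard
figures (replicate scatter, concordance quadrants, category bars, MRM
ratios).

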