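---
title: "Methods: design of the oxymito pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: design of the oxymito pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxymito)
```

This vignette records the scientific and numerical design of the
package: the procedure each stage implements, the assumptions behind
it, the defaults and why they were chosen, what the synthetic-data
generator does and does not emulate, and the decisions taken where the
design was genuinely open.

## The experimental design being modelled

Two control, two hypoxia-adapted (LOF) and two hyperoxia-adapted (HOF)
mitochondrial preparations are labelled with iTRAQ reporters 113, 115,
116, 117, 118 and 119 (channels 114 and 121 of the 8-plex kit unused)
and analyzed together; every MS/MS spectrum therefore carries six
reporter intensities that encode per-sample abundance for one peptide.
The analysis consumes the search engine's PSM report — it does not
re-run peptide-spectrum matching, which is an external tool's job.

## Identification filtering

PSMs pass three gates, all inclusive ("at least"):

* peptide identification probability ≥ 0.80 and protein probability
  ≥ 0.90 (`filter_thresholds()`);
* a peptide-level target-decoy FDR ≤ 0.5%: the most permissive score
  cutoff with `#decoys/#targets` at or above it ≤ 0.005. The plain
  ratio estimator is the default because it matches the common practice
  of the instrument generation modelled here; the conservative
  `(#decoys + 1)/#targets` variant is one argument away. With no decoys
  in the input the estimate is 0 and nothing beyond the confidence
  filters is removed;
* ≥ 2 distinct, tag-labelled, protein-unique peptide sequences per
  quantifiable protein. "Unique" means the sequence maps to exactly one
  accession in the supplied table; modifications are ignored because
  the report format does not carry them. Shared peptides are excluded
  both from uniqueness counting and from quantification. No parsimony
  grouping is attempted — accession identity is the protein unit.

Injection reproducibility is summarised as a peptide-set overlap. The
denominator convention is not standardised in the field, so both are
implemented; the default is the Jaccard form `100·|A∩B|/|A∪B|`, with
`mean-relative` (`100·|A∩B|/((|A|+|B|)/2)`) available.

## Reporter quantification

Isotope-impurity correction solves the linear system `P x = observed`
per spectrum, where column *j* of `P` gives the fraction of channel-*j*
reagent signal observed in each channel. Correction happens at PSM
level, before any normalization, because contamination is a physical
per-spectrum effect. Components driven negative by noise are clamped to
zero and flagged rather than propagated. The default purity matrix is
the identity (no correction); `purity_example()` ships a vendor-style
matrix that is explicitly synthetic — real corrections must come from
the reagent lot certificate. The round-trip `correct(P·x) = x` is
verified to 1e-8 relative error in the test suite.

Channels are then globally scaled so each channel's PSM-level intensity
median equals the control channel C1's median (control-anchored median
normalization). Whether the original analysis normalized at PSM or
protein level is not determinable from its description; PSM level was
chosen because the statistical test below runs on PSM-level values and
should see normalized data. The operation is idempotent.

Protein intensity is the **sum** of its retained PSMs' intensities (not
mean or median): summation is robust to PSM count, keeps spectral-count
weighting, and makes protein ratios invariant to global rescaling.
Zeros propagate and are excluded pairwise in comparisons — never
imputed.

Replicate QC reports Pearson r and the regression slope on log2 protein
intensities, and the fold-change distribution `max(a,b)/min(a,b)` in
bins `[1, 1.2)`, `[1.2, 1.5]`, `(1.5, ∞)`. Both boundaries belong to
the middle bin, which is the only reading consistent with describing
the bins as "smaller than 1.2" and "between 1.2 and 1.5".

## The differential consensus rule

Each adapted group yields four replicate-cross ratios (sample replicate
over control replicate) with Mann–Whitney p-values computed on the
protein's PSM-level intensities in the two channels being compared.
The p-value unit (PSM-level intensity sets per channel pair) is the
natural reading of a per-protein rank test on tag intensities and is
the one implemented.

`mann_whitney_p()` uses exact null enumeration when the smaller group
has ≤ 12 observations and there are no ties, otherwise the normal
approximation with tie and continuity corrections. The exact branch is
validated against a full permutation-enumeration oracle to 1e-12 in the
tests.

A protein is differential only when both criteria hold **and agree in
direction**:

1. some ratio > 1.5 or < 0.67 with p < 0.05 — strict inequalities.
   The source methods use strict wording while the results section
   writes "≥ 1.5 fold"; strict was implemented and the thresholds are
   configurable;
2. at least three of four ratios on the same side of 1, each with
   p < 0.05. "Same trend" deliberately means the same side of 1 rather
   than beyond 1.5/0.67: reported shared-protein mean fold changes of
   ~1.30–1.35 are only attainable under this reading.

The conflicting case (criterion 1 up, criterion 2 down, or vice versa)
is not defined by the original description; such proteins are reported
as `none` with a `criteria_conflict` flag rather than silently
resolved. Proteins with an undefined ratio (zero control) or with too
few PSMs to test are likewise flagged, never dropped. No
multiple-testing correction is applied by default — fidelity to the
consensus rule is the point; the rule's strictness itself keeps the
global null well below a single-test α (the acceptance suite measures
the realized null call rate over 20 seeds × 500 proteins).

Contaminant exclusion is annotation-driven: differential proteins
annotated to the configured non-mitochondrial organelles have their
direction reset with a flag. Annotations are data, never inferred.

Shared calls between LOF and HOF report each group's mean ± SEM
(sd/√4) over the four ratios, matching the mean ± SEM presentation of
shared-protein tables.

## Protein–mRNA concordance

Differential proteins are joined to per-group expression-array log2
fold changes; the protein ordinate is the log2 of the mean of the four
ratios. Quadrants follow standard Cartesian numbering with mRNA on the
abscissa (1: both up; 3: both down; concordant = 1 or 3); a zero on
either axis is a `boundary` case excluded from rates. The concordance
rate is invariant to swapping the axes, so the plotting convention
carries no statistical weight. Percentages are reported rounded to the
nearest integer, matching conventional presentation; raw values are
retained. mRNA values are consumed as given — no microarray
re-processing — and are assumed to be fold changes, the only reading
consistent with sign-based quadrant semantics.

## Abundance stratification

Spectral-count strata are high > 50, medium 10–50 (both endpoints
inclusive), low < 10; they partition the non-negative integers. Length
bins are ≤ 100, (100, 500], (500, 1000], (1000, 5000], (5000, 10000]
amino acids; the nominal 10000 cap is treated as open-ended with a
warning, so pathological inputs are counted rather than lost. The test
behind between-group category-proportion comparisons is not named in
the source presentation; Fisher's exact test was chosen because
per-category counts are small, with a two-proportion z-test available.
Fisher p-values are validated against direct hypergeometric tail
enumeration for all tables with n ≤ 30.

## MRM confirmation

Candidate peptides come from an in-house tryptic digestion (cleave
after K/R, not before P, zero missed cleavages) filtered by four rules:
protein-unique across the supplied proteome, no Cys/Met, 7–25 residues,
no missed cleavage. Protein abundance per sample and replicate is the
sum of transition areas with S/N **strictly** greater than 10; cells
with all transitions filtered are flagged `NA`. Ratios normalize each
replicate measurement by the protein's mean control abundance, and
groups are compared with a two-sample, two-sided t-test. Equal
variances are pooled by default — the spreadsheet-era two-sample test
this mirrors is ambiguous, and Welch is available via `var_equal =
FALSE`. The replicate unit is all 2 biological × 3 technical = 6
measurements per group, the only structure consistent with the stated
n = 6; `average_technical = TRUE` collapses to biological replicates
(n = 2) for users who prefer the stricter unit. Zero-within-group
variance with a real shift makes the t-test degenerate; such
comparisons are flagged and reported as p < 1e-12 rather than NaN.

## Stereology

Grid intercept counting places a rows × cols lattice (default 9 × 13,
the manual-counting layout) with nodes at **cell centers**, not
corners: centers avoid edge-pixel bias and make manual recounts
reproducible. Volume fraction is `100·n_mito/(n_mito + n_cyto)`;
excluded intercepts (extracellular space, staining artifacts) enter
neither numerator nor denominator. Group summaries give mean ± SEM
(sd/√n) and a two-sample t-test against control (the original figure's
test is unnamed; Mann–Whitney is available). Object density counts
8-connected mitochondrion regions — implemented as an iterative
minimum-label propagation over the mask — divided by the non-excluded
area.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions the pipeline was designed around, chosen once:

* **cohort**: 718 proteins; 55/718 ≈ 7.7% differential in LOF,
  75/718 ≈ 10.4% in HOF; shared fraction 0.13 of the unique
  differential set (15 of 115); |log2 effects| uniform on [0.8, 2.0]
  with independent signs. Differential counts equal
  `round(frac · n)` exactly, so truth bookkeeping is exact;
* **abundance**: lognormal baseline (log2 mean 10, sd 2), the standard
  heavy-tailed proteome abundance model. PSM counts are a shifted
  Poisson whose rate scales with baseline abundance, which is what
  makes the spectral-count strata heavy-tailed (roughly 15/29/56
  high/medium/low in the emulated study; the generator reproduces a
  spread of this shape rather than those exact percentages);
* **noise**: per-PSM per-channel multiplicative lognormal noise with
  σ = 0.12 (log2), a per-protein per-channel replicate effect with
  σ = 0.04 emulating duplicate-preparation scatter, and a per-PSM
  baseline spread of 0.4 around the protein baseline. The two noise
  scales were calibrated once against the emulated study's replicate
  QC — about 99% of control-vs-control protein fold changes below
  1.2-fold — and then frozen. One consequence is intentionally
  accepted: with log2 baseline sd 2, the replicate Pearson r on log2
  intensities is ≈ 0.999, higher than the 0.92–0.98 a real instrument
  shows, because a generator cannot simultaneously match that r and
  the 99%-below-1.2-fold distribution; the fold-change QC is the one
  that gates the differential calls, so it wins;
* **identification layer**: target peptide probabilities ~ Beta(9, 1),
  decoys ~ Beta(1.6, 4) — overlapping the low-scoring target tail so
  the FDR threshold has real work; 3% decoy rows; 99% of peptides
  labelled; 2% of peptides shared between two accessions; 17% of
  proteins annotated to non-mitochondrial organelles;
* **injections**: each peptide is observed in both injections with
  probability 0.78 (the emulated overlap), else in one; peptides
  observed in both are guaranteed at least one spectrum per injection;
* **mRNA**: sign-concordant with the true protein effect with
  probability 0.58 (between the two observed group rates), 96% array
  coverage, null proteins get N(0, 0.2) log2 values;
* **MRM**: per-transition lognormal response factors shared across
  samples, areas proportional to group abundance × noise, a
  configurable fraction of transitions drawn below S/N 10, and the
  2 × 3 replicate layout;
* **masks**: a smoothed Gaussian field thresholded at the exact
  quantile for the requested mitochondrial area fraction (realized
  fraction exact to rounding), with an optional second field for
  excluded regions.

All randomness flows from one seed through per-module derived seeds, so
any generator can be re-run independently and identical configurations
are byte-identical. What the generator does **not** emulate: raw
spectra, chromatographic elution, isotopic envelopes (simulation starts
at the PSM report), batch or retention-time drift, peptide-level
ionization chemistry, and correlated protein modules. Passing tests on
this synthetic data therefore demonstrate that the pipeline's logic is
correct under the stated statistical structure — not that a real
instrument run would achieve the same sensitivity.

## Problem sizes and numerical conventions

The simulation-based properties use 500-protein cohorts over 10–20
seeds (null call rate, sensitivity/FDP), 256×256-pixel phantoms with a
200×200 grid over 20 seeds (stereology), and full enumeration up to
n = 6 per group (rank test) and n = 30 (Fisher) — sizes chosen so the
whole suite re-derives every property from scratch in a couple of
minutes on one core. Tolerances: 1e-12 for exact-test agreement, 1e-10
for Fisher enumeration, 1e-8 relative for the impurity round trip.
Ties in the rank test force the corrected normal approximation; fully
tied comparisons return p = 1. Degenerate inputs fail fast with
stage-attributed errors (empty post-filter tables, zero-median
channels, singular purity matrices, grids larger than masks).

## Known limitations

* The consensus rule is the faithful implementation of its source, not
  a recommendation: moderated-variance models would dominate it at low
  spectral counts, and are deliberately out of scope.
* FDR estimation assumes decoy scores model false-target scores; the
  suite checks the realized false-match proportion only under the
  generator's score model.
* Uniqueness (both for quantification and MRM selection) is evaluated
  against the supplied table only — an incomplete proteome table
  overstates uniqueness.
* The stereology estimator assumes the mask's label field is correct;
  no segmentation from grayscale micrographs is attempted.
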