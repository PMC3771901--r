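#' Confidence and FDR thresholds for PSM filtering
#'
#' Defaults follow the study design this pipeline implements: peptide
#' probability at least 80%, protein probability at least 90%, peptide-level
#' target-decoy FDR at most 0.5%, and at least two tag-labelled unique
#' peptides per quantifiable protein. All thresholds are inclusive
#' ("at least").
#'
#' @param peptide_prob_min Minimum peptide identification probability.
#' @param protein_prob_min Minimum protein identification probability.
#' @param peptide_fdr_max Maximum peptide-level target-decoy FDR.
#' @param min_unique_labeled_peptides Minimum count of distinct, labelled,
#'   protein-unique peptide sequences for a protein to be quantifiable.
#'
#' @return A list of class `filter_thresholds`.
#' @export
#' @examples
#' filter_thresholds()
filter_thresholds <- function(peptide_prob_min = 0.80,
                              protein_prob_min = 0.90,
                              peptide_fdr_max = 0.005,
                              min_unique_labeled_peptides = 2L) {
  stopifnot(
    peptide_prob_min >= 0, peptide_prob_min <= 1,
    protein_prob_min >= 0, protein_prob_min <= 1,
    peptide_fdr_max >= 0, peptide_fdr_max <= 1,
    min_unique_labeled_peptides >= 1
  )
  structure(
    list(
      peptide_prob_min = peptide_prob_min,
      protein_prob_min = protein_prob_min,
      peptide_fdr_max = peptide_fdr_max,
      min_unique_labeled_peptides = as.integer(min_unique_labeled_peptides)
    ),
    class = "filter_thresholds"
  )
}

#' Channel design: sample-to-reporter mapping
#'
#' The six-sample design labels two control (C1, C2), two hypoxia-adapted
#' (LOF1, LOF2) and two hyperoxia-adapted (HOF1, HOF2) mitochondrial
#' preparations with reporters 113, 115, 116, 117, 118 and 119 respectively
#' (channels 114 and 121 of the 8-plex kit are unused). C1 anchors the
#' median normalization.
#'
#' @param channels Named integer vector mapping sample name to reporter m/z.
#' @param reference_sample Sample whose intensity median anchors
#'   normalization.
#'
#' @return A list of class `channel_design` with elements `channels` and
#'   `reference_sample`.
#' @export
#' @examples
#' channel_design()
channel_design <- function(channels = c(C1 = 113L, C2 = 115L, LOF1 = 116L,
                                        LOF2 = 117L, HOF1 = 118L, HOF2 = 119L),
                           reference_sample = "C1") {
  if (anyDuplicated(channels) || anyDuplicated(names(channels))) {
    abort("channels must map distinct samples to distinct reporters")
  }
  if (!reference_sample %in% names(channels)) {
    abort("reference_sample must be one of the designed samples")
  }
  structure(
    list(channels = channels, reference_sample = reference_sample),
    class = "channel_design"
  )
}

#' Samples of a channel design
#' @param design A [channel_design()].
#' @return Character vector of sample names in channel order.
#' @export
design_samples <- function(design) names(design$channels)

#' Comparison scheme for the replicate-consensus differential caller
#'
#' Each adapted group is compared to control through the four replicate-cross
#' ratios (e.g. LOF1/C1, LOF1/C2, LOF2/C1, LOF2/C2). A protein is called
#' differential when (1) at least one ratio exceeds `up_threshold` or falls
#' below `down_threshold` with p < `alpha`, and (2) at least three of the four
#' ratios lie on the same side of 1 each with p < `alpha`, with both criteria
#' agreeing in direction.
#'
#' @param group `"LOF"` or `"HOF"` (or any sample prefix with replicates
#'   `<group>1`, `<group>2` in the design).
#' @param up_threshold Ratio above which criterion 1 counts an up signal
#'   (strict inequality).
#' @param down_threshold Ratio below which criterion 1 counts a down signal
#'   (strict inequality).
#' @param alpha Per-ratio significance level for the Mann-Whitney test.
#' @param control Character vector of the two control sample names.
#'
#' @return A list of class `comparison_scheme`; `$pairs` is a tibble with
#'   columns `sample` and `control`.
#' @export
#' @examples
#' comparison_scheme("LOF")$pairs
comparison_scheme <- function(group = c("LOF", "HOF"),
                              up_threshold = 1.5,
                              down_threshold = 0.67,
                              alpha = 0.05,
                              control = c("C1", "C2")) {
  group <- match.arg(group)
  stopifnot(down_threshold < 1, up_threshold > 1, alpha > 0, alpha < 1,
            length(control) == 2)
  reps <- paste0(group, 1:2)
  pairs <- tidyr::expand_grid(sample = reps, control = control)
  structure(
    list(group = group, pairs = pairs, up_threshold = up_threshold,
         down_threshold = down_threshold, alpha = alpha),
    class = "comparison_scheme"
  )
}

#' Identity purity matrix
#'
#' The default when no vendor lot sheet is supplied: no cross-channel
#' contamination is assumed or corrected.
#'
#' @param samples Sample (channel) names labelling rows and columns.
#' @return Identity matrix with dimnames `samples`.
#' @export
purity_identity <- function(samples = .oxymito_samples) {
  diag(length(samples)) |>
    (\(m) {
      dimnames(m) <- list(samples, samples)
      m
    })()
}

#' Vendor-style example purity matrix (synthetic)
#'
#' A plausible isotope-impurity matrix in the style of an 8-plex reagent
#' certificate of analysis: each column j gives the fraction of channel-j
#' reagent signal observed in each channel, with -1/+1 Da satellites of about
#' 2-6%. These values are illustrative only -- real corrections must use the
#' lot-specific certificate shipped with the reagent kit.
#'
#' @param samples Sample names, in channel order.
#' @return A column-stochastic-ish, diagonally dominant matrix.
#' @export
#' @examples
#' round(purity_example(), 3)
purity_example <- function(samples = .oxymito_samples) {
  k <- length(samples)
  minus1 <- 0.02  # satellite one reporter below
  plus1 <- 0.05   # satellite one reporter above
  p <- diag(1 - minus1 - plus1, k)
  for (j in seq_len(k)) {
    if (j > 1) p[j - 1, j] <- minus1
    if (j < k) p[j + 1, j] <- plus1
  }
  dimnames(p) <- list(samples, samples)
  p
}

#' Validate a purity matrix
#'
#' Checks that the matrix is square, non-negative, column sums do not exceed
#' 1 (within 1e-9), and the diagonal dominates each column.
#'
#' @param purity Square numeric matrix over the used channels.
#' @return The matrix, invisibly, or an error.
#' @export
validate_purity <- function(purity) {
  if (!is.matrix(purity) || nrow(purity) != ncol(purity)) {
    abort("purity must be a square matrix")
  }
  if (any(purity < 0)) abort("purity entries must be non-negative")
  if (any(colSums(purity) > 1 + 1e-9)) {
    abort("purity column sums must not exceed 1")
  }
  if (any(diag(purity) < apply(purity - diag(diag(purity)), 2, max))) {
    abort("purity must be diagonally dominant (diagonal is the main signal)")
  }
  invisible(purity)
}
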