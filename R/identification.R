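#' Estimate the peptide-level target-decoy FDR threshold
#'
#' Finds the most permissive `peptide_prob` cutoff at which the simple
#' target-decoy ratio `#decoys above cutoff / #targets above cutoff` does not
#' exceed `fdr_max`, applies it, and removes the decoys from the returned
#' table. With no decoys anywhere the lowest observed score is accepted and
#' the FDR estimate is 0.
#'
#' @param psms Tibble of PSM records with `peptide_prob` and `is_decoy`.
#' @param fdr_max Maximum acceptable peptide FDR (default 0.005).
#' @param plus_one Use the conservative `(#decoy + 1) / #target` estimator
#'   instead of the plain ratio.
#' @return A list: `threshold` (accepted `peptide_prob` cutoff), `fdr`
#'   (estimate at the cutoff), `n_removed`, and `psms` (filtered,
#'   decoy-free table).
#' @export
#' @examples
#' sim <- sim_psm_table(sim_config(n_proteins = 30, seed = 3))
#' estimate_peptide_fdr(sim$psms)$fdr
estimate_peptide_fdr <- function(psms, fdr_max = 0.005, plus_one = FALSE) {
  if (!all(c("peptide_prob", "is_decoy") %in% names(psms))) {
    abort("psms must carry peptide_prob and is_decoy columns")
  }
  if (!any(!psms$is_decoy)) abort("no target PSMs in input")
  cuts <- sort(unique(psms$peptide_prob))
  # counts at-or-above each candidate cutoff, via reverse cumulative sums
  dec_at <- table(factor(psms$peptide_prob[psms$is_decoy], levels = cuts))
  tar_at <- table(factor(psms$peptide_prob[!psms$is_decoy], levels = cuts))
  dec_above <- rev(cumsum(rev(as.integer(dec_at))))
  tar_above <- rev(cumsum(rev(as.integer(tar_at))))
  num <- if (plus_one) dec_above + 1 else dec_above
  fdr <- ifelse(tar_above == 0, Inf, num / tar_above)
  ok <- which(fdr <= fdr_max)
  if (length(ok) == 0) {
    abort("no cutoff attains the requested FDR (all PSMs decoy-dominated)")
  }
  threshold <- cuts[min(ok)]
  kept <- psms %>% filter(.data$peptide_prob >= threshold, !.data$is_decoy)
  list(
    threshold = threshold,
    fdr = fdr[min(ok)],
    n_removed = nrow(psms) - nrow(kept),
    psms = kept
  )
}

#' Apply peptide and protein confidence filters
#'
#' Retains PSMs whose peptide probability and protein probability meet the
#' inclusive thresholds (defaults: peptide >= 80%, protein >= 90%).
#'
#' @param psms Tibble of PSM records.
#' @param thresholds A [filter_thresholds()].
#' @return The filtered tibble, with attribute `n_removed`.
#' @export
apply_confidence_filters <- function(psms, thresholds = filter_thresholds()) {
  if (!all(c("peptide_prob", "protein_prob") %in% names(psms))) {
    abort("psms must carry peptide_prob and protein_prob columns")
  }
  out <- psms %>%
    filter(.data$peptide_prob >= thresholds$peptide_prob_min,
           .data$protein_prob >= thresholds$protein_prob_min)
  attr(out, "n_removed") <- nrow(psms) - nrow(out)
  out
}

# split semicolon-joined accession lists
.accessions <- function(protein_ids) strsplit(protein_ids, ";", fixed = TRUE)

#' Infer quantifiable proteins
#'
#' Groups filtered PSMs by accession and retains proteins with at least
#' `min_unique` distinct, tag-labelled peptide sequences that map to exactly
#' one accession. Shared peptides (multiple accessions) are excluded both
#' from uniqueness counting and from quantification; their PSMs are dropped
#' from the per-protein PSM sets.
#'
#' @param psms Filtered PSM tibble with `protein_ids`, `peptide`,
#'   `is_labeled`, `spectrum_id`.
#' @param min_unique Minimum count of unique labelled peptides (default 2).
#' @return A tibble of protein groups: `protein_id`,
#'   `unique_labeled_peptides`, `spectral_count`, and list-column `psm_ids`.
#' @export
infer_quantifiable_proteins <- function(psms, min_unique = 2L) {
  acc <- .accessions(psms$protein_ids)
  unique_map <- lengths(acc) == 1L
  flat <- psms %>%
    mutate(.unique = unique_map, .acc = acc) %>%
    filter(.data$.unique) %>%
    mutate(protein_id = vapply(.data$.acc, `[[`, character(1), 1L)) %>%
    select(-".acc", -".unique")
  groups <- flat %>%
    group_by(.data$protein_id) %>%
    summarise(
      unique_labeled_peptides = dplyr::n_distinct(.data$peptide[.data$is_labeled]),
      spectral_count = n(),
      psm_ids = list(.data$spectrum_id),
      .groups = "drop"
    ) %>%
    filter(.data$unique_labeled_peptides >= min_unique)
  groups
}

#' Peptide-identification overlap between parallel injections
#'
#' @param set_a,set_b Character vectors of peptide sequences identified in
#'   each injection.
#' @param mode `"jaccard"` (`100 |A&B| / |A|B|`-union) or `"mean-relative"`
#'   (`100 |A&B| / ((|A|+|B|)/2)`).
#' @return Overlap percentage.
#' @export
#' @examples
#' injection_overlap(letters[1:8], letters[5:12])
injection_overlap <- function(set_a, set_b,
                              mode = c("jaccard", "mean-relative")) {
  mode <- match.arg(mode)
  a <- unique(set_a)
  b <- unique(set_b)
  if (length(a) == 0 && length(b) == 0) abort("both peptide sets are empty")
  both <- length(intersect(a, b))
  denom <- switch(mode,
    jaccard = length(union(a, b)),
    `mean-relative` = (length(a) + length(b)) / 2
  )
  100 * both / denom
}

#' Run the full identification filter stage
#'
#' Applies, in order: target-decoy FDR thresholding (decoys removed),
#' peptide/protein confidence filters, and quantifiable-protein inference.
#' Returns the retained PSMs restricted to quantifiable proteins plus a
#' per-rule audit of counts removed.
#'
#' @param psms Raw PSM tibble (targets and decoys).
#' @param thresholds A [filter_thresholds()].
#' @return A list: `psms` (retained, unique-mapping PSMs of quantifiable
#'   proteins with a resolved `protein_id` column), `proteins` (protein
#'   group tibble), `fdr_threshold`, and `report` (named counts).
#' @export
filter_identifications <- function(psms, thresholds = filter_thresholds()) {
  n0 <- nrow(psms)
  fdr <- estimate_peptide_fdr(psms, thresholds$peptide_fdr_max)
  conf <- apply_confidence_filters(fdr$psms, thresholds)
  groups <- infer_quantifiable_proteins(
    conf, thresholds$min_unique_labeled_peptides)
  acc <- .accessions(conf$protein_ids)
  kept <- conf %>%
    mutate(.n_acc = lengths(acc),
           protein_id = vapply(acc, `[[`, character(1), 1L)) %>%
    filter(.data$.n_acc == 1L, .data$protein_id %in% groups$protein_id) %>%
    select(-".n_acc")
  list(
    psms = kept,
    proteins = groups,
    fdr_threshold = fdr$threshold,
    report = c(
      n_input_psms = n0,
      n_removed_fdr_decoy = fdr$n_removed,
      n_removed_confidence = attr(conf, "n_removed"),
      n_removed_not_quantifiable = nrow(conf) - nrow(kept),
      n_retained_psms = nrow(kept),
      n_quantifiable_proteins = nrow(groups)
    )
  )
}
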