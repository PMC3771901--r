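#' Correct reporter-ion isotope impurities
#'
#' Each tag's isotopic envelope bleeds a known fraction of its signal into
#' neighbouring reporter channels; given the vendor purity matrix `P` with
#' `P[i, j]` the fraction of channel-j reagent observed in channel i, the
#' true per-channel signals `x` satisfy `P x = observed`. This solves that
#' linear system per PSM. Negative solution components (possible with noisy
#' low signals) are clamped to zero and flagged.
#'
#' @param psms Tibble with one intensity column per designed sample, or a
#'   numeric matrix (rows = spectra, columns = channels).
#' @param purity Purity matrix with dimnames matching the sample columns.
#' @param design A [channel_design()] naming the intensity columns.
#' @return The input with corrected intensities; a logical `clamped` column
#'   (or attribute for matrix input) marks spectra with clamped components.
#' @export
#' @examples
#' p <- purity_example(c("A", "B"))[1:2, 1:2]
#' correct_isotope_impurity(matrix(c(100, 10), 1, 2,
#'   dimnames = list(NULL, c("A", "B"))), p)
correct_isotope_impurity <- function(psms, purity,
                                     design = channel_design()) {
  validate_purity(purity)
  samples <- colnames(purity) %||% design_samples(design)
  if (is.matrix(psms)) {
    x <- t(solve(purity, t(psms[, samples, drop = FALSE])))
    clamped <- apply(x < 0, 1, any)
    x[x < 0] <- 0
    attr(x, "clamped") <- clamped
    return(x)
  }
  m <- as.matrix(psms[, samples])
  det_p <- det(purity)
  if (!is.finite(det_p) || abs(det_p) < 1e-12) {
    abort("purity matrix is singular")
  }
  x <- t(solve(purity, t(m)))
  clamped <- apply(x < 0, 1, any)
  x[x < 0] <- 0
  out <- psms
  out[, samples] <- as_tibble(x)
  out$clamped <- clamped
  out
}

#' Normalize channels to the control's intensity median
#'
#' Scales every channel by the scalar that equates its PSM-level intensity
#' median with the reference channel's median (control-anchored global
#' normalization).
#'
#' @param psms Tibble of (impurity-corrected) PSM records.
#' @param design A [channel_design()]; its `reference_sample` anchors the
#'   medians.
#' @return The normalized tibble with attribute `norm_factors`, the named
#'   per-channel scalars.
#' @export
normalize_channels <- function(psms, design = channel_design()) {
  samples <- design_samples(design)
  meds <- vapply(samples, function(s) median(psms[[s]]), numeric(1))
  if (any(meds == 0)) {
    abort(paste("channel(s) with zero median intensity:",
                paste(samples[meds == 0], collapse = ", ")))
  }
  factors <- meds[design$reference_sample] / meds
  out <- psms
  for (s in samples) out[[s]] <- out[[s]] * factors[[s]]
  attr(out, "norm_factors") <- factors
  out
}

#' Aggregate PSM intensities to protein level
#'
#' Protein channel intensity is the sum of its retained PSMs' channel
#' intensities. PSM-level intensity matrices are retained per protein (as a
#' list-column) because the differential caller's rank tests operate on
#' PSM-level values.
#'
#' @param psms Normalized PSM tibble with a resolved `protein_id` column.
#' @param groups Protein-group tibble from [infer_quantifiable_proteins()];
#'   when supplied, only its proteins are aggregated and spectral counts are
#'   taken from it.
#' @param design A [channel_design()].
#' @return A protein quant tibble: `protein_id`, `spectral_count`, one
#'   summed intensity column per sample, and list-column `psm_intensities`
#'   (matrix rows = PSMs, columns = samples).
#' @export
aggregate_protein_intensities <- function(psms, groups = NULL,
                                          design = channel_design()) {
  samples <- design_samples(design)
  if (!is.null(groups)) {
    psms <- psms %>% filter(.data$protein_id %in% groups$protein_id)
  }
  if (nrow(psms) == 0) abort("no PSMs left to aggregate")
  quant <- psms %>%
    group_by(.data$protein_id) %>%
    summarise(
      spectral_count = n(),
      psm_intensities = list(as.matrix(
        dplyr::pick(dplyr::all_of(samples)))),
      across(dplyr::all_of(samples), sum),
      .groups = "drop"
    )
  quant
}

#' Replicate correlation on log2 protein intensities
#'
#' Pearson r and least-squares regression slope between two samples' log2
#' protein intensities. Proteins with a zero intensity in either sample are
#' excluded pairwise and counted.
#'
#' @param quant Protein quant tibble.
#' @param sample_a,sample_b Sample names to compare.
#' @return A one-row tibble: `sample_a`, `sample_b`, `pearson_r`, `slope`,
#'   `n_used`, `n_excluded`.
#' @export
replicate_correlation <- function(quant, sample_a, sample_b) {
  a <- quant[[sample_a]]
  b <- quant[[sample_b]]
  ok <- a > 0 & b > 0
  if (sum(ok) < 3) abort("fewer than 3 proteins with positive intensities")
  la <- log2(a[ok])
  lb <- log2(b[ok])
  tibble(
    sample_a = sample_a, sample_b = sample_b,
    pearson_r = cor(la, lb),
    slope = unname(coef(lm(lb ~ la))[2]),
    n_used = sum(ok), n_excluded = sum(!ok)
  )
}

#' Fold-change distribution between replicate samples
#'
#' Per protein, fold = max(a, b) / min(a, b); the distribution is reported
#' over the bins [1, 1.2), [1.2, 1.5] and (1.5, Inf) -- boundary folds of
#' exactly 1.2 or 1.5 fall in the middle bin.
#'
#' @param quant Protein quant tibble.
#' @param sample_a,sample_b Sample names to compare.
#' @return A tibble with `bin` (`<1.2`, `1.2-1.5`, `>1.5`), `n`, `percent`.
#' @export
fold_change_distribution <- function(quant, sample_a, sample_b) {
  a <- quant[[sample_a]]
  b <- quant[[sample_b]]
  if (any(a <= 0 | b <= 0)) {
    abort("fold changes undefined for non-positive intensities")
  }
  fold <- pmax(a, b) / pmin(a, b)
  bin <- cut(fold, c(1, 1.2, 1.5, Inf), right = FALSE,
             labels = c("<1.2", "1.2-1.5", ">1.5"),
             include.lowest = TRUE)
  bin[fold == 1.5] <- "1.2-1.5"  # closed upper boundary of the middle bin
  tibble(bin = factor(c("<1.2", "1.2-1.5", ">1.5"),
                      levels = c("<1.2", "1.2-1.5", ">1.5"))) %>%
    left_join(tibble(bin = bin) %>% count(.data$bin), by = "bin") %>%
    mutate(n = tidyr::replace_na(.data$n, 0L),
           percent = 100 * .data$n / length(fold))
}
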