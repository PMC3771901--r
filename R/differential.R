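#' Two-sided Mann-Whitney p-value for two PSM intensity sets
#'
#' Exact null enumeration is used when the smaller group has at most
#' `exact_max_n` observations and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#' Lists shorter than 2 make the comparison untestable (`NA`).
#'
#' @param a,b Numeric vectors of PSM-level intensities.
#' @param exact_max_n Largest small-group size for the exact branch.
#' @return Two-sided p-value, or `NA_real_` if either list has fewer than
#'   two values.
#' @export
#' @examples
#' mann_whitney_p(1:3, 4:6)  # 0.1
mann_whitney_p <- function(a, b, exact_max_n = 12L) {
  if (length(a) < 2 || length(b) < 2) return(NA_real_)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && min(length(a), length(b)) <= exact_max_n
  suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = TRUE)$p.value
  )
}

#' Compute the four replicate-cross ratio tests for each protein
#'
#' For each scheme pair (e.g. LOF1/C1), the ratio is the protein-level
#' summed intensity quotient and the p-value a Mann-Whitney test on the
#' protein's PSM-level intensities in the two channels. Zero control
#' intensity leaves the ratio undefined (`NA`) and flags the protein.
#'
#' @param quant Protein quant tibble from [aggregate_protein_intensities()].
#' @param scheme A [comparison_scheme()].
#' @return A tibble with one row per protein x pair: `protein_id`, `group`,
#'   `sample`, `control`, `ratio`, `p_value`, `n_psms`.
#' @export
compute_ratio_tests <- function(quant, scheme) {
  pairs <- scheme$pairs
  used <- unique(c(pairs$sample, pairs$control))
  intens <- as.matrix(quant[, used])
  num_mat <- intens[, pairs$sample, drop = FALSE]
  den_mat <- intens[, pairs$control, drop = FALSE]
  purrr::map(seq_len(nrow(quant)), function(i) {
    m <- quant$psm_intensities[[i]]
    p <- vapply(seq_len(nrow(pairs)), function(k) {
      mann_whitney_p(m[, pairs$sample[k]], m[, pairs$control[k]])
    }, numeric(1))
    tibble(
      protein_id = quant$protein_id[i],
      group = scheme$group,
      sample = pairs$sample,
      control = pairs$control,
      ratio = ifelse(den_mat[i, ] > 0, num_mat[i, ] / den_mat[i, ], NA_real_),
      p_value = p,
      n_psms = nrow(m)
    )
  }) %>% dplyr::bind_rows()
}

#' Classify proteins by the two-criteria consensus rule
#'
#' Criterion 1: at least one of the four ratios exceeds the up threshold or
#' falls below the down threshold (strict inequalities) with p < alpha.
#' Criterion 2: at least three of the four ratios lie on the same side of 1,
#' each with p < alpha. A protein is differential only when both criteria
#' hold and agree in direction; undefined ratios or untestable p-values
#' yield `direction = "none"` with a flag.
#'
#' @param tests Ratio-test tibble from [compute_ratio_tests()].
#' @param scheme The [comparison_scheme()] that produced `tests`.
#' @return One row per protein: `protein_id`, `group`, `direction`
#'   (`up`/`down`/`none`), `criterion1_met`, `criterion2_met`,
#'   `mean_ratio`, `sem_ratio`, `min_p`, `flag` (`ok`, `undefined_ratio`,
#'   `untestable`, or `criteria_conflict`).
#' @export
classify_differential <- function(tests, scheme) {
  alpha <- scheme$alpha
  up <- scheme$up_threshold
  down <- scheme$down_threshold
  tests %>%
    group_by(.data$protein_id, .data$group) %>%
    summarise(
      n_pairs = n(),
      mean_ratio = mean(.data$ratio),
      sem_ratio = sd(.data$ratio) / sqrt(n()),
      min_p = suppressWarnings(min(.data$p_value, na.rm = TRUE)),
      .c1_up = any(.data$ratio > up & .data$p_value < alpha, na.rm = TRUE),
      .c1_down = any(.data$ratio < down & .data$p_value < alpha, na.rm = TRUE),
      .c2_up = sum(.data$ratio > 1 & .data$p_value < alpha, na.rm = TRUE) >= 3,
      .c2_down = sum(.data$ratio < 1 & .data$p_value < alpha, na.rm = TRUE) >= 3,
      .bad_ratio = anyNA(.data$ratio),
      .bad_p = anyNA(.data$p_value),
      .groups = "drop"
    ) %>%
    mutate(
      criterion1_met = .data$.c1_up | .data$.c1_down,
      criterion2_met = .data$.c2_up | .data$.c2_down,
      direction = dplyr::case_when(
        .data$.bad_ratio | .data$.bad_p ~ "none",
        .data$.c1_up & .data$.c2_up ~ "up",
        .data$.c1_down & .data$.c2_down ~ "down",
        .default = "none"
      ),
      flag = dplyr::case_when(
        .data$.bad_ratio ~ "undefined_ratio",
        .data$.bad_p ~ "untestable",
        .data$criterion1_met & .data$criterion2_met &
          .data$direction == "none" ~ "criteria_conflict",
        .default = "ok"
      )
    ) %>%
    select("protein_id", "group", "direction", "criterion1_met",
           "criterion2_met", "mean_ratio", "sem_ratio", "min_p", "flag")
}

#' Call differential proteins for one group
#'
#' Convenience wrapper running [compute_ratio_tests()] then
#' [classify_differential()]; returns an object of class `diff_calls` (a
#' tibble) with the ratio tests attached as attribute `tests`.
#'
#' @param quant Protein quant tibble.
#' @param group `"LOF"` or `"HOF"`.
#' @param ... Passed to [comparison_scheme()].
#' @return A `diff_calls` tibble.
#' @export
#' @examples
#' sim <- sim_psm_table(sim_config(n_proteins = 30, seed = 5))
#' stage <- filter_identifications(sim$psms)
#' quant <- aggregate_protein_intensities(
#'   normalize_channels(stage$psms), stage$proteins)
#' calls <- call_differential(quant, "LOF")
#' dplyr::count(calls, direction)
call_differential <- function(quant, group = c("LOF", "HOF"), ...) {
  scheme <- comparison_scheme(match.arg(group), ...)
  tests <- compute_ratio_tests(quant, scheme)
  calls <- classify_differential(tests, scheme)
  structure(calls, tests = tests, scheme = scheme,
            class = c("diff_calls", class(calls)))
}

#' Exclude annotated organelle contaminants from differential calls
#'
#' The mitochondrial preparation is not purity-certified, so confidently
#' non-mitochondrial proteins among the differential calls are excluded:
#' their direction is reset to `none` and a flag is set. Unannotated
#' proteins are retained.
#'
#' @param calls A `diff_calls` tibble.
#' @param annotation Tibble with `protein_id` and `organelle`.
#' @param excluded_organelles Character vector of organelle labels treated
#'   as contamination sources.
#' @return The calls tibble with `excluded_as_contaminant` set and
#'   contaminated directions reset; attribute `n_excluded` counts resets.
#' @export
exclude_contaminants <- function(calls, annotation,
                                 excluded_organelles = c("nucleus",
                                                         "extracellular")) {
  ann <- annotation %>% select("protein_id", "organelle") %>% distinct()
  out <- calls %>%
    left_join(ann, by = "protein_id") %>%
    mutate(
      excluded_as_contaminant = !is.na(.data$organelle) &
        .data$organelle %in% excluded_organelles &
        .data$direction != "none",
      direction = if_else(.data$excluded_as_contaminant, "none",
                          .data$direction)
    ) %>%
    select(-"organelle")
  attr(out, "n_excluded") <- sum(out$excluded_as_contaminant)
  class(out) <- class(calls)
  out
}

#' Intersect LOF and HOF differential calls
#'
#' Proteins differential in both groups, with each group's direction and the
#' mean and SEM (sd / sqrt(4)) of its four replicate-cross ratios.
#'
#' @param lof_calls,hof_calls `diff_calls` tibbles for the two groups.
#' @return A tibble: `protein_id`, `direction_lof`, `direction_hof`,
#'   `mean_ratio_lof`, `sem_ratio_lof`, `mean_ratio_hof`, `sem_ratio_hof`.
#' @export
intersect_calls <- function(lof_calls, hof_calls) {
  lof <- lof_calls %>%
    filter(.data$direction != "none") %>%
    select("protein_id", direction_lof = "direction",
           mean_ratio_lof = "mean_ratio", sem_ratio_lof = "sem_ratio")
  hof <- hof_calls %>%
    filter(.data$direction != "none") %>%
    select("protein_id", direction_hof = "direction",
           mean_ratio_hof = "mean_ratio", sem_ratio_hof = "sem_ratio")
  inner_join(lof, hof, by = "protein_id") %>%
    select("protein_id", "direction_lof", "direction_hof",
           "mean_ratio_lof", "sem_ratio_lof",
           "mean_ratio_hof", "sem_ratio_hof")
}
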