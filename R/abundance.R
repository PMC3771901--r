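#' Stratify proteins by spectral count
#'
#' High abundance: more than 50 spectra; medium: 10 to 50 inclusive; low:
#' fewer than 10. The three strata partition the non-negative integers.
#'
#' @param spectral_count Non-negative integer vector.
#' @return Factor with levels `high`, `medium`, `low`.
#' @export
#' @examples
#' stratify_abundance(c(51, 50, 10, 9))
stratify_abundance <- function(spectral_count) {
  if (any(spectral_count < 0)) abort("spectral counts must be non-negative")
  factor(
    dplyr::case_when(
      spectral_count > 50 ~ "high",
      spectral_count >= 10 ~ "medium",
      .default = "low"
    ),
    levels = c("high", "medium", "low")
  )
}

#' Abundance-stratum distribution of a protein subset
#'
#' @param proteins Tibble with `protein_id` and `spectral_count`.
#' @param subset Optional character vector of protein ids; defaults to all.
#' @return Tibble `stratum`, `n`, `percent` (percentages sum to 100 within
#'   rounding).
#' @export
stratum_distribution <- function(proteins, subset = NULL) {
  if (!is.null(subset)) {
    proteins <- proteins %>% filter(.data$protein_id %in% subset)
  }
  if (nrow(proteins) == 0) abort("empty protein subset")
  tibble(stratum = stratify_abundance(proteins$spectral_count)) %>%
    count(.data$stratum, .drop = FALSE) %>%
    mutate(percent = 100 * .data$n / sum(.data$n))
}

#' Protein-length distribution within each abundance stratum
#'
#' Length bins (amino acids): <=100, (100, 500], (500, 1000], (1000, 5000],
#' and >5000 (nominally capped at 10000; longer proteins are counted in the
#' top bin with a warning). Row percentages within each stratum sum to 100.
#'
#' @param proteins Tibble with `spectral_count` and `length`.
#' @return Tibble `stratum`, `length_bin`, `n`, `percent`.
#' @export
length_group_distribution <- function(proteins) {
  if (any(proteins$length <= 0)) abort("protein lengths must be positive")
  if (any(proteins$length > 10000)) {
    warn("lengths above 10000 aa counted in the top length bin")
  }
  bins <- cut(proteins$length, c(0, 100, 500, 1000, 5000, Inf),
              labels = c("<=100", "100-500", "500-1000", "1000-5000",
                         "5000-10000"))
  tibble(
    stratum = stratify_abundance(proteins$spectral_count),
    length_bin = bins
  ) %>%
    count(.data$stratum, .data$length_bin, .drop = FALSE) %>%
    group_by(.data$stratum) %>%
    mutate(percent = if (sum(.data$n) > 0) 100 * .data$n / sum(.data$n) else 0) %>%
    ungroup()
}

#' Functional-category distribution of a protein subset
#'
#' Per category: member count, percentage of the subset, and (when a calls
#' table is supplied) the up/down direction split among differential
#' proteins. Unannotated proteins leave the percentages summing below 100.
#'
#' @param proteins Tibble with `protein_id`.
#' @param annotation Tibble with `protein_id` and `category`.
#' @param subset Optional protein-id subset.
#' @param calls Optional `diff_calls` tibble supplying directions.
#' @return Tibble `category`, `n`, `percent`, and `n_up`/`n_down` when
#'   `calls` is given.
#' @export
category_distribution <- function(proteins, annotation, subset = NULL,
                                  calls = NULL) {
  if (!is.null(subset)) {
    proteins <- proteins %>% filter(.data$protein_id %in% subset)
  }
  n_total <- nrow(proteins)
  ann <- annotation %>% select("protein_id", "category") %>% distinct()
  tab <- proteins %>%
    inner_join(ann, by = "protein_id") %>%
    count(.data$category) %>%
    mutate(percent = 100 * .data$n / n_total)
  if (!is.null(calls)) {
    dirs <- calls %>%
      select("protein_id", "direction") %>%
      inner_join(ann, by = "protein_id") %>%
      filter(.data$protein_id %in% proteins$protein_id) %>%
      group_by(.data$category) %>%
      summarise(n_up = sum(.data$direction == "up"),
                n_down = sum(.data$direction == "down"), .groups = "drop")
    tab <- left_join(tab, dirs, by = "category") %>%
      mutate(across(c("n_up", "n_down"), ~ tidyr::replace_na(.x, 0L)))
  }
  tab
}

#' Compare two category proportions
#'
#' Two-sided test of k_a/n_a versus k_b/n_b. The default is Fisher's exact
#' test on the 2x2 table, appropriate for the small per-category counts
#' involved; a two-proportion z-test (without continuity correction) is
#' available.
#'
#' @param k_a,n_a,k_b,n_b Successes and totals of the two groups.
#' @param method `"fisher"` or `"z"`.
#' @return Two-sided p-value.
#' @export
#' @examples
#' compare_proportions(8, 10, 2, 10)  # ~0.023
compare_proportions <- function(k_a, n_a, k_b, n_b,
                                method = c("fisher", "z")) {
  method <- match.arg(method)
  if (k_a > n_a || k_b > n_b || n_a < 1 || n_b < 1 ||
      k_a < 0 || k_b < 0) {
    abort("invalid counts")
  }
  if (method == "fisher") {
    fisher.test(matrix(c(k_a, n_a - k_a, k_b, n_b - k_b), 2, byrow = TRUE))$p.value
  } else {
    suppressWarnings(
      prop.test(c(k_a, k_b), c(n_a, n_b), correct = FALSE)$p.value
    )
  }
}
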