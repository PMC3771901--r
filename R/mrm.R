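#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to lysine (K) or arginine (R) except when the next
#' residue is proline (P); zero missed cleavages.
#'
#' @param sequence Amino-acid string over the 20-letter alphabet.
#' @return Character vector of peptides in N-to-C order.
#' @export
#' @examples
#' digest_tryptic("MAGWKTTESTPEPTIDERLVCK")
digest_tryptic <- function(sequence) {
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", sequence)) {
    abort("sequence contains invalid amino-acid characters")
  }
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & chars[cut_after + 1L] != "P"]
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  substring(sequence, starts, ends)
}

#' Select MRM-suitable peptides
#'
#' Applies the four selection rules to the tryptic digest of each target:
#' (1) the peptide is unique to one protein across the supplied proteome,
#' (2) contains no cysteine or methionine (labile under sample handling),
#' (3) is 7-25 residues long, and (4) carries no missed cleavage (enforced
#' by the digestion itself).
#'
#' @param sequences Named character vector of protein sequences (names =
#'   protein ids); uniqueness is evaluated over this whole table.
#' @param targets Optional protein ids to report candidates for; defaults
#'   to all.
#' @param min_length,max_length Peptide length bounds (inclusive).
#' @return Tibble `protein_id`, `peptide`; proteins with no candidate are
#'   reported in attribute `no_candidates`.
#' @export
select_mrm_peptides <- function(sequences, targets = NULL,
                                min_length = 7L, max_length = 25L) {
  if (is.null(names(sequences))) abort("sequences must be named by protein id")
  digest <- purrr::imap(sequences, ~ tibble(protein_id = .y,
                                            peptide = digest_tryptic(.x))) %>%
    dplyr::bind_rows() %>%
    distinct()
  pep_owners <- digest %>% count(.data$peptide, name = "n_proteins")
  targets <- targets %||% names(sequences)
  cand <- digest %>%
    filter(.data$protein_id %in% targets) %>%
    left_join(pep_owners, by = "peptide") %>%
    filter(
      .data$n_proteins == 1L,
      !grepl("[CM]", .data$peptide),
      nchar(.data$peptide) >= min_length,
      nchar(.data$peptide) <= max_length
    ) %>%
    select("protein_id", "peptide")
  attr(cand, "no_candidates") <- setdiff(targets, cand$protein_id)
  cand
}

#' Quantify MRM protein abundance from transition areas
#'
#' Protein abundance per sample and replicate is the sum of transition areas
#' whose signal-to-noise strictly exceeds `sn_min`. Protein/sample/replicate
#' cells whose transitions are all filtered out get `NA` abundance with a
#' flag.
#'
#' @param transitions Transition tibble (see [sim_mrm_table()] for columns).
#' @param sn_min S/N threshold; peaks must exceed it strictly (default 10).
#' @return Tibble `protein_id`, `sample`, `bio_replicate`, `tech_replicate`,
#'   `abundance`, `n_transitions`, `all_filtered`.
#' @export
#' @examples
#' tr <- tibble::tibble(protein_id = "P", sample = "C", bio_replicate = 1,
#'   tech_replicate = 1, area = c(100, 200, 300),
#'   signal_to_noise = c(5, 15, 20))
#' mrm_quantify(tr)$abundance  # 500
mrm_quantify <- function(transitions, sn_min = 10) {
  transitions %>%
    group_by(.data$protein_id, .data$sample, .data$bio_replicate,
             .data$tech_replicate) %>%
    summarise(
      abundance = {
        ok <- .data$signal_to_noise > sn_min
        if (any(ok)) sum(.data$area[ok]) else NA_real_
      },
      n_transitions = sum(.data$signal_to_noise > sn_min),
      .groups = "drop"
    ) %>%
    mutate(all_filtered = is.na(.data$abundance))
}

#' Normalize MRM abundances to control and test group differences
#'
#' Each replicate measurement is divided by the mean control abundance of
#' its protein; group means of these ratios are compared to control with a
#' two-sample, two-sided t-test across the n = 6 measurements per group
#' (2 biological x 3 technical replicates). Equal variances are pooled by
#' default; `var_equal = FALSE` gives Welch. Degenerate comparisons with
#' zero within-group variance are flagged and reported as p < 1e-12.
#'
#' @param abundances Tibble from [mrm_quantify()].
#' @param control Control sample label.
#' @param var_equal Pool variances (classic two-sample t-test).
#' @param average_technical Average technical replicates within biological
#'   replicate before testing (reduces n to the number of biological
#'   replicates).
#' @return A tibble of class `mrm_result`: `protein_id`, `sample`,
#'   `mean_ratio`, `sd_ratio`, `n`, `p_value`, `degenerate`.
#' @export
mrm_normalize_test <- function(abundances, control = "C", var_equal = TRUE,
                               average_technical = FALSE) {
  if (average_technical) {
    abundances <- abundances %>%
      group_by(.data$protein_id, .data$sample, .data$bio_replicate) %>%
      summarise(abundance = mean(.data$abundance, na.rm = TRUE),
                .groups = "drop")
  }
  ctrl_mean <- abundances %>%
    filter(.data$sample == control) %>%
    group_by(.data$protein_id) %>%
    summarise(ctrl = mean(.data$abundance, na.rm = TRUE), .groups = "drop")
  ratios <- abundances %>%
    inner_join(ctrl_mean, by = "protein_id") %>%
    mutate(ratio = .data$abundance / .data$ctrl)
  out <- ratios %>%
    group_by(.data$protein_id, .data$sample) %>%
    summarise(
      mean_ratio = mean(.data$ratio, na.rm = TRUE),
      sd_ratio = sd(.data$ratio[!is.na(.data$ratio)]),
      n = sum(!is.na(.data$ratio)),
      .groups = "drop"
    )
  p_of <- function(pid, smp) {
    x <- ratios$ratio[ratios$protein_id == pid & ratios$sample == smp]
    y <- ratios$ratio[ratios$protein_id == pid & ratios$sample == control]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) return(c(NA_real_, NA))
    if (sd(x) == 0 && sd(y) == 0) {
      if (isTRUE(all.equal(mean(x), mean(y)))) return(c(1, FALSE))
      return(c(1e-12, TRUE))
    }
    c(t.test(x, y, var.equal = var_equal)$p.value, FALSE)
  }
  stats <- purrr::map2(out$protein_id, out$sample, p_of)
  out$p_value <- vapply(stats, `[[`, numeric(1), 1L)
  out$degenerate <- as.logical(vapply(stats, `[[`, numeric(1), 2L))
  structure(out, class = c("mrm_result", class(out)))
}
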