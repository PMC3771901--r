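#' Match differential proteins to mRNA fold changes
#'
#' Joins each differential protein to its group's expression-array record.
#' Uncovered proteins are counted and excluded from quadrant statistics. The
#' protein fold change used for the scatter is the log2 of the mean of the
#' group's four replicate-cross ratios.
#'
#' @param calls A `diff_calls` tibble (one group).
#' @param mrna Tibble with `gene_id`, `group`, `mrna_log2fc` (one record per
#'   gene per group).
#' @param id_map Optional tibble `protein_id` -> `gene_id`; identity mapping
#'   assumed when `NULL`.
#' @return A tibble of matched differential proteins: `protein_id`, `group`,
#'   `protein_log2fc`, `mrna_log2fc`; attributes `n_uncovered` and
#'   `n_differential`.
#' @export
match_mrna <- function(calls, mrna, id_map = NULL) {
  grp <- unique(calls$group)
  mg <- mrna %>% filter(.data$group %in% grp)
  if (anyDuplicated(mg[c("gene_id", "group")])) {
    abort("duplicate mRNA records for a gene-group")
  }
  diff <- calls %>% filter(.data$direction != "none")
  if (is.null(id_map)) {
    id_map <- tibble(protein_id = diff$protein_id, gene_id = diff$protein_id)
  }
  matched <- diff %>%
    left_join(id_map, by = "protein_id") %>%
    inner_join(mg, by = c("gene_id", "group")) %>%
    mutate(protein_log2fc = log2(.data$mean_ratio)) %>%
    select("protein_id", "group", "protein_log2fc", "mrna_log2fc")
  attr(matched, "n_differential") <- nrow(diff)
  attr(matched, "n_uncovered") <- nrow(diff) - nrow(matched)
  matched
}

#' Assign concordance quadrants
#'
#' Standard Cartesian quadrants with mRNA log2 fold change on the abscissa
#' and protein log2 fold change on the ordinate: quadrant 1 both up,
#' 3 both down (concordant); 2 protein up / mRNA down, 4 protein down /
#' mRNA up (discordant). A zero on either axis is classified `boundary` and
#' excluded from rate computations.
#'
#' @param matched Tibble from [match_mrna()] (or any tibble with
#'   `protein_log2fc` and `mrna_log2fc`).
#' @return The input with `quadrant` (`"1"`..`"4"` or `"boundary"`) and
#'   `concordant` columns.
#' @export
#' @examples
#' assign_quadrant(tibble::tibble(protein_log2fc = c(0.8, 0.6, -0.3, 0),
#'                                mrna_log2fc = c(0.5, -0.4, -0.2, 0.4)))
assign_quadrant <- function(matched) {
  p <- matched$protein_log2fc
  m <- matched$mrna_log2fc
  if (any(!is.finite(p)) || any(!is.finite(m))) {
    abort("fold changes must be finite")
  }
  q <- dplyr::case_when(
    p == 0 | m == 0 ~ "boundary",
    p > 0 & m > 0 ~ "1",
    p > 0 & m < 0 ~ "2",
    p < 0 & m < 0 ~ "3",
    .default = "4"
  )
  matched %>%
    mutate(quadrant = q, concordant = q %in% c("1", "3"))
}

#' Overall concordance rate
#'
#' @param assignments Tibble from [assign_quadrant()].
#' @param digits Rounding for the reported percentage (0 = nearest integer,
#'   matching the conventional presentation).
#' @return A list: `counts` (named Q1..Q4 + boundary), `n_concordant`,
#'   `percent_concordant` (rounded), `percent_raw`.
#' @export
#' @examples
#' # 14 up- plus 15 down-concordant of 53 classified -> 55%
#' x <- tibble::tibble(
#'   protein_log2fc = c(rep(1, 14), rep(-1, 15), rep(1, 10), rep(-1, 14)),
#'   mrna_log2fc = c(rep(1, 14), rep(-1, 15), rep(-1, 10), rep(1, 14)))
#' concordance_rate(assign_quadrant(x))$percent_concordant
concordance_rate <- function(assignments, digits = 0) {
  counts <- vapply(c("1", "2", "3", "4", "boundary"),
                   function(q) sum(assignments$quadrant == q), integer(1))
  names(counts) <- c("Q1", "Q2", "Q3", "Q4", "boundary")
  total <- sum(counts[1:4])
  if (total == 0) abort("all assignments lie on a boundary")
  pct <- 100 * (counts[["Q1"]] + counts[["Q3"]]) / total
  list(
    counts = counts,
    n_concordant = counts[["Q1"]] + counts[["Q3"]],
    percent_concordant = round(pct, digits),
    percent_raw = pct
  )
}

#' Per-category and pooled concordance
#'
#' Counts concordant proteins per functional category and pools a stated
#' subset of categories into one rate, as done when asking whether e.g.
#' respiration-related proteins track their mRNAs.
#'
#' @param assignments Tibble from [assign_quadrant()].
#' @param annotation Tibble with `protein_id` and `category`.
#' @param pooled_categories Categories pooled for the summary percentage;
#'   defaults to all categories present.
#' @return A list: `per_category` tibble (`category`, `concordant`, `total`,
#'   `percent`) and `pooled` (list with `concordant`, `total`, `percent`
#'   rounded to integer).
#' @export
category_concordance <- function(assignments, annotation,
                                 pooled_categories = NULL) {
  ann <- annotation %>% select("protein_id", "category") %>% distinct()
  tab <- assignments %>%
    filter(.data$quadrant != "boundary") %>%
    inner_join(ann, by = "protein_id") %>%
    group_by(.data$category) %>%
    summarise(concordant = sum(.data$concordant), total = n(),
              .groups = "drop") %>%
    mutate(percent = 100 * .data$concordant / .data$total)
  pooled_categories <- pooled_categories %||% tab$category
  pooled <- tab %>% filter(.data$category %in% pooled_categories)
  list(
    per_category = tab,
    pooled = pool_concordance(pooled$concordant, pooled$total)
  )
}

#' Pool concordant/total counts into one percentage
#'
#' Direct arithmetic on per-category counts: the pooled rate is
#' `100 * sum(concordant) / sum(total)`, rounded to the nearest integer for
#' reporting.
#'
#' @param concordant,total Integer vectors of per-category counts.
#' @return A list: `concordant`, `total`, `percent` (rounded), `percent_raw`.
#' @export
#' @examples
#' pool_concordance(c(27, 4, 8, 6), c(35, 6, 12, 8))$percent  # 74
pool_concordance <- function(concordant, total) {
  stopifnot(length(concordant) == length(total), all(concordant <= total))
  pct <- 100 * sum(concordant) / sum(total)
  list(concordant = sum(concordant), total = sum(total),
       percent = round(pct), percent_raw = pct)
}
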