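#' Write the synthetic input bundle to disk
#'
#' Generates every table the pipeline consumes (PSM report, annotation,
#' mRNA fold changes, MRM transitions) plus the ground truth, as headered
#' tab-separated files, and returns a manifest.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param mrm_targets Number of truly differential HOF proteins to monitor
#'   by MRM (down-regulated ones preferred, emulating the complex-I panel).
#' @return Invisible named character vector of written paths (the manifest),
#'   also printed.
#' @export
simulate_inputs <- function(config, dir, mrm_targets = 10L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- sim_psm_table(config)
  truth <- sim$truth
  mrna <- sim_mrna_table(truth, config$mrna_concordance_prob,
                         config$mrna_coverage, seed = config$seed)
  down <- truth$protein_id[truth$true_log2fc_hof < 0]
  targets <- head(c(down, truth$protein_id[truth$is_differential_hof]),
                  min(mrm_targets, sum(truth$is_differential_hof)))
  targets <- unique(targets)
  mrm <- if (length(targets) > 0) {
    sim_mrm_table(targets, truth, seed = config$seed)
  }
  annotation <- truth %>%
    select("protein_id", "organelle", "category", "length")

  paths <- c(
    psms = file.path(dir, "psms.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    mrna = file.path(dir, "mrna.tsv"),
    mrm = file.path(dir, "mrm.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  readr::write_tsv(sim$psms, paths["psms"])
  readr::write_tsv(annotation, paths["annotation"])
  readr::write_tsv(mrna, paths["mrna"])
  if (!is.null(mrm)) readr::write_tsv(mrm, paths["mrm"]) else
    paths <- paths[names(paths) != "mrm"]
  readr::write_tsv(truth, paths["truth"])
  inform(paste0("wrote ", length(paths), " files:\n  ",
                paste(paths, collapse = "\n  ")))
  invisible(paths)
}

#' Run the full quantitative pipeline
#'
#' Executes identification filtering, reporter quantification, differential
#' calling for both adapted groups, contaminant exclusion, protein-mRNA
#' concordance, and abundance profiling; optionally MRM confirmation. Every
#' reported count is recomputable from the returned stage outputs.
#'
#' @param psms Raw PSM tibble, or a path to a PSM TSV.
#' @param annotation Annotation tibble (`protein_id`, `organelle`,
#'   `category`, optionally `length`) or TSV path; optional.
#' @param mrna mRNA tibble (`gene_id`, `group`, `mrna_log2fc`) or TSV path;
#'   optional.
#' @param mrm MRM transition tibble or TSV path; optional.
#' @param thresholds A [filter_thresholds()].
#' @param design A [channel_design()].
#' @param purity Purity matrix (default identity: correction disabled).
#' @param excluded_organelles Organelles treated as contamination.
#' @param out_dir Optional directory; stage TSVs and a JSON report are
#'   written there.
#' @param ... Passed to [comparison_scheme()] for both groups.
#' @return A list of class `oxymito_run`: stage outputs (`filter`, `quant`,
#'   `calls_lof`, `calls_hof`, `shared`, `concordance_lof`,
#'   `concordance_hof`, `strata`, `mrm`) and `report`, a named list of the
#'   headline counts.
#' @export
#' @examples
#' cfg <- sim_config(n_proteins = 40, seed = 11)
#' sim <- sim_psm_table(cfg)
#' run <- run_pipeline(sim$psms,
#'   annotation = sim$truth[c("protein_id", "organelle", "category", "length")],
#'   mrna = sim_mrna_table(sim$truth, seed = 11))
#' run$report$n_quantifiable_proteins
run_pipeline <- function(psms,
                         annotation = NULL,
                         mrna = NULL,
                         mrm = NULL,
                         thresholds = filter_thresholds(),
                         design = channel_design(),
                         purity = NULL,
                         excluded_organelles = c("nucleus", "extracellular"),
                         out_dir = NULL,
                         ...) {
  read_maybe <- function(x) {
    if (is.character(x)) readr::read_tsv(x, show_col_types = FALSE) else x
  }
  psms <- read_maybe(psms)
  annotation <- read_maybe(annotation)
  mrna <- read_maybe(mrna)
  mrm <- read_maybe(mrm)
  if (is.null(purity)) purity <- purity_identity(design_samples(design))

  stage <- filter_identifications(psms, thresholds)
  if (nrow(stage$psms) == 0) abort("no PSMs survive identification filters")

  corrected <- correct_isotope_impurity(stage$psms, purity, design)
  normalized <- normalize_channels(corrected, design)
  quant <- aggregate_protein_intensities(normalized, stage$proteins, design)

  calls_lof <- call_differential(quant, "LOF", ...)
  calls_hof <- call_differential(quant, "HOF", ...)
  if (!is.null(annotation)) {
    calls_lof <- exclude_contaminants(calls_lof, annotation,
                                      excluded_organelles)
    calls_hof <- exclude_contaminants(calls_hof, annotation,
                                      excluded_organelles)
  }
  shared <- intersect_calls(calls_lof, calls_hof)

  conc <- function(calls) {
    if (is.null(mrna)) return(NULL)
    matched <- match_mrna(calls, mrna)
    if (nrow(matched) == 0) return(NULL)
    a <- assign_quadrant(matched)
    list(assignments = a, rate = concordance_rate(a),
         n_uncovered = attr(matched, "n_uncovered"))
  }
  conc_lof <- conc(calls_lof)
  conc_hof <- conc(calls_hof)

  diff_ids <- union(calls_lof$protein_id[calls_lof$direction != "none"],
                    calls_hof$protein_id[calls_hof$direction != "none"])
  strata <- list(
    all = stratum_distribution(quant),
    differential = if (length(diff_ids) > 0) {
      stratum_distribution(quant, diff_ids)
    }
  )

  mrm_out <- if (!is.null(mrm)) mrm_normalize_test(mrm_quantify(mrm))

  report <- list(
    n_input_psms = unname(stage$report["n_input_psms"]),
    n_retained_psms = unname(stage$report["n_retained_psms"]),
    fdr_threshold = stage$fdr_threshold,
    n_quantifiable_proteins = nrow(quant),
    n_differential_lof = sum(calls_lof$direction != "none"),
    n_differential_hof = sum(calls_hof$direction != "none"),
    n_differential_unique = length(diff_ids),
    n_shared = nrow(shared),
    n_contaminants_excluded =
      (attr(calls_lof, "n_excluded") %||% 0) +
      (attr(calls_hof, "n_excluded") %||% 0),
    concordance_pct_lof = if (!is.null(conc_lof)) {
      conc_lof$rate$percent_concordant
    },
    concordance_pct_hof = if (!is.null(conc_hof)) {
      conc_hof$rate$percent_concordant
    },
    stratum_pct_all = setNames(strata$all$percent,
                               as.character(strata$all$stratum))
  )

  out <- structure(
    list(filter = stage, quant = quant, calls_lof = calls_lof,
         calls_hof = calls_hof, shared = shared,
         concordance_lof = conc_lof, concordance_hof = conc_hof,
         strata = strata, mrm = mrm_out, report = report),
    class = "oxymito_run"
  )
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

#' Write pipeline stage outputs and the JSON report
#'
#' @param run An `oxymito_run` object.
#' @param dir Output directory.
#' @return Invisible vector of written paths.
#' @export
write_run <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  w <- function(x, name) {
    p <- file.path(dir, name)
    readr::write_tsv(x, p)
    paths <<- c(paths, p)
  }
  w(run$quant %>% select(-"psm_intensities"), "protein_quant.tsv")
  w(as_tibble(run$calls_lof), "differential_lof.tsv")
  w(as_tibble(run$calls_hof), "differential_hof.tsv")
  w(run$shared, "differential_shared.tsv")
  if (!is.null(run$concordance_lof)) {
    w(run$concordance_lof$assignments, "concordance_lof.tsv")
  }
  if (!is.null(run$concordance_hof)) {
    w(run$concordance_hof$assignments, "concordance_hof.tsv")
  }
  if (!is.null(run$mrm)) w(as_tibble(run$mrm), "mrm_ratios.tsv")
  p <- file.path(dir, "report.json")
  jsonlite::write_json(run$report, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}

#' @export
print.oxymito_run <- function(x, ...) {
  r <- x$report
  cat("<oxymito pipeline run>\n")
  cat(sprintf("  PSMs: %d in, %d retained (FDR cutoff %.3f)\n",
              r$n_input_psms, r$n_retained_psms, r$fdr_threshold))
  cat(sprintf("  quantifiable proteins: %d\n", r$n_quantifiable_proteins))
  cat(sprintf("  differential: %d LOF, %d HOF (%d unique, %d shared)\n",
              r$n_differential_lof, r$n_differential_hof,
              r$n_differential_unique, r$n_shared))
  if (!is.null(r$concordance_pct_lof)) {
    cat(sprintf("  protein-mRNA concordance: %g%% LOF, %g%% HOF\n",
                r$concordance_pct_lof, r$concordance_pct_hof))
  }
  invisible(x)
}
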