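#' Simulation configuration
#'
#' Parameterizes the synthetic-data generator that emulates the six-channel
#' isobaric-tag experiment (two control, two hypoxia-adapted LOF and two
#' hyperoxia-adapted HOF mitochondrial preparations) together with its
#' companion mRNA, MRM and stereology inputs. Defaults reproduce the study
#' conditions the pipeline was designed around: 718 quantified proteins of
#' which roughly 7.7% are differential in LOF and 10.4% in HOF with a shared
#' fraction of 0.13, absolute log2 effects between 0.8 and 2, small
#' multiplicative reporter noise, and a heavy-tailed spectral-count
#' distribution driven by a lognormal baseline abundance.
#'
#' @param n_proteins Number of target proteins to simulate.
#' @param frac_differential_lof,frac_differential_hof Fraction of proteins
#'   truly differential in each adapted group.
#' @param frac_shared Shared-effect fraction: number of proteins differential
#'   in both groups divided by the number of unique differential proteins.
#' @param effect_log2_range Interval of |log2 fold change| for true effects;
#'   lower bound must be positive.
#' @param noise_sigma Std dev (log2 scale) of multiplicative lognormal noise
#'   applied per PSM per channel.
#' @param replicate_sigma Std dev (log2 scale) of the per-protein,
#'   per-channel replicate effect emulating duplicate-preparation scatter.
#' @param psm_spread Std dev (log2 scale) of per-PSM baseline variation
#'   around the protein baseline.
#' @param psms_per_protein_mean Mean PSM count per protein.
#' @param psms_per_protein_min Hard minimum PSM count per protein (>= 1).
#' @param baseline_log2_mean,baseline_log2_sd Lognormal baseline abundance
#'   parameters (log2 scale); the heavy tail produces the spectral-count
#'   spread the abundance strata describe.
#' @param decoy_fraction Fraction of all PSM rows flagged as decoys.
#' @param labeled_fraction Fraction of target peptides carrying the tag.
#' @param shared_peptide_fraction Fraction of peptides mapping to two
#'   accessions (excluded from uniqueness counting downstream).
#' @param contaminant_fraction Fraction of proteins annotated to
#'   non-mitochondrial organelles.
#' @param injection_overlap Expected Jaccard overlap of peptide
#'   identifications between the two parallel injections.
#' @param mrna_concordance_prob Probability that a differential protein's
#'   mRNA fold change shares its sign.
#' @param mrna_coverage Fraction of proteins covered by the expression array.
#' @param category_weights Named fractions over the nine functional
#'   categories; must sum to 1.
#' @param purity Purity matrix used to forward-contaminate reporter signals.
#' @param design A [channel_design()].
#' @param seed Integer seed; all generator randomness derives from it.
#'
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_proteins = 50, seed = 1)
sim_config <- function(n_proteins = 718,
                       frac_differential_lof = 55 / 718,
                       frac_differential_hof = 75 / 718,
                       frac_shared = 0.13,
                       effect_log2_range = c(0.8, 2.0),
                       noise_sigma = 0.12,
                       replicate_sigma = 0.04,
                       psm_spread = 0.4,
                       psms_per_protein_mean = 12,
                       psms_per_protein_min = 2L,
                       baseline_log2_mean = 10,
                       baseline_log2_sd = 2,
                       decoy_fraction = 0.03,
                       labeled_fraction = 0.99,
                       shared_peptide_fraction = 0.02,
                       contaminant_fraction = 0.17,
                       injection_overlap = 0.78,
                       mrna_concordance_prob = 0.58,
                       mrna_coverage = 0.96,
                       category_weights = NULL,
                       purity = NULL,
                       design = channel_design(),
                       seed = 42L) {
  if (is.null(category_weights)) {
    category_weights <- c(
      respiratory_chain = 0.30, membrane_transporter = 0.16,
      carbohydrate_lipid_metabolism = 0.12, calcium_regulation = 0.09,
      peptide_amino_acid_metabolism = 0.07, oxidation_sensitive = 0.06,
      chaperone = 0.07, translation = 0.06, detoxification = 0.07
    )
  }
  if (is.null(purity)) purity <- purity_identity(design_samples(design))
  if (n_proteins < 1) abort("n_proteins must be positive")
  fracs <- c(frac_differential_lof, frac_differential_hof, frac_shared,
             decoy_fraction, labeled_fraction, shared_peptide_fraction,
             contaminant_fraction, injection_overlap, mrna_concordance_prob,
             mrna_coverage)
  if (any(fracs < 0 | fracs > 1)) abort("all fractions must lie in [0, 1]")
  if (abs(sum(category_weights) - 1) > 1e-9) {
    abort("category_weights must sum to 1")
  }
  if (length(effect_log2_range) != 2 || effect_log2_range[1] <= 0 ||
      diff(effect_log2_range) < 0) {
    abort("effect_log2_range must be an interval with positive lower bound")
  }
  if (psms_per_protein_min < 1 ||
      psms_per_protein_mean < psms_per_protein_min) {
    abort("psms_per_protein_mean must be >= psms_per_protein_min >= 1")
  }
  validate_purity(purity)
  structure(
    list(
      n_proteins = as.integer(n_proteins),
      frac_differential_lof = frac_differential_lof,
      frac_differential_hof = frac_differential_hof,
      frac_shared = frac_shared,
      effect_log2_range = effect_log2_range,
      noise_sigma = noise_sigma,
      replicate_sigma = replicate_sigma,
      psm_spread = psm_spread,
      psms_per_protein_mean = psms_per_protein_mean,
      psms_per_protein_min = as.integer(psms_per_protein_min),
      baseline_log2_mean = baseline_log2_mean,
      baseline_log2_sd = baseline_log2_sd,
      decoy_fraction = decoy_fraction,
      labeled_fraction = labeled_fraction,
      shared_peptide_fraction = shared_peptide_fraction,
      contaminant_fraction = contaminant_fraction,
      injection_overlap = injection_overlap,
      mrna_concordance_prob = mrna_concordance_prob,
      mrna_coverage = mrna_coverage,
      category_weights = category_weights,
      purity = purity,
      design = design,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Derive a module-local seed from the master seed, kept within 32-bit range.
.sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 131L + offset) %% 2147480000)
}

# Run code under a temporary RNG state, restoring the caller's stream.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.random_peptide <- function(n, min_len = 8, max_len = 20) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  lens <- sample(min_len:max_len, n, replace = TRUE)
  vapply(lens, function(l) paste(sample(aa, l, replace = TRUE), collapse = ""),
         character(1))
}

#' Simulate ground truth for a protein cohort
#'
#' Draws per-protein baseline abundance, length, functional category,
#' organelle annotation, and signed log2 effects for the LOF and HOF groups.
#' Differential counts equal `round(frac * n_proteins)` exactly; the shared
#' set (differential in both groups) is sized so that
#' `shared / unique_differential = frac_shared` as closely as the counts
#' allow. Effect signs are drawn independently per group.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per protein: `protein_id`, `baseline_log2`,
#'   `length`, `category`, `organelle`, `true_log2fc_lof`, `true_log2fc_hof`,
#'   `is_differential_lof`, `is_differential_hof`.
#' @export
sim_ground_truth <- function(config) {
  n <- config$n_proteins
  .with_seed(.sub_seed(config$seed, 1L), {
    ids <- sprintf("PROT%04d", seq_len(n))
    baseline <- rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)
    len <- pmax(50L, pmin(9000L, round(2^rnorm(n, log2(420), 0.9))))
    category <- sample(names(config$category_weights), n, replace = TRUE,
                       prob = config$category_weights)
    organelle <- ifelse(
      runif(n) < config$contaminant_fraction,
      sample(c("nucleus", "extracellular", "endoplasmic reticulum",
               "lipid particle", "cytoplasm", "membrane"),
             n, replace = TRUE),
      "mitochondria"
    )

    n_lof <- round(config$frac_differential_lof * n)
    n_hof <- round(config$frac_differential_hof * n)
    # shared/unique = frac_shared  =>  shared = frac*(n_lof+n_hof)/(1+frac)
    n_shared <- min(n_lof, n_hof,
                    round(config$frac_shared * (n_lof + n_hof) /
                            (1 + config$frac_shared)))
    idx <- sample.int(n)
    shared <- idx[seq_len(n_shared)]
    lof_only <- idx[n_shared + seq_len(n_lof - n_shared)]
    hof_only <- idx[n_shared + (n_lof - n_shared) + seq_len(n_hof - n_shared)]
    lof_set <- c(shared, lof_only)
    hof_set <- c(shared, hof_only)

    draw_effect <- function(k) {
      sample(c(-1, 1), k, replace = TRUE) *
        runif(k, config$effect_log2_range[1], config$effect_log2_range[2])
    }
    fc_lof <- numeric(n)
    fc_hof <- numeric(n)
    fc_lof[lof_set] <- draw_effect(length(lof_set))
    fc_hof[hof_set] <- draw_effect(length(hof_set))

    tibble(
      protein_id = ids,
      baseline_log2 = baseline,
      length = len,
      category = category,
      organelle = organelle,
      true_log2fc_lof = fc_lof,
      true_log2fc_hof = fc_hof,
      is_differential_lof = fc_lof != 0,
      is_differential_hof = fc_hof != 0
    )
  })
}

#' Simulate a PSM report table with known ground truth
#'
#' Generates peptide-spectrum matches for every protein of a simulated
#' cohort. Per protein, the PSM count is `psms_per_protein_min` plus a
#' Poisson draw whose rate scales with the protein's baseline abundance, so
#' spectral counts inherit the lognormal heavy tail. Each PSM carries
#' reporter intensities for the six designed channels built as
#' `baseline * 2^(channel effect) * 2^(replicate effect) * noise`, then
#' forward-contaminated by the configured purity matrix. Decoy PSMs are
#' appended with scores drawn from a low distribution overlapping the weak
#' tail of the targets. Identical config and seed give identical tables.
#'
#' @param config A [sim_config()].
#' @param truth Optional pre-computed [sim_ground_truth()] tibble; generated
#'   from `config` when `NULL`.
#' @return A list with elements `psms` (tibble of PSM records, one intensity
#'   column per designed sample) and `truth`.
#' @export
#' @examples
#' sim <- sim_psm_table(sim_config(n_proteins = 20, seed = 7))
#' dplyr::glimpse(sim$psms)
sim_psm_table <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(truth)) truth <- sim_ground_truth(config)
  samples <- design_samples(config$design)
  n <- config$n_proteins

  psms <- .with_seed(.sub_seed(config$seed, 2L), {
    # PSM counts: shifted Poisson with abundance-proportional rate
    abundance <- 2^truth$baseline_log2
    w <- abundance / mean(abundance)
    extra_mean <- max(config$psms_per_protein_mean - config$psms_per_protein_min, 0)
    n_psm <- config$psms_per_protein_min + rpois(n, extra_mean * w)

    protein_prob <- pmin(1, rbeta(n, 14, 0.9))

    per_protein <- purrr::map(seq_len(n), function(i) {
      k <- n_psm[i]
      n_pep <- 1L + rbinom(1L, max(k - 1L, 0L), 0.5)
      pep_seq <- .random_peptide(n_pep)
      pep_labeled <- runif(n_pep) < config$labeled_fraction
      pep_shared <- runif(n_pep) < config$shared_peptide_fraction
      # injection status: both with prob = target Jaccard overlap
      u <- runif(n_pep)
      pep_status <- ifelse(u < config$injection_overlap, "both",
                           ifelse(u < config$injection_overlap +
                                    (1 - config$injection_overlap) / 2,
                                  "inj1", "inj2"))
      # assign PSMs to peptides: each peptide used at least once
      pep_of <- c(seq_len(n_pep),
                  if (k > n_pep) sample.int(n_pep, k - n_pep, replace = TRUE))
      # peptides seen in both injections need at least two spectra
      short_both <- which(pep_status == "both" &
                            tabulate(pep_of, n_pep) < 2L)
      pep_of <- c(pep_of, short_both)
      k <- length(pep_of)
      inj <- integer(k)
      for (p in seq_len(n_pep)) {
        rows <- which(pep_of == p)
        inj[rows] <- switch(pep_status[p],
          inj1 = 1L,
          inj2 = 2L,
          both = {
            x <- sample.int(2L, length(rows), replace = TRUE)
            x[1] <- 1L; if (length(rows) > 1) x[2] <- 2L
            x
          })
      }
      prot_ids <- rep(truth$protein_id[i], n_pep)
      if (any(pep_shared) && n > 1) {
        other <- sample(setdiff(seq_len(n), i), sum(pep_shared),
                        replace = TRUE)
        prot_ids[pep_shared] <- paste(truth$protein_id[i],
                                      truth$protein_id[other], sep = ";")
      }
      tibble(
        protein_id = truth$protein_id[i],
        protein_ids = prot_ids[pep_of],
        peptide = pep_seq[pep_of],
        is_labeled = pep_labeled[pep_of],
        injection = paste0("inj", inj),
        peptide_prob = pmin(1, rbeta(k, 9, 1)),
        protein_prob = protein_prob[i]
      )
    })
    tab <- dplyr::bind_rows(per_protein)
    tab$spectrum_id <- sprintf("SPEC%06d", seq_len(nrow(tab)))
    tab$is_decoy <- FALSE

    # channel intensities (log2 forward model), then purity contamination
    effect <- matrix(0, nrow(tab), length(samples),
                     dimnames = list(NULL, samples))
    i_of <- match(tab$protein_id, truth$protein_id)
    effect[, c("LOF1", "LOF2")] <- truth$true_log2fc_lof[i_of]
    effect[, c("HOF1", "HOF2")] <- truth$true_log2fc_hof[i_of]
    rep_eff <- matrix(rnorm(n * length(samples), 0, config$replicate_sigma),
                      n, length(samples))
    psm_base <- truth$baseline_log2[i_of] + rnorm(nrow(tab), 0, config$psm_spread)
    noise <- matrix(rnorm(nrow(tab) * length(samples), 0, config$noise_sigma),
                    nrow(tab), length(samples))
    log2_true <- psm_base + effect + rep_eff[i_of, , drop = FALSE] + noise
    observed <- 2^log2_true %*% t(config$purity)
    colnames(observed) <- samples
    tab <- dplyr::bind_cols(tab, as_tibble(observed))

    # decoy PSMs with low, target-overlapping scores
    n_decoy <- round(config$decoy_fraction / (1 - config$decoy_fraction) *
                       nrow(tab))
    if (n_decoy > 0) {
      dec <- tibble(
        protein_id = sprintf("DECOY%04d", seq_len(n_decoy)),
        protein_ids = sprintf("DECOY%04d", seq_len(n_decoy)),
        peptide = .random_peptide(n_decoy),
        is_labeled = TRUE,
        injection = paste0("inj", sample.int(2L, n_decoy, replace = TRUE)),
        peptide_prob = pmin(1, rbeta(n_decoy, 1.6, 4)),
        protein_prob = pmin(1, rbeta(n_decoy, 1.6, 4)),
        spectrum_id = sprintf("DSPEC%05d", seq_len(n_decoy)),
        is_decoy = TRUE
      )
      dec_int <- matrix(2^rnorm(n_decoy * length(samples), 6, 1),
                        n_decoy, length(samples),
                        dimnames = list(NULL, samples))
      dec <- dplyr::bind_cols(dec, as_tibble(dec_int))
      tab <- dplyr::bind_rows(tab, dec)
    }
    select(tab, "spectrum_id", "peptide", "protein_ids", "protein_id",
           "peptide_prob", "protein_prob", "is_decoy", "is_labeled",
           "injection", dplyr::all_of(samples))
  })
  list(psms = psms, truth = truth)
}

#' Simulate an expression-array mRNA fold-change table
#'
#' For each covered protein of a simulated cohort, emits a per-group mRNA
#' log2 fold change. Differential proteins get an mRNA sign matching their
#' true protein sign with probability `concordance_prob`; non-differential
#' proteins get small zero-centred values. A `1 - coverage` fraction of
#' proteins has no record, emulating array non-coverage.
#'
#' @param truth A [sim_ground_truth()] tibble.
#' @param concordance_prob Sign-concordance probability in [0, 1].
#' @param coverage Fraction of proteins represented on the array.
#' @param magnitude_range Interval of |mRNA log2 fold change| for
#'   differential proteins.
#' @param null_sd Std dev of mRNA log2 fold changes of non-differential
#'   proteins.
#' @param seed Integer seed.
#' @return A tibble: `gene_id`, `group` (LOF/HOF), `mrna_log2fc`.
#' @export
sim_mrna_table <- function(truth, concordance_prob = 0.58, coverage = 0.96,
                           magnitude_range = c(0.3, 2.0), null_sd = 0.2,
                           seed = 42L) {
  if (nrow(truth) == 0) abort("truth must be non-empty")
  if (concordance_prob < 0 || concordance_prob > 1) {
    abort("concordance_prob must lie in [0, 1]")
  }
  .with_seed(.sub_seed(seed, 3L), {
    covered <- runif(nrow(truth)) < coverage
    per_group <- function(group, fc) {
      n <- nrow(truth)
      mag <- runif(n, magnitude_range[1], magnitude_range[2])
      concord <- runif(n) < concordance_prob
      sign_mrna <- ifelse(concord, sign(fc), -sign(fc))
      val <- ifelse(fc != 0, sign_mrna * mag, rnorm(n, 0, null_sd))
      tibble(gene_id = truth$protein_id, group = group, mrna_log2fc = val,
             covered = covered)
    }
    dplyr::bind_rows(
      per_group("LOF", truth$true_log2fc_lof),
      per_group("HOF", truth$true_log2fc_hof)
    ) %>%
      filter(.data$covered) %>%
      select(-"covered")
  })
}

#' Simulate an MRM transition report
#'
#' Emits transition areas for a set of target proteins across control, LOF
#' and HOF samples, with two biological replicates per sample each measured
#' in technical triplicate. Areas are proportional to the group's true
#' abundance (from `truth`) times multiplicative lognormal noise; a
#' configurable fraction of transitions is drawn with S/N below 10 so the
#' downstream quality filter has work to do.
#'
#' @param targets Character vector of protein ids (must appear in `truth`).
#' @param truth A [sim_ground_truth()] tibble.
#' @param transitions_per_peptide Transitions monitored per peptide.
#' @param peptides_per_target Peptides monitored per protein.
#' @param noise_sigma Std dev (log2) of area noise.
#' @param frac_below_sn Fraction of transitions with S/N drawn below 10.
#' @param seed Integer seed.
#' @return A tibble of transition records: `protein_id`, `peptide`,
#'   `transition_id`, `sample`, `bio_replicate`, `tech_replicate`, `area`,
#'   `signal_to_noise`.
#' @export
sim_mrm_table <- function(targets, truth, transitions_per_peptide = 3L,
                          peptides_per_target = 1L, noise_sigma = 0.1,
                          frac_below_sn = 0.1, seed = 42L) {
  if (length(targets) == 0) abort("targets must be non-empty")
  if (!all(targets %in% truth$protein_id)) {
    abort("all targets must appear in truth")
  }
  .with_seed(.sub_seed(seed, 4L), {
    grid <- tidyr::expand_grid(
      protein_id = targets,
      pep_idx = seq_len(peptides_per_target),
      transition = seq_len(transitions_per_peptide),
      sample = c("C", "LOF", "HOF"),
      bio_replicate = 1:2,
      tech_replicate = 1:3
    )
    i_of <- match(grid$protein_id, truth$protein_id)
    effect <- dplyr::case_when(
      grid$sample == "LOF" ~ truth$true_log2fc_lof[i_of],
      grid$sample == "HOF" ~ truth$true_log2fc_hof[i_of],
      .default = 0
    )
    # per protein/peptide/transition response factor, shared across samples
    key <- paste(grid$protein_id, grid$pep_idx, grid$transition)
    ukey <- unique(key)
    resp <- setNames(2^rnorm(length(ukey), 14, 1), ukey)
    pep_seq <- setNames(.random_peptide(length(targets) * peptides_per_target,
                                        min_len = 7, max_len = 25),
                        as.vector(outer(targets, seq_len(peptides_per_target),
                                        paste, sep = ".")))
    area <- resp[key] * 2^effect *
      2^rnorm(nrow(grid), 0, noise_sigma)
    low <- runif(nrow(grid)) < frac_below_sn
    sn <- ifelse(low, runif(nrow(grid), 1, 10), 2^rnorm(nrow(grid), 5.3, 0.8))
    tibble(
      protein_id = grid$protein_id,
      peptide = pep_seq[paste(grid$protein_id, grid$pep_idx, sep = ".")],
      transition_id = sprintf("%s.t%d", grid$protein_id,
                              (grid$pep_idx - 1L) * transitions_per_peptide +
                                grid$transition),
      sample = grid$sample,
      bio_replicate = grid$bio_replicate,
      tech_replicate = grid$tech_replicate,
      area = unname(area),
      signal_to_noise = sn
    )
  })
}

# clamped box blur along rows of a matrix
.box_blur_rows <- function(m, r) {
  n <- ncol(m)
  cs <- cbind(0, t(apply(m, 1, cumsum)))
  hi <- pmin(seq_len(n) + r, n)
  lo <- pmax(seq_len(n) - r, 1L)
  (cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]) /
    rep(hi - lo + 1L, each = nrow(m))
}

#' Simulate a labelled organelle mask phantom
#'
#' Builds a smooth random field, thresholds it at the quantile that yields
#' exactly the requested mitochondrial pixel-area fraction among
#' non-excluded pixels, and optionally excludes a second smooth region
#' (e.g. extracellular space). The realized fraction is within 1% of
#' `true_fraction` by construction.
#'
#' @param width,height Mask dimensions in pixels.
#' @param true_fraction Target mitochondrion area fraction of the
#'   non-excluded area, in [0, 1].
#' @param excluded_fraction Fraction of pixels labelled excluded.
#' @param smoothness Box-blur radius controlling blob size, in pixels.
#' @param seed Integer seed.
#' @return An integer matrix (`height` x `width`) of class `labeled_mask`
#'   with values 0 = excluded, 1 = cytoplasm, 2 = mitochondrion, and
#'   attribute `true_fraction`.
#' @export
#' @examples
#' m <- sim_labeled_mask(64, 64, 0.3, seed = 1)
#' mean(m[m != 0] == 2)
sim_labeled_mask <- function(width, height, true_fraction,
                             excluded_fraction = 0, smoothness = 8L,
                             seed = 42L) {
  if (width < 2 || height < 2) abort("mask dimensions are degenerate")
  if (true_fraction < 0 || true_fraction > 1) {
    abort("true_fraction must lie in [0, 1]")
  }
  .with_seed(.sub_seed(seed, 5L), {
    field <- matrix(rnorm(width * height), height, width)
    for (i in 1:2) {
      field <- .box_blur_rows(field, smoothness)
      field <- t(.box_blur_rows(t(field), smoothness))
    }
    mask <- matrix(1L, height, width)
    if (excluded_fraction > 0) {
      exc_field <- matrix(rnorm(width * height), height, width)
      exc_field <- t(.box_blur_rows(t(.box_blur_rows(exc_field, smoothness)),
                                    smoothness))
      n_exc <- round(excluded_fraction * length(mask))
      mask[order(exc_field, decreasing = TRUE)[seq_len(n_exc)]] <- 0L
    }
    open <- which(mask != 0L)
    n_mito <- round(true_fraction * length(open))
    mito <- open[order(field[open], decreasing = TRUE)[seq_len(n_mito)]]
    mask[mito] <- 2L
    structure(mask, class = c("labeled_mask", "matrix", "array"),
              true_fraction = true_fraction)
  })
}

#' Write a labelled mask as an 8-bit PNG
#'
#' Label values are stored as 8-bit grey levels 0, 1, 2 (divided by 255 in
#' the PNG); [read_labeled_mask()] restores them.
#'
#' @param mask A [sim_labeled_mask()] matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_labeled_mask <- function(mask, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort("the png package is required to write masks")
  }
  png::writePNG(unclass(mask) / 255, path)
  invisible(path)
}

#' @rdname write_labeled_mask
#' @export
read_labeled_mask <- function(path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort("the png package is required to read masks")
  }
  m <- round(png::readPNG(path) * 255)
  storage.mode(m) <- "integer"
  structure(m, class = c("labeled_mask", "matrix", "array"))
}
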