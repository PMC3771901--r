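#' Count grid intercepts on a labelled mask
#'
#' Overlays an evenly spaced rows x cols point grid (default 9 x 13, the
#' manual-counting layout) with nodes at cell centers and reads each node's
#' label from the mask.
#'
#' @param mask A [sim_labeled_mask()]-style integer matrix (0 excluded,
#'   1 cytoplasm, 2 mitochondrion).
#' @param rows,cols Grid dimensions.
#' @return A one-row tibble: `n_mito`, `n_cyto`, `n_excluded`, `rows`,
#'   `cols` (their sum always equals `rows * cols`).
#' @export
#' @examples
#' m <- sim_labeled_mask(64, 64, 0.4, seed = 2)
#' overlay_grid_count(m)
overlay_grid_count <- function(mask, rows = 9L, cols = 13L) {
  h <- nrow(mask)
  w <- ncol(mask)
  if (rows > h || cols > w) abort("grid exceeds mask dimensions")
  ri <- ceiling((seq_len(rows) - 0.5) * h / rows)
  ci <- ceiling((seq_len(cols) - 0.5) * w / cols)
  labels <- mask[ri, ci, drop = FALSE]
  tibble(
    n_mito = sum(labels == 2L),
    n_cyto = sum(labels == 1L),
    n_excluded = sum(labels == 0L),
    rows = as.integer(rows),
    cols = as.integer(cols)
  )
}

#' Mitochondrial volume fraction from intercept counts
#'
#' `100 * n_mito / (n_mito + n_cyto)`; excluded intercepts enter neither
#' numerator nor denominator.
#'
#' @param counts Tibble with `n_mito` and `n_cyto` (one or more rows).
#' @return Numeric vector of percentages.
#' @export
#' @examples
#' volume_fraction(tibble::tibble(n_mito = 27, n_cyto = 90))  # 23.1
volume_fraction <- function(counts) {
  denom <- counts$n_mito + counts$n_cyto
  if (any(denom == 0)) abort("no cytoplasm or mitochondrion intercepts")
  100 * counts$n_mito / denom
}

#' Summarize per-image volume fractions by group
#'
#' Mean and SEM (sd / sqrt(n)) per group and a pairwise two-sided test of
#' each group against the control (two-sample t-test by default; the
#' Mann-Whitney alternative is available for small or skewed samples).
#'
#' @param fractions Tibble with `image_id`, `group`, `fraction` (percent).
#' @param control Control group label.
#' @param test `"t"` or `"wilcox"`.
#' @return Tibble `group`, `n`, `mean`, `sem`, `p_vs_control` (`NA` for the
#'   control row).
#' @export
summarize_stereology <- function(fractions, control = "C",
                                 test = c("t", "wilcox")) {
  test <- match.arg(test)
  if (any(table(fractions$group) < 2)) {
    abort("each group needs at least 2 images")
  }
  ctrl <- fractions$fraction[fractions$group == control]
  fractions %>%
    group_by(.data$group) %>%
    summarise(
      n = n(),
      mean = mean(.data$fraction),
      sem = sd(.data$fraction) / sqrt(n()),
      .groups = "drop"
    ) %>%
    mutate(p_vs_control = purrr::map_dbl(.data$group, function(g) {
      if (g == control) return(NA_real_)
      x <- fractions$fraction[fractions$group == g]
      if (sd(x) == 0 && sd(ctrl) == 0) {
        return(if (isTRUE(all.equal(mean(x), mean(ctrl)))) 1 else 1e-12)
      }
      if (test == "t") t.test(x, ctrl)$p.value
      else suppressWarnings(wilcox.test(x, ctrl)$p.value)
    }))
}

# 8-connected component labelling by iterative minimum-label propagation
.label_components <- function(binary) {
  h <- nrow(binary)
  w <- ncol(binary)
  lab <- matrix(Inf, h, w)
  lab[binary] <- seq_len(sum(binary))
  shift <- function(m, dr, dc) {
    out <- matrix(Inf, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
    out
  }
  repeat {
    new <- lab
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      new <- pmin(new, shift(lab, dr, dc))
    }
    new[!binary] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  lab
}

#' Mitochondrial object density of a labelled mask
#'
#' Counts 8-connected mitochondrion (label 2) regions and divides by the
#' non-excluded mask area, optionally converted by a physical pixel size.
#'
#' @param mask Labelled mask matrix.
#' @param pixel_size Optional side length of a pixel in physical units;
#'   densities are then per unit area instead of per pixel.
#' @return A list: `n_objects`, `area` (non-excluded), `density`.
#' @export
mito_object_density <- function(mask, pixel_size = NULL) {
  binary <- unclass(mask) == 2L
  lab <- .label_components(binary)
  n_obj <- length(unique(lab[is.finite(lab)]))
  area_px <- sum(unclass(mask) != 0L)
  area <- if (is.null(pixel_size)) area_px else area_px * pixel_size^2
  list(n_objects = n_obj, area = area, density = n_obj / area)
}
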