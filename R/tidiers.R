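#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a differential-call result
#'
#' One row per protein x replicate-cross ratio pair, joined with the call.
#'
#' @param x A `diff_calls` object from [call_differential()].
#' @param ... Unused.
#' @return A tibble of ratio tests with `direction` attached.
#' @export
tidy.diff_calls <- function(x, ...) {
  tests <- attr(x, "tests")
  if (is.null(tests)) return(as_tibble(x))
  tests %>%
    left_join(as_tibble(x) %>% select("protein_id", "direction", "flag"),
              by = "protein_id")
}

#' Glance at a differential-call result
#'
#' @param x A `diff_calls` object.
#' @param ... Unused.
#' @return A one-row tibble: `group`, `n_proteins`, `n_up`, `n_down`,
#'   `n_differential`, `n_untestable`.
#' @export
glance.diff_calls <- function(x, ...) {
  tibble(
    group = unique(x$group),
    n_proteins = nrow(x),
    n_up = sum(x$direction == "up"),
    n_down = sum(x$direction == "down"),
    n_differential = sum(x$direction != "none"),
    n_untestable = sum(x$flag %in% c("untestable", "undefined_ratio"))
  )
}

#' Tidy an MRM result
#' @param x An `mrm_result` object.
#' @param ... Unused.
#' @return The underlying tibble.
#' @export
tidy.mrm_result <- function(x, ...) as_tibble(x)

#' Glance at an MRM result
#' @param x An `mrm_result` object.
#' @param ... Unused.
#' @return One-row tibble with counts of targets and significant calls per
#'   sample.
#' @export
glance.mrm_result <- function(x, ...) {
  non_ctrl <- x %>% filter(!is.na(.data$p_value))
  tibble(
    n_targets = dplyr::n_distinct(x$protein_id),
    n_significant = sum(non_ctrl$p_value < 0.05, na.rm = TRUE)
  )
}
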