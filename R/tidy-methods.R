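#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an accuracy evaluation
#'
#' @param x a `bs_accuracy` from [evaluate_accuracy()].
#' @param ... unused.
#' @return a tibble with one row per (stratum, outcome) and columns `stratum`,
#'   `outcome`, `n`, `fraction`.
#' @export
tidy.bs_accuracy <- function(x, ...) {
  s <- x$summary
  tidyr::pivot_longer(s, c("n_correct", "n_incorrect", "n_discarded"),
                      names_to = "outcome", names_prefix = "n_",
                      values_to = "n") |>
    dplyr::mutate(fraction = .data$n / .data$n_total) |>
    dplyr::select("stratum", "outcome", "n", "fraction")
}

#' Summarise an accuracy evaluation in one row
#'
#' @param x a `bs_accuracy`.
#' @param ... unused.
#' @return a one-row tibble: totals plus percent correct/incorrect/discarded
#'   for the unfiltered and MAPQ-thresholded strata.
#' @export
glance.bs_accuracy <- function(x, ...) {
  s <- x$summary
  pct <- function(i, col) 100 * s[[col]][i] / s$n_total[i]
  tibble(
    n_total = s$n_total[1L],
    mapq_threshold = x$threshold,
    correct_pct = pct(1L, "n_correct"),
    incorrect_pct = pct(1L, "n_incorrect"),
    discarded_pct = pct(1L, "n_discarded"),
    correct_pct_mapq = pct(2L, "n_correct"),
    incorrect_pct_mapq = pct(2L, "n_incorrect"),
    discarded_pct_mapq = pct(2L, "n_discarded")
  )
}

#' Plot per-context methylation level distributions
#'
#' @param object a `bs_counts` tibble.
#' @param ... unused.
#' @return a ggplot histogram of per-site methylation percentages, faceted by
#'   context.
#' @export
autoplot.bs_counts <- function(object, ...) {
  df <- meth_percent(as_tibble(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pct)) +
    ggplot2::geom_histogram(bins = 40, boundary = 0) +
    ggplot2::facet_wrap(~context, scales = "free_y") +
    ggplot2::labs(x = "% methylation", y = "cytosines") +
    ggplot2::theme_bw()
}
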