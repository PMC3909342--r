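#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a one-way ANOVA
#'
#' @param x An `anova_oneway` object.
#' @param ... Unused.
#' @return One-row-per-term tibble in the usual ANOVA-table layout.
#' @export
tidy.anova_oneway <- function(x, ...) {
  tibble::tibble(
    term = c("between", "within"),
    df = c(x$df_between, x$df_within),
    sumsq = c(x$ss_between, x$ss_within),
    meansq = c(x$ss_between / x$df_between, x$ss_within / x$df_within),
    statistic = c(x$F, NA_real_),
    p.value = c(x$p, NA_real_)
  )
}

#' @rdname tidy.anova_oneway
#' @export
glance.anova_oneway <- function(x, ...) {
  tibble::tibble(
    statistic = x$F, df_between = x$df_between, df_within = x$df_within,
    p.value = x$p, n_groups = length(x$group_labels), n_total = sum(x$n),
    flag = x$flag
  )
}

#' Tidy Tukey HSD results
#'
#' @param x A `tukey_hsd` object.
#' @param ... Unused.
#' @return Tibble with one row per pairwise comparison (`contrast`,
#'   `estimate`, `conf.low`, `conf.high`, `adj.p.value`).
#' @export
tidy.tukey_hsd <- function(x, ...) {
  tibble::tibble(
    contrast = paste(x$group2, x$group1, sep = "-"),
    estimate = x$mean_diff,
    conf.low = x$ci_low,
    conf.high = x$ci_high,
    adj.p.value = x$p_adj
  )
}

#' Tidy a cohort analysis
#'
#' @param x A `cohort_analysis` object.
#' @param ... Unused.
#' @return The summary tibble (one row per diagnostic group x structure x
#'   DVH point x modality).
#' @export
tidy.cohort_analysis <- function(x, ...) x$summaries

#' @rdname tidy.cohort_analysis
#' @export
glance.cohort_analysis <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$summaries),
    n_tests = nrow(x$anova),
    n_significant = sum(x$anova$significant),
    alpha = x$alpha
  )
}
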