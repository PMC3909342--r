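#' Percentage difference with respect to CT
#'
#' The study's basic comparison quantity: 100 * (MRI - CT) / CT, the
#' per-patient percentage deviation of an MRI-based DVH-point value from its
#' CT reference. Vectorised.
#'
#' @param mri_value,ct_value Numeric vectors; `ct_value` must be nonzero.
#' @return Percentage differences.
#' @export
#' @examples
#' percent_diff(102, 100)  # 2
percent_diff <- function(mri_value, ct_value) {
  if (any(ct_value == 0)) {
    stop("CT value of 0 encountered: percentage difference is undefined (degenerate DVH point)",
         call. = FALSE)
  }
  100 * (mri_value - ct_value) / ct_value
}

#' Per-patient percentage differences for a cohort table
#'
#' Pivots a long cohort table (one row per patient x structure x DVH point x
#' modality) into percentage differences of every MRI variant with respect
#' to CT.
#'
#' @param cohort Tibble with columns `patient_id`, `diagnosis`, `structure`,
#'   `dvh_point`, `modality`, `value`; one `CT` row per key.
#' @return Tibble with columns `patient_id`, `diagnosis`, `structure`,
#'   `dvh_point`, `modality` (the MRI variant), `pct_diff`.
#' @export
cohort_percent_diffs <- function(cohort) {
  stopifnot(all(c("patient_id", "structure", "dvh_point", "modality", "value") %in% names(cohort)))
  if (!"diagnosis" %in% names(cohort)) cohort$diagnosis <- NA_character_
  ct <- dplyr::filter(cohort, .data$modality == "CT")
  if (nrow(ct) == 0L) stop("cohort table contains no CT rows", call. = FALSE)
  mri <- dplyr::filter(cohort, .data$modality != "CT")
  joined <- dplyr::inner_join(
    mri,
    dplyr::select(ct, "patient_id", "structure", "dvh_point", ct_value = "value"),
    by = c("patient_id", "structure", "dvh_point")
  )
  missing_ct <- dplyr::anti_join(
    mri, ct, by = c("patient_id", "structure", "dvh_point")
  )
  if (nrow(missing_ct) > 0L) {
    stop(sprintf("%d rows have no matching CT value (first: patient '%s', %s %s)",
                 nrow(missing_ct), missing_ct$patient_id[1],
                 missing_ct$structure[1], missing_ct$dvh_point[1]), call. = FALSE)
  }
  joined |>
    dplyr::mutate(pct_diff = percent_diff(.data$value, .data$ct_value)) |>
    dplyr::select("patient_id", "diagnosis", "structure", "dvh_point",
                  "modality", "pct_diff")
}

#' Summarise percentage differences as mean +/- 2 SD
#'
#' For each diagnostic group x structure x DVH point x MRI variant, the
#' sample mean and SD (n - 1 denominator) of the per-patient percentage
#' differences, and the half-width of the conservative interval mean +/- 2 SD.
#' That interval approximates the range containing 95% of individual
#' patients' deviations; it is a population (tolerance-type) interval, not a
#' confidence interval of the mean. An exact 95% CI of the mean
#' (t-based) is also reported for comparison.
#'
#' @param diffs Output of [cohort_percent_diffs()], or any tibble with a
#'   `pct_diff` column and the grouping columns.
#' @param by Grouping columns.
#' @return Tibble with `n`, `mean_pct`, `sd_pct`, `half_width_2sd`,
#'   `ci_mean_low`, `ci_mean_high`, and a formatted `label` such as
#'   `"1.3 ± 1.4"`.
#' @export
summarize_diffs <- function(diffs,
                            by = c("diagnosis", "structure", "dvh_point", "modality")) {
  by <- intersect(by, names(diffs))
  out <- diffs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_pct = mean(.data$pct_diff),
      sd_pct = stats::sd(.data$pct_diff),
      .groups = "drop"
    )
  if (any(out$n < 2L)) {
    stop("each summary cell needs at least 2 patients for a defined SD", call. = FALSE)
  }
  out |>
    dplyr::mutate(
      half_width_2sd = 2 * .data$sd_pct,
      ci_mean_low = .data$mean_pct -
        stats::qt(0.975, .data$n - 1) * .data$sd_pct / sqrt(.data$n),
      ci_mean_high = .data$mean_pct +
        stats::qt(0.975, .data$n - 1) * .data$sd_pct / sqrt(.data$n),
      label = format_pm(.data$mean_pct, .data$half_width_2sd)
    )
}

#' Render "mean plus-minus half-width" strings
#'
#' One-decimal rendering used in commissioning reports, e.g. `"1.3 ± 1.4"`.
#'
#' @param mean,half_width Numeric vectors.
#' @param digits Decimal places (default 1).
#' @return Character vector.
#' @export
format_pm <- function(mean, half_width, digits = 1) {
  sprintf("%.*f ± %.*f", digits, round(mean, digits), digits, round(half_width, digits))
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA computed from the between/within
#' sum-of-squares decomposition: F = MSB/MSW with (k - 1, N - k) degrees of
#' freedom and a p-value from the F distribution. Implemented directly from
#' the decomposition so that the arithmetic is transparent and testable; it
#' agrees with `stats::aov` to numerical precision.
#'
#' @param groups A named list of numeric vectors (one per group), or a data
#'   frame with `value` and `group` columns.
#' @return An `anova_oneway` object: list with `F`, `df_between`,
#'   `df_within`, `p`, `ss_between`, `ss_within`, `group_labels`, `n`,
#'   `flag` (`"ok"`, `"zero_within_variance"`, or `"all_identical"`).
#' @export
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))  # F = 3
one_way_anova <- function(groups) {
  groups <- as_group_list(groups)
  k <- length(groups)
  ns <- lengths(groups)
  if (k < 2L) stop("at least two groups are required", call. = FALSE)
  if (any(ns < 2L)) stop("every group needs at least two observations", call. = FALSE)
  N <- sum(ns)
  all_values <- unlist(groups, use.names = FALSE)
  grand <- mean(all_values)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(seq_len(k), function(i) sum((groups[[i]] - means[i])^2), numeric(1)))
  dfb <- k - 1L
  dfw <- N - k
  flag <- "ok"
  if (ssw == 0 && ssb == 0) {
    flag <- "all_identical"
    Fstat <- NaN
    p <- NaN
  } else if (ssw == 0) {
    flag <- "zero_within_variance"
    Fstat <- Inf
    p <- 0
  } else {
    Fstat <- (ssb / dfb) / (ssw / dfw)
    p <- stats::pf(Fstat, dfb, dfw, lower.tail = FALSE)
  }
  structure(
    list(F = Fstat, df_between = dfb, df_within = dfw, p = p,
         ss_between = ssb, ss_within = ssw,
         group_labels = names(groups), n = ns, flag = flag),
    class = "anova_oneway"
  )
}

as_group_list <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("value", "group") %in% names(groups)))
    groups <- split(groups$value, groups$group)
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  lapply(groups, as.numeric)
}

#' Tukey HSD pairwise comparisons
#'
#' All-pairs comparison of group means after a one-way ANOVA, controlling
#' the family-wise error rate via the studentized-range distribution.
#' Unequal group sizes are handled by the Tukey--Kramer standard error
#' sqrt(MSW/2 * (1/n_i + 1/n_j)). Simultaneous confidence intervals use the
#' studentized-range quantile at the requested confidence level.
#'
#' @param groups As for [one_way_anova()].
#' @param conf_level Simultaneous confidence level (default 0.95).
#' @return A `tukey_hsd` tibble: one row per pair with `mean_diff`,
#'   `ci_low`, `ci_high`, `p_adj`.
#' @export
tukey_hsd <- function(groups, conf_level = 0.95) {
  groups <- as_group_list(groups)
  an <- one_way_anova(groups)
  if (an$flag != "ok") {
    stop("Tukey HSD undefined: ", an$flag, call. = FALSE)
  }
  msw <- an$ss_within / an$df_within
  means <- vapply(groups, mean, numeric(1))
  ns <- lengths(groups)
  k <- length(groups)
  pairs <- utils::combn(k, 2)
  qcrit <- stats::qtukey(conf_level, nmeans = k, df = an$df_within)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    diff <- unname(means[i2] - means[i1])
    se <- unname(sqrt(msw / 2 * (1 / ns[i1] + 1 / ns[i2])))
    q <- abs(diff) / se
    tibble::tibble(
      group1 = names(groups)[i1],
      group2 = names(groups)[i2],
      mean_diff = diff,
      ci_low = diff - qcrit * se,
      ci_high = diff + qcrit * se,
      p_adj = stats::ptukey(q, nmeans = k, df = an$df_within, lower.tail = FALSE)
    )
  })
  structure(out, class = c("tukey_hsd", class(out)),
            df_within = an$df_within, nmeans = k, conf_level = conf_level)
}

#' Check ANOVA assumptions
#'
#' Per-group Shapiro--Wilk normality tests and a median-centred Levene
#' (Brown--Forsythe) test of homogeneity of variances — the latter computed
#' as a one-way ANOVA of the absolute deviations from the group medians.
#' Degenerate inputs (constant groups, n < 3) are reported as not
#' assessable rather than failing.
#'
#' @param groups As for [one_way_anova()].
#' @param alpha Significance level for the pass/fail flags (default 0.05).
#' @return List with `normality` (tibble: group, n, W, p, pass),
#'   `homogeneity` (list: F, df, p, pass), and overall `assessable` flags.
#' @export
check_assumptions <- function(groups, alpha = 0.05) {
  groups <- as_group_list(groups)
  norm <- purrr::imap_dfr(groups, function(x, nm) {
    if (length(x) < 3L || stats::sd(x) == 0) {
      tibble::tibble(group = nm, n = length(x), W = NA_real_, p = NA_real_, pass = NA)
    } else {
      sw <- stats::shapiro.test(x)
      tibble::tibble(group = nm, n = length(x), W = unname(sw$statistic),
                     p = sw$p.value, pass = sw$p.value >= alpha)
    }
  })
  centered <- purrr::map(groups, function(x) abs(x - stats::median(x)))
  homog <- if (all(vapply(centered, stats::sd, numeric(1)) == 0)) {
    list(F = NA_real_, df = c(NA_integer_, NA_integer_), p = NA_real_, pass = NA)
  } else {
    lv <- one_way_anova(centered)
    list(F = lv$F, df = c(lv$df_between, lv$df_within), p = lv$p,
         pass = if (is.nan(lv$p)) NA else lv$p >= alpha)
  }
  list(
    normality = norm,
    homogeneity = homog,
    assessable = list(normality = !all(is.na(norm$pass)),
                      homogeneity = !is.na(homog$pass))
  )
}

#' Power to detect a relative mean dose difference
#'
#' Power of a t-test to detect a mean difference of `detectable_rel_diff`
#' percent of a baseline DVH-point value, given the observed SD, via the
#' noncentral t distribution. Three designs are supported: `one_sample`
#' (mean of per-patient differences against 0, and equivalently `paired`)
#' and `two_sample` (two independent groups of `n` patients each, common
#' SD).
#'
#' @param baseline_mean Baseline DVH-point value (Gy).
#' @param sd Standard deviation (Gy) — of the differences for
#'   one-sample/paired, per group for two-sample.
#' @param detectable_rel_diff Relative difference to detect, in percent of
#'   `baseline_mean`.
#' @param n Patients (per group for `two_sample`).
#' @param design `"one_sample"`, `"paired"`, or `"two_sample"`.
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power (probability in \[0, 1\]).
#' @export
#' @examples
#' power_mean_difference(1.94, 0.03, 2, 21)  # essentially 1
power_mean_difference <- function(baseline_mean, sd, detectable_rel_diff, n,
                                  design = c("one_sample", "paired", "two_sample"),
                                  alpha = 0.05) {
  design <- match.arg(design)
  stopifnot(sd > 0, n >= 2, alpha > 0, alpha < 1)
  delta <- baseline_mean * detectable_rel_diff / 100
  if (design %in% c("one_sample", "paired")) {
    df <- n - 1
    ncp <- delta / (sd / sqrt(n))
  } else {
    df <- 2 * n - 2
    ncp <- delta / (sd * sqrt(2 / n))
  }
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tcrit, df, ncp = ncp, lower.tail = TRUE)
}

#' Full cohort analysis
#'
#' The statistical pipeline applied to a long cohort table: per-patient
#' percentage differences with respect to CT, mean +/- 2 SD summaries per
#' diagnostic group x structure x DVH point x MRI variant, a one-way ANOVA
#' across modalities (CT and all MRI variants, raw DVH-point values as
#' groups), and Tukey HSD pairwise comparisons whenever the ANOVA is
#' significant at `alpha`. An optional stratification column (for instance
#' prescription dose level for rectum) splits groups before analysis;
#' strata with fewer than 2 patients are dropped with a warning.
#'
#' The ANOVA treats the modalities as independent groups even though the
#' same patients underlie each — replicating common commissioning practice;
#' set `paired = TRUE` to instead run the ANOVA on within-patient
#' differences from the patient mean (a conservative repeated-measures
#' variant).
#'
#' @param cohort Long cohort tibble (see [cohort_percent_diffs()]).
#' @param alpha Significance level gating the Tukey step.
#' @param stratify_by Optional column name in `cohort` used to split each
#'   (diagnosis, structure) analysis into strata.
#' @param paired Use within-patient centred values in the ANOVA.
#' @return A `cohort_analysis` object: list of tibbles `summaries`, `anova`,
#'   `tukey`, plus `alpha`.
#' @export
analyze_cohort <- function(cohort, alpha = 0.05, stratify_by = NULL, paired = FALSE) {
  if (!is.null(stratify_by)) {
    stopifnot(stratify_by %in% names(cohort))
    cohort <- cohort |>
      dplyr::mutate(structure = paste0(.data$structure, " [",
                                       .data[[stratify_by]], "]"))
  }
  counts <- cohort |>
    dplyr::distinct(.data$diagnosis, .data$structure, .data$patient_id) |>
    dplyr::count(.data$diagnosis, .data$structure)
  small <- dplyr::filter(counts, .data$n < 2L)
  if (nrow(small) > 0L) {
    warning(sprintf("dropping %d stratum/strata with fewer than 2 patients (%s)",
                    nrow(small),
                    paste(small$structure, collapse = ", ")), call. = FALSE)
    cohort <- dplyr::anti_join(cohort, small,
                               by = c("diagnosis", "structure"))
  }

  diffs <- cohort_percent_diffs(cohort)
  summaries <- summarize_diffs(diffs)

  keys <- dplyr::distinct(cohort, .data$diagnosis, .data$structure, .data$dvh_point)
  anova_rows <- purrr::pmap(keys, function(diagnosis, structure, dvh_point) {
    sub <- cohort[cohort$diagnosis == diagnosis &
                    cohort$structure == structure &
                    cohort$dvh_point == dvh_point, ]
    if (paired) {
      sub <- sub |>
        dplyr::group_by(.data$patient_id) |>
        dplyr::mutate(value = .data$value - mean(.data$value)) |>
        dplyr::ungroup()
    }
    groups <- split(sub$value, sub$modality)
    an <- one_way_anova(groups)
    tk <- if (an$flag == "ok" && is.finite(an$F) && an$p < alpha) {
      tukey_hsd(groups) |>
        dplyr::mutate(diagnosis = diagnosis, structure = structure,
                      dvh_point = dvh_point, .before = 1)
    } else NULL
    list(
      anova = tibble::tibble(
        diagnosis = diagnosis, structure = structure, dvh_point = dvh_point,
        F = an$F, df_between = an$df_between, df_within = an$df_within,
        p = an$p, significant = !is.nan(an$p) && an$p < alpha, flag = an$flag
      ),
      tukey = tk
    )
  })

  structure(
    list(
      summaries = summaries,
      anova = dplyr::bind_rows(purrr::map(anova_rows, "anova")),
      tukey = dplyr::bind_rows(purrr::compact(purrr::map(anova_rows, "tukey"))),
      alpha = alpha
    ),
    class = "cohort_analysis"
  )
}

#' @export
print.anova_oneway <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g [%s]\n",
              x$df_between, x$df_within, x$F, x$p, x$flag))
  invisible(x)
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("<cohort_analysis> %d summary cells, %d ANOVA tests (%d significant at alpha = %g)\n",
              nrow(x$summaries), nrow(x$anova), sum(x$anova$significant), x$alpha))
  invisible(x)
}
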