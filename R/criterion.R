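#' Cohort reliability criterion specification
#'
#' The acceptance rule for MRI-only dose calculation: approximately 95% of
#' patients must deviate from the CT-based calculation by no more than the
#' tolerance. Operationally, the conservative interval mean +/- 2 SD of the
#' per-patient percentage differences must lie entirely inside
#' \[-tolerance, +tolerance\], boundaries inclusive.
#'
#' @param tolerance Dose-difference tolerance in percent (default 2).
#' @param coverage Nominal fraction of patients the interval should cover
#'   (default 0.95; informational — the implemented rule is mean +/- 2 SD).
#' @param interval_rule Currently only `"mean_pm_2sd"`.
#' @return A `criterion_spec` list.
#' @export
criterion_spec <- function(tolerance = 2, coverage = 0.95,
                           interval_rule = "mean_pm_2sd") {
  stopifnot(tolerance > 0, coverage > 0, coverage < 1,
            interval_rule == "mean_pm_2sd")
  structure(list(tolerance = tolerance, coverage = coverage,
                 interval_rule = interval_rule),
            class = "criterion_spec")
}

#' Evaluate the reliability criterion on difference summaries
#'
#' Applies the criterion to each row of a summary table: the interval
#' mean_pct +/- 2 sd_pct must be contained in \[-tolerance, +tolerance\]
#' (inclusive). The signed `margin` — tolerance minus the worse interval
#' edge's distance from zero — is reported so that near-boundary cells are
#' visible; it is >= 0 exactly when the cell passes.
#'
#' @param summaries Tibble with columns `mean_pct` and either `sd_pct` or
#'   `half_width_2sd` (e.g. from [summarize_diffs()] or
#'   [reference_summaries()]).
#' @param spec A [criterion_spec()].
#' @return The input with added columns `interval_low`, `interval_high`,
#'   `passed`, `margin`.
#' @export
#' @examples
#' evaluate_criterion(tibble::tibble(mean_pct = 1.3, sd_pct = 0.7))  # fails at 2%
evaluate_criterion <- function(summaries, spec = criterion_spec()) {
  stopifnot(inherits(spec, "criterion_spec"))
  summaries <- tibble::as_tibble(summaries)
  if (!"half_width_2sd" %in% names(summaries)) {
    stopifnot("sd_pct" %in% names(summaries))
    summaries$half_width_2sd <- 2 * summaries$sd_pct
  }
  if (any(!is.finite(summaries$half_width_2sd))) {
    stop("undefined SD in summaries (need n >= 2)", call. = FALSE)
  }
  tol <- spec$tolerance
  summaries |>
    dplyr::mutate(
      interval_low = .data$mean_pct - .data$half_width_2sd,
      interval_high = .data$mean_pct + .data$half_width_2sd,
      passed = .data$interval_low >= -tol & .data$interval_high <= tol,
      margin = tol - pmax(abs(.data$interval_low), abs(.data$interval_high))
    )
}

#' Pass/fail decision matrix across diagnoses, DVH points and modalities
#'
#' Evaluates the criterion on a full set of summaries and arranges the
#' result as one decision per (diagnosis, structure, DVH point, modality),
#' ordered within each DVH point by descending unit-density mean difference
#' (the ordering used in commissioning interval plots).
#'
#' @param summaries Summary tibble keyed by `diagnosis`, `dvh_point`,
#'   `modality` (and optionally `structure`).
#' @param spec A [criterion_spec()].
#' @param sort_modality Modality whose mean orders the diagnoses
#'   (default `"MRI_u"`).
#' @return A `decision_matrix` tibble of criterion decisions with margins.
#' @export
decision_matrix <- function(summaries, spec = criterion_spec(),
                            sort_modality = "MRI_u") {
  dec <- evaluate_criterion(summaries, spec)
  if (all(c("diagnosis", "dvh_point", "modality") %in% names(dec)) &&
      sort_modality %in% dec$modality) {
    key <- intersect(c("diagnosis", "structure", "dvh_point"), names(dec))
    ord <- dec |>
      dplyr::filter(.data$modality == sort_modality) |>
      dplyr::select(dplyr::all_of(key), sort_mean = "mean_pct")
    dec <- dec |>
      dplyr::left_join(ord, by = key) |>
      dplyr::arrange(.data$dvh_point, dplyr::desc(.data$sort_mean), .data$modality) |>
      dplyr::select(-"sort_mean")
  }
  structure(dec, class = c("decision_matrix", class(dec)),
            tolerance = spec$tolerance)
}

#' Combine uncertainty components in quadrature
#'
#' Root-sum-of-squares aggregation of independent percentage uncertainty
#' components, as used in radiotherapy uncertainty budgets: combining a 1%
#' CT dose-calculation uncertainty with a 2% MRI contribution yields
#' sqrt(1 + 4) = 2.236..., conventionally reported as 2.2%.
#'
#' @param components Numeric vector of non-negative percentage
#'   uncertainties, optionally named.
#' @return An `uncertainty_budget`: list with `components` (tibble),
#'   `combined` (exact), `reported` (one decimal).
#' @export
#' @examples
#' quadrature_combine(c(CT = 1, MRI = 2))
quadrature_combine <- function(components) {
  if (any(components < 0)) stop("uncertainty components must be >= 0", call. = FALSE)
  labels <- names(components) %||% paste0("component_", seq_along(components))
  combined <- sqrt(sum(components^2))
  structure(
    list(
      components = tibble::tibble(label = labels, uncertainty_pct = unname(components)),
      combined = combined,
      reported = round(combined, 1)
    ),
    class = "uncertainty_budget"
  )
}

#' Maximum MRI uncertainty allowed by a quadrature budget
#'
#' Inverts the quadrature rule: given the CT dose-calculation uncertainty
#' and the total dose-calculation budget, the largest MRI-specific
#' uncertainty that still fits is sqrt(budget^2 - ct^2). A budget no larger
#' than the CT uncertainty leaves no MRI allowance and is an error.
#'
#' @param ct_uncertainty CT dose-calculation uncertainty, percent.
#' @param dose_calc_budget Total dose-calculation uncertainty budget,
#'   percent; must exceed `ct_uncertainty`.
#' @return Allowed MRI uncertainty in percent.
#' @export
#' @examples
#' required_mri_uncertainty(1, sqrt(5))  # 2
required_mri_uncertainty <- function(ct_uncertainty, dose_calc_budget) {
  stopifnot(ct_uncertainty >= 0)
  if (dose_calc_budget <= ct_uncertainty) {
    stop("budget must exceed the CT uncertainty: no feasible MRI allowance",
         call. = FALSE)
  }
  sqrt(dose_calc_budget^2 - ct_uncertainty^2)
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  cat(sprintf("<uncertainty_budget> combined %.4g%% (reported %.1f%%) from %d components\n",
              x$combined, x$reported, nrow(x$components)))
  invisible(x)
}
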