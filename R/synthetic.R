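#' Reference commissioning cohort summaries
#'
#' Machine-readable copy of the published summary statistics from a
#' 57-patient MRI-only commissioning cohort (18 head-and-neck, 21 prostate,
#' 10 vesica, 8 pelvic patients): for each diagnostic group, structure, DVH
#' point and density-override modality, the mean percentage dose difference
#' with respect to CT and the printed plus/minus value. The printed
#' plus/minus values are two standard deviations of the per-patient
#' differences (the conservative ~95% interval half-width), so
#' `sd_pct = half_width_2sd / 2`. Rectum rows for the prostate group are
#' stratified by prescription dose level (`Rectum_hi`: 12 patients,
#' `Rectum_lo`: 9).
#'
#' These summaries are the emulation target of [simulate_cohort()] and the
#' regression fixture for [decision_matrix()].
#'
#' @return Tibble with columns `diagnosis`, `structure`, `n`, `dvh_point`,
#'   `modality`, `mean_pct`, `half_width_2sd`, `sd_pct`.
#' @export
#' @examples
#' dplyr::filter(reference_summaries(), structure == "PTV", modality == "MRI_u")
reference_summaries <- function() {
  raw <- tibble::tribble(
    ~diagnosis, ~structure,    ~n,  ~dvh_point, ~mri_u_mean, ~mri_u_hw, ~mri_b_mean, ~mri_b_hw, ~mri_bc_mean, ~mri_bc_hw,
    "Prostate", "PTV",         21L, "D_median",  1.3,   1.4,  -0.0002, 1.1,  NA,    NA,
    "Prostate", "PTV",         21L, "D_98%",     1.4,   1.9,  -0.03,   1.7,  NA,    NA,
    "Prostate", "PTV",         21L, "D_2%",      1.4,   1.3,  -0.02,   1.0,  NA,    NA,
    "Prostate", "Rectum_hi",   12L, "D_10%",     2.0,   1.7,   0.6,    1.6,  NA,    NA,
    "Prostate", "Rectum_hi",   12L, "D_30%",     1.9,   2.5,   0.8,    2.5,  NA,    NA,
    "Prostate", "Rectum_hi",   12L, "D_60%",     1.0,   3.0,   0.2,    3.0,  NA,    NA,
    "Prostate", "Rectum_lo",    9L, "D_10%",     2.2,   3.0,   0.9,    3.0,  NA,    NA,
    "Prostate", "Rectum_lo",    9L, "D_30%",     0.8,   1.5,  -0.008,  1.3,  NA,    NA,
    "Prostate", "Rectum_lo",    9L, "D_60%",    -0.06,  1.6,  -0.7,    1.6,  NA,    NA,
    "HN",       "PTV",         18L, "D_median",  1.0,   1.9,  -0.6,    1.2,  -0.02, 3.0,
    "HN",       "PTV",         18L, "D_98%",     1.6,   2.3,  -0.006,  1.8,  -1.0,  2.8,
    "HN",       "PTV",         18L, "D_2%",      1.2,   2.0,  -0.4,    0.9,   0.4,  4.3,
    "HN",       "Medulla",     18L, "D_max",     0.8,   3.6,  -1.4,    3.8,  -1.4,  3.6,
    "HN",       "Parotid sin", 16L, "D_mean",   -1.2,   6.8,   2.5,    7.4,  -1.3,  8.7,
    "HN",       "Parotid dxt", 16L, "D_mean",    1.7,   7.4,   0.2,    6.8,   1.4,  8.9,
    "Vesica",   "PTV",         10L, "D_median",  0.4,   1.2,  -0.3,    1.3,  NA,    NA,
    "Vesica",   "PTV",         10L, "D_98%",    -0.9,   4.8,  -1.4,    4.2,  NA,    NA,
    "Vesica",   "PTV",         10L, "D_2%",      1.1,   1.5,   0.2,    1.8,  NA,    NA,
    "Vesica",   "Rectum",      10L, "D_2cm3",    0.7,   1.6,  -0.1,    1.7,  NA,    NA,
    "Vesica",   "Rectum",      10L, "V_40Gy",   -0.1,   3.0,  -0.6,    3.2,  NA,    NA,
    "Vesica",   "Femur sin",   10L, "D_max",     1.4,   3.4,  -0.6,    1.9,  NA,    NA,
    "Vesica",   "Femur dxt",   10L, "D_max",     0.7,   2.0,  -0.7,    2.0,  NA,    NA,
    "Vesica",   "Intestine",    8L, "D_2cm3",   -0.5,   3.5,  -0.9,    3.4,  NA,    NA,
    "Vesica",   "Intestine",    8L, "V_35Gy",    4.2,   8.0,   3.5,    7.6,  NA,    NA,
    "Pelvic",   "PTV",          8L, "D_median", -0.2,   1.3,  -0.3,    1.2,  NA,    NA,
    "Pelvic",   "PTV",          8L, "D_98%",    -0.9,   2.0,  -1.5,    2.0,  NA,    NA,
    "Pelvic",   "PTV",          8L, "D_2%",      0.8,   1.4,   0.03,   1.6,  NA,    NA,
    "Pelvic",   "Femur sin",    8L, "D_mean",    0.3,   1.1,  -0.5,    1.3,  NA,    NA,
    "Pelvic",   "Femur sin",    8L, "D_max",     0.07,  1.5,  -0.2,    3.3,  NA,    NA,
    "Pelvic",   "Femur dxt",    8L, "D_mean",    0.1,   3.1,  -0.2,    2.2,  NA,    NA,
    "Pelvic",   "Femur dxt",    8L, "D_max",     0.3,   2.5,  -0.4,    1.4,  NA,    NA
  )
  long <- raw |>
    tidyr::pivot_longer(
      cols = dplyr::starts_with("mri_"),
      names_to = c("modality", ".value"),
      names_pattern = "mri_(u|b|bc)_(mean|hw)"
    ) |>
    dplyr::filter(!is.na(.data$mean)) |>
    dplyr::mutate(
      modality = dplyr::recode(.data$modality,
                               u = "MRI_u", b = "MRI_b", bc = "MRI_b_c"),
      mean_pct = .data$mean,
      half_width_2sd = .data$hw,
      sd_pct = .data$hw / 2
    ) |>
    dplyr::select("diagnosis", "structure", "n", "dvh_point", "modality",
                  "mean_pct", "half_width_2sd", "sd_pct")
  long
}

#' Default CT baseline values per DVH point
#'
#' Plausible CT-based baseline values (Gy, or % volume for V-type points)
#' used by [simulate_cohort()] when none are supplied. D-type PTV points sit
#' near typical prescription doses; OAR points lower. Percentage differences
#' are scale-free, so these baselines affect only the absolute scale of the
#' simulated table, not any downstream statistic.
#'
#' @return Named numeric vector keyed by DVH point label.
#' @export
default_ct_baselines <- function() {
  c("D_median" = 60, "D_98%" = 57, "D_2%" = 62, "D_10%" = 55, "D_30%" = 45,
    "D_60%" = 30, "D_max" = 48, "D_mean" = 26, "D_2cm3" = 50,
    "V_40Gy" = 40, "V_35Gy" = 30)
}

#' Simulate a cohort DVH-point table
#'
#' Generates a long cohort table with the statistical structure the analysis
#' assumes: for each patient, CT values equal the per-point baseline
#' (optionally jittered), and each MRI-variant value is
#' CT * (1 + delta/100) with delta drawn from Normal(mean_pct, sd_pct)
#' independently per patient x structure x DVH point x modality. Defaults
#' emulate the reference commissioning cohort ([reference_summaries()]).
#'
#' An optional shared per-patient component (`patient_sd`) adds a common
#' Normal(0, patient_sd) term to all of a patient's deltas, emulating the
#' within-patient correlation of real paired dose recalculations. An
#' optional contamination mixture (`contam_prob`, `contam_scale`) replaces a
#' delta's SD by `contam_scale * sd_pct` with probability `contam_prob`,
#' emulating heavy-tailed outliers such as bowel gas pockets; both default
#' off.
#'
#' @param config Tibble with columns `diagnosis`, `structure`, `n`,
#'   `dvh_point`, `modality`, `mean_pct`, `sd_pct` (defaults to
#'   [reference_summaries()]).
#' @param ct_baselines Named vector mapping DVH point label to CT baseline;
#'   defaults to [default_ct_baselines()].
#' @param ct_jitter_sd SD of a multiplicative jitter on CT baselines per
#'   patient (fractional; default 0, i.e. constant baselines).
#' @param patient_sd Shared per-patient delta component SD, percent
#'   (default 0).
#' @param contam_prob,contam_scale Contamination mixture (defaults 0, 1).
#' @param seed Integer seed; the generator is fully reproducible given it.
#' @return Long cohort tibble: `patient_id`, `diagnosis`, `structure`,
#'   `dvh_point`, `modality`, `value`, `unit`.
#' @export
#' @examples
#' tab <- simulate_cohort(seed = 1)
#' dplyr::count(tab, diagnosis, modality)
simulate_cohort <- function(config = reference_summaries(),
                            ct_baselines = default_ct_baselines(),
                            ct_jitter_sd = 0,
                            patient_sd = 0,
                            contam_prob = 0, contam_scale = 1,
                            seed = NULL) {
  stopifnot(all(c("diagnosis", "structure", "n", "dvh_point", "modality",
                  "mean_pct", "sd_pct") %in% names(config)),
            all(config$n >= 2), all(config$sd_pct >= 0),
            contam_prob >= 0, contam_prob <= 1, contam_scale > 0)
  if (!is.null(seed)) set.seed(seed)

  missing_bl <- setdiff(unique(config$dvh_point), names(ct_baselines))
  if (length(missing_bl)) {
    stop("no CT baseline for DVH point(s): ", paste(missing_bl, collapse = ", "),
         call. = FALSE)
  }

  # patients are shared across structures/points within a diagnosis; a
  # structure observed in fewer patients uses the first n of the group
  group_n <- config |>
    dplyr::group_by(.data$diagnosis) |>
    dplyr::summarise(n_max = max(.data$n), .groups = "drop")

  patient_effects <- group_n |>
    dplyr::mutate(patients = purrr::map2(.data$diagnosis, .data$n_max, function(d, n) {
      tibble::tibble(
        patient_idx = seq_len(n),
        patient_id = sprintf("%s_%02d", d, seq_len(n)),
        patient_shift = if (patient_sd > 0) stats::rnorm(n, 0, patient_sd) else rep(0, n),
        ct_jitter = if (ct_jitter_sd > 0) stats::rnorm(n, 0, ct_jitter_sd) else rep(0, n)
      )
    })) |>
    tidyr::unnest("patients")

  cells <- config |>
    dplyr::mutate(cell = dplyr::row_number())
  rows <- cells |>
    dplyr::mutate(patient_idx = purrr::map(.data$n, seq_len)) |>
    tidyr::unnest("patient_idx") |>
    dplyr::left_join(
      dplyr::select(patient_effects, "diagnosis", "patient_idx",
                    "patient_id", "patient_shift", "ct_jitter"),
      by = c("diagnosis", "patient_idx")
    )

  m <- nrow(rows)
  wide_sd <- if (contam_prob > 0) {
    ifelse(stats::runif(m) < contam_prob, contam_scale, 1)
  } else 1
  delta <- stats::rnorm(m, rows$mean_pct, rows$sd_pct * wide_sd) + rows$patient_shift
  ct_value <- unname(ct_baselines[rows$dvh_point]) * (1 + rows$ct_jitter)

  out <- rows |>
    dplyr::mutate(
      ct_value = ct_value,
      value = ct_value * (1 + delta / 100),
      unit = ifelse(grepl("^V_", .data$dvh_point), "%", "Gy")
    )

  ct_rows <- out |>
    dplyr::distinct(.data$patient_id, .data$diagnosis, .data$structure,
                    .data$dvh_point, .data$ct_value, .data$unit) |>
    dplyr::mutate(modality = "CT", value = .data$ct_value)

  dplyr::bind_rows(
    dplyr::select(ct_rows, "patient_id", "diagnosis", "structure",
                  "dvh_point", "modality", "value", "unit"),
    dplyr::select(out, "patient_id", "diagnosis", "structure",
                  "dvh_point", "modality", "value", "unit")
  ) |>
    dplyr::arrange(.data$diagnosis, .data$patient_id, .data$structure,
                   .data$dvh_point, .data$modality)
}

#' Simulate a paired CT/MRI dose distribution on a toy phantom
#'
#' Builds a spherical phantom — body, PTV at the centre, a bone shell, an
#' optional air cavity and an OAR sphere — with a CT dose field equal to the
#' prescription inside the PTV and a smooth radial falloff outside, then an
#' MRI dose field equal to the CT dose scaled by a per-patient global factor
#' (1 + delta/100) and optionally modulated by a smooth spatial error field.
#' This emulates, at toy scale, the dose-shape and perturbation structure of
#' a clinically approved plan recalculated on a density-corrected MRI; it
#' makes no attempt at beam/arc realism.
#'
#' @param shape Grid dimensions (length 3, default `c(24, 24, 24)`).
#' @param spacing Voxel spacing in mm (default 2 mm isotropic).
#' @param prescription_gy Prescription dose (default 60 Gy).
#' @param ptv_radius_mm,body_radius_mm,oar_offset_mm,oar_radius_mm Geometry.
#' @param falloff_mm Exponential dose falloff scale outside the PTV.
#' @param delta_mean_pct,delta_sd_pct Per-patient global dose scaling
#'   percentage: delta ~ Normal(mean, sd).
#' @param spatial_amplitude Amplitude of a smooth low-order spatial
#'   modulation of the MRI dose (fractional, default 0 = pure scaling).
#' @param patient_seed Integer seed for this patient's perturbation draws.
#' @return List with `ct`, `mri` ([dose_grid()]s), `masks` (named list of
#'   [structure_mask()]s: body, PTV, OAR, bone, cavity), and `delta_pct`
#'   (the drawn global scaling, percent).
#' @export
simulate_dose_pair <- function(shape = c(24, 24, 24), spacing = c(2, 2, 2),
                               prescription_gy = 60,
                               ptv_radius_mm = 8, body_radius_mm = 22,
                               oar_offset_mm = 12, oar_radius_mm = 4,
                               falloff_mm = 10,
                               delta_mean_pct = 0, delta_sd_pct = 0,
                               spatial_amplitude = 0,
                               patient_seed = NULL) {
  stopifnot(prescription_gy > 0, ptv_radius_mm < body_radius_mm)
  if (!is.null(patient_seed)) set.seed(patient_seed)
  ctr <- (shape + 1) / 2
  ax <- purrr::map(1:3, function(i) ((seq_len(shape[i])) - ctr[i]) * spacing[i])
  r <- sqrt(
    outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  )
  body <- r <= body_radius_mm
  ptv <- r <= ptv_radius_mm
  # bone: a thin shell inside the body surface
  bone <- body & r >= body_radius_mm - 4 & r <= body_radius_mm - 1
  oar_r <- sqrt(
    outer(outer((ax[[1]] - oar_offset_mm)^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  )
  oar <- body & oar_r <= oar_radius_mm & !ptv & !bone
  cavity <- body & oar_r <= oar_radius_mm / 2 & !ptv & !bone
  if (!any(oar)) stop("OAR geometry is empty; enlarge the body or move the OAR",
                      call. = FALSE)

  dose <- array(0, dim = shape)
  dose[ptv] <- prescription_gy
  outside <- !ptv
  dose[outside] <- prescription_gy * exp(-(pmax(r[outside] - ptv_radius_mm, 0)) / falloff_mm)
  dose[!body] <- 0

  delta <- stats::rnorm(1, delta_mean_pct, delta_sd_pct)
  mri_dose <- dose * (1 + delta / 100)
  if (spatial_amplitude > 0) {
    phases <- stats::runif(3, 0, 2 * pi)
    field <- spatial_amplitude * (
      outer(outer(sin(2 * pi * ax[[1]] / (2 * body_radius_mm) + phases[1]),
                  cos(2 * pi * ax[[2]] / (2 * body_radius_mm) + phases[2]), `+`) / 2,
            sin(2 * pi * ax[[3]] / (2 * body_radius_mm) + phases[3]), `+`) / 2
    )
    mri_dose <- mri_dose * (1 + field)
    mri_dose[mri_dose < 0] <- 0
  }

  mk <- function(vox, name, role) structure_mask(vox, name, role, spacing)
  list(
    ct = dose_grid(dose, spacing, modality = "CT"),
    mri = dose_grid(mri_dose, spacing, modality = "MRI_u"),
    masks = list(
      body = mk(body, "body", "body"),
      PTV = mk(ptv, "PTV", "PTV"),
      OAR = mk(oar, "OAR", "OAR"),
      bone = mk(bone, "bone", "bone"),
      cavity = mk(cavity, "cavity", "cavity")
    ),
    delta_pct = delta
  )
}
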