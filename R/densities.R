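#' Bundled bone electron-density table
#'
#' Reference electron densities for the bone tissues used in bulk density
#' override of MRI, one row per diagnostic group. Pelvic-region entries
#' (femur) carry two age anchors between which density is interpolated
#' linearly; the cranium entry is age-independent and has a single adult
#' value. The `hu_lookup` column holds the HU each group's bone was assigned
#' in the reference commissioning cohort, evaluated at that group's mean age.
#'
#' @return A tibble with columns `diagnosis`, `tissue`, `density_young`,
#'   `age_young`, `density_old`, `age_old`, `age_independent`, `mean_age`,
#'   `hu_lookup`.
#' @export
#' @examples
#' bone_density_table()
bone_density_table <- function() {
  tibble::tribble(
    ~diagnosis, ~tissue,                    ~density_young, ~age_young, ~density_old, ~age_old, ~age_independent, ~mean_age, ~hu_lookup,
    "HN",       "skeleton-cranium (whole)", 1.61,           NA_real_,   NA_real_,     NA_real_, TRUE,             NA_real_,  971,
    "Prostate", "skeleton-femur (whole)",   1.33,           30,         1.22,         90,       FALSE,            66.8,      349,
    "Pelvic",   "skeleton-femur (whole)",   1.33,           30,         1.22,         90,       FALSE,            64.7,      356,
    "Vesica",   "skeleton-femur (whole)",   1.33,           30,         1.22,         90,       FALSE,            78.8,      309
  )
}

#' Interpolate an electron density at a given age
#'
#' Linear interpolation between a tissue's two age anchors. Age-independent
#' entries (cranium) return their single adult value for any non-negative
#' age. Ages more than 20 years outside the anchor interval are refused;
#' ages outside the interval but within that margin trigger a warning, since
#' the linear model is then an extrapolation.
#'
#' @param age Patient (or group mean) age in years.
#' @param entry One row of [bone_density_table()] (or a list with the same
#'   fields).
#' @return Density in g/cm3.
#' @export
#' @examples
#' femur <- dplyr::filter(bone_density_table(), diagnosis == "Prostate")
#' interpolate_electron_density(66.8, femur)
interpolate_electron_density <- function(age, entry) {
  stopifnot(is.numeric(age), length(age) == 1L)
  if (is.na(age) || age < 0) {
    stop("`age` must be a non-negative number of years.", call. = FALSE)
  }
  entry <- as.list(entry)
  if (isTRUE(entry$age_independent)) {
    return(entry$density_young)
  }
  a0 <- entry$age_young
  a1 <- entry$age_old
  d0 <- entry$density_young
  d1 <- entry$density_old
  stopifnot(a0 < a1, d0 > 0, d1 > 0)
  if (age < a0 - 20 || age > a1 + 20) {
    stop(sprintf(
      "age %.1f is more than 20 years outside the anchor interval [%g, %g]",
      age, a0, a1
    ), call. = FALSE)
  }
  if (age < a0 || age > a1) {
    warning(sprintf(
      "age %.1f is outside the anchor interval [%g, %g]; density is extrapolated",
      age, a0, a1
    ), call. = FALSE)
  }
  d0 + (age - a0) / (a1 - a0) * (d1 - d0)
}

#' Fit a linear density-to-HU calibration
#'
#' Least-squares line HU = intercept + slope * density through the supplied
#' calibration points. The default points pair the femur densities
#' interpolated at the three pelvic-region group mean ages (66.8, 64.7,
#' 78.8 years) with the HU values those groups were assigned (349, 356,
#' 309); these three pairs are mutually collinear to numerical precision.
#' The fit's residuals and its prediction at water density (1.0 g/cm3) are
#' stored as diagnostics: a calibration reverse-engineered from bone points
#' alone need not, and here does not, pass near (1.0, 0 HU).
#'
#' @param points A data frame with columns `density` (g/cm3) and `hu`, at
#'   least two rows with distinct densities. Defaults to the three
#'   pelvic-region pairs described above.
#' @return An object of class `hu_calibration`: a list with `slope`,
#'   `intercept`, `points` (with fitted values and residuals),
#'   `max_abs_residual`, and `water_hu`.
#' @export
#' @examples
#' cal <- fit_hu_calibration()
#' predict(cal, 1.33)
fit_hu_calibration <- function(points = NULL) {
  if (is.null(points)) {
    tab <- bone_density_table()
    pel <- dplyr::filter(tab, !.data$age_independent)
    points <- tibble::tibble(
      density = purrr::map2_dbl(
        pel$mean_age, seq_len(nrow(pel)),
        function(a, i) interpolate_electron_density(a, pel[i, ])
      ),
      hu = pel$hu_lookup
    )
  }
  points <- tibble::as_tibble(points)
  stopifnot(all(c("density", "hu") %in% names(points)))
  if (nrow(points) < 2L) {
    stop("at least two calibration points are required", call. = FALSE)
  }
  if (length(unique(points$density)) < 2L) {
    stop("calibration points are degenerate: all densities are equal", call. = FALSE)
  }
  fit <- stats::lm(hu ~ density, data = points)
  co <- stats::coef(fit)
  points$fitted <- as.numeric(stats::fitted(fit))
  points$residual <- as.numeric(stats::resid(fit))
  structure(
    list(
      slope = unname(co["density"]),
      intercept = unname(co["(Intercept)"]),
      points = points,
      max_abs_residual = max(abs(points$residual)),
      water_hu = unname(co["(Intercept)"] + co["density"] * 1.0)
    ),
    class = "hu_calibration"
  )
}

#' @export
predict.hu_calibration <- function(object, density = NULL, ...) {
  if (is.null(density)) density <- object$points$density
  object$intercept + object$slope * density
}

#' @export
print.hu_calibration <- function(x, ...) {
  cat(sprintf(
    "<hu_calibration> HU = %.2f + %.2f * density (g/cm3)\n", x$intercept, x$slope
  ))
  cat(sprintf(
    "  %d points, max |residual| %.3g HU, HU at water density %.1f\n",
    nrow(x$points), x$max_abs_residual, x$water_hu
  ))
  invisible(x)
}

#' Bone HU for a diagnostic group
#'
#' Returns the bone HU to assign under bulk density override for a diagnostic
#' group. By default (`mode = "direct_lookup"`) the bundled per-group HU is
#' returned whenever the requested age matches the group's tabulated mean age
#' (or the entry is age-independent); otherwise, and always under
#' `mode = "linear"`, the density is interpolated at the requested age and
#' mapped through the linear calibration. Age-independent entries (cranium)
#' always use direct lookup: the cranium point does not lie on the line fit
#' to the pelvic-region pairs.
#'
#' @param diagnosis Diagnostic group label present in `table`.
#' @param mean_age Age in years at which to evaluate; defaults to the
#'   group's tabulated mean age.
#' @param table Electron-density table, defaults to [bone_density_table()].
#' @param calibration An `hu_calibration`, defaults to [fit_hu_calibration()].
#' @param mode `"direct_lookup"` (default) or `"linear"`.
#' @return HU (scalar). The result carries an attribute `hu_mode` recording
#'   which path produced it.
#' @export
#' @examples
#' hu_for_group("HN")         # 971, direct lookup
#' hu_for_group("Prostate")   # 349, direct lookup at the group mean age
hu_for_group <- function(diagnosis, mean_age = NULL,
                         table = bone_density_table(),
                         calibration = fit_hu_calibration(),
                         mode = c("direct_lookup", "linear")) {
  mode <- match.arg(mode)
  entry <- dplyr::filter(table, .data$diagnosis == !!diagnosis)
  if (nrow(entry) != 1L) {
    stop(sprintf("unknown diagnosis '%s'", diagnosis), call. = FALSE)
  }
  if (isTRUE(entry$age_independent)) {
    return(structure(entry$hu_lookup, hu_mode = "direct_lookup"))
  }
  if (is.null(mean_age)) mean_age <- entry$mean_age
  if (mode == "direct_lookup" && !is.na(entry$mean_age) &&
      isTRUE(all.equal(mean_age, entry$mean_age))) {
    return(structure(entry$hu_lookup, hu_mode = "direct_lookup"))
  }
  dens <- interpolate_electron_density(mean_age, entry)
  structure(unname(predict(calibration, dens)), hu_mode = "linear")
}

#' Bulk density-override strategy
#'
#' Describes one of the three override geometries used when recalculating a
#' treatment plan on MRI: `unit` (whole body water-equivalent, HU 0), `bulk`
#' (body water plus bone at a bone-specific HU), and `bulk_cavity` (bulk plus
#' air cavities at the HU of air).
#'
#' @param name One of `"unit"`, `"bulk"`, `"bulk_cavity"`.
#' @param bone_hu Bone HU (ignored for `unit`).
#' @param cavity_hu Air-cavity HU; defaults to -1000 (Hounsfield definition
#'   of air).
#' @param body_hu Soft-tissue HU; defaults to 0 (water).
#' @return A `bulk_strategy` list.
#' @export
bulk_strategy <- function(name = c("unit", "bulk", "bulk_cavity"),
                          bone_hu = NULL, cavity_hu = -1000, body_hu = 0) {
  name <- match.arg(name)
  if (name != "unit") {
    if (is.null(bone_hu)) stop("`bone_hu` is required for bulk strategies", call. = FALSE)
    if (!(cavity_hu <= body_hu && body_hu <= bone_hu)) {
      stop("require cavity_hu <= body_hu <= bone_hu", call. = FALSE)
    }
  }
  structure(
    list(name = name, bone_hu = bone_hu, cavity_hu = cavity_hu, body_hu = body_hu),
    class = "bulk_strategy"
  )
}

#' Apply a bulk density override to structure masks
#'
#' Builds the per-voxel HU map a treatment planning system would use for an
#' MRI-only dose recalculation: every body voxel gets the soft-tissue HU,
#' bone voxels the bone HU (strategies `bulk`, `bulk_cavity`), cavity voxels
#' the air HU (`bulk_cavity` only). Voxels outside the body are background
#' (NA). Bone and cavity masks must be disjoint subsets of the body.
#'
#' @param body,bone,cavity `structure_mask` objects (bone/cavity may be NULL
#'   when the strategy ignores them).
#' @param strategy A [bulk_strategy()].
#' @return A `density_override_map`: list with `hu` (3-D array, NA outside
#'   body) and `provenance`.
#' @export
assign_bulk_densities <- function(body, bone = NULL, cavity = NULL, strategy) {
  stopifnot(inherits(strategy, "bulk_strategy"))
  bvox <- mask_voxels(body)
  check_alignment <- function(m, label) {
    if (!is.null(m)) {
      if (!identical(dim(mask_voxels(m)), dim(bvox)) ||
          !isTRUE(all.equal(mask_spacing(m), mask_spacing(body)))) {
        stop(sprintf("%s mask is not aligned to the body mask", label), call. = FALSE)
      }
    }
  }
  check_alignment(bone, "bone")
  check_alignment(cavity, "cavity")
  hu <- array(NA_real_, dim = dim(bvox))
  hu[bvox] <- strategy$body_hu
  if (strategy$name %in% c("bulk", "bulk_cavity") && !is.null(bone)) {
    bo <- mask_voxels(bone)
    if (any(bo & !bvox)) stop("bone mask extends outside the body", call. = FALSE)
    hu[bo] <- strategy$bone_hu
  }
  if (strategy$name == "bulk_cavity" && !is.null(cavity)) {
    cv <- mask_voxels(cavity)
    if (any(cv & !bvox)) stop("cavity mask extends outside the body", call. = FALSE)
    if (!is.null(bone) && any(cv & mask_voxels(bone))) {
      stop("bone and cavity masks overlap", call. = FALSE)
    }
    hu[cv] <- strategy$cavity_hu
  }
  structure(
    list(
      hu = hu,
      spacing = mask_spacing(body),
      provenance = list(strategy = strategy$name,
                        bone_hu = strategy$bone_hu,
                        cavity_hu = strategy$cavity_hu,
                        body_hu = strategy$body_hu)
    ),
    class = "density_override_map"
  )
}
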