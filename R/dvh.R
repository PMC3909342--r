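#' Construct a dose grid
#'
#' A 3-D scalar dose field with its voxel geometry. Doses are absorbed dose
#' in Gy; spacing is the voxel edge length in mm along each axis.
#'
#' @param values 3-D numeric array of doses (Gy), all finite and >= 0.
#' @param spacing Numeric length-3, voxel spacing in mm, all > 0.
#' @param origin Numeric length-3, world coordinates of the first voxel (mm).
#' @param modality One of `"CT"`, `"MRI_u"`, `"MRI_b"`, `"MRI_b_c"`.
#' @return A `dose_grid` object.
#' @export
dose_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      modality = c("CT", "MRI_u", "MRI_b", "MRI_b_c")) {
  modality <- match.arg(modality)
  values <- as.array(values)
  stopifnot(length(dim(values)) == 3L, length(spacing) == 3L, length(origin) == 3L)
  if (!all(is.finite(values))) stop("dose values must be finite", call. = FALSE)
  if (any(values < 0)) stop("dose values must be non-negative", call. = FALSE)
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  structure(
    list(values = values, spacing = as.numeric(spacing),
         origin = as.numeric(origin), modality = modality),
    class = "dose_grid"
  )
}

#' Construct a structure mask
#'
#' A boolean region aligned to a dose grid: target volume, organ at risk,
#' body outline, bone, or air cavity.
#'
#' @param voxels 3-D logical array (numeric input is thresholded at 0.5).
#' @param name Structure name.
#' @param role One of `"PTV"`, `"OAR"`, `"body"`, `"bone"`, `"cavity"`.
#' @param spacing Voxel spacing in mm.
#' @return A `structure_mask` object.
#' @export
structure_mask <- function(voxels, name = "structure",
                           role = c("PTV", "OAR", "body", "bone", "cavity"),
                           spacing = c(1, 1, 1)) {
  role <- match.arg(role)
  voxels <- as.array(voxels)
  stopifnot(length(dim(voxels)) == 3L)
  if (!is.logical(voxels)) voxels <- voxels > 0.5
  structure(
    list(voxels = voxels, name = name, role = role, spacing = as.numeric(spacing)),
    class = "structure_mask"
  )
}

mask_voxels <- function(m) m$voxels
mask_spacing <- function(m) m$spacing

check_grid_mask <- function(grid, mask) {
  stopifnot(inherits(grid, "dose_grid"), inherits(mask, "structure_mask"))
  if (!identical(dim(grid$values), dim(mask$voxels))) {
    stop(sprintf(
      "geometry mismatch: grid is %s, mask '%s' is %s",
      paste(dim(grid$values), collapse = "x"), mask$name,
      paste(dim(mask$voxels), collapse = "x")
    ), call. = FALSE)
  }
  if (!isTRUE(all.equal(grid$spacing, mask$spacing))) {
    stop(sprintf(
      "spacing mismatch: grid (%s) mm vs mask '%s' (%s) mm",
      paste(grid$spacing, collapse = ", "), mask$name,
      paste(mask$spacing, collapse = ", ")
    ), call. = FALSE)
  }
  if (!any(mask$voxels)) stop(sprintf("mask '%s' is empty", mask$name), call. = FALSE)
  invisible(TRUE)
}

#' Cumulative dose-volume histogram
#'
#' Exact empirical cumulative DVH of the doses inside a structure: for each
#' distinct in-mask dose, the fraction of structure volume receiving at
#' least that dose. No binning or smoothing is applied, so every DVH point
#' extracted from the curve is an exact order statistic of the voxel dose
#' multiset.
#'
#' @param grid A [dose_grid()].
#' @param mask A [structure_mask()] aligned to `grid`, non-empty.
#' @return A `dvh_curve`: tibble with columns `dose` (ascending distinct Gy),
#'   `n_ge` (voxels receiving >= dose), `frac_ge` (volume fraction), and
#'   attributes `n_voxels`, `voxel_volume_cm3`, `mean_dose`, `structure`,
#'   `modality`.
#' @export
#' @examples
#' g <- dose_grid(array(runif(64, 50, 70), c(4, 4, 4)))
#' m <- structure_mask(array(TRUE, c(4, 4, 4)), "PTV", "PTV")
#' cumulative_dvh(g, m)
cumulative_dvh <- function(grid, mask) {
  check_grid_mask(grid, mask)
  doses <- grid$values[mask$voxels]
  n <- length(doses)
  tab <- sort(unique(doses))
  # voxels receiving >= d for each distinct d: n minus count strictly below d
  counts <- tabulate(match(doses, tab), nbins = length(tab))
  n_lt <- cumsum(c(0, counts[-length(counts)]))
  n_ge <- n - n_lt
  curve <- tibble::tibble(dose = tab, n_ge = n_ge, frac_ge = n_ge / n)
  structure(
    curve,
    n_voxels = n,
    voxel_volume_cm3 = prod(grid$spacing) / 1000,
    mean_dose = mean(doses),
    max_dose = max(doses),
    structure = mask$name,
    modality = grid$modality,
    class = c("dvh_curve", class(curve))
  )
}

#' Extract a DVH point from a cumulative DVH
#'
#' Implements the ICRU 83 style point metrics on the exact empirical curve:
#' \describe{
#'   \item{`D_percent`}{D_x\%: the smallest dose d such that the fraction of
#'     volume receiving >= d is <= x/100 — the minimum dose within the
#'     hottest x\% of the structure. `D_median` is `D_percent` at x = 50.}
#'   \item{`D_cm3`}{D_x cm3: as `D_percent` with x = 100 * volume / structure
#'     volume.}
#'   \item{`D_mean`, `D_max`}{arithmetic mean / maximum in-mask dose.}
#'   \item{`V_dose`}{V_x Gy: percentage of structure volume receiving at
#'     least x Gy.}
#' }
#' An optional linear-interpolation mode evaluates D_x\% by interpolating
#' the cumulative curve, for comparison with commercial systems that report
#' interpolated DVH points; the exact voxel-counting rule is the default.
#'
#' @param curve A `dvh_curve` from [cumulative_dvh()].
#' @param kind One of `"D_percent"`, `"D_cm3"`, `"D_median"`, `"D_mean"`,
#'   `"D_max"`, `"V_dose"`.
#' @param parameter Percent volume (`D_percent`), cm3 (`D_cm3`), or Gy
#'   (`V_dose`); unused otherwise.
#' @param interpolate Use linear interpolation for D_x\% instead of the exact
#'   empirical quantile.
#' @return Dose in Gy for D-type points; percent volume for `V_dose`.
#' @export
#' @examples
#' g <- dose_grid(array(1:10, c(10, 1, 1)))
#' m <- structure_mask(array(TRUE, c(10, 1, 1)), role = "PTV")
#' cv <- cumulative_dvh(g, m)
#' dvh_point(cv, "D_percent", 2)  # near-maximum dose D2%
#' dvh_point(cv, "V_dose", 7)     # 40: four of ten voxels receive >= 7 Gy
dvh_point <- function(curve, kind, parameter = NULL, interpolate = FALSE) {
  stopifnot(inherits(curve, "dvh_curve"))
  kind <- match.arg(kind, c("D_percent", "D_cm3", "D_median", "D_mean", "D_max", "V_dose"))
  vol_cm3 <- attr(curve, "n_voxels") * attr(curve, "voxel_volume_cm3")
  if (kind == "D_median") {
    kind <- "D_percent"
    parameter <- 50
  }
  if (kind == "D_cm3") {
    stopifnot(is.numeric(parameter), parameter > 0)
    if (parameter > vol_cm3) {
      stop(sprintf("requested %.3g cm3 exceeds structure volume %.3g cm3",
                   parameter, vol_cm3), call. = FALSE)
    }
    kind <- "D_percent"
    parameter <- 100 * parameter / vol_cm3
  }
  switch(kind,
    D_percent = {
      stopifnot(is.numeric(parameter), parameter > 0, parameter <= 100)
      if (interpolate) {
        d_percent_interpolated(curve, parameter)
      } else {
        # smallest dose whose exceedance fraction is <= x/100; when x spans
        # less than one voxel the hottest-x% set is the hottest voxel itself
        ok <- curve$frac_ge <= parameter / 100 + 1e-12
        if (any(ok)) min(curve$dose[ok]) else attr(curve, "max_dose")
      }
    },
    D_mean = attr(curve, "mean_dose"),
    D_max = attr(curve, "max_dose"),
    V_dose = {
      stopifnot(is.numeric(parameter), parameter > 0)
      n <- attr(curve, "n_voxels")
      # voxels receiving >= parameter: first tabulated dose at or above it
      i <- which(curve$dose >= parameter)
      100 * (if (length(i)) curve$n_ge[min(i)] else 0L) / n
    }
  )
}

d_percent_interpolated <- function(curve, x) {
  f <- x / 100
  if (f >= curve$frac_ge[1]) return(curve$dose[1])
  if (f <= curve$frac_ge[nrow(curve)]) return(curve$dose[nrow(curve)])
  stats::approx(rev(curve$frac_ge), rev(curve$dose), xout = f, ties = "ordered")$y
}

#' Parse a DVH point label
#'
#' Converts labels of the form used in clinical protocols — `"D_2%"`,
#' `"D_98%"`, `"D_median"`, `"D_mean"`, `"D_max"`, `"D_2cm3"`, `"V_40Gy"` —
#' into the (kind, parameter) pair consumed by [dvh_point()].
#'
#' @param label Character label.
#' @return List with `kind` and `parameter`.
#' @export
parse_dvh_point <- function(label) {
  if (label %in% c("D_median", "D_mean", "D_max")) {
    return(list(kind = label, parameter = NULL))
  }
  m <- regmatches(label, regexec("^D_([0-9.]+)%$", label))[[1]]
  if (length(m)) return(list(kind = "D_percent", parameter = as.numeric(m[2])))
  m <- regmatches(label, regexec("^D_([0-9.]+)cm3$", label))[[1]]
  if (length(m)) return(list(kind = "D_cm3", parameter = as.numeric(m[2])))
  m <- regmatches(label, regexec("^V_([0-9.]+)Gy$", label))[[1]]
  if (length(m)) return(list(kind = "V_dose", parameter = as.numeric(m[2])))
  stop(sprintf("cannot parse DVH point label '%s'", label), call. = FALSE)
}

#' Extract DVH points for a patient cohort
#'
#' Runs the DVH engine over every patient, structure and modality and
#' returns the long-format cohort table that feeds the statistical analysis.
#'
#' @param patients A list, one element per patient, each a list with
#'   `patient_id`, `diagnosis`, `grids` (named list of [dose_grid()]s, must
#'   include `"CT"`), and `masks` (named list of [structure_mask()]s keyed by
#'   structure name).
#' @param points Character vector of DVH point labels (see
#'   [parse_dvh_point()]), or a named list mapping structure name to its
#'   label vector.
#' @param interpolate Passed to [dvh_point()].
#' @return A tibble with columns `patient_id`, `diagnosis`, `structure`,
#'   `dvh_point`, `modality`, `value`, `unit`, ordered deterministically.
#' @export
extract_cohort <- function(patients, points, interpolate = FALSE) {
  rows <- purrr::map(patients, function(p) {
    stopifnot(!is.null(p$grids), !is.null(p$masks))
    if (!"CT" %in% names(p$grids)) {
      stop(sprintf("patient '%s' has no CT grid", p$patient_id), call. = FALSE)
    }
    purrr::imap(p$masks, function(mask, sname) {
      labels <- if (is.list(points)) points[[sname]] else points
      if (is.null(labels)) return(NULL)
      purrr::imap(p$grids, function(grid, mod) {
        cv <- cumulative_dvh(grid, mask)
        purrr::map(labels, function(lb) {
          spec <- parse_dvh_point(lb)
          tibble::tibble(
            patient_id = p$patient_id,
            diagnosis = p$diagnosis %||% NA_character_,
            structure = sname,
            dvh_point = lb,
            modality = mod,
            value = dvh_point(cv, spec$kind, spec$parameter, interpolate = interpolate),
            unit = if (spec$kind == "V_dose") "%" else "Gy"
          )
        })
      })
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(purrr::flatten(purrr::flatten(rows))))
  dplyr::arrange(out, .data$patient_id, .data$structure, .data$dvh_point, .data$modality)
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf(
    "<dose_grid %s> %s voxels, spacing (%s) mm, dose range [%.3g, %.3g] Gy\n",
    x$modality, paste(dim(x$values), collapse = "x"),
    paste(x$spacing, collapse = ", "), min(x$values), max(x$values)
  ))
  invisible(x)
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf(
    "<structure_mask '%s' (%s)> %s voxels, %d in mask\n",
    x$name, x$role, paste(dim(x$voxels), collapse = "x"), sum(x$voxels)
  ))
  invisible(x)
}
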