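#' Read and write dose grids and structure masks as NIfTI
#'
#' Dose grids and masks are stored one volume per file in NIfTI format, with
#' voxel spacing carried in the header (`pixdim`, mm). Mask files holding
#' non-boolean payloads are thresholded at 0.5 with a warning unless the
#' stored values are already exactly 0/1.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param grid A [dose_grid()] (for writing).
#' @param modality Modality label to attach on read.
#' @param reference Optional [dose_grid()] whose geometry the file must
#'   match; a mismatch is an error naming both geometries.
#' @return `read_dose_grid` returns a [dose_grid()]; `write_dose_grid`
#'   returns `path` invisibly.
#' @name raster_io
NULL

#' @rdname raster_io
#' @export
write_dose_grid <- function(grid, path) {
  stopifnot(inherits(grid, "dose_grid"))
  img <- RNifti::asNifti(grid$values)
  RNifti::pixdim(img) <- grid$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname raster_io
#' @export
read_dose_grid <- function(path, modality = "CT", reference = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim = dim(img))
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  g <- dose_grid(vals, spacing = spacing, modality = modality)
  if (!is.null(reference)) {
    if (!identical(dim(g$values), dim(reference$values))) {
      stop(sprintf("geometry mismatch: file %s is %s, reference is %s",
                   path, paste(dim(g$values), collapse = "x"),
                   paste(dim(reference$values), collapse = "x")), call. = FALSE)
    }
    if (!isTRUE(all.equal(g$spacing, reference$spacing, tolerance = 1e-6))) {
      stop(sprintf("spacing mismatch: file %s has (%s) mm, reference (%s) mm",
                   path, paste(signif(g$spacing, 6), collapse = ", "),
                   paste(signif(reference$spacing, 6), collapse = ", ")),
           call. = FALSE)
    }
  }
  g
}

#' @rdname raster_io
#' @param name,role Passed to [structure_mask()] on read.
#' @export
read_structure_mask <- function(path, name = "structure", role = "OAR",
                                reference = NULL) {
  g <- read_dose_grid(path, modality = "CT", reference = reference)
  vals <- g$values
  if (!all(vals %in% c(0, 1))) {
    warning(sprintf("mask file %s holds non-boolean values; thresholding at 0.5", path),
            call. = FALSE)
  }
  structure_mask(vals > 0.5, name = name, role = role, spacing = g$spacing)
}

#' @rdname raster_io
#' @param mask A [structure_mask()] (for writing).
#' @export
write_structure_mask <- function(mask, path) {
  stopifnot(inherits(mask, "structure_mask"))
  img <- RNifti::asNifti(array(as.numeric(mask$voxels), dim = dim(mask$voxels)))
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

cohort_schema <- c("patient_id", "diagnosis", "structure", "dvh_point",
                   "modality", "value", "unit")

#' Read a cohort DVH-point table from CSV
#'
#' The long cohort schema: one row per patient x structure x DVH point x
#' modality, with columns `patient_id`, `diagnosis`, `structure`,
#' `dvh_point`, `modality`, `value`, `unit`. Duplicate keys are an error
#' listing the offending rows.
#'
#' @param path CSV file path.
#' @return Cohort tibble.
#' @export
read_cohort_csv <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(setdiff(cohort_schema, "unit"), names(tab))
  if (length(missing)) {
    stop("cohort CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dup <- tab |>
    dplyr::count(.data$patient_id, .data$structure, .data$dvh_point,
                 .data$modality) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    stop("duplicate (patient, structure, DVH point, modality) keys:\n",
         paste(utils::capture.output(print(as.data.frame(dup))), collapse = "\n"),
         call. = FALSE)
  }
  tab
}

#' @rdname read_cohort_csv
#' @param cohort Cohort tibble.
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' Write analysis results to a directory
#'
#' Emits the machine-readable outputs of a cohort analysis: `summaries.csv`
#' (with the formatted "mean ± 2SD" labels), `anova.csv`, `tukey.csv`,
#' `decisions.csv` (the criterion decision matrix), and `provenance.json`
#' recording the criterion settings, seed, package version and a hash of the
#' input table so a run can be reproduced exactly.
#'
#' @param analysis A `cohort_analysis` from [analyze_cohort()].
#' @param dir Output directory (created if needed).
#' @param spec A [criterion_spec()] used for the decision matrix.
#' @param seed Seed to record in the provenance block (optional).
#' @param cohort The input cohort table (optional, hashed into provenance).
#' @return `dir`, invisibly.
#' @export
write_results <- function(analysis, dir, spec = criterion_spec(),
                          seed = NULL, cohort = NULL) {
  stopifnot(inherits(analysis, "cohort_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(analysis$summaries, file.path(dir, "summaries.csv"))
  readr::write_csv(analysis$anova, file.path(dir, "anova.csv"))
  if (nrow(analysis$tukey) > 0L) {
    readr::write_csv(analysis$tukey, file.path(dir, "tukey.csv"))
  }
  dec <- decision_matrix(analysis$summaries, spec)
  readr::write_csv(dec, file.path(dir, "decisions.csv"))
  prov <- list(
    package = "mridose",
    version = as.character(utils::packageVersion("mridose")),
    seed = seed,
    criterion = list(tolerance = spec$tolerance, coverage = spec$coverage,
                     interval_rule = spec$interval_rule),
    alpha = analysis$alpha,
    input_hash = if (!is.null(cohort)) {
      rlang::hash(cohort)
    } else NULL,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(dir)
}
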