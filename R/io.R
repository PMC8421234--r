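cohort_columns <- c("id", "gender", "age", "t_stage", "n_stage",
                    "clinical_stage", "chemotherapy", "volume_cc",
                    "dmin_gy", "dmax_gy", "dmean_gy", "fx_dose_gy",
                    paste0("v", c(10, 20, 30, 40, 45, 50, 60, 70)),
                    "outcome_12m")

#' Read and write cohort tables
#'
#' The cohort CSV schema (version 1) has one row per patient and columns
#' `id`, `gender` (0 = male, 1 = female), `age` (years), `t_stage` (1-4),
#' `n_stage` (0-3), `clinical_stage` (1-4), `chemotherapy` (0/1),
#' `volume_cc`, `dmin_gy`, `dmax_gy`, `dmean_gy`, `fx_dose_gy`,
#' `v10`..`v70` (percent), `outcome_12m` (0/1 hypothyroidism at 12 months).
#' Units are fixed package-wide: Gy, cc, years. Reading validates the
#' schema and reports the offending column and row on failure;
#' `read_cohort(write_cohort(x))` returns `x` up to numeric formatting.
#'
#' @param path CSV file path.
#' @return `read_cohort`: a validated cohort data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  coh <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(coh)
  coh
}

#' @rdname read_cohort
#' @param cohort a cohort data frame conforming to the schema.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(cohort[, cohort_columns], path, row.names = FALSE)
  invisible(path)
}

validate_cohort <- function(cohort) {
  check_cohort(cohort, cohort_columns)
  if (anyDuplicated(cohort$id))
    stop("duplicate patient ids", call. = FALSE)
  check_col <- function(col, ok, what) {
    bad <- which(!ok(cohort[[col]]))
    if (length(bad))
      stop(sprintf("column '%s': %s (first offending row: %d)",
                   col, what, bad[1]), call. = FALSE)
  }
  check_col("outcome_12m", function(v) !is.na(v) & v %in% c(0, 1),
            "outcome must be 0 or 1")
  check_col("volume_cc", function(v) !is.na(v) & v > 0,
            "volume must be > 0 cc")
  check_col("age", function(v) !is.na(v) & v > 0, "age must be > 0")
  for (col in c("dmin_gy", "dmax_gy", "dmean_gy", "fx_dose_gy"))
    check_col(col, function(v) !is.na(v) & v >= 0, "dose must be >= 0 Gy")
  for (col in paste0("v", c(10, 20, 30, 40, 45, 50, 60, 70)))
    check_col(col, function(v) !is.na(v) & v >= 0 & v <= 100,
              "Vx must be a percentage in [0, 100]")
  invisible(TRUE)
}

#' Read and write NTCP model parameter files
#'
#' JSON with fields `b0`, `b_dmean`, `b_volume` and a free-form `metadata`
#' object (e.g. `alpha_beta`, `endpoint`, `units`).
#'
#' @param path JSON file path.
#' @return `read_model`: an [ntcp_model()] (metadata attached as attribute
#'   `metadata`).
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("b0", "b_dmean", "b_volume")
  if (!all(need %in% names(obj)))
    stop("model file must contain fields: ", paste(need, collapse = ", "),
         call. = FALSE)
  m <- ntcp_model(obj$b0, obj$b_dmean, obj$b_volume)
  attr(m, "metadata") <- obj$metadata
  m
}

#' @rdname read_model
#' @param model an [ntcp_model()].
#' @param metadata optional named list stored alongside the coefficients.
#' @export
write_model <- function(model, path, metadata = NULL) {
  stopifnot(inherits(model, "ntcp_model"))
  obj <- list(b0 = model$b0, b_dmean = model$b_dmean,
              b_volume = model$b_volume)
  if (!is.null(metadata)) obj$metadata <- metadata
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write dose grids
#'
#' Stores a [dose_grid()] as two files sharing a basename: `<path>.json`, a
#' sidecar header `{shape, spacing_mm, origin_mm, dose_kind}`, and
#' `<path>.bin`, the voxel values as little-endian float64 in column-major
#' order. Values round-trip at machine precision. A [structure_mask()] can
#' be round-tripped as a 0/1 grid via `structure_mask(grid$values)`.
#'
#' @param path basename (without extension) for the pair of files.
#' @return `read_grid`: a [dose_grid()].
#' @export
read_grid <- function(path) {
  hdr_path <- paste0(path, ".json")
  bin_path <- paste0(path, ".bin")
  if (!file.exists(hdr_path) || !file.exists(bin_path))
    stop("grid files not found: ", hdr_path, " / ", bin_path, call. = FALSE)
  hdr <- jsonlite::read_json(hdr_path, simplifyVector = TRUE)
  shape <- as.integer(hdr$shape)
  vals <- readBin(bin_path, what = "double", n = prod(shape), size = 8,
                  endian = "little")
  if (length(vals) != prod(shape))
    stop("grid binary has ", length(vals), " values, header promises ",
         prod(shape), call. = FALSE)
  dose_grid(array(vals, dim = shape), spacing = hdr$spacing_mm,
            origin = hdr$origin_mm, dose_kind = hdr$dose_kind)
}

#' @rdname read_grid
#' @param grid a [dose_grid()].
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "dose_grid"))
  jsonlite::write_json(
    list(shape = dim(grid$values), spacing_mm = grid$spacing,
         origin_mm = grid$origin, dose_kind = grid$dose_kind),
    paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  writeBin(as.vector(grid$values), paste0(path, ".bin"), size = 8,
           endian = "little")
  invisible(path)
}
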