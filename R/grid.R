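#' Dose grid
#'
#' A 3-D lattice of per-voxel absorbed dose together with its geometry.
#' Doses are in Gy, voxel spacing and origin in mm. `dose_kind` records
#' whether the values are physical dose or equivalent dose in 2 Gy
#' fractions (EQD2); [convert_to_eqd2()] refuses to convert a grid twice.
#'
#' Voxel indices are 0-based and physical coordinates refer to voxel
#' centers: the center of voxel `(i, j, k)` is `origin + c(i, j, k) * spacing`.
#'
#' @param values numeric 3-D array of per-voxel dose (Gy); finite, >= 0.
#' @param spacing numeric length-3 voxel size per axis (mm); all > 0.
#' @param origin numeric length-3 physical coordinate of the first voxel
#'   center (mm).
#' @param dose_kind `"physical"` or `"eqd2"`.
#' @return An object of class `dose_grid`.
#' @seealso [structure_mask()], [convert_to_eqd2()], [dose_metrics()]
#' @export
#' @examples
#' g <- dose_grid(array(44, c(4, 4, 4)))
#' g
dose_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      dose_kind = c("physical", "eqd2")) {
  dose_kind <- match.arg(dose_kind)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array", call. = FALSE)
  if (length(values) == 0L)
    stop("dose grid must be non-empty", call. = FALSE)
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values)))
    stop("all dose values must be finite numbers", call. = FALSE)
  if (any(values < 0))
    stop("dose values must be >= 0 Gy", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive voxel sizes (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite coordinates (mm)", call. = FALSE)
  structure(
    list(values = values, spacing = spacing, origin = origin,
         dose_kind = dose_kind),
    class = "dose_grid"
  )
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf(
    "Dose grid (%s): %s voxels, spacing %s mm, dose %.2f-%.2f Gy\n",
    x$dose_kind, paste(dim(x$values), collapse = " x "),
    paste(format(x$spacing, trim = TRUE), collapse = " x "),
    min(x$values), max(x$values)))
  invisible(x)
}

#' Binary structure mask
#'
#' Marks the voxels of a congruent [dose_grid()] that belong to one
#' anatomical structure (here typically the thyroid gland).
#'
#' @param include logical 3-D array; `TRUE` for voxels inside the structure.
#'   At least one voxel must be included.
#' @param name label for the structure.
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(include, name = "structure") {
  if (is.numeric(include)) include <- array(include > 0.5, dim = dim(include))
  if (!is.array(include) || length(dim(include)) != 3L || !is.logical(include))
    stop("`include` must be a logical 3-D array", call. = FALSE)
  if (anyNA(include))
    stop("mask must not contain NA", call. = FALSE)
  if (!any(include))
    stop("mask must include at least one voxel", call. = FALSE)
  structure(list(include = include, name = as.character(name)[1]),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("Structure mask '%s': %d of %d voxels included\n",
              x$name, sum(x$include), length(x$include)))
  invisible(x)
}

#' Structure volume in cubic centimeters
#'
#' @param mask a [structure_mask()].
#' @param grid the congruent [dose_grid()] supplying the voxel geometry.
#' @return Volume in cc (`#voxels * voxel volume mm^3 / 1000`).
#' @export
volume_cc <- function(mask, grid) {
  check_congruent(grid, mask)
  sum(mask$include) * prod(grid$spacing) / 1000
}

check_congruent <- function(grid, mask) {
  stopifnot(inherits(grid, "dose_grid"), inherits(mask, "structure_mask"))
  if (!identical(dim(grid$values), dim(mask$include)))
    stop("mask and dose grid have different lattice shapes", call. = FALSE)
  invisible(TRUE)
}
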