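#' Cumulative dose-volume histogram
#'
#' Cumulative DVH of a structure: at each dose edge `x`, the percentage of
#' the structure's voxels receiving at least `x` Gy. Edges run from 0 to the
#' first multiple of `bin_width` at or above the structure's maximum dose,
#' so the curve starts at 100% and is monotone non-increasing.
#'
#' @param grid a [dose_grid()].
#' @param mask a congruent [structure_mask()].
#' @param bin_width dose bin width in Gy (> 0); default 0.1 Gy.
#' @return A data frame of class `dvh_curve` with columns `dose_gy` and
#'   `cum_volume_pct`.
#' @export
cumulative_dvh <- function(grid, mask, bin_width = 0.1) {
  check_congruent(grid, mask)
  if (!is.numeric(bin_width) || length(bin_width) != 1L ||
      !is.finite(bin_width) || bin_width <= 0)
    stop("`bin_width` must be a single positive dose (Gy)", call. = FALSE)
  doses <- grid$values[mask$include]
  dmax <- max(doses)
  edges <- seq(0, ceiling(dmax / bin_width) * bin_width, by = bin_width)
  # count-at-or-above via one sort + findInterval: O((V + bins) log V)
  srt <- sort(doses)
  n <- length(srt)
  at_or_above <- n - findInterval(edges, srt, left.open = TRUE)
  out <- data.frame(dose_gy = edges,
                    cum_volume_pct = 100 * at_or_above / n)
  class(out) <- c("dvh_curve", "data.frame")
  out
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("Cumulative DVH: %d edges, 0-%.2f Gy\n",
              nrow(x), max(x$dose_gy)))
  NextMethod()
}

#' Dose-volume metrics for a structure
#'
#' Computes the summary dose metrics used in thyroid NTCP modelling:
#' minimum, maximum and mean dose over the masked voxels (exact, unbinned),
#' the relative volumes Vx receiving at least x Gy (inclusive threshold,
#' the usual DVH convention), the structure volume in cc, and the
#' fractionated dose, defined as mean dose divided by the fraction count.
#' The fractionated dose is the physical mean dose per fraction when the
#' grid passed in holds physical dose.
#'
#' @param grid a [dose_grid()] (physical or EQD2).
#' @param mask a congruent [structure_mask()].
#' @param n_fractions number of treatment fractions.
#' @param vx_levels dose levels x (Gy) at which Vx is reported; default
#'   10, 20, 30, 40, 45, 50, 60, 70 Gy.
#' @return An object of class `dose_metrics`: a list with elements
#'   `d_min`, `d_max`, `d_mean`, `fractionated_dose` (Gy), `vx` (named
#'   percentage vector), `volume_cc`, and `dose_kind`.
#' @export
#' @examples
#' g <- dose_grid(array(45, c(4, 4, 4)), dose_kind = "eqd2")
#' m <- structure_mask(array(TRUE, c(4, 4, 4)), "thyroid")
#' dose_metrics(g, m, n_fractions = 30)
dose_metrics <- function(grid, mask, n_fractions,
                         vx_levels = c(10, 20, 30, 40, 45, 50, 60, 70)) {
  check_congruent(grid, mask)
  n_fractions <- check_fractions(n_fractions)
  doses <- grid$values[mask$include]
  vx <- vapply(vx_levels, function(x) 100 * mean(doses >= x), numeric(1))
  names(vx) <- paste0("v", vx_levels)
  structure(
    list(d_min = min(doses), d_max = max(doses), d_mean = mean(doses),
         fractionated_dose = mean(doses) / n_fractions,
         vx = vx, volume_cc = volume_cc(mask, grid),
         dose_kind = grid$dose_kind),
    class = "dose_metrics"
  )
}

#' @export
print.dose_metrics <- function(x, ...) {
  cat(sprintf("Dose metrics (%s), volume %.2f cc\n", x$dose_kind,
              x$volume_cc))
  cat(sprintf("  Dmin %.2f  Dmean %.2f  Dmax %.2f Gy, %.2f Gy/fraction\n",
              x$d_min, x$d_mean, x$d_max, x$fractionated_dose))
  cat("  ", paste(sprintf("%s=%.1f%%", toupper(names(x$vx)), x$vx),
                  collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.dose_metrics <- function(x, ...) {
  out <- data.frame(dmin_gy = x$d_min, dmax_gy = x$d_max,
                    dmean_gy = x$d_mean, fx_dose_gy = x$fractionated_dose,
                    volume_cc = x$volume_cc)
  vx <- as.data.frame(as.list(x$vx))
  cbind(out, vx)
}

#' Write a DVH curve to CSV
#'
#' @param dvh a `dvh_curve` from [cumulative_dvh()].
#' @param path output CSV path (columns `dose_gy`, `cum_volume_pct`).
#' @export
write_dvh <- function(dvh, path) {
  stopifnot(inherits(dvh, "dvh_curve"))
  utils::write.csv(as.data.frame(dvh), path, row.names = FALSE)
  invisible(path)
}
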