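#' Equivalent dose in 2 Gy fractions (EQD2)
#'
#' Converts a total dose `D` delivered in fractions of size `d` to the dose
#' that would produce the same biological effect if given at 2 Gy per
#' fraction, under the linear-quadratic model:
#' \deqn{EQD2 = D \frac{d + \alpha/\beta}{2 + \alpha/\beta}}
#'
#' The thyroid is a late-reacting tissue; the conventional
#' \eqn{\alpha/\beta} for it is 3 Gy, the default here. At `fraction_dose = 2`
#' the conversion is the identity for any \eqn{\alpha/\beta}.
#'
#' @param total_dose total physical dose D (Gy), >= 0; vectorized.
#' @param fraction_dose dose per fraction d (Gy), >= 0; vectorized.
#' @param alpha_beta linear-quadratic \eqn{\alpha/\beta} ratio (Gy), > 0.
#' @return EQD2 in Gy.
#' @export
#' @examples
#' eqd2(50, 2)        # 2 Gy/fraction: unchanged
#' eqd2(60, 1.5)      # hypofractionated organ-at-risk dose: 54 Gy
eqd2 <- function(total_dose, fraction_dose, alpha_beta = 3) {
  if (!is.numeric(total_dose) || anyNA(total_dose) || any(total_dose < 0))
    stop("`total_dose` must be >= 0 Gy", call. = FALSE)
  if (!is.numeric(fraction_dose) || anyNA(fraction_dose) ||
      any(fraction_dose < 0))
    stop("`fraction_dose` must be >= 0 Gy", call. = FALSE)
  if (!is.numeric(alpha_beta) || length(alpha_beta) != 1L ||
      !is.finite(alpha_beta) || alpha_beta <= 0)
    stop("`alpha_beta` must be a single positive value (Gy)", call. = FALSE)
  # evaluate the ratio first so fraction_dose = 2 is the exact identity
  total_dose * ((fraction_dose + alpha_beta) / (2 + alpha_beta))
}

#' Voxel-wise EQD2 conversion of a physical dose grid
#'
#' Converts every voxel of a physical dose grid to EQD2, assuming the whole
#' course is delivered in `n_fractions` equal fractions so that the per-voxel
#' fraction dose is `D_v / n_fractions`. This matches simultaneous-boost
#' IMRT, where each voxel receives its own fraction size but the fraction
#' count is uniform. Geometry metadata is preserved; the result is marked
#' `dose_kind = "eqd2"` and cannot be converted again.
#'
#' @param grid a [dose_grid()] with `dose_kind = "physical"`.
#' @param n_fractions number of treatment fractions (integer >= 1).
#' @param alpha_beta \eqn{\alpha/\beta} ratio (Gy); default 3 Gy (thyroid).
#' @return A [dose_grid()] with `dose_kind = "eqd2"`.
#' @export
#' @examples
#' g <- dose_grid(array(44, c(3, 3, 3)))
#' convert_to_eqd2(g, n_fractions = 33)  # d = 1.33 Gy: EQD2 < physical
convert_to_eqd2 <- function(grid, n_fractions, alpha_beta = 3) {
  stopifnot(inherits(grid, "dose_grid"))
  if (grid$dose_kind != "physical")
    stop("grid is already EQD2; double conversion is forbidden",
         call. = FALSE)
  n_fractions <- check_fractions(n_fractions)
  out <- eqd2(grid$values, grid$values / n_fractions, alpha_beta)
  dose_grid(array(out, dim = dim(grid$values)),
            spacing = grid$spacing, origin = grid$origin, dose_kind = "eqd2")
}

check_fractions <- function(n_fractions) {
  if (!is.numeric(n_fractions) || length(n_fractions) != 1L ||
      !is.finite(n_fractions) || n_fractions < 1 ||
      n_fractions != round(n_fractions))
    stop("`n_fractions` must be a positive integer", call. = FALSE)
  as.integer(n_fractions)
}
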