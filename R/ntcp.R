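#' Logistic NTCP model for radiation-induced hypothyroidism
#'
#' Parameter object for the two-variable logistic ("mixture") NTCP model
#' \deqn{NTCP = (1 + e^{-S})^{-1}, \quad
#'       S = b_0 + b_{Dmean} \cdot Dmean + b_{vol} \cdot volume}
#' with the mean thyroid EQD2 dose in Gy and the thyroid volume in cc.
#' The defaults are the published coefficients for 12-month hypothyroidism
#' after neck IMRT: risk rises with mean dose (OR > 1 per Gy) and falls
#' with gland volume (OR < 1 per cc).
#'
#' @param b0 intercept on the log-odds scale.
#' @param b_dmean log-odds per Gy of mean thyroid EQD2 dose.
#' @param b_volume log-odds per cc of thyroid volume.
#' @return An object of class `ntcp_model`.
#' @seealso [ntcp()], [tolerance_dose()], [ntcp_curve()], [as_ntcp_model()]
#' @export
#' @examples
#' m <- published_ntcp_model()
#' ntcp(m, dmean = 41.79, volume = 16.60)
#' tolerance_dose(m, volume = 16.60, p = c(0.05, 0.10))
ntcp_model <- function(b0 = -1.385, b_dmean = 0.093, b_volume = -0.188) {
  co <- c(b0 = b0, b_dmean = b_dmean, b_volume = b_volume)
  if (!is.numeric(co) || any(!is.finite(co)))
    stop("all coefficients must be finite numbers", call. = FALSE)
  structure(list(b0 = b0, b_dmean = b_dmean, b_volume = b_volume),
            class = "ntcp_model")
}

#' @rdname ntcp_model
#' @export
published_ntcp_model <- function() ntcp_model()

#' @export
print.ntcp_model <- function(x, ...) {
  cat("Logistic NTCP model: NTCP = 1 / (1 + exp(-S))\n")
  cat(sprintf("  S = %.3f + (%.3f x Dmean[Gy]) + (%.3f x volume[cc])\n",
              x$b0, x$b_dmean, x$b_volume))
  cat(sprintf("  OR = %.3f per Gy, %.3f per cc\n",
              exp(x$b_dmean), exp(x$b_volume)))
  invisible(x)
}

#' @export
coef.ntcp_model <- function(object, ...) {
  c(b0 = object$b0, b_dmean = object$b_dmean, b_volume = object$b_volume)
}

check_dose_volume <- function(dmean, volume) {
  if (!is.numeric(dmean) || anyNA(dmean) || any(!is.finite(dmean)) ||
      any(dmean < 0))
    stop("`dmean` must be finite and >= 0 Gy", call. = FALSE)
  if (!is.numeric(volume) || anyNA(volume) || any(!is.finite(volume)) ||
      any(volume <= 0))
    stop("`volume` must be finite and > 0 cc", call. = FALSE)
  invisible(TRUE)
}

#' Linear predictor S of an NTCP model
#'
#' @param model an [ntcp_model()].
#' @param dmean mean thyroid EQD2 dose (Gy), >= 0; vectorized.
#' @param volume thyroid volume (cc), > 0; vectorized.
#' @return Log-odds `S = b0 + b_dmean * dmean + b_volume * volume`.
#' @export
linear_predictor <- function(model, dmean, volume) {
  stopifnot(inherits(model, "ntcp_model"))
  check_dose_volume(dmean, volume)
  model$b0 + model$b_dmean * dmean + model$b_volume * volume
}

#' Complication probability
#'
#' Evaluates `NTCP = 1 / (1 + exp(-S))`. Strictly increasing in `dmean` and
#' strictly decreasing in `volume` for the published coefficient signs.
#'
#' @inheritParams linear_predictor
#' @return Probability in (0, 1).
#' @export
ntcp <- function(model, dmean, volume) {
  stats::plogis(linear_predictor(model, dmean, volume))
}

#' @export
predict.ntcp_model <- function(object, dmean, volume,
                               type = c("response", "link"), ...) {
  type <- match.arg(type)
  s <- linear_predictor(object, dmean, volume)
  if (type == "link") s else stats::plogis(s)
}

#' Odds ratio from a logistic coefficient
#'
#' @param coefficient per-unit log-odds.
#' @param se optional standard error; when given, a Wald confidence interval
#'   `exp(coefficient +/- z * se)` is attached.
#' @param conf_level confidence level for the interval.
#' @return The odds ratio `exp(coefficient)`; with `se`, a named vector
#'   `c(odds_ratio, ci_low, ci_high)`.
#' @export
#' @examples
#' odds_ratio(-0.188)  # 0.829 per cc
#' odds_ratio(0.093)   # 1.097 per Gy
odds_ratio <- function(coefficient, se = NULL, conf_level = 0.95) {
  if (!is.numeric(coefficient) || length(coefficient) != 1L ||
      !is.finite(coefficient))
    stop("`coefficient` must be a single finite number", call. = FALSE)
  if (is.null(se)) return(exp(coefficient))
  if (!is.numeric(se) || length(se) != 1L || !is.finite(se) || se <= 0)
    stop("`se` must be a single positive number", call. = FALSE)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  c(odds_ratio = exp(coefficient), ci_low = exp(coefficient - z * se),
    ci_high = exp(coefficient + z * se))
}

#' Tolerance dose for a target complication probability
#'
#' Closed-form inversion of the NTCP model: the mean thyroid EQD2 dose at
#' which a gland of the given volume reaches complication probability `p`,
#' \deqn{Dmean = (logit(p) - b_0 - b_{vol} \cdot volume) / b_{Dmean}.}
#' `tolerance_dose(model, V, p)` and `ntcp(model, ., V)` are exact inverses.
#' TD5/1 and TD10/1 in the hypothyroidism literature are `p = 0.05` and
#' `p = 0.10` at the 12-month endpoint.
#'
#' A mathematically negative dose (very small `p` and/or large volume) is
#' returned as-is with a warning and attribute `extrapolated`: the model is
#' being evaluated outside any physically reachable regime.
#'
#' @param model an [ntcp_model()] with `b_dmean != 0`.
#' @param volume thyroid volume (cc).
#' @param p target complication probability in (0, 1); vectorized.
#' @return Dmean in Gy (vector along `p`).
#' @export
tolerance_dose <- function(model, volume, p) {
  stopifnot(inherits(model, "ntcp_model"))
  check_dose_volume(0, volume)
  if (!is.numeric(p) || anyNA(p) || any(p <= 0) || any(p >= 1))
    stop("`p` must be in (0, 1)", call. = FALSE)
  if (model$b_dmean == 0)
    stop("tolerance dose undefined: b_dmean is 0", call. = FALSE)
  d <- (stats::qlogis(p) - model$b0 - model$b_volume * volume) / model$b_dmean
  if (any(d < 0)) {
    warning("tolerance dose is negative: extrapolation outside the ",
            "physical dose range", call. = FALSE)
    attr(d, "extrapolated") <- d < 0
  }
  d
}

#' NTCP-versus-dose curves at fixed volumes
#'
#' Tabulates NTCP over a dose range for one or more thyroid volumes. With a
#' negative volume coefficient the curves are strictly ordered: at every
#' dose, a smaller gland has the higher complication probability.
#'
#' @param model an [ntcp_model()].
#' @param volumes thyroid volumes (cc); default the 10/15/20/25 cc levels
#'   conventionally plotted.
#' @param dose_range `c(lo, hi)` in Gy, `lo < hi`.
#' @param step dose step in Gy (> 0).
#' @return A data frame of class `ntcp_curve` with columns `dose_gy`,
#'   `volume_cc`, `ntcp`.
#' @export
ntcp_curve <- function(model, volumes = c(10, 15, 20, 25),
                       dose_range = c(0, 60), step = 0.5) {
  stopifnot(inherits(model, "ntcp_model"))
  if (length(dose_range) != 2L || !all(is.finite(dose_range)) ||
      dose_range[1] >= dose_range[2])
    stop("`dose_range` must be c(lo, hi) with lo < hi", call. = FALSE)
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("`step` must be a positive dose (Gy)", call. = FALSE)
  doses <- seq(dose_range[1], dose_range[2], by = step)
  out <- do.call(rbind, lapply(volumes, function(v) {
    data.frame(dose_gy = doses, volume_cc = v,
               ntcp = ntcp(model, doses, v))
  }))
  class(out) <- c("ntcp_curve", "data.frame")
  out
}

#' @export
plot.ntcp_curve <- function(x, ...) {
  vols <- sort(unique(x$volume_cc))
  cols <- grDevices::hcl.colors(max(length(vols), 2), "Dark 2")
  graphics::plot(NA, xlim = range(x$dose_gy), ylim = c(0, 1),
                 xlab = "Mean thyroid EQD2 dose (Gy)", ylab = "NTCP", ...)
  for (i in seq_along(vols)) {
    sub <- x[x$volume_cc == vols[i], ]
    graphics::lines(sub$dose_gy, sub$ntcp, col = cols[i], lwd = 2)
  }
  graphics::legend("topleft", legend = sprintf("%g cc", vols),
                   col = cols[seq_along(vols)], lwd = 2, bty = "n")
  invisible(x)
}

#' @export
plot.ntcp_model <- function(x, volumes = c(10, 15, 20, 25),
                            dose_range = c(0, 60), step = 0.5, ...) {
  plot(ntcp_curve(x, volumes, dose_range, step), ...)
}

#' Extract an NTCP parameter object from a fitted cohort model
#'
#' Maps a fitted [ntcp_fit()] with terms `dmean` and `volume` (cohort
#' columns `dmean_gy`, `volume_cc`) onto an [ntcp_model()].
#'
#' @param fit an [ntcp_fit()] whose covariates are exactly the mean-dose and
#'   volume columns.
#' @param dmean_col,volume_col coefficient names to map.
#' @return An [ntcp_model()].
#' @export
as_ntcp_model <- function(fit, dmean_col = "dmean_gy",
                          volume_col = "volume_cc") {
  cf <- coef(fit)
  need <- c("(Intercept)", dmean_col, volume_col)
  if (!all(need %in% names(cf)))
    stop("fit must contain coefficients: ", paste(need, collapse = ", "),
         call. = FALSE)
  ntcp_model(b0 = unname(cf["(Intercept)"]),
             b_dmean = unname(cf[dmean_col]),
             b_volume = unname(cf[volume_col]))
}
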