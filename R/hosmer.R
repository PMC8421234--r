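#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Deciles-of-risk calibration test: subjects are grouped by quantiles of
#' predicted probability (ties kept together), and the statistic
#' \deqn{\chi^2 = \sum_g \frac{(O_g - E_g)^2}{E_g (1 - E_g/n_g)}}
#' is referred to a chi-square distribution with `g - 2` degrees of freedom,
#' the reference appropriate when the probabilities come from a logistic
#' model fitted to the same data.
#'
#' When there are fewer distinct predicted values than requested groups the
#' grouping is reduced with a warning; if fewer than 3 groups remain the
#' statistic is returned with `p_value = NA` (calibration cannot be
#' assessed).
#'
#' @param predicted predicted probabilities in (0, 1).
#' @param observed binary outcomes (0/1), same length.
#' @param n_groups requested number of risk groups (>= 3); default 10.
#' @return An object of class `hosmer_lemeshow`: list with `statistic`,
#'   `df`, `p_value`, `n_groups` (after any reduction), and `table`
#'   (per-group `n`, `observed`, `expected`).
#' @export
hosmer_lemeshow <- function(predicted, observed, n_groups = 10L) {
  if (!is.numeric(predicted) || anyNA(predicted) ||
      any(predicted <= 0 | predicted >= 1))
    stop("`predicted` must be probabilities strictly in (0, 1)",
         call. = FALSE)
  observed <- as.numeric(observed)
  if (anyNA(observed) || !all(observed %in% c(0, 1)))
    stop("`observed` must be binary 0/1", call. = FALSE)
  if (length(predicted) != length(observed))
    stop("`predicted` and `observed` must have equal length", call. = FALSE)
  if (!is.numeric(n_groups) || length(n_groups) != 1L || n_groups < 3)
    stop("`n_groups` must be >= 3", call. = FALSE)
  n_groups <- as.integer(n_groups)

  br <- unique(stats::quantile(predicted,
                               probs = seq(0, 1, length.out = n_groups + 1)))
  g <- length(br) - 1L
  if (g < n_groups)
    warning(sprintf(
      "only %d distinct risk group(s) available; reduced from %d",
      max(g, 1L), n_groups), call. = FALSE)
  if (g < 1L) {  # all predictions identical
    grp <- factor(rep(1L, length(predicted)))
  } else {
    grp <- cut(predicted, breaks = br, include.lowest = TRUE)
  }
  n_g <- as.vector(table(grp))
  o_g <- as.vector(tapply(observed, grp, sum))
  e_g <- as.vector(tapply(predicted, grp, sum))
  chi <- sum((o_g - e_g)^2 / (e_g * (1 - e_g / n_g)))
  g_eff <- length(n_g)
  df <- g_eff - 2L
  p <- if (df >= 1L) stats::pchisq(chi, df, lower.tail = FALSE) else NA_real_
  structure(
    list(statistic = chi, df = df, p_value = p, n_groups = g_eff,
         table = data.frame(group = seq_len(g_eff), n = n_g,
                            observed = o_g, expected = e_g)),
    class = "hosmer_lemeshow"
  )
}

#' @export
print.hosmer_lemeshow <- function(x, ...) {
  cat(sprintf(
    "Hosmer-Lemeshow test: chi-square = %.3f, df = %d, p = %s (%d groups)\n",
    x$statistic, x$df,
    if (is.na(x$p_value)) "NA" else sprintf("%.3f", x$p_value), x$n_groups))
  invisible(x)
}
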