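#' Forward stepwise logistic regression by likelihood-ratio entry
#'
#' Starting from the intercept-only model, repeatedly fits the current model
#' plus each remaining candidate, computes the likelihood-ratio test of the
#' addition (1 df), and enters the candidate with the smallest LR p-value,
#' provided it is below `p_enter`. Stops when no candidate qualifies.
#' The LR criterion is used rather than Wald or conditional entry: it is the
#' most reliable of the classical stepwise criteria, particularly at
#' moderate sample sizes.
#'
#' Candidates are normally the cluster representatives from
#' [correlation_clusters()]; feeding a whole collinear block in defeats the
#' purpose of the screen.
#'
#' @param cohort cohort data frame.
#' @param candidates character vector of candidate column names.
#' @param p_enter LR p-value below which a candidate may enter; default 0.05.
#' @param outcome name of the binary outcome column.
#' @param tol,max_iter passed to [fit_logistic()].
#' @return An [ntcp_fit()] object for the final model, with an extra element
#'   `selection`: a data frame trace (`step`, `added`, `lr_stat`,
#'   `p_value`), empty when no candidate entered (intercept-only model).
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_sim_config(n = 500), seed = 2)
#' sel <- forward_select(coh, c("age", "dmean_gy", "volume_cc"))
#' sel$selection
forward_select <- function(cohort, candidates, p_enter = 0.05,
                           outcome = "outcome_12m", tol = 1e-8,
                           max_iter = 100L) {
  check_cohort(cohort, c(candidates, outcome))
  if (!(is.numeric(p_enter) && length(p_enter) == 1L &&
        p_enter > 0 && p_enter < 1))
    stop("`p_enter` must be in (0, 1)", call. = FALSE)
  selected <- character(0)
  remaining <- candidates
  trace <- data.frame(step = integer(0), added = character(0),
                      lr_stat = numeric(0), p_value = numeric(0),
                      stringsAsFactors = FALSE)
  fit_for <- function(vars) {
    f <- stats::reformulate(if (length(vars)) vars else "1",
                            response = outcome)
    ntcp_fit(f, cohort, tol = tol, max_iter = max_iter)
  }
  current <- fit_for(selected)
  step <- 0L
  while (length(remaining)) {
    ll0 <- current$log_likelihood
    stats_ <- vapply(remaining, function(v) {
      fit <- tryCatch(fit_for(c(selected, v)), error = function(e) NULL)
      if (is.null(fit)) return(c(NA_real_, NA_real_))
      lr <- 2 * (fit$log_likelihood - ll0)
      c(lr, stats::pchisq(lr, df = 1, lower.tail = FALSE))
    }, numeric(2))
    p <- stats_[2, ]
    if (all(is.na(p)) || min(p, na.rm = TRUE) >= p_enter) break
    best <- remaining[which.min(p)]
    step <- step + 1L
    trace <- rbind(trace, data.frame(
      step = step, added = best, lr_stat = stats_[1, which.min(p)],
      p_value = min(p, na.rm = TRUE), stringsAsFactors = FALSE))
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
    current <- fit_for(selected)
  }
  current$selection <- trace
  current$selected <- selected
  current
}
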