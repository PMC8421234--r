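#' Maximum-likelihood logistic regression by Newton-Raphson (IRLS)
#'
#' The fitting engine used throughout the package. Maximises the Bernoulli
#' log-likelihood by Newton iterations with step halving, starting from the
#' zero coefficient vector. Convergence is declared when the log-likelihood
#' changes by less than `tol`; Wald standard errors come from the inverse of
#' the observed information at the optimum.
#'
#' Complete or quasi-complete separation makes the MLE diverge; it is
#' detected as a coefficient magnitude exceeding 15 on the standardised
#' working scale and raised as an error of class `"separation_error"`, so
#' callers (e.g. [univariate_screen()]) can record the failure and move on.
#'
#' @param x design matrix, one column per term; include an intercept column
#'   of ones yourself (or use the [ntcp_fit()] formula interface).
#' @param y binary outcome vector (0/1), same length as `nrow(x)`.
#' @param tol convergence tolerance on the log-likelihood change.
#' @param max_iter maximum Newton iterations.
#' @return An object of class `logistic_fit`: list with `coefficients`,
#'   `se`, `vcov`, `log_likelihood`, `n_iterations`, `converged`, `n`,
#'   `fitted`, `x`, `y`.
#' @seealso [ntcp_fit()] for the formula interface.
#' @export
fit_logistic <- function(x, y, tol = 1e-8, max_iter = 100L) {
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x)) stop("design matrix must be numeric, no NA",
                                       call. = FALSE)
  y <- as.numeric(y)
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop("outcome must be binary 0/1 with no NA", call. = FALSE)
  if (nrow(x) != length(y)) stop("nrow(x) != length(y)", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("both outcome classes must be present", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  is_intercept <- apply(x, 2, function(col) all(col == col[1]) && col[1] == 1)
  bad <- vapply(seq_len(ncol(x)), function(j)
    !is_intercept[j] && stats::var(x[, j]) == 0, logical(1))
  if (any(bad))
    stop("zero-variance covariate: ", paste(colnames(x)[bad], collapse = ", "),
         call. = FALSE)

  loglik <- function(eta) {
    # sum(y*eta - log(1 + exp(eta))), stable for large |eta|
    sum(y * eta - ifelse(eta > 30, eta, log1p(exp(eta))))
  }
  beta <- rep(0, ncol(x))
  eta <- drop(x %*% beta)
  ll <- loglik(eta)
  converged <- FALSE
  iter <- 0L
  # column scales for the separation check, so the |beta| > 15 rule is
  # applied per standard deviation of the covariate, not per raw unit
  scales <- apply(x, 2, function(col)
    if (all(col == col[1])) 1 else stats::sd(col))
  while (iter < max_iter) {
    iter <- iter + 1L
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    info <- crossprod(x, x * w)
    score <- crossprod(x, y - mu)
    step <- tryCatch(solve(info, score), error = function(e)
      stop(errorCondition(
        paste0("information matrix is singular (separation or collinearity): ",
               conditionMessage(e)),
        class = c("separation_error", "error", "condition"))))
    # step halving if the full Newton step overshoots
    lambda <- 1
    repeat {
      beta_new <- beta + lambda * drop(step)
      ll_new <- loglik(drop(x %*% beta_new))
      if (ll_new >= ll - 1e-12 || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    delta <- ll_new - ll
    beta <- beta_new
    eta <- drop(x %*% beta)
    ll <- ll_new
    if (any(abs(beta * scales) > 15))
      stop(errorCondition(
        "diverging coefficients: complete or quasi-complete separation",
        class = c("separation_error", "error", "condition")))
    if (abs(delta) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("fit_logistic did not converge in ", max_iter, " iterations")
  mu <- stats::plogis(eta)
  info <- crossprod(x, x * (mu * (1 - mu)))
  vc <- solve(info)
  dimnames(vc) <- list(colnames(x), colnames(x))
  names(beta) <- colnames(x)
  structure(
    list(coefficients = beta, se = sqrt(diag(vc)), vcov = vc,
         log_likelihood = ll, n_iterations = iter, converged = converged,
         n = length(y), fitted = mu, x = x, y = y),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit: n = %d, logLik = %.4f, %d iterations%s\n",
              x$n, x$log_likelihood, x$n_iterations,
              if (x$converged) "" else " (NOT converged)"))
  print(x$coefficients)
  invisible(x)
}

#' Fit a logistic NTCP model to a cohort
#'
#' Formula interface over [fit_logistic()]: fits
#' `outcome ~ covariates` by maximum likelihood and returns a model object
#' with the usual accessor methods (`print`, `summary`, `coef`, `vcov`,
#' `confint`, `predict`, `residuals`, `simulate`, `logLik`). `summary()`
#' reports per-unit odds ratios with 95% Wald intervals, the form in which
#' thyroid NTCP models are usually published.
#'
#' @param formula model formula; the response must be a 0/1 outcome (e.g.
#'   `outcome_12m ~ dmean_gy + volume_cc`).
#' @param data data frame containing the variables.
#' @param tol,max_iter passed to [fit_logistic()].
#' @return An object of class `ntcp_fit`.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_sim_config(n = 400), seed = 1)
#' fit <- ntcp_fit(outcome_12m ~ dmean_gy + volume_cc, coh)
#' summary(fit)
ntcp_fit <- function(formula, data, tol = 1e-8, max_iter = 100L) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  x <- stats::model.matrix(attr(mf, "terms"), mf)
  fit <- fit_logistic(x, y, tol = tol, max_iter = max_iter)
  fit$call <- match.call()
  fit$formula <- formula
  fit$terms <- attr(mf, "terms")
  class(fit) <- c("ntcp_fit", "logistic_fit")
  fit
}

#' @export
print.ntcp_fit <- function(x, ...) {
  cat("NTCP logistic model\n")
  if (!is.null(x$call)) cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("n = %d, logLik = %.4f%s\n", x$n, x$log_likelihood,
              if (x$converged) "" else " (NOT converged)"))
  cat("Coefficients (log-odds per unit):\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
coef.logistic_fit <- function(object, ...) object$coefficients

#' @export
vcov.logistic_fit <- function(object, ...) object$vcov

#' @export
logLik.logistic_fit <- function(object, ...) {
  structure(object$log_likelihood, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
nobs.logistic_fit <- function(object, ...) object$n

#' @export
fitted.logistic_fit <- function(object, ...) object$fitted

#' @export
confint.logistic_fit <- function(object, parm, level = 0.95, ...) {
  cf <- object$coefficients
  if (missing(parm)) parm <- names(cf)
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(cf[parm] - z * object$se[parm], cf[parm] + z * object$se[parm])
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                              1 - (1 - level) / 2))
  out
}

#' @export
summary.ntcp_fit <- function(object, ...) {
  z <- object$coefficients / object$se
  p <- 2 * stats::pnorm(-abs(z))
  zc <- stats::qnorm(0.975)
  tab <- data.frame(
    estimate = object$coefficients, se = object$se, z = z, p_value = p,
    odds_ratio = exp(object$coefficients),
    or_low = exp(object$coefficients - zc * object$se),
    or_high = exp(object$coefficients + zc * object$se))
  structure(list(call = object$call, coefficients = tab, n = object$n,
                 log_likelihood = object$log_likelihood,
                 converged = object$converged,
                 n_iterations = object$n_iterations),
            class = "summary.ntcp_fit")
}

#' @export
print.summary.ntcp_fit <- function(x, digits = 4, ...) {
  cat("NTCP logistic model\n")
  if (!is.null(x$call)) cat("Call: ", deparse(x$call), "\n", sep = "")
  print(round(x$coefficients, digits))
  cat(sprintf("n = %d, logLik = %.4f, converged in %d iterations\n",
              x$n, x$log_likelihood, x$n_iterations))
  invisible(x)
}

#' @export
predict.ntcp_fit <- function(object, newdata = NULL,
                             type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- drop(object$x %*% object$coefficients)
  } else {
    tt <- stats::delete.response(object$terms)
    mf <- stats::model.frame(tt, newdata, na.action = stats::na.fail)
    x <- stats::model.matrix(tt, mf)
    eta <- drop(x %*% object$coefficients)
  }
  if (type == "link") eta else stats::plogis(eta)
}

#' @export
residuals.ntcp_fit <- function(object,
                               type = c("deviance", "pearson", "response"),
                               ...) {
  type <- match.arg(type)
  y <- object$y
  mu <- object$fitted
  switch(type,
    response = y - mu,
    pearson = (y - mu) / sqrt(mu * (1 - mu)),
    deviance = sign(y - mu) *
      sqrt(-2 * (y * log(mu) + (1 - y) * log1p(-mu))))
}

#' @export
simulate.ntcp_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- as.data.frame(replicate(
    nsim, stats::rbinom(object$n, 1L, object$fitted)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
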