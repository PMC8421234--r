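#' Spearman rank correlation
#'
#' Rank correlation with midranks for ties, via `stats::cor`. Used to detect
#' collinear dose metrics before multivariate modelling.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Correlation in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y) ||
      length(x) < 3L || anyNA(x) || anyNA(y))
    stop("`x` and `y` must be numeric, equal length >= 3, no NA",
         call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("Spearman correlation undefined for a constant vector",
         call. = FALSE)
  stats::cor(x, y, method = "spearman")
}

#' Univariate logistic screening of candidate predictors
#'
#' Fits one single-covariate logistic regression of the 12-month outcome per
#' candidate factor and reports the per-unit odds ratio with 95% Wald
#' interval and Wald p-value. A factor whose fit fails (zero variance,
#' separation) gets a failure record instead of aborting the screen. No
#' multiplicity correction is applied, matching common clinical practice in
#' this setting; interpret the p-values accordingly.
#'
#' @param cohort cohort data frame (see [read_cohort()] for the schema);
#'   must contain `outcome_12m` and every factor named.
#' @param factors character vector of column names to screen.
#' @param outcome name of the binary outcome column.
#' @return A data frame of class `univariate_screen`, one row per factor in
#'   the requested order: `factor`, `estimate`, `se`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `p_value`, `error` (NA when the fit succeeded).
#' @export
univariate_screen <- function(cohort, factors, outcome = "outcome_12m") {
  check_cohort(cohort, c(factors, outcome))
  y <- cohort[[outcome]]
  rows <- lapply(factors, function(f) {
    res <- tryCatch({
      x <- cbind(`(Intercept)` = 1, cohort[[f]])
      colnames(x)[2] <- f
      fit <- fit_logistic(x, y)
      b <- fit$coefficients[2]
      s <- fit$se[2]
      zc <- stats::qnorm(0.975)
      data.frame(factor = f, estimate = b, se = s, odds_ratio = exp(b),
                 ci_low = exp(b - zc * s), ci_high = exp(b + zc * s),
                 p_value = 2 * stats::pnorm(-abs(b / s)),
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(factor = f, estimate = NA_real_, se = NA_real_,
                 odds_ratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 p_value = NA_real_, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("univariate_screen", "data.frame")
  out
}

#' Collinearity clusters of screened factors
#'
#' Builds a graph over the factors with an edge wherever the absolute
#' Spearman correlation exceeds `rho_threshold`; its connected components
#' are the collinearity clusters. Each cluster is represented by the member
#' with the smallest univariate p-value (ties broken by the larger absolute
#' Wald z), so the downstream multivariate model sees one representative per
#' cluster instead of a block of near-duplicate dose metrics.
#'
#' @param cohort cohort data frame.
#' @param factors numeric factor columns to cluster.
#' @param rho_threshold absolute Spearman correlation above which two
#'   factors are considered collinear; default 0.8.
#' @param screen optional precomputed [univariate_screen()] result covering
#'   `factors`; computed internally when omitted.
#' @param outcome name of the binary outcome column.
#' @return An object of class `correlation_clusters`: list with `clusters`
#'   (list of character vectors), `representatives` (one per cluster),
#'   `rho` (Spearman matrix), `threshold`.
#' @export
correlation_clusters <- function(cohort, factors, rho_threshold = 0.8,
                                 screen = NULL, outcome = "outcome_12m") {
  check_cohort(cohort, factors)
  if (!(is.numeric(rho_threshold) && length(rho_threshold) == 1L &&
        rho_threshold > 0 && rho_threshold < 1))
    stop("`rho_threshold` must be in (0, 1)", call. = FALSE)
  k <- length(factors)
  rho <- matrix(NA_real_, k, k, dimnames = list(factors, factors))
  diag(rho) <- 1
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      r <- tryCatch(spearman_rho(cohort[[factors[i]]], cohort[[factors[j]]]),
                    error = function(e) {
                      warning("correlation undefined for ", factors[i], " / ",
                              factors[j], "; treated as no edge",
                              call. = FALSE)
                      NA_real_
                    })
      rho[i, j] <- rho[j, i] <- r
    }
  }
  adj <- !is.na(rho) & abs(rho) > rho_threshold
  # connected components by BFS
  comp <- rep(NA_integer_, k)
  nc <- 0L
  for (i in seq_len(k)) {
    if (!is.na(comp[i])) next
    nc <- nc + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- nc
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  if (is.null(screen)) screen <- univariate_screen(cohort, factors, outcome)
  clusters <- split(factors, comp)
  reps <- vapply(clusters, function(members) {
    sc <- screen[match(members, screen$factor), ]
    p <- sc$p_value
    z <- abs(sc$estimate / sc$se)
    p[is.na(p)] <- Inf
    z[is.na(z)] <- -Inf
    best <- which(p == min(p))
    if (length(best) > 1L) best <- best[which.max(z[best])]
    members[best[1]]
  }, character(1))
  structure(list(clusters = unname(clusters),
                 representatives = unname(reps),
                 rho = rho, threshold = rho_threshold),
            class = "correlation_clusters")
}

#' @export
print.correlation_clusters <- function(x, ...) {
  cat(sprintf("Collinearity clusters (|Spearman rho| > %.2f):\n",
              x$threshold))
  for (i in seq_along(x$clusters)) {
    cat(sprintf("  [%d] %s  -> representative: %s\n", i,
                paste(x$clusters[[i]], collapse = ", "),
                x$representatives[i]))
  }
  invisible(x)
}

check_cohort <- function(cohort, cols) {
  if (!is.data.frame(cohort)) stop("cohort must be a data frame",
                                   call. = FALSE)
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}
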