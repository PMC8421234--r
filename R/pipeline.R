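#' Pipeline configuration
#'
#' Bundles the analysis constants: the thyroid \eqn{\alpha/\beta} (3 Gy),
#' DVH bin width, Vx report levels, the Spearman collinearity threshold
#' (0.8), the forward-entry p-value (0.05), the number of Hosmer-Lemeshow
#' risk groups (10), the tolerance-dose probability levels, and the curve
#' volumes/dose range.
#'
#' @param alpha_beta linear-quadratic \eqn{\alpha/\beta} (Gy).
#' @param dvh_bin_width DVH bin width (Gy).
#' @param vx_levels Vx dose levels (Gy).
#' @param rho_threshold Spearman collinearity threshold.
#' @param p_screen univariate significance level a cluster representative
#'   must reach to be carried into the multivariate step.
#' @param p_enter forward-selection entry p-value.
#' @param hl_groups Hosmer-Lemeshow risk groups.
#' @param td_levels complication probabilities for the tolerance-dose table.
#' @param curve_volumes thyroid volumes (cc) for the NTCP curves.
#' @param dose_range,dose_step curve dose range and step (Gy).
#' @param seed optional seed recorded in the manifest and set before the run.
#' @return A list of class `run_config`.
#' @export
run_config <- function(alpha_beta = 3, dvh_bin_width = 0.1,
                       vx_levels = c(10, 20, 30, 40, 45, 50, 60, 70),
                       rho_threshold = 0.8, p_screen = 0.05, p_enter = 0.05,
                       hl_groups = 10,
                       td_levels = c(0.05, 0.10),
                       curve_volumes = c(10, 15, 20, 25),
                       dose_range = c(0, 60), dose_step = 0.5,
                       seed = NULL) {
  stopifnot(alpha_beta > 0, dvh_bin_width > 0, rho_threshold > 0,
            rho_threshold < 1, p_screen > 0, p_screen < 1, p_enter > 0,
            p_enter < 1, hl_groups >= 3,
            all(td_levels > 0 & td_levels < 1))
  structure(list(alpha_beta = alpha_beta, dvh_bin_width = dvh_bin_width,
                 vx_levels = vx_levels, rho_threshold = rho_threshold,
                 p_screen = p_screen, p_enter = p_enter,
                 hl_groups = hl_groups,
                 td_levels = td_levels, curve_volumes = curve_volumes,
                 dose_range = dose_range, dose_step = dose_step,
                 seed = seed),
            class = "run_config")
}

default_screen_factors <- function() {
  c("gender", "age", "t_stage", "n_stage", "clinical_stage", "chemotherapy",
    "volume_cc", "dmin_gy", "dmax_gy", "dmean_gy", "fx_dose_gy",
    paste0("v", c(10, 20, 30, 40, 45, 50, 60, 70)))
}

#' Run the full NTCP analysis pipeline on a cohort
#'
#' Executes the published analysis end to end on a cohort table:
#' univariate logistic screening of every candidate factor, Spearman
#' collinearity clustering with representative selection, forward
#' likelihood-ratio logistic selection over the univariately significant
#' representatives (representatives whose screen p-value is at or above
#' `p_screen` do not proceed to the multivariate step),
#' Hosmer-Lemeshow calibration of the final model, and — when both the
#' mean-dose and volume terms were selected — tolerance doses at the
#' cohort's median thyroid volume and NTCP-versus-dose curves at the
#' configured volume levels.
#'
#' A stage failure aborts with the failing stage named; results of the
#' completed stages are attached to the error condition as `partial`.
#'
#' @param cohort a cohort data frame or a path to a cohort CSV
#'   (see [read_cohort()]).
#' @param config a [run_config()].
#' @param factors candidate factor columns to screen; defaults to the full
#'   documented set.
#' @return An object of class `ntcp_pipeline`: list with `screen`,
#'   `clusters`, `model` (the final [ntcp_fit()]), `calibration`,
#'   `tolerance_doses`, `curves`, `ntcp_model` (when extractable),
#'   `manifest` (config snapshot, package version, cohort summary).
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_sim_config(n = 500), seed = 3)
#' res <- run_pipeline(coh)
#' res
run_pipeline <- function(cohort, config = run_config(),
                         factors = default_screen_factors()) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  validate_cohort(cohort)
  if (!is.null(config$seed)) set.seed(config$seed)
  done <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(errorCondition(
        paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
        class = c("pipeline_error", "error", "condition"),
        partial = done))
    })
  }
  done$screen <- stage("univariate_screen",
                       univariate_screen(cohort, factors))
  done$clusters <- stage("correlation_clusters",
                         correlation_clusters(cohort, factors,
                                              rho_threshold = config$rho_threshold,
                                              screen = done$screen))
  done$candidates <- stage("candidate_filter", {
    reps <- done$clusters$representatives
    p <- done$screen$p_value[match(reps, done$screen$factor)]
    reps[!is.na(p) & p < config$p_screen]
  })
  done$model <- stage("forward_select",
                      forward_select(cohort, done$candidates,
                                     p_enter = config$p_enter))
  done$calibration <- stage("hosmer_lemeshow", {
    if (length(done$model$selected))
      hosmer_lemeshow(fitted(done$model), cohort$outcome_12m,
                      n_groups = config$hl_groups)
    else NULL  # intercept-only: a single risk value, calibration undefined
  })
  has_core <- all(c("dmean_gy", "volume_cc") %in% done$model$selected) &&
    length(done$model$selected) == 2L
  if (has_core) {
    done$ntcp_model <- as_ntcp_model(done$model)
    med_vol <- stats::median(cohort$volume_cc)
    done$tolerance_doses <- data.frame(
      p = config$td_levels, volume_cc = med_vol,
      dmean_gy = tolerance_dose(done$ntcp_model, med_vol, config$td_levels))
    done$curves <- ntcp_curve(done$ntcp_model, config$curve_volumes,
                              config$dose_range, config$dose_step)
  } else {
    done$ntcp_model <- NULL
    done$tolerance_doses <- NULL
    done$curves <- NULL
  }
  done$manifest <- list(
    package_version = as.character(utils::packageVersion("thyroNTCP")),
    config = unclass(config), n_patients = nrow(cohort),
    n_events = sum(cohort$outcome_12m), factors = factors,
    selected = done$model$selected)
  class(done) <- "ntcp_pipeline"
  done
}

#' @export
print.ntcp_pipeline <- function(x, ...) {
  cat(sprintf("NTCP pipeline: %d patients, %d events\n",
              x$manifest$n_patients, x$manifest$n_events))
  cat(sprintf("Representatives screened: %s\n",
              paste(x$clusters$representatives, collapse = ", ")))
  cat(sprintf("Selected: %s\n",
              if (length(x$manifest$selected))
                paste(x$manifest$selected, collapse = ", ")
              else "(none: intercept-only)"))
  if (!is.null(x$calibration)) print(x$calibration)
  if (!is.null(x$tolerance_doses)) {
    cat("Tolerance doses at the cohort median volume:\n")
    print(x$tolerance_doses, row.names = FALSE)
  }
  invisible(x)
}
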