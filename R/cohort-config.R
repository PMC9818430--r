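#' Configuration for the synthetic-cohort generator
#'
#' Collects every parameter of the generative joint model: fixed effects of
#' the transformed-scale trajectory, the random intercept/slope covariance,
#' residual noise, hazard coefficients, the piecewise-constant baseline
#' hazard of the resectability-decision process, the visit schedule, and the
#' marginal distributions of baseline covariates.
#'
#' The defaults emulate a neoadjuvant-chemotherapy cohort of advanced
#' ovarian cancer: 77 patients, baseline CA-125 median near 926 IU/mL with a
#' heavy right tail, measurements roughly every 3 weeks with 2-6 samples per
#' patient (median 5), 3-9 chemotherapy cycles (median 6), ~88% ascites,
#' ~39% epigastric peritoneal carcinomatosis, ~16% needing paracentesis, and
#' ~52% of patients judged resectable by the end of follow-up. The trajectory
#' works on the transformed scale `log(sqrt(CA-125))`; the per-cycle and
#' per-paracentesis effects default to `log(0.89)` and `log(0.76)`
#' (multiplicative declines on the transformed scale). Hazard coefficients
#' default to `log(0.57)` per performance-status unit and `log(0.39)` for
#' epigastric carcinomatosis; the current-value association is negative
#' (higher CA-125, lower chance of a resectable decision). The baseline
#' hazard is near zero before week 9 -- a decision requires at least three
#' cycles -- then rises.
#'
#' @param n_patients Number of patients to simulate.
#' @param beta Length-4 fixed effects on the transformed scale:
#'   intercept, per-week slope, per-completed-cycle effect,
#'   per-paracentesis effect.
#' @param D 2x2 symmetric positive-semidefinite covariance of the random
#'   intercept and slope (transformed scale).
#' @param sigma Residual standard deviation on the transformed scale.
#' @param gamma_ps Log hazard ratio per performance-status unit.
#' @param gamma_pc Log hazard ratio for epigastric peritoneal carcinomatosis.
#' @param alpha Association: log hazard ratio per unit of the current
#'   (noiseless) transformed biomarker value.
#' @param baseline_hazard List with `breaks` (increasing interior knot times,
#'   weeks) and `rates` (length `length(breaks) + 1`, per-week rates >= 0,
#'   at least one positive).
#' @param visit_interval_weeks Scheduled measurement (and chemotherapy
#'   cycle) spacing in weeks.
#' @param max_followup_weeks Administrative end of follow-up; patients with
#'   no decision by then are censored there.
#' @param covariate_marginals Named list of probability vectors:
#'   `ps` (levels 0-3), `pc_epigastric` (single probability), `ascites`
#'   (single probability), `paracenteses` (named by count),
#'   `cycles` (named by total cycles), `n_samples` (named by per-patient
#'   measurement count, support within 2-6).
#' @param seed Integer seed making [generate_cohort()] reproducible.
#' @return A validated list of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(n_patients = 10)
#' cfg$beta
#' @export
cohort_config <- function(n_patients = 77,
                          beta = c(3.4155, -0.05, log(0.89), log(0.76)),
                          D = matrix(c(0.81, -0.018, -0.018, 0.0025), 2, 2),
                          sigma = 0.25,
                          gamma_ps = log(0.57),
                          gamma_pc = log(0.39),
                          alpha = -0.35,
                          baseline_hazard = list(
                            breaks = c(9, 15, 21),
                            rates = c(0.002, 0.085, 0.136, 0.187)
                          ),
                          visit_interval_weeks = 3,
                          max_followup_weeks = 27,
                          covariate_marginals = default_covariate_marginals(),
                          seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients), beta = unname(beta), D = unname(D),
    sigma = sigma, gamma_ps = gamma_ps, gamma_pc = gamma_pc, alpha = alpha,
    baseline_hazard = baseline_hazard,
    visit_interval_weeks = visit_interval_weeks,
    max_followup_weeks = max_followup_weeks,
    covariate_marginals = covariate_marginals, seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

#' @rdname cohort_config
#' @export
default_covariate_marginals <- function() {
  list(
    ps = c(`0` = 0.571, `1` = 0.338, `2` = 0.078, `3` = 0.013),
    pc_epigastric = 0.39,
    ascites = 0.883,
    paracenteses = c(`0` = 0.844, `1` = 0.039, `2` = 0.091, `4` = 0.013, `6` = 0.013),
    cycles = c(`3` = 0.13, `4` = 0.27, `5` = 0.08, `6` = 0.32,
               `7` = 0.10, `8` = 0.06, `9` = 0.04),
    n_samples = c(`2` = 0.08, `3` = 0.12, `4` = 0.20, `5` = 0.35, `6` = 0.25)
  )
}

validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (cfg$n_patients < 0) {
    rlang::abort("`n_patients` must be nonnegative.", class = "ca125jm_error_config")
  }
  if (length(cfg$beta) != 4L || !all(is.finite(cfg$beta))) {
    rlang::abort("`beta` must be 4 finite reals.", class = "ca125jm_error_config")
  }
  if (!is.matrix(cfg$D) || !all(dim(cfg$D) == 2L) || !is_psd2(cfg$D)) {
    rlang::abort("`D` must be a symmetric PSD 2x2 matrix.",
                 class = "ca125jm_error_config")
  }
  if (!is.finite(cfg$sigma) || cfg$sigma <= 0) {
    rlang::abort("`sigma` must be a positive residual SD.",
                 class = "ca125jm_error_config")
  }
  bh <- cfg$baseline_hazard
  if (!is.list(bh) || is.null(bh$rates) ||
      length(bh$rates) != length(bh$breaks) + 1L) {
    rlang::abort("`baseline_hazard` needs `breaks` and `rates` with length(rates) == length(breaks) + 1.",
                 class = "ca125jm_error_config")
  }
  if (any(bh$rates < 0) || !any(bh$rates > 0)) {
    rlang::abort("baseline hazard rates must be >= 0 with at least one > 0.",
                 class = "ca125jm_error_config")
  }
  if (is.unsorted(bh$breaks, strictly = TRUE)) {
    rlang::abort("baseline hazard breaks must be strictly increasing.",
                 class = "ca125jm_error_config")
  }
  if (cfg$visit_interval_weeks <= 0 || cfg$max_followup_weeks <= 0) {
    rlang::abort("visit interval and max follow-up must be positive.",
                 class = "ca125jm_error_config")
  }
  cm <- cfg$covariate_marginals
  for (nm in c("ps", "paracenteses", "cycles", "n_samples")) {
    p <- cm[[nm]]
    if (is.null(p) || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      rlang::abort(paste0("covariate marginal `", nm, "` must be probabilities summing to 1."),
                   class = "ca125jm_error_config")
    }
  }
  for (nm in c("pc_epigastric", "ascites")) {
    p <- cm[[nm]]
    if (is.null(p) || p < 0 || p > 1) {
      rlang::abort(paste0("`", nm, "` must be a probability."),
                   class = "ca125jm_error_config")
    }
  }
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  patients:", x$n_patients, " seed:", x$seed, "\n")
  cat("  beta (intercept, slope, cycle, paracentesis):",
      paste(signif(x$beta, 4), collapse = ", "), "\n")
  cat("  sigma:", signif(x$sigma, 4),
      " D: [", paste(signif(x$D, 3), collapse = ", "), "]\n")
  cat("  gamma (ps, pc):", signif(x$gamma_ps, 4), signif(x$gamma_pc, 4),
      " alpha:", signif(x$alpha, 4), "\n")
  cat("  baseline hazard rates:", paste(signif(x$baseline_hazard$rates, 3), collapse = ", "),
      " breaks:", paste(x$baseline_hazard$breaks, collapse = ", "), "\n")
  invisible(x)
}
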