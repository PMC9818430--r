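#' Simulate one CA-125 measurement trajectory
#'
#' Draws the scheduled measurements for a single patient under the
#' generative linear mixed-effects model. Measurements sit on the visit grid
#' `0, visit_interval, ...` truncated at `min(decision_time, max_followup)`;
#' the patient contributes their first `n_samples` scheduled visits
#' (measurement typically stops after the third or fourth chemotherapy
#' cycle even when treatment continues). The transformed mean is
#' `m(t) = (b0 + beta1) + (beta2 + b1) t + beta3 cycles(t) + beta4 para(t)`
#' with Gaussian residual noise, back-transformed to IU/mL as `exp(2 y)`.
#'
#' @param config A [cohort_config()].
#' @param patient A one-row data frame (or list) with `patient_id`,
#'   `decision_time_weeks`, `n_cycles_total`, and random effects `b0`, `b1`;
#'   optionally `para_times` (vector of paracentesis times) and `n_samples`
#'   (measurement count, drawn from the configured marginal when absent).
#'   Uses R's global RNG stream.
#' @return A tibble of longitudinal records: `patient_id`, `t_weeks`,
#'   `ca125_iu_ml`, `cycles_completed`, `paracenteses_cum`.
#' @export
simulate_trajectory <- function(config, patient) {
  config <- validate_cohort_config(config)
  patient <- as.list(patient)
  dt <- config$visit_interval_weeks
  t_stop <- min(patient$decision_time_weeks, config$max_followup_weeks)
  grid <- seq(0, t_stop, by = dt)
  n_target <- patient$n_samples %||% draw_marginal(config$covariate_marginals$n_samples, 1)
  times <- grid[seq_len(min(length(grid), n_target))]
  para_times <- sort(unlist(patient$para_times) %||% numeric(0))
  cycles <- pmin(floor(times / dt), patient$n_cycles_total)
  para <- step_count(para_times, times)
  m <- (config$beta[1] + patient$b0) + (config$beta[2] + patient$b1) * times +
    config$beta[3] * cycles + config$beta[4] * para
  y <- m + stats::rnorm(length(times), 0, config$sigma)
  tibble::tibble(
    patient_id = rep(patient$patient_id, length(times)),
    t_weeks = times,
    ca125_iu_ml = inv_transform_ca125(y),
    cycles_completed = as.integer(cycles),
    paracenteses_cum = as.integer(para)
  )
}

#' Simulate the time of the resectability decision
#'
#' Inverts the cumulative hazard of the generative model against an
#' exponential draw: the event time solves `H(t) = -log(U)` with
#' `h(t) = lambda(t) exp(gamma_ps ps + gamma_pc pc + alpha m(t))` and `m(t)`
#' the noiseless transformed trajectory. The cumulative hazard is
#' integrated piecewise (Gauss-Legendre within each baseline-hazard piece
#' and covariate segment) and the crossing bracketed by root-finding.
#' Draws beyond `max_followup_weeks` are censored there.
#'
#' @inheritParams simulate_trajectory
#' @param patient One-row data frame or list with `ps`, `pc_epigastric`,
#'   `n_cycles_total`, random effects `b0`, `b1`, optional `para_times`.
#' @param b Optional length-2 random-effects vector overriding
#'   `patient$b0/b1`.
#' @return A list with `time` (weeks) and `resectable` (logical).
#' @export
simulate_event_time <- function(config, patient, b = NULL) {
  config <- validate_cohort_config(config)
  patient <- as.list(patient)
  if (is.null(b)) b <- c(patient$b0, patient$b1)
  dt <- config$visit_interval_weeks
  tmax <- config$max_followup_weeks
  cyc_jumps <- dt * seq_len(patient$n_cycles_total %||% ceiling(tmax / dt))
  para_times <- sort(unlist(patient$para_times) %||% numeric(0))
  lin <- config$gamma_ps * patient$ps + config$gamma_pc * as.numeric(patient$pc_epigastric)
  Hfun <- function(t) {
    cum_hazard_subject(
      t, config$beta, b, config$alpha, lin,
      config$baseline_hazard$rates, config$baseline_hazard$breaks,
      cyc_jumps, para_times
    )
  }
  target <- stats::rexp(1)
  H_max <- Hfun(tmax)
  if (H_max <= target) {
    return(list(time = tmax, resectable = FALSE))
  }
  root <- stats::uniroot(function(t) Hfun(t) - target,
                         lower = 0, upper = tmax, tol = 1e-8)$root
  list(time = root, resectable = TRUE)
}

draw_marginal <- function(p, n) {
  vals <- as.numeric(names(p))
  vals[sample.int(length(p), n, replace = TRUE, prob = p)]
}

#' Generate a synthetic neoadjuvant-chemotherapy cohort
#'
#' Draws baseline covariates from the configured marginals, random effects
#' from `N(0, D)`, a decision time from the joint-model hazard, and the
#' measurement trajectory, for `n_patients` patients. Decision times are
#' floored at one visit interval so every patient carries at least a
#' baseline and one on-treatment sample. The generating truth (parameters
#' and per-patient random effects) is kept alongside for recovery studies.
#'
#' @param config A [cohort_config()]; `config$seed` makes the draw
#'   reproducible.
#' @return An object of class `ca125_cohort`: a list with tibbles
#'   `longitudinal` and `baseline`, and `truth` (the config plus a tibble of
#'   per-patient random effects).
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 5, seed = 42))
#' coh$baseline
#' @export
generate_cohort <- function(config) {
  config <- validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  cm <- config$covariate_marginals
  empty_long <- tibble::tibble(
    patient_id = character(), t_weeks = numeric(), ca125_iu_ml = numeric(),
    cycles_completed = integer(), paracenteses_cum = integer()
  )
  empty_base <- tibble::tibble(
    patient_id = character(), ps = integer(), pc_epigastric = logical(),
    ascites = logical(), n_cycles_total = integer(),
    n_paracenteses_total = integer(), decision_time_weeks = numeric(),
    resectable = logical()
  )
  if (n == 0L) {
    out <- list(longitudinal = empty_long, baseline = empty_base,
                truth = list(config = config,
                             random_effects = tibble::tibble(
                               patient_id = character(), b0 = numeric(), b1 = numeric())))
    class(out) <- "ca125_cohort"
    return(out)
  }

  ids <- sprintf("P%03d", seq_len(n))
  ps <- draw_marginal(cm$ps, n)
  pc <- stats::runif(n) < cm$pc_epigastric
  n_para <- draw_marginal(cm$paracenteses, n)
  # paracentesis implies symptomatic ascites; keep the ascites marginal exact
  p_para_any <- sum(cm$paracenteses[as.numeric(names(cm$paracenteses)) > 0])
  p_asc_rest <- max(0, min(1, (cm$ascites - p_para_any) / (1 - p_para_any)))
  ascites <- n_para > 0 | stats::runif(n) < p_asc_rest
  n_cycles <- draw_marginal(cm$cycles, n)
  n_samples <- draw_marginal(cm$n_samples, n)
  L <- chol2_lower(config$D)
  b <- t(L %*% matrix(stats::rnorm(2 * n), 2, n))
  # paracenteses cluster in the symptomatic early-to-mid treatment phase
  para_times <- lapply(seq_len(n), function(i) {
    if (n_para[i] == 0) numeric(0) else
      sort(stats::runif(n_para[i], 0, 0.6 * config$max_followup_weeks))
  })

  longitudinal <- vector("list", n)
  baseline <- vector("list", n)
  for (i in seq_len(n)) {
    pat <- list(
      patient_id = ids[i], ps = ps[i], pc_epigastric = pc[i],
      n_cycles_total = n_cycles[i], b0 = b[i, 1], b1 = b[i, 2],
      para_times = para_times[[i]], n_samples = n_samples[i]
    )
    ev <- simulate_event_time(config, pat)
    decision <- max(ev$time, config$visit_interval_weeks)
    pat$decision_time_weeks <- decision
    longitudinal[[i]] <- simulate_trajectory(config, pat)
    baseline[[i]] <- tibble::tibble(
      patient_id = ids[i], ps = as.integer(ps[i]), pc_epigastric = pc[i],
      ascites = ascites[i], n_cycles_total = as.integer(n_cycles[i]),
      n_paracenteses_total = as.integer(n_para[i]),
      decision_time_weeks = decision, resectable = ev$resectable
    )
  }
  out <- list(
    longitudinal = dplyr::bind_rows(longitudinal),
    baseline = dplyr::bind_rows(baseline),
    truth = list(
      config = config,
      random_effects = tibble::tibble(patient_id = ids, b0 = b[, 1], b1 = b[, 2])
    )
  )
  class(out) <- "ca125_cohort"
  out
}

#' @export
print.ca125_cohort <- function(x, ...) {
  cat("<ca125_cohort> ", nrow(x$baseline), " patients, ",
      nrow(x$longitudinal), " CA-125 measurements, ",
      sum(x$baseline$resectable), " resectable decisions\n", sep = "")
  invisible(x)
}

#' Four reference patient trajectories
#'
#' Packaged measurement histories of four illustrative patients (A-D)
#' spanning the clinically important contrasts: a steep marker decline
#' ending in a resectable decision (A), a flat high trajectory ending
#' unresectable (B), a decline with epigastric carcinomatosis ending
#' resectable (C), and a steep decline that nonetheless ended unresectable
#' (D). Decision times and within-treatment paracentesis timings are not
#' part of the printed histories and are reconstructed conventionally
#' (decision three weeks after the last sample; paracenteses at early
#' visits).
#'
#' @return A list with tibbles `longitudinal` and `baseline` in the same
#'   schema as [generate_cohort()].
#' @examples
#' fx <- fixture_patients()
#' fx$longitudinal
#' @export
fixture_patients <- function() {
  longitudinal <- tibble::tibble(
    patient_id = c(rep("A", 6), rep("B", 3), rep("C", 4), rep("D", 6)),
    t_weeks = c(0, 3, 6, 9, 12, 15,
                0, 3, 6,
                0, 9, 14, 17,
                0, 3, 6, 9, 12, 17),
    ca125_iu_ml = c(3328, 830, 121, 37, 19, 16,
                    748, 706, 649,
                    679, 91, 48, 44,
                    5192, 2057, 344, 93, 37, 19),
    cycles_completed = as.integer(c(0, 1, 2, 3, 4, 5,
                                    0, 1, 2,
                                    0, 3, 4, 5,
                                    0, 1, 2, 3, 4, 5)),
    paracenteses_cum = as.integer(c(0, 0, 0, 0, 0, 0,
                                    0, 1, 2,
                                    0, 0, 0, 0,
                                    0, 0, 1, 1, 1, 1))
  )
  baseline <- tibble::tibble(
    patient_id = c("A", "B", "C", "D"),
    ps = c(1L, 0L, 1L, 1L),
    pc_epigastric = c(FALSE, TRUE, TRUE, TRUE),
    ascites = c(TRUE, TRUE, TRUE, TRUE),
    n_cycles_total = c(6L, 4L, 6L, 6L),
    n_paracenteses_total = c(0L, 2L, 0L, 1L),
    decision_time_weeks = c(18, 9, 20, 20),
    resectable = c(TRUE, FALSE, TRUE, FALSE)
  )
  list(longitudinal = longitudinal, baseline = baseline)
}
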