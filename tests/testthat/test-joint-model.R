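# Oracles for the joint-model log posterior (closed forms and brute-force
# quadrature) and behavioural checks of the Metropolis-within-Gibbs sampler.

default_params <- function(K, gamma = c(0, 0)) {
  list(beta = c(3.4, -0.05, -0.1, -0.2),
       D = matrix(c(0.6, -0.01, -0.01, 0.003), 2, 2),
       sigma = 0.3, gamma = gamma, alpha = 0,
       lam = seq(0.05, 0.05 * K, length.out = K))
}

test_that("with the association and covariates off, the survival term is the
          piecewise-exponential log-likelihood", {
  tt <- toy_tables()
  d <- jm_data(tt$longitudinal, tt$baseline, breaks = c(4.5, 6))
  pars <- default_params(d$K)
  b <- matrix(0, d$n, 2)
  parts <- jm_log_posterior(d, pars, b, parts = TRUE)
  # closed form: sum delta*log(lam(T)) - sum Lambda0(T)
  edges <- c(0, d$breaks, Inf)
  Lam0 <- vapply(d$time, function(T) {
    sum(pars$lam * pmax(pmin(T, edges[-1]) - edges[-length(edges)], 0))
  }, numeric(1))
  closed <- sum(d$delta * log(pars$lam[d$pieceT])) - sum(Lam0)
  expect_equal(parts$survival, closed, tolerance = 1e-10)
})

test_that("zero-length follow-up leaves only longitudinal and prior terms", {
  tt <- toy_tables()
  base0 <- tt$baseline
  base0$decision_time_weeks <- 0
  base0$resectable <- FALSE
  long0 <- tt$longitudinal[tt$longitudinal$t_weeks == 0, ]
  d <- jm_data(long0, base0, breaks = c(2, 4))
  pars <- default_params(d$K, gamma = c(0.3, -0.2))
  pars$alpha <- 0.4
  parts <- jm_log_posterior(d, pars, matrix(0.1, d$n, 2), parts = TRUE)
  expect_equal(parts$survival, 0, tolerance = 1e-12)
})

test_that("Gauss-Legendre survival term matches a 50,000-point trapezoid on a
          two-subject toy with a live association", {
  longitudinal <- tibble::tibble(
    patient_id = c("u", "u", "u", "v", "v"),
    t_weeks = c(0, 3, 6, 0, 4),
    ca125_iu_ml = c(1000, 500, 200, 800, 750),
    cycles_completed = c(0L, 1L, 2L, 0L, 1L),
    paracenteses_cum = c(0L, 0L, 0L, 0L, 1L)
  )
  baseline <- tibble::tibble(
    patient_id = c("u", "v"), ps = c(1L, 0L),
    pc_epigastric = c(TRUE, FALSE), ascites = c(TRUE, TRUE),
    n_cycles_total = c(2L, 1L), n_paracenteses_total = c(0L, 1L),
    decision_time_weeks = c(8, 6.5), resectable = c(TRUE, FALSE)
  )
  d <- jm_data(longitudinal, baseline, breaks = c(3.7, 5.2))
  pars <- list(beta = c(3.3, -0.07, -0.12, -0.25),
               D = diag(c(0.5, 0.004)), sigma = 0.25,
               gamma = c(-0.5, -0.9), alpha = -0.4,
               lam = c(0.02, 0.08, 0.15))
  b <- matrix(c(0.3, -0.2, -0.02, 0.01), 2, 2)
  parts <- jm_log_posterior(d, pars, b, parts = TRUE)

  # brute-force oracle: dense trapezoid with the same covariate paths
  # (counts at or before the last observation, then the visit-cadence
  # extension up to the baseline totals; both subjects are already at
  # their totals so no extension jumps occur)
  W <- cbind(c(1, 0), c(1, 0))
  oracle <- 0
  for (i in 1:2) {
    id <- baseline$patient_id[i]
    rows <- longitudinal[longitudinal$patient_id == id, ]
    Tm <- baseline$decision_time_weeks[i]
    tg <- seq(0, Tm, length.out = 50000)
    cyc <- approx(rows$t_weeks, rows$cycles_completed, xout = tg,
                  method = "constant", rule = 2)$y
    par_ <- approx(rows$t_weeks, rows$paracenteses_cum, xout = tg,
                   method = "constant", rule = 2)$y
    m <- (pars$beta[1] + b[i, 1]) + (pars$beta[2] + b[i, 2]) * tg +
      pars$beta[3] * cyc + pars$beta[4] * par_
    lamt <- pars$lam[findInterval(tg, c(3.7, 5.2)) + 1]
    eta <- sum(pars$gamma * c(baseline$ps[i], baseline$pc_epigastric[i]))
    h <- lamt * exp(eta + pars$alpha * m)
    H <- sum((h[-1] + h[-length(h)]) / 2) * (tg[2] - tg[1])
    delta <- as.numeric(baseline$resectable[i])
    oracle <- oracle + delta * log(h[length(h)]) - H
  }
  expect_equal(parts$survival, oracle, tolerance = 1e-6)
})

test_that("the posterior decomposes additively: perturbing the responses
          leaves survival, random-effect and prior terms unchanged", {
  tt <- toy_tables()
  d1 <- jm_data(tt$longitudinal, tt$baseline)
  long2 <- tt$longitudinal
  long2$ca125_iu_ml <- long2$ca125_iu_ml * 2
  d2 <- jm_data(long2, tt$baseline)
  pars <- default_params(d1$K, gamma = c(0.2, 0.1))
  pars$alpha <- 0.3
  b <- matrix(c(0.2, -0.1, 0.05, 0.01, 0, -0.02), 3, 2)
  p1 <- jm_log_posterior(d1, pars, b, parts = TRUE)
  p2 <- jm_log_posterior(d2, pars, b, parts = TRUE)
  expect_false(isTRUE(all.equal(p1$longitudinal, p2$longitudinal)))
  expect_equal(p1$survival, p2$survival, tolerance = 1e-12)
  expect_equal(p1$ranef, p2$ranef, tolerance = 1e-12)
  expect_equal(p1$prior, p2$prior, tolerance = 1e-12)
})

test_that("non-finite contributions are reported by term", {
  tt <- toy_tables()
  d <- jm_data(tt$longitudinal, tt$baseline)
  pars <- default_params(d$K)
  pars$lam <- rep(0, d$K)  # zero rate at an observed event time
  expect_error(jm_log_posterior(d, pars, matrix(0, d$n, 2)),
               class = "ca125jm_error_posterior", regexp = "survival")
})

test_that("the sampler is deterministic given seed and settings", {
  coh <- generate_cohort(cohort_config(n_patients = 20, seed = 33))
  f1 <- suppressWarnings(fit_jm(coh$longitudinal, coh$baseline,
                                control = tiny_control(), seed = 4))
  f2 <- suppressWarnings(fit_jm(coh$longitudinal, coh$baseline,
                                control = tiny_control(), seed = 4))
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$b_samples, f2$b_samples)
  f3 <- suppressWarnings(fit_jm(coh$longitudinal, coh$baseline,
                                control = tiny_control(), seed = 5))
  expect_false(identical(f1$samples$alpha, f3$samples$alpha))
})

test_that("kept-draw bookkeeping matches chains x (n_iter - burn_in) / thin", {
  coh <- generate_cohort(cohort_config(n_patients = 15, seed = 34))
  ctrl <- jm_control(n_chains = 2, n_iter = 240, burn_in = 120, thin = 4)
  fit <- suppressWarnings(fit_jm(coh$longitudinal, coh$baseline,
                                 control = ctrl, seed = 1))
  expect_equal(nrow(fit$samples), 2 * (240 - 120) / 4)
  expect_true(all(is.finite(fit$diagnostics$ess)))
})

test_that("hazard coefficients sample their prior when the data carry no
          survival information", {
  # one subject, one observation, censored immediately: the survival term
  # vanishes, so the conditional for gamma is its N(0, 10^2) prior
  longitudinal <- tibble::tibble(
    patient_id = "solo", t_weeks = 0, ca125_iu_ml = 900,
    cycles_completed = 0L, paracenteses_cum = 0L
  )
  baseline <- tibble::tibble(
    patient_id = "solo", ps = 1L, pc_epigastric = TRUE, ascites = TRUE,
    n_cycles_total = 0L, n_paracenteses_total = 0L,
    decision_time_weeks = 1e-9, resectable = FALSE
  )
  ctrl <- jm_control(n_chains = 1, n_iter = 4000, burn_in = 500, thin = 2)
  fit <- suppressWarnings(fit_jm(longitudinal, baseline, breaks = c(1, 2),
                                 control = ctrl, seed = 9))
  g <- fit$samples$gamma_ps
  expect_gt(stats::sd(g), 6)
  expect_lt(stats::sd(g), 14)
  expect_lt(abs(mean(g)), 2.5 * stats::sd(g) / sqrt(20))  # ~20 effective draws
})

test_that("with no events the baseline-rate posterior concentrates below the
          prior mean", {
  coh <- generate_cohort(cohort_config(
    n_patients = 30,
    baseline_hazard = list(breaks = 27, rates = c(0, 1)), seed = 35
  ))
  expect_true(all(!coh$baseline$resectable))
  fit <- suppressWarnings(fit_jm(coh$longitudinal, coh$baseline,
                                 breaks = c(9, 18),
                                 control = tiny_control(600, 300, 3),
                                 seed = 2))
  # Gamma(0.1, 0.1) prior mean is 1; exposure shrinks every rate well below
  expect_true(all(colMeans(fit$samples[paste0("lambda", 1:3)]) < 0.5))
})
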