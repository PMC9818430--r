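test_that("marginal log-likelihood reduces to the Gaussian normalizer for a
          single centred observation with unit variance", {
  one <- tibble::tibble(patient_id = "s1", t_weeks = 0, ca125_iu_ml = exp(2),
                        cycles_completed = 0L, paracenteses_cum = 0L)
  # transformed y = 1; beta chosen so the residual is zero; D = 0, sigma = 1
  ll <- lme_marginal_loglik(one, beta = c(1, 0, 0, 0),
                            D = matrix(0, 2, 2), sigma = 1)
  expect_equal(ll, -0.5 * log(2 * pi), tolerance = 1e-12)
})

test_that("with no random effects the model collapses to independent
          Gaussians", {
  tt <- toy_tables()$longitudinal
  beta <- c(3.2, -0.1, -0.05, -0.2)
  sigma <- 0.4
  ll <- lme_marginal_loglik(tt, beta, matrix(0, 2, 2), sigma)
  y <- transform_ca125(tt$ca125_iu_ml)
  mu <- beta[1] + beta[2] * tt$t_weeks + beta[3] * tt$cycles_completed +
    beta[4] * tt$paracenteses_cum
  expect_equal(ll, sum(dnorm(y, mu, sigma, log = TRUE)), tolerance = 1e-12)
})

test_that("stable factorization agrees with the dense-covariance oracle", {
  coh <- generate_cohort(cohort_config(n_patients = 10, seed = 17))
  beta <- c(3.4, -0.05, -0.1, -0.2)
  D <- matrix(c(0.7, -0.01, -0.01, 0.004), 2, 2)
  expect_equal(
    lme_marginal_loglik(coh$longitudinal, beta, D, 0.3),
    dense_lme_loglik(coh$longitudinal, beta, D, 0.3),
    tolerance = 1e-8
  )
  # and on the hand-sized toy
  tt <- toy_tables()$longitudinal
  expect_equal(
    lme_marginal_loglik(tt, beta, D, 0.25),
    dense_lme_loglik(tt, beta, D, 0.25),
    tolerance = 1e-8
  )
})

test_that("noise-free linear data are interpolated exactly", {
  beta <- c(3.5, -0.08, -0.12, -0.3)
  grid <- expand.grid(id = sprintf("s%02d", 1:8), t = c(0, 3, 6, 9))
  cyc <- pmin(floor(grid$t / 3), 2)  # cap breaks the t/cycles collinearity
  par <- as.integer(grid$t >= 6 & grid$id %in% c("s01", "s02"))
  y <- beta[1] + beta[2] * grid$t + beta[3] * cyc + beta[4] * par
  dat <- tibble::tibble(
    patient_id = as.character(grid$id), t_weeks = grid$t,
    ca125_iu_ml = exp(2 * y), cycles_completed = as.integer(cyc),
    paracenteses_cum = as.integer(par)
  )
  dat <- dat[order(dat$patient_id, dat$t_weeks), ]
  fit <- fit_lme(dat)
  expect_equal(unname(fit$beta_hat), beta, tolerance = 1e-6)
})

test_that("rank-deficient designs are rejected with the collinear column
          named", {
  tt <- toy_tables()$longitudinal
  tt$cycles_completed <- as.integer(tt$t_weeks / 3)  # exact collinearity
  expect_error(fit_lme(tt), class = "ca125jm_error_design",
               regexp = "cycles|t_weeks")
})

test_that("fixed effects are recovered within 3 standard errors across
          seeded replicates", {
  truth <- cohort_config(n_patients = 200)
  hits <- matrix(NA, 20, 4)
  for (r in 1:20) {
    coh <- generate_cohort(cohort_config(n_patients = 200, seed = 2000 + r))
    fit <- fit_lme(coh$longitudinal)
    hits[r, ] <- abs(fit$beta_hat - truth$beta) < 3 * fit$se_beta
  }
  # per-component coverage of a 3-SE interval should be near 1
  expect_true(all(colMeans(hits) >= 0.95))
})

test_that("a cohort generated with a negative per-cycle effect yields a
          negative fitted per-cycle coefficient", {
  coh <- generate_cohort(cohort_config(n_patients = 150, seed = 31))
  fit <- fit_lme(coh$longitudinal)
  expect_lt(fit$beta_hat["cycles"], 0)
  expect_lt(fit$beta_hat["paracenteses"], 0)
})

test_that("fitted optimum dominates the generating truth (ML property)", {
  cfg <- cohort_config(n_patients = 60)
  for (s in c(5, 6, 7)) {
    coh <- generate_cohort(cohort_config(n_patients = 60, seed = s))
    fit <- fit_lme(coh$longitudinal)
    ll_truth <- lme_marginal_loglik(coh$longitudinal, cfg$beta, cfg$D,
                                    cfg$sigma)
    expect_gte(fit$loglik, ll_truth - 1e-6)
  }
})

test_that("fit is invariant to subject ordering and absorbs time shifts in
          the intercept", {
  coh <- generate_cohort(cohort_config(n_patients = 40, seed = 8))
  fit <- fit_lme(coh$longitudinal)
  shuffled <- coh$longitudinal[order(rev(coh$longitudinal$patient_id),
                                     coh$longitudinal$t_weeks), ]
  fit2 <- fit_lme(shuffled)
  expect_equal(unname(fit2$beta_hat), unname(fit$beta_hat), tolerance = 1e-4)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-6)
  shifted <- coh$longitudinal
  shifted$t_weeks <- shifted$t_weeks + 5
  fit3 <- fit_lme(shifted)
  expect_equal(unname(fit3$beta_hat[2]), unname(fit$beta_hat[2]),
               tolerance = 1e-3)
  expect_equal(unname(fit3$beta_hat[1]),
               unname(fit$beta_hat[1] - 5 * fit$beta_hat[2]),
               tolerance = 1e-3)
})

test_that("maximum-likelihood fit agrees with an independent mixed-model
          implementation", {
  skip_if_not_installed("lme4")
  coh <- generate_cohort(cohort_config(n_patients = 80, seed = 12))
  dat <- coh$longitudinal
  dat$y <- transform_ca125(dat$ca125_iu_ml)
  ref <- lme4::lmer(
    y ~ t_weeks + cycles_completed + paracenteses_cum + (1 + t_weeks | patient_id),
    data = dat, REML = FALSE,
    control = lme4::lmerControl(check.conv.singular = "ignore")
  )
  fit <- fit_lme(coh$longitudinal)
  expect_equal(unname(fit$beta_hat), unname(lme4::fixef(ref)),
               tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-4)
})

test_that("empirical Bayes effects follow the conjugate closed form", {
  # subject lying exactly on the population mean has zero predicted effects
  beta <- c(3.4, -0.05, 0, 0)
  onmean <- tibble::tibble(
    patient_id = "s1", t_weeks = c(0, 3, 6),
    ca125_iu_ml = exp(2 * (beta[1] + beta[2] * c(0, 3, 6))),
    cycles_completed = 0L, paracenteses_cum = 0L
  )
  fit <- list(beta_hat = beta, D_hat = diag(c(0.5, 0.01)), sigma_hat = 0.3)
  class(fit) <- "ca125_lme"
  eb <- predict_random_effects(fit, onmean)
  expect_equal(c(eb$b0, eb$b1), c(0, 0), tolerance = 1e-10)

  # degenerate prior pins every subject at zero
  fit0 <- fit
  fit0$D_hat <- matrix(0, 2, 2)
  eb0 <- predict_random_effects(fit0, toy_tables()$longitudinal)
  expect_true(all(abs(c(eb0$b0, eb0$b1)) < 1e-12))

  # two-observation toy against a dense Bayes-rule computation
  two <- tibble::tibble(
    patient_id = "s1", t_weeks = c(0, 4), ca125_iu_ml = c(1500, 300),
    cycles_completed = c(0L, 1L), paracenteses_cum = c(0L, 0L)
  )
  D <- matrix(c(0.6, -0.02, -0.02, 0.005), 2, 2)
  fit2 <- list(beta_hat = c(3.3, -0.06, -0.1, -0.2), D_hat = D,
               sigma_hat = 0.25)
  class(fit2) <- "ca125_lme"
  eb2 <- predict_random_effects(fit2, two)
  Z <- cbind(1, two$t_weeks)
  X <- cbind(1, two$t_weeks, two$cycles_completed, two$paracenteses_cum)
  r <- transform_ca125(two$ca125_iu_ml) - drop(X %*% fit2$beta_hat)
  oracle <- drop(solve(solve(D) + crossprod(Z) / 0.25^2,
                       crossprod(Z, r) / 0.25^2))
  expect_equal(c(eb2$b0, eb2$b1), oracle, tolerance = 1e-8)
})
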