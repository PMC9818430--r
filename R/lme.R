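# Linear mixed-effects sub-model for transformed CA-125 trajectories.
#
# Model: y_ij = x_ij' beta + z_ij' b_i + e_ij, b_i ~ N(0, D), e ~ N(0, s^2),
# with x = (1, t, cycles, paracenteses) and z = (1, t). Fitting maximizes
# the exact Gaussian marginal likelihood (maximum likelihood, not REML, so
# the standalone fit and the joint model's longitudinal contribution share
# one objective). beta is profiled out by GLS; the quasi-Newton search runs
# over the Cholesky factor of D and log sigma, which enforces positivity
# without constraints.

lme_design <- function(longitudinal) {
  required <- c("patient_id", "t_weeks", "ca125_iu_ml",
                "cycles_completed", "paracenteses_cum")
  missing <- setdiff(required, names(longitudinal))
  if (length(missing)) {
    rlang::abort(paste0("longitudinal table lacks column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "ca125jm_error_schema")
  }
  sub <- match(longitudinal$patient_id, unique(longitudinal$patient_id))
  X <- cbind(
    intercept = 1,
    t_weeks = longitudinal$t_weeks,
    cycles = as.numeric(longitudinal$cycles_completed),
    paracenteses = as.numeric(longitudinal$paracenteses_cum)
  )
  ids <- unique(longitudinal$patient_id)
  list(
    y = transform_ca125(longitudinal$ca125_iu_ml),
    X = X,
    t = longitudinal$t_weeks,
    sub = sub,
    ids = ids,
    idx = split(seq_along(sub), factor(sub, levels = seq_along(ids)))
  )
}

#' Exact marginal log-likelihood of the longitudinal sub-model
#'
#' Sums, over subjects, the log-density of the transformed responses under
#' `N(X_i beta, Z_i D Z_i' + sigma^2 I)`, evaluated through the Cholesky
#' factor of each subject's marginal covariance (numerically stable; no
#' explicit inverse).
#'
#' @param longitudinal Longitudinal table (see [generate_cohort()] schema).
#' @param beta Length-4 fixed effects (intercept, time, cycles,
#'   paracenteses) on the transformed scale.
#' @param D 2x2 random intercept/slope covariance.
#' @param sigma Residual SD (> 0).
#' @return The marginal log-likelihood (a scalar).
#' @export
lme_marginal_loglik <- function(longitudinal, beta, D, sigma) {
  d <- lme_design(longitudinal)
  if (!is_psd2(D) || sigma <= 0) {
    rlang::abort("D must be symmetric PSD and sigma > 0.",
                 class = "ca125jm_error_domain")
  }
  r <- d$y - drop(d$X %*% beta)
  ll <- 0
  for (i in seq_along(d$ids)) {
    idx <- d$idx[[i]]
    Zi <- cbind(1, d$t[idx])
    Vi <- Zi %*% D %*% t(Zi) + diag(sigma^2, length(idx))
    R <- tryCatch(chol(Vi), error = function(e) {
      rlang::abort("marginal covariance is not positive definite.",
                   class = "ca125jm_error_domain")
    })
    u <- backsolve(R, r[idx], transpose = TRUE)
    ll <- ll - 0.5 * length(idx) * log(2 * pi) - sum(log(diag(R))) -
      0.5 * sum(u^2)
  }
  ll
}

# GLS beta, its covariance, and the profiled log-likelihood in one pass
# over the per-subject Cholesky factors of V_i = Z_i D Z_i' + sigma^2 I.
lme_gls <- function(d, D, sigma, loglik = FALSE) {
  p <- ncol(d$X)
  XtVX <- matrix(0, p, p)
  XtVy <- numeric(p)
  ytVy <- 0
  logdet <- 0
  for (i in seq_along(d$ids)) {
    idx <- d$idx[[i]]
    Zi <- cbind(1, d$t[idx])
    Vi <- Zi %*% D %*% t(Zi) + diag(sigma^2, length(idx))
    R <- chol(Vi)
    Xi <- backsolve(R, d$X[idx, , drop = FALSE], transpose = TRUE)
    yi <- backsolve(R, d$y[idx], transpose = TRUE)
    XtVX <- XtVX + crossprod(Xi)
    XtVy <- XtVy + crossprod(Xi, yi)
    ytVy <- ytVy + sum(yi^2)
    logdet <- logdet + 2 * sum(log(diag(R)))
  }
  beta <- drop(solve(XtVX, XtVy))
  out <- list(beta = beta, vcov = solve(XtVX))
  if (loglik) {
    quad <- ytVy - 2 * sum(beta * XtVy) + drop(beta %*% XtVX %*% beta)
    out$loglik <- -0.5 * (length(d$y) * log(2 * pi) + logdet + quad)
  }
  out
}

theta_to_varpars <- function(theta) {
  L <- matrix(c(exp(theta[1]), theta[2], 0, exp(theta[3])), 2, 2)
  list(D = L %*% t(L), sigma = exp(theta[4]))
}

#' Fit the linear mixed-effects sub-model
#'
#' Maximum-likelihood fit of the transformed-CA-125 trajectory model with
#' random intercept and slope. Starts from an OLS fit (D small, sigma from
#' the residuals) and runs BFGS on the profiled marginal likelihood.
#'
#' @param longitudinal Longitudinal table.
#' @param start Optional list with elements `beta`, `D`, `sigma` used as the
#'   starting point (only `D` and `sigma` matter; beta is profiled).
#' @param reltol Relative-objective convergence tolerance.
#' @return An object of class `ca125_lme` with elements `beta_hat`, `se_beta`,
#'   `D_hat`, `sigma_hat`, `loglik`, `n_subjects`, `n_obs`, `converged`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 30, seed = 7))
#' fit <- fit_lme(coh$longitudinal)
#' tidy(fit)
#' @export
fit_lme <- function(longitudinal, start = NULL, reltol = 1e-8) {
  d <- lme_design(longitudinal)
  qrX <- qr(d$X)
  if (qrX$rank < ncol(d$X)) {
    bad <- colnames(d$X)[qrX$pivot[-seq_len(qrX$rank)]]
    rlang::abort(paste0("design is rank deficient; collinear column(s): ",
                        paste(bad, collapse = ", ")),
                 class = "ca125jm_error_design")
  }
  ols <- qr.coef(qrX, d$y)
  res <- d$y - drop(d$X %*% ols)
  s0 <- max(stats::sd(res), 1e-4)
  theta0 <- c(log(s0 * 0.8), 0, log(s0 * 0.05), log(s0 * 0.8))
  if (!is.null(start)) {
    L <- chol2_lower(start$D)
    theta0 <- c(log(max(L[1, 1], 1e-6)), L[2, 1], log(max(L[2, 2], 1e-6)),
                log(start$sigma))
  }
  negprof <- function(theta) {
    if (any(!is.finite(theta)) || any(abs(theta) > 30)) return(1e10)
    vp <- theta_to_varpars(theta)
    if (!all(is.finite(vp$D)) || !is.finite(vp$sigma) || vp$sigma <= 0) {
      return(1e10)
    }
    gls <- tryCatch(lme_gls(d, vp$D, vp$sigma, loglik = TRUE),
                    error = function(e) NULL)
    if (is.null(gls) || !is.finite(gls$loglik)) return(1e10)
    -gls$loglik
  }
  opt <- stats::optim(theta0, negprof, method = "BFGS",
                      control = list(reltol = reltol, maxit = 500))
  vp <- theta_to_varpars(opt$par)
  gls <- lme_gls(d, vp$D, vp$sigma)
  grad_norm <- max(abs(numeric_grad(negprof, opt$par)))
  out <- list(
    beta_hat = stats::setNames(gls$beta, colnames(d$X)),
    se_beta = stats::setNames(sqrt(diag(gls$vcov)), colnames(d$X)),
    vcov_beta = gls$vcov,
    D_hat = vp$D, sigma_hat = vp$sigma,
    loglik = -opt$value,
    n_subjects = length(d$ids), n_obs = length(d$y),
    converged = opt$convergence == 0,
    grad_norm = grad_norm
  )
  class(out) <- "ca125_lme"
  out
}

numeric_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(j) {
    xp <- x; xm <- x
    xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

#' Empirical-Bayes random effects given a fitted longitudinal model
#'
#' Posterior mean of each subject's random intercept and slope under the
#' fitted Gaussian model (closed form), with the subject's fitted
#' trajectory at their measurement times. Subjects present in the fit's
#' schema but contributing zero observations get the prior mean `(0, 0)`
#' and are flagged.
#'
#' @param fit A `ca125_lme` fit.
#' @param longitudinal Longitudinal table with the subjects to predict.
#' @return A tibble with one row per subject: `patient_id`, `b0`, `b1`,
#'   `n_obs`, `flagged`; the fitted values are attached as attribute
#'   `"fitted"` (a tibble aligned with the input rows).
#' @export
predict_random_effects <- function(fit, longitudinal) {
  d <- lme_design(longitudinal)
  r <- d$y - drop(d$X %*% fit$beta_hat)
  D <- fit$D_hat
  s2 <- fit$sigma_hat^2
  out <- purrr::map_dfr(seq_along(d$ids), function(i) {
    idx <- which(d$sub == i)
    if (length(idx) == 0L) {
      return(tibble::tibble(patient_id = d$ids[i], b0 = 0, b1 = 0,
                            n_obs = 0L, flagged = TRUE))
    }
    Zi <- cbind(1, d$t[idx])
    Vi <- Zi %*% D %*% t(Zi) + diag(s2, length(idx))
    bi <- drop(D %*% t(Zi) %*% solve(Vi, r[idx]))
    tibble::tibble(patient_id = d$ids[i], b0 = bi[1], b1 = bi[2],
                   n_obs = length(idx), flagged = FALSE)
  })
  b0 <- out$b0[d$sub]
  b1 <- out$b1[d$sub]
  fitted <- tibble::tibble(
    patient_id = longitudinal$patient_id,
    t_weeks = d$t,
    fitted_transformed = drop(d$X %*% fit$beta_hat) + b0 + b1 * d$t
  )
  fitted$fitted_ca125 <- inv_transform_ca125(fitted$fitted_transformed)
  attr(out, "fitted") <- fitted
  out
}

#' @export
print.ca125_lme <- function(x, ...) {
  cat("<ca125_lme> ML fit,", x$n_subjects, "subjects,", x$n_obs, "observations\n")
  cat("  logLik:", format(x$loglik, digits = 6),
      if (!x$converged) " (NOT converged)" else "", "\n")
  print(round(rbind(estimate = x$beta_hat, se = x$se_beta), 4))
  cat("  sigma:", signif(x$sigma_hat, 4),
      " D: [", paste(signif(x$D_hat, 3), collapse = ", "), "]\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ca125_lme <- function(x, ...) {
  tibble::tibble(
    term = names(x$beta_hat),
    estimate = unname(x$beta_hat),
    std.error = unname(x$se_beta),
    statistic = unname(x$beta_hat / x$se_beta),
    p.value = 2 * stats::pnorm(-abs(unname(x$beta_hat / x$se_beta)))
  )
}

#' @exportS3Method generics::glance
glance.ca125_lme <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, sigma = x$sigma_hat,
    sd_intercept = sqrt(x$D_hat[1, 1]), sd_slope = sqrt(x$D_hat[2, 2]),
    cor_int_slope = ifelse(prod(diag(x$D_hat)) > 0,
                           x$D_hat[1, 2] / sqrt(prod(diag(x$D_hat))), NA_real_),
    nobs = x$n_obs, n_subjects = x$n_subjects, converged = x$converged
  )
}
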