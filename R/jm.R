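# Bayesian joint model linking the CA-125 trajectory to the hazard of a
# resectability decision through the current (noiseless) transformed value:
#
#   y_ij | b_i ~ N(m_i(t_ij), sigma^2)
#   m_i(t) = (beta1 + b0i) + (beta2 + b1i) t + beta3 cycles_i(t) + beta4 para_i(t)
#   h_i(t) = lambda(t) exp(gamma' w_i + alpha m_i(t)),  b_i ~ N(0, D)
#
# lambda(t) is piecewise constant with knots at event-time quantiles.
# Priors: N(0, 10^2) on beta, gamma, alpha; half-N(0, 10) on sigma and on
# the random-effect SDs; uniform correlation; Gamma(0.1, 0.1) on each
# baseline rate. Inference is Metropolis-within-Gibbs with adaptive
# random-walk scales tuned during burn-in and frozen afterwards.

#' Assemble the joint-model data structure
#'
#' Validates and indexes the longitudinal and baseline tables, chooses the
#' baseline-hazard knots (event-time quantiles), reconstructs each
#' subject's time-varying covariate step functions (carried forward from
#' the observed cumulative counts, then extended at the visit cadence up
#' to the baseline totals), and precomputes the Gauss-Legendre quadrature
#' grid used for every cumulative-hazard evaluation.
#'
#' @param longitudinal,baseline Cohort tables (see [generate_cohort()]).
#' @param covariates Baseline covariate columns entering the hazard.
#' @param n_pieces Number of piecewise-constant baseline-hazard pieces.
#' @param breaks Optional explicit interior knots (overrides `n_pieces`).
#' @param visit_interval Cycle cadence in weeks, used to extend covariate
#'   paths beyond the last measurement.
#' @return A list of class `jm_data`.
#' @export
jm_data <- function(longitudinal, baseline,
                    covariates = c("ps", "pc_epigastric"),
                    n_pieces = 5, breaks = NULL, visit_interval = 3) {
  d <- lme_design(longitudinal)
  ids <- baseline$patient_id
  if (!setequal(ids, d$ids)) {
    rlang::abort("longitudinal and baseline tables must cover the same patients.",
                 class = "ca125jm_error_orphan")
  }
  sub <- match(longitudinal$patient_id, ids)
  n <- length(ids)
  W <- as.matrix(dplyr::mutate(baseline[, covariates, drop = FALSE],
                               dplyr::across(dplyr::everything(), as.numeric)))
  time <- baseline$decision_time_weeks
  delta <- as.numeric(baseline$resectable)
  if (is.null(breaks)) {
    ev <- time[delta == 1]
    if (length(unique(ev)) >= n_pieces) {
      breaks <- unname(stats::quantile(ev, probs = seq_len(n_pieces - 1) / n_pieces,
                                       type = 1))
      breaks <- unique(breaks)
    } else {
      breaks <- unique(stats::quantile(time, probs = c(1 / 3, 2 / 3), type = 1))
    }
  }
  K <- length(breaks) + 1L

  paths <- lapply(seq_len(n), function(i) {
    idx <- which(sub == i)
    idx <- idx[order(longitudinal$t_weeks[idx])]
    tt <- longitudinal$t_weeks[idx]
    cyc <- longitudinal$cycles_completed[idx]
    par <- longitudinal$paracenteses_cum[idx]
    cj <- covariate_jumps(tt, cyc, baseline$n_cycles_total[i], visit_interval)
    pj <- covariate_jumps(tt, par, baseline$n_paracenteses_total[i], visit_interval)
    list(cyc = cj, para = pj)
  })

  qs <- lapply(seq_len(n), function(i) {
    g <- quad_grid(time[i], breaks, paths[[i]]$cyc$jumps, paths[[i]]$para$jumps)
    list(
      sub = rep(i, length(g$t)), t = g$t, w = g$w, piece = g$piece,
      cyc = paths[[i]]$cyc$offset + step_count(paths[[i]]$cyc$jumps, g$t),
      par = paths[[i]]$para$offset + step_count(paths[[i]]$para$jumps, g$t)
    )
  })
  qsub <- unlist(lapply(qs, `[[`, "sub"))
  structure(list(
    ids = ids, n = n,
    y = d$y, X = d$X, t_obs = d$t, sub = sub,
    W = W, covariates = covariates, time = time, delta = delta,
    breaks = breaks, K = K, visit_interval = visit_interval,
    paths = paths,
    qsub = qsub,
    qt = unlist(lapply(qs, `[[`, "t")),
    qw = unlist(lapply(qs, `[[`, "w")),
    qpiece = unlist(lapply(qs, `[[`, "piece")),
    qcyc = unlist(lapply(qs, `[[`, "cyc")),
    qpar = unlist(lapply(qs, `[[`, "par")),
    pieceT = findInterval(time, breaks) + 1L,
    cycT = vapply(seq_len(n), function(i)
      paths[[i]]$cyc$offset + length(paths[[i]]$cyc$jumps[paths[[i]]$cyc$jumps <= time[i]]),
      numeric(1)),
    parT = vapply(seq_len(n), function(i)
      paths[[i]]$para$offset + length(paths[[i]]$para$jumps[paths[[i]]$para$jumps <= time[i]]),
      numeric(1))
  ), class = "jm_data")
}

# Observed cumulative-count step function: jumps at the observation times
# where the recorded count increments (carried forward in between), then
# extended past the last observation at the visit cadence up to the
# baseline total.
covariate_jumps <- function(tt, value, total, visit_interval) {
  offset <- value[1]
  jumps <- numeric(0)
  if (length(tt) > 1) {
    inc <- diff(value)
    jumps <- rep(tt[-1], pmax(inc, 0))
  }
  last_val <- value[length(value)]
  remaining <- max(0, (total %||% last_val) - last_val)
  if (remaining > 0) {
    jumps <- c(jumps, tt[length(tt)] + visit_interval * seq_len(remaining))
  }
  list(offset = offset, jumps = jumps)
}

# --- log-posterior pieces -------------------------------------------------

jm_parts <- function(data, params, b) {
  beta <- params$beta; sigma <- params$sigma; D <- params$D
  gamma <- params$gamma; alpha <- params$alpha; lam <- params$lam
  b0 <- b[, 1]; b1 <- b[, 2]
  r <- data$y - drop(data$X %*% beta) - b0[data$sub] - b1[data$sub] * data$t_obs
  ll_long <- sum(stats::dnorm(r, 0, sigma, log = TRUE))

  if (length(data$qt)) {
    m_node <- (beta[1] + b0[data$qsub]) + (beta[2] + b1[data$qsub]) * data$qt +
      beta[3] * data$qcyc + beta[4] * data$qpar
    H <- drop(rowsum(data$qw * lam[data$qpiece] * exp(alpha * m_node),
                     data$qsub, reorder = TRUE))
  } else {
    H <- numeric(data$n)
  }
  eta <- drop(data$W %*% gamma)
  mT <- (beta[1] + b0) + (beta[2] + b1) * data$time +
    beta[3] * data$cycT + beta[4] * data$parT
  ll_surv <- sum(data$delta * (log(lam[data$pieceT]) + eta + alpha * mT)) -
    sum(exp(eta) * H)

  L <- chol2_lower(D)
  u <- forwardsolve(L, t(b))
  ll_b <- -data$n * log(2 * pi) - data$n * (log(L[1, 1]) + log(L[2, 2])) -
    0.5 * sum(u^2)

  s0 <- sqrt(D[1, 1]); s1 <- sqrt(D[2, 2])
  lp <- sum(stats::dnorm(c(beta, gamma, alpha), 0, 10, log = TRUE)) +
    log(2) + stats::dnorm(sigma, 0, 10, log = TRUE) +
    log(2) + stats::dnorm(s0, 0, 10, log = TRUE) +
    log(2) + stats::dnorm(s1, 0, 10, log = TRUE) +
    sum(stats::dgamma(lam, shape = 0.1, rate = 0.1, log = TRUE))
  list(longitudinal = ll_long, survival = ll_surv, ranef = ll_b, prior = lp)
}

#' Joint-model log posterior
#'
#' Sum of the longitudinal Gaussian log-density, the survival
#' log-likelihood under the piecewise baseline hazard with current-value
#' association (cumulative hazard by 7-node Gauss-Legendre quadrature on
#' each piece/covariate segment), the `N(0, D)` density of the random
#' effects, and the log-priors.
#'
#' @param data A [jm_data()] object.
#' @param params List with `beta` (4), `D` (2x2), `sigma`, `gamma`,
#'   `alpha`, `lam` (one rate per baseline piece).
#' @param b n-by-2 matrix of subject random effects.
#' @param parts Return the four additive components instead of their sum.
#' @return Scalar log posterior, or a named list when `parts = TRUE`.
#' @export
jm_log_posterior <- function(data, params, b, parts = FALSE) {
  stopifnot(inherits(data, "jm_data"))
  pieces <- jm_parts(data, params, b)
  bad <- names(pieces)[!vapply(pieces, is.finite, logical(1))]
  if (length(bad)) {
    rlang::abort(paste0("non-finite log-posterior contribution in term(s): ",
                        paste(bad, collapse = ", ")),
                 class = "ca125jm_error_posterior")
  }
  if (parts) pieces else sum(unlist(pieces))
}

#' MCMC settings for the joint model
#'
#' @param n_chains,n_iter,burn_in,thin Chain layout. `n_iter` counts
#'   post-initialization iterations per chain including burn-in.
#' @param adapt_target_scalar,adapt_target_b Acceptance-rate targets for
#'   scalar and random-effect random-walk updates (tuned during burn-in,
#'   then frozen).
#' @return A list of class `jm_control`.
#' @export
jm_control <- function(n_chains = 2, n_iter = 20000, burn_in = 10000,
                       thin = 10, adapt_target_scalar = 0.40,
                       adapt_target_b = 0.25) {
  stopifnot(n_iter > burn_in, thin >= 1, n_chains >= 1)
  structure(list(n_chains = n_chains, n_iter = n_iter, burn_in = burn_in,
                 thin = thin, adapt_target_scalar = adapt_target_scalar,
                 adapt_target_b = adapt_target_b), class = "jm_control")
}

#' Fit the Bayesian joint model
#'
#' Metropolis-within-Gibbs over the trajectory fixed effects, residual SD,
#' random-effects covariance, hazard coefficients, association, log
#' baseline rates, and every subject's random effects (the latter updated
#' jointly in one vectorized pass, valid because they are conditionally
#' independent given the parameters). Chains start at the separate
#' linear-mixed-effects and proportional-hazards estimates with empirical
#' Bayes random effects. Potential-scale-reduction (split R-hat) and
#' effective sample size are computed per monitored scalar; any R-hat
#' above 1.1 flags the posterior as not converged.
#'
#' @inheritParams jm_data
#' @param control A [jm_control()].
#' @param seed Integer seed; the fit is reproducible given the seed and
#'   settings.
#' @return An object of class `ca125_jm`: `samples` (tibble of kept draws),
#'   `b_samples` (array draws x subjects x 2), `diagnostics`, `data`,
#'   `control`, `seed`, `converged`, `accept_rates`.
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_config(n_patients = 40, seed = 11))
#' fit <- fit_jm(coh$longitudinal, coh$baseline,
#'               control = jm_control(n_chains = 1, n_iter = 500,
#'                                    burn_in = 250, thin = 5), seed = 1)
#' tidy(fit)
#' }
#' @export
fit_jm <- function(longitudinal, baseline,
                   covariates = c("ps", "pc_epigastric"),
                   n_pieces = 5, breaks = NULL, visit_interval = 3,
                   control = jm_control(), seed = 1L) {
  data <- jm_data(longitudinal, baseline, covariates, n_pieces, breaks,
                  visit_interval)
  init <- jm_init(data, longitudinal, baseline, covariates)
  chains <- vector("list", control$n_chains)
  for (ch in seq_len(control$n_chains)) {
    set.seed(as.integer(seed) + 1009L * (ch - 1L))
    chains[[ch]] <- jm_run_chain(data, init, control, chain_id = ch)
  }
  samples <- dplyr::bind_rows(lapply(chains, `[[`, "draws"))
  b_samples <- do.call(abind1, lapply(chains, `[[`, "b_draws"))
  par_cols <- setdiff(names(samples), c("chain", "iteration"))
  diagnostics <- mcmc_diagnostics(samples, par_cols)
  converged <- all(diagnostics$rhat < 1.1, na.rm = TRUE)
  if (!converged) {
    rlang::warn(paste0(
      "JOINT MODEL NOT CONVERGED: max split R-hat = ",
      signif(max(diagnostics$rhat, na.rm = TRUE), 4),
      " (> 1.1). Increase n_iter/burn_in."
    ), class = "ca125jm_warn_nonconvergence")
  }
  out <- list(
    samples = samples, b_samples = b_samples, diagnostics = diagnostics,
    data = data, control = control, seed = as.integer(seed),
    init = init, converged = converged,
    accept_rates = lapply(chains, `[[`, "accept")
  )
  class(out) <- "ca125_jm"
  out
}

abind1 <- function(...) {
  arrs <- list(...)
  out <- array(NA_real_, dim = c(sum(vapply(arrs, function(a) dim(a)[1], numeric(1))),
                                 dim(arrs[[1]])[2], dim(arrs[[1]])[3]))
  at <- 0
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

jm_init <- function(data, longitudinal, baseline, covariates) {
  lme <- tryCatch(fit_lme(longitudinal), error = function(e) NULL)
  if (is.null(lme)) {
    # degenerate longitudinal design (e.g. a single subject/observation):
    # start from a flat trajectory with weakly spread variance components
    lme <- list(
      beta_hat = c(mean(transform_ca125(longitudinal$ca125_iu_ml)), 0, 0, 0),
      se_beta = c(0.2, 0.05, 0.05, 0.05),
      D_hat = diag(c(0.5, 0.01)), sigma_hat = 0.3
    )
    class(lme) <- "ca125_lme"
  }
  cox <- tryCatch(
    suppressWarnings(fit_cox(baseline, covariates)),
    error = function(e) NULL
  )
  gamma0 <- if (is.null(cox)) rep(0, ncol(data$W)) else
    pmin(pmax(unname(cox$gamma_hat), -5), 5)
  eb <- predict_random_effects(lme, longitudinal)
  b0 <- as.matrix(eb[match(data$ids, eb$patient_id), c("b0", "b1")])
  D0 <- lme$D_hat
  ev <- eigen(D0, symmetric = TRUE)
  D0 <- ev$vectors %*% diag(pmax(ev$values, 1e-4)) %*% t(ev$vectors)
  # crude piecewise exposure-rate start at alpha = 0
  eta <- drop(data$W %*% gamma0)
  expo <- numeric(data$K)
  dk <- numeric(data$K)
  edges <- c(0, data$breaks, Inf)
  for (k in seq_len(data$K)) {
    expo[k] <- sum(exp(eta) * pmax(pmin(data$time, edges[k + 1]) - edges[k], 0))
    dk[k] <- sum(data$delta[data$pieceT == k])
  }
  lam0 <- (dk + 0.5) / pmax(expo, 1e-8)
  list(
    beta = unname(lme$beta_hat), sigma = lme$sigma_hat, D = D0,
    gamma = gamma0, alpha = 0, lam = lam0,
    b = b0, lme = lme, cox = cox
  )
}

# One chain of the Metropolis-within-Gibbs sampler.
jm_run_chain <- function(data, init, control, chain_id) {
  n <- data$n; K <- data$K; p <- ncol(data$W)
  # state
  beta <- init$beta
  lsig <- log(init$sigma)
  L0 <- chol2_lower(init$D)
  s0 <- sqrt(init$D[1, 1]); s1 <- sqrt(init$D[2, 2])
  rho <- init$D[1, 2] / (s0 * s1)
  dpar <- c(log(s0), log(s1), atanh(pmin(pmax(rho, -0.99), 0.99)))
  gamma <- init$gamma
  alpha <- init$alpha
  llam <- log(pmax(init$lam, 1e-8))
  b <- init$b

  # precomputed quadrature bookkeeping for the n x K exposure matrix
  grp <- (data$qsub - 1L) * K + data$qpiece
  ugrp <- sort(unique(grp))
  gidx <- match(grp, ugrp)
  Apos <- cbind(((ugrp - 1L) %/% K) + 1L, ((ugrp - 1L) %% K) + 1L)
  makeA <- function(beta, alpha, b) {
    m <- (beta[1] + b[data$qsub, 1]) + (beta[2] + b[data$qsub, 2]) * data$qt +
      beta[3] * data$qcyc + beta[4] * data$qpar
    val <- data$qw * exp(alpha * m)
    A <- matrix(0, n, K)
    A[Apos] <- drop(rowsum(val, gidx, reorder = TRUE))
    A
  }
  mT_of <- function(beta, b) {
    (beta[1] + b[, 1]) + (beta[2] + b[, 2]) * data$time +
      beta[3] * data$cycT + beta[4] * data$parT
  }
  ll_long_of <- function(beta, sigma, b) {
    r <- data$y - drop(data$X %*% beta) - b[data$sub, 1] -
      b[data$sub, 2] * data$t_obs
    -length(r) * (log(sigma) + 0.5 * log(2 * pi)) - sum(r^2) / (2 * sigma^2)
  }
  ll_surv_of <- function(A, mT, gamma, alpha, lam) {
    eta <- drop(data$W %*% gamma)
    sum(data$delta * (log(lam[data$pieceT]) + eta + alpha * mT)) -
      sum(exp(eta) * drop(A %*% lam))
  }
  lp_b_of <- function(b, dpar) {
    s0 <- exp(dpar[1]); s1 <- exp(dpar[2]); rho <- tanh(dpar[3])
    L <- matrix(c(s0, s1 * rho, 0, s1 * sqrt(1 - rho^2)), 2, 2)
    u <- forwardsolve(L, t(b))
    -n * log(2 * pi) - n * (log(L[1, 1]) + log(L[2, 2])) - 0.5 * sum(u^2)
  }
  # per-subject pieces for the vectorized b update
  sub_f <- factor(data$sub, levels = seq_len(n))
  nobs_i <- as.numeric(table(sub_f))
  ll_long_i_of <- function(beta, sigma, b) {
    r <- data$y - drop(data$X %*% beta) - b[data$sub, 1] -
      b[data$sub, 2] * data$t_obs
    rs <- numeric(n)
    agg <- rowsum(r^2, data$sub, reorder = TRUE)
    rs[as.integer(rownames(agg))] <- agg
    -nobs_i * log(sigma) - rs / (2 * sigma^2)
  }
  H_i_of <- function(beta, alpha, b, lam) {
    m <- (beta[1] + b[data$qsub, 1]) + (beta[2] + b[data$qsub, 2]) * data$qt +
      beta[3] * data$qcyc + beta[4] * data$qpar
    drop(rowsum(data$qw * lam[data$qpiece] * exp(alpha * m), data$qsub,
                reorder = TRUE))
  }
  lp_b_i_of <- function(b, dpar) {
    s0 <- exp(dpar[1]); s1 <- exp(dpar[2]); rho <- tanh(dpar[3])
    L <- matrix(c(s0, s1 * rho, 0, s1 * sqrt(1 - rho^2)), 2, 2)
    u <- forwardsolve(L, t(b))
    -(log(L[1, 1]) + log(L[2, 2])) - 0.5 * colSums(u^2)
  }

  prior_scalar <- function(x) -0.5 * x^2 / 100          # N(0, 10^2), const dropped
  prior_lsig <- function(ls) { s <- exp(ls); -s^2 / 200 + ls }
  prior_dpar <- function(dp) {
    s0 <- exp(dp[1]); s1 <- exp(dp[2]); rho <- tanh(dp[3])
    (-s0^2 / 200 + dp[1]) + (-s1^2 / 200 + dp[2]) + log(1 - rho^2)
  }
  prior_llam <- function(ll) 0.1 * ll - 0.1 * exp(ll)   # Gamma(0.1, 0.1) + Jacobian

  # caches
  A <- makeA(beta, alpha, b)
  mT <- mT_of(beta, b)
  ll_long <- ll_long_of(beta, exp(lsig), b)
  ll_surv <- ll_surv_of(A, mT, gamma, alpha, exp(llam))
  lp_b <- lp_b_of(b, dpar)

  # adaptive scales
  sc_beta <- log(pmax(init$lme$se_beta, 0.01))
  sc_lsig <- log(0.1)
  sc_dpar <- rep(log(0.2), 3)
  sc_gamma <- rep(log(0.15), p)
  sc_alpha <- log(0.1)
  sc_llam <- rep(log(0.3), K)
  sc_b <- rep(log(1.0), n)
  sc_shift <- c(log(0.2), log(0.02))
  sc_ridge <- log(0.02)
  acc <- list(beta = numeric(4), ridge = 0, shift = numeric(2), lsig = 0,
              dpar = numeric(3), gamma = numeric(p), alpha = 0,
              llam = numeric(K), b = 0)

  kept <- floor((control$n_iter - control$burn_in) / control$thin)
  par_names <- c(paste0("beta", 1:4), "sigma", "sd_intercept", "sd_slope",
                 "cor_b", paste0("gamma_", data$covariates), "alpha",
                 paste0("lambda", seq_len(K)))
  draws <- matrix(NA_real_, kept, length(par_names),
                  dimnames = list(NULL, par_names))
  b_draws <- array(NA_real_, dim = c(kept, n, 2))
  krow <- 0L
  tgt_s <- control$adapt_target_scalar
  tgt_b <- control$adapt_target_b

  for (it in seq_len(control$n_iter)) {
    adapting <- it <= control$burn_in
    rate <- min(0.25, 5 / sqrt(it))

    # (1) trajectory fixed effects
    for (j in 1:4) {
      prop <- beta
      prop[j] <- prop[j] + exp(sc_beta[j]) * stats::rnorm(1)
      A_p <- makeA(prop, alpha, b)
      mT_p <- mT_of(prop, b)
      ll_long_p <- ll_long_of(prop, exp(lsig), b)
      ll_surv_p <- ll_surv_of(A_p, mT_p, gamma, alpha, exp(llam))
      lr <- (ll_long_p + ll_surv_p + prior_scalar(prop[j])) -
        (ll_long + ll_surv + prior_scalar(beta[j]))
      ok <- is.finite(lr) && log(stats::runif(1)) < lr
      if (ok) {
        beta <- prop; A <- A_p; mT <- mT_p
        ll_long <- ll_long_p; ll_surv <- ll_surv_p
      }
      if (adapting) sc_beta[j] <- sc_beta[j] + rate * ((ok) - tgt_s)
      acc$beta[j] <- acc$beta[j] + ok
    }

    # (1a) ridge move for (slope, per-cycle): cycles(t) is nearly t divided
    # by the visit interval, so these two are close to collinear; propose
    # along the trade-off direction to traverse the likelihood ridge.
    {
      del <- exp(sc_ridge) * stats::rnorm(1)
      prop <- beta
      prop[2] <- prop[2] + del
      prop[3] <- prop[3] - del * data$visit_interval
      A_p <- makeA(prop, alpha, b)
      mT_p <- mT_of(prop, b)
      ll_long_p <- ll_long_of(prop, exp(lsig), b)
      ll_surv_p <- ll_surv_of(A_p, mT_p, gamma, alpha, exp(llam))
      lr <- (ll_long_p + ll_surv_p + prior_scalar(prop[2]) + prior_scalar(prop[3])) -
        (ll_long + ll_surv + prior_scalar(beta[2]) + prior_scalar(beta[3]))
      ok <- is.finite(lr) && log(stats::runif(1)) < lr
      if (ok) {
        beta <- prop; A <- A_p; mT <- mT_p
        ll_long <- ll_long_p; ll_surv <- ll_surv_p
      }
      if (adapting) sc_ridge <- sc_ridge + rate * ((ok) - tgt_s)
      acc$ridge <- acc$ridge + ok
    }

    # (1b) translation moves: shift beta_j and all b_{.,j} oppositely.
    # m_i(t) is unchanged, so both likelihoods cancel and only the priors
    # enter; this decouples the fixed intercept/slope from the random-effect
    # means, whose coupling otherwise dominates the autocorrelation time.
    for (j in 1:2) {
      del <- exp(sc_shift[j]) * stats::rnorm(1)
      b_p <- b
      b_p[, j] <- b_p[, j] - del
      lp_b_p <- lp_b_of(b_p, dpar)
      lr <- (lp_b_p + prior_scalar(beta[j] + del)) -
        (lp_b + prior_scalar(beta[j]))
      ok <- is.finite(lr) && log(stats::runif(1)) < lr
      if (ok) {
        beta[j] <- beta[j] + del
        b <- b_p
        lp_b <- lp_b_p
      }
      if (adapting) sc_shift[j] <- sc_shift[j] + rate * ((ok) - tgt_s)
      acc$shift[j] <- acc$shift[j] + ok
    }

    # (2) residual SD
    {
      prop <- lsig + exp(sc_lsig) * stats::rnorm(1)
      ll_long_p <- ll_long_of(beta, exp(prop), b)
      lr <- (ll_long_p + prior_lsig(prop)) - (ll_long + prior_lsig(lsig))
      ok <- is.finite(lr) && log(stats::runif(1)) < lr
      if (ok) { lsig <- prop; ll_long <- ll_long_p }
      if (adapting) sc_lsig <- sc_lsig + rate * ((ok) - tgt_s)
      acc$lsig <- acc$lsig + ok
    }

    # (3) random-effects covariance (scales + correlation)
    for (j in 1:3) {
      prop <- dpar
      prop[j] <- prop[j] + exp(sc_dpar[j]) * stats::rnorm(1)
      lp_b_p <- lp_b_of(b, prop)
      lr <- (lp_b_p + prior_dpar(prop)) - (lp_b + prior_dpar(dpar))
      ok <- is.finite(lr) && log(stats::runif(1)) < lr
      if (ok) { dpar <- prop; lp_b <- lp_b_p }
      if (adapting) sc_dpar[j] <- sc_dpar[j] + rate * ((ok) - tgt_s)
      acc$dpar[j] <- acc$dpar[j] + ok
    }

    # (4) hazard covariate coefficients (exposure matrix cached)
    for (j in seq_len(p)) {
      prop <- gamma
      prop[j] <- prop[j] + exp(sc_gamma[j]) * stats::rnorm(1)
      ll_surv_p <- ll_surv_of(A, mT, prop, alpha, exp(llam))
      lr <- (ll_surv_p + prior_scalar(prop[j])) -
        (ll_surv + prior_scalar(gamma[j]))
      ok <- is.finite(lr) && log(stats::runif(1)) < lr
      if (ok) { gamma <- prop; ll_surv <- ll_surv_p }
      if (adapting) sc_gamma[j] <- sc_gamma[j] + rate * ((ok) - tgt_s)
      acc$gamma[j] <- acc$gamma[j] + ok
    }

    # (5) association
    {
      prop <- alpha + exp(sc_alpha) * stats::rnorm(1)
      A_p <- makeA(beta, prop, b)
      ll_surv_p <- ll_surv_of(A_p, mT, gamma, prop, exp(llam))
      lr <- (ll_surv_p + prior_scalar(prop)) - (ll_surv + prior_scalar(alpha))
      ok <- is.finite(lr) && log(stats::runif(1)) < lr
      if (ok) { alpha <- prop; A <- A_p; ll_surv <- ll_surv_p }
      if (adapting) sc_alpha <- sc_alpha + rate * ((ok) - tgt_s)
      acc$alpha <- acc$alpha + ok
    }

    # (6) log baseline rates (cheap via cached exposure columns)
    eta_now <- drop(data$W %*% gamma)
    expo_eta <- exp(eta_now)
    for (k in seq_len(K)) {
      prop <- llam
      prop[k] <- prop[k] + exp(sc_llam[k]) * stats::rnorm(1)
      lam_p <- exp(prop)
      dH <- (lam_p[k] - exp(llam[k])) * sum(expo_eta * A[, k])
      dev <- sum(data$delta[data$pieceT == k]) * (prop[k] - llam[k])
      lr <- dev - dH + prior_llam(prop[k]) - prior_llam(llam[k])
      ok <- is.finite(lr) && log(stats::runif(1)) < lr
      if (ok) {
        ll_surv <- ll_surv + dev - dH
        llam <- prop
      }
      if (adapting) sc_llam[k] <- sc_llam[k] + rate * ((ok) - tgt_s)
      acc$llam[k] <- acc$llam[k] + ok
    }

    # (7) all random effects in one vectorized conditional pass
    {
      s0c <- exp(dpar[1]); s1c <- exp(dpar[2]); rhoc <- tanh(dpar[3])
      Lc <- matrix(c(s0c, s1c * rhoc, 0, s1c * sqrt(1 - rhoc^2)), 2, 2)
      eps <- matrix(stats::rnorm(2 * n), 2, n)
      b_p <- b + t(Lc %*% eps) * exp(sc_b)
      sig <- exp(lsig); lam <- exp(llam)
      ll_i <- ll_long_i_of(beta, sig, b)
      ll_i_p <- ll_long_i_of(beta, sig, b_p)
      H_i <- H_i_of(beta, alpha, b, lam)
      H_i_p <- H_i_of(beta, alpha, b_p, lam)
      sv_i <- data$delta * alpha * (b[, 1] + b[, 2] * data$time) - expo_eta * H_i
      sv_i_p <- data$delta * alpha * (b_p[, 1] + b_p[, 2] * data$time) -
        expo_eta * H_i_p
      pr_i <- lp_b_i_of(b, dpar)
      pr_i_p <- lp_b_i_of(b_p, dpar)
      lr <- (ll_i_p + sv_i_p + pr_i_p) - (ll_i + sv_i + pr_i)
      ok <- is.finite(lr) & log(stats::runif(n)) < lr
      if (any(ok)) b[ok, ] <- b_p[ok, ]
      # refresh caches that depend on b
      A <- makeA(beta, alpha, b)
      mT <- mT_of(beta, b)
      ll_long <- ll_long_of(beta, exp(lsig), b)
      ll_surv <- ll_surv_of(A, mT, gamma, alpha, exp(llam))
      lp_b <- lp_b_of(b, dpar)
      if (adapting) sc_b <- sc_b + rate * (ok - tgt_b)
      acc$b <- acc$b + mean(ok)
    }

    if (it > control$burn_in &&
        (it - control$burn_in) %% control$thin == 0L) {
      krow <- krow + 1L
      draws[krow, ] <- c(beta, exp(lsig), exp(dpar[1]), exp(dpar[2]),
                         tanh(dpar[3]), gamma, alpha, exp(llam))
      b_draws[krow, , ] <- b
    }
  }

  draws <- tibble::as_tibble(draws)
  draws$chain <- chain_id
  draws$iteration <- seq_len(krow)
  list(draws = draws, b_draws = b_draws,
       accept = lapply(acc, function(a) a / control$n_iter))
}

# --- diagnostics ----------------------------------------------------------

split_rhat <- function(x_by_chain) {
  halves <- unlist(lapply(x_by_chain, function(x) {
    h <- floor(length(x) / 2)
    if (h < 2) return(list())
    list(x[seq_len(h)], x[(h + 1):(2 * h)])
  }), recursive = FALSE)
  m <- length(halves)
  if (m < 2) return(NA_real_)
  nlen <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  B <- nlen * stats::var(means)
  Wv <- mean(vars)
  if (Wv == 0) return(1)
  sqrt(((nlen - 1) / nlen * Wv + B / nlen) / Wv)
}

ess_basic <- function(x_by_chain) {
  total <- sum(lengths(x_by_chain))
  rho_sum <- 0
  ok <- TRUE
  lag <- 1
  maxlag <- min(lengths(x_by_chain)) - 2
  while (ok && lag < maxlag) {
    rhos <- vapply(x_by_chain, function(x) {
      n <- length(x)
      xc <- x - mean(x)
      denom <- sum(xc^2)
      if (denom == 0) return(0)
      sum(xc[1:(n - lag)] * xc[(lag + 1):n]) / denom
    }, numeric(1))
    r <- mean(rhos)
    if (r < 0.05) ok <- FALSE else rho_sum <- rho_sum + r
    lag <- lag + 1
  }
  max(1, total / (1 + 2 * rho_sum))
}

mcmc_diagnostics <- function(samples, par_cols) {
  purrr::map_dfr(par_cols, function(pc) {
    xs <- split(samples[[pc]], samples$chain)
    tibble::tibble(
      parameter = pc,
      mean = mean(samples[[pc]]),
      sd = stats::sd(samples[[pc]]),
      rhat = split_rhat(xs),
      ess = ess_basic(xs)
    )
  })
}

#' @export
print.ca125_jm <- function(x, ...) {
  cat("<ca125_jm> ", x$data$n, " subjects, ",
      sum(x$data$delta), " events, ",
      nrow(x$samples), " kept draws (",
      x$control$n_chains, " chain(s))",
      if (!x$converged) "  ** NOT CONVERGED **", "\n", sep = "")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ca125_jm <- function(x, conf_level = 0.95, ...) {
  par_cols <- setdiff(names(x$samples), c("chain", "iteration"))
  lo <- (1 - conf_level) / 2
  purrr::map_dfr(par_cols, function(pc) {
    v <- x$samples[[pc]]
    dg <- x$diagnostics[x$diagnostics$parameter == pc, ]
    tibble::tibble(
      term = pc, estimate = mean(v), std.error = stats::sd(v),
      conf.low = unname(stats::quantile(v, lo)),
      conf.high = unname(stats::quantile(v, 1 - lo)),
      rhat = dg$rhat, ess = dg$ess
    )
  })
}

#' @exportS3Method generics::glance
glance.ca125_jm <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$data$n, n_obs = length(x$data$y),
    n_events = sum(x$data$delta), n_draws = nrow(x$samples),
    n_chains = x$control$n_chains,
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    min_ess = min(x$diagnostics$ess, na.rm = TRUE),
    converged = x$converged
  )
}
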