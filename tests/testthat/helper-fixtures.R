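# Shared builders for small deterministic datasets used across tests.

# a hand-sized longitudinal/baseline pair with exact values, no randomness
toy_tables <- function() {
  longitudinal <- tibble::tibble(
    patient_id = c("s1", "s1", "s1", "s2", "s2", "s3"),
    t_weeks = c(0, 3, 6, 0, 3, 0),
    ca125_iu_ml = c(900, 400, 150, 1200, 800, 600),
    cycles_completed = c(0L, 1L, 2L, 0L, 1L, 0L),
    paracenteses_cum = c(0L, 0L, 1L, 0L, 1L, 0L)
  )
  baseline <- tibble::tibble(
    patient_id = c("s1", "s2", "s3"),
    ps = c(0L, 1L, 2L),
    pc_epigastric = c(FALSE, TRUE, FALSE),
    ascites = c(TRUE, TRUE, FALSE),
    n_cycles_total = c(4L, 3L, 3L),
    n_paracenteses_total = c(1L, 1L, 0L),
    decision_time_weeks = c(8, 5, 4),
    resectable = c(TRUE, FALSE, TRUE)
  )
  list(longitudinal = longitudinal, baseline = baseline)
}

# quick reduced-budget MCMC settings for sampler smoke tests
tiny_control <- function(n_iter = 300, burn_in = 150, thin = 3, chains = 1) {
  jm_control(n_chains = chains, n_iter = n_iter, burn_in = burn_in, thin = thin)
}

# dense-matrix oracle for the LME marginal log-likelihood: one multivariate
# normal over all observations, block covariance assembled explicitly
dense_lme_loglik <- function(longitudinal, beta, D, sigma) {
  ids <- unique(longitudinal$patient_id)
  y <- log(longitudinal$ca125_iu_ml) / 2
  X <- cbind(1, longitudinal$t_weeks, longitudinal$cycles_completed,
             longitudinal$paracenteses_cum)
  n <- length(y)
  V <- diag(sigma^2, n)
  for (id in ids) {
    idx <- which(longitudinal$patient_id == id)
    Zi <- cbind(1, longitudinal$t_weeks[idx])
    V[idx, idx] <- V[idx, idx] + Zi %*% D %*% t(Zi)
  }
  r <- y - drop(X %*% beta)
  -0.5 * n * log(2 * pi) - 0.5 * determinant(V)$modulus[1] -
    0.5 * drop(r %*% solve(V, r))
}

# Efron log partial likelihood computed independently (naive direct sums)
naive_efron_loglik <- function(gamma, time, status, X) {
  eta <- drop(X %*% gamma)
  ll <- 0
  for (tj in sort(unique(time[status == 1]))) {
    Dset <- which(time == tj & status == 1)
    Rset <- which(time >= tj)
    dj <- length(Dset)
    ll <- ll + sum(eta[Dset])
    for (l in seq_len(dj) - 1) {
      ll <- ll - log(sum(exp(eta[Rset])) - (l / dj) * sum(exp(eta[Dset])))
    }
  }
  ll
}
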