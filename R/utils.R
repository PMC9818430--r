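# Internal numerical helpers shared across modules.

# 7-node Gauss-Legendre rule on [-1, 1]; constants frozen to full double
# precision so no runtime dependency is needed to regenerate them.
GL7_NODES <- c(
  -0.94910791234275838, -0.74153118559939424, -0.40584515137739713, 0,
  0.40584515137739713, 0.74153118559939446, 0.94910791234275849
)
GL7_WEIGHTS <- c(
  0.12948496616887029, 0.27970539148927603, 0.38183005050511887,
  0.41795918367346990, 0.38183005050511892, 0.27970539148927703,
  0.12948496616886948
)

`%||%` <- rlang::`%||%`

# value of a counting step function (number of jump times <= t); jumps sorted
step_count <- function(jumps, t) {
  if (length(jumps) == 0L) return(rep(0, length(t)))
  findInterval(t, jumps)
}

# lower-triangular Cholesky of a 2x2 PSD matrix, tolerant of zero variance
chol2_lower <- function(D) {
  l11 <- sqrt(max(D[1, 1], 0))
  l21 <- if (l11 > 0) D[2, 1] / l11 else 0
  l22 <- sqrt(max(D[2, 2] - l21^2, 0))
  matrix(c(l11, l21, 0, l22), 2, 2)
}

is_psd2 <- function(D, tol = 1e-10) {
  all(is.finite(D)) &&
    isTRUE(all.equal(D, t(D), tolerance = 1e-8)) &&
    min(eigen(D, symmetric = TRUE, only.values = TRUE)$values) >= -tol
}

# Kaplan-Meier estimator of the censoring survival function G(t).
# Returns a function G(t, minus = FALSE); minus = TRUE gives the left limit.
km_censoring <- function(time, status) {
  ord <- order(time)
  time <- time[ord]
  cens <- 1 - status[ord]
  ut <- unique(time)
  n_at_risk <- vapply(ut, function(s) sum(time >= s), numeric(1))
  d_cens <- vapply(ut, function(s) sum(cens[time == s]), numeric(1))
  surv <- cumprod(1 - d_cens / n_at_risk)
  function(t, minus = FALSE) {
    idx <- if (minus) findInterval(t, ut, left.open = TRUE) else findInterval(t, ut)
    out <- c(1, surv)[idx + 1L]
    out
  }
}
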