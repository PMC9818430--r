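# Piecewise-constant baseline hazard with a current-value biomarker link.
#
# The hazard of a resectability decision is
#   h_i(t) = lambda(t) * exp(gamma' w_i + alpha * m_i(t)),
# where lambda(t) is piecewise constant and m_i(t) is the subject's
# noiseless transformed trajectory, piecewise linear in t between jumps of
# the cumulative cycle / paracentesis counts. The cumulative hazard is
# integrated with a 7-node Gauss-Legendre rule on every sub-interval cut at
# hazard knots, covariate jump times, and any requested extra times, which
# is accurate far beyond 1e-10 for exp(linear) integrands on such short
# segments.

# Sub-interval quadrature grid up to t_end for one subject.
# jumps: sorted covariate jump times (cycles and paracenteses pooled is NOT
# ok -- values are needed separately, so pass both and cut at their union).
quad_grid <- function(t_end, hazard_breaks, cyc_jumps, para_jumps,
                      extra = numeric(0)) {
  if (t_end <= 0) {
    return(list(t = numeric(0), w = numeric(0), piece = integer(0),
                seg_end = numeric(0)))
  }
  cuts <- sort(unique(c(
    0, t_end,
    hazard_breaks[hazard_breaks > 0 & hazard_breaks < t_end],
    cyc_jumps[cyc_jumps > 0 & cyc_jumps < t_end],
    para_jumps[para_jumps > 0 & para_jumps < t_end],
    extra[extra > 0 & extra < t_end]
  )))
  a <- cuts[-length(cuts)]
  b <- cuts[-1L]
  half <- (b - a) / 2
  mid <- (a + b) / 2
  tt <- as.vector(outer(GL7_NODES, half) + rep(mid, each = 7L))
  ww <- as.vector(outer(GL7_WEIGHTS, half))
  piece <- findInterval(tt, hazard_breaks) + 1L
  list(t = tt, w = ww, piece = piece,
       seg_end = rep(b, each = 7L))
}

# Scalar cumulative hazard H(t) for one subject; m(s) evaluated from the
# trajectory parameters and covariate step functions. Used by the simulator
# and as the building block of root-finding event draws.
cum_hazard_subject <- function(t, beta, b, alpha, lin_pred, rates, breaks,
                               cyc_jumps, para_jumps, cyc0 = 0, para0 = 0) {
  g <- quad_grid(t, breaks, cyc_jumps, para_jumps)
  if (length(g$t) == 0) return(0)
  cyc <- cyc0 + step_count(cyc_jumps, g$t)
  para <- para0 + step_count(para_jumps, g$t)
  m <- (beta[1] + b[1]) + (beta[2] + b[2]) * g$t + beta[3] * cyc + beta[4] * para
  H <- sum(g$w * rates[g$piece] * exp(alpha * m)) * exp(lin_pred)
  if (!is.finite(H)) {
    bad <- which(!is.finite(rates) | rates < 0)
    rlang::abort(
      paste0("cumulative hazard is not finite on [0, ", signif(t, 4),
             "]; check baseline hazard rates",
             if (length(bad)) paste0(" lambda_", paste(bad, collapse = ","))),
      class = "ca125jm_error_hazard"
    )
  }
  H
}
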