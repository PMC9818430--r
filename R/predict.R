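# Subject-level dynamic prediction: probability that a resectability
# decision occurs by horizon u, given that the patient is decision-free at
# the landmark t and given the CA-125 history up to t. For each posterior
# draw the patient's random effects are drawn from their exact Gaussian
# conditional given the history (the longitudinal model is linear-Gaussian,
# so the conditional is conjugate and needs no inner sampler), then
#   P(T <= u | T > t, b, theta) = 1 - S(u | b, theta) / S(t | b, theta)
# with S from the piecewise Gauss-Legendre cumulative hazard. The report is
# the Monte-Carlo mean and 2.5/97.5 percentiles across draws.

patient_quad <- function(fit, history, baseline_row, horizons) {
  data <- fit$data
  dt <- data$visit_interval
  if (nrow(history) > 0) {
    ord <- order(history$t_weeks)
    tt <- history$t_weeks[ord]
    cj <- covariate_jumps(tt, history$cycles_completed[ord],
                          baseline_row$n_cycles_total, dt)
    pj <- covariate_jumps(tt, history$paracenteses_cum[ord],
                          baseline_row$n_paracenteses_total, dt)
  } else {
    cj <- list(offset = 0,
               jumps = dt * seq_len(baseline_row$n_cycles_total %||% 0))
    pj <- list(offset = 0,
               jumps = dt * seq_len(baseline_row$n_paracenteses_total %||% 0))
  }
  u_max <- max(horizons)
  g <- quad_grid(u_max, data$breaks, cj$jumps, pj$jumps, extra = horizons)
  # index of the first horizon >= each node's segment end
  hidx <- findInterval(g$seg_end - 1e-9, horizons) + 1L
  list(
    t = g$t, w = g$w, piece = g$piece, hidx = hidx,
    cyc = cj$offset + step_count(cj$jumps, g$t),
    par = pj$offset + step_count(pj$jumps, g$t)
  )
}

# exact Gaussian conditional of b given the history under one draw of theta
draw_conditional_b <- function(history, beta, D, sigma) {
  if (nrow(history) == 0) {
    return(drop(chol2_lower(D) %*% stats::rnorm(2)))
  }
  y <- transform_ca125(history$ca125_iu_ml)
  X <- cbind(1, history$t_weeks, history$cycles_completed,
             history$paracenteses_cum)
  Z <- cbind(1, history$t_weeks)
  r <- y - drop(X %*% beta)
  Dinv <- tryCatch(solve(D), error = function(e) solve(D + diag(1e-10, 2)))
  Q <- Dinv + crossprod(Z) / sigma^2
  mu <- solve(Q, crossprod(Z, r) / sigma^2)
  R <- chol(Q)
  drop(mu + backsolve(R, stats::rnorm(2)))
}

#' Dynamic prediction of the resectability-decision probability
#'
#' @param fit A fitted [fit_jm()] posterior.
#' @param history Longitudinal records of the patient up to the landmark
#'   (may have zero rows: the prediction then uses baseline covariates
#'   alone, marginalized over the random-effects prior).
#' @param baseline_row One-row data frame with the hazard covariates used
#'   in the fit plus `n_cycles_total` and `n_paracenteses_total` (to extend
#'   the covariate path beyond the history).
#' @param landmark Landmark time t in weeks; defaults to the last history
#'   time (0 for an empty history). All history times must be `<=`
#'   landmark.
#' @param horizons Increasing grid of horizons `>= landmark`; default
#'   weekly steps from the landmark to the largest decision time seen at
#'   fitting.
#' @param n_draws Number of posterior draws used (taken evenly through the
#'   kept sample).
#' @return A tibble of class `ca125_dynpred` with columns `patient_id`,
#'   `landmark`, `horizon`, `prob`, `conf.low`, `conf.high`, `n_mc`; the
#'   history is attached as attribute `"history"` for plotting.
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_config(n_patients = 40, seed = 2))
#' fit <- fit_jm(coh$longitudinal, coh$baseline,
#'               control = jm_control(n_chains = 1, n_iter = 400,
#'                                    burn_in = 200, thin = 4))
#' fx <- fixture_patients()
#' pr <- predict_event_probability(
#'   fit, dplyr::filter(fx$longitudinal, patient_id == "A"),
#'   dplyr::filter(fx$baseline, patient_id == "A")
#' )
#' }
#' @export
predict_event_probability <- function(fit, history, baseline_row,
                                      landmark = NULL, horizons = NULL,
                                      n_draws = 200) {
  stopifnot(inherits(fit, "ca125_jm"))
  if (nrow(fit$samples) == 0) {
    rlang::abort("posterior has no draws.", class = "ca125jm_error_posterior")
  }
  baseline_row <- as.list(baseline_row)
  landmark <- landmark %||% if (nrow(history)) max(history$t_weeks) else 0
  if (nrow(history) && any(history$t_weeks > landmark + 1e-9)) {
    rlang::abort("history contains measurement times after the landmark.",
                 class = "ca125jm_error_landmark")
  }
  if (is.null(horizons)) {
    u_max <- max(max(fit$data$time), landmark)
    horizons <- unique(c(landmark, seq(ceiling(landmark), u_max, by = 1)))
    horizons <- sort(horizons[horizons >= landmark])
  }
  if (is.unsorted(horizons, strictly = TRUE) || any(horizons < landmark - 1e-9)) {
    rlang::abort("`horizons` must be strictly increasing and >= landmark.",
                 class = "ca125jm_error_landmark")
  }
  if (abs(horizons[1] - landmark) > 1e-9) horizons <- c(landmark, horizons)

  q <- patient_quad(fit, history, baseline_row, horizons)
  wvec <- as.numeric(unlist(baseline_row[fit$data$covariates]))
  M <- nrow(fit$samples)
  idx <- unique(round(seq(1, M, length.out = min(n_draws, M))))
  smp <- fit$samples
  K <- fit$data$K
  lam_cols <- paste0("lambda", seq_len(K))
  gam_cols <- paste0("gamma_", fit$data$covariates)
  nh <- length(horizons)
  probs <- matrix(0, length(idx), nh)
  for (m in seq_along(idx)) {
    i <- idx[m]
    beta <- unlist(smp[i, c("beta1", "beta2", "beta3", "beta4")],
                   use.names = FALSE)
    sigma <- smp$sigma[i]
    s0 <- smp$sd_intercept[i]; s1 <- smp$sd_slope[i]; rho <- smp$cor_b[i]
    D <- matrix(c(s0^2, rho * s0 * s1, rho * s0 * s1, s1^2), 2, 2)
    gamma <- unlist(smp[i, gam_cols], use.names = FALSE)
    alpha <- smp$alpha[i]
    lam <- unlist(smp[i, lam_cols], use.names = FALSE)
    b <- draw_conditional_b(history, beta, D, sigma)
    if (length(q$t)) {
      mnode <- (beta[1] + b[1]) + (beta[2] + b[2]) * q$t +
        beta[3] * q$cyc + beta[4] * q$par
      contrib <- q$w * lam[q$piece] * exp(alpha * mnode) *
        exp(sum(gamma * wvec))
      bins <- numeric(nh)
      agg <- rowsum(contrib, q$hidx)
      bins[as.integer(rownames(agg))] <- agg
      Hh <- cumsum(bins)
      probs[m, ] <- 1 - exp(-(Hh - Hh[1]))
    }
  }
  out <- tibble::tibble(
    patient_id = rep(baseline_row$patient_id %||% "new", nh),
    landmark = landmark,
    horizon = horizons,
    prob = colMeans(probs),
    conf.low = apply(probs, 2, stats::quantile, 0.025),
    conf.high = apply(probs, 2, stats::quantile, 0.975),
    n_mc = length(idx)
  )
  class(out) <- c("ca125_dynpred", class(out))
  attr(out, "history") <- history
  out
}

#' Sequential (landmark-by-landmark) dynamic prediction
#'
#' Re-evaluates the event-probability forecast at every measurement time,
#' each time conditioning only on the records available by that landmark --
#' the update behaviour a clinician sees as new CA-125 values arrive.
#'
#' @inheritParams predict_event_probability
#' @param stream Longitudinal records of the patient in time order (a
#'   zero-row stream yields a single baseline-only prediction at t = 0).
#' @param horizon_max Largest horizon; default the largest decision time
#'   seen at fitting.
#' @return A tibble of class `ca125_dynpred` (and `ca125_dynpred_seq`) with
#'   one block of horizon rows per landmark.
#' @export
sequential_update <- function(fit, stream, baseline_row, horizon_max = NULL,
                              n_draws = 200) {
  if (nrow(stream) && is.unsorted(stream$t_weeks, strictly = TRUE)) {
    rlang::abort("measurement stream is out of time order.",
                 class = "ca125jm_error_stream")
  }
  horizon_max <- horizon_max %||% max(fit$data$time)
  landmarks <- if (nrow(stream)) unique(stream$t_weeks) else 0
  out <- purrr::map_dfr(landmarks, function(lm) {
    hz <- unique(c(lm, seq(ceiling(lm), horizon_max, by = 1)))
    hz <- sort(hz[hz >= lm])
    predict_event_probability(
      fit, dplyr::filter(stream, .data$t_weeks <= lm + 1e-9), baseline_row,
      landmark = lm, horizons = hz, n_draws = n_draws
    )
  })
  class(out) <- c("ca125_dynpred_seq", "ca125_dynpred", class(tibble::tibble()))
  attr(out, "history") <- stream
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.ca125_dynpred <- function(object, ...) {
  hist <- attr(object, "history")
  p_prob <- tibble::tibble(
    panel = "P(resectable decision)",
    t = object$horizon, value = object$prob,
    lo = object$conf.low, hi = object$conf.high,
    landmark = object$landmark
  )
  if (inherits(object, "ca125_dynpred_seq")) {
    final <- dplyr::filter(dplyr::group_by(object, .data$landmark),
                           .data$horizon == max(.data$horizon))
    p_prob <- tibble::tibble(
      panel = "P(resectable decision)",
      t = final$landmark, value = final$prob,
      lo = final$conf.low, hi = final$conf.high,
      landmark = final$landmark
    )
  }
  dfs <- p_prob
  if (!is.null(hist) && nrow(hist)) {
    dfs <- dplyr::bind_rows(
      tibble::tibble(panel = "CA-125 (IU/mL)", t = hist$t_weeks,
                     value = hist$ca125_iu_ml, lo = NA_real_, hi = NA_real_,
                     landmark = NA_real_),
      p_prob
    )
  }
  ggplot2::ggplot(dfs, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "steelblue", alpha = 0.25, na.rm = TRUE) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~panel, scales = "free", ncol = 2) +
    ggplot2::labs(x = "weeks since first chemotherapy cycle", y = NULL) +
    ggplot2::theme_minimal()
}

#' Spaghetti plot of cohort CA-125 trajectories
#'
#' Individual marker trajectories on a log scale, split by the eventual
#' resectability decision, with the per-group median overlaid.
#'
#' @param longitudinal,baseline Cohort tables.
#' @return A ggplot object.
#' @export
plot_cohort <- function(longitudinal, baseline) {
  df <- dplyr::left_join(longitudinal,
                         baseline[, c("patient_id", "resectable")],
                         by = "patient_id")
  df$group <- ifelse(df$resectable, "resectable", "not resectable")
  med <- dplyr::summarise(
    dplyr::group_by(df, .data$group, .data$t_weeks),
    ca125 = stats::median(.data$ca125_iu_ml), .groups = "drop"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$t_weeks, .data$ca125_iu_ml,
                                   group = .data$patient_id)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::geom_line(data = med,
                       ggplot2::aes(y = .data$ca125, group = .data$group),
                       color = "blue", linewidth = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "weeks since first chemotherapy cycle",
                  y = "CA-125 (IU/mL)") +
    ggplot2::theme_minimal()
}
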