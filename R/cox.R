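# Proportional-hazards sub-model for the resectability decision.
#
# Patients are followed from the first chemotherapy cycle to the operability
# decision; a resectable decision is the event and a non-resectable decision
# is censoring at the same time. The partial likelihood uses Efron's tie
# correction (decision dates cluster on review-meeting grids, so ties are
# expected) and is maximized by Newton-Raphson with step-halving.

cox_prepare <- function(baseline, covariates,
                        time = "decision_time_weeks", status = "resectable") {
  missing <- setdiff(c(time, status, covariates), names(baseline))
  if (length(missing)) {
    rlang::abort(paste0("baseline table lacks column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "ca125jm_error_schema")
  }
  Xm <- as.matrix(dplyr::mutate(baseline[, covariates, drop = FALSE],
                                dplyr::across(dplyr::everything(), as.numeric)))
  list(time = baseline[[time]], status = as.numeric(baseline[[status]]), X = Xm)
}

# Efron log partial likelihood, gradient and Hessian in one pass.
cox_efron <- function(gamma, time, status, X, derivatives = TRUE) {
  eta <- drop(X %*% gamma)
  w <- exp(eta)
  ll <- 0
  p <- ncol(X)
  grad <- numeric(p)
  hess <- matrix(0, p, p)
  for (tj in sort(unique(time[status == 1]))) {
    Dset <- which(time == tj & status == 1)
    Rset <- which(time >= tj)
    dj <- length(Dset)
    sR <- sum(w[Rset]); sD <- sum(w[Dset])
    aR <- colSums(X[Rset, , drop = FALSE] * w[Rset])
    aD <- colSums(X[Dset, , drop = FALSE] * w[Dset])
    bR <- crossprod(X[Rset, , drop = FALSE] * sqrt(w[Rset]))
    bD <- crossprod(X[Dset, , drop = FALSE] * sqrt(w[Dset]))
    ll <- ll + sum(eta[Dset])
    for (l in seq_len(dj) - 1) {
      f <- l / dj
      s <- sR - f * sD
      ll <- ll - log(s)
      if (derivatives) {
        a <- aR - f * aD
        bmat <- bR - f * bD
        grad <- grad - a / s
        hess <- hess - (bmat / s - tcrossprod(a) / s^2)
      }
    }
    if (derivatives) grad <- grad + colSums(X[Dset, , drop = FALSE])
  }
  list(loglik = ll, grad = grad, hess = hess)
}

#' Efron-corrected Cox log partial likelihood
#'
#' @param baseline Baseline table with `decision_time_weeks` and
#'   `resectable` (event = resectable decision; non-resectable = censored).
#' @param gamma Coefficient vector aligned with `covariates`.
#' @param covariates Character vector of covariate column names.
#' @return Scalar log partial likelihood.
#' @export
cox_partial_loglik <- function(baseline, gamma, covariates) {
  d <- cox_prepare(baseline, covariates)
  if (sum(d$status) == 0) {
    rlang::abort("no events (resectable decisions) in the data.",
                 class = "ca125jm_error_noevents")
  }
  cox_efron(gamma, d$time, d$status, d$X, derivatives = FALSE)$loglik
}

#' Fit the proportional-hazards sub-model
#'
#' Newton-Raphson with step-halving from `gamma = 0`; convergence when the
#' gradient max-norm drops below `tol`. Monotone likelihood (perfect
#' separation) is flagged when a coefficient passes 15 in absolute value
#' and the fit is returned with `converged = FALSE`.
#'
#' @inheritParams cox_partial_loglik
#' @param tol Gradient max-norm tolerance.
#' @param max_iter Newton iteration cap.
#' @return An object of class `ca125_cox`: coefficients, standard errors
#'   from the inverse observed information, hazard ratios with Wald 95%
#'   intervals and p-values, `loglik`, `converged`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 60, seed = 3))
#' fit_cox(coh$baseline, c("ps", "pc_epigastric"))
#' @export
fit_cox <- function(baseline, covariates, tol = 1e-8, max_iter = 50) {
  d <- cox_prepare(baseline, covariates)
  if (sum(d$status) == 0) {
    rlang::abort("no events (resectable decisions) in the data.",
                 class = "ca125jm_error_noevents")
  }
  const <- apply(d$X, 2, function(x) stats::var(x) == 0)
  if (any(const)) {
    rlang::abort(paste0("constant covariate(s): ",
                        paste(covariates[const], collapse = ", ")),
                 class = "ca125jm_error_design")
  }
  p <- ncol(d$X)
  gamma <- numeric(p)
  cur <- cox_efron(gamma, d$time, d$status, d$X)
  converged <- FALSE
  separated <- FALSE
  for (it in seq_len(max_iter)) {
    if (max(abs(cur$grad)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(-cur$hess, cur$grad), error = function(e) NULL)
    if (is.null(step)) break
    for (half in 0:20) {
      cand <- gamma + step / 2^half
      nxt <- cox_efron(cand, d$time, d$status, d$X)
      if (is.finite(nxt$loglik) && nxt$loglik >= cur$loglik - 1e-12) break
    }
    gamma <- cand
    cur <- nxt
    if (any(abs(gamma) > 15)) { separated <- TRUE; break }
  }
  if (separated) {
    rlang::warn("monotone partial likelihood (separation) detected; estimates diverge.",
                class = "ca125jm_warn_separation")
    converged <- FALSE
  }
  vc <- tryCatch(solve(-cur$hess), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(vc), 0))
  z <- gamma / se
  out <- list(
    gamma_hat = stats::setNames(gamma, covariates),
    se = stats::setNames(se, covariates),
    vcov = vc,
    hr = exp(gamma),
    ci95 = cbind(lower = exp(gamma - 1.96 * se), upper = exp(gamma + 1.96 * se)),
    p = 2 * stats::pnorm(-abs(z)),
    loglik = cur$loglik,
    n = length(d$time), n_events = sum(d$status),
    converged = converged
  )
  class(out) <- "ca125_cox"
  out
}

#' @export
print.ca125_cox <- function(x, ...) {
  cat("<ca125_cox>", x$n, "patients,", x$n_events, "events",
      if (!x$converged) "(NOT converged)", "\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ca125_cox <- function(x, ...) {
  tibble::tibble(
    term = names(x$gamma_hat),
    estimate = unname(x$gamma_hat),
    std.error = unname(x$se),
    hr = unname(x$hr),
    conf.low = unname(x$ci95[, "lower"]),
    conf.high = unname(x$ci95[, "upper"]),
    p.value = unname(x$p)
  )
}

#' @exportS3Method generics::glance
glance.ca125_cox <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, nobs = x$n, n_events = x$n_events,
                 converged = x$converged)
}

#' Univariate covariate screening
#'
#' Fits one single-covariate proportional-hazards model per candidate and
#' tabulates hazard ratios, intervals and Wald p-values, sorted by p-value.
#' Constant candidates are skipped with a warning. Candidates passing
#' `p < alpha` feed the multivariate sub-model and the joint model.
#'
#' @inheritParams cox_partial_loglik
#' @param candidates Character vector of candidate covariate columns.
#' @param alpha Selection threshold on the Wald p-value.
#' @return A tibble with one row per screened candidate and a logical
#'   `selected` column.
#' @export
univariate_screen <- function(baseline, candidates, alpha = 0.05) {
  empty <- tibble::tibble(term = character(), estimate = numeric(),
                          std.error = numeric(), hr = numeric(),
                          conf.low = numeric(), conf.high = numeric(),
                          p.value = numeric(), selected = logical())
  if (length(candidates) == 0L) return(empty)
  rows <- purrr::map(candidates, function(v) {
    x <- baseline[[v]]
    if (is.null(x) || stats::var(as.numeric(x)) == 0) {
      rlang::warn(paste0("candidate `", v, "` has zero variance; skipped."))
      return(NULL)
    }
    tidy(fit_cox(baseline, v))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) return(empty)
  out <- dplyr::arrange(out, .data$p.value)
  dplyr::mutate(out, selected = .data$p.value < alpha)
}
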