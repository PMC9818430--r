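# Discrimination and calibration machinery: stratified k-fold
# cross-validation of the joint model with time-dependent AUC and a
# Brier-type prediction error, both with inverse-probability-of-censoring
# weights from a Kaplan-Meier estimator of the censoring distribution;
# fixed cut-off comparator rules; and simple two-group cohort tests.

#' Stratified k-fold split
#'
#' Partitions patients into `k` folds of sizes differing by at most one,
#' balancing the outcome proportion across folds (shuffle within stratum,
#' deal cyclically, carrying the deal position across strata).
#'
#' @param ids Patient identifiers.
#' @param k Number of folds (>= 2; `k = length(ids)` is leave-one-out).
#' @param stratify_by Optional vector (same length as `ids`) whose levels
#'   are balanced across folds, typically the resectability outcome.
#' @param seed Integer seed.
#' @return A tibble with `patient_id` and `fold`.
#' @export
kfold_split <- function(ids, k, stratify_by = NULL, seed = 1L) {
  if (k < 2) rlang::abort("`k` must be at least 2.", class = "ca125jm_error_cv")
  if (k > length(ids)) {
    rlang::abort("`k` cannot exceed the number of patients.",
                 class = "ca125jm_error_cv")
  }
  set.seed(as.integer(seed))
  strata <- if (is.null(stratify_by)) rep(1L, length(ids)) else
    as.integer(factor(stratify_by))
  fold <- integer(length(ids))
  pos <- 0L
  for (s in sort(unique(strata))) {
    idx <- which(strata == s)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((pos + seq_along(idx) - 1L) %% k) + 1L
    pos <- pos + length(idx)
  }
  tibble::tibble(patient_id = ids, fold = fold)
}

ipcw_weights <- function(time, status, landmark, horizon) {
  at_risk <- time > landmark
  G <- km_censoring(time[at_risk], status[at_risk])
  case <- at_risk & status == 1 & time <= horizon
  control <- (time > horizon) | (time >= horizon & status == 0)
  w <- numeric(length(time))
  Gl <- G(landmark)
  w[case] <- Gl / pmax(G(time[case], minus = TRUE), 1e-10)
  w[control & at_risk] <- Gl / pmax(G(horizon, minus = TRUE), 1e-10)
  list(case = case, control = control & at_risk, w = w, at_risk = at_risk)
}

#' Time-dependent AUC with censoring weights
#'
#' Probability that a randomly chosen case (event in `(landmark, horizon]`)
#' receives a higher predicted risk than a randomly chosen control
#' (event-free at the horizon), ties counted one half (Mann-Whitney form),
#' with inverse-probability-of-censoring weights from a Kaplan-Meier
#' estimator of the censoring distribution among patients at risk at the
#' landmark.
#'
#' @param predictions Data frame with columns `risk` (predicted event
#'   probability or any risk score), `time` (decision time), `status`
#'   (1 = resectable decision, 0 = censored).
#' @param landmark,horizon Evaluation window `(landmark, horizon]` in weeks.
#' @return Scalar AUC in `[0, 1]`; `NA` with a warning when there are no
#'   cases or no controls.
#' @export
time_dependent_auc <- function(predictions, landmark, horizon) {
  p <- predictions$risk; time <- predictions$time; status <- predictions$status
  ww <- ipcw_weights(time, status, landmark, horizon)
  if (!any(ww$case) || !any(ww$control)) {
    rlang::warn("AUC undefined: no cases or no controls in the window.",
                class = "ca125jm_warn_auc_undefined")
    return(NA_real_)
  }
  pi_ <- p[ww$case]; wi <- ww$w[ww$case]
  pj <- p[ww$control]; wj <- ww$w[ww$control]
  cmp <- outer(pi_, pj, function(a, b) (a > b) + 0.5 * (a == b))
  sum(outer(wi, wj) * cmp) / (sum(wi) * sum(wj))
}

#' Brier-type prediction error with censoring weights
#'
#' Censoring-weighted mean squared difference between the event indicator
#' by the horizon and the predicted probability, over patients at risk at
#' the landmark; patients censored inside the window get weight zero.
#'
#' @inheritParams time_dependent_auc
#' @return Scalar prediction error (>= 0); `NA` with a warning when no
#'   patient has an observable outcome at the horizon.
#' @export
prediction_error <- function(predictions, landmark, horizon) {
  p <- predictions$risk; time <- predictions$time; status <- predictions$status
  ww <- ipcw_weights(time, status, landmark, horizon)
  n_t <- sum(ww$at_risk)
  if (n_t == 0 || !any(ww$case | ww$control)) {
    rlang::warn("prediction error undefined: no observable outcomes at the horizon.",
                class = "ca125jm_warn_pe_undefined")
    return(NA_real_)
  }
  sq <- numeric(length(p))
  sq[ww$case] <- ww$w[ww$case] * (1 - p[ww$case])^2
  sq[ww$control] <- ww$w[ww$control] * (0 - p[ww$control])^2
  sum(sq[ww$at_risk]) / n_t
}

#' Cross-validate the joint model
#'
#' Stratified k-fold cross-validation: the joint model is refitted on each
#' training split (a reduced MCMC budget is the intended use), test-fold
#' patients still decision-free at the landmark are predicted from their
#' history up to the landmark, and discrimination (time-dependent AUC) and
#' accuracy (prediction error) are computed per fold.
#'
#' @inheritParams fit_jm
#' @param k Number of folds.
#' @param landmark Prediction landmark in weeks (default week 9, the end
#'   of the third cycle).
#' @param horizon Evaluation horizon; default the largest decision time.
#' @param n_draws Posterior draws per prediction.
#' @return An object of class `ca125_cv`: per-fold tibble `folds`, the
#'   fold assignment, and summary statistics.
#' @export
cross_validate_jm <- function(longitudinal, baseline,
                              covariates = c("ps", "pc_epigastric"),
                              k = 5, landmark = 9, horizon = NULL,
                              n_pieces = 5,
                              control = jm_control(n_chains = 1, n_iter = 2000,
                                                   burn_in = 1000, thin = 2),
                              n_draws = 200, seed = 1L) {
  horizon <- horizon %||% max(baseline$decision_time_weeks)
  assignment <- kfold_split(baseline$patient_id, k,
                            stratify_by = baseline$resectable, seed = seed)
  folds <- purrr::map_dfr(seq_len(k), function(f) {
    test_ids <- assignment$patient_id[assignment$fold == f]
    train_b <- dplyr::filter(baseline, !.data$patient_id %in% test_ids)
    train_l <- dplyr::filter(longitudinal, !.data$patient_id %in% test_ids)
    if (sum(train_b$resectable) == 0) {
      rlang::warn(paste0("fold ", f, " skipped: training split has no events."))
      return(NULL)
    }
    fit <- suppressWarnings(fit_jm(train_l, train_b, covariates,
                                   n_pieces = n_pieces, control = control,
                                   seed = as.integer(seed) + f))
    test_b <- dplyr::filter(baseline, .data$patient_id %in% test_ids,
                            .data$decision_time_weeks > landmark)
    if (nrow(test_b) == 0) return(NULL)
    risk <- vapply(seq_len(nrow(test_b)), function(i) {
      hist_i <- dplyr::filter(longitudinal,
                              .data$patient_id == test_b$patient_id[i],
                              .data$t_weeks <= landmark + 1e-9)
      pr <- predict_event_probability(fit, hist_i, test_b[i, ],
                                      landmark = landmark,
                                      horizons = c(landmark, horizon),
                                      n_draws = n_draws)
      pr$prob[nrow(pr)]
    }, numeric(1))
    preds <- tibble::tibble(risk = risk, time = test_b$decision_time_weeks,
                            status = as.numeric(test_b$resectable))
    tibble::tibble(
      fold = f, n_test = nrow(test_b),
      auc = suppressWarnings(time_dependent_auc(preds, landmark, horizon)),
      pe = suppressWarnings(prediction_error(preds, landmark, horizon))
    )
  })
  out <- list(
    folds = folds, assignment = assignment,
    landmark = landmark, horizon = horizon, k = k, seed = as.integer(seed),
    auc_mean = mean(folds$auc, na.rm = TRUE),
    auc_range = range(folds$auc, na.rm = TRUE),
    pe_mean = mean(folds$pe, na.rm = TRUE),
    pe_range = range(folds$pe, na.rm = TRUE)
  )
  class(out) <- "ca125_cv"
  out
}

#' @export
print.ca125_cv <- function(x, ...) {
  cat("<ca125_cv> ", x$k, "-fold, landmark ", x$landmark, "w, horizon ",
      x$horizon, "w\n", sep = "")
  cat(sprintf("  AUC %.1f%% [%.1f-%.1f]   PE %.2f%% [%.2f-%.2f]\n",
              100 * x$auc_mean, 100 * x$auc_range[1], 100 * x$auc_range[2],
              100 * x$pe_mean, 100 * x$pe_range[1], 100 * x$pe_range[2]))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ca125_cv <- function(x, ...) x$folds

#' @exportS3Method generics::glance
glance.ca125_cv <- function(x, ...) {
  tibble::tibble(
    k = x$k, landmark = x$landmark, horizon = x$horizon,
    auc_mean = x$auc_mean, auc_min = x$auc_range[1], auc_max = x$auc_range[2],
    pe_mean = x$pe_mean, pe_min = x$pe_range[1], pe_max = x$pe_range[2]
  )
}

#' AUC of a fixed CA-125 cut-off rule
#'
#' Evaluates the classical single-time-point comparators: the binary rule
#' "CA-125 below `threshold` at `timing`" scored against the resectability
#' outcome (Mann-Whitney AUC of a binary predictor; equivalently the
#' balanced accuracy of the rule's ROC point). Patients without a
#' measurement matching the timing are excluded and counted.
#'
#' @param longitudinal,baseline Cohort tables.
#' @param threshold Cut-off in IU/mL.
#' @param timing One of `"after_cycle3"` (first value recorded with at
#'   least three completed cycles), `"nadir"` (minimum over the recorded
#'   trajectory), `"pre_surgery"` (last recorded value).
#' @return A tibble with `timing`, `threshold`, `auc`, `n_used`,
#'   `n_excluded`.
#' @export
cutoff_predictor_auc <- function(longitudinal, baseline, threshold = 75,
                                 timing = c("after_cycle3", "nadir", "pre_surgery")) {
  timing <- match.arg(timing)
  val <- purrr::map_dbl(baseline$patient_id, function(id) {
    tr <- dplyr::arrange(
      dplyr::filter(longitudinal, .data$patient_id == id), .data$t_weeks)
    if (nrow(tr) == 0) return(NA_real_)
    switch(timing,
      after_cycle3 = {
        i <- which(tr$cycles_completed >= 3)
        if (length(i)) tr$ca125_iu_ml[i[1]] else NA_real_
      },
      nadir = min(tr$ca125_iu_ml),
      pre_surgery = tr$ca125_iu_ml[nrow(tr)]
    )
  })
  use <- !is.na(val)
  rule <- as.numeric(val[use] < threshold)
  y <- as.numeric(baseline$resectable[use])
  pos <- rule[y == 1]; neg <- rule[y == 0]
  auc <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  tibble::tibble(timing = timing, threshold = threshold, auc = auc,
                 n_used = sum(use), n_excluded = sum(!use))
}

#' Odds ratio of a 2x2 table
#'
#' `OR = ad / bc` with Haldane's 0.5 continuity correction when any cell is
#' zero, a Woolf log-scale 95% confidence interval, and a two-sided Fisher
#' exact p-value.
#'
#' @param a,b,c,d Nonnegative counts: rows are exposure, columns outcome
#'   (`a` exposed-with-outcome, `b` exposed-without, `c` unexposed-with,
#'   `d` unexposed-without).
#' @return A tibble with `or`, `conf.low`, `conf.high`, `p.value`.
#' @export
odds_ratio_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) {
    rlang::abort("counts must be nonnegative.", class = "ca125jm_error_counts")
  }
  if (a + b == 0 || c + d == 0) {
    rlang::abort("each exposure row must contain at least one subject.",
                 class = "ca125jm_error_counts")
  }
  adj <- if (any(counts == 0)) counts + 0.5 else counts
  or <- (adj[1] * adj[4]) / (adj[2] * adj[3])
  se <- sqrt(sum(1 / adj))
  p <- stats::fisher.test(matrix(c(a, b, c, d), 2, 2, byrow = TRUE))$p.value
  tibble::tibble(
    or = or,
    conf.low = exp(log(or) - 1.96 * se),
    conf.high = exp(log(or) + 1.96 * se),
    p.value = p
  )
}

#' Two-group comparisons of baseline characteristics
#'
#' Compares each listed variable between resectable and non-resectable
#' patients: Fisher's exact test for categorical/logical variables (counts
#' and percentages reported), Mann-Whitney for continuous variables
#' (medians and interquartile ranges reported).
#'
#' @param baseline Baseline table with a logical `resectable` column.
#' @param variables Character vector of columns to compare.
#' @return A tibble with one row per variable: type, per-group summary
#'   strings, and the p-value.
#' @export
two_group_tests <- function(baseline, variables) {
  g <- factor(ifelse(baseline$resectable, "yes", "no"), levels = c("no", "yes"))
  purrr::map_dfr(variables, function(v) {
    x <- baseline[[v]]
    if (is.null(x)) {
      rlang::abort(paste0("unknown variable `", v, "`."),
                   class = "ca125jm_error_schema")
    }
    categorical <- is.logical(x) || is.factor(x) || is.character(x) ||
      (is.numeric(x) && length(unique(x)) <= 4)
    if (categorical) {
      tab <- table(factor(x), g)
      p <- stats::fisher.test(tab)$p.value
      smr <- function(lvl) {
        cnt <- tab[, lvl]
        paste(paste0(rownames(tab), ":", cnt), collapse = " ")
      }
      tibble::tibble(variable = v, type = "categorical",
                     summary_no = smr("no"), summary_yes = smr("yes"),
                     p.value = p)
    } else {
      p <- stats::wilcox.test(x ~ g, exact = FALSE)$p.value
      smr <- function(lvl) {
        xi <- x[g == lvl]
        sprintf("%.1f [%.1f-%.1f]", stats::median(xi),
                stats::quantile(xi, 0.25), stats::quantile(xi, 0.75))
      }
      tibble::tibble(variable = v, type = "continuous",
                     summary_no = smr("no"), summary_yes = smr("yes"),
                     p.value = p)
    }
  })
}
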