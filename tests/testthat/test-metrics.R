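test_that("stratified folds partition the cohort with balanced sizes and
          outcomes", {
  ids <- sprintf("P%02d", 1:77)
  outcome <- rep(c(TRUE, FALSE), c(40, 37))
  f <- kfold_split(ids, 5, stratify_by = outcome, seed = 3)
  sizes <- sort(as.integer(table(f$fold)), decreasing = TRUE)
  expect_equal(sizes, c(16L, 16L, 15L, 15L, 15L))
  expect_setequal(f$patient_id, ids)
  # outcome balance: 40 events over 5 folds = 8 each
  ev <- table(f$fold[outcome])
  expect_true(all(ev == 8))
  expect_identical(f, kfold_split(ids, 5, stratify_by = outcome, seed = 3))
  expect_false(identical(f$fold,
                         kfold_split(ids, 5, outcome, seed = 4)$fold))
})

test_that("leave-one-out and degenerate k are handled", {
  ids <- letters[1:6]
  loo <- kfold_split(ids, 6, seed = 1)
  expect_equal(sort(loo$fold), 1:6)
  expect_error(kfold_split(ids, 1), class = "ca125jm_error_cv")
  expect_error(kfold_split(ids, 10), class = "ca125jm_error_cv")
})

test_that("time-dependent AUC hits the trivial endpoints", {
  perfect <- tibble::tibble(risk = c(0.9, 0.8, 0.2, 0.1),
                            time = c(5, 6, 20, 20),
                            status = c(1, 1, 0, 0))
  expect_equal(time_dependent_auc(perfect, 0, 10), 1)
  flat <- perfect
  flat$risk <- 0.4
  expect_equal(time_dependent_auc(flat, 0, 10), 0.5)
  nocase <- perfect
  nocase$status <- 0
  nocase$time <- c(20, 20, 20, 20)
  expect_warning(a <- time_dependent_auc(nocase, 0, 10),
                 class = "ca125jm_warn_auc_undefined")
  expect_true(is.na(a))
})

test_that("six-subject toy matches the weighted pair-count hand calculation", {
  toy <- tibble::tibble(
    risk = c(0.9, 0.5, 0.8, 0.3, 0.5, 0.6),
    time = c(4, 8, 6, 12, 10, 11),
    status = c(1, 1, 0, 0, 0, 1)
  )
  # censoring KM among subjects at risk at t=2: drops at 6 (4/5), 10 (2/3);
  # case weights 1/G(T-): (1, 1.25); control weights 1/G(10-) = 1.25;
  # pair sum = 3.75 + 1.5625 + 0.78125 + 0 = 6.09375 over 2.25 * 3.75
  expect_equal(time_dependent_auc(toy, 2, 10), 6.09375 / 8.4375,
               tolerance = 1e-12)
  # prediction error from the same hand-weighted computation
  pe_hand <- (1 * (1 - 0.9)^2 + 1.25 * (1 - 0.5)^2 +
                1.25 * (0.3^2 + 0.5^2 + 0.6^2)) / 6
  expect_equal(prediction_error(toy, 2, 10), pe_hand, tolerance = 1e-12)
})

test_that("prediction error has its algebraic fixed points", {
  oracle <- tibble::tibble(risk = c(1, 1, 0, 0), time = c(3, 4, 20, 20),
                           status = c(1, 1, 0, 0))
  expect_equal(prediction_error(oracle, 0, 10), 0)
  half <- oracle
  half$risk <- 0.5
  expect_equal(prediction_error(half, 0, 10), 0.25)
})

test_that("AUC of a predictor and of its negation sum to one", {
  set.seed(9)
  dat <- tibble::tibble(risk = runif(40), time = runif(40, 1, 30),
                        status = rbinom(40, 1, 0.6))
  a1 <- time_dependent_auc(dat, 2, 20)
  dat2 <- dat
  dat2$risk <- -dat$risk
  expect_equal(a1 + time_dependent_auc(dat2, 2, 20), 1, tolerance = 1e-12)
})

test_that("metrics are invariant to subject relabeling", {
  set.seed(10)
  dat <- tibble::tibble(risk = runif(30), time = runif(30, 1, 30),
                        status = rbinom(30, 1, 0.5))
  perm <- dat[sample.int(30), ]
  expect_equal(time_dependent_auc(dat, 1, 20),
               time_dependent_auc(perm, 1, 20), tolerance = 1e-12)
  expect_equal(prediction_error(dat, 1, 20), prediction_error(perm, 1, 20),
               tolerance = 1e-12)
})

test_that("the true conditional probability minimizes prediction error", {
  set.seed(12)
  n <- 600
  p_true <- plogis(rnorm(n, 0, 1.5))
  event <- runif(n) < p_true
  dat <- tibble::tibble(risk = p_true,
                        time = ifelse(event, 5, 50),
                        status = as.numeric(event))
  pe_oracle <- prediction_error(dat, 0, 10)
  for (const in seq(0.1, 0.9, 0.2)) {
    datc <- dat
    datc$risk <- const
    expect_lt(pe_oracle, prediction_error(datc, 0, 10))
  }
})

test_that("fixed cut-off rules score as expected", {
  # a cohort where the nadir rule reproduces the outcome exactly
  long <- tibble::tibble(
    patient_id = rep(sprintf("p%d", 1:10), each = 2),
    t_weeks = rep(c(0, 9), 10),
    ca125_iu_ml = as.vector(rbind(rep(1000, 10),
                                  c(rep(30, 5), rep(400, 5)))),
    cycles_completed = rep(c(0L, 3L), 10),
    paracenteses_cum = 0L
  )
  base <- tibble::tibble(
    patient_id = sprintf("p%d", 1:10),
    resectable = c(rep(TRUE, 5), rep(FALSE, 5)),
    decision_time_weeks = 12
  )
  out <- cutoff_predictor_auc(long, base, threshold = 75, timing = "nadir")
  expect_equal(out$auc, 1)
  expect_equal(out$n_used, 10)
  # after-cycle-3 timing uses the first on-threshold measurement
  out3 <- cutoff_predictor_auc(long, base, threshold = 75,
                               timing = "after_cycle3")
  expect_equal(out3$auc, 1)
  # a rule unrelated to the outcome sits near chance on a null cohort
  coh <- generate_cohort(cohort_config(n_patients = 400, alpha = 0,
                                       gamma_ps = 0, gamma_pc = 0,
                                       seed = 88))
  nul <- cutoff_predictor_auc(coh$longitudinal, coh$baseline, 75,
                              "after_cycle3")
  expect_lt(abs(nul$auc - 0.5), 0.08)
})

test_that("odds ratios follow ad/bc with Haldane correction and Fisher p", {
  ref <- odds_ratio_2x2(33, 7, 13, 24)
  expect_equal(ref$or, 33 * 24 / (7 * 13), tolerance = 1e-12)
  expect_equal(ref$or, 8.7033, tolerance = 1e-4)
  expect_equal(ref$p.value,
               stats::fisher.test(matrix(c(33, 7, 13, 24), 2, byrow = TRUE))$p.value)
  expect_equal(odds_ratio_2x2(10, 10, 10, 10)$or, 1)
  hal <- odds_ratio_2x2(5, 0, 3, 7)
  expect_equal(hal$or, (5.5 * 7.5) / (0.5 * 3.5), tolerance = 1e-12)
  expect_error(odds_ratio_2x2(0, 0, 3, 7), class = "ca125jm_error_counts")
  expect_error(odds_ratio_2x2(-1, 2, 3, 7), class = "ca125jm_error_counts")
})

test_that("two-group tables use exact tests for categories and rank tests
          for continuous variables", {
  base <- tibble::tibble(
    patient_id = sprintf("p%02d", 1:40),
    resectable = rep(c(TRUE, FALSE), 20),
    same = rep(c(TRUE, FALSE), each = 20)[order(rep(1:20, 2))],
    gap = c(rep(1:20, each = 1), rep(101:120, each = 1))[order(rep(c(TRUE, FALSE), 20), decreasing = TRUE)]
  )
  # identical distribution across groups: exact p = 1
  b2 <- tibble::tibble(
    patient_id = sprintf("q%02d", 1:40),
    resectable = rep(c(TRUE, FALSE), each = 20),
    marker = rep(c("x", "y"), 20)
  )
  out <- two_group_tests(b2, "marker")
  expect_equal(out$p.value, 1)
  # disjoint continuous supports separate decisively
  b3 <- tibble::tibble(
    patient_id = sprintf("r%02d", 1:40),
    resectable = rep(c(TRUE, FALSE), each = 20),
    pci = c(runif(20, 0, 5), runif(20, 50, 60))
  )
  out3 <- two_group_tests(b3, "pci")
  expect_equal(out3$type, "continuous")
  expect_lt(out3$p.value, 0.001)
  # an epigastric-involvement split of 20/37 vs 10/40 against the
  # fisher.test oracle
  b4 <- tibble::tibble(
    patient_id = sprintf("s%02d", 1:77),
    resectable = rep(c(FALSE, TRUE), c(37, 40)),
    pc_hh = c(rep(c(TRUE, FALSE), c(20, 17)), rep(c(TRUE, FALSE), c(10, 30)))
  )
  out4 <- two_group_tests(b4, "pc_hh")
  oracle <- stats::fisher.test(table(b4$pc_hh, b4$resectable))$p.value
  expect_equal(out4$p.value, oracle)
  expect_lt(out4$p.value, 0.05)
  expect_error(two_group_tests(b4, "missing_col"),
               class = "ca125jm_error_schema")
})
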