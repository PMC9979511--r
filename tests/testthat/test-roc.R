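# Tie-aware AUC, ROC geometry, Youden cut-points, chi-square and the
# adjusted logistic model.

test_that("AUC equals the pairwise Mann-Whitney oracle on random instances", {
  set.seed(101)
  for (i in 1:200) {
    inst <- random_auc_instance()
    ref <- oracle_pairwise_auc(inst$scores, inst$labels)
    r <- univariate_auc(inst$scores, inst$labels)
    expect_equal(r$auc, max(ref, 1 - ref), tolerance = 1e-12)
    expect_equal(r$orientation, if (ref >= 0.5) 1L else -1L)
  }
})

test_that("AUC equals the trapezoidal area under the reported ROC points", {
  set.seed(102)
  for (i in 1:25) {
    inst <- random_auc_instance()
    r <- univariate_auc(inst$scores, inst$labels)
    p <- r$points
    trap <- sum(diff(p$fpr) * (utils::head(p$tpr, -1) + utils::tail(p$tpr, -1)) / 2)
    expect_equal(r$auc, trap, tolerance = 1e-12)
    # curve is monotone with the required endpoints
    expect_true(all(diff(p$fpr) >= 0) && all(diff(p$tpr) >= 0))
    expect_equal(c(p$fpr[1], p$tpr[1]), c(0, 0))
    expect_equal(c(p$fpr[nrow(p)], p$tpr[nrow(p)]), c(1, 1))
    expect_gte(r$auc, 0.5)
  }
})

test_that("complement symmetry: auc(scores) + auc(-scores) = 1 pre-orientation", {
  set.seed(103)
  for (i in 1:50) {
    inst <- random_auc_instance()
    a <- oracle_pairwise_auc(inst$scores, inst$labels)
    b <- oracle_pairwise_auc(-inst$scores, inst$labels)
    expect_equal(a + b, 1, tolerance = 1e-12)
    # oriented magnitudes agree between the two sign conventions
    expect_equal(univariate_auc(inst$scores, inst$labels)$auc,
                 univariate_auc(-inst$scores, inst$labels)$auc,
                 tolerance = 1e-12)
  }
})

test_that("degenerate and edge inputs behave as defined", {
  lab <- rep(c("RA", "OA"), each = 3)
  expect_equal(univariate_auc(rep(2, 6), lab)$auc, 0.5)          # all ties
  expect_equal(univariate_auc(c(1, 2, 3, 0, 0, 0), lab)$auc, 1)  # separation
  expect_error(univariate_auc(1:3, rep("RA", 3)), "both disease classes")
  expect_error(univariate_auc(c(NA, NA), c("RA", "OA")), "missing|both")
  r <- univariate_auc(c(1, NA, 0, 2), c("RA", "RA", "OA", "OA"))
  expect_equal(r$n_missing, 1)
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(104)
  for (i in 1:10) {
    inst <- random_auc_instance()
    ref <- as.numeric(suppressMessages(pROC::auc(
      pROC::roc(inst$labels, as.numeric(inst$scores), levels = c("OA", "RA"),
                direction = "<"))))
    expect_equal(univariate_auc(inst$scores, inst$labels)$auc,
                 max(ref, 1 - ref), tolerance = 1e-10)
  }
})

test_that("Youden cut equals the exhaustive scan oracle", {
  set.seed(105)
  for (i in 1:100) {
    inst <- random_auc_instance()
    r <- univariate_auc(inst$scores, inst$labels)
    thr <- youden_threshold(r)
    ref <- oracle_youden(inst$scores, inst$labels, r$orientation)
    expect_equal(thr$J, ref$J, tolerance = 1e-12)
    expect_equal(thr$sensitivity + thr$specificity - 1, thr$J,
                 tolerance = 1e-12)
  }
})

test_that("Youden handles perfect and degenerate separators", {
  lab <- rep(c("RA", "OA"), each = 3)
  thr <- youden_threshold(univariate_auc(c(5, 6, 7, 1, 2, 3), lab))
  expect_equal(thr$J, 1)
  expect_equal(thr$sensitivity, 1)
  expect_equal(thr$specificity, 1)
  flat <- youden_threshold(univariate_auc(rep(1, 6), lab))
  expect_equal(flat$J, 0)
})

test_that("chi-square matches published group comparisons and null behavior", {
  # sex distribution of the reference cohorts: 90/57 vs 50/10 female/male
  sex <- rbind(OA = c(90, 57), RA = c(50, 10))
  res <- chi_square_feature(sex)
  expect_equal(res$df, 1)
  expect_equal(round(res$p_value, 3), 0.002)
  # identical distributions: statistic 0, p 1
  same <- rbind(OA = c(30, 20), RA = c(30, 20))
  res0 <- chi_square_feature(same)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  # zero margins are the caller's responsibility
  expect_error(chi_square_feature(rbind(c(0, 0), c(1, 2))), "zero-margin")
  expect_error(chi_square_feature(rbind(c(3, 0), c(2, 0))), "zero-margin")
})

test_that("adjusted logistic recovers known effects and flags separation", {
  # null exposure: coefficient near zero at large n
  spec <- default_cohort_spec()
  for (f in names(spec$marginals)) {
    spec$marginals[[f]]$RA <- spec$marginals[[f]]$OA  # no signal anywhere
  }
  spec$n_oa <- 2500L; spec$n_ra <- 2500L
  coh <- sample_cohort(spec, seed = 21)
  fit <- adjusted_logistic(coh, "detritus", "lymphocytic_inflammation")
  est <- fit$coefficients$estimate[fit$coefficients$term == "detritus"]
  expect_lt(abs(est), 0.15)
  expect_gt(fit$exposure_lrt_p, 0.01)

  # known log-odds 1 for a binary exposure, n = 5000: recovered within 0.1
  set.seed(22)
  n <- 5000
  x <- rbinom(n, 1, 0.4)
  z <- rbinom(n, 1, 0.5)
  p <- plogis(-0.5 + 1.0 * x + 0.3 * z)
  df <- blank_cohort_df(n)
  df$patient_id <- sprintf("S%05d", 1:n)
  df$disease <- ifelse(rbinom(n, 1, p) == 1, "RA", "OA")
  df$detritus <- x
  df$fibrin <- z
  coh2 <- as_synovial_cohort(df)
  fit2 <- adjusted_logistic(coh2, "detritus", "fibrin")
  est2 <- fit2$coefficients$estimate[fit2$coefficients$term == "detritus"]
  expect_lt(abs(est2 - 1.0), 0.1)

  # reference cohort: fibrosis stays associated (toward OA) after
  # adjusting for lymphocytic inflammation
  ref <- reference_cohort()
  fit3 <- adjusted_logistic(ref, "fibrosis", "lymphocytic_inflammation")
  expect_lt(fit3$exposure_lrt_p, 0.05)
  fib <- fit3$coefficients[grepl("^fibrosis", fit3$coefficients$term), ]
  expect_true(all(fib$estimate < 0))   # higher fibrosis -> OA

  # perfect separation is reported, not silent
  df3 <- blank_cohort_df(40)
  df3$neutrophils <- as.integer(df3$disease == "RA")
  expect_warning(adjusted_logistic(as_synovial_cohort(df3),
                                   "neutrophils", "fibrin"),
                 "separation")
})
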