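test_that("group-difference tests gate on normality and detect separation", {
  set.seed(1)
  x <- rnorm(30)
  same <- group_difference_test(c(x, x), rep(c(0, 1), each = 30))
  expect_equal(same$p, 1)
  expect_equal(same$test_used, "t")

  sep <- group_difference_test(c(1, 2, 3, 101, 102, 103),
                               rep(c(0, 1), each = 3))
  expect_lt(sep$p, 0.01)

  # heavy-tailed values fail the gate and fall to Mann-Whitney
  set.seed(2)
  y <- exp(rnorm(40, 0, 2))
  mw <- group_difference_test(c(y, y * 2), rep(c(0, 1), each = 40))
  expect_equal(mw$test_used, "mann-whitney")

  # constant group skips the gate
  cst <- group_difference_test(c(rep(5, 10), rnorm(10)),
                               rep(c(0, 1), each = 10))
  expect_equal(cst$test_used, "mann-whitney")
})

test_that("Mann-Whitney U equals the brute-force pair count", {
  expect_equal(mann_whitney_u(c(1, 3, 5), c(2, 4, 6)), 6)
  set.seed(4)
  for (i in 1:20) {
    x <- sample(100, 8); y <- sample(100, 11)
    expect_equal(mann_whitney_u(x, y), oracle_u(x, y))
  }
})

test_that("AUROC follows the pair-fraction definition", {
  expect_equal(auroc(1:4, c(0, 0, 1, 1)), 1)
  expect_equal(auroc(1:4, c(0, 1, 0, 1)), 0.75)
  expect_equal(auroc(rep(2, 6), rep(c(0, 1), 3)), 0.5)
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
  # complement symmetry for tie-free scores
  set.seed(5)
  s <- runif(30); l <- rep(c(0, 1), 15)
  expect_equal(auroc(s, l) + auroc(-s, l), 1)
  # equals the trapezoidal area under the empirical ROC curve
  thr <- sort(unique(s), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(s[l == 1] >= t), 1), 1)
  fpr <- c(0, vapply(thr, function(t) mean(s[l == 0] >= t), 1), 1)
  expect_equal(auroc(s, l), sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2),
               tolerance = 1e-12)
})

test_that("LOOCV emits one held-out probability per subject and ranks a
           strongly monotone feature like the raw feature", {
  set.seed(6)
  x <- c(rnorm(10, 0), rnorm(10, 6))
  l <- rep(c(0, 1), each = 10)
  cv <- loocv_logistic(x, l)
  expect_length(cv$scores, 20)
  expect_true(all(cv$scores >= 0 & cv$scores <= 1))
  expect_equal(auroc(cv$scores, l), auroc(x, l))
  expect_error(loocv_logistic(x[1:8], l[1:8]), "n >= 10")
  expect_error(loocv_logistic(cbind(x, x, x), l), "1-2 columns")
})

test_that("pairwise cross-validated AUROC is unbiased at the null where the
           pooled estimator is pessimistic", {
  set.seed(7)
  reps <- 60
  lp <- po <- numeric(reps)
  for (r in seq_len(reps)) {
    x <- rnorm(60)
    l <- rep(c(0, 1), 30)
    lp[r] <- lpocv_auroc(x, l)
    po[r] <- auroc(loocv_logistic(x, l)$scores, l)
  }
  expect_lt(abs(mean(lp) - 0.5), 0.02)
  expect_lt(mean(po), 0.45)  # documented pessimistic pooling bias
})

test_that("pairwise cross-validated AUROC matches the raw AUROC for a
           strong predictor", {
  set.seed(8)
  x <- c(rnorm(40, 0), rnorm(40, 2))
  l <- rep(c(0, 1), each = 40)
  expect_equal(lpocv_auroc(x, l), auroc(x, l), tolerance = 0.03)
})

test_that("DeLong comparisons behave on degenerate and antithetic scores", {
  set.seed(9)
  s <- rnorm(80); l <- rep(c(0, 1), 40)
  self <- delong_test(s, s, l)
  expect_true(self$flag_zero_var)
  expect_equal(self$p, 1)
  anti <- delong_test(s, -s, l)
  expect_equal(anti$auc_b, 1 - anti$auc_a, tolerance = 1e-12)
  expect_gt(self$var_a, 0)
})

test_that("DeLong test agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  x <- c(rnorm(60), rnorm(60, 1))
  l <- rep(c(0, 1), each = 60)
  a <- x + rnorm(120, 0, 0.5)
  b <- x + rnorm(120, 0, 1.5)
  ours <- delong_test(a, b, l)
  ref <- pROC::roc.test(pROC::roc(l, a, quiet = TRUE),
                        pROC::roc(l, b, quiet = TRUE), method = "delong")
  expect_equal(ours$p, ref$p.value, tolerance = 1e-8)
  expect_equal(ours$auc_a, as.numeric(ref$estimate[1]), tolerance = 1e-12)
  expect_equal(ours$auc_b, as.numeric(ref$estimate[2]), tolerance = 1e-12)
})

test_that("DeLong single-AUROC variance shrinks with sample size", {
  set.seed(10)
  v <- vapply(c(50, 200, 800), function(n) {
    s <- c(rnorm(n / 2), rnorm(n / 2, 1))
    delong_variance(s, rep(c(0, 1), each = n / 2))
  }, numeric(1))
  expect_true(all(diff(v) < 0))
  expect_lt(v[3], v[1] / 8)
})

test_that("cohort reports cover singles plus combinations and rank the
           descriptors as the group statistics imply", {
  ctrl <- reference_group_spec("control", 200)
  frac <- reference_group_spec("fracture", 200)
  co <- sample_descriptor_cohort(ctrl, frac, seed = 13)
  rep1 <- build_reports(co)
  nvars <- length(setdiff(names(co), c("subject_id", "group")))
  expect_equal(nrow(rep1$auroc_table),
               nvars + length(default_combinations()))
  expect_true(all(rep1$auroc_table$AUROC >= 0 &
                    rep1$auroc_table$AUROC <= 1))
  expect_true(all(rep1$group_summary$p > 0 & rep1$group_summary$p <= 1))
  au <- function(nm) rep1$auroc_table$AUROC[rep1$auroc_table$descriptor == nm]
  # binormal ordering from the reference means/SDs:
  # residual displacement > strength > nonlinear energy
  expect_gt(au("D3_mm"), au("F0_N"))
  expect_gt(au("F0_N"), au("E_nl_Nmm"))
  # combination at least as good as its best single component
  expect_gt(au("F0_N + D3_mm"), max(au("F0_N"), au("D3_mm")) - 0.02)
  expect_error(build_reports(co, combinations = list(c("F0_N", "nope"))),
               "missing column")
})

test_that("null cohorts give chance-level discrimination", {
  ctrl <- reference_group_spec("control", 64)
  null_frac <- ctrl; null_frac$label <- "fracture"
  co <- sample_descriptor_cohort(ctrl, null_frac, seed = 17)
  rep0 <- build_reports(co, combinations = list())
  # the pairwise estimator has a null spread of ~0.10 at 64 + 64, so the
  # mean absolute deviation over (correlated) descriptors stays well below
  # the weakest real signal (~0.2 above chance) without being tiny
  expect_lt(mean(abs(rep0$auroc_table$AUROC - 0.5)), 0.15)
  expect_lt(mean(rep0$auroc_table$AUROC) - 0.5, 0.1)
})
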