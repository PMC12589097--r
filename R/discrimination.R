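# ---------------------------------------------------------------------------
# Case-control discrimination statistics: normality-gated group tests,
# leave-one-out cross-validated logistic scores, AUROC (Mann-Whitney
# formulation), and the DeLong test for correlated AUROCs.
# ---------------------------------------------------------------------------

#' Group-difference test with a normality gate
#'
#' Applies a Shapiro-Wilk normality test (alpha = 0.05) to each group; if
#' both pass, an unpaired two-sample t-test is used (Welch by default),
#' otherwise the Mann-Whitney U test. Groups containing constant values
#' skip the gate and take the Mann-Whitney path with tie correction.
#'
#' @param values Numeric vector.
#' @param labels Binary group membership (0/1, logical, or 2-level factor).
#' @param welch Use the Welch (unequal-variance) t-test variant.
#' @param alpha Normality-gate significance level.
#' @return List with `p`, `test_used` (`"t"` or `"mann-whitney"`), and the
#'   per-group Shapiro p-values (`NA` where degenerate).
#' @export
group_difference_test <- function(values, labels, welch = TRUE,
                                  alpha = 0.05) {
  labels <- as_binary_labels(labels)
  x <- values[labels == 0]; y <- values[labels == 1]
  if (length(x) < 3 || length(y) < 3)
    stop("need at least 3 observations per group")
  sw <- function(v) {
    if (length(unique(v)) < 3 || length(v) > 5000) return(NA_real_)
    stats::shapiro.test(v)$p.value
  }
  px <- sw(x); py <- sw(y)
  normal <- !is.na(px) && !is.na(py) && px >= alpha && py >= alpha
  if (normal && stats::sd(x) + stats::sd(y) > 0) {
    p <- stats::t.test(x, y, var.equal = !welch)$p.value
    list(p = p, test_used = "t", shapiro_p = c(px, py))
  } else {
    p <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = TRUE)$p.value)
    list(p = p, test_used = "mann-whitney", shapiro_p = c(px, py))
  }
}

as_binary_labels <- function(labels) {
  if (is.factor(labels) || is.character(labels)) {
    lv <- sort(unique(as.character(labels)))
    if (length(lv) != 2) stop("labels must have exactly two levels")
    # fracture/case is the positive class when recognisable
    pos <- if ("fracture" %in% lv) "fracture" else lv[2]
    return(as.integer(as.character(labels) == pos))
  }
  if (is.logical(labels)) return(as.integer(labels))
  if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
  as.integer(labels)
}

#' Mann-Whitney U statistic (pair-count form)
#'
#' Number of (second-group, first-group) pairs won by the second group,
#' ties counted 1/2.
#'
#' @param x First-group values.
#' @param y Second-group values.
#' @return U statistic for `y` over `x`.
#' @export
mann_whitney_u <- function(x, y) {
  r <- rank(c(x, y))
  ry <- sum(r[(length(x) + 1):(length(x) + length(y))])
  ry - length(y) * (length(y) + 1) / 2
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Fraction of (case, control) pairs in which the case scores higher, with
#' ties counted 1/2: `U / (n1 n0)`.
#'
#' @param scores Numeric predictor or probability, higher = more case-like.
#' @param labels Binary labels (1/`"fracture"` = case).
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  mann_whitney_u(scores[labels == 0], scores[labels == 1]) / (n1 * n0)
}

#' Leave-one-out cross-validated logistic scores
#'
#' For each subject, fits an unpenalised logistic regression (with
#' intercept, features standardised inside the training fold) on the
#' remaining n-1 subjects and records the held-out predicted probability.
#' Perfect separation in a fold is handled by capping the standardised
#' coefficients at `cap`.
#'
#' @param features Numeric vector, matrix or data.frame of 1-2 descriptor
#'   columns.
#' @param labels Binary labels (1/`"fracture"` = case).
#' @param cap Coefficient cap after standardisation.
#' @return List with `scores` (held-out probabilities) and `labels`.
#' @export
loocv_logistic <- function(features, labels, cap = 50) {
  X <- as.matrix(features)
  labels <- as_binary_labels(labels)
  n <- nrow(X)
  if (n < 10) stop("LOOCV logistic needs n >= 10")
  if (ncol(X) > 2) stop("univariate or paired combinations only (1-2 columns)")
  scores <- as.numeric(cpp_loocv_scores(X, labels, cap))
  list(scores = scores, labels = labels)
}

#' Leave-pair-out cross-validated AUROC of a logistic model
#'
#' Every (case, control) pair is held out in turn, the logistic model is
#' refit (with in-fold standardisation) on the remaining n - 2 subjects,
#' and the AUROC is the fraction of pairs whose held-out case probability
#' exceeds the held-out control probability (ties 1/2). Unlike the AUROC
#' of pooled leave-one-out probabilities -- which is pessimistically biased
#' for weak predictors because each fold's calibration shifts against its
#' held-out subject -- the pairwise estimator is nearly unbiased, and is
#' the cross-validated AUROC this package reports for cohort-level
#' discrimination.
#'
#' @param features Numeric vector, matrix or data.frame of 1-2 columns.
#' @param labels Binary labels (1/`"fracture"` = case).
#' @param cap Coefficient cap after standardisation.
#' @return AUROC in [0, 1].
#' @export
lpocv_auroc <- function(features, labels, cap = 50) {
  X <- as.matrix(features)
  labels <- as_binary_labels(labels)
  if (ncol(X) > 2) stop("univariate or paired combinations only (1-2 columns)")
  if (nrow(X) < 10) stop("LPOCV needs n >= 10")
  if (!all(c(0, 1) %in% labels)) stop("both classes must be present")
  cpp_lpocv_auroc(X, labels, cap)
}

#' DeLong test for two correlated AUROCs
#'
#' Placement-value (structural-component) variance/covariance estimator of
#' DeLong et al. for AUROCs computed from paired scores on the same
#' subjects, with a two-sided normal test on the AUROC difference.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Binary labels shared by both score vectors.
#' @return List with `auc_a`, `auc_b`, `var_a`, `var_b`, `cov_ab`, `z`,
#'   `p`, and `flag_zero_var` when the difference has no variance
#'   (identical rankings; `p` = 1).
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as_binary_labels(labels)
  v <- delong_components(cbind(scores_a, scores_b), labels)
  auc <- v$auc
  S <- v$S
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  if (var_diff <= .Machine$double.eps * 100) {
    return(list(auc_a = auc[1], auc_b = auc[2], var_a = S[1, 1],
                var_b = S[2, 2], cov_ab = S[1, 2], z = 0, p = 1,
                flag_zero_var = TRUE))
  }
  z <- (auc[1] - auc[2]) / sqrt(var_diff)
  list(auc_a = auc[1], auc_b = auc[2], var_a = S[1, 1], var_b = S[2, 2],
       cov_ab = S[1, 2], z = z, p = 2 * stats::pnorm(-abs(z)),
       flag_zero_var = FALSE)
}

# DeLong placement values for a score matrix (columns = markers):
# V10[i] = P(score_case_i > score_control) (ties 1/2), V01 likewise.
delong_components <- function(S, labels) {
  S <- as.matrix(S)
  cases <- S[labels == 1, , drop = FALSE]
  ctrls <- S[labels == 0, , drop = FALSE]
  m <- nrow(cases); n <- nrow(ctrls)
  if (m == 0 || n == 0) stop("both classes must be present")
  k <- ncol(S)
  auc <- numeric(k)
  V10 <- matrix(0, m, k); V01 <- matrix(0, n, k)
  for (j in seq_len(k)) {
    # placement by midranks (O(N log N))
    r <- rank(c(cases[, j], ctrls[, j]))
    rc <- r[seq_len(m)]; rn <- r[m + seq_len(n)]
    V10[, j] <- (rc - rank(cases[, j])) / n
    V01[, j] <- 1 - (rn - rank(ctrls[, j])) / m
    auc[j] <- sum(V10[, j]) / m
  }
  S10 <- stats::cov(V10); S01 <- stats::cov(V01)
  list(auc = auc, S = S10 / m + S01 / n)
}

#' Variance of a single AUROC by the DeLong estimator
#' @param scores Score vector.
#' @param labels Binary labels.
#' @return Variance estimate of the AUROC.
#' @export
delong_variance <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  delong_components(cbind(scores), labels)$S[1, 1]
}

#' Group-summary and AUROC discrimination reports for a cohort
#'
#' Builds the two standard report tables from a labelled cohort: a
#' per-variable group summary (mean +/- SD per group with the
#' normality-gated difference test) and an AUROC table for all single
#' descriptors and the requested descriptor pairs, each AUROC computed
#' from pooled LOOCV logistic probabilities, with DeLong p-values versus
#' the reference variables.
#'
#' @param cohort Data.frame with a `group` column and numeric variable
#'   columns (e.g. from [sample_descriptor_cohort()]).
#' @param combinations List of character pairs of descriptor names (default:
#'   the strength-based and elastic-force-based pairings).
#' @param references Character vector of reference variables for the DeLong
#'   comparisons (default `c("aBMD", "trab_vBMD")`, kept if present).
#' @param estimator `"lpocv"` (default) reports the leave-pair-out
#'   cross-validated AUROC ([lpocv_auroc()]); `"pooled"` reports the AUROC
#'   of pooled leave-one-out probabilities, which is pessimistically biased
#'   for weak predictors. DeLong comparisons always use the pooled
#'   per-subject scores, which pair across markers.
#' @return List of class `discrimination_report` with data.frames
#'   `group_summary` and `auroc_table`.
#' @export
build_reports <- function(cohort, combinations = default_combinations(),
                          references = c("aBMD", "trab_vBMD"),
                          estimator = c("lpocv", "pooled")) {
  estimator <- match.arg(estimator)
  if (!"group" %in% names(cohort)) stop("cohort lacks a 'group' column")
  labels <- as_binary_labels(cohort$group)
  vars <- setdiff(names(cohort), c("subject_id", "group"))
  vars <- vars[vapply(cohort[vars], is.numeric, logical(1))]
  for (cmb in combinations) {
    miss <- setdiff(cmb, vars)
    if (length(miss))
      stop("combination references missing column(s): ",
           paste(miss, collapse = ", "))
  }
  references <- intersect(references, vars)

  gs <- do.call(rbind, lapply(vars, function(v) {
    gd <- group_difference_test(cohort[[v]], labels)
    x <- cohort[[v]][labels == 0]; y <- cohort[[v]][labels == 1]
    data.frame(parameter = v,
               control_mean = mean(x), control_sd = stats::sd(x),
               fracture_mean = mean(y), fracture_sd = stats::sd(y),
               p = gd$p, test_used = gd$test_used)
  }))

  all_feats <- c(as.list(vars), combinations)
  names(all_feats) <- vapply(all_feats, paste, character(1), collapse = " + ")
  cv <- lapply(all_feats, function(ft)
    loocv_logistic(cohort[, ft, drop = FALSE], labels))
  ref_cv <- cv[references]
  at <- do.call(rbind, lapply(names(all_feats), function(nm) {
    sc <- cv[[nm]]$scores
    au <- if (estimator == "lpocv")
      lpocv_auroc(cohort[, all_feats[[nm]], drop = FALSE], labels)
    else auroc(sc, labels)
    row <- data.frame(descriptor = nm, AUROC = au)
    for (rf in references) {
      pv <- if (nm == rf) NA_real_ else
        delong_test(sc, ref_cv[[rf]]$scores, labels)$p
      row[[paste0("p_vs_", rf)]] <- pv
    }
    row
  }))
  structure(list(group_summary = gs, auroc_table = at,
                 references = references),
            class = "discrimination_report")
}

#' Default descriptor pairings for combined discrimination
#'
#' Strength (`F0_N`) and linear elastic force (`F1_N`) each paired with the
#' displacement- and energy-type descriptors.
#' @return List of character pairs.
#' @export
default_combinations <- function() {
  c(lapply(c("D0_mm", "E_nl_Nmm", "D2_mm", "D3_mm", "E_dis_Nmm", "E_res_Nmm"),
           function(v) c("F0_N", v)),
    lapply(c("D1_mm", "E_lin_Nmm", "D2_mm", "D3_mm", "E_dis_Nmm", "E_res_Nmm"),
           function(v) c("F1_N", v)))
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat("Group summary (mean +/- sd, difference test):\n")
  print(x$group_summary, row.names = FALSE, digits = 4)
  cat("\nLOOCV-logistic AUROC table:\n")
  print(x$auroc_table, row.names = FALSE, digits = 3)
  invisible(x)
}
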