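# ROC/AUC machinery for nested obesity-classification models.
#
# The AUC is the Mann-Whitney probability that a random case outscores a
# random control (ties counted half), equal to the trapezoidal area under
# the empirical ROC. Variances, confidence intervals and paired curve
# comparisons use the DeLong placement estimator (via pROC), the offline
# equivalent of web-based paired ROC tests.

#' Area under the ROC curve
#'
#' Mann-Whitney estimate via midranks: ties count one half. Invariant under
#' any strictly increasing transform of the scores.
#'
#' @param scores numeric predicted scores/probabilities.
#' @param labels binary outcome (0/1 or logical), 1 = case.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC with DeLong confidence interval and test against 0.5
#'
#' Variance from the DeLong paired-placements estimator, Wald 95% CI, and a
#' two-sided asymptotic p-value against the null AUC = 0.5.
#'
#' @param scores,labels as in [auc()].
#' @param conf_level confidence level (default 0.95).
#' @return list: `auc`, `ci` (length 2), `p`, `n_cases`, `n_controls`.
#' @export
auc_ci_and_test <- function(scores, labels, conf_level = 0.95) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1, na.rm = TRUE); n0 <- sum(labels == 0, na.rm = TRUE)
  if (n1 < 2 || n0 < 2) {
    stop("need at least 2 cases and 2 controls (variance undefined)",
         call. = FALSE)
  }
  r <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  a <- as.numeric(pROC::auc(r))
  v <- as.numeric(pROC::var(r, method = "delong"))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(v)
  p <- if (se == 0) {
    if (abs(a - 0.5) < .Machine$double.eps^0.5) 1 else 0
  } else {
    2 * stats::pnorm(-abs(a - 0.5) / se)
  }
  list(auc = a,
       ci = c(max(0, a - z * se), min(1, a + z * se)),
       p = p, n_cases = n1, n_controls = n0)
}

#' Paired DeLong test between two ROC curves
#'
#' Tests the AUC difference of two models scored on the same subjects,
#' accounting for the correlation between the curves.
#'
#' @param scores_a,scores_b the two models' scores for identical subjects.
#' @param labels shared binary outcome.
#' @return list: `delta_auc` (AUC_b - AUC_a), `auc_a`, `auc_b`, `p`.
#' @export
paired_auc_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop("score vectors and labels must cover identical subjects",
         call. = FALSE)
  }
  labels <- as.integer(labels)
  a_a <- auc(scores_a, labels)
  a_b <- auc(scores_b, labels)
  if (identical(rank(scores_a), rank(scores_b))) {
    return(list(delta_auc = 0, auc_a = a_a, auc_b = a_b, p = 1))
  }
  ra <- pROC::roc(labels, scores_a, quiet = TRUE, direction = "<")
  rb <- pROC::roc(labels, scores_b, quiet = TRUE, direction = "<")
  tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  p <- as.numeric(tst$p.value)
  if (is.nan(p)) p <- 1       # zero-variance difference
  list(delta_auc = a_b - a_a, auc_a = a_a, auc_b = a_b, p = p)
}

#' Empirical ROC curve points
#'
#' @param scores,labels as in [auc()].
#' @return data.frame of (fpr, tpr) stepping through score thresholds from
#'   most to least extreme.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  # collapse tied scores into single steps
  s <- scores[ord]
  last <- !duplicated(s, fromLast = TRUE)
  tpr <- cumsum(y == 1)[last] / n1
  fpr <- cumsum(y == 0)[last] / n0
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

#' One-row ROC summary for a model x outcome
#'
#' @param scores,labels as in [auc()].
#' @param outcome,model labels for the report.
#' @return data.frame row: outcome, model, n_cases, n_controls, auc, ci_lo,
#'   ci_hi, p_model.
#' @export
roc_summary <- function(scores, labels, outcome = "", model = "") {
  s <- auc_ci_and_test(scores, labels)
  data.frame(outcome = outcome, model = model, n_cases = s$n_cases,
             n_controls = s$n_controls, auc = s$auc, ci_lo = s$ci[1],
             ci_hi = s$ci[2], p_model = s$p, stringsAsFactors = FALSE)
}

#' Nested-model AUC report
#'
#' Given ROC summaries of nested models in entry order (covariates, then
#' + SNP-GRSS, then + CNV) within each outcome, appends the change from the
#' previous model: delta AUC and percent delta AUC (100 * delta / previous
#' AUC).
#'
#' @param summaries data.frame of [roc_summary()] rows, models in nested
#'   order within each outcome.
#' @return the report with `delta_auc` and `pct_delta_auc` columns (NA for
#'   each outcome's first model).
#' @export
delta_auc_report <- function(summaries) {
  out <- summaries
  out$delta_auc <- NA_real_
  out$pct_delta_auc <- NA_real_
  for (oc in unique(out$outcome)) {
    idx <- which(out$outcome == oc)
    if (length(idx) < 2) next
    prev <- out$auc[idx[-length(idx)]]
    cur <- out$auc[idx[-1]]
    out$delta_auc[idx[-1]] <- cur - prev
    out$pct_delta_auc[idx[-1]] <- 100 * (cur - prev) / prev
  }
  out
}
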