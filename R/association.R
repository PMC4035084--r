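# Covariate-adjusted association models: OLS and logistic fits with
# centering, an interaction scan at a Bonferroni threshold, nested-model F
# tests, incremental R^2 attribution and the descriptive 2x2 chi-square.

#' Center predictor columns
#'
#' Subtracts the mean (over analyzed subjects) from each requested numeric
#' column, recording the subtracted means for back-transformation. Centering
#' changes intercepts (and lower-order terms in interaction models) but no
#' top-level slope.
#'
#' @param data data.frame.
#' @param terms character vector of column names to center.
#' @return list with `data` (centered) and `centers` (named numeric).
#' @export
center_predictors <- function(data, terms) {
  centers <- numeric(0)
  for (t in terms) {
    mu <- mean(data[[t]], na.rm = TRUE)
    data[[t]] <- data[[t]] - mu
    centers[t] <- mu
  }
  list(data = data, centers = centers)
}

#' Fit an ordinary least squares model
#'
#' Thin wrapper around [stats::lm()] returning a `model_fit`: the
#' coefficient table (estimate, SE, t, p), R^2, overall F with degrees of
#' freedom, residual sum of squares and the n used. Rank-deficient designs
#' are an error naming the aliased terms.
#'
#' @param formula model formula.
#' @param data data.frame.
#' @return object of class `model_fit` (family "linear").
#' @export
fit_linear <- function(formula, data) {
  fit <- stats::lm(formula, data = data)
  if (fit$rank < length(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  s <- summary(fit)
  co <- s$coefficients
  structure(list(
    family = "linear",
    response = deparse(formula[[2]]),
    terms = rownames(co),
    coefficients = data.frame(term = rownames(co),
                              estimate = co[, 1], se = co[, 2],
                              statistic = co[, 3], p = co[, 4],
                              row.names = NULL, stringsAsFactors = FALSE),
    r_squared = s$r.squared,
    fstatistic = s$fstatistic,
    rss = sum(stats::residuals(fit)^2),
    n = length(stats::residuals(fit)),
    df_residual = fit$df.residual,
    formula = formula,
    lm = fit
  ), class = "model_fit")
}

#' Fit a binary logistic model
#'
#' Maximum-likelihood logistic regression via [stats::glm()]; the
#' coefficient table carries odds ratios (exp(coefficient)) and z
#' statistics, and fitted probabilities are exposed for ROC analysis.
#' Single-class outcomes and (quasi-)complete separation are errors.
#'
#' @param formula model formula with a binary response.
#' @param data data.frame.
#' @return object of class `model_fit` (family "logistic") with
#'   `fitted_probabilities`.
#' @export
fit_logistic <- function(formula, data) {
  y <- stats::model.response(stats::model.frame(formula, data))
  if (length(unique(y[!is.na(y)])) < 2) {
    stop("outcome has a single class", call. = FALSE)
  }
  fit <- suppressWarnings(stats::glm(formula, data = data,
                                     family = stats::binomial()))
  if (!fit$converged) stop("logistic fit did not converge", call. = FALSE)
  p <- stats::fitted(fit)
  if (any(p < 1e-10 | p > 1 - 1e-10)) {
    stop("fitted probabilities at 0/1: complete or quasi-complete separation",
         call. = FALSE)
  }
  s <- summary(fit)
  co <- s$coefficients
  structure(list(
    family = "logistic",
    response = deparse(formula[[2]]),
    terms = rownames(co),
    coefficients = data.frame(term = rownames(co),
                              estimate = co[, 1], se = co[, 2],
                              statistic = co[, 3], p = co[, 4],
                              odds_ratio = exp(co[, 1]),
                              row.names = NULL, stringsAsFactors = FALSE),
    n = length(stats::residuals(fit)),
    fitted_probabilities = p,
    formula = formula,
    glm = fit
  ), class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("model_fit (%s): %s, n = %d\n", x$family,
              deparse(x$formula), x$n))
  print(x$coefficients, digits = 4)
  if (x$family == "linear") cat(sprintf("R-squared: %.4f\n", x$r_squared))
  invisible(x)
}

#' Variance-inflation diagnostic
#'
#' VIF_j = 1 / (1 - R^2_j) from regressing each model-matrix column on the
#' others; used to screen correlated predictors (e.g. a SNP tagging a CNV).
#'
#' @param fit a linear `model_fit`.
#' @return named numeric of VIFs (intercept excluded).
#' @export
vif_diagnostic <- function(fit) {
  X <- stats::model.matrix(fit$lm)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  vapply(seq_len(ncol(X)), function(j) {
    r2 <- summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    1 / (1 - r2)
  }, numeric(1)) |> stats::setNames(colnames(X))
}

#' Scan covariate x predictor interactions
#'
#' Each candidate interaction is added one at a time to the base model; a
#' term whose interaction coefficient reaches p < `alpha` (Bonferroni-style
#' threshold, default 0.002) is accepted, and all accepted terms are then
#' added jointly to form the final model. Candidates are tested in the order
#' given, so the scan is deterministic.
#'
#' @param base_formula formula of the base model.
#' @param data data.frame.
#' @param candidates character vector of interaction terms ("a:b").
#' @param alpha acceptance threshold on the interaction p-value.
#' @param family "linear" or "logistic".
#' @return list: `accepted` terms, `scan` (term, p per candidate),
#'   `final` model_fit (base model when nothing is accepted).
#' @export
scan_interactions <- function(base_formula, data, candidates, alpha = 0.002,
                              family = c("linear", "logistic")) {
  family <- match.arg(family)
  fitter <- if (family == "linear") fit_linear else fit_logistic
  pvals <- numeric(length(candidates))
  for (k in seq_along(candidates)) {
    f_k <- stats::update.formula(base_formula,
                                 paste(". ~ . +", candidates[k]))
    fit_k <- fitter(f_k, data)
    co <- fit_k$coefficients
    # the interaction row is the one added last by model.matrix
    row <- co[nrow(co), ]
    pvals[k] <- row$p
  }
  accepted <- candidates[pvals < alpha]
  final_formula <- if (length(accepted) > 0) {
    stats::update.formula(base_formula,
                          paste(". ~ . +", paste(accepted, collapse = " + ")))
  } else base_formula
  list(accepted = accepted,
       scan = data.frame(term = candidates, p = pvals,
                         accepted = pvals < alpha, stringsAsFactors = FALSE),
       final = fitter(final_formula, data))
}

#' Nested-model F test
#'
#' F = ((RSS_r - RSS_f)/q) / (RSS_f/(n - p_f)) with q the number of added
#' coefficients; p-value from F(q, n - p_f). Models must be fit on the same
#' subjects and the reduced model's terms must nest in the full model's.
#'
#' @param reduced,full linear `model_fit`s.
#' @return list: `F`, `df1`, `df2`, `p`.
#' @export
nested_f_test <- function(reduced, full) {
  if (reduced$n != full$n) {
    stop("models must be fit on the same subjects", call. = FALSE)
  }
  if (!all(reduced$terms %in% full$terms)) {
    stop("models are not nested", call. = FALSE)
  }
  q <- length(full$terms) - length(reduced$terms)
  if (q == 0) return(list(F = 0, df1 = 0, df2 = full$df_residual, p = 1))
  fstat <- ((reduced$rss - full$rss) / q) / (full$rss / full$df_residual)
  list(F = fstat, df1 = q, df2 = full$df_residual,
       p = stats::pf(fstat, q, full$df_residual, lower.tail = FALSE))
}

#' Incremental R^2 of nested linear models
#'
#' Delta R^2 = R^2_full - R^2_reduced. With a list of successively nested
#' fits, attributes the increment of each added block sequentially.
#'
#' @param fits either two `model_fit`s (reduced, full) or a list of nested
#'   fits in entry order.
#' @param ... the full model when `fits` is the reduced model.
#' @return for a pair, the scalar delta R^2; for a list, a data.frame with
#'   each step's delta.
#' @export
incremental_r2 <- function(fits, ...) {
  extra <- list(...)
  if (inherits(fits, "model_fit")) {
    full <- extra[[1]]
    if (!all(fits$terms %in% full$terms) || fits$n != full$n) {
      stop("models are not nested on identical subjects", call. = FALSE)
    }
    return(full$r_squared - fits$r_squared)
  }
  r2 <- vapply(fits, `[[`, numeric(1), "r_squared")
  data.frame(step = seq_along(fits)[-1],
             delta_r2 = diff(r2), cumulative_r2 = r2[-1])
}

#' Pearson chi-square for a 2x2 table
#'
#' chi^2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)), no continuity
#' correction; p-value from chi-square with 1 df. Used for the descriptive
#' sex-by-dependence contrasts.
#'
#' @param tab 2x2 matrix (or table) of non-negative counts.
#' @return list: `chi2`, `df`, `p`.
#' @export
pearson_chi2_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0)) {
    stop("need a 2x2 table of non-negative counts", call. = FALSE)
  }
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("zero margin in 2x2 table", call. = FALSE)
  n <- sum(tab)
  chi2 <- n * (a * d - b * c)^2 / prod(margins)
  list(chi2 = chi2, df = 1L,
       p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}
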