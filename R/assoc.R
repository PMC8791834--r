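# Association statistics: univariable logistic odds ratios with BH-FDR,
# proportional-odds trend tests over ordinal RCB, and rank-sum comparisons
# against the pCR class.

#' Univariable (or multiple) logistic regression association with pCR
#'
#' Maximum-likelihood logistic fit of a binary pCR outcome on one feature
#' (optionally adjusting covariates), reporting the odds ratio, Wald 95% CI
#' and two-sided p-value. Complete or quasi-complete separation is flagged
#' and such results carry `separation = TRUE` (excluded from FDR by default
#' in [associate_features()]).
#'
#' @param feature Numeric (or 0/1) predictor vector.
#' @param pcr Binary outcome (logical or 0/1), TRUE = pCR.
#' @param covariates Optional data.frame of adjustment covariates.
#' @param conf Confidence level (default 0.95).
#' @return One-row data.frame: `odds_ratio`, `ci_low`, `ci_high`, `p_value`,
#'   `direction` ("toward pCR" / "toward residual disease"), `separation`.
#' @export
univariable_logistic <- function(feature, pcr, covariates = NULL,
                                 conf = 0.95) {
  y <- as.integer(pcr)
  if (length(unique(y[!is.na(y)])) < 2) stop("both outcome classes required")
  if (stats::sd(feature, na.rm = TRUE) == 0) {
    stop("constant feature: logistic fit is degenerate")
  }
  dat <- data.frame(.y = y, .x = feature)
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = dat, family = stats::binomial())
  )
  co <- summary(fit)$coefficients[".x", ]
  beta <- co[["Estimate"]]
  se <- co[["Std. Error"]]
  z <- stats::qnorm(1 - (1 - conf) / 2)
  # Diverging coefficients / huge SEs indicate separation.
  sep <- !fit$converged || abs(beta) > 15 || se > 100
  data.frame(
    odds_ratio = exp(beta),
    ci_low = exp(beta - z * se),
    ci_high = exp(beta + z * se),
    p_value = co[["Pr(>|z|)"]],
    direction = if (beta >= 0) "toward pCR" else "toward residual disease",
    separation = sep,
    stringsAsFactors = FALSE
  )
}

#' Proportional-odds trend test over ordered RCB classes
#'
#' Fits an ordinal logistic (proportional-odds) model with the ordered RCB
#' response (pCR > RCB-I > RCB-II > RCB-III, i.e. increasing = better
#' response) and a single feature, and tests monotonic association with a
#' likelihood-ratio test against the intercept-only model.
#'
#' @param feature Numeric predictor.
#' @param rcb RCB labels ("pCR", "RCB-I", "RCB-II", "RCB-III") or an ordered
#'   factor.
#' @return One-row data.frame: `coefficient` (log-odds toward pCR per unit),
#'   `se`, `p_value` (LR test).
#' @export
ordinal_trend <- function(feature, rcb) {
  y <- if (is.ordered(rcb)) rcb else as_rcb_factor(rcb)
  ok <- !is.na(feature) & !is.na(y)
  feature <- feature[ok]; y <- droplevels(y[ok])
  if (nlevels(y) < 2) stop("need at least 2 response classes")
  if (nlevels(y) == 2) {
    # Degenerate two-class case nests the binary logistic model.
    fit <- stats::glm(I(y == levels(y)[2]) ~ feature,
                      family = stats::binomial())
    null <- stats::glm(I(y == levels(y)[2]) ~ 1, family = stats::binomial())
    lr <- as.numeric(2 * (stats::logLik(fit) - stats::logLik(null)))
    co <- summary(fit)$coefficients["feature", ]
    return(data.frame(coefficient = co[["Estimate"]],
                      se = co[["Std. Error"]],
                      p_value = stats::pchisq(lr, df = 1,
                                              lower.tail = FALSE)))
  }
  dat <- data.frame(y = y, x = feature)
  fit <- tryCatch(
    MASS::polr(y ~ x, data = dat, Hess = TRUE),
    error = function(e) stop("proportional-odds fit failed: ",
                             conditionMessage(e))
  )
  null <- MASS::polr(y ~ 1, data = dat)
  lr <- as.numeric(2 * (stats::logLik(fit) - stats::logLik(null)))
  se <- sqrt(diag(stats::vcov(fit)))[["x"]]
  data.frame(coefficient = unname(stats::coef(fit)[["x"]]), se = se,
             p_value = stats::pchisq(max(lr, 0), df = 1, lower.tail = FALSE))
}

#' Rank-sum comparisons of each RCB class against pCR
#'
#' Two-sided Wilcoxon rank-sum tests of the feature in every residual-disease
#' class versus the pCR comparator; exact enumeration when the combined class
#' sizes are <= 20, normal approximation with continuity correction
#' otherwise.
#'
#' @param feature Numeric vector.
#' @param classes Class labels (pCR must be one of them).
#' @param reference Comparator class (default "pCR").
#' @return data.frame `class`, `n`, `p_value` (one row per non-reference
#'   class; empty classes skipped with a warning).
#' @export
ranksum_by_class <- function(feature, classes, reference = "pCR") {
  classes <- as.character(classes)
  ref <- feature[classes == reference & !is.na(feature)]
  if (length(ref) == 0) stop("reference class '", reference, "' is empty")
  others <- setdiff(unique(classes), reference)
  rows <- lapply(others, function(cl) {
    x <- feature[classes == cl & !is.na(feature)]
    if (length(x) == 0) {
      warning("class '", cl, "' is empty; skipped")
      return(NULL)
    }
    exact <- (length(x) + length(ref)) <= 20
    p <- suppressWarnings(
      stats::wilcox.test(x, ref, alternative = "two.sided",
                         exact = exact, correct = TRUE)$p.value
    )
    data.frame(class = cl, n = length(x), p_value = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p Vector of p-values in [0, 1].
#' @return q-values (monotone step-up).
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Univariable association scan over a feature matrix
#'
#' Runs [univariable_logistic()] per feature against the binary pCR outcome
#' and adjusts p-values by Benjamini-Hochberg FDR (separated fits excluded
#' from the adjustment by default and reported with NA q).
#'
#' @param X Patients x features numeric matrix / data.frame.
#' @param pcr Binary outcome.
#' @param exclude_separated Exclude flagged separation fits from FDR.
#' @return Tidy data.frame, one row per feature, ordered by p-value.
#' @export
associate_features <- function(X, pcr, exclude_separated = TRUE) {
  X <- as.data.frame(X)
  rows <- lapply(names(X), function(nm) {
    r <- tryCatch(univariable_logistic(X[[nm]], pcr),
                  error = function(e) NULL)
    if (is.null(r)) return(NULL)
    cbind(data.frame(feature = nm, stringsAsFactors = FALSE), r)
  })
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  use <- if (exclude_separated) !out$separation else rep(TRUE, nrow(out))
  out$q_value[use] <- fdr_adjust(out$p_value[use])
  out[order(out$p_value), ]
}
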