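# Model evaluation (ROC/AUC with bootstrap and DeLong uncertainty,
# precision-recall), drop-one feature importance, and the clinical-impact
# projection of the confusion matrix onto a 100-patient cohort.

#' Area under the ROC curve
#'
#' Empirical AUC by the rank (pairwise-concordance) formula, handling ties
#' by mid-rank — equivalent to trapezoidal integration of the ROC curve.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (1 = positive/pCR).
#' @return AUC in [0, 1].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong variance of the empirical AUC via placement values.
delong_ci <- function(scores, labels, conf = 0.95) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(x, function(a) mean(psi(a, y)), 0.0)
  v01 <- vapply(y, function(b) mean(psi(x, b)), 0.0)
  auc <- mean(v10)
  v <- stats::var(v10) / length(x) + stats::var(v01) / length(y)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  c(low = max(0, auc - z * sqrt(v)), high = min(1, auc + z * sqrt(v)))
}

roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  lab <- as.integer(labels)[ord]
  tpr <- c(0, cumsum(lab) / sum(lab))
  fpr <- c(0, cumsum(1 - lab) / sum(1 - lab))
  data.frame(fpr = fpr, tpr = tpr)
}

pr_curve <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  lab <- as.integer(labels)[ord]
  tp <- cumsum(lab)
  precision <- tp / seq_along(lab)
  recall <- tp / sum(lab)
  ap <- sum(diff(c(0, recall)) * precision)
  list(curve = data.frame(recall = recall, precision = precision),
       average_precision = ap)
}

#' Evaluate a model (or raw scores) on a test cohort
#'
#' Empirical ROC and AUC, AUC standard deviation over 100 bootstrap replicas
#' of the test set, a DeLong 95% confidence interval, the precision-recall
#' curve with average precision, and the confusion matrix at a score
#' threshold (default 0.5).
#'
#' @param model A `neo_model`/`neo_predictor`, or a numeric score vector.
#' @param X_test Test feature matrix (ignored when scores are supplied).
#' @param y_test Binary labels.
#' @param n_boot Bootstrap replicas (default 100).
#' @param threshold Score cut-off for the confusion matrix.
#' @param boot_seed Seed of the bootstrap resampling.
#' @return list of class `neo_evaluation`: `auc`, `auc_bootstrap_sd`,
#'   `auc_delong_ci`, `roc`, `pr`, `average_precision`, `confusion`,
#'   `scores`.
#' @export
evaluate <- function(model, X_test = NULL, y_test, n_boot = 100,
                     threshold = 0.5, boot_seed = 1) {
  y <- as.integer(y_test)
  if (length(unique(y)) < 2) stop("both classes required in y_test")
  scores <- if (is.numeric(model)) model else predict(model, X_test)
  auc <- auc_score(scores, y)
  set.seed(boot_seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    idx <- sample(length(y), replace = TRUE)
    if (length(unique(y[idx])) < 2) return(NA_real_)
    auc_score(scores[idx], y[idx])
  }, 0.0)
  pr <- pr_curve(scores, y)
  pred_pos <- scores >= threshold
  confusion <- matrix(c(sum(pred_pos & y == 1), sum(pred_pos & y == 0),
                        sum(!pred_pos & y == 1), sum(!pred_pos & y == 0)),
                      2, 2, dimnames = list(c("pred_pCR", "pred_RD"),
                                            c("pCR", "RD")))
  structure(list(auc = auc, auc_bootstrap_sd = stats::sd(boot, na.rm = TRUE),
                 auc_delong_ci = delong_ci(scores, y),
                 roc = roc_points(scores, y), pr = pr$curve,
                 average_precision = pr$average_precision,
                 confusion = confusion, scores = scores),
            class = "neo_evaluation")
}

#' @export
#' @method print neo_evaluation
print.neo_evaluation <- function(x, ...) {
  cat(sprintf("AUC %.3f (bootstrap SD %.3f, DeLong 95%% CI %.3f-%.3f), AP %.3f\n",
              x$auc, x$auc_bootstrap_sd, x$auc_delong_ci[["low"]],
              x$auc_delong_ci[["high"]], x$average_precision))
  invisible(x)
}

#' Drop-one feature importance z-scores
#'
#' For each classification algorithm separately, refits the full pipeline
#' with each feature removed and measures the AUC change on the training
#' cohort, \eqn{\Delta_i = AUC_{nominal} - AUC_{drop,i}}. The unsigned
#' importance is \eqn{z_i = |\Delta_i| / \sigma(\Delta)} and the signed
#' importance is \eqn{-\Delta_i / \sigma(\Delta)}, so a feature that adds
#' predictive value (dropping it lowers the AUC) gets a negative signed z.
#' Scores are reported per algorithm and averaged across the three.
#'
#' @param model A `neo_model` or single `neo_predictor` (its frozen
#'   hyperparameters are reused for the drop refits).
#' @param X,y Training data.
#' @return data.frame: `feature`, per-algorithm unsigned z, `z_unsigned`
#'   (average), `z_signed` (average), sorted by decreasing `z_unsigned`.
#' @export
feature_importance <- function(model, X, y) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (ncol(X) < 2) stop("cannot drop features from a single-feature matrix")
  predictors <- if (inherits(model, "neo_model")) model$predictors
    else list(model)
  algos <- c("lr", "svm", "rf")
  # Mean over the model's predictors of the per-algorithm AUC change.
  delta <- array(0, dim = c(ncol(X), 3, length(predictors)),
                 dimnames = list(colnames(X), algos, NULL))
  for (pi in seq_along(predictors)) {
    hp <- predictors[[pi]]$hp
    sd_ <- predictors[[pi]]$seed %||% 1
    full <- fit_predictor(X, y, hp, seed = sd_)
    auc_nom <- apply(predictor_scores(full, X), 2,
                     function(s) auc_score(s, y))
    for (j in seq_len(ncol(X))) {
      fit_j <- fit_predictor(X[, -j, drop = FALSE], y, hp, seed = sd_)
      auc_j <- apply(predictor_scores(fit_j, X[, -j, drop = FALSE]), 2,
                     function(s) auc_score(s, y))
      delta[j, , pi] <- auc_nom - auc_j
    }
  }
  d <- apply(delta, c(1, 2), mean)
  sig <- apply(d, 2, stats::sd)
  sig[sig == 0] <- 1
  z_alg <- sweep(d, 2, sig, "/")
  out <- data.frame(
    feature = rownames(d),
    z_lr = abs(z_alg[, "lr"]), z_svm = abs(z_alg[, "svm"]),
    z_rf = abs(z_alg[, "rf"]),
    z_unsigned = rowMeans(abs(z_alg)),
    z_signed = rowMeans(-z_alg),
    stringsAsFactors = FALSE
  )
  out[order(-out$z_unsigned), ]
}

#' Projected clinical impact at a false-negative budget
#'
#' Finds the highest score threshold such that at most `fn_budget` pCR cases
#' fall below it (cases below the threshold are called chemoresistant /
#' predicted non-responders), then rescales the resulting confusion matrix
#' to a cohort of `cohort_size` patients by largest-remainder rounding.
#'
#' @param scores Test-set prediction scores.
#' @param labels Binary labels (1 = pCR).
#' @param fn_budget Allowed false negatives (0 or 2 in the reference
#'   operating points).
#' @param cohort_size Projection cohort size (default 100).
#' @return list: `threshold`, `confusion` (test-set counts: tn, fn, tp,
#'   fp), `projected` (counts per `cohort_size`:
#'   `identified_non_responders`, `false_negatives`, plus tp/fp).
#' @export
clinical_impact <- function(scores, labels, fn_budget = 0,
                            cohort_size = 100) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2) stop("both classes required")
  if (fn_budget >= sum(y == 1)) {
    stop("fn_budget >= number of pCR cases: threshold is degenerate")
  }
  cand <- sort(unique(c(scores, Inf)))
  fn_at <- vapply(cand, function(t) sum(y == 1 & scores < t), 0L)
  ok <- cand[fn_at <= fn_budget]
  thr <- max(ok)
  # resolve ties (identical confusion matrices) toward the lower threshold
  tn_at <- vapply(cand, function(t) sum(y == 0 & scores < t), 0L)
  same <- cand[fn_at == sum(y == 1 & scores < thr) &
                 tn_at == sum(y == 0 & scores < thr)]
  thr <- min(same)
  below <- scores < thr
  conf <- c(tn = sum(below & y == 0), fn = sum(below & y == 1),
            tp = sum(!below & y == 1), fp = sum(!below & y == 0))
  proj <- largest_remainder_round(conf, cohort_size)
  names(proj) <- names(conf)
  list(threshold = thr,
       confusion = conf,
       projected = c(identified_non_responders = proj[["tn"]],
                     false_negatives = proj[["fn"]],
                     tp = proj[["tp"]], fp = proj[["fp"]]))
}

#' Ordinal RCB trend of predictor scores
#'
#' Tests whether model scores are monotonically associated with residual
#' cancer burden by a proportional-odds likelihood-ratio test
#' (delegates to [ordinal_trend()]).
#'
#' @param scores Predictor scores.
#' @param rcb RCB labels.
#' @return As [ordinal_trend()].
#' @export
score_rcb_monotonicity <- function(scores, rcb) {
  ordinal_trend(scores, rcb)
}
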