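# The pCR predictor: a four-step pipeline (collinearity removal, k-best
# selection, z-scaling, classification) ending in three classifiers —
# elastic-net logistic regression, a support vector classifier and a random
# forest — whose probabilities are averaged. Five such predictors trained
# with distinct cross-validation seeds form the model.

#' Hyperparameter search space
#'
#' Bounds of the randomized search: elastic-net C in [1e-3, 1e3]
#' (log-uniform) and L1 ratio in [0.1, 1]; SVM kernel in {radial, sigmoid,
#' linear} with gamma in [1e-9, 1e-2] (log-uniform) and C in [1e-3, 1e3];
#' random forest with 5-100 trees, maximum-feature fraction 0.05-0.70 and
#' minimum samples per split 2-15; and k for the univariable selection step.
#'
#' @param k_max Upper bound of the k-best draw (defaults to the number of
#'   available features at draw time).
#' @return list of bounds, class `hyperparameter_space`.
#' @export
hyperparameter_space <- function(k_max = NULL) {
  structure(list(
    lr_C = c(1e-3, 1e3), lr_l1 = c(0.1, 1),
    svm_kernel = c("radial", "sigmoid", "linear"),
    svm_gamma = c(1e-9, 1e-2), svm_C = c(1e-3, 1e3),
    rf_trees = c(5L, 100L), rf_max_feat = c(0.05, 0.70),
    rf_min_split = c(2L, 15L),
    k_max = k_max
  ), class = "hyperparameter_space")
}

runif_log <- function(bounds) exp(stats::runif(1, log(bounds[1]),
                                               log(bounds[2])))

draw_hyperparameters <- function(space, n_features) {
  k_max <- space$k_max %||% n_features
  list(
    lr_C = runif_log(space$lr_C),
    lr_l1 = stats::runif(1, space$lr_l1[1], space$lr_l1[2]),
    svm_kernel = sample(space$svm_kernel, 1),
    svm_gamma = runif_log(space$svm_gamma),
    svm_C = runif_log(space$svm_C),
    rf_trees = sample(space$rf_trees[1]:space$rf_trees[2], 1),
    rf_max_feat = stats::runif(1, space$rf_max_feat[1],
                               space$rf_max_feat[2]),
    rf_min_split = sample(space$rf_min_split[1]:space$rf_min_split[2], 1),
    k = sample(seq_len(min(k_max, n_features)), 1)
  )
}

#' Default hyperparameters (midpoints of the search space)
#' @return Named list usable by [fit_predictor()].
#' @export
default_hyperparameters <- function() {
  list(lr_C = 1, lr_l1 = 0.5, svm_kernel = "radial", svm_gamma = 1e-3,
       svm_C = 1, rf_trees = 100L, rf_max_feat = 0.3, rf_min_split = 2L,
       k = Inf)
}

# Platt (sigmoid) calibration of SVM decision values into probabilities,
# fitted on the training data.
fit_platt <- function(dv, y) {
  fit <- suppressWarnings(
    stats::glm(y ~ dv, family = stats::binomial())
  )
  stats::coef(fit)
}

predict_platt <- function(coefs, dv) {
  stats::plogis(coefs[1] + coefs[2] * dv)
}

#' Fit a single predictor (preprocessing chain + classifier trio)
#'
#' Fits, in order: collinearity keep-list, ANOVA-F k-best keep-list,
#' z-scaling parameters, then the three classifiers on the scaled selected
#' features. The predictor score for a sample is the unweighted mean of the
#' three class probabilities. SVM margin scores are mapped to probabilities
#' via a sigmoid (Platt) calibration fitted on the training data.
#'
#' @param X Patients x features matrix (cleaned, no missing values).
#' @param y Binary outcome (0/1).
#' @param hp Hyperparameter list (see [default_hyperparameters()]).
#' @param seed Seed for the stochastic classifier fits.
#' @return Object of class `neo_predictor`.
#' @export
fit_predictor <- function(X, y, hp = default_hyperparameters(), seed = 1) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both outcome classes required")
  keep1 <- collinearity_filter(X, y, threshold = 0.8)
  X1 <- X[, keep1, drop = FALSE]
  k <- min(hp$k, ncol(X1))
  keep2 <- select_kbest(X1, y, k)
  X2 <- X1[, keep2, drop = FALSE]
  centre <- colMeans(X2)
  scale_ <- apply(X2, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  Z <- scale(X2, center = centre, scale = scale_)

  set.seed(seed)
  # glmnet requires >= 2 columns; pad single-feature fits with a zero column
  Zg <- if (ncol(Z) == 1) cbind(Z, .pad = 0) else Z
  lr <- glmnet::glmnet(Zg, factor(y), family = "binomial",
                       alpha = hp$lr_l1,
                       lambda = 1 / (hp$lr_C * length(y)))
  svm_fit <- e1071::svm(Z, factor(y), kernel = hp$svm_kernel,
                        gamma = hp$svm_gamma, cost = hp$svm_C,
                        scale = FALSE)
  platt <- fit_platt(as.numeric(attr(stats::predict(svm_fit, Z,
                                                    decision.values = TRUE),
                                     "decision.values")), y)
  rf <- randomForest::randomForest(
    Z, factor(y),
    ntree = hp$rf_trees,
    mtry = max(1, round(hp$rf_max_feat * ncol(Z))),
    nodesize = max(1, ceiling(hp$rf_min_split / 2))
  )
  structure(list(hp = hp, keep_collinearity = keep1, keep_kbest = keep2,
                 centre = centre, scale = scale_, lr = lr, svm = svm_fit,
                 platt = platt, rf = rf, positive = "1", seed = seed),
            class = "neo_predictor")
}

predictor_scores <- function(object, X) {
  X <- as.matrix(X)
  Z <- scale(X[, object$keep_kbest, drop = FALSE],
             center = object$centre, scale = object$scale)
  Zg <- if (ncol(Z) == 1) cbind(Z, .pad = 0) else Z
  p_lr <- as.numeric(stats::predict(object$lr, Zg, type = "response"))
  # Decision-value orientation is absorbed by the Platt slope, which was
  # fitted on training decision values from the same SVM.
  dv <- as.numeric(attr(stats::predict(object$svm, Z,
                                       decision.values = TRUE),
                        "decision.values"))
  p_svm <- as.numeric(predict_platt(object$platt, dv))
  p_rf <- stats::predict(object$rf, Z, type = "prob")[, "1"]
  cbind(lr = p_lr, svm = p_svm, rf = as.numeric(p_rf))
}

#' @export
#' @method predict neo_predictor
predict.neo_predictor <- function(object, newdata, ...) {
  rowMeans(predictor_scores(object, newdata))
}

make_folds <- function(y, n_folds, seed) {
  set.seed(seed)
  idx <- seq_along(y)
  folds <- integer(length(y))
  for (cls in unique(y)) {
    members <- sample(idx[y == cls])
    folds[members] <- rep_len(seq_len(n_folds), length(members))
  }
  folds
}

#' Randomized hyperparameter search by stratified cross-validation
#'
#' Draws `n_iter` joint hyperparameter settings (log-uniform for the C and
#' gamma parameters), scores each by mean AUC over stratified `n_folds`-fold
#' cross-validation of the full pipeline (all preprocessing refitted inside
#' each training fold), and returns the best draw (ties resolved to the
#' first drawn).
#'
#' @param X,y Training data.
#' @param space [hyperparameter_space()].
#' @param n_iter Number of random draws (>= 1).
#' @param cv_seed Seed fixing both the folds and the draw sequence.
#' @param n_folds Number of folds (default 5).
#' @return list: `hp` (best draw), `cv_auc`, `all` (per-draw AUCs).
#' @export
tune <- function(X, y, space = hyperparameter_space(), n_iter = 100,
                 cv_seed = 1, n_folds = 5) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  X <- as.matrix(X)
  y <- as.integer(y)
  if (min(table(y)) < n_folds) stop("too few samples of one class per fold")
  folds <- make_folds(y, n_folds, cv_seed)
  set.seed(substream_seed(cv_seed, 7))
  draws <- replicate(n_iter, draw_hyperparameters(space, ncol(X)),
                     simplify = FALSE)
  aucs <- vapply(seq_len(n_iter), function(d) {
    hp <- draws[[d]]
    fold_auc <- vapply(seq_len(n_folds), function(f) {
      tr <- folds != f
      fit <- fit_predictor(X[tr, , drop = FALSE], y[tr], hp,
                           seed = substream_seed(cv_seed, 100 + f))
      s <- predict(fit, X[!tr, , drop = FALSE])
      if (length(unique(y[!tr])) < 2) return(NA_real_)
      auc_score(s, y[!tr])
    }, 0.0)
    mean(fold_auc, na.rm = TRUE)
  }, 0.0)
  best <- which.max(aucs)
  list(hp = draws[[best]], cv_auc = aucs[best], all = aucs)
}

#' Train a seed-averaged ensemble model
#'
#' Repeats the randomized cross-validation optimization once per seed (by
#' default five distinct seeds), refits each tuned predictor on the full
#' training cohort, and averages the five predictor scores at prediction
#' time.
#'
#' @param X,y Training data.
#' @param seeds Cross-validation seeds (default 1:5; duplicates warn).
#' @param n_iter Random-search iterations per seed (default 100; the
#'   reference configuration used 1000).
#' @param space Hyperparameter space.
#' @return Object of class `neo_model` (list of `neo_predictor`s with their
#'   cross-validation AUCs).
#' @export
train_model <- function(X, y, seeds = 1:5, n_iter = 100,
                        space = hyperparameter_space()) {
  if (anyDuplicated(seeds)) warning("duplicate cross-validation seeds")
  X <- as.matrix(X)
  y <- as.integer(y)
  predictors <- lapply(seeds, function(s) {
    tuned <- tune(X, y, space, n_iter = n_iter, cv_seed = s)
    fit <- fit_predictor(X, y, tuned$hp, seed = substream_seed(s, 9))
    fit$cv_auc <- tuned$cv_auc
    fit
  })
  structure(list(predictors = predictors, seeds = seeds,
                 features = colnames(X),
                 cv_auc = vapply(predictors, function(p) p$cv_auc, 0.0)),
            class = "neo_model")
}

#' @export
#' @method predict neo_model
predict.neo_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)[, object$features, drop = FALSE]
  rowMeans(vapply(object$predictors, function(p) predict(p, newdata),
                  numeric(nrow(newdata))))
}

#' @export
#' @method print neo_model
print.neo_model <- function(x, ...) {
  cat("Ensemble pCR model:", length(x$predictors), "seed-predictors over",
      length(x$features), "features; CV AUC",
      paste(sprintf("%.3f", x$cv_auc), collapse = ", "), "\n")
  invisible(x)
}

#' Train the nested series of six data-integration models
#'
#' Trains one ensemble model per cumulative feature configuration:
#' (1) clinical; (2) clinical+DNA; (3) clinical+RNA; (4) clinical+DNA+RNA;
#' (5) +digital pathology; (6) +treatment.
#'
#' @param features A `neo_features` object (training cohort).
#' @param seeds,n_iter Passed to [train_model()].
#' @return Named list of six `neo_model`s.
#' @export
run_nested_models <- function(features, seeds = 1:5, n_iter = 100) {
  tags <- features$modality
  subsets <- list(
    clinical = "clinical",
    clinical_dna = c("clinical", "DNA"),
    clinical_rna = c("clinical", "RNA"),
    clinical_dna_rna = c("clinical", "DNA", "RNA"),
    clinical_dna_rna_digpath = c("clinical", "DNA", "RNA", "DigPath"),
    fully_integrated = c("clinical", "DNA", "RNA", "DigPath", "treatment")
  )
  lapply(subsets, function(mods) {
    cols <- names(tags)[tags %in% mods]
    if (length(cols) == 0) stop("empty feature subset: ",
                                paste(mods, collapse = "+"))
    train_model(features$X[, cols, drop = FALSE], features$pcr,
                seeds = seeds, n_iter = n_iter)
  })
}
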