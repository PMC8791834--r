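# Predictor pipeline: filtering steps, the classifier trio, tuning,
# seed-averaged models, evaluation, importance and clinical impact.

make_signal_data <- function(n = 120, p = 6, seed = 61, beta = 2) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- rbinom(n, 1, plogis(beta * X[, 1]))
  list(X = X, y = y)
}

test_that("collinearity filter keeps the response-correlated representative", {
  set.seed(62)
  y <- rbinom(80, 1, 0.4)
  base <- rnorm(80) + y
  X <- cbind(a_copy = base + rnorm(80, 0, 1e-6), b_orig = base,
             other = rnorm(80))
  kept <- collinearity_filter(X, y)
  expect_length(kept, 2)
  expect_true("other" %in% kept)
  # the kept duplicate is the one with higher |cor(x, y)|
  ry <- abs(cor(X[, c("a_copy", "b_orig")], y))
  expect_equal(intersect(kept, c("a_copy", "b_orig")),
               rownames(ry)[which.max(ry)])

  # exact ties resolve lexicographically by name
  Xt <- cbind(zz = base, aa = base)
  expect_equal(intersect(collinearity_filter(Xt, y), c("aa", "zz")), "aa")

  # r exactly at the threshold is kept (strictly above removed)
  x1 <- rnorm(200)
  x2 <- rnorm(200)
  x2 <- x1 * 0.8 + x2 * sqrt(1 - 0.64)
  # rescale to force cor exactly 0.8 via construction on residuals
  e <- residuals(lm(x2 ~ x1))
  x2 <- 0.8 * scale(x1)[, 1] + sqrt(1 - 0.64) * scale(e)[, 1]
  Xb <- cbind(u = scale(x1)[, 1], v = x2)
  expect_equal(abs(cor(Xb))[1, 2], 0.8, tolerance = 1e-12)
  expect_length(collinearity_filter(Xb, rbinom(200, 1, 0.5),
                                    threshold = 0.8), 2)

  # independent features pass through untouched
  Xi <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("x", "y2", "z")))
  expect_equal(sort(collinearity_filter(Xi, rbinom(100, 1, 0.5))),
               c("x", "y2", "z"))
  expect_warning(collinearity_filter(cbind(Xi, cst = 1),
                                     rbinom(100, 1, 0.5)), "zero-variance")
})

test_that("k-best selection ranks by the ANOVA F statistic", {
  d <- make_signal_data(n = 200, p = 20, seed = 63, beta = 3)
  expect_equal(sort(select_kbest(d$X, d$y, k = 50)), sort(colnames(d$X)))
  hits <- vapply(1:10, function(i) {
    di <- make_signal_data(n = 200, p = 20, seed = 100 + i, beta = 3)
    select_kbest(di$X, di$y, k = 1) == "f1"
  }, TRUE)
  expect_gte(mean(hits), 0.9)

  # closed-form check against R's own one-way ANOVA
  x <- c(1.2, 3.4, 0.7, 4.1, 2.2, 5.0)
  g <- c(0, 1, 0, 1, 0, 1)
  f_mine <- neopredict:::anova_f(matrix(x, dimnames = list(NULL, "x")), g)
  f_aov <- summary(aov(x ~ factor(g)))[[1]]$`F value`[1]
  expect_equal(unname(f_mine), f_aov, tolerance = 1e-10)
  expect_error(select_kbest(matrix(x), g, k = 0), "k must be")
})

test_that("a predictor averages three calibrated classifiers", {
  d <- make_signal_data(seed = 64)
  fit <- fit_predictor(d$X, d$y, seed = 2)
  s <- predict(fit, d$X)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(s, rowMeans(neopredict:::predictor_scores(fit, d$X)))
  # pipeline order: k-best keep-list is a subset of the collinearity list
  expect_true(all(fit$keep_kbest %in% fit$keep_collinearity))

  # linearly separable toy data is fit perfectly in training
  Xs <- cbind(a = c(rnorm(30, -3), rnorm(30, 3)), b = rnorm(60))
  ys <- rep(0:1, each = 30)
  fs <- fit_predictor(Xs, ys, seed = 3)
  expect_equal(auc_score(predict(fs, Xs), ys), 1.0)
  expect_error(fit_predictor(d$X, rep(1, nrow(d$X))), "both outcome")
})

test_that("prediction commutes with row permutation (no test leakage)", {
  d <- make_signal_data(seed = 65)
  fit <- fit_predictor(d$X, d$y, seed = 4)
  Xnew <- matrix(rnorm(40 * ncol(d$X)), 40,
                 dimnames = list(NULL, colnames(d$X)))
  perm <- sample(40)
  expect_equal(predict(fit, Xnew[perm, ]), predict(fit, Xnew)[perm])
})

test_that("tuning is deterministic and honours n_iter", {
  d <- make_signal_data(seed = 66)
  t1 <- tune(d$X, d$y, n_iter = 1, cv_seed = 9)
  expect_length(t1$all, 1)
  t2 <- tune(d$X, d$y, n_iter = 4, cv_seed = 9)
  t3 <- tune(d$X, d$y, n_iter = 4, cv_seed = 9)
  expect_identical(t2$hp, t3$hp)
  expect_equal(t2$all, t3$all)
  expect_error(tune(d$X, d$y, n_iter = 0), "n_iter")
})

test_that("a five-seed model averages predictors; same seeds collapse", {
  d <- make_signal_data(seed = 67)
  m1 <- suppressWarnings(train_model(d$X, d$y, seeds = c(3, 3), n_iter = 2))
  expect_warning(train_model(d$X, d$y, seeds = c(3, 3), n_iter = 1),
                 "duplicate")
  single <- predict(m1$predictors[[1]], d$X)
  expect_equal(predict(m1, d$X), single)

  m2 <- train_model(d$X, d$y, seeds = 1:2, n_iter = 2)
  m3 <- train_model(d$X, d$y, seeds = 1:2, n_iter = 2)
  expect_equal(predict(m2, d$X), predict(m3, d$X))
})

test_that("the nested series produces six models on tagged subsets", {
  fm <- small_features()
  models <- run_nested_models(fm, seeds = 1, n_iter = 1)
  expect_length(models, 6)
  expect_named(models, c("clinical", "clinical_dna", "clinical_rna",
                         "clinical_dna_rna", "clinical_dna_rna_digpath",
                         "fully_integrated"))
  clin_cols <- names(fm$modality)[fm$modality == "clinical"]
  expect_equal(sort(models$clinical$features), sort(clin_cols))
  expect_length(models$fully_integrated$features, 34)
})

test_that("evaluation reports AUC, uncertainty and precision-recall", {
  scores <- c(0.9, 0.3, 0.6, 0.1)
  labels <- c(1, 1, 0, 0)
  ev <- evaluate(scores, y_test = labels)
  expect_equal(ev$auc, 0.75)   # 3 of 4 concordant pairs
  expect_equal(evaluate(c(0.9, 0.8, 0.2, 0.1), y_test = labels)$auc, 1.0)
  expect_equal(evaluate(c(0.1, 0.2, 0.8, 0.9), y_test = labels)$auc, 0.0)
  expect_error(evaluate(scores, y_test = c(1, 1, 1, 1)), "both classes")

  # DeLong interval cross-checked against an established implementation
  set.seed(68)
  s <- c(rnorm(40, 1), rnorm(60))
  y <- rep(c(1, 0), c(40, 60))
  ci <- neopredict:::delong_ci(s, y)
  ref <- as.numeric(pROC::ci.auc(pROC::roc(y, s, quiet = TRUE),
                                 method = "delong"))
  expect_equal(unname(ci), ref[c(1, 3)], tolerance = 1e-6)
  expect_equal(auc_score(s, y), ref[2], tolerance = 1e-12)

  # average precision against a hand computation on a small case
  pr <- neopredict:::pr_curve(scores, labels)
  expect_equal(pr$average_precision, 0.5 * 1 + 0.5 * 2 / 3)
})

test_that("drop-one importance finds the planted dominant feature", {
  d <- make_signal_data(n = 150, p = 5, seed = 69, beta = 2.5)
  fit <- fit_predictor(d$X, d$y, seed = 5)
  imp <- feature_importance(fit, d$X, d$y)
  expect_equal(imp$feature[1], "f1")
  expect_true(all(imp$z_unsigned >= 0))
  # the value-adding dominant feature carries a negative signed z
  expect_lt(imp$z_signed[imp$feature == "f1"], 0)
  expect_error(feature_importance(fit, d$X[, 1, drop = FALSE], d$y),
               "single-feature")
})

test_that("clinical impact equals an exhaustive threshold sweep", {
  # perfect classifier at 26% prevalence: all 74 non-responders identified
  scores <- c(rep(0.9, 26), rep(0.1, 74))
  labels <- rep(c(1, 0), c(26, 74))
  ci <- clinical_impact(scores, labels, fn_budget = 0)
  expect_equal(unname(ci$projected[["identified_non_responders"]]), 74)
  expect_equal(unname(ci$projected[["false_negatives"]]), 0)
  expect_lte(ci$threshold, min(scores[labels == 1]))

  # crafted score sets vs a brute-force sweep oracle
  sweep_oracle <- function(s, y, budget) {
    cand <- sort(unique(c(s, Inf)))
    best <- -1
    for (t in cand) {
      fn <- sum(y == 1 & s < t)
      tn <- sum(y == 0 & s < t)
      if (fn <= budget && tn > best) best <- tn
    }
    best
  }
  set.seed(70)
  for (rep_i in 1:10) {
    s <- round(runif(10), 2)
    y <- rbinom(10, 1, 0.4)
    if (length(unique(y)) < 2) next
    for (budget in 0:min(2, sum(y) - 1)) {
      got <- clinical_impact(s, y, fn_budget = budget)
      expect_equal(unname(got$confusion[["tn"]]),
                   sweep_oracle(s, y, budget),
                   info = paste("rep", rep_i, "budget", budget))
    }
  }
  expect_error(clinical_impact(scores, labels, fn_budget = 26),
               "degenerate")
})

test_that("model scores carry the ordinal RCB trend of their inputs", {
  set.seed(71)
  lat <- rnorm(300)
  rcb <- cut(lat, c(-Inf, -0.9, 0.2, 0.65, Inf),
             labels = c("RCB-III", "RCB-II", "RCB-I", "pCR"))
  r <- score_rcb_monotonicity(lat + rnorm(300, 0, 0.3),
                              as.character(rcb))
  expect_lt(r$p_value, 1e-10)
  rp <- score_rcb_monotonicity(sample(lat), as.character(rcb))
  expect_gt(rp$p_value, 0.001)
})
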