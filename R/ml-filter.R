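# Feature filtering steps of the predictor pipeline: collinearity reduction
# and univariable (ANOVA F) selection.

#' Collinearity reduction keep-list
#'
#' Greedy pass over features sorted by descending absolute Pearson
#' correlation with the response (ties broken lexicographically by name):
#' a feature is kept iff its absolute pairwise correlation with every
#' already-kept feature is at or below the threshold, so groups of mutually
#' correlated features (> 0.8) are represented by the member most correlated
#' with the response. Zero-variance features are dropped with a warning
#' before filtering.
#'
#' @param X Patients x features matrix.
#' @param y Binary response.
#' @param threshold Correlation threshold; strictly above it is removed
#'   (default 0.8).
#' @return Character keep-list of feature names.
#' @export
collinearity_filter <- function(X, y, threshold = 0.8) {
  X <- as.matrix(X)
  if (ncol(X) < 2) return(colnames(X))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance feature(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  ry <- abs(suppressWarnings(stats::cor(X, as.numeric(y))))[, 1]
  ord <- order(-ry, colnames(X))
  cm <- abs(suppressWarnings(stats::cor(X)))
  kept <- integer(0)
  for (j in ord) {
    if (length(kept) == 0 || all(cm[j, kept] <= threshold)) {
      kept <- c(kept, j)
    }
  }
  colnames(X)[sort(kept)]
}

# One-way ANOVA F statistic of each column against a binary grouping
# (closed form: between / within mean squares).
anova_f <- function(X, y) {
  X <- as.matrix(X)
  y <- as.integer(y)
  n <- nrow(X)
  stopifnot(length(unique(y)) == 2)
  apply(X, 2, function(x) {
    m <- tapply(x, y, mean)
    nn <- tabulate(y + 1L, 2L)
    gm <- mean(x)
    ssb <- sum(nn * (m - gm)^2)
    ssw <- sum(vapply(unique(y), function(g)
      sum((x[y == g] - mean(x[y == g]))^2), 0.0))
    msb <- ssb / 1
    msw <- ssw / (n - 2)
    if (msw == 0) Inf else msb / msw
  })
}

#' Top-k features by ANOVA F against the binary outcome
#'
#' @param X Patients x features matrix.
#' @param y Binary outcome.
#' @param k Number of features to keep (capped at ncol(X)).
#' @return Character keep-list (original column order), ties broken by name.
#' @export
select_kbest <- function(X, y, k) {
  if (k < 1) stop("k must be >= 1")
  X <- as.matrix(X)
  f <- anova_f(X, y)
  ord <- order(-f, colnames(X))
  keep <- colnames(X)[sort(ord[seq_len(min(k, ncol(X)))])]
  keep
}
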