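# Expression normalization and transcriptomic scores.

# Independent step-by-step TMM oracle following the published definition:
# reference = sample whose 75th count percentile (scaled by library size) is
# closest to the mean; M/A values on doubly-positive genes; 30% M-trim and
# 5% A-trim; precision-weighted mean of the surviving M values.
tmm_oracle <- function(counts) {
  lib <- colSums(counts)
  f75 <- apply(counts, 2, function(x) quantile(x, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  fac <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)  # placeholder; rescaled below like edgeR
    o <- counts[, ref] / lib[ref]
    s <- counts[, j] / lib[j]
    keep <- o > 0 & s > 0
    o <- o[keep]; s <- s[keep]
    M <- log2(s / o)
    A <- 0.5 * log2(s * o)
    w <- (1 - counts[keep, j] / lib[j]) / counts[keep, j] +
      (1 - counts[keep, ref] / lib[ref]) / counts[keep, ref]
    n <- length(M)
    loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    keep2 <- rank(M) >= loM & rank(M) <= hiM &
      rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
  }, 0.0)
  fac[ref] <- 1
  # edgeR rescales factors to multiply to 1
  fac / exp(mean(log(fac)))
}

test_that("TMM factors match an independent hand computation", {
  set.seed(21)
  counts <- matrix(rpois(5 * 3, lambda = c(50, 200, 1000, 80, 400)),
                   nrow = 5, dimnames = list(paste0("g", 1:5),
                                             paste0("s", 1:3)))
  counts[, 2] <- counts[, 2] * 3L   # composition/library difference
  norm <- tmm_tpm_normalize(counts, lengths = rep(1000, 5))
  expect_equal(unname(norm$tmm_factors), unname(tmm_oracle(counts)),
               tolerance = 1e-6)
})

test_that("identical libraries give unit factors and TPM sums to 1e6", {
  counts <- matrix(rep(c(10L, 60L, 300L, 800L), 3), nrow = 4,
                   dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  norm <- tmm_tpm_normalize(counts, lengths = c(500, 1000, 2000, 1500))
  expect_equal(unname(norm$tmm_factors), rep(1, 3))
  expect_equal(unname(colSums(norm$tpm)), rep(1e6, 3), tolerance = 1e-3)
  # idempotence: re-normalizing a TPM-like matrix changes nothing
  tpm_like <- round(norm$tpm)
  norm2 <- tmm_tpm_normalize(tpm_like, lengths = rep(1000, 4))
  expect_equal(norm2$tpm / tpm_like,
               matrix(1, 4, 3, dimnames = dimnames(tpm_like)),
               tolerance = 0.01)
  expect_error(tmm_tpm_normalize(cbind(counts, s4 = 0L), rep(1000, 4)),
               "all-zero")
})

test_that("ssgsea is rank-based and orders planted signal correctly", {
  set.seed(22)
  expr <- matrix(rnorm(300 * 20, 5), 300, 20,
                 dimnames = list(paste0("g", 1:300), paste0("s", 1:20)))
  set <- paste0("g", 1:25)
  expr[set, 1:10] <- expr[set, 1:10] + 2
  sc <- ssgsea_score(expr, set)
  expect_true(all(sc$score[1:10] > sc$score[11:20]))

  # strictly increasing per-sample transform leaves scores unchanged
  expr2 <- expr
  expr2[, 3] <- exp(expr2[, 3] / 2)
  expect_equal(ssgsea_score(expr2, set)$score, sc$score)

  # planted set beats random same-size sets
  set.seed(23)
  rand_scores <- replicate(20, {
    rs <- sample(setdiff(rownames(expr), set), length(set))
    mean(ssgsea_score(expr, rs)$score[1:10])
  })
  expect_true(mean(sc$score[1:10]) > max(rand_scores))

  # complement set is anti-correlated
  comp <- setdiff(rownames(expr), set)
  expect_lt(cor(sc$score, ssgsea_score(expr, comp)$score,
                method = "spearman"), 0)
  expect_error(ssgsea_score(expr, c("nope1", "nope2")), "no member genes")
})

test_that("metagene scores match their closed forms", {
  tpm <- matrix(1, 8, 2, dimnames = list(c("GZMA", "PRF1", "BUB1B", "CDK1",
                                           "AURKB", "TTK", "UGCG", "CERT1"),
                                         c("a", "b")))
  cyt <- metagene_score(tpm, c("GZMA", "PRF1"), mode = "geomean")
  expect_equal(unname(cyt), c(1.01, 1.01))

  tax <- metagene_score(tpm, taxane_metagene_genes()$mitotic,
                        mode = "difference",
                        genes_b = taxane_metagene_genes()$ceramide)
  expect_equal(unname(tax), c(0, 0))

  dan <- metagene_score(matrix(3.99, 2, 1,
                               dimnames = list(c("x1", "x2"), "s")),
                        c("x1", "x2"), mode = "log_geomean")
  expect_equal(unname(dan), 2.0)
  expect_error(metagene_score(tpm * -1, c("GZMA", "PRF1")), "negative")
})

test_that("immunophenotype class z-scores average per-gene z-scores", {
  set.seed(24)
  expr <- matrix(rnorm(40 * 10, 4), 40, 10,
                 dimnames = list(paste0("g", 1:40), paste0("s", 1:10)))
  groups <- list(effector = paste0("g", 1:10),
                 suppressor = paste0("g", 11:20))
  expr[groups$effector, 4] <- expr[groups$effector, 4] + 3
  z <- immunophenotype_zscores(expr, groups)
  expect_equal(which.max(z[, "effector"]), c(s4 = 4L))
  # single-gene class equals that gene's z-score
  z1 <- immunophenotype_zscores(expr, list(solo = "g21"))
  expect_equal(unname(z1[, 1]),
               unname((expr["g21", ] - mean(expr["g21", ])) /
                        sd(expr["g21", ])))
  const <- expr
  const["g1", ] <- 7
  expect_warning(z2 <- immunophenotype_zscores(const, groups),
                 "zero-variance")
  # all-identical samples give all-zero class scores
  same <- matrix(5, 40, 4, dimnames = list(rownames(expr), paste0("t", 1:4)))
  z3 <- suppressWarnings(immunophenotype_zscores(same, groups))
  expect_true(all(z3 == 0))
})

test_that("dysfunction/exclusion input normalization centres per sample", {
  const <- matrix(7, 5, 3, dimnames = list(paste0("g", 1:5),
                                           paste0("s", 1:3)))
  expect_true(all(tide_normalize(const) == 0))
  set.seed(25)
  tpm <- matrix(rexp(50 * 4, 0.1), 50, 4,
                dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
  out <- tide_normalize(tpm)
  expect_equal(unname(colMeans(out)), rep(0, 4))
  # multiplying one sample's (TPM+1) by a constant shifts log2 uniformly,
  # so its centred profile is unchanged
  tpm2 <- tpm
  tpm2[, 2] <- (tpm2[, 2] + 1) * 8 - 1
  expect_equal(tide_normalize(tpm2)[, 2], out[, 2])
})

test_that("above-mean dichotomization uses a strict inequality", {
  expect_equal(dichotomize_high(c(0, 1)), c(FALSE, TRUE))
  expect_equal(dichotomize_high(rep(2, 5)), rep(FALSE, 5))
  set.seed(26)
  v <- rnorm(149)
  expect_equal(sum(dichotomize_high(v)), sum(v > mean(v)))
})
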