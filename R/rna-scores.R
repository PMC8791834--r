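# Transcriptomic scores: single-sample gene-set enrichment, immune and
# proliferation metagenes, immunophenotype class z-scores.

match_set_genes <- function(expr, genes, set_name = "gene set",
                            min_fraction = 0.5) {
  genes <- unique(genes)
  present <- genes[genes %in% rownames(expr)]
  if (length(present) == 0) {
    stop(set_name, ": no member genes found in the expression matrix")
  }
  if (length(present) < length(genes)) {
    missing <- setdiff(genes, present)
    msg <- sprintf("%s: %d/%d genes missing (%s)", set_name,
                   length(missing), length(genes),
                   paste(utils::head(missing, 5), collapse = ", "))
    if (length(present) < min_fraction * length(genes)) stop(msg)
    warning(msg)
  }
  present
}

#' Single-sample gene-set enrichment scores (ssGSEA)
#'
#' Rank-based single-sample enrichment: genes are ranked within each sample,
#' and the score is the integrated difference between the weighted empirical
#' distribution of in-set genes (rank weight exponent `alpha`) and the
#' uniform distribution of out-of-set genes, walked down the expression-
#' ordered gene list. Scores are normalized by the absolute range across
#' samples, so they are comparable within a cohort.
#'
#' @param expr Genes x samples matrix (log2 TPM recommended); only ranks are
#'   used, so any strictly increasing per-sample transform gives identical
#'   scores.
#' @param genes Character vector of set member symbols.
#' @param alpha Rank weight exponent (default 0.25).
#' @param normalize Divide by the score range across samples (default TRUE).
#' @param set_name Label used in messages.
#' @return data.frame `sample`, `score`, `high` (score above cohort mean).
#' @export
ssgsea_score <- function(expr, genes, alpha = 0.25, normalize = TRUE,
                         set_name = "gene set") {
  expr <- as.matrix(expr)
  genes <- match_set_genes(expr, genes, set_name)
  n <- nrow(expr)
  in_set <- rownames(expr) %in% genes
  n_out <- n - sum(in_set)
  if (n_out == 0) stop("gene set covers the whole matrix")
  es <- vapply(seq_len(ncol(expr)), function(j) {
    r <- rank(expr[, j], ties.method = "average")
    ord <- order(r, decreasing = TRUE)
    ins <- in_set[ord]
    w <- r[ord]^alpha
    w[!ins] <- 0
    step_in <- cumsum(w) / sum(w)
    step_out <- cumsum(!ins) / n_out
    sum(step_in - step_out)
  }, 0.0)
  if (normalize) {
    rng <- max(es) - min(es)
    if (rng > 0) es <- es / rng
  }
  data.frame(sample = colnames(expr) %||% as.character(seq_along(es)),
             score = es, high = dichotomize_high(es),
             stringsAsFactors = FALSE)
}

#' Metagene scores (cytolytic activity, taxane response, marker log-geomeans)
#'
#' Three modes over TPM expression:
#' \itemize{
#'   \item `geomean`: \code{exp(mean(log(TPM + offset)))} of the member genes
#'     — e.g. the cytolytic score, geometric mean of GZMA and PRF1 with a
#'     0.01 offset;
#'   \item `log_geomean`: \code{mean(log2(TPM + offset))} — the marker-gene
#'     cell scores (e.g. Danaher-style enrichment);
#'   \item `difference`: geometric mean of `genes` minus geometric mean of
#'     `genes_b` — the taxane response metagene, mitotic (BUB1B, CDK1,
#'     AURKB, TTK) minus ceramide (UGCG, CERT1).
#' }
#'
#' @param tpm Genes x samples TPM matrix (non-negative).
#' @param genes Member genes (set A for `difference`).
#' @param mode One of "geomean", "log_geomean", "difference".
#' @param genes_b Set B for `difference` mode.
#' @param offset Added before taking logs (default 0.01).
#' @return Named numeric vector of per-sample scores.
#' @export
metagene_score <- function(tpm,
                           genes = c("GZMA", "PRF1"),
                           mode = c("geomean", "log_geomean", "difference"),
                           genes_b = c("UGCG", "CERT1"),
                           offset = 0.01) {
  mode <- match.arg(mode)
  tpm <- as.matrix(tpm)
  if (any(tpm < 0, na.rm = TRUE)) stop("negative TPM values")
  ga <- match_set_genes(tpm, genes, "metagene")
  col_geomean <- function(g) {
    apply(tpm[g, , drop = FALSE] + offset, 2, function(x) exp(mean(log(x))))
  }
  out <- switch(mode,
    geomean = col_geomean(ga),
    log_geomean = colMeans(log2(tpm[ga, , drop = FALSE] + offset)),
    difference = {
      gb <- match_set_genes(tpm, genes_b, "metagene (set B)")
      col_geomean(ga) - col_geomean(gb)
    })
  stats::setNames(out, colnames(tpm))
}

#' Mitotic/ceramide gene defaults of the taxane response metagene
#' @return list with `mitotic` and `ceramide` gene symbol vectors.
#' @export
taxane_metagene_genes <- function() {
  list(mitotic = c("BUB1B", "CDK1", "AURKB", "TTK"),
       ceramide = c("UGCG", "CERT1"))
}

#' Immunophenotype class z-scores
#'
#' Z-scores each gene across samples and averages within each configured
#' immune class (e.g. MHC molecules, immunomodulators, effector cells,
#' suppressor cells).
#'
#' @param expr Genes x samples matrix (TPM or log layer).
#' @param groups Named list of gene symbol vectors, one per class.
#' @return Samples x classes matrix of mean z-scores.
#' @export
immunophenotype_zscores <- function(expr, groups) {
  expr <- as.matrix(expr)
  stopifnot(is.list(groups), length(groups) >= 1, !is.null(names(groups)))
  out <- sapply(names(groups), function(cl) {
    g <- match_set_genes(expr, groups[[cl]], cl)
    sub <- expr[g, , drop = FALSE]
    mu <- rowMeans(sub)
    sdv <- apply(sub, 1, stats::sd)
    zero <- sdv == 0
    if (any(zero)) {
      warning(cl, ": ", sum(zero), " zero-variance gene(s), z set to 0")
      sdv[zero] <- Inf
    }
    colMeans(sweep(sweep(sub, 1, mu, "-"), 1, sdv, "/"))
  })
  rownames(out) <- colnames(expr)
  out
}

#' Above-mean dichotomization of cohort scores
#'
#' @param scores Numeric vector (>= 2 values).
#' @return Logical vector: strictly above the cohort mean.
#' @export
dichotomize_high <- function(scores) {
  stopifnot(length(scores) >= 2)
  scores > mean(scores)
}
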