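# Mutational signature decomposition: constrained least-squares fit of a
# 96-class trinucleotide catalogue against a reference signature matrix,
# with exposures normalized against the clock-like signature 1.

#' The 96 trinucleotide mutation classes in standard (COSMIC) order
#'
#' Six pyrimidine substitution types (C>A, C>G, C>T, T>A, T>C, T>G), each in
#' 16 flanking-base contexts, e.g. "A[C>A]A".
#' @return Character vector of length 96.
#' @export
trinucleotide_classes <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(bases, bases, function(l, r)
      paste0(l, "[", s, "]", r))))
  }))
}

#' Synthetic reference signature matrix
#'
#' Generates a deterministic 96 x S matrix of synthetic mutational signature
#' profiles (columns sum to 1). Column 1 plays the role of the clock-like
#' "age" signature used as the normalization reference; columns are named
#' `Signature_1` ... `Signature_S`. This is a synthetic stand-in with the
#' same shape and conventions as the published reference frameworks; supply a
#' real matrix via [read_signature_matrix()] for real data.
#'
#' @param n_signatures Number of signature columns (default 13, so that
#'   the clock (1, 5), HRD-like (3) and APOBEC-like (13) slots all exist).
#' @param seed Seed fixing the synthetic profiles (default 20).
#' @param concentration Dirichlet-like concentration; smaller values give
#'   spikier, more mutually distinguishable profiles.
#' @return 96 x S numeric matrix, rownames = [trinucleotide_classes()].
#' @export
synthetic_signature_matrix <- function(n_signatures = 13, seed = 20,
                                       concentration = 0.15) {
  stopifnot(n_signatures >= 2)
  with_seed(seed, {
    m <- matrix(stats::rgamma(96 * n_signatures, shape = concentration),
                nrow = 96)
    m <- sweep(m, 2, colSums(m), "/")
    rownames(m) <- trinucleotide_classes()
    colnames(m) <- paste0("Signature_", seq_len(n_signatures))
    m
  })
}

#' Read a 96 x S reference signature matrix from TSV
#'
#' First column = trinucleotide class, remaining columns = signatures.
#' @param path TSV path.
#' @return Numeric matrix with class rownames; columns renormalized checked.
#' @export
read_signature_matrix <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m <- m[match(trinucleotide_classes(), rownames(m)), , drop = FALSE]
  if (anyNA(m)) stop("signature matrix does not cover the 96 classes")
  if (any(abs(colSums(m) - 1) > 1e-6)) {
    stop("reference signature columns must each sum to 1")
  }
  m
}

#' Tabulate a trinucleotide catalogue from per-mutation context labels
#'
#' @param contexts Character vector of 96-class labels.
#' @return Named integer 96-vector in standard order.
#' @export
context_catalogue <- function(contexts) {
  cls <- trinucleotide_classes()
  bad <- setdiff(unique(contexts), cls)
  if (length(bad)) stop("unknown trinucleotide class: ", bad[1])
  tab <- table(factor(contexts, levels = cls))
  stats::setNames(as.integer(tab), cls)
}

#' Fit mutational signature exposures
#'
#' Nonnegative least-squares fit of the (normalized) catalogue against the
#' reference signatures; weights below the discard threshold are zeroed and
#' the remainder renormalized to sum to 1. Tumours with 10 or fewer mutations
#' return a no-result marker (all-NA weights) since sparse catalogues cannot
#' be decomposed reliably.
#'
#' @param catalogue Integer 96-vector of mutation counts per class.
#' @param reference 96 x S matrix, columns sum to 1
#'   (e.g. [synthetic_signature_matrix()]).
#' @param min_mutations Minimum mutation count; catalogues with
#'   `sum(catalogue) <= min_mutations` are not fitted (default 10).
#' @param discard_threshold Weights below this are zeroed (default 0.06).
#' @return list: `weights` (named S-vector summing to 1, or all NA),
#'   `reconstruction_error` (L2 norm of residual on the normalized
#'   catalogue), `n_mutations`.
#' @export
fit_signature_exposures <- function(catalogue, reference,
                                    min_mutations = 10,
                                    discard_threshold = 0.06) {
  stopifnot(length(catalogue) == nrow(reference))
  if (any(abs(colSums(reference) - 1) > 1e-6)) {
    stop("reference signature columns must each sum to 1")
  }
  n <- sum(catalogue)
  sig_names <- colnames(reference)
  if (n <= min_mutations) {
    return(list(weights = stats::setNames(rep(NA_real_, ncol(reference)),
                                          sig_names),
                reconstruction_error = NA_real_, n_mutations = n))
  }
  target <- catalogue / n
  fit <- pracma::lsqnonneg(reference, target)
  w <- fit$x
  w[w < discard_threshold] <- 0
  if (sum(w) > 0) w <- w / sum(w)
  list(weights = stats::setNames(w, sig_names),
       reconstruction_error = sqrt(sum((reference %*% w - target)^2)),
       n_mutations = n)
}

#' Normalize signature exposures against signature 1
#'
#' Log2 ratio of each signature's weight to the clock-like signature-1 weight
#' (pseudo-count keeps the ratio finite), plus the non-clock fraction
#' 1 - (w1 + w5).
#'
#' @param weights Named weight vector from [fit_signature_exposures()].
#' @param pseudo_count Added to numerator and denominator (default 0.01).
#' @param clock_signatures Names of clock-like signatures (default
#'   Signature_1 and Signature_5).
#' @return list: `log2_ratio` (named vector), `nonclock_fraction`.
#' @export
normalize_exposures <- function(weights, pseudo_count = 0.01,
                                clock_signatures = c("Signature_1",
                                                     "Signature_5")) {
  if (all(is.na(weights))) {
    return(list(log2_ratio = weights, nonclock_fraction = NA_real_))
  }
  ref <- weights[[clock_signatures[1]]]
  ratio <- log2((weights + pseudo_count) / (ref + pseudo_count))
  clock <- sum(weights[names(weights) %in% clock_signatures])
  list(log2_ratio = ratio, nonclock_fraction = 1 - clock)
}
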