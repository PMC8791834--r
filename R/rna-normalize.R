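# Expression normalization: TMM scale factors, then FPKM, then TPM, matching
# the TMM -> FPKM -> TPM chain used for all downstream transcriptomic scores.

#' TMM-normalized FPKM and TPM layers from raw counts
#'
#' Computes trimmed-mean-of-M-values scale factors (30% M trim, 5% A trim,
#' reference sample = upper quartile closest to the mean upper quartile),
#' converts counts to FPKM using the effective (TMM-scaled) library sizes and
#' gene lengths, and rescales each sample to one million to obtain TPM.
#'
#' @param counts Genes x samples matrix of raw counts (non-negative).
#' @param lengths Per-gene lengths in bp (> 0), recycled/named-matched to
#'   rows of `counts`.
#' @return list with `counts`, `lengths`, `tmm_factors`,
#'   `effective_lib_size`, `fpkm`, `tpm`, `log2_tpm` (log2(TPM + 1)).
#' @export
tmm_tpm_normalize <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least 2 samples")
  if (any(counts < 0)) stop("negative counts")
  if (!is.null(names(lengths)) && !is.null(rownames(counts))) {
    lengths <- lengths[rownames(counts)]
  }
  lengths <- rep_len(lengths, nrow(counts))
  if (any(is.na(lengths) | lengths <= 0)) stop("gene lengths must be > 0")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("all-zero sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  eff <- lib * f
  # FPKM: reads per kilobase of transcript per million effectively sequenced.
  fpkm <- counts / (lengths / 1e3)
  fpkm <- sweep(fpkm, 2, eff / 1e6, "/")
  tpm <- sweep(fpkm, 2, colSums(fpkm), "/") * 1e6
  list(counts = counts, lengths = lengths, tmm_factors = f,
       effective_lib_size = eff, fpkm = fpkm, tpm = tpm,
       log2_tpm = log2(tpm + 1))
}

#' Normalize expression for T cell dysfunction/exclusion scoring
#'
#' log2(TPM + 1), centred by subtracting each sample's mean log2 expression
#' over all genes (the input contract of bulk dysfunction/exclusion scorers).
#'
#' @param tpm Genes x samples TPM matrix.
#' @return Centred log2 matrix (every column mean is 0).
#' @export
tide_normalize <- function(tpm) {
  lg <- log2(as.matrix(tpm) + 1)
  sweep(lg, 2, colMeans(lg), "-")
}
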