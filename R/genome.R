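#' Default autosomal genome model
#'
#' Chromosome lengths and centromere intervals for the 22 human autosomes
#' (GRCh37-like coordinates rounded to 0.1 Mb). The HRD scar components and
#' the allelic-imbalance calls need to know where telomeres and centromeres
#' are; analyses here are autosome-only, so sex chromosomes are omitted.
#'
#' @return A data.frame with columns `chrom`, `length`, `centromere_start`,
#'   `centromere_end` (1-based bp).
#' @export
default_genome_model <- function() {
  mb <- 1e6
  d <- data.frame(
    chrom = as.character(1:22),
    length = c(249.3, 243.2, 198.0, 191.2, 180.9, 171.1, 159.1, 146.4,
               141.2, 135.5, 135.0, 133.9, 115.2, 107.3, 102.5, 90.4,
               81.2, 78.1, 59.1, 63.0, 48.1, 51.3) * mb,
    centromere_mid = c(125.0, 93.3, 91.0, 50.4, 48.4, 61.0, 59.9, 45.6,
                       49.0, 40.2, 53.7, 35.8, 17.9, 17.6, 19.0, 36.6,
                       24.0, 17.2, 26.5, 27.5, 13.2, 14.7) * mb,
    stringsAsFactors = FALSE
  )
  d$centromere_start <- pmax(1, d$centromere_mid - 1.5 * mb)
  d$centromere_end <- d$centromere_mid + 1.5 * mb
  d$centromere_mid <- NULL
  d
}

#' Read a genome model from a TSV file
#'
#' @param path TSV with header columns chrom, length, centromere_start,
#'   centromere_end.
#' @return data.frame as [default_genome_model()].
#' @export
read_genome_model <- function(path) {
  d <- utils::read.delim(path, colClasses = c(chrom = "character"))
  stop_if_missing_cols(d, c("chrom", "length", "centromere_start",
                            "centromere_end"), "genome model")
  if (any(d$length <= 0)) stop("genome model: chromosome lengths must be > 0")
  d
}
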