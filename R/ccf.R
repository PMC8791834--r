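# Clonal reconstruction: cancer cell fraction, clonality calls, mutation
# burden and driver flags derived from a somatic mutation table.

#' Cancer cell fraction of somatic mutations
#'
#' Converts variant allele fractions to cancer cell fractions given tumour
#' purity and the local copy-number context:
#' \deqn{CCF = \frac{VAF}{p}\,\big((1-p)\,CN_{normal} + p\,CN_{tumour}\big)}
#' where \eqn{p} is tumour purity, \eqn{CN_{normal}} the germline copy number
#' and \eqn{CN_{tumour}} the total tumour copy number at the locus. CCF values
#' above 1 are reported unclipped (they arise from sampling noise and from
#' multiplicity > 1, which this estimator does not model).
#'
#' @param vaf Variant allele fraction(s) in [0, 1].
#' @param purity Tumour purity in (0, 1]. Recycled.
#' @param cn_normal Germline copy number (2 on autosomes). Recycled.
#' @param cn_tumour Total tumour copy number at the locus. Recycled.
#' @return Numeric vector of CCF point estimates (NA where purity or copy
#'   number is missing/invalid).
#' @seealso [classify_clonality()] for confidence intervals and clonal calls.
#' @export
compute_ccf <- function(vaf, purity, cn_normal = 2, cn_tumour = 2) {
  n <- length(vaf)
  purity <- rep_len(purity, n)
  cn_normal <- rep_len(cn_normal, n)
  cn_tumour <- rep_len(cn_tumour, n)
  bad <- is.na(purity) | purity <= 0 | is.na(cn_normal) | is.na(cn_tumour)
  mult <- ((1 - purity) * cn_normal + purity * cn_tumour) / purity
  out <- vaf * mult
  out[bad] <- NA_real_
  out
}

#' Clonality classification of somatic mutations
#'
#' Computes a 95% Wilson score interval on the VAF (alt / total reads), maps
#' both ends through the same purity/copy-number multiplier as the CCF point
#' estimate, and classifies a mutation as clonal when the CCF confidence
#' interval overlaps 1 (low <= 1 <= high), subclonal otherwise. Note that
#' under this rule a CI lying entirely above 1 is labelled subclonal; such
#' calls are flagged in `ci_above_one`.
#'
#' @param alt,total Alt-supporting and total read counts.
#' @param purity,cn_normal,cn_tumour As in [compute_ccf()].
#' @param conf Confidence level (default 0.95).
#' @return data.frame with columns `ccf`, `ccf_low`, `ccf_high`, `clonality`
#'   ("clonal"/"subclonal", NA when not classifiable) and `ci_above_one`.
#' @export
classify_clonality <- function(alt, total, purity, cn_normal = 2,
                               cn_tumour = 2, conf = 0.95) {
  n <- length(alt)
  stopifnot(length(total) == n)
  if (any(total == 0, na.rm = TRUE)) stop("total read count of 0")
  if (any(alt > total, na.rm = TRUE)) stop("alt reads exceed total reads")
  purity <- rep_len(purity, n)
  cn_normal <- rep_len(cn_normal, n)
  cn_tumour <- rep_len(cn_tumour, n)
  vaf <- alt / total
  ccf <- compute_ccf(vaf, purity, cn_normal, cn_tumour)
  mult <- ifelse(!is.na(purity) & purity > 0,
                 ((1 - purity) * cn_normal + purity * cn_tumour) / purity,
                 NA_real_)
  # Wilson score interval, vectorized over mutations
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- alt / total
  denom <- 1 + z^2 / total
  centre <- (p + z^2 / (2 * total)) / denom
  half <- z * sqrt(p * (1 - p) / total + z^2 / (4 * total^2)) / denom
  lo <- pmax(0, centre - half) * mult
  hi <- pmin(1, centre + half) * mult
  clonal <- ifelse(is.na(lo), NA, lo <= 1 & hi >= 1)
  data.frame(
    ccf = ccf, ccf_low = lo, ccf_high = hi,
    clonality = ifelse(is.na(clonal), NA_character_,
                       ifelse(clonal, "clonal", "subclonal")),
    ci_above_one = !is.na(lo) & lo > 1,
    stringsAsFactors = FALSE
  )
}

#' Percentage of subclonal mutations per patient
#'
#' @param mutations Mutation table with columns `patient`, `alt_reads`,
#'   `total_reads`, `purity`, `cn_normal`, `cn_tumour`.
#' @return data.frame with columns `patient`, `n_classifiable`,
#'   `pct_subclonal` (NA, not 0, when no mutation is classifiable).
#' @export
pct_subclonal <- function(mutations) {
  stop_if_missing_cols(mutations, c("patient", "alt_reads", "total_reads",
                                    "purity", "cn_normal", "cn_tumour"),
                       "mutation table")
  cl <- classify_clonality(mutations$alt_reads, mutations$total_reads,
                           mutations$purity, mutations$cn_normal,
                           mutations$cn_tumour)
  ok <- !is.na(cl$clonality)
  pat <- unique(mutations$patient)
  n_cls <- vapply(pat, function(p) sum(ok & mutations$patient == p), 0L)
  n_sub <- vapply(pat, function(p)
    sum(ok & mutations$patient == p & cl$clonality == "subclonal"), 0L)
  data.frame(
    patient = pat,
    n_classifiable = n_cls,
    pct_subclonal = ifelse(n_cls > 0, 100 * n_sub / n_cls, NA_real_),
    stringsAsFactors = FALSE
  )
}

#' Tumour mutation burden
#'
#' Somatic mutation count divided by the sequenced exome footprint
#' (45.54 Mb for the exome platform modelled here).
#'
#' @param n_mutations Mutation count(s).
#' @param footprint_mb Sequenced megabases (default 45.54).
#' @return Mutations per megabase.
#' @export
compute_tmb <- function(n_mutations, footprint_mb = 45.54) {
  stopifnot(footprint_mb > 0, all(n_mutations >= 0))
  n_mutations / footprint_mb
}

#' Per-patient driver gene mutation flags
#'
#' @param mutations Mutation table with columns `patient`, `gene`.
#' @param drivers Character vector of driver gene symbols
#'   (default TP53, PIK3CA).
#' @param patients Optional patient universe; defaults to patients present in
#'   the table (patients with no mutations then get all-zero rows only if
#'   listed here).
#' @return data.frame: `patient` plus one 0/1 column per driver
#'   (`mut_<GENE>`).
#' @export
driver_flags <- function(mutations, drivers = c("TP53", "PIK3CA"),
                         patients = NULL) {
  stop_if_missing_cols(mutations, c("patient", "gene"), "mutation table")
  patients <- patients %||% unique(mutations$patient)
  out <- data.frame(patient = patients, stringsAsFactors = FALSE)
  for (g in drivers) {
    hit <- unique(mutations$patient[mutations$gene == g])
    out[[paste0("mut_", g)]] <- as.integer(patients %in% hit)
  }
  out
}
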