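# HLA class I loss of heterozygosity and neoantigen filtering. Allele copy
# numbers / significance and peptide binding affinities are inputs (produced
# upstream by dedicated tools); this module applies the decision rules.

#' Call HLA allele loss of heterozygosity
#'
#' An allele is called as lost when its estimated copy number is below 0.5
#' and the loss is statistically significant.
#'
#' @param alleles data.frame with columns `patient`, `allele`, `cn`
#'   (allele-specific copy number >= 0) and `p_value`.
#' @param alpha Significance level for the loss call (default 0.05).
#' @return Input with added logical `loh` column, plus attribute
#'   `patient_any_loh`: data.frame (`patient`, `any_loh`).
#' @export
call_hla_loh <- function(alleles, alpha = 0.05) {
  stop_if_missing_cols(alleles, c("patient", "allele", "cn", "p_value"),
                       "HLA allele table")
  if (any(alleles$cn < 0, na.rm = TRUE)) stop("negative HLA copy number")
  miss <- is.na(alleles$p_value)
  if (any(miss)) {
    warning(sum(miss), " allele(s) without significance skipped")
  }
  alleles$loh <- !miss & !is.na(alleles$cn) &
    alleles$cn < 0.5 & alleles$p_value < alpha
  pats <- unique(alleles$patient)
  attr(alleles, "patient_any_loh") <- data.frame(
    patient = pats,
    any_loh = vapply(pats, function(p)
      any(alleles$loh[alleles$patient == p]), TRUE),
    stringsAsFactors = FALSE
  )
  alleles
}

#' Presentation impact of HLA LOH
#'
#' Summarizes how many neoantigens become unpresentable after HLA LOH (their
#' only presenting alleles are lost) and, per LOH event, whether the lost
#' allele presented at least as many neoepitopes as the retained allele of
#' the same locus.
#'
#' @param alleles Output of [call_hla_loh()] (needs `patient`, `allele`,
#'   `loh`; optional `locus` column pairing alleles — defaults to the prefix
#'   of the allele name before the last "*").
#' @param neoepitopes data.frame with `patient`, `peptide`,
#'   `presenting_allele` (one row per peptide-allele presentation).
#' @return list with `pct_unpresentable` (percentage of distinct presented
#'   neoantigens whose presenting alleles are all lost) and
#'   `frac_lost_presented_ge_retained` (fraction of LOH events where the lost
#'   allele presented >= the retained partner allele), plus the per-event
#'   table.
#' @export
hla_loh_impact <- function(alleles, neoepitopes) {
  stop_if_missing_cols(alleles, c("patient", "allele", "loh"), "allele table")
  stop_if_missing_cols(neoepitopes, c("patient", "peptide",
                                      "presenting_allele"), "neoepitope table")
  if (!"locus" %in% names(alleles)) {
    alleles$locus <- sub("\\*.*$", "", alleles$allele)
  }
  lost <- alleles[alleles$loh, , drop = FALSE]

  # Unpresentable neoantigens: distinct (patient, peptide) pairs all of whose
  # presenting alleles are lost in that patient.
  key <- paste(neoepitopes$patient, neoepitopes$peptide, sep = "\r")
  allele_lost <- mapply(function(p, a)
    any(lost$patient == p & lost$allele == a),
    neoepitopes$patient, neoepitopes$presenting_allele)
  n_total <- length(unique(key))
  unpres <- tapply(allele_lost, key, all)
  pct_unpresentable <- if (n_total == 0) 0 else 100 * sum(unpres) / n_total

  # Per LOH event: compare epitope counts of the lost allele vs its retained
  # partner at the same locus.
  events <- NULL
  if (nrow(lost) > 0) {
    n_pres <- function(p, a) {
      length(unique(neoepitopes$peptide[neoepitopes$patient == p &
                                          neoepitopes$presenting_allele == a]))
    }
    rows <- lapply(seq_len(nrow(lost)), function(i) {
      p <- lost$patient[i]
      partner <- alleles[alleles$patient == p &
                           alleles$locus == lost$locus[i] &
                           alleles$allele != lost$allele[i] &
                           !alleles$loh, , drop = FALSE]
      n_lost <- n_pres(p, lost$allele[i])
      n_ret <- if (nrow(partner)) {
        max(vapply(partner$allele, function(a) n_pres(p, a), 0L))
      } else 0L
      data.frame(patient = p, lost_allele = lost$allele[i],
                 n_lost = n_lost, n_retained = n_ret,
                 lost_ge_retained = n_lost >= n_ret,
                 stringsAsFactors = FALSE)
    })
    events <- do.call(rbind, rows)
  }
  list(
    pct_unpresentable = pct_unpresentable,
    frac_lost_presented_ge_retained =
      if (is.null(events) || nrow(events) == 0) NA_real_
      else mean(events$lost_ge_retained),
    events = events
  )
}

#' Filter candidate neoantigens
#'
#' Retains candidate neoepitopes of length 8-11 whose mutant binding affinity
#' is below 500 nM (strict), stronger than the wild-type peptide's affinity
#' (lower nM), and whose source gene is expressed above 1 TPM.
#'
#' @param candidates data.frame with columns `peptide_length`, `mut_nM`,
#'   `wt_nM`, `tpm` (plus any identifiers, carried through).
#' @param affinity_cutoff Mutant affinity threshold in nM (default 500).
#' @param tpm_cutoff Expression threshold in TPM (default 1).
#' @return The retained subset, with attribute `n_retained`.
#' @export
filter_neoantigens <- function(candidates, affinity_cutoff = 500,
                               tpm_cutoff = 1) {
  stop_if_missing_cols(candidates, c("peptide_length", "mut_nM", "wt_nM",
                                     "tpm"), "neoantigen candidate table")
  if (any(candidates$mut_nM < 0 | candidates$wt_nM < 0, na.rm = TRUE)) {
    stop("negative binding affinity")
  }
  if (any(!candidates$peptide_length %in% 8:11)) {
    stop("peptide lengths must be in 8-11")
  }
  keep <- !is.na(candidates$mut_nM) & !is.na(candidates$wt_nM) &
    !is.na(candidates$tpm) &
    candidates$mut_nM < affinity_cutoff &
    candidates$mut_nM < candidates$wt_nM &
    candidates$tpm > tpm_cutoff
  out <- candidates[keep, , drop = FALSE]
  attr(out, "n_retained") <- sum(keep)
  out
}
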