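# HRD scar scoring from allele-specific copy-number segments, plus the
# fraction of the genome altered relative to ploidy.

check_segments <- function(seg) {
  stop_if_missing_cols(seg, c("chrom", "start", "end", "major_cn", "minor_cn"),
                       "segment table")
  if (any(seg$start > seg$end)) stop("segment with start > end")
  if (any(seg$major_cn < 0 | seg$minor_cn < 0)) stop("negative copy number")
  o <- order(seg$chrom, seg$start)
  same <- seg$chrom[o][-1] == seg$chrom[o][-length(o)]
  if (any(same & seg$start[o][-1] <= seg$end[o][-length(o)])) {
    stop("overlapping segments on chromosome ",
         seg$chrom[o][-1][which(same & seg$start[o][-1] <=
                                  seg$end[o][-length(o)])[1]])
  }
  invisible(seg)
}

# Merge adjacent same-state runs (used after short-segment removal in the
# LST computation, so breakpoints always separate distinct allele states).
# Works on parallel vectors sorted by start.
merge_same_state_vec <- function(start, end, major, minor) {
  state_change <- c(TRUE, major[-1] != major[-length(major)] |
                      minor[-1] != minor[-length(minor)])
  grp <- cumsum(state_change)
  list(start = start[state_change],
       end = as.numeric(tapply(end, grp, max)),
       major = major[state_change], minor = minor[state_change])
}

hrd_one_patient <- function(seg, genome_model, telomere_tol = 1e3) {
  check_segments(seg)
  gm <- genome_model
  idx <- match(seg$chrom, gm$chrom)
  if (anyNA(idx)) {
    stop("chromosome ", seg$chrom[which(is.na(idx))[1]],
         " not in the genome model")
  }
  o <- order(idx, seg$start)
  chrom <- idx[o]
  start <- seg$start[o]; end <- seg$end[o]
  major <- seg$major_cn[o]; minor <- seg$minor_cn[o]
  len <- end - start + 1
  chr_len <- gm$length[chrom]
  at_p_telo <- start <= 1 + telomere_tol
  at_q_telo <- end >= chr_len - telomere_tol
  whole <- at_p_telo & at_q_telo

  # Large LOH: minor allele lost, > 15 Mb, not the whole chromosome.
  loh <- sum(minor == 0 & major > 0 & len > 15e6 & !whole)

  # Telomeric allelic imbalance: unbalanced segment touching a telomere
  # without crossing the centromere.
  crosses <- start < gm$centromere_start[chrom] &
    end > gm$centromere_end[chrom]
  tai <- sum(major != minor & (at_p_telo | at_q_telo) & !crosses)

  # Large-scale transitions: after dropping segments < 3 Mb and merging
  # identical neighbours, count breakpoints whose flanks are both >= 10 Mb
  # and separated by < 3 Mb.
  lst <- 0L
  keep <- len >= 3e6
  for (c_i in unique(chrom)) {
    sel <- keep & chrom == c_i
    if (sum(sel) < 2) next
    m <- merge_same_state_vec(start[sel], end[sel], major[sel], minor[sel])
    nl <- length(m$start)
    if (nl < 2) next
    l2 <- m$end - m$start + 1
    gap <- m$start[-1] - m$end[-nl] - 1
    lst <- lst + sum(l2[-nl] >= 10e6 & l2[-1] >= 10e6 & gap < 3e6)
  }
  c(tai = tai, loh = loh, lst = lst, hrd_total = tai + loh + lst)
}

#' HRD scar score (TAI + LOH + LST)
#'
#' Computes the three components of the homologous recombination deficiency
#' scar score from allele-specific copy-number segments: the number of
#' telomeric allelic imbalances (TAI), of large (> 15 Mb) non-whole-chromosome
#' LOH segments, and of large-scale state transitions (LST; breakpoints with
#' both flanks >= 10 Mb after removal of segments < 3 Mb), summed into the
#' total HRD score.
#'
#' @param segments Segment table (`patient` optional, `chrom`, `start`, `end`,
#'   `major_cn`, `minor_cn`; 1-based inclusive, non-overlapping per
#'   chromosome).
#' @param genome_model data.frame as [default_genome_model()].
#' @param telomere_tol Distance (bp) within which a segment end is considered
#'   to touch a telomere.
#' @return data.frame with one row per patient: `patient`, `tai`, `loh`,
#'   `lst`, `hrd_total`.
#' @export
compute_hrd <- function(segments, genome_model = default_genome_model(),
                        telomere_tol = 1e3) {
  if (!"patient" %in% names(segments)) segments$patient <- "sample"
  by_pat <- split(segments, segments$patient)
  res <- t(vapply(by_pat, hrd_one_patient, c(tai = 0, loh = 0, lst = 0,
                                             hrd_total = 0),
                  genome_model = genome_model,
                  telomere_tol = telomere_tol))
  cbind(data.frame(patient = names(by_pat), stringsAsFactors = FALSE),
        as.data.frame(res))
}

#' Fraction of the genome with copy number different from ploidy
#'
#' Length-weighted fraction of the covered autosomal genome whose total copy
#' number (major + minor) differs from the rounded ploidy.
#'
#' @param segments Segment table as in [compute_hrd()] (single patient or
#'   `patient` column).
#' @param ploidy Tumour ploidy (> 0); per-patient vector or scalar.
#' @return data.frame `patient`, `cna_fraction`.
#' @export
genome_altered_fraction <- function(segments, ploidy = 2) {
  if (!"patient" %in% names(segments)) segments$patient <- "sample"
  stopifnot(all(ploidy > 0))
  by_pat <- split(segments, segments$patient)
  ploidy <- rep_len(ploidy, length(by_pat))
  frac <- vapply(seq_along(by_pat), function(i) {
    s <- by_pat[[i]]
    check_segments(s)
    len <- s$end - s$start + 1
    if (sum(len) == 0) stop("zero covered genome for patient ",
                            names(by_pat)[i])
    tot <- s$major_cn + s$minor_cn
    sum(len[tot != round(ploidy[i])]) / sum(len)
  }, 0.0)
  data.frame(patient = names(by_pat), cna_fraction = frac,
             stringsAsFactors = FALSE)
}
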