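# Shared fixtures: a small cached synthetic cohort and crafted-table
# builders used across test files.

# One small cohort, simulated once per test run.
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(simulation_config(n_patients = 60,
                                                  seed = 42))
    }
    cache
  }
})

small_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressWarnings(build_feature_matrix(small_cohort()))
    }
    cache
  }
})

# A single-chromosome genome model for crafted segment tests:
# 200 Mb chromosome "1" with a centromere at 90-93 Mb.
toy_genome <- function() {
  data.frame(chrom = "1", length = 200e6,
             centromere_start = 90e6, centromere_end = 93e6,
             stringsAsFactors = FALSE)
}

seg_row <- function(start, end, major, minor, chrom = "1",
                    patient = "S1") {
  data.frame(patient = patient, chrom = chrom, start = start, end = end,
             major_cn = major, minor_cn = minor, stringsAsFactors = FALSE)
}

# Independent brute-force re-derivation of the three HRD components,
# written against the published scar definitions (not sharing code with
# compute_hrd).
hrd_oracle <- function(seg, gm, telomere_tol = 1e3) {
  tai <- 0; loh <- 0; lst <- 0
  for (ch in unique(seg$chrom)) {
    g <- gm[gm$chrom == ch, ]
    s <- seg[seg$chrom == ch, ]
    s <- s[order(s$start), ]
    for (i in seq_len(nrow(s))) {
      len <- s$end[i] - s$start[i] + 1
      p_telo <- s$start[i] <= 1 + telomere_tol
      q_telo <- s$end[i] >= g$length - telomere_tol
      if (s$minor_cn[i] == 0 && s$major_cn[i] > 0 && len > 15e6 &&
          !(p_telo && q_telo)) loh <- loh + 1
      crosses <- s$start[i] < g$centromere_start &&
        s$end[i] > g$centromere_end
      if (s$major_cn[i] != s$minor_cn[i] && (p_telo || q_telo) &&
          !crosses) tai <- tai + 1
    }
    s2 <- s[(s$end - s$start + 1) >= 3e6, ]
    if (nrow(s2) > 1) {
      # merge identical adjacent states
      i <- 1
      while (i < nrow(s2)) {
        if (s2$major_cn[i] == s2$major_cn[i + 1] &&
            s2$minor_cn[i] == s2$minor_cn[i + 1]) {
          s2$end[i] <- s2$end[i + 1]
          s2 <- s2[-(i + 1), ]
        } else i <- i + 1
      }
      if (nrow(s2) > 1) {
        for (i in seq_len(nrow(s2) - 1)) {
          l1 <- s2$end[i] - s2$start[i] + 1
          l2 <- s2$end[i + 1] - s2$start[i + 1] + 1
          gap <- s2$start[i + 1] - s2$end[i] - 1
          if (l1 >= 10e6 && l2 >= 10e6 && gap < 3e6) lst <- lst + 1
        }
      }
    }
  }
  c(tai = tai, loh = loh, lst = lst)
}

# Random non-overlapping segments on the toy genome.
random_segments <- function(n_seg, seed) {
  set.seed(seed)
  bounds <- sort(sample(seq(1e6, 199e6, by = 1e6), n_seg + 1))
  a <- sample(0:3, n_seg, replace = TRUE)
  b <- sample(0:2, n_seg, replace = TRUE)
  seg_row(start = bounds[-length(bounds)],
          end = bounds[-1] - 1,
          major = pmax(a, b), minor = pmin(a, b))
}
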