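# DNA features: CCF and clonality, mutation burden, signature fitting,
# HRD scars, HLA LOH and neoantigen filtering.

test_that("compute_ccf reproduces the purity/copy-number conversion", {
  expect_equal(compute_ccf(0.5, purity = 1, 2, 2), 1.0)
  expect_equal(compute_ccf(0.25, purity = 0.5, 2, 2), 1.0)
  expect_equal(compute_ccf(0.2, purity = 0.8, 2, 3), 0.70)
  # values above 1 are reported unclipped
  expect_equal(compute_ccf(1, purity = 1, 2, 2), 2.0)
  # invalid purity yields NA, not an answer
  expect_true(is.na(compute_ccf(0.5, purity = 0)))
})

test_that("clonality calls follow the CI-overlaps-1 rule", {
  cl <- classify_clonality(c(50, 10, 100), c(100, 100, 100), purity = 1)
  expect_equal(cl$clonality, c("clonal", "subclonal", "subclonal"))
  # alt = 50/100: Wilson CI on VAF approx (.40, .60) -> CCF CI (.80, 1.20)
  expect_equal(cl$ccf_low[1], 0.803, tolerance = 1e-2)
  expect_equal(cl$ccf_high[1], 1.197, tolerance = 1e-2)
  # alt = 10/100: CI upper far below 1
  expect_lt(cl$ccf_high[2], 0.5)
  # VAF = 1 at purity 1: CCF = 2, CI entirely above 1 -> subclonal, flagged
  expect_equal(cl$ccf[3], 2)
  expect_true(cl$ci_above_one[3])
  expect_error(classify_clonality(0, 0, 1), "total read count")
})

test_that("clonality CI is monotone in alt count", {
  cl <- classify_clonality(0:80, rep(80, 81), purity = 0.7,
                           cn_tumour = 2)
  expect_true(all(diff(cl$ccf_low) >= -1e-12))
  expect_true(all(diff(cl$ccf_high) >= -1e-12))
  # once the CI has moved past 1 from below, it never comes back
  state <- match(cl$clonality, c("subclonal", "clonal"))
  first_clonal <- which(state == 2)[1]
  later_sub <- which(state == 1 & seq_along(state) > first_clonal)
  if (length(later_sub)) {
    expect_true(all(cl$ccf_low[later_sub] > 1))
  }
})

test_that("pct_subclonal counts classifiable mutations only", {
  mk <- function(alt, total) {
    data.frame(patient = "A", alt_reads = alt, total_reads = total,
               purity = 1, cn_normal = 2, cn_tumour = 2)
  }
  all_clonal <- mk(c(48, 52, 50), c(100, 100, 100))
  expect_equal(pct_subclonal(all_clonal)$pct_subclonal, 0)
  mixed <- mk(c(rep(50, 7), rep(10, 3)), rep(100, 10))
  expect_equal(pct_subclonal(mixed)$pct_subclonal, 30)
  # unclassifiable-only patient gives NA, not 0
  none <- mk(50, 100)
  none$purity <- NA
  expect_true(is.na(pct_subclonal(none)$pct_subclonal))
})

test_that("TMB is count over footprint and additive on disjoint sets", {
  expect_equal(compute_tmb(0), 0)
  expect_equal(compute_tmb(4554), 100)
  expect_equal(compute_tmb(105), 105 / 45.54)
  expect_equal(compute_tmb(30) + compute_tmb(75), compute_tmb(105))
})

test_that("signature fitting recovers pure and mixed catalogues", {
  ref <- synthetic_signature_matrix()
  pure <- round(ref[, "Signature_3"] * 5000)
  fit <- fit_signature_exposures(pure, ref)
  expect_equal(unname(fit$weights[["Signature_3"]]), 1, tolerance = 0.02)
  expect_true(all(fit$weights[setdiff(names(fit$weights),
                                      "Signature_3")] < 0.05))

  mix <- 0.6 * ref[, "Signature_3"] + 0.4 * ref[, "Signature_13"]
  fit2 <- fit_signature_exposures(round(mix * 1e5), ref)
  # grid-search oracle over two-signature mixtures
  grid <- seq(0, 1, by = 0.001)
  errs <- vapply(grid, function(w)
    sum((w * ref[, "Signature_3"] + (1 - w) * ref[, "Signature_13"] -
           round(mix * 1e5) / sum(round(mix * 1e5)))^2), 0.0)
  w_star <- grid[which.min(errs)]
  expect_equal(unname(fit2$weights[["Signature_3"]]), w_star,
               tolerance = 0.05)
  expect_equal(unname(fit2$weights[["Signature_3"]]), 0.6, tolerance = 0.05)
  expect_equal(unname(fit2$weights[["Signature_13"]]), 0.4,
               tolerance = 0.05)

  # 10 mutations: below the > 10 threshold, no result
  few <- c(rep(1, 10), rep(0, 86))
  expect_true(all(is.na(fit_signature_exposures(few, ref)$weights)))
})

test_that("exposure normalization is a log2 ratio against signature 1", {
  w <- c(Signature_1 = 0.2, Signature_3 = 0.2, Signature_5 = 0.6)
  nr <- normalize_exposures(w)
  expect_equal(unname(nr$log2_ratio[["Signature_3"]]), 0)
  w2 <- c(Signature_1 = 0.2, Signature_3 = 0.8, Signature_5 = 0)
  expect_equal(unname(normalize_exposures(w2)$log2_ratio[["Signature_3"]]),
               2, tolerance = 0.1)
  expect_equal(normalize_exposures(c(Signature_1 = 1, Signature_3 = 0,
                                     Signature_5 = 0))$nonclock_fraction, 0)
})

test_that("HRD components follow the scar definitions on crafted segments", {
  gm <- toy_genome()
  balanced <- seg_row(1, 200e6, 1, 1)
  expect_equal(compute_hrd(balanced, gm)$hrd_total, 0)

  # interstitial 20 Mb LOH, otherwise balanced
  loh <- rbind(seg_row(1, 99999999, 1, 1),
               seg_row(100e6, 119999999, 1, 0),
               seg_row(120e6, 200e6, 1, 1))
  r <- compute_hrd(loh, gm)
  expect_equal(r$loh, 1)
  expect_equal(r$tai, 0)

  # 40 Mb (2,1) then 40 Mb (2,2) adjacent -> one large-scale transition
  lst <- rbind(seg_row(100e6, 139999999, 2, 1),
               seg_row(140e6, 179999999, 2, 2))
  expect_equal(compute_hrd(lst, gm)$lst, 1)

  expect_error(compute_hrd(rbind(seg_row(1, 50e6, 1, 1),
                                 seg_row(40e6, 90e6, 2, 1)), gm),
               "overlapping")
})

test_that("HRD equals exhaustive rule application and ignores row order", {
  gm <- toy_genome()
  for (seed in 1:8) {
    seg <- random_segments(n_seg = sample(3:20, 1), seed = seed)
    got <- compute_hrd(seg, gm)
    want <- hrd_oracle(seg, gm)
    expect_equal(c(tai = got$tai, loh = got$loh, lst = got$lst), want,
                 info = paste("seed", seed))
    shuffled <- seg[sample(nrow(seg)), ]
    expect_equal(compute_hrd(shuffled, gm), got)
  }
})

test_that("genome-altered fraction is length-weighted vs ploidy", {
  all2 <- seg_row(1, 100e6, 1, 1)
  expect_equal(genome_altered_fraction(all2)$cna_fraction, 0)
  half <- rbind(seg_row(1, 100e6, 2, 1), seg_row(100000001, 200e6, 1, 1))
  expect_equal(genome_altered_fraction(half)$cna_fraction, 0.5)
  mixed <- random_segments(12, seed = 9)
  len <- mixed$end - mixed$start + 1
  hand <- sum(len[mixed$major_cn + mixed$minor_cn != 2]) / sum(len)
  expect_equal(genome_altered_fraction(mixed)$cna_fraction, hand)
})

test_that("HLA LOH calls require both low copy number and significance", {
  tab <- data.frame(patient = "A",
                    allele = c("HLA-A*01:01", "HLA-A*02:01", "HLA-B*07:02"),
                    cn = c(0.3, 0.9, 0.3),
                    p_value = c(0.01, 0.001, 0.2))
  r <- call_hla_loh(tab)
  expect_equal(r$loh, c(TRUE, FALSE, FALSE))
  expect_true(attr(r, "patient_any_loh")$any_loh)
  tab$p_value[1] <- NA
  expect_warning(r2 <- call_hla_loh(tab), "skipped")
  expect_false(any(r2$loh))
})

test_that("HLA LOH presentation impact matches enumeration", {
  alleles <- data.frame(
    patient = "A",
    allele = c("HLA-A*01", "HLA-A*02"),
    locus = "HLA-A",
    loh = c(FALSE, FALSE)
  )
  neo <- data.frame(patient = "A",
                    peptide = paste0("p", 1:10),
                    presenting_allele = rep(c("HLA-A*01", "HLA-A*02"),
                                            c(3, 7)))
  expect_equal(hla_loh_impact(alleles, neo)$pct_unpresentable, 0)

  alleles$loh <- c(TRUE, FALSE)
  imp <- hla_loh_impact(alleles, neo)
  expect_equal(imp$pct_unpresentable, 30)
  # the lost allele presented 3 < 7 of the retained one
  expect_equal(imp$frac_lost_presented_ge_retained, 0)

  # crafted 4-event table across patients
  al4 <- data.frame(
    patient = rep(c("A", "B", "C", "D"), each = 2),
    allele = paste0("HLA-A*", sprintf("%02d", 1:8)),
    locus = "HLA-A",
    loh = rep(c(TRUE, FALSE), 4)
  )
  counts_lost <- c(5, 2, 3, 0)
  counts_ret <- c(5, 4, 1, 2)
  neo4 <- do.call(rbind, lapply(1:4, function(i) {
    p <- c("A", "B", "C", "D")[i]
    la <- al4$allele[al4$patient == p & al4$loh]
    ra <- al4$allele[al4$patient == p & !al4$loh]
    rbind(
      if (counts_lost[i]) data.frame(patient = p,
                                     peptide = paste0(p, "L", seq_len(counts_lost[i])),
                                     presenting_allele = la),
      if (counts_ret[i]) data.frame(patient = p,
                                    peptide = paste0(p, "R", seq_len(counts_ret[i])),
                                    presenting_allele = ra)
    )
  }))
  imp4 <- hla_loh_impact(al4, neo4)
  expect_equal(imp4$frac_lost_presented_ge_retained,
               mean(counts_lost >= counts_ret))
})

test_that("neoantigen filter applies the three retention conditions", {
  toy <- data.frame(
    peptide_length = c(9, 10, 8, 11, 9),
    mut_nM = c(499, 500, 100, 100, 450),
    wt_nM = c(600, 900, 90, 500, 800),
    tpm = c(2, 2, 5, 5, 0.5)
  )
  kept <- filter_neoantigens(toy)
  brute <- toy[toy$mut_nM < 500 & toy$mut_nM < toy$wt_nM & toy$tpm > 1, ]
  expect_equal(attr(kept, "n_retained"), nrow(brute))
  expect_equal(kept$mut_nM, brute$mut_nM)
  # 499 nM boundary retained, 500 nM rejected, weaker-than-WT rejected
  expect_true(499 %in% kept$mut_nM)
  expect_false(500 %in% kept$mut_nM)
  expect_false(100 %in% kept$mut_nM[kept$wt_nM == 90])
  expect_error(filter_neoantigens(transform(toy, mut_nM = -1)), "negative")
  expect_error(filter_neoantigens(transform(toy, peptide_length = 7)),
               "8-11")
})

test_that("driver flags equal hand counts", {
  mut <- data.frame(
    patient = c("A", "A", "B", "C", "D", "E", "F", "F"),
    gene = c("TP53", "g0001", "PIK3CA", "TP53", "g0002", "g0003",
             "TP53", "PIK3CA")
  )
  fl <- driver_flags(mut, patients = LETTERS[1:6])
  expect_equal(fl$mut_TP53, c(1, 0, 1, 0, 0, 1))
  expect_equal(fl$mut_PIK3CA, c(0, 1, 0, 0, 0, 1))
  none <- driver_flags(mut[0, ], patients = c("X", "Y"))
  expect_true(all(none$mut_TP53 == 0))
})
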