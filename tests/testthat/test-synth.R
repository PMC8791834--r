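# Synthetic cohort generator: determinism, null model, planted effect
# directions, and the per-modality simulators.

test_that("identical seeds give byte-identical cohort bundles", {
  cfg <- simulation_config(n_patients = 40, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  for (tab in c("clinical", "mutations", "segments", "affinities",
                "hla_alleles", "tide", "outcomes")) {
    expect_identical(a[[tab]], b[[tab]], info = tab)
  }
  expect_identical(a$expression$counts, b$expression$counts)
  expect_identical(a$cells, b$cells)
  expect_identical(a$ground_truth$latent, b$ground_truth$latent)
  # a different seed gives a different cohort
  c2 <- simulate_cohort(simulation_config(n_patients = 40, seed = 8))
  expect_false(identical(a$mutations, c2$mutations))
})

test_that("all-zero effects reproduce the cutpoint prior and a null scan", {
  es <- default_effect_sizes() * 0
  co <- simulate_cohort(simulation_config(n_patients = 400, seed = 5,
                                          effect_sizes = es))
  probs <- diff(c(0, pnorm(co$config$rcb_cutpoints), 1))
  names(probs) <- c("RCB-III", "RCB-II", "RCB-I", "pCR")
  counts <- table(factor(co$outcomes$rcb, names(probs)))
  # each class within 4 binomial SDs of its prior expectation
  for (k in names(probs)) {
    se <- sqrt(400 * probs[k] * (1 - probs[k]))
    expect_lt(abs(counts[[k]] - 400 * probs[k]), 4 * se)
  }
})

test_that("a lone positive TMB effect induces a positive RCB trend", {
  es <- default_effect_sizes() * 0
  es["tmb"] <- 1
  co <- simulate_cohort(simulation_config(n_patients = 500, seed = 6,
                                          effect_sizes = es))
  n_mut <- table(factor(co$mutations$patient, co$clinical$patient))
  tmb <- compute_tmb(as.integer(n_mut))
  rcb_rank <- as.integer(factor(co$outcomes$rcb,
                                c("RCB-III", "RCB-II", "RCB-I", "pCR"),
                                ordered = TRUE))
  expect_gt(cor(tmb, rcb_rank, method = "spearman"), 0.15)
})

test_that("simulated read counts invert the CCF formula", {
  set.seed(11)
  pure <- simulate_mutations(rep(1, 4000), purity = 1, depth_mean = 100)
  expect_equal(mean(pure$vaf), 0.5, tolerance = 0.01)
  half <- simulate_mutations(rep(1, 4000), purity = 0.5, depth_mean = 100)
  expect_equal(mean(half$vaf), 0.25, tolerance = 0.01)
  # zero-copy context is resampled, never emitted
  z <- simulate_mutations(rep(0.8, 200), purity = 0.8, depth_mean = 50,
                          cn_tumour = 0)
  expect_true(all(z$cn_tumour > 0))
})

test_that("CCF estimation round-trips the generator at high depth", {
  set.seed(12)
  ccf_true <- runif(2000, 0.1, 1)
  sim <- simulate_mutations(ccf_true, purity = 0.6, depth_mean = 1e4,
                            cn_tumour = sample(1:4, 2000, replace = TRUE))
  est <- compute_ccf(sim$vaf, sim$purity, sim$cn_normal, sim$cn_tumour)
  expect_lt(mean(abs(est - ccf_true)), 0.02)
})

test_that("expression shifts are recoverable and library-size invariant", {
  cfg <- simulation_config(n_patients = 20, seed = 3)
  set.seed(30)
  params <- data.frame(ggi = c(rep(2, 5), rep(-2, 5)), stat1 = 0,
                       dysfunction = 0, er_negative = 0, her2_positive = 0)
  ex <- simulate_expression(cfg, params)
  norm <- tmm_tpm_normalize(ex$counts, ex$lengths)
  sc <- ssgsea_score(norm$log2_tpm, ex$gene_sets$GGI)
  expect_true(all(sc$score[1:5] > sc$score[6:10]))

  # doubling one library leaves its TPM essentially unchanged
  counts2 <- ex$counts
  counts2[, 1] <- counts2[, 1] * 2L
  norm2 <- tmm_tpm_normalize(counts2, ex$lengths)
  rel <- abs(norm2$tpm[, 1] - norm$tpm[, 1]) / (norm$tpm[, 1] + 1)
  expect_lt(stats::median(rel), 0.01)

  # zero planted shift: score carries no response information
  set.seed(31)
  params0 <- data.frame(ggi = 0, stat1 = 0, dysfunction = 0,
                        er_negative = 0, her2_positive = 0)[rep(1, 60), ]
  ex0 <- simulate_expression(cfg, params0,
                             sample_ids = sprintf("S%03d", 1:60))
  sc0 <- ssgsea_score(tmm_tpm_normalize(ex0$counts, ex0$lengths)$log2_tpm,
                      ex0$gene_sets$GGI)
  fake_latent <- rnorm(60)
  expect_lt(abs(cor(sc0$score, fake_latent, method = "spearman")), 0.3)
})

test_that("cell simulation is homogeneous Poisson with the given mix", {
  set.seed(13)
  lam <- 4e-4
  win <- c(1000, 1000)
  counts <- replicate(40, nrow(simulate_cells(lam, c(cancer = 1,
                                                     stromal = 0,
                                                     lymphocyte = 0), win)))
  expect_equal(mean(counts), lam * prod(win), tolerance = 0.05)
  one <- simulate_cells(lam, c(cancer = 1, stromal = 0, lymphocyte = 0),
                        win)
  expect_equal(unname(cell_fractions(one)), c(1, 0, 0))
  expect_error(simulate_cells(lam, window = c(0, 10)), "area")
  expect_error(simulate_cells(0.1, class_mix = c(cancer = 0.7)), "sum")
})

test_that("affinity candidates respect length bounds and plantable filters", {
  mut <- data.frame(patient = rep(c("A", "B"), each = 30),
                    gene = "g0001")
  set.seed(14)
  aff <- simulate_affinities(mut, candidates_per_mutation = 1)
  expect_true(all(aff$candidates$peptide_length %in% 8:11))
  # ground-truth pass counts equal an independent triple-condition count
  cand <- aff$candidates
  brute <- vapply(c("A", "B"), function(p) {
    s <- cand[cand$patient == p, ]
    sum(s$mut_nM < 500 & s$mut_nM < s$wt_nM & s$tpm > 1)
  }, 0L)
  expect_equal(aff$truth$n_passing, unname(brute))
  expect_equal(attr(filter_neoantigens(cand), "n_retained"), sum(brute))
  # hopeless binders are never retained
  hopeless <- transform(cand, mut_nM = 1e4)
  expect_equal(attr(filter_neoantigens(hopeless), "n_retained"), 0)
})

test_that("degenerate configurations are rejected", {
  expect_error(simulation_config(rcb_cutpoints = c(0, 0, 1)), "ascending")
  expect_error(simulation_config(n_patients = 4), "fewer than 2")
  expect_error(simulation_config(purity_range = c(0, 0.9)), "purity")
  expect_error(simulation_config(n_genes = 50), "n_genes")
  expect_error(simulation_config(subtype_mix = c(a = 0.5, b = 0.2)),
               "sum to 1")
  gm0 <- default_genome_model()[0, ]
  expect_error(simulation_config(genome_model = gm0), "empty genome")
})
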