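# Synthetic multi-omic cohort generator. Every downstream feature extractor
# has a planted ground truth here: true CCFs, true signature weights, true
# cell intensities, and known effect directions on the latent response.

# ---- gene universe ---------------------------------------------------------

# Marker genes named in the downstream scores; the rest of the universe is
# generic ("g0001", ...). Gene blocks host the planted proliferation/immune
# signals. Deterministic given the config seed.
gene_universe <- function(cfg) {
  markers <- c("ESR1", "PGR", "ERBB2", "GZMA", "PRF1",
               "BUB1B", "CDK1", "AURKB", "TTK", "UGCG", "CERT1")
  n_gen <- cfg$n_genes - length(markers)
  generic <- sprintf("g%04d", seq_len(n_gen))
  genes <- c(markers, generic)
  blocks <- list(
    ggi = generic[1:40], escell = generic[41:65], stat1 = generic[66:95],
    danaher_cd8 = generic[96:103], danaher_mast = generic[104:108],
    mhc = generic[109:118], immunomodulator = generic[119:128],
    effector = generic[129:138], suppressor = generic[139:148]
  )
  with_seed(substream_seed(cfg$seed, 50), {
    lengths <- stats::setNames(sample(500:5000, length(genes),
                                      replace = TRUE), genes)
    mu <- stats::setNames(stats::rnorm(length(genes), 4, 1.2), genes)
  })
  mu[c("ESR1", "PGR", "ERBB2")] <- c(7, 6, 6)
  mu[c("GZMA", "PRF1")] <- 4
  mu[c("BUB1B", "CDK1", "AURKB", "TTK")] <- 5
  mu[c("UGCG", "CERT1")] <- 5
  gene_sets <- list(GGI = blocks$ggi, ESCELL = blocks$escell,
                    STAT1 = blocks$stat1, DANAHER_CD8 = blocks$danaher_cd8,
                    DANAHER_MAST = blocks$danaher_mast)
  immuno_groups <- blocks[c("mhc", "immunomodulator", "effector",
                            "suppressor")]
  list(genes = genes, blocks = blocks, lengths = lengths, baseline = mu,
       gene_sets = gene_sets, immuno_groups = immuno_groups)
}

# ---- latent model ----------------------------------------------------------

simulate_latent <- function(cfg) {
  traits_names <- generator_traits(cfg)
  n <- cfg$n_patients
  with_seed(substream_seed(cfg$seed, 1), {
    traits <- matrix(stats::rnorm(n * length(traits_names)), nrow = n,
                     dimnames = list(NULL, traits_names))
    beta <- stats::setNames(rep(0, length(traits_names)), traits_names)
    beta[names(cfg$effect_sizes)] <- cfg$effect_sizes
    s <- cfg$latent_noise_sd
    signal <- if (sum(beta^2) > 0) {
      as.vector(traits %*% beta) / sqrt(sum(beta^2)) * sqrt(max(0, 1 - s^2))
    } else rep(0, n)
    latent <- signal + stats::rnorm(n, 0, if (sum(beta^2) > 0) s else 1)
    rcb <- cut(latent, c(-Inf, cfg$rcb_cutpoints, Inf),
               labels = rcb_levels())
    list(traits = traits,
         latent = latent,
         rcb = factor(as.character(rcb), levels = rcb_levels(),
                      ordered = TRUE),
         pcr = rcb == "pCR")
  })
}

# ---- mutations -------------------------------------------------------------

#' Simulate read counts for mutations of known cancer cell fraction
#'
#' Inverse of the CCF estimator: the expected variant allele fraction is
#' \eqn{VAF = CCF \cdot p / ((1-p) CN_{normal} + p\, CN_{tumour})}, the
#' sequencing depth is Poisson around `depth_mean` (floored at 25x) and alt
#' counts are binomial. Tumour copy number 0 at a mutant locus is rejected
#' and resampled from `cn_weights`.
#'
#' @param true_ccf Vector of true cancer cell fractions in [0, 1].
#' @param purity Tumour purity in (0, 1].
#' @param depth_mean Mean sequencing depth.
#' @param cn_tumour Total tumour copy number per mutation (recycled).
#' @param cn_normal Germline copy number (default 2).
#' @param cn_weights Named weights over copy states used to resample
#'   zero-copy contexts.
#' @return data.frame: `true_ccf`, `cn_normal`, `cn_tumour`, `purity`,
#'   `expected_vaf`, `total_reads`, `alt_reads`, `vaf`, `observed`
#'   (alt >= 1).
#' @export
simulate_mutations <- function(true_ccf, purity, depth_mean,
                               cn_tumour = 2, cn_normal = 2,
                               cn_weights = c(`1` = 0.1, `2` = 0.6,
                                              `3` = 0.2, `4` = 0.1)) {
  stopifnot(purity > 0, purity <= 1, all(true_ccf >= 0 & true_ccf <= 1))
  m <- length(true_ccf)
  cn_tumour <- rep_len(cn_tumour, m)
  zero <- cn_tumour == 0
  if (any(zero)) {
    cn_tumour[zero] <- as.integer(sample(names(cn_weights), sum(zero),
                                         replace = TRUE, prob = cn_weights))
  }
  vaf_true <- true_ccf * purity / ((1 - purity) * cn_normal +
                                     purity * cn_tumour)
  depth <- pmax(25L, stats::rpois(m, depth_mean))
  alt <- stats::rbinom(m, depth, vaf_true)
  data.frame(true_ccf = true_ccf, cn_normal = cn_normal,
             cn_tumour = cn_tumour, purity = purity,
             expected_vaf = vaf_true, total_reads = depth, alt_reads = alt,
             vaf = alt / depth, observed = alt >= 1)
}

# Cohort-level mutation table; one row per observed mutation. Mutation count
# scales with the TMB trait, subclonal fraction with the subclonality trait,
# trinucleotide contexts mix clock and HRD/APOBEC signatures by trait.
simulate_mutation_table <- function(cfg, lat, purity, uni) {
  ref <- cfg$signature_reference
  classes <- rownames(ref)
  sig_n <- colnames(ref)
  n <- cfg$n_patients
  out <- vector("list", n)
  truth <- vector("list", n)
  sig_w <- matrix(0, n, ncol(ref), dimnames = list(NULL, sig_n))
  t <- lat$traits
  tp53 <- t[, "tp53"] > stats::qnorm(1 - 0.57)
  pik3ca <- t[, "pik3ca"] > stats::qnorm(1 - 0.26)
  for (i in seq_len(n)) {
    n_mut <- stats::rpois(1, cfg$mu_mutations * exp(0.45 * t[i, "tmb"]))
    n_mut <- max(n_mut, 3L)
    pi_sub <- stats::plogis(stats::qlogis(0.25) + 0.7 *
                              t[i, "pct_subclonal"])
    subclonal <- stats::runif(n_mut) < pi_sub
    ccf <- ifelse(subclonal, 0.1 + 0.65 * stats::rbeta(n_mut, 2, 2), 1)
    cn_t <- as.integer(sample(names(cfg$cn_weights), n_mut, replace = TRUE,
                              prob = cfg$cn_weights))
    sim <- simulate_mutations(ccf, purity[i], cfg$depth_mean, cn_t,
                              cn_weights = cfg$cn_weights)
    # Patient signature mixture over a 4-signature active set; HRD (sig 3)
    # and APOBEC (sig 13 when present) scale with their traits.
    w <- stats::setNames(rep(0, ncol(ref)), sig_n)
    apo_sig <- if ("Signature_13" %in% sig_n) "Signature_13" else
      sig_n[min(4, length(sig_n))]
    w["Signature_1"] <- 1
    if ("Signature_5" %in% sig_n) w["Signature_5"] <- 0.5
    if ("Signature_3" %in% sig_n) {
      w["Signature_3"] <- exp(0.9 * t[i, "hrd"] - 0.6)
    }
    w[apo_sig] <- w[apo_sig] + exp(0.9 * t[i, "apobec"] - 1.1)
    w <- w / sum(w)
    sig_w[i, ] <- w
    ctx <- sample(classes, n_mut, replace = TRUE, prob = as.vector(ref %*% w))
    gm <- cfg$genome_model
    chr_i <- sample(nrow(gm), n_mut, replace = TRUE, prob = gm$length)
    genes <- sample(uni$genes, n_mut, replace = TRUE)
    if (tp53[i]) genes[1] <- "TP53"
    if (pik3ca[i]) genes[min(2, n_mut)] <- "PIK3CA"
    tab <- data.frame(
      patient = sprintf("P%03d", i), chrom = gm$chrom[chr_i],
      pos = floor(stats::runif(n_mut, 1, gm$length[chr_i])),
      ref = sample(c("A", "C", "G", "T"), n_mut, replace = TRUE),
      alt = sample(c("A", "C", "G", "T"), n_mut, replace = TRUE),
      gene = genes, alt_reads = sim$alt_reads,
      total_reads = sim$total_reads, cn_normal = sim$cn_normal,
      cn_tumour = sim$cn_tumour, purity = purity[i], context96 = ctx,
      stringsAsFactors = FALSE
    )
    keep <- sim$observed
    out[[i]] <- tab[keep, , drop = FALSE]
    truth[[i]] <- data.frame(patient = sprintf("P%03d", i),
                             true_ccf = sim$true_ccf[keep])
  }
  list(mutations = do.call(rbind, out), true_ccf = do.call(rbind, truth),
       signature_weights = sig_w, tp53 = tp53, pik3ca = pik3ca)
}

# ---- copy-number segments --------------------------------------------------

# Per-patient allele-specific segments: a balanced (1,1) background with
# planted HRD scars (interstitial LOH, telomeric imbalance, large-scale
# transitions) whose counts scale with the HRD trait, plus whole-chromosome
# gains scaling with the copy-number-alteration trait.
simulate_segment_table <- function(cfg, lat) {
  gm <- cfg$genome_model
  t <- lat$traits
  n <- cfg$n_patients
  out <- vector("list", n)
  for (i in seq_len(n)) {
    lam <- exp(0.55 + 0.55 * t[i, "hrd"])
    k <- pmin(c(stats::rpois(1, lam), stats::rpois(1, lam),
                stats::rpois(1, lam)), 6L)
    hosts <- sample(nrow(gm), sum(k))   # one event per chromosome
    ev_type <- rep(c("loh", "tai", "lst"), k)
    p_gain <- stats::plogis(-1.4 + 0.9 * t[i, "cna"])
    rest <- setdiff(seq_len(nrow(gm)), hosts)
    gains <- rest[stats::runif(length(rest)) < p_gain]
    chromv <- startv <- endv <- majv <- minv <- vector("list", nrow(gm))
    for (c_i in seq_len(nrow(gm))) {
      L <- gm$length[c_i]
      ce <- gm$centromere_end[c_i]
      cs <- gm$centromere_start[c_i]
      if (c_i %in% hosts) {
        type <- ev_type[match(c_i, hosts)]
        if (type == "loh") {
          # interstitial > 15 Mb LOH on the q arm
          len <- floor(stats::runif(1, 16e6, min(40e6, L - ce - 8e6)))
          s0 <- floor(ce + 2e6)
          startv[[c_i]] <- c(1, s0, s0 + len)
          endv[[c_i]] <- c(s0 - 1, s0 + len - 1, L)
          majv[[c_i]] <- c(1, 1, 1); minv[[c_i]] <- c(1, 0, 1)
        } else if (type == "tai") {
          # telomeric imbalance on the p arm, short of the centromere
          len <- floor(stats::runif(1, 12e6, max(13e6, cs - 2e6)))
          startv[[c_i]] <- c(1, len + 1); endv[[c_i]] <- c(len, L)
          majv[[c_i]] <- c(2, 1); minv[[c_i]] <- c(1, 1)
        } else {
          # one large-scale transition mid-q, balanced states
          b <- floor(stats::runif(1, ce + 12e6, L - 12e6))
          startv[[c_i]] <- c(1, b + 1); endv[[c_i]] <- c(b, L)
          majv[[c_i]] <- c(1, 2); minv[[c_i]] <- c(1, 2)
        }
      } else {
        startv[[c_i]] <- 1; endv[[c_i]] <- L
        majv[[c_i]] <- if (c_i %in% gains) 2 else 1
        minv[[c_i]] <- 1
      }
      chromv[[c_i]] <- rep(gm$chrom[c_i], length(startv[[c_i]]))
    }
    out[[i]] <- data.frame(
      patient = sprintf("P%03d", i), chrom = unlist(chromv),
      start = unlist(startv), end = unlist(endv),
      major_cn = unlist(majv), minor_cn = unlist(minv),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# ---- expression ------------------------------------------------------------

#' Simulate a raw expression count matrix with planted gene-block shifts
#'
#' Log-normal-Poisson counts over the configured gene universe. Designated
#' proliferation (GGI, ES-cell, mitotic) and immune (STAT1, cytolytic,
#' marker) gene blocks are shifted on the log2 scale by the supplied
#' per-patient trait values, so downstream signature scoring can recover
#' them. ESR1/PGR track ER status and ERBB2 tracks HER2 status.
#'
#' @param cfg `simulation_config`.
#' @param params data.frame with one row per sample and columns `ggi`,
#'   `stat1`, `dysfunction` (numeric traits), `er_negative`, `her2_positive`
#'   (0/1).
#' @param sample_ids Column names of the output matrix.
#' @return list: `counts` (genes x samples integer matrix), `lengths`
#'   (named bp vector), `gene_sets`, `immuno_groups`.
#' @export
simulate_expression <- function(cfg, params,
                                sample_ids = sprintf("P%03d",
                                                     seq_len(nrow(params)))) {
  uni <- gene_universe(cfg)
  n <- nrow(params)
  g <- length(uni$genes)
  shift <- matrix(0, g, n, dimnames = list(uni$genes, sample_ids))
  b <- uni$blocks
  add <- function(genes, v) shift[genes, ] <<- shift[genes, ] +
    matrix(v, length(genes), n, byrow = TRUE)
  add(b$ggi, 0.9 * params$ggi)
  add(b$escell, 0.7 * params$ggi)
  add(c("BUB1B", "CDK1", "AURKB", "TTK"), 0.8 * params$ggi)
  add(b$stat1, 0.9 * params$stat1)
  add(c("GZMA", "PRF1"), 0.9 * params$stat1)
  add(b$danaher_cd8, 0.9 * params$stat1)
  add(b$mhc, 0.7 * params$stat1)
  add(b$immunomodulator, 0.7 * params$stat1)
  add(b$effector, 0.7 * params$stat1)
  add(b$danaher_mast, 0.8 * params$dysfunction)
  add(b$suppressor, 0.7 * params$dysfunction)
  add(c("ESR1", "PGR"), -2.5 * params$er_negative)
  add("ERBB2", 2.5 * params$her2_positive)
  libfac <- exp(stats::rnorm(n, 0, 0.3))
  lam <- 2^(uni$baseline + shift + stats::rnorm(g * n, 0, 0.25))
  lam <- sweep(lam, 2, libfac, "*")
  counts <- matrix(stats::rpois(g * n, lam), g, n,
                   dimnames = list(uni$genes, sample_ids))
  list(counts = counts, lengths = uni$lengths, gene_sets = uni$gene_sets,
       immuno_groups = uni$immuno_groups)
}

# ---- cells -----------------------------------------------------------------

#' Simulate a classified cell table (homogeneous spatial Poisson process)
#'
#' Per-class counts are Poisson with mean intensity x window area x class
#' proportion; positions are uniform in the window.
#'
#' @param intensity Total cell intensity (cells per px^2), > 0.
#' @param class_mix Proportions over the cell classes (sums to 1).
#' @param window c(width, height) in pixels; area must be > 0.
#' @return data.frame `x`, `y`, `class`.
#' @export
simulate_cells <- function(intensity,
                           class_mix = c(cancer = 0.5, stromal = 0.3,
                                         lymphocyte = 0.2),
                           window = c(1500, 1500)) {
  stopifnot(intensity > 0)
  if (length(window) == 1) window <- rep(window, 2)
  area <- prod(window)
  if (area <= 0) stop("window area must be > 0")
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  rows <- lapply(names(class_mix), function(cl) {
    m <- stats::rpois(1, intensity * class_mix[[cl]] * area)
    if (m == 0) return(NULL)
    data.frame(x = stats::runif(m, 0, window[1]),
               y = stats::runif(m, 0, window[2]),
               class = cl, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(x = numeric(), y = numeric(),
                                      class = character())
  out
}

# ---- neoepitope affinities -------------------------------------------------

#' Simulate candidate neoepitope affinities for a mutation table
#'
#' Each somatic mutation spawns a Poisson number of candidate peptides of
#' length 8-11 with log-normal mutant and wild-type binding affinities and a
#' source-gene expression level; the number of candidates passing the
#' standard filters (< 500 nM, stronger than wild type, > 1 TPM) is recorded
#' per patient as ground truth.
#'
#' @param mutations Mutation table with `patient`, `gene` columns.
#' @param n_hla_alleles Alleles per patient (default 6; two each of HLA-A/B/C
#'   named per patient).
#' @param candidates_per_mutation Poisson mean (default 0.7).
#' @return list: `candidates` (patient, peptide, peptide_length, mut_nM,
#'   wt_nM, tpm, presenting_allele, gene), `truth` (patient,
#'   n_passing).
#' @export
simulate_affinities <- function(mutations, n_hla_alleles = 6,
                                candidates_per_mutation = 0.7) {
  stop_if_missing_cols(mutations, c("patient", "gene"), "mutation table")
  loci <- rep(c("A", "B", "C"), length.out = n_hla_alleles)
  copy <- stats::ave(seq_len(n_hla_alleles), loci, FUN = seq_along)
  pats <- unique(mutations$patient)
  rows <- vector("list", length(pats))
  for (k in seq_along(pats)) {
    p <- pats[k]
    alleles <- sprintf("HLA-%s*%02d:%02d", loci, copy,
                       (k + seq_len(n_hla_alleles)) %% 90 + 1)
    mut <- mutations[mutations$patient == p, , drop = FALSE]
    n_cand <- stats::rpois(nrow(mut), candidates_per_mutation)
    tot <- sum(n_cand)
    if (tot == 0) {
      rows[[k]] <- NULL
      next
    }
    src <- rep(seq_len(nrow(mut)), n_cand)
    rows[[k]] <- data.frame(
      patient = p,
      peptide = sprintf("%s_pep%03d", p, seq_len(tot)),
      peptide_length = sample(8:11, tot, replace = TRUE),
      mut_nM = exp(stats::rnorm(tot, log(1200), 1.6)),
      wt_nM = NA_real_,
      tpm = exp(stats::rnorm(tot, log(3), 1.3)),
      presenting_allele = sample(alleles, tot, replace = TRUE),
      gene = mut$gene[src], stringsAsFactors = FALSE
    )
    rows[[k]]$wt_nM <- rows[[k]]$mut_nM *
      exp(stats::rnorm(tot, 0.8, 0.9))
  }
  cand <- do.call(rbind, rows)
  if (is.null(cand)) {
    cand <- data.frame(patient = character(), peptide = character(),
                       peptide_length = integer(), mut_nM = numeric(),
                       wt_nM = numeric(), tpm = numeric(),
                       presenting_allele = character(), gene = character())
  }
  pass <- cand$mut_nM < 500 & cand$mut_nM < cand$wt_nM & cand$tpm > 1
  truth <- data.frame(
    patient = pats,
    n_passing = vapply(pats, function(p)
      sum(pass & cand$patient == p), 0L),
    stringsAsFactors = FALSE
  )
  list(candidates = cand, truth = truth)
}

# ---- HLA alleles -----------------------------------------------------------

simulate_hla_table <- function(cfg, lat) {
  n <- cfg$n_patients
  flag <- lat$traits[, "hla_loh"] > stats::qnorm(1 - 0.17)
  loci <- rep(c("A", "B", "C"), length.out = cfg$n_hla_alleles)
  copy <- stats::ave(seq_len(cfg$n_hla_alleles), loci, FUN = seq_along)
  rows <- lapply(seq_len(n), function(i) {
    alleles <- sprintf("HLA-%s*%02d:%02d", loci, copy,
                       (i + seq_len(cfg$n_hla_alleles)) %% 90 + 1)
    cn <- stats::runif(cfg$n_hla_alleles, 0.7, 1.4)
    pv <- stats::runif(cfg$n_hla_alleles, 0.05, 0.95)
    if (flag[i]) {
      j <- sample(cfg$n_hla_alleles, 1)
      cn[j] <- stats::runif(1, 0.05, 0.45)
      pv[j] <- stats::runif(1, 0.0005, 0.04)
    }
    data.frame(patient = sprintf("P%03d", i), allele = alleles,
               locus = loci, cn = cn, p_value = pv,
               stringsAsFactors = FALSE)
  })
  list(alleles = do.call(rbind, rows), any_loh_true = flag)
}

# ---- cohort ----------------------------------------------------------------

#' Simulate a complete synthetic multi-omic cohort
#'
#' Generates, under one master seed, every table the feature pipeline
#' consumes: clinical covariates and treatment flags, a somatic mutation
#' table with copy-number context and purity, allele-specific segments, a
#' raw expression count matrix with gene lengths and gene sets, classified
#' cell tables, candidate neoepitope affinities, HLA allele copy-number
#' estimates, dysfunction/exclusion scores, and the ordinal RCB / binary pCR
#' outcomes — plus the generating ground truth.
#'
#' @param cfg A [simulation_config()].
#' @return Object of class `neo_cohort`: list with elements `clinical`,
#'   `mutations`, `segments`, `expression` (counts, lengths, gene_sets,
#'   immuno_groups), `cells` (named list of per-patient cell tables),
#'   `affinities`, `hla_alleles`, `tide`, `outcomes`, `ground_truth`,
#'   `config`.
#' @export
simulate_cohort <- function(cfg = simulation_config()) {
  validate_simulation_config(cfg)
  if (all(cfg$effect_sizes == 0) && length(cfg$effect_sizes) == 0) {
    stop("configuration error: empty effect_sizes")
  }
  uni <- gene_universe(cfg)
  lat <- simulate_latent(cfg)
  n <- cfg$n_patients
  ids <- sprintf("P%03d", seq_len(n))
  t <- lat$traits

  purity <- with_seed(substream_seed(cfg$seed, 2),
                      stats::runif(n, cfg$purity_range[1],
                                   cfg$purity_range[2]))
  mut <- with_seed(substream_seed(cfg$seed, 3),
                   simulate_mutation_table(cfg, lat, purity, uni))
  seg <- with_seed(substream_seed(cfg$seed, 4),
                   simulate_segment_table(cfg, lat))

  er_negative <- as.integer(t[, "er_negative"] >
                              stats::qnorm(1 - sum(cfg$subtype_mix[
                                c("er_neg_her2_pos", "er_neg_her2_neg")])))
  p_her2_erpos <- cfg$subtype_mix[["er_pos_her2_pos"]] /
    sum(cfg$subtype_mix[c("er_pos_her2_neg", "er_pos_her2_pos")])
  p_her2_erneg <- cfg$subtype_mix[["er_neg_her2_pos"]] /
    sum(cfg$subtype_mix[c("er_neg_her2_pos", "er_neg_her2_neg")])

  clin <- with_seed(substream_seed(cfg$seed, 5), {
    her2 <- as.integer(stats::runif(n) <
                         ifelse(er_negative == 1, p_her2_erneg,
                                p_her2_erpos))
    grade <- cut(t[, "grade"], c(-Inf, stats::qnorm(c(0.10, 0.50)), Inf),
                 labels = FALSE)
    chemo_cycles <- ifelse(stats::runif(n) < 0.02, 1L,
                           sample(c(4L, 5L, 6L), n, replace = TRUE,
                                  prob = c(0.1, 0.1, 0.8)))
    her2_cycles <- ifelse(her2 == 1,
                          ifelse(stats::runif(n) < 0.03, 0L,
                                 sample(2:4, n, replace = TRUE)), 0L)
    received_anthracycline <- as.integer(stats::runif(n) < 0.87)
    taxane_first <- as.integer(stats::runif(n) < 0.65)
    data.frame(
      patient = ids,
      age = round(pmin(80, pmax(25, stats::rnorm(n, 51, 10)))),
      tumour_size = round(exp(log(2.8) + 0.25 * t[, "tumour_size"] +
                                stats::rnorm(n, 0, 0.2)), 1),
      grade = grade,
      er_positive = 1L - er_negative,
      her2_positive = her2,
      ln_positive = as.integer(t[, "node_negative"] <= stats::qnorm(0.5)),
      chemo_cycles = chemo_cycles, her2_cycles = her2_cycles,
      received_anthracycline = received_anthracycline,
      received_anti_her2 = as.integer(her2_cycles > 0),
      taxane_first = taxane_first,
      anthracycline_first = as.integer(received_anthracycline == 1 &
                                         taxane_first == 0),
      stringsAsFactors = FALSE
    )
  })

  expr <- with_seed(substream_seed(cfg$seed, 6), {
    params <- data.frame(ggi = t[, "ggi"], stat1 = t[, "stat1"],
                         dysfunction = t[, "dysfunction"],
                         er_negative = er_negative,
                         her2_positive = clin$her2_positive)
    simulate_expression(cfg, params, ids)
  })

  cells <- with_seed(substream_seed(cfg$seed, 7), {
    lam_l <- cfg$cell_intensity[["lymphocyte"]] *
      exp(0.5 * t[, "lymphocyte_density"])
    lapply(seq_len(n), function(i) {
      lam <- c(cancer = cfg$cell_intensity[["cancer"]],
               stromal = cfg$cell_intensity[["stromal"]],
               lymphocyte = lam_l[i])
      simulate_cells(sum(lam), lam / sum(lam), cfg$window)
    })
  })
  names(cells) <- ids
  lymph_intensity_true <- cfg$cell_intensity[["lymphocyte"]] *
    exp(0.5 * t[, "lymphocyte_density"])

  aff <- with_seed(substream_seed(cfg$seed, 8),
                   simulate_affinities(mut$mutations, cfg$n_hla_alleles))
  hla <- with_seed(substream_seed(cfg$seed, 9), simulate_hla_table(cfg, lat))
  tide <- with_seed(substream_seed(cfg$seed, 10), data.frame(
    patient = ids,
    dysfunction = 0.9 * t[, "dysfunction"] + stats::rnorm(n, 0, 0.45),
    exclusion = 0.9 * t[, "exclusion"] + stats::rnorm(n, 0, 0.45),
    stringsAsFactors = FALSE
  ))

  out <- list(
    clinical = cbind(clin, data.frame(rcb = as.character(lat$rcb),
                                      pcr = as.integer(lat$pcr))),
    mutations = mut$mutations,
    segments = seg,
    expression = expr,
    cells = cells,
    affinities = aff$candidates,
    hla_alleles = hla$alleles,
    tide = tide,
    outcomes = data.frame(patient = ids, rcb = as.character(lat$rcb),
                          pcr = as.integer(lat$pcr),
                          stringsAsFactors = FALSE),
    ground_truth = list(latent = lat$latent, traits = lat$traits,
                        rcb = lat$rcb, purity = purity,
                        true_ccf = mut$true_ccf,
                        signature_weights = mut$signature_weights,
                        lymphocyte_intensity = lymph_intensity_true,
                        n_neoantigens = aff$truth,
                        hla_loh = hla$any_loh_true,
                        tp53 = mut$tp53, pik3ca = mut$pik3ca),
    config = cfg
  )
  class(out) <- "neo_cohort"
  out
}

#' @export
#' @method print neo_cohort
print.neo_cohort <- function(x, ...) {
  cat("Synthetic multi-omic cohort:", x$config$n_patients, "patients,",
      nrow(x$mutations), "somatic mutations,",
      nrow(x$expression$counts), "genes\n")
  print(table(x$outcomes$rcb))
  invisible(x)
}
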