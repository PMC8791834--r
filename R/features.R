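# Assembly of the patients x features predictor matrix from the raw cohort
# tables, with modality tags, plus the data-cleaning rules applied before
# model training.

#' Canonical feature definitions
#'
#' Reads the versioned feature-definition file (name, modality, source
#' operation, direction note). The fully integrated predictor configuration
#' uses exactly these 34 features; [build_feature_matrix()] validates its
#' output against this list.
#'
#' @param path Optional path to an alternative definition TSV.
#' @return data.frame with columns `name`, `modality`, `source`,
#'   `direction_note`.
#' @export
feature_definitions <- function(path = NULL) {
  path <- path %||% system.file("extdata", "feature_definitions.tsv",
                                package = "neopredict", mustWork = TRUE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stop_if_missing_cols(d, c("name", "modality"), "feature definitions")
  if (anyDuplicated(d$name)) stop("duplicate feature names in definitions")
  d
}

#' Feature matrix container
#'
#' @param X Patients x features numeric matrix (rownames = patient ids).
#' @param modality Named character vector tagging each feature with
#'   clinical/DNA/RNA/DigPath/treatment.
#' @param pcr Binary outcome (0/1).
#' @param rcb Optional ordinal RCB labels.
#' @return Object of class `neo_features`.
#' @export
feature_matrix <- function(X, modality, pcr, rcb = NULL) {
  X <- as.matrix(X)
  stopifnot(!is.null(colnames(X)), length(modality) == ncol(X),
            length(pcr) == nrow(X))
  if (anyDuplicated(colnames(X))) stop("feature names must be unique")
  names(modality) <- colnames(X)
  structure(list(X = X, modality = modality, pcr = as.integer(pcr),
                 rcb = rcb, patients = rownames(X)),
            class = "neo_features")
}

#' @export
#' @method print neo_features
print.neo_features <- function(x, ...) {
  cat("Feature matrix:", nrow(x$X), "patients x", ncol(x$X), "features (",
      paste(sprintf("%s:%d", names(table(x$modality)), table(x$modality)),
            collapse = ", "), ")\n")
  invisible(x)
}

impute_median <- function(x, name) {
  if (anyNA(x)) {
    med <- stats::median(x, na.rm = TRUE)
    warning(sprintf("%s: %d missing value(s) imputed with the cohort median",
                    name, sum(is.na(x))))
    x[is.na(x)] <- med
  }
  x
}

#' Build the full predictor feature matrix from a cohort
#'
#' Runs every feature-derivation operation over the raw tables of a
#' (synthetic or real) cohort bundle: mutation burden, clonality, neoantigen
#' load, HRD and copy-number scores, driver flags, HLA LOH, signature
#' exposures, TMM/TPM normalization and all transcriptomic scores,
#' nearest-neighbour lymphocyte density and fractions, and the clinical and
#' treatment covariates. Validates the result against the feature-definition
#' file.
#'
#' @param cohort A `neo_cohort` (see [simulate_cohort()]) or a list with the
#'   same table layout.
#' @param definitions Feature definitions (default [feature_definitions()]).
#' @param hrd_signature,apobec_signature Reference signature columns whose
#'   normalized exposures become the two signature features.
#' @return A `neo_features` object with exactly the defined features.
#' @export
build_feature_matrix <- function(cohort,
                                 definitions = feature_definitions(),
                                 hrd_signature = "Signature_3",
                                 apobec_signature = "Signature_13") {
  clin <- cohort$clinical
  ids <- clin$patient
  n <- length(ids)
  mut <- cohort$mutations
  at <- function(d, col) d[[col]][match(ids, d$patient)]

  # --- DNA ---
  n_mut <- vapply(ids, function(p) sum(mut$patient == p), 0L)
  tmb <- compute_tmb(n_mut)
  psub <- at(pct_subclonal(mut), "pct_subclonal")
  hrd <- at(compute_hrd(cohort$segments, cohort$config$genome_model %||%
                          default_genome_model()), "hrd_total")
  cna <- at(genome_altered_fraction(cohort$segments), "cna_fraction")
  drv <- driver_flags(mut, patients = ids)
  hla <- call_hla_loh(cohort$hla_alleles)
  hla_flag <- as.integer(at(attr(hla, "patient_any_loh"), "any_loh"))
  kept <- filter_neoantigens(cohort$affinities)
  n_neo <- vapply(ids, function(p) sum(kept$patient == p), 0L)
  ref <- cohort$config$signature_reference %||% synthetic_signature_matrix()
  if (!apobec_signature %in% colnames(ref)) {
    apobec_signature <- colnames(ref)[min(4, ncol(ref))]
  }
  sig_feats <- t(vapply(ids, function(p) {
    cat96 <- context_catalogue(mut$context96[mut$patient == p])
    fit <- fit_signature_exposures(cat96, ref)
    nr <- normalize_exposures(fit$weights)
    c(nr$log2_ratio[[hrd_signature]], nr$log2_ratio[[apobec_signature]])
  }, c(0, 0)))

  # --- RNA ---
  ex <- tmm_tpm_normalize(cohort$expression$counts,
                          cohort$expression$lengths)
  gs <- cohort$expression$gene_sets
  lg <- ex$log2_tpm[, ids, drop = FALSE]
  tpm <- ex$tpm[, ids, drop = FALSE]
  ggi <- ssgsea_score(lg, gs$GGI, set_name = "GGI")$score
  escell <- ssgsea_score(lg, gs$ESCELL, set_name = "ES-cell")$score
  stat1 <- ssgsea_score(lg, gs$STAT1, set_name = "STAT1")$score
  cyt <- metagene_score(tpm, c("GZMA", "PRF1"), mode = "geomean")
  tax <- metagene_score(tpm, taxane_metagene_genes()$mitotic,
                        mode = "difference",
                        genes_b = taxane_metagene_genes()$ceramide)
  cd8 <- metagene_score(tpm, gs$DANAHER_CD8, mode = "log_geomean")
  mast <- metagene_score(tpm, gs$DANAHER_MAST, mode = "log_geomean")

  # --- digital pathology ---
  dens <- vapply(ids, function(p)
    knn_density(cohort$cells[[p]])$median, 0.0)
  lfrac <- vapply(ids, function(p)
    cell_fractions(cohort$cells[[p]])[["lymphocyte"]], 0.0)

  X <- cbind(
    age = clin$age, tumour_size = clin$tumour_size, grade = clin$grade,
    er_positive = clin$er_positive, her2_positive = clin$her2_positive,
    ln_positive = clin$ln_positive,
    tmb = tmb, pct_subclonal = psub, n_neoantigens = n_neo,
    hrd_score = hrd, cna_fraction = cna,
    mut_TP53 = at(drv, "mut_TP53"), mut_PIK3CA = at(drv, "mut_PIK3CA"),
    hla_loh = hla_flag,
    sig_hrd_exposure = sig_feats[, 1],
    sig_apobec_exposure = sig_feats[, 2],
    ggi_score = ggi, escell_score = escell, stat1_score = stat1,
    cytolytic_score = cyt, taxane_metagene = tax,
    danaher_cd8 = cd8, danaher_mast = mast,
    tcell_dysfunction = at(cohort$tide, "dysfunction"),
    tcell_exclusion = at(cohort$tide, "exclusion"),
    expr_ESR1 = lg["ESR1", ], expr_PGR = lg["PGR", ],
    expr_ERBB2 = lg["ERBB2", ],
    lymphocyte_density = dens, lymphocyte_fraction = lfrac,
    received_anthracycline = clin$received_anthracycline,
    received_anti_her2 = clin$received_anti_her2,
    taxane_first = clin$taxane_first,
    anthracycline_first = clin$anthracycline_first
  )
  rownames(X) <- ids
  if (!identical(sort(colnames(X)), sort(definitions$name))) {
    stop("assembled features do not match the feature-definition file")
  }
  X <- X[, definitions$name, drop = FALSE]
  for (j in seq_len(ncol(X))) X[, j] <- impute_median(X[, j],
                                                      colnames(X)[j])
  feature_matrix(X, stats::setNames(definitions$modality, definitions$name),
                 pcr = clin$pcr, rcb = clin$rcb)
}

#' Clean a feature matrix before training or validation
#'
#' Training mode: a missing tumour size is set to 1.1 x the largest size in
#' the cohort, and under-treated cases (no chemotherapy cycle, or HER2+
#' without an anti-HER2 cycle) are excluded. Validation mode: missing
#' treatment features are set to zero and no cases are excluded.
#'
#' @param features A `neo_features` object.
#' @param clinical Clinical table with `patient`, `chemo_cycles`,
#'   `her2_cycles`, `her2_positive` (needed for the under-treatment rule).
#' @param mode "training" or "validation".
#' @param exclude_undertreated Apply the exposure filter (training mode).
#' @return Cleaned `neo_features`; attribute `excluded` lists removed
#'   patients.
#' @export
clean_training_data <- function(features, clinical = NULL,
                                mode = c("training", "validation"),
                                exclude_undertreated = TRUE) {
  mode <- match.arg(mode)
  X <- features$X
  if (is.null(features$pcr) || anyNA(features$pcr)) {
    stop("outcome missing: cannot clean a matrix without pCR labels")
  }
  if ("tumour_size" %in% colnames(X) && anyNA(X[, "tumour_size"])) {
    X[is.na(X[, "tumour_size"]), "tumour_size"] <-
      1.1 * max(X[, "tumour_size"], na.rm = TRUE)
  }
  excluded <- character()
  keep <- rep(TRUE, nrow(X))
  if (mode == "training" && exclude_undertreated && !is.null(clinical)) {
    cl <- clinical[match(rownames(X), clinical$patient), ]
    under <- cl$chemo_cycles < 1 |
      (cl$her2_positive == 1 & cl$her2_cycles < 1)
    under[is.na(under)] <- FALSE
    keep <- !under
    excluded <- rownames(X)[under]
  }
  if (mode == "validation") {
    tcols <- names(features$modality)[features$modality == "treatment"]
    for (cc in intersect(tcols, colnames(X))) {
      X[is.na(X[, cc]), cc] <- 0
    }
  }
  out <- feature_matrix(X[keep, , drop = FALSE], features$modality,
                        features$pcr[keep],
                        if (!is.null(features$rcb)) features$rcb[keep])
  attr(out, "excluded") <- excluded
  out
}

#' Cohort summary counts
#'
#' Counting operations over deposited-style tables: total somatic mutation
#' records, number of cases with TP53 / PIK3CA mutations, and the RCB class
#' distribution.
#'
#' @param mutations Mutation table (`patient`, `gene`).
#' @param clinical Clinical table with an `rcb` column.
#' @return list: `n_mutation_records`, `n_tp53_cases`, `n_pik3ca_cases`,
#'   `rcb_counts` (named vector over pCR/RCB-I/RCB-II/RCB-III).
#' @export
cohort_summary_counts <- function(mutations, clinical) {
  drv <- driver_flags(mutations)
  rcb <- factor(clinical$rcb, levels = rev(rcb_levels()))
  list(
    n_mutation_records = nrow(mutations),
    n_tp53_cases = sum(drv$mut_TP53),
    n_pik3ca_cases = sum(drv$mut_PIK3CA),
    rcb_counts = stats::setNames(as.integer(table(rcb)),
                                 levels(rcb))
  )
}
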