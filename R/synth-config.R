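# Configuration of the synthetic multi-omic cohort generator.

#' Default latent effect sizes of the cohort generator
#'
#' Signed log-odds-scale effects of each latent trait on the response scale,
#' oriented so positive values push toward pCR. Signs follow the reported
#' effect directions: higher mutation burden, HRD, copy-number alteration,
#' proliferation and immune infiltration favour pCR; higher subclonality,
#' T cell dysfunction/exclusion and HLA LOH favour residual disease.
#'
#' @return Named numeric vector.
#' @export
default_effect_sizes <- function() {
  c(tmb = 0.9, pct_subclonal = -0.7, hrd = 0.9, cna = 0.6,
    ggi = 1.1, stat1 = 1.0, lymphocyte_density = 0.9,
    dysfunction = -0.6, exclusion = -0.4,
    grade = 0.6, er_negative = 0.6, node_negative = 0.4, tumour_size = -0.2,
    tp53 = 0.4, pik3ca = -0.3, apobec = 0.3, hla_loh = -0.3)
}

#' Simulation configuration for synthetic multi-omic cohorts
#'
#' Defines the generative model: a Gaussian latent response score driven by
#' independent standard-normal patient traits weighted by `effect_sizes`,
#' binned into the four ordered RCB classes by fixed cutpoints
#' (a proportional-odds generative model), with every data modality
#' (mutations, allele-specific segments, expression counts, cell tables,
#' neoepitope affinities, HLA allele estimates, clinical covariates)
#' generated conditional on the traits.
#'
#' @param n_patients Cohort size (default 200, the desk-scale training size;
#'   a companion 75-patient cohort mirrors the validation proportions).
#' @param seed Master seed; per-table substreams are derived by fixed
#'   offsets.
#' @param effect_sizes Named vector, see [default_effect_sizes()]. Traits
#'   with zero effect still generate data but carry no response signal.
#' @param rcb_cutpoints Three ascending cutpoints on the standard-normal
#'   latent scale separating RCB-III | RCB-II | RCB-I | pCR. Defaults give
#'   class priors 18% / 40% / 16% / 26% (the observed response mix).
#' @param latent_noise_sd SD of the latent residual not explained by traits
#'   (default 0.3).
#' @param purity_range Tumour purity interval (default 0.2-0.9).
#' @param depth_mean Mean sequencing depth at mutant loci (default 160).
#' @param mu_mutations Baseline mean somatic mutation count per tumour
#'   (default 64, i.e. about 1.4 mutations/Mb over a 45.54 Mb footprint).
#' @param cn_weights Sampling weights of tumour total copy number states
#'   1-4 at mutant loci (germline copy number fixed at 2; autosomes only).
#' @param n_genes Number of expression genes (>= 200 so every scored gene
#'   block fits; default 1000).
#' @param subtype_mix Proportions of the four ER/HER2 strata (must sum
#'   to 1).
#' @param window Pathology window width/height in pixels.
#' @param cell_intensity Baseline intensities (cells per px^2) of the three
#'   cell classes; the lymphocyte intensity is modulated by the
#'   immune-infiltration trait.
#' @param signature_reference 96 x S reference signature matrix.
#' @param n_hla_alleles HLA class I alleles per patient (default 6).
#' @param genome_model Chromosome lengths/centromeres.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 200,
                              seed = 1,
                              effect_sizes = default_effect_sizes(),
                              rcb_cutpoints = stats::qnorm(c(0.18, 0.58,
                                                             0.74)),
                              latent_noise_sd = 0.3,
                              purity_range = c(0.2, 0.9),
                              depth_mean = 160,
                              mu_mutations = 64,
                              cn_weights = c(`1` = 0.10, `2` = 0.60,
                                             `3` = 0.20, `4` = 0.10),
                              n_genes = 1000,
                              subtype_mix = c(er_pos_her2_neg = 0.40,
                                              er_pos_her2_pos = 0.21,
                                              er_neg_her2_pos = 0.18,
                                              er_neg_her2_neg = 0.21),
                              window = c(1500, 1500),
                              cell_intensity = c(cancer = 3.5e-4,
                                                 stromal = 2.2e-4,
                                                 lymphocyte = 1.5e-4),
                              signature_reference =
                                synthetic_signature_matrix(),
                              n_hla_alleles = 6,
                              genome_model = default_genome_model()) {
  cfg <- list(n_patients = n_patients, seed = seed,
              effect_sizes = effect_sizes, rcb_cutpoints = rcb_cutpoints,
              latent_noise_sd = latent_noise_sd, purity_range = purity_range,
              depth_mean = depth_mean, mu_mutations = mu_mutations,
              cn_weights = cn_weights, n_genes = n_genes,
              subtype_mix = subtype_mix, window = window,
              cell_intensity = cell_intensity,
              signature_reference = signature_reference,
              n_hla_alleles = n_hla_alleles, genome_model = genome_model)
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    if (n_patients < 1) stop("configuration error: n_patients < 1")
    if (is.null(names(effect_sizes)) || any(names(effect_sizes) == "")) {
      stop("configuration error: effect_sizes must be a named vector")
    }
    if (length(rcb_cutpoints) != 3 || any(diff(rcb_cutpoints) <= 0)) {
      stop("configuration error: rcb_cutpoints must be 3 strictly ",
           "ascending values")
    }
    probs <- diff(c(0, stats::pnorm(rcb_cutpoints), 1))
    if (n_patients * min(probs) < 2) {
      stop("configuration error: fewer than 2 patients expected in an RCB ",
           "class under these cutpoints")
    }
    if (purity_range[1] <= 0 || purity_range[2] > 1 ||
        purity_range[1] > purity_range[2]) {
      stop("configuration error: purity_range must lie in (0, 1]")
    }
    if (depth_mean <= 0) stop("configuration error: depth_mean <= 0")
    if (abs(sum(subtype_mix) - 1) > 1e-8) {
      stop("configuration error: subtype_mix must sum to 1")
    }
    if (n_genes < 200) stop("configuration error: n_genes < 200 cannot ",
                            "host the scored gene blocks")
    if (nrow(genome_model) == 0) stop("configuration error: empty genome")
    if (any(cn_weights < 0) || sum(cn_weights) <= 0) {
      stop("configuration error: invalid cn_weights")
    }
    if (any(cell_intensity <= 0)) {
      stop("configuration error: cell intensities must be > 0")
    }
  })
  cfg
}

# Trait names the generator always draws (superset of effect_sizes keys).
generator_traits <- function(cfg) {
  unique(c(names(cfg$effect_sizes),
           c("tmb", "pct_subclonal", "hrd", "cna", "ggi", "stat1",
             "lymphocyte_density", "dysfunction", "exclusion", "grade",
             "er_negative", "node_negative", "tumour_size", "tp53",
             "pik3ca", "apobec", "hla_loh")))
}
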