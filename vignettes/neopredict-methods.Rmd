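---
title: "Methods: multi-omic response features and the ensemble pCR predictor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omic response features and the ensemble pCR predictor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`neopredict` implements an end-to-end analysis of pre-treatment breast-tumour
multi-omic profiles against neoadjuvant therapy response: derivation of DNA,
RNA and digital-pathology features; association statistics against the
ordinal residual cancer burden (RCB) scale; and a seed-averaged ensemble
classifier of pathological complete response (pCR). Because the motivating
cohort data are controlled-access, the package ships a fully synthetic
multi-omic generator with known ground truth, and every stage is tested
against that ground truth. This vignette records the models, the tunable
parameters and the design decisions.

# DNA features

**Cancer cell fraction and clonality.** For a mutation with variant allele
fraction $VAF$, tumour purity $p$, germline copy number $CN_{normal}$ and
total tumour copy number $CN_{tumour}$,
$$\mathrm{CCF} = \frac{VAF}{p}\left((1-p)\,CN_{normal} + p\,CN_{tumour}\right).$$
Point estimates above 1 are reported unclipped; they arise from sampling
noise and from mutation multiplicity, which this estimator deliberately does
not model (a documented limitation — multiplicity would require a second
latent variable the input tables do not constrain). The binomial confidence
interval on $VAF$ uses the Wilson score interval at 95% (the default of the
binconf-style tools in this field; the method behind the published "binomial
CI" is not otherwise specified), mapped through the same multiplier as the
point estimate. A mutation is *clonal* iff its CCF interval contains 1. Read
verbatim, this rule classifies an interval lying entirely **above** 1 as
subclonal; the intent is ambiguous, so the rule is implemented verbatim and
such calls are flagged in a `ci_above_one` column so users can audit them.

**Mutation burden** is the somatic count divided by the 45.54 Mb sequenced
exome footprint.

**Signature exposures.** Trinucleotide catalogues (96 classes, standard
pyrimidine-centred order) from tumours with more than 10 mutations are fit
by non-negative least squares against a reference signature matrix; weights
below 0.06 (the cited decomposition tool's default discard threshold) are
zeroed and the rest renormalized. Exposures are reported as
$\log_2((w_s + c)/(w_1 + c))$ against the clock-like signature 1 with
pseudo-count $c = 0.01$ — small relative to the 0.06 threshold, and keeping
the ratio finite when the signature-1 weight is zero. The non-clock fraction
is $1 - (w_1 + w_5)$. No third-party reference matrix is bundled: the
package generates a *synthetic* labelled 96×13 reference
(`synthetic_signature_matrix()`), and real matrices load from TSV.

**HRD scars.** The published score delegates its component definitions to
the scar-scoring literature, so they are fixed here explicitly: LOH = number
of segments with minor copy 0, major copy > 0, longer than 15 Mb and not
spanning the whole chromosome; TAI = number of allelically imbalanced
segments touching a telomere without crossing the centromere; LST = number
of breakpoints whose flanking segments are each ≥ 10 Mb and separated by
< 3 Mb, computed after removing segments < 3 Mb and merging identical
neighbours (so every counted breakpoint is a genuine state transition). The
total is the sum. A "touching" tolerance of 1 kb absorbs coordinate
round-off.

**Copy-number altered fraction** is the length-weighted fraction of covered
autosomal genome whose total copy number differs from the rounded ploidy.
An alternative reading ("different from 2" regardless of ploidy) exists;
the ploidy-relative reading was chosen because the segment tables carry
ploidy and the feature otherwise conflates whole-genome doubling with
instability. At the default ploidy of 2 the two readings coincide.

**HLA LOH and neoantigens.** An HLA allele is lost iff its copy number is
below 0.5 *and* the loss is statistically significant; the significance
level is set to 0.05 (the source text says only "statistically
significant"). Candidate neoepitopes of length 8–11 are retained iff the
mutant binding affinity is < 500 nM (strict), stronger than the wild-type
peptide, and the source gene exceeds 1 TPM.

# RNA features

Counts are normalized by TMM (30% M-trim, 5% A-trim, upper-quartile
reference — delegated to edgeR, the tool the original analysis used, and
cross-checked in the tests against an independent step-by-step oracle), then
converted to FPKM with the effective library sizes and rescaled per sample
to one million (TPM). This TMM→FPKM→TPM chain is unusual — TPM directly from
counts is more common — but it is implemented as described because the
normalized library sizes change the inter-sample scaling.

Single-sample enrichment uses the ssGSEA form: per-sample gene ranks, a
weighted running-sum difference between in-set and out-of-set empirical
distributions with weight exponent 0.25, integrated over the list and
normalized by the score range across samples. The original analysis used a
GSVA-package call without specifying the per-signature method; ssGSEA was
fixed as the single-sample method here because it is the variant defined for
individual samples without distributional assumptions across the cohort.
Scores are rank-based, hence invariant to any strictly increasing per-sample
transform (tested). "High" scores are those strictly above the cohort mean.

Metagenes: the cytolytic score is the geometric mean of GZMA and PRF1 TPM
with the stated 0.01 offset; marker-panel scores (e.g. CD8, mast cells) are
means of $\log_2(TPM + 0.01)$; the taxane response metagene is the geometric
mean of BUB1B, CDK1, AURKB and TTK minus that of UGCG and CERT1.
Immunophenotype classes average per-gene z-scores across samples;
zero-variance genes contribute 0 with a warning. The dysfunction/exclusion
input contract is $\log_2(TPM+1)$ centred by the per-sample mean ("average
log2 expression of all genes" could also mean a global or per-gene mean;
per-sample centring was chosen because the downstream scorer compares genes
within a sample, and the centring property is what the tests pin down).
The dysfunction and exclusion scores themselves are pluggable inputs.

Gene identity is by symbol; set members missing from the matrix are dropped
with a warning when at least half the set maps, and error otherwise.

# Digital pathology

For each cell of a target class, density is
$\Sigma_N = N/(\pi d_N^2)$ (pixel$^{-2}$) with $d_N$ the distance to the
$N$th nearest neighbour within the density-defining population (the same
class by default), $N = 50$. The slide-level summary statistic is not named
in the source; the **median** of per-cell densities is the default (robust
to clustering) and the mean is also emitted. Stability is checked over
$N \in \{40, 45, 50, 55, 60\}$. No edge correction is applied (none was
applied originally); densities near window boundaries are therefore biased
upward slightly, which the homogeneous-Poisson recovery test bounds at ~10%
for $\lambda \cdot \text{area} \ge 2000$. Duplicate coordinates are jittered
by machine epsilon with a warning.

# Association statistics

Univariable logistic regression reports $e^{\hat\beta}$ with Wald 95%
intervals (profile-likelihood intervals are the plausible alternative; Wald
was chosen for exact correspondence with the odds-ratio scale and is noted
as such). Complete separation is flagged and excluded from FDR by default.
Ordinal trends use the proportional-odds model over
pCR > RCB-I > RCB-II > RCB-III via `MASS::polr` (the original tool), with
likelihood-ratio p-values against the intercept-only model; the two-class
degenerate case collapses to binary logistic regression (tested to 1e-6).
Rank-sum comparisons use pCR as the comparator, exact enumeration for
combined n ≤ 20 and the continuity-corrected normal approximation
otherwise. FDR is Benjamini–Hochberg.

# The predictor

Each predictor is a four-step pipeline: (1) collinearity reduction — greedy
pass over features sorted by decreasing $|r|$ with the outcome (ties by
name), keeping a feature iff its $|r|$ with every kept feature is ≤ 0.8;
(2) top-$k$ selection by one-way ANOVA F; (3) z-scaling; (4) three
classifiers whose probabilities are averaged: elastic-net logistic
regression ($C \in [10^{-3}, 10^3]$ log-uniform, L1 ratio $\in [0.1, 1]$;
glmnet with $\lambda = 1/(nC)$), an SVM (radial/sigmoid/linear kernel,
$\gamma \in [10^{-9}, 10^{-2}]$ log-uniform, $C \in [10^{-3}, 10^3]$) and a
random forest (5–100 trees, 5–70% feature fraction, minimum split 2–15).
$k$ is drawn jointly with the classifier hyperparameters (whether it was
tuned jointly originally is unstated; joint tuning is the natural reading of
a single randomized search). SVM margins become probabilities through a
Platt sigmoid fitted on training decision values — the original averaging of
margin scores with probabilities is unspecified, and an in-training sigmoid
keeps the fit deterministic under a fixed seed.

Hyperparameters are tuned by randomized search scored by mean AUC over
stratified five-fold cross-validation (stratification guarantees both
classes per fold at 26% prevalence and n ≈ 160; whether the original folds
were stratified is unknown). The search is repeated with five
cross-validation seeds; each tuned predictor is refit on the full training
cohort, and the model score is the mean of the five predictor scores. The
default search length is 100 draws (the reference configuration used 1000;
the package parameter `n_iter` restores it).

Six nested models are trained on cumulative modality subsets: clinical;
+DNA; +RNA; +DNA+RNA; +digital pathology; +treatment. The fully integrated
configuration has exactly the 34 features of the versioned definition file
(`inst/extdata/feature_definitions.tsv`), validated at assembly time.

Evaluation reports the empirical AUC (mid-rank concordance), its SD over 100
test-set bootstrap replicas, a DeLong 95% interval (own implementation,
cross-checked against pROC in the tests), and precision-recall with average
precision. Drop-one importance refits each pipeline without each feature and
reports $z_i = |\Delta_i|/\sigma(\Delta)$ per algorithm and averaged, with
signed $z_i = -\Delta_i/\sigma(\Delta)$ so value-adding features are
negative; the AUC is measured on the full training cohort after refit (where
it was measured originally is unstated; a CV-based variant would be slower
and noisier at this cohort size). The clinical-impact projection takes the
highest threshold admitting at most 0 or 2 false negatives, and rescales the
confusion matrix to 100 patients by largest-remainder rounding; threshold
ties resolve toward the lower threshold (fewer false negatives).

# The synthetic generator

The generator is a proportional-odds generative model: independent
standard-normal patient traits $t_k$ (mutation burden, subclonality, HRD,
copy-number load, proliferation, immune infiltration, dysfunction,
exclusion, clinical axes, driver flags, HLA LOH) combine with signed weights
$\beta_k$ into a latent response
$L = \sqrt{1-\sigma^2}\,\beta^\top t/\lVert\beta\rVert + \varepsilon$,
$\varepsilon \sim N(0, \sigma)$, binned by fixed cutpoints into the four
RCB classes. Defaults encode the reported effect directions (higher
TMB/HRD/CNA/proliferation/immune density toward pCR; subclonality,
dysfunction, exclusion and HLA LOH toward residual disease). Chosen study
conditions, fixed once: cohort sizes 200 + 75 mirroring the training /
external-validation proportions at desk scale; cutpoints at the 18/40/16/26%
class mix observed clinically; latent noise $\sigma = 0.3$, giving a strong
planted multi-omic signal (held-out AUC ≈ 0.9 for the integrated model)
while clinical covariates alone carry only a modest share of it; purity
0.2–0.9; depth 160×; ~64 mutations per tumour (≈ 1.4/Mb); 1000 genes
(enough for every scored block plus a large out-of-set background, small
enough for fast cohort replicates); 1500×1500 px cell windows with a few
hundred lymphocytes per slide.

Each modality is generated *through the quantity its extractor estimates*:
read counts are binomial around the inverted CCF formula; segments are a
balanced background with planted LOH/TAI/LST scars and whole-chromosome
gains; trinucleotide contexts are drawn from trait-weighted mixtures of the
synthetic reference signatures; expression is log-normal-Poisson with
trait-shifted gene blocks; cells are homogeneous spatial Poisson; neoepitope
candidates carry log-normal affinities with the planted pass count recorded.
Determinism: one master seed, per-table substreams at fixed offsets.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: linkage between traits (real proliferation and
immune axes are correlated), intratumour spatial structure of cells
(clustered, not Poisson), signature flat-field noise, batch effects in
expression, and measurement artefacts in segmentation. Results on this
generator validate the *machinery* (formulas, rules, pipeline order, absence
of leakage) and the qualitative claims (integration beats clinical-only;
monotone RCB trend), not clinical performance.

# Numerical choices and degenerate inputs

Zero-variance features are dropped (filters) or z-set to 0 (immuno classes)
with warnings; a patient with no classifiable mutation gets a missing, not
zero, subclonality; tumours with ≤ 10 mutations get missing signature
exposures; slide summaries with fewer than $N+1$ target cells are missing.
Missing values surviving feature assembly are imputed with the cohort median
with a warning, so the matrix entering the predictor is complete. glmnet
single-feature fits are padded with a zero column. Random-forest
`nodesize` is mapped from the minimum-samples-per-split bound as
$\lceil s/2 \rceil$. Test problem sizes (replicate counts, search lengths)
are the package's desk-scale defaults; `n_iter` and the seed count scale
them back up.

# Known limitations

Mutation multiplicity is not modelled in the CCF; the clonality rule flags
rather than resolves intervals above 1; no edge correction in densities;
the synthetic signature reference is not COSMIC; TIDE-style dysfunction and
exclusion scores are inputs, not re-implemented; external microarray
validation cohorts are out of scope.
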