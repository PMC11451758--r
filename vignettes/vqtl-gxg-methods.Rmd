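---
title: "Variance QTLs and gene-gene interactions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance QTLs and gene-gene interactions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vqtlgxg)
```

## The scientific problem

Gene-gene (GxG) interactions — epistasis — are hard to find by brute force:
testing all SNP pairs in a biobank squanders power on multiplicity. A more
tractable route prioritizes *variance quantitative trait loci* (vQTLs):
variants associated with the **variance** of a trait rather than its mean.
Under an interaction, the effect of one variant depends on the genotype at
another locus, so the trait variance at the first locus differs across its
genotype groups even when its mean effect is small or absent. vQTLs are
therefore enriched for involvement in GxG and gene-environment interactions,
and a genome-wide interaction scan seeded at a vQTL needs only one scan's
worth of multiplicity.

This package implements that strategy end to end on synthetic cohorts that
emulate the statistical structure of biobank blood-trait data: two vQTL
discovery routes (a genome-wide variance scan and a candidate-gene
dispersion-model scan), SNP-by-SNP interaction models for quantitative
traits and binary disease outcomes, joint models that disambiguate apparent
cis epistasis driven by linkage disequilibrium (LD), stratified effect
displays, internal LD estimation, and analytic power for the interaction
test.

## Phenotype preparation

Quantitative traits are rank inverse normal transformed (RINT),

$$y^{*}_i = \Phi^{-1}\!\left(\frac{r_i - 3/8}{n + 1/4}\right),$$

with mid-ranks for ties (`rint()`). The Blom offset 3/8 is the standard
GWAS convention; the transform is invariant to any strictly monotone
rescaling of the raw trait, which matters for lab assays with arbitrary
units. The *variance phenotype* is the element-wise square of the OLS
residual of the RINT trait after covariate adjustment
(`squared_residual_phenotype()`): a variant whose genotype predicts this
phenotype predicts the trait's residual variance.

Two covariate conventions coexist in biobank practice and both are
supported: the association-model set (age, age$^2$, sex, first 10 principal
components) and the residualization set for the variance phenotype (age,
age$^2$, sex, first 5 PCs). Neither is privileged; `scale_test()` takes both
explicitly, and the pipeline defaults follow the convention of each stage.
Because the residual is already orthogonal to the residualization
covariates, re-including them in the variance-stage association model is
harmless; a flag (`covariates_in_variance_scan`) disables it.

Electronic-health-record labs are aggregated per individual as the median of
repeated values after discarding measurements more than 3-fold above the
upper limit of normal (`aggregate_labs()`), since hospital-based cohorts
over-represent acute illness.

## The Scale test and vQTL calling

`scale_test()` runs two per-variant OLS association scans with identical
variant filtering: the RINT trait (mean effects) and the squared residual
(variance effects). Each fit is `phenotype ~ intercept + dosage +
covariates` with a Wald test on the dosage coefficient against the
$t_{n-k}$ reference. A variant is called a vQTL (`call_vqtls()`) when

$$P_{\mathrm{variance}} < 5\times10^{-8} \quad\text{and}\quad
  P_{\mathrm{mean}} > 5\times10^{-8},$$

i.e. a genome-wide-significant variance association *without* a significant
mean effect. Default scan filters are minor allele frequency $\ge$ 0.001
and missing-call rate $\le$ 0.1; candidate-gene analyses use MAF > 10%
(`bonferroni_threshold(m)` = 0.05/m over the variants tested in the gene).

The scans are fixed-effects OLS with PC covariates. Biobank analyses
typically use mixed models to absorb relatedness and fine structure; the
synthetic cohorts here are unrelated by construction, so the fixed-effects
fit preserves the scientific content (which phenotype is regressed on what)
at a fraction of the cost. This is a deliberate simplification and the main
caveat when transferring conclusions to real, structured cohorts.

## The double generalized linear model

For candidate genes, `fit_dglm()` estimates mean and dispersion effects
jointly. The mean submodel is Gaussian; the dispersion submodel is a gamma
GLM with log link,

$$\log \phi_i = \mathbf{z}_i^\top \gamma,$$

whose response is the squared mean-model residual and whose coefficient on
the focal genotype, $\beta_{\mathrm{dispersion}}$, is the per-allele
log-multiplicative change in residual variance. Fitting alternates (a) a
weighted least-squares mean fit with weights $1/\phi_i$ and (b) the gamma
dispersion fit with leverage-adjusted prior weights $(1-h_i)/2$, until the
extended quasi-likelihood changes by less than $10^{-8}$ (relative), at most
50 alternations. The focal genotype appears in *both* designs so that a pure
mean effect cannot masquerade as dispersion.

Numerical choices worth stating:

* The leverage adjustment $(1-h_i)/2$ is the REML-flavoured scheme; a plain
  maximum-likelihood variant (uniform weights $1/2$) is available via
  `leverage_adjust = FALSE`. With leverage weights the alternation target is
  the leverage-weighted quasi-likelihood, so the *unweighted* extended
  quasi-likelihood trace is guaranteed monotone only in the ML variant; in
  practice both converge in a handful of iterations.
* Dispersion-coefficient covariance is $(Z^\top W Z)^{-1}$ with
  $W = \mathrm{diag}\{(1-h_i)/2\}$ — the gamma dispersion of 2 folded into
  the $(1-h)$ weights. In the homoscedastic intercept-only case this
  reproduces the exact $\chi^2_1$ information
  $\mathrm{Var}(\widehat{\log\phi}) = 2/(n-k)$, and the null distribution of
  dispersion p-values is uniform in simulation (the test suite checks both).
* Exact zero squared residuals (probability zero for continuous data) are
  floored at the smallest positive double before the gamma fit.
* Non-convergence is reported as a flag, never an exception; rank-deficient
  designs are errors.

The generator's variance effects are log-linear per allele
(`trait_spec(gamma_var = ...)`), which makes this dispersion submodel
correctly specified — parameter recovery is then a clean end-to-end check
rather than an approximation study.

## Interaction models

`interaction_test()` fits

$$y \sim \beta_0 + \beta_1 g_1 + \beta_2 g_2 + \beta_{\mathrm{int}}\,
  g_1 g_2 + \text{covariates}$$

by OLS for quantitative traits and by maximum-likelihood logistic
regression for binary outcomes (so $\beta_{\mathrm{int}}$ is an interaction
log odds ratio; this is the natural scale for prevalent-disease models and
is how binary interaction coefficients are reported here). All 95%
confidence intervals are Wald, $\hat\beta \pm 1.96\,\mathrm{SE}$ —
matching the stratified-display convention — and no profile-likelihood
intervals are computed. Logistic fits run IRLS (`stats::glm.fit`) with up to
100 iterations at tolerance $10^{-10}$; complete separation is flagged when
any coefficient exceeds 20 in absolute value.

`interaction_scan()` tests a focal variant (typically a called vQTL)
against every other passing variant, reporting raw p-values plus a
Bonferroni column; no default filtering is applied because interaction
follow-up is usually on ranks. `joint_interaction_test()` puts two product
terms in one model,

$$y \sim g_f + g_a + g_b + g_f g_a + g_f g_b + \text{covariates},$$

the device that separates a true interaction partner from a variant that
merely tags it through LD (cis epistasis): in simulations where $g_a$ is an
LD proxy (D' $\approx$ 0.95) of the true partner $g_b$, the joint model
retains the $g_f g_b$ term and nulls $g_f g_a$.

`pathogenic_allele_count()` sums dosages across two pathogenic sites in the
same gene — compound heterozygotes carry two pathogenic alleles — and pools
counts $\ge 2$ into group "2" for stratified displays (the raw sum is
retained). `stratified_trait_means()` and `stratified_odds_ratios()`
reproduce the figure-style summaries: per genotype-combination means with
$\mathrm{SE} = s/\sqrt{n}$, and 2$\times$2 odds ratios against a reference
combination with log-scale Wald intervals
($\mathrm{SE}_{\log\mathrm{OR}} = \sqrt{1/a + 1/b + 1/c + 1/d}$, 0.5 added
to all four cells when any cell is empty, flagged).

## Linkage disequilibrium

`ld_from_haplotypes()` computes $D = p_{AB} - p_A p_B$, $D' = D/D_{\max}$
with the sign-dependent bound, and $R^2 = D^2 / (p_A q_A p_B q_B)$ from
phased counts. For unphased genotypes, `em_haplotype_freqs()` runs the
classical two-locus EM over the double-heterozygote phase ambiguity,
initialized at linkage equilibrium (the two-locus likelihood is unimodal in
practice, so this avoids seed dependence), iterating to $10^{-10}$ on
frequencies with a non-decreasing observed-data log-likelihood. The "A"/"B"
orientation is the alternate allele at each locus; $D$'s sign is reported
under that orientation. This internal estimator replaces reference-panel
lookups, which are deliberately out of scope; panel-based LD values from
external populations are not reproducible here.

## Power analysis

The single-df Wald test of $\beta_{\mathrm{int}}$ has non-centrality

$$\lambda = \frac{n\,\beta_{\mathrm{int}}^2\,
  \mathrm{Var}(\text{interaction term})}{\sigma_y^2},$$

and power is the upper tail of $\chi^2_1(\lambda)$ beyond the central
upper-$\alpha$ quantile. Two conventions for the interaction-term variance
are implemented side by side because the choice is consequential and the
convention used in biobank power paragraphs is typically left implicit:

* **product** — $\mathrm{Var}(G_1 G_2) = E[G_1^2]E[G_2^2] -
  (E[G_1]E[G_2])^2$ under HWE and inter-locus independence: the variance of
  the mean-centered product, *not* residualized for main effects. This mode
  reproduces the conventional biobank-scale claims (e.g. >80% power at
  MAF 0.10 for a 0.05-SD interaction at $n = 400{,}000$,
  $\alpha = 5\times10^{-8}$) and is the default for reproduction.
* **adjusted** — $\mathrm{Var}(G_1)\mathrm{Var}(G_2) = 4 p_1 q_1 p_2 q_2$:
  the main-effect-residualized variance, which is the asymptotically correct
  non-centrality for the Wald test when main effects are in the fitted
  model. This is the mode that `simulated_power()` — the Monte-Carlo oracle
  fitting the full 4-parameter regression — matches within sampling error.

Product-mode variance always dominates adjusted-mode variance, so
product-mode power is an upper bound on the achievable Wald power at the
same spec. Main effects (default 0.01 SD per allele) enter the simulation
oracle but are omitted from the analytic non-centrality, since the fitted
main-effect terms absorb them.

## The synthetic-cohort generator

`simulate_genotypes()` draws unlinked HWE genotypes (dosage ~
Binomial(2, p)); `simulate_ld_pair()` draws phased haplotypes from the
four-class distribution implied by ($p_A$, $p_B$, $D'$), with genotypes as
the sum of two haplotypes, so EM estimates can be validated against phased
truth. `simulate_trait()` composes per-allele mean effects, pairwise
interaction effects, covariate effects, and Gaussian noise whose log
variance is linear in genotype; `simulate_binary()` is the logistic
counterpart (a logistic rather than liability-threshold model, matching the
logistic interaction models fitted downstream). Covariates are age ~
Uniform(40, 70) years, sex ~ Bernoulli(0.5), PCs iid standard normal —
shape-compatible with biobank covariate lists without modeling population
structure. All randomness flows through one explicit integer seed per call
with the caller's RNG state restored; identical seeds give bit-identical
output.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: realistic LD beyond one target-D' pair,
relatedness and population structure, imputation dosage uncertainty,
ancestry-differentiated allele frequencies (a known source of spurious
vQTLs), and case-control ascertainment.

## The demonstration cohort

`demo_config()` plants one discoverable signal and is sized analytically,
not by trial: cohort $n = 20{,}000$; focal variant `vq1` (frequency 0.30)
interacting with partner `par1` (frequency 0.25) at
$\beta_{\mathrm{int}} = 0.5$ SD; focal main effect
$-2 \times 0.25 \times 0.5 = -0.25$, exactly cancelling the marginal mean
effect induced by the interaction ($\beta_{\mathrm{int}} \cdot E[g_2]$ per
focal allele). The cancellation mirrors the suppressing-interaction pattern
seen in real blood-trait pairs and makes the focal variant a clean vQTL:
expected variance-scan Wald statistic $\approx$ 9–10 against the 5.45
needed at $5\times10^{-8}$, and interaction Wald statistic $\approx$ 28.
The focal variant sits inside the single candidate region so the
dispersion-scan route flags the same signal. Eight background variants
share the region; 50 more are unlinked genome background.

## Validation problem sizes and finite-sample behaviour

The test suite validates at sizes chosen to balance statistical resolution
against desk-scale runtime: null calibration of the variance scan on 2000
variants at $n = 50{,}000$; dispersion-effect recovery at $n = 100{,}000$
with 500 null replicates for p-value uniformity; interaction recovery at
$n = 200{,}000$ with 500 null replicates for size; 1000-replicate
power cross-validation at an interior operating point
(adjusted-mode power $\approx$ 0.5 at $n = 2000$); 25 seeded end-to-end
pipeline replicates.

One finite-sample property deserves emphasis. The genomic-control
$\lambda$ of a scan — median association $\chi^2$ over its null median — is
itself an estimate. From a panel of $m$ variants its sampling SE is
$\approx 1.25\,/(f(m_{0.5})\sqrt{m}\cdot m_{0.5}/0.455)$, about 0.05 at
$m = 2000$; and when all variants are scanned against one shared
squared-residual phenotype (excess kurtosis $\approx$ 12), the realized
$\lambda$ varies a further few percent with the phenotype draw. Single
small-panel $\lambda$ values of 0.88–1.13 are therefore compatible with a
perfectly calibrated scan, as direct replication confirms; the conventional
[0.95, 1.05] interpretation band is meaningful only when $\lambda$ is
estimated from very large variant panels. The scan's *systematic*
calibration is better assessed by the type-I error rate at nominal
$\alpha$, which is stable at 0.05 across replicates here.

## Interfaces and the pipeline

`run_pipeline()` orchestrates the whole analysis from one validated config
(construct with `pipeline_config()`, read from YAML with
`read_pipeline_config()`): simulate or read genotypes (minimal GT-only
VCF 4.2 through vcfR, or a dosage TSV; 1-based coordinates throughout;
multiallelic records skipped and counted), prepare phenotypes, Scale test,
vQTL calls, candidate-region dispersion scans, interaction scans for each
focal variant, stratified means and EM LD for the top pair, and a power
table. Every stage writes a self-describing TSV (stage name and config hash
in header comments) and a JSON run report with per-stage counts and timings;
runs are byte-identical given the seed. Stage failures halt with the stage
name and a machine-readable error code, retaining partial outputs.

The package functions are the primary interface; a thin Rscript wrapper
(`inst/scripts/vqtlgxg-pipeline.R`) exposes the same config-driven run for
shell use. A single config-driven entry point was chosen over per-analysis
subcommands because each subcommand would be a one-line call into the
corresponding exported function.

## Known limitations

Fixed-effects association only (no mixed models); no LD clumping,
conditional analysis, or meta-analysis; no Firth penalization for separated
logistic fits (separation is flagged instead); power analysis covers the
quantitative-trait Wald test at a single $\alpha$, not binary outcomes or
LD between the interacting loci; the VCF dialect is GT-only. The
dispersion-response convention (squared residuals with leverage-adjusted
weights) is one of several in circulation; the unadjusted variant is
provided for comparison, and both agree in sign and closely in magnitude in
all simulations here.
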