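---
title: "Methods: predicted-expression association in related cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicted-expression association in related cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Transcriptome-wide association (TWAS / PrediXcan-style) tests whether the
*genetically regulated* component of a gene's expression is associated with a
trait. It proceeds in two stages: train per-gene models that predict
expression from nearby (cis) genotypes in a reference cohort with both
genotypes and expression, then impute predicted expression
$T_g = \sum_k \omega_{kg} X_k$ into a genotyped target cohort and regress the
trait on it, gene by gene.

In outbred model-organism populations — the motivating case is heterogeneous
stock (HS) rats, descended from eight inbred founders and maintained with
substantial familial relatedness — the target cohort violates the
independence assumption of ordinary least squares. Both the trait and the
predicted expression are heritable, so relatives share both, residuals are
correlated within families, and the naive per-gene regression is strongly
anticonservative. This package implements the association stage as a mixed
model solved by whitening, together with the training stage, a
synthetic-cohort generator, the type-I-error calibration study that
validates the correction, multi-tissue p-value combination, and
cross-species enrichment.

## Model and whitening

The per-gene association model is

$$Y = T b + u + \epsilon,\qquad
\mathrm{cov}(u + \epsilon) = \sigma^2\left(h^2\,\mathrm{GRM} + (1-h^2) I\right)
 = \sigma^2 \Gamma,$$

where $u$ is a polygenic random effect whose covariance is the genetic
relatedness matrix and $\epsilon$ is iid noise. The GRM is the GCTA
estimator,

$$\mathrm{GRM}_{ij} = \frac{1}{M} \sum_{k=1}^{M}
\frac{(X_{ik} - 2p_k)(X_{jk} - 2p_k)}{2 p_k (1 - p_k)},$$

with $p_k$ the sample frequency of the effect allele and $M$ the number of
polymorphic variants retained (monomorphic variants are excluded from both
the sum and $M$). Allele frequencies are computed from the loaded sample —
the self-contained choice, matching GCTA's default when no external
frequencies are given.

Premultiplying the model by $\Gamma^{-1/2}$ decorrelates the errors:
$\tilde Y = \Gamma^{-1/2} Y$, $\tilde T = \Gamma^{-1/2} T$, and
$\mathrm{cov}(\Gamma^{-1/2}(u + \epsilon)) = \sigma^2 I$. Each gene is then
tested by OLS of $\tilde Y$ on $[\,\tilde\imath,\ \tilde T_g\,]$, where
$\tilde\imath = \Gamma^{-1/2}\mathbf{1}$. The transformed model is
sometimes written without an intercept, but $\Gamma^{-1/2}\mathbf{1}$ is not
constant, and leaving the mean unmodeled inflates the test — so the
transformed intercept column is always included. The test statistic is
$t = \hat b/\mathrm{se}(\hat b)$ on $n - 2$ degrees of freedom, two-sided.

Numerical choices: $\Gamma^{-1/2}$ is the *symmetric* inverse square root
from the eigendecomposition of the GRM (deterministic and self-adjoint;
any square root would whiten). GRM eigenvalues are clamped below at zero —
the GRM is PSD by construction and negative eigenvalues are floating-point
noise. A transformed eigenvalue $h^2\lambda_i + 1 - h^2$ at or below
`1e-10` is treated as a singular $\Gamma$ and raises an error.

$h^2$ and $\sigma^2$ are properties of the trait under the null,
independent of any gene, so they are estimated **once** per trait
(`estimate_h2()`) and reused across genes. The estimator is profile maximum
likelihood: one eigendecomposition rotates the model to independent
coordinates; given $h^2$, the GLS intercept and $\sigma^2$ are closed-form;
the 1-D profile over $h^2 \in [0,1]$ is minimized with `optimize()`
(tolerance `1e-6`) and compared against both boundary values. When the GRM
has no eigenvalue spread (e.g. an identity GRM) the likelihood is flat in
$h^2$; the fit returns $h^2 = 0$ flagged non-identifiable. The same
estimator applied to a cis-window GRM serves as the per-gene cis
variance-component estimate.

By default the GRM uses **all genome-wide variants, unpruned, all
chromosomes**. Leave-one-chromosome-out and LD-pruned GRMs are explicit
opt-ins (`exclude_chrom`, `variant_subset = ld_prune(...)`) precisely
because the calibration experiments show they under-correct: a polygenic
null carries signal from every variant, and a GRM that omits the tested
gene's chromosome, or collapses high-LD blocks, no longer accounts for the
part of that signal the cis predictors track.

## Training stage

Expression preprocessing mirrors the standard eQTL pipeline: per-gene
rank-based inverse-normal transform with the Blom offset $c = 3/8$ (the
common default; no offset is canonical) and average ranks for ties;
a Shapiro–Wilk filter (default $\alpha = 0.05$, configurable — the test is
standard, the threshold is a package choice) that removes genes whose
transformed values are still non-normal, which happens with excessive ties
(many zero TPMs); then residualization on declared covariates plus the top
`n_pcs = 7` expression principal components. Phenotype covariates are
screened marginally and regressed out only if significant (p < 0.05) *and*
explaining more than 2% of trait variance; marginal (rather than joint)
screening is chosen for determinism.

Per-gene models are elastic net at mixing parameter $\alpha = 0.5$ on the
cis window — 1 Mb upstream of the transcription start to 1 Mb downstream of
the transcription end, 1-based inclusive, clipped at 1, strand ignored.
The penalty is chosen by glmnet's internal 10-fold CV; reported performance
is the out-of-fold Pearson correlation over an *outer* 10-fold CV with
seeded folds shared across $\alpha$ values. The nested design gives an
honest `cv_R` (slightly conservative relative to non-nested reporting);
final weights come from a fit on all samples at the selected penalty, on
the dosage scale (the predictdb convention). Zero-variance predictions are
recorded as `cv_R = cv_R2 = 0`, so they fail the performance filter
(`cv_R2 > 0.01` and `cv_R >= 0`) deterministically. `mixing_sweep()`
evaluates a grid of $\alpha$ (the conventional 11 steps of 0.1): sparse cis
architectures lose performance toward the ridge end; infinitesimal ones do
not — the package's tests reproduce both behaviours on simulated
architectures.

Imputation into the target cohort matches model variants by id and aligns
alleles: swapped ref/eff dosages are flipped ($2 - X$), strand-ambiguous
(A/T, C/G) variants are kept as-is with a warning, irreconcilable or absent
variants contribute zero and are tallied in a coverage report.

## The synthetic cohort

`simulate_cohort()` provides all test data without downloads. It emulates
the features of an HS-rat-like target cohort that drive the statistical
problem:

- **Relatedness**: families of full sibs produced by gene-dropping two
  recombined gametes from two founders per family (Haldane crossovers at
  1 cM/Mb). Sibships give GRM off-diagonals near 0.5 within families and
  near 0 between — the block structure the whitening must remove.
- **LD**: founder haplotypes from a thresholded AR(1) Gaussian copula,
  which preserves marginal frequencies while giving tunable local LD
  (`ld_rho`, default 0.9; a per-chromosome vector lets one chromosome act
  as a dense, near-perfect-LD block). Allele frequencies themselves drift
  smoothly along the chromosome with the same parameter — linked variants
  share genealogy and hence similar frequencies, and without matched
  frequencies two binary variants cannot reach high r² at all.
- **Sparse cis architecture**: each gene has `n_causal_per_gene = 2` causal
  cis variants with normal effects and noise scaled so the cis component
  explains `h2_expr = 0.3` of expression variance — values a cis-eQTL study
  of a few hundred samples would call typical and that let most trained
  models pass the performance filter.

Defaults are n = 600 individuals in 100 families, 5 chromosomes × 150
variants over 30 Mb (so a ±1 Mb cis window holds ~10–20 variants), 340
genes, founder frequencies U(0.05, 0.95). What the generator does **not**
emulate: realistic recombination maps and allele-frequency spectra,
population structure beyond sibships, trans-eQTLs, expression count noise
(it emits residual-stage expression directly). Passing tests therefore show
the *statistical machinery* is correct under the stated model, not that any
particular biological dataset satisfies the model.

Null phenotypes are drawn as $Y = u + \epsilon$ in either of two equivalent
representations: $u = \sqrt{\sigma^2 h^2}\,\mathrm{GRM}^{1/2} z$ with iid
normal $z$, or the fully polygenic
$u = \sum_k X^{\mathrm{std}}_k \delta_k$ with
$\delta_k \sim N(0, \sigma^2 h^2 / M)$ on standardized dosages — the scaling
chosen so $\mathrm{cov}(u) = \sigma^2 h^2\,\mathrm{GRM}$ holds exactly
under the GCTA GRM definition, which is how the equivalence of the two
representations is verified empirically in the tests. $\sigma^2$ defaults
to 1: only the $h^2 : (1-h^2)$ ratio affects p-values.

## The calibration study

`calibration_study()` is the package's central experiment. Models are
trained on a family-disjoint half of the cohort (families are never split
across training and target sets); for each $h^2$ on the grid (default
$\{0.1, 0.2, 0.4, 0.6, 0.8\}$ — a 5-point grid spanning the conventional
0.1–0.8 range) and each replicate, a null phenotype is drawn, its $h^2$ is
re-estimated from the data (as a real analysis would), and both the
whitened and the naive association are run against the predicted
expression of every filtered gene. Pooled over genes and replicates, a
calibrated test has its fraction of p-values below $\alpha$ equal to
$\alpha$; the naive test's fraction at $\alpha = 0.05$ runs 3–4× too high
on the default cohort.

The shipped study sizes — 300 gene models × 30 replicates = 9,000 pooled
tests at $h^2 = 0.4$, n = 600 — keep the experiment at desk scale (a few
minutes end to end) while making the binomial uncertainty on the
false-positive rate small (±0.7 percentage points, 3 SD, at
$\alpha = 0.05$). The extreme tail ($\alpha = 10^{-6}$) is only measurable
with millions of pooled tests; at this scale the corresponding check is
that essentially no test lands below it.

## Multi-tissue combination and cross-species enrichment

Per-tissue p-values for a gene are combined with the Cauchy combination
(ACAT): $S = \sum_i w_i \tan((0.5 - p_i)\pi) / \sum_i w_i$, combined
$p = 1/2 - \arctan(S)/\pi$; equal weights by default. The transformation is
robust to unknown correlation between tissues. For $p_i < 10^{-15}$ the
tangent is replaced by its asymptote $w_i/(p_i \pi)$ for numerical
stability. Significance is declared by Bonferroni, $\alpha / n_\mathrm{tests}$;
the testing universe (all genes with at least one surviving tissue model,
or a narrower set) is deliberately a configuration value.

Cross-species enrichment maps orthologs (many-to-many collapsed to first
occurrence — deterministic, and unlike min-p policies not biased toward
significance), thresholds species a at its Bonferroni level and species b
at a nominal 0.05 by default (the b-side convention is not standardized;
both are arguments), and tests the 2×2 table with Fisher's exact test
(two-sided by default, one-sided available). The reported odds ratio is
the sample OR with a Haldane 0.5 correction on zero cells, alongside the
exact p.

## Degenerate inputs and tie-breaks

- Missing dosages are mean-imputed per variant at load; coordinates are
  1-based inclusive everywhere (VCF/GTF convention).
- Constant expression traits, constant phenotypes, and empty id
  intersections raise errors rather than propagating NaNs.
- A whitened predictor with zero variance yields `p = 1` with a flag, not
  an error, so genome-wide scans survive degenerate genes.
- LD pruning is greedy per chromosome in position order: within each
  window the later variant of any pair above the r² threshold is dropped,
  and the window advances by a fixed variant count — the `--indep-pairwise`
  convention.
- All stochastic functions take explicit seeds and restore the caller's
  RNG state; identical seeds give bit-identical output.

## Known limitations

- The h² profile likelihood is unimodal in practice but is optimized by a
  single bounded 1-D search; pathological multimodality would need a grid.
- The generator's two-founder families produce only full sibs — no
  half-sib or multi-generation structure.
- Summary-statistics-based association (no individual-level data) is out
  of scope, as are BSLMM-style sparse variance components, trans models,
  and q-value estimation beyond Bonferroni.
- The eigendecomposition is O(n³): practical to tens of thousands of
  individuals, not biobank scale.
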