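---
title: "Single-step and SNP-weighted genomic evaluation: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step and SNP-weighted genomic evaluation: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistical machinery it
implements: the repeatability animal model, the three relationship kernels
(pedigree, single-step, weighted single-step), the iterative SNP-weighting
scheme, the LR validation method, and the synthetic-data generator that
makes all of it testable without proprietary recording data. It also
records the numerical and design decisions that were genuinely open, and
what the passing tests do and do not establish.

## The repeatability animal model

Repeated records on the same cow (here: an early-lactation milk trait
measured in up to five parities, treated as repeated expressions of one
trait) are modelled as

$$ y = Xb + Z_a u + Z_p p + e, \qquad
   u \sim N(0, K\sigma^2_u),\;
   p \sim N(0, I\sigma^2_{pe}),\;
   e \sim N(0, I\sigma^2_e), $$

where $u$ is the additive genetic effect of every animal in the pedigree,
$p$ a per-animal permanent-environment effect shared by that animal's
records, and $K$ the relationship kernel. The genetic correlation between
records is assumed 1 (no random regression, no heterogeneous residual
variance — out of scope). Fixed effects follow dairy convention:
herd-year-season of calving as a factor, standardized days in milk with a
quadratic term, and standardized calving age with constant, linear and
quadratic regressions nested within parity.

Identifiability choices: treatment (drop-first-reference) coding per
factor, so solutions are unique and reproducible; estimable functions —
fitted values and EBV — are invariant to the reference level, and a test
asserts this. The "constant nested within parity" terms are parameterized
as intercept + parity contrasts, which spans the same column space.
DIM and calving age are z-scored **within the analyzed dataset**, so a
partial dataset is standardized on its own records; this matches the idea
that each evaluation run standardizes with what it can see. Columns that
are empty after nesting are dropped; a genuinely rank-deficient fixed
design is an error naming the offending columns rather than a silent
pseudo-inverse.

Variance components ($\sigma^2_u, \sigma^2_{pe}, \sigma^2_e$) are inputs.
REML estimation is deliberately out of scope: the machinery under test is
prediction, weighting and validation, and for simulated data the true
generating values are available and used.

## Relationship kernels

**Pedigree (ABLUP).** The sparse $A^{-1}$ is assembled directly by
Henderson's rules with inbreeding: each animal contributes $1/m_i$ to the
pattern, $m_i = 0.5 - 0.25(f_s + f_d)$ with $f = -1$ substituted for an
unknown parent, which folds the one- and zero-known-parent cases into one
expression. Inbreeding comes from the Meuwissen–Luo ancestor-tracing
recursion (compiled code; effectively linear memory). The dense tabular
method is kept as a second, independent path: tests require
$A^{-1}_{\text{Henderson}} \cdot A_{\text{tabular}} = I$ to $10^{-8}$ on
pedigrees up to 500 animals, and `inbreeding()` to equal
$\operatorname{diag}(A) - 1$ to $10^{-12}$. Unknown parents are unrelated
founders — a single implicit genetic group; unknown-parent groups and
metafounders are not supported.

**Genomic and single-step.** $G = \lambda Z D Z'$ with
$\lambda = 1/(2\sum_i p_i(1-p_i))$, $Z$ the dosage matrix centered by
$2p_i$, and $D$ the SNP weights (identity for plain ssGBLUP). Three
conventions worth stating:

* $p_i$ is the **observed frequency of the counted allele** among the
  genotyped animals, not folded to the minor allele. $p(1-p)$ is symmetric
  so $\lambda$ is identical either way, but centering requires the counted
  allele's frequency for each $Z$ column to sum to zero.
* Missing dosages are imputed to the column mean $2p_i$ before centering,
  contributing exactly zero to $Z$.
* Because every column of $Z$ sums to zero, the all-ones vector is in the
  null space of $G$: a raw observed-frequency $G$ is always singular.
  Invertibility comes from blending, $G^* = \alpha G + (1-\alpha)A_{22}$,
  with $\alpha = 0.95$ by default (standard single-step practice). An
  optional `tune_g()` rescales $G$ to the $A_{22}$ means first; it is off
  by default since the source analysis does not state such an adjustment.

$H^{-1} = A^{-1} + \begin{pmatrix}0&0\\0&G^{*-1}-A_{22}^{-1}\end{pmatrix}$
is built sparsely; a test checks it against the dense inverse of the
conditional-expectation $H$ on a toy. QC is a plain MAF filter (default
`maf_min = 0.01`) plus removal of monomorphic SNPs, with $p$, $N$,
$\lambda$ recomputed on the retained panel.

## The iterative SNP-weighting scheme

Starting from $D_{(1)} = I$ (so iteration 1 **is** ssGBLUP, and a test
requires bit-level equality with a stand-alone ssGBLUP run):

1. solve the model with the current $G^*_{(t)}$;
2. backsolve SNP effects
   $\hat u_{\text{snp}} = \lambda D_{(t)} Z' G^{*-1}_{(t)} \hat u_{\text{geno}}$;
3. nonlinear-A weights
   $d_i = CT^{\min(|\hat u_i|/SD(\hat u),\, c) - 2}$;
4. rescale so $\operatorname{trace}(D_{(t+1)}) = \operatorname{trace}(D_{(t)}) = N$;
5. rebuild $G^*$, $H^{-1}$, and repeat; the default runs 5 solves.

Parameters, defaults, and why:

* **CT** (dimensionless, $\ge 1$): departure from the normal-effects
  assumption; $CT = 1$ leaves all weights at 1 (a tested fixed point).
  Default 1.125; 1.05–2.0 is the range usually explored, larger values
  concentrating weight on SNPs with large backsolved effects.
* **sd_cap** $c = 5$: the standardized effect entering the exponent is
  capped, preventing a single SNP from exploding the weights at large CT
  (a known failure mode of nonlinear-A weighting); the cap's effect is
  tested directly.
* **n_iter = 5** solves. Accuracy typically peaks at the second iteration,
  after which weights over-concentrate; the per-iteration trace is kept so
  users can pick.
* $p_i$ and $\lambda$ are computed once at iteration 1 and held fixed:
  the weighting changes $D$, not the panel.
* $SD$ is the population (divisor $N$) standard deviation — at panel sizes
  of interest the $N$ vs $N-1$ distinction is far below the noise, but it
  is fixed for reproducibility.
* $G^*$ is re-blended with the same $\alpha$ at every iteration.

Trace preservation ($\sum_i d_i = N$ to $10^{-10}$ at every iteration,
across the CT grid) is asserted in the acceptance tests.

## LR validation

The partial dataset removes records with `record_year > cutoff`; pedigree
and genotypes are untouched. The validation population is the young
genotyped animals (born after a threshold year, optionally restricted to
females, optionally required to carry no partial-data records). Metrics
over the validation animals, with the sample ($n-1$) covariance
convention:

* accuracy $\widehat{acc} = \sqrt{\operatorname{cov}(\hat u_p, \hat u_w)
  / ((1-\bar f)\sigma^2_u)}$. The square root follows the LR method's
  definition; the typeset source formula omits the radical, which we treat
  as a typesetting loss — both the root and the raw ratio (`acc2`) are
  returned so either convention can be read off. A negative covariance is
  reported as 0 with a warning.
* bias $\mu_{w,p} = \overline{\hat u_p} - \overline{\hat u_w}$ (trait
  units; scales with the trait, a tested equivariance),
* dispersion $b_{w,p} = \operatorname{cov}(\hat u_w,\hat u_p)/
  \operatorname{var}(\hat u_p)$,
* slope $b_{p,w} = \operatorname{cov}(\hat u_p,\hat u_w)/
  \operatorname{var}(\hat u_w)$ (the partial/whole reliability ratio);
  $b_{w,p}\, b_{p,w} = r^2$ exactly, which is tested.

$\bar f$ is the mean inbreeding of the validation animals from the full
pedigree; $\sigma^2_u$ comes from configuration, with a switch for
partial- vs whole-dataset values when both are supplied.

**A caveat the tests surfaced and document.** The LR accuracy is designed
to compare a *given* evaluation model against itself with less data. When
two *different* kernels are compared (ssGBLUP vs weighted ssGBLUP), the
re-weighted kernel is shared by the partial and whole runs, which raises
$\operatorname{cov}(\hat u_p, \hat u_w)$ even when the ranking of animals
does not improve. On simulated *polygenic* traits (500 QTL) the
LR-accuracy gap between weighted and unweighted single-step sits slightly
above zero while the true-accuracy gap (correlation with simulated
breeding values) is centered on zero — the latter is asserted as a
property test. The same mechanism plausibly contributes to LR accuracy
rising monotonically with CT while bias worsens. Conclusions about
*weighting* drawn from LR accuracy alone should therefore be read
together with the bias and dispersion metrics.

## Solvers and numerics

Henderson's MME are assembled sparsely (`Matrix`), with variance ratios
$\lambda_a = \sigma^2_e/\sigma^2_u$ on the $K^{-1}$ block and
$\lambda_{pe} = \sigma^2_e/\sigma^2_{pe}$ on the permanent-environment
block (one level per animal *with records*). Systems up to 20,000
equations are solved by sparse LDL Cholesky; larger ones by
Jacobi-preconditioned conjugate gradients to a relative residual of
$10^{-8}$ (non-convergence is an error carrying the residual, never a
silent return). Direct and PCG paths are cross-checked to $10^{-6}$ on a
500-animal system; the pedigree path is checked against a dense GLS
oracle, and the identity-kernel MME against closed-form ridge regression.
Dense inversions ($G^*$, $A_{22}$) use Cholesky; a singular $G^*$ is an
error instructing the user to blend.

## The synthetic-data generator

`sim_config()` fixes everything under one integer seed (derived
sub-seeds stay far below $2^{31}$): a discrete-generation pedigree with
random sire–dam mating (sexes make selfing impossible), gene-dropped
unlinked biallelic SNPs with founder frequencies uniform on a configurable
range, a trait that is the dosage-weighted sum of a configurable number of
QTL rescaled so the founder TBV variance equals $\sigma^2_u$, per-animal
permanent-environment effects, and 1–3 records per cow with
herd-year-season, DIM and calving-age effects and record years that follow
the birth year (first calving at age two, one parity per year — typical of
dairy recording). Defaults emulate the motivating study's structure at
desk scale: heritability 0.30 and repeatability 0.50 on unit total
variance, trait mean 9.04 (the mmol/L scale of milk citrate),
herd-year-season variance 0.2, an oligogenic architecture (5 QTL with
equal magnitudes and random signs; gamma magnitudes optional), 30%
genotyped, and a record-year range supporting a partial/whole split.
Determinism is tested byte-for-byte through the plain-text writers.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: linkage and LD structure (loci are unlinked, so
"QTL detection" by weighting is easier than on a real genome where panel
SNPs tag causal loci imperfectly), selection and non-random mating,
heterogeneous herd sizes and seasonal calving patterns, genotyping that
targets elite animals, and the chemometric error of spectra-predicted
phenotypes. Directional conclusions (genomic > pedigree accuracy;
weighting helps oligogenic traits at iteration 2) transfer; absolute
metric values do not.

Problem sizes used by the test suite were chosen to keep the full run in a
few minutes on one core while leaving the directional effects well clear
of noise: module tests use a 330-animal fixture (60 founders, 4
generations, 200 SNPs, ~100 genotyped); directional validation uses 3,000
animals, 1,000 SNPs, 30% genotyped, 10 seeds; simulator calibration uses
5,000 animals with three records per cow.

## Known limitations

Single trait, single-kernel univariate model only; no REML; no
unknown-parent groups or metafounders; no APY or other large-scale $G$
approximations (genotyped sets are held dense); dense tabular $A$ limited
to 20,000 animals; the CLI genotype dialects cover BLUPF90-style and CSV
only. Weighting schemes other than nonlinear-A (windowed variance shares,
GWAS-informed weights) are out of scope.
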