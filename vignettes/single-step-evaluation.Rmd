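---
title: "Single-step genomic evaluation of days open: models, choices and limits"
author: "ssgblup authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step genomic evaluation of days open}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Days open (DO) — the interval from calving to the next successful
conception — is the workhorse fertility trait of dairy recording
schemes: easy to record, economically important, and notoriously hard
to select on because its heritability in tropical crossbred
populations is around 0.02. At such low heritability almost all
phenotypic variation is environmental, so genetic evaluation leans
heavily on the covariance structure among relatives, and the marginal
information added by SNP genotypes (single-step GBLUP) is worth
quantifying carefully. This package implements that full evaluation
chain — repeatability animal model, pedigree and genomic relationship
matrices, AI-REML variance components, EBV/GEBV prediction with
theoretical accuracies, and a window-based GWAS on back-solved SNP
effects — together with a simulator that generates pedigrees,
genotypes and repeated phenotype records with exactly the covariance
structure the model assumes.

# The model

All evaluation steps work with the repeatability animal model

$$ y = Xb + Qh + Zu + Wp + e $$

where $y$ holds the repeated DO records (one per parity), $b$ the
fixed effects of breed group (3 levels), parity (up to 5) and
year-month of calving, $h \sim N(0, I\sigma^2_h)$ the random herd-year
effect, $u \sim N(0, K\sigma^2_u)$ the additive genetic effects,
$p \sim N(0, I\sigma^2_p)$ the permanent-environment effect shared by
a cow's records, and $e \sim N(0, I\sigma^2_e)$ the residual. The
relationship matrix $K$ is the pedigree numerator matrix $A$ for a
classical (AIREML/BLUP) run; for a single-step (ssGAIREML) run its
inverse is replaced by

$$ H^{-1} = A^{-1} +
   \begin{pmatrix} 0 & 0 \\ 0 & G^{*-1} - A_{22}^{-1} \end{pmatrix} $$

with $G^*$ the blended and tuned VanRaden genomic relationship of the
genotyped animals and $A_{22}$ their pedigree relationship.
Heritability uses the full phenotypic denominator including the
herd-year variance,

$$ h^2 = \frac{\sigma^2_u}
  {\sigma^2_h + \sigma^2_u + \sigma^2_p + \sigma^2_e}, $$

and repeatability is $(\sigma^2_u + \sigma^2_p)$ over the same
denominator.

# Relationship matrices

`buildA()` uses the tabular method; `inbreeding()` is its diagonal
minus one, so the two are consistent by construction. `buildAInverse()`
applies Henderson's rules with the inbreeding-adjusted Mendelian
sampling variances and is verified in the tests against the dense
inverse. Genomic relationships follow VanRaden's first method,
$G = WW' / 2\sum p_j(1-p_j)$ with $W$ the allele counts centred by
$2p_j$ and $p_j$ the *observed* frequencies; no method is prescribed
by the evaluation literature chain this mirrors, and method 1 with
observed frequencies is the field default. Because observed-frequency
centring leaves $G$ singular by construction, `blendG()` first matches
the mean diagonal and off-diagonal of $G$ to $A_{22}$ (a two-parameter
affine tune) and then blends $G^* = 0.95\,G + 0.05\,A_{22}$; both
steps are standard numerical conditioning and also place $G$ and
$A_{22}$ on a common base. The H-inverse correction uses no additional
$\tau/\omega$ scaling.

Genotype quality control keeps markers with call rate at least 0.90
and minor allele frequency strictly above 0.05, drops animals below a
0.90 call rate (the marker threshold mirrored, since no separate
animal threshold is standard), and mean-imputes remaining missing
calls at $2p_j$.

# Variance components

`remlEstimate()` is an average-information REML. Each iteration
factorizes the mixed model equations once; the permanent-environment
block is diagonal and is absorbed through its Schur complement, so the
dense factorization covers only the fixed, herd-year and animal
equations (exact, not approximated — the tests compare the absorbed
and plain paths through the GLS and likelihood oracles). First
derivatives come from the EM identities (quadratic forms plus exact
traces of the inverse coefficient matrix), second derivatives from the
average-information matrix of the working variates $Z_i u_i /
\sigma^2_i$ and $e/\sigma^2_e$. Updates are guarded component-wise: a
proposal that would turn a component negative decays that component
geometrically instead, and components pinned at the floor
($10^{-6}$ of the phenotypic variance) are fixed out of the AI system
until their EM update pulls them clear. Convergence is declared when
the largest relative component change among active components falls
below `tol` (default `1e-8`); standard errors are
$\sqrt{\mathrm{diag}(AI^{-1})}$. Starting values split the phenotypic
variance equally over the included components — deliberately
uninformative, since the guarded AI steps converge in 10–20 iterations
from there. Boundary collapses of weakly identified components at
small sample sizes are genuine REML optima (the tests verify the
internal likelihood against a dense-V oracle), not algorithm failures.

# Accuracy

Theoretical accuracy of an animal's EBV/GEBV is
$\sqrt{1 - \mathrm{PEV}_i / (d_i \sigma^2_u)}$, where PEV comes from
the diagonal of the inverse coefficient matrix and $d_i$ is the
diagonal of the relationship matrix the equations were built with:
$1 + F_i$ in a pedigree run, the exact H diagonal in a single-step
run. For non-inbred animals in a pedigree run this is precisely the
classical $\sqrt{1 - \mathrm{PEV}/\sigma^2_u}$. The single-step
generalization matters: normalizing genomic PEVs by the pedigree
diagonal systematically mis-scales genotyped animals (whose model
variance is $\mathrm{diag}(G^*)\,\sigma^2_u$, not $(1+F)\sigma^2_u$),
to the point of reversing the expected accuracy advantage of
single-step over pedigree evaluation; with the model-consistent
denominator that advantage holds in essentially every simulated
replicate. PEVs require a direct solve (the dense inverse is exact and
practical to roughly ten thousand equations); the PCG solver is for
larger systems where only solutions are needed.

# ssGWAS

SNP effects are back-solved from the GEBVs of the genotyped animals,
$\hat a = D W' G_w^{-1} \hat u / k$ with $k = 2\sum p_j q_j$, $D$ the
marker weights and $G_w = WDW'/k$. $G_w$ inherits the mean-direction
singularity of observed-frequency centring, so it is inverted with a
tolerance-based eigen pseudo-inverse that equals the ordinary inverse
whenever $G_w$ is non-singular; an optional ridge is available, while
blending with $A_{22}$ is deliberately reserved for the evaluation
step. One pass (equal weights) is the default; with more iterations
the weights $d_j \propto \hat a_j^2\, 2p_j q_j$ are renormalized each
round so the weighted total marker variance is conserved.

Window variances use sliding (step 1) windows of five adjacent SNPs
within a chromosome, computed as the empirical variance of the window
score $W_w \hat a_w$ across genotyped animals relative to the variance
of the full marker score — covariance-aware, not a sum of squared
effects. Windows at or above 0.25% of the total additive variance are
flagged. Per-SNP significance uses the two-sided normal test on
$\hat a_j / \mathrm{sd}(\hat a_j)$, with the sampling variance
propagated from the prediction-error covariance of the genotyped
animals through the back-solve transform, against the genome-wide
constant $-\log_{10}(5\times10^{-8}) = 7.30$. Whether the window and
per-SNP screens are applied jointly or separately is left to the user:
both are always emitted. Gene annotation reports, for each significant
SNP, genes overlapping it (distance 0, "on target") or within 37 kb
(inclusive), with the signed convention that positive distances lie
right of the gene end and negative distances left of the gene start;
BED input is converted from 0-based half-open to 1-based inclusive on
read.

# The synthetic-data generator

No real records are distributed, so the generator is the package's
test bed. It emulates, at roughly 1/20 scale, a tropical crossbred
dairy population: ~1,500 recorded cows in the final generation of a
discrete-generation pedigree, 1–5 parities per cow, 3 breed groups
(fixed effects +0.372, 0, −1.508 days so the lowest-Holstein-fraction
group is favourable), 50 herd-year and 24 year-month levels, true
variances (herd-year 30.41, additive 18.23, permanent environment
51.19, residual 707.87 days²), records editable to the 35–150 day
window by *dropping* (not truncating) out-of-range values, and a
50k-style SNP panel scaled to 2,500 markers on 29 autosomes for a
genotyped subset of the final generation.

Choices the model does not dictate, and why:

* **Mating structure.** Discrete generations with random dams and an
  AI-style sire team: each generation is fathered by a team of
  `sireFraction` (default 0.05) times its size, giving paternal
  half-sib families of roughly twenty daughters — the structure
  artificial insemination imposes on real dairy populations, and the
  family structure that makes $\sigma^2_u$ estimable from 1,500 cows.
  Very small sire teams (2% and below) make replicate estimates
  unstable because the realized between-family variance itself
  fluctuates; very large ones dilute the half-sib signal.
* **Breeding values** are drawn by the recursive Mendelian-sampling
  form $u_i = \tfrac12(u_s + u_d) + \phi_i$ with
  $\mathrm{Var}(\phi_i) = \sigma^2_u(\tfrac12 - \tfrac14(F_s + F_d))$,
  so $\mathrm{Var}(u) = A\sigma^2_u$ exactly without ever forming $A$.
  Optional QTL add effects through centred marker codes on top of the
  polygenic part.
* **Genotypes** are gene-dropped (founder alleles Bernoulli at a MAF
  drawn uniformly from `mafRange`, one allele inherited per parent),
  markers unlinked. Unlinked markers mean realized genomic
  relationships converge to the pedigree expectation as the panel
  grows — real genomes have linkage, so real $G$ carries more
  realized-relationship signal than this generator produces. Passing
  tests therefore demonstrate the machinery, not the field gain of
  genomic selection.
* **Herd-year and year-month** are assigned per record uniformly at
  random; real herds confound herd-year with cow far more strongly.
* **Editing.** The default drops records outside 35–150 days, as data
  editing would; the variance-recovery studies run unbounded because
  selection by truncation biases the components the tests are meant to
  recover.

# Problem sizes and studies

The shipped checks use these scales, chosen so the full suite runs
comfortably on one CPU:

* heritability recovery: 10 replicates of ~1,500 cows (1–3 parities,
  ~2,300 pedigree animals, ~2,500 mixed-model equations after
  absorption), pedigree AI-REML each — the mean recovered $h^2$
  rounds to 0.02 at the simulated truth of 0.0226;
* parameter recovery and SE calibration: 20 replicates at 400 cows;
* single-step vs pedigree accuracy direction: 20 replicates at 200
  cows with 1,500 markers and the same (true) variance components in
  both runs;
* QTL localization: 20 replicates of 1,000 cows, 2,500 markers, 95%
  genotyped, a QTL at 5% of additive variance, two weight iterations,
  under a moderately heritable configuration ($h^2 \approx 0.48$) —
  at $h^2 = 0.02$ breeding values are essentially family means, so no
  within-family marker signal can surface; this is a property of the
  trait, not of the method, and matches the real-data observation
  that the largest window explains only ~0.27% of variance;
* null calibration: 20 replicates without QTL, no SNP above 7.30.

# Known limitations

* Dense factorizations bound the exact-PEV and REML paths at roughly
  10⁴ equations; beyond that only PCG solutions (no accuracies) are
  offered. No APY or other large-scale H approximations.
* Single trait, repeatability model only: no maternal effects,
  genetic groups, random regression, or heterogeneous residual
  variances.
* The generator does not model selection, culling, heat stress, or
  dominance/heterosis of crossbreeding.
* Marker-trait linkage is absent (markers unlinked, QTL optional), so
  genomic accuracy gains in simulation are conservative relative to
  real data.
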