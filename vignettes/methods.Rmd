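---
title: "Models and methods for multi-trait association and pleiotropy-versus-linkage analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for multi-trait association and pleiotropy-versus-linkage analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheatmt)
```

## Scope

`wheatmt` analyses the joint genetic architecture of correlated quantitative
traits — the grain-yield syndrome of inbred wheat panels is the motivating
case — in three layers:

1. **Phenotype layer.** A two-stage analysis of multi-environment
   alpha-lattice trials: per-environment best linear unbiased estimators
   (BLUEs) of genotype means, across-environment BLUEs, variance components
   and heritabilities.
2. **Association layer.** Bivariate (and three-trait) mixed-model
   association scans with a kinship-structured polygenic term, a Wald-test
   hierarchy, and multiple-testing corrections including the effective
   number of independent markers.
3. **Pleiotropy layer.** A two-dimensional likelihood-ratio scan that asks,
   for a marker jointly associated with two traits, whether one locus
   (pleiotropy) or two tightly linked loci (close linkage) better explain
   the data — plus a simulation suite quantifying the power and Type I
   error of that test.

A synthetic-data module generates inbred panels, kinship, and phenotypes
with the statistical structure all of this assumes, so the entire pipeline
is testable without any external data.

## Two-stage phenotypic analysis

Stage 1 fits, per trait and environment,
`value ~ genotype (fixed) + replicate (random) + block-in-replicate (random) + error`
by REML (`lme4`). Genotype BLUEs and the per-environment plot error
variance $\sigma^2_{e,j}$ are carried forward; environments with a single
replicate contribute their raw plot values, flagged. Stage 2 combines the
stage-1 BLUEs with `value ~ genotype (fixed) + environment (random) + error`;
a parallel random-genotype fit yields $\sigma^2_G$ and the stage-2
residual $\sigma^2_{e}$.

The stage-2 residual mixes genotype-by-environment interaction with the
carry-over error of the stage-1 means. The interaction component is
recovered by subtraction. One subtlety deserves a note: the carry-over
error of a stage-1 genotype mean in environment $j$ is
$\sigma^2_{e,j}/n_{rep,j}$, not $\sigma^2_{e,j}$ itself, so the package
subtracts the entry-mean-basis average
$\overline{\sigma^2_{e,j}/n_{rep,j}}$ (over replicated environments). The
plot-basis average $\sigma^2_{Error}=\overline{\sigma^2_{e,j}}$ is still
reported and is the quantity that enters the plot-basis heritability

$$h^2_{Plot} = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_{G\times E} +
\sigma^2_{Error}},\qquad
h^2_{Entry} = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_{G\times E}/J +
\sigma^2_{Error}/(rJ)}$$

with $J$ environments and $r$ replicates. Subtracting the full plot-basis
error instead would over-correct by $\sigma^2_{Error}(1-1/r)$ and, in our
recovery simulations, drives the interaction component to zero whenever
error variance dominates; the entry-mean-basis subtraction recovers the
simulated components without bias (see `test-phenostage.R`). A negative
difference is floored at zero with a warning.

## The mixed-model engine

All association and pleiotropy machinery rests on the multivariate mixed
model with observations $y_{kji}$ (trait $k$, environment $j$, genotype
$i$), fixed trait-by-environment means plus optional fixed marker terms,
and random effects

$$\mathbf g \sim N(0,\; \mathbf G_0 \otimes \mathbf A), \qquad
\mathbf e \sim N(0,\; \mathbf R_0 \otimes \mathbf I),$$

where $\mathbf G_0$ and $\mathbf R_0$ are unstructured $t\times t$
(co)variance matrices and $\mathbf A = 2(\mathbf J - \mathbf{RD})$ is the
relationship matrix built from Rogers' distances (identical inbreds share
$A=2$; bending adds $-\lambda_{min}+10^{-6}$ to the diagonal if the raw
matrix is not positive semidefinite).

**Computation.** $\mathbf A$ is eigendecomposed once
($\mathbf A = \mathbf U \mathbf D \mathbf U'$) and every
trait-environment cell of the data is rotated by $\mathbf U'$. In the
rotated basis the model separates into $n$ independent small vectors (one
per genotype, length = number of trait-environment cells $m$), inside
which the genetic term contributes a rank-$\le t$ component
$d_i\,\mathbf T \mathbf G_0 \mathbf T'$. Each likelihood evaluation then
costs $O(nm^2)$ after an $m\times m$ eigen step, so full (RE)ML fits per
marker or per grid point are affordable; the implementation was verified
against a dense Kronecker multivariate-normal oracle.

**Parameterisation and optimisation.** $\mathbf G_0$ and $\mathbf R_0$ are
parameterised by their Cholesky factors with log-diagonals, which keeps
both matrices positive semidefinite by construction and extends unchanged
from $t=2$ to $t=3$ (the zero-covariance constraint of the
genetic-correlation test maps exactly to a zero Cholesky off-diagonal for
$t=2$). The profiled likelihood (fixed effects solved by GLS) is maximised
by Nelder-Mead with a polishing restart; derivative-free search is robust
at variance boundaries. Convergence: relative change below `1e-10`,
generous iteration caps, flagged otherwise. Boundary estimates
($|r_g|>0.999$) are flagged.

**Unbalanced traits; missing data.** Trait pairs measured in unequal
environment sets are handled by restricting the error structure to the
observed trait-environment cells. Genotypes with missing records inside an
observed cell are removed (row deletion, with $\mathbf A$ subset
accordingly) because the eigen-rotation requires genotype balance; whole
missing cells cost nothing.

**Tests.** The genetic correlation $r_g = s_{12}/\sqrt{s_{11}s_{22}}$ is
tested by a REML likelihood ratio against the $s_{12}=0$ refit (same fixed
effects, so REML LRs are valid), referred to $\chi^2_1$ with the LR floored
at zero. Fixed-effect hypotheses use Wald statistics
$\hat\theta'\,\mathrm{Var}(\hat\theta)^{-1}\hat\theta$ with
$\mathrm{Var}(\hat\theta)$ the corresponding block of
$(\mathbf X'\mathbf V^{-1}\mathbf X)^{-1}$ (the C11 block of the
mixed-model equations); singular blocks fall back to a generalized inverse
with rank-adjusted df.

## Bivariate association scans

For each marker the scan fits trait-by-environment means, per-trait marker
main effects, marker-by-environment interaction contrasts (reference =
first environment of each trait), and the polygenic term, re-estimating
variance components per marker. The test hierarchy is: a global Wald test
of both marker main effects (df 2), one df-1 test per trait, and global /
per-trait tests of the interaction contrasts. A marker is declared
potentially pleiotropic only when the global test passes the genome-wide
correction *and* both individual tests pass the post-hoc level (0.05 by
default; the gating level is configurable since it is a convention, not a
derived quantity).

Multiple-testing corrections: Benjamini-Hochberg q-values on the global
p-values (within trait pair), Bonferroni ($\alpha/m$), and the
$M_{eff}$ variant ($\alpha/M_{eff}$), where $M_{eff}$ sums, over
chromosomes, the number of eigenvalues of the marker $r^2$ matrix needed
to reach 95% of its total variation. The $r^2$ matrices are built from
markers with unique map positions, uncentered, with negative eigenvalues
floored at zero — the plain reading of applying principal component
analysis to an $r^2$ matrix; centering is a documented non-choice.
Because thresholds satisfy $\alpha/m \le \alpha/M_{eff}$ and BH rejects at
least everything a fixed $\alpha/m$ threshold does, the three significance
sets are nested.

Markers significant in more than one trait pair can be promoted to a
three-trait fit; the marker is declared simultaneously associated only if
all three per-trait Wald tests pass the corrected level (default
$\alpha = 0.1$ with $M_{eff}$, mirroring how such higher-order signals are
screened in practice).

Explained-variance bookkeeping divides sequential (Type-I) regression
$R^2$ per marker by the trait's entry-mean heritability to express marker
contributions as shares of genetic rather than phenotypic variance. A
stability summary regresses per-environment BLUEs on environment, marker,
and marker-by-environment terms and reports the ratio of marker
main-effect to interaction sums of squares.

## Pleiotropy versus close linkage

For a target marker with an LD window (markers on the same chromosome with
$r^2>0.5$ to the target; markers lacking such neighbours are untestable),
the scan compares, on across-environment BLUEs,

* the **pleiotropic model** $y_{ki}=\mu_k+\alpha_k m_i + g_{ki}+e_{ki}$
  with a single position $m$ from the candidate set, and
* the **linkage model** with trait 1 regressed on $m_1$ and trait 2 on
  $m_2$, over ordered pairs from the candidate set,

both with covariance $\mathbf G_0\otimes\mathbf A +
\mathbf R_0\otimes\mathbf I$. $L_0$ is the maximum log-likelihood on the
diagonal of the two-dimensional space, $L_1$ the maximum over the whole
grid, and $LR = 2(L_1-L_0)$ is referred to $\chi^2_1$ at $\alpha=0.05$.
Three numerical commitments:

* **ML, not REML**, at every grid point: the two models differ in fixed
  effects, so REML likelihoods would not be comparable.
* Both trait assignments of every unordered pair are scanned and the
  maximum taken; the diagonal is part of the grid, so $L_1\ge L_0$ and
  $LR\ge 0$ hold structurally and are asserted per scan.
* Variance components are re-estimated by full ML at every grid point by
  default; `fast = TRUE` re-uses the components estimated at the best
  single position (a profile approximation that can only lower the LR,
  also asserted in tests). The $\chi^2_1$ reference is retained although
  the two models are not strictly nested — the simulation suite measures
  the realized Type I error, which is the honest check of that
  approximation.

For disentangled pairs, `count_haplotypes()` tabulates the four two-locus
allele combinations over inbred genotypes (heterozygotes excluded and
counted) and annotates each haplotype with the predicted effect direction
per trait.

## Synthetic data

`simulate_genotypes()` builds inbred lines as founder-haplotype mosaics:
each line walks along a chromosome switching among `n_founders` founders
with probability $1-\exp(-d/\text{ld\_decay\_cM})$ per map step, and
`kinship_strength` is the probability of drawing the founder from a
family-specific pool, which creates related line groups and an informative
$\mathbf A$. Founder alleles are redrawn until every realized minor allele
frequency falls inside `maf_range`. This reproduces the *second moments*
downstream analyses rest on — MAF spectrum, LD decaying with map distance,
kinship structure — and deliberately nothing else: no selection history,
no genotyping-error model, no realistic demography. Passing tests
therefore certify the statistical machinery, not robustness to artefacts
of real genotyping pipelines.

`simulate_marker_pair()` engineers a locus pair with target MAFs and
$r^2$ from the two-locus haplotype-frequency parameterisation
($D$ from $r$, bounded by the classical feasibility constraints —
infeasible combinations are refused with the attainable $r^2$ bound), with
bounded rejection sampling (default 200 attempts) until realized MAFs are
within ±0.02 and realized $r^2$ within ±0.03.

`simulate_phenotypes()` draws polygenic values with covariance
$\mathbf G_0\otimes\mathbf A$, scaled so the expected *sample* variance
among lines equals the requested genetic variance — variety panels have a
high relatedness baseline (mean off-diagonal $A$ well above 0), which
would otherwise silently deflate every realized variance component — adds
additive QTL contributions, iid genotype-by-environment deviations,
random replicate and incomplete-block effects (blocks of 10 plots by
default), and plot error.

## The power / Type I error simulation study

Each grid cell simulates, on a fixed synthetic panel of 372 inbreds with
its estimated kinship:

* **linkage mode** — a marker pair at the cell's MAF and $r^2$, the first
  marker carrying the trait-1 QTL and the second the trait-2 QTL;
  candidate positions for the scan are the pair itself;
* **pleiotropy mode** — a single causal marker affecting both traits, with
  two engineered window neighbours at $r^2\approx 0.70$ and $0.55$
  (values fixed once, inside the $r^2>0.5$ window range the method
  requires).

QTL effects are scaled so each locus explains the stated percentage of its
trait's genetic variance, $\alpha=\sqrt{(pct/100)\,\sigma^2_G/(4p(1-p))}$
for 0/2-coded inbred dosages; the polygenic share is reduced
correspondingly. The two traits have total genetic variance 1 and
residuals fixed by plot-basis heritabilities of 0.44 and 0.60
(`powersim_traits()`), background genetic and residual correlations zero —
the traits are connected only through the simulated QTLs. Each cell runs
100 independent replicates (seeded hierarchically, reproducible end to
end) of the full-profile ML scan at $\alpha=0.05$ and reports the
rejection proportion with its binomial standard error.

Problem sizes used by the default test run: the Type I grid at 50
replicates per cell, the full linkage grid at 30, and `scripts/acceptance.R`
at the complete 100; the kinship panel is 21 chromosomes × 40 markers.

**What this reconstruction does and does not pin down.** The qualitative
operating characteristics are robust here: Type I error close to the
nominal 0.05, power increasing with QTL size and MAF and
decreasing with $r^2$ between the linked loci. The absolute power levels,
however, depend on details of the original study's simulation protocol
that are not recoverable from its published description (it relied on the
real variety panel and on supplementary methods unavailable here); a
back-of-envelope noncentrality calculation,
$LR \approx n \cdot (pct/100)(1-r^2) / (V/\sigma^2_G)$, shows that *any*
calibration faithful to the published heritabilities puts the easiest
cells near power 1, whereas the published peak is 0.58. The package
therefore reproduces the test, its calibration under the null, and the
direction and ordering of all trends, while absolute power at the
strong-signal cells is higher than the published table; the comparison is
reported as-is rather than tuned.

## Known limitations

* The engine requires genotype-balance within each observed
  trait-environment cell (row deletion otherwise); plot-level missingness
  is handled upstream by the two-stage pipeline.
* Spatial field trends, epistasis, haplotype-based association and
  physical (bp) coordinates are out of scope.
* The 2D scan evaluates marker positions only — no interval mapping
  between markers.
* $\chi^2$ references for the LR tests carry the usual
  boundary/non-nestedness caveats; simulation-based calibration is built
  in for the 2D test.
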