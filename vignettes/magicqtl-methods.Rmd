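---
title: "Whole-genome multitrait QTL analysis in MAGIC: models and methods"
author: "magicqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-genome multitrait QTL analysis in MAGIC: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Multiparent Advanced Generation Inter-Cross (MAGIC) populations descend
from more than two founders through intercrossing followed by selfing.
Because several founders segregate at every locus, marker scores are
often only partially informative about which founder contributed a
line's allele, and QTL analysis works instead with *founder
probabilities*: the posterior probability, for each line, marker (or
interval) and founder, that the allele descends from that founder.

`magicqtl` implements a whole-genome, multitrait / multienvironment QTL
analysis for four-way MAGIC recombinant inbred lines (RILs).  Rather
than scanning loci one at a time, founder-indexed QTL effects for
*every* interval enter one linear mixed model simultaneously as random
effects.  Putative QTL are extracted by forward selection, each round
combining a likelihood-ratio test for whether any QTL variance remains
with a multivariate outlier statistic that locates the most discrepant
interval.

# The model

For $n_g$ lines scored on $t$ traits (or in $t$ environments) with $m$
replicates, the base mixed model is

$$ y = X\tau + Z_g u_g + e, $$

with trait-specific intercepts $\tau$, genetic line effects $u_g$, and
residuals $e \sim N(0, R \otimes I)$ with $R$ diagonal by trait (or an
unstructured $t \times t$ matrix across traits within a plot).  The
genetic effects decompose as

$$ u_g = (I_t \otimes P)\,a + u_p, $$

where $P$ is the $n_g \times (r-c)\,n_f$ matrix of interval-averaged
founder probabilities ($r$ markers, $c$ chromosomes, $n_f = 4$
founders), $a$ holds the founder-by-interval QTL sizes with working
covariance $G_a \otimes I$, and $u_p \sim N(0, G_p \otimes I)$ is the
polygenic effect with an unstructured $t \times t$ trait covariance.

**Dimension reduction.** Fitting $(I_t \otimes P)a$ directly would
involve tens of thousands of effects.  The model is replaced by the
exactly equivalent

$$ u_g = (I_t \otimes (PP')^{1/2})\,a^* + u_p, $$

whose dimension is the number of lines.  Interval-level predictions are
recovered by $\tilde a = (I_t \otimes P'(PP')^{-1/2})\tilde a^*$ along
with the matching variances.  The test suite verifies this equivalence
against a dense fit of the unreduced model on random toy data sets
(likelihoods to $10^{-6}$, BLUPs to $10^{-5}$).

**Presence test.** Each selection round tests $H_0\!: G_a = 0$ by
fitting working models with *diagonal* trait covariance for both the
genome term and the polygenic term, with and without the genome term.
The statistic $X^2_{LR} = 2(\hat\ell - \hat\ell_0)$ sits on the
boundary of the parameter space under $H_0$; its null is the binomial
mixture of chi-squares

$$ X^2_{LR} \sim (1/2)^t \sum_{k=0}^{t} \binom{t}{k}\chi^2_k , $$

implemented in `mixture_chisq_pvalue()` (Monte-Carlo checked in the
acceptance suite).  Selection stops when the test is retained at level
$\alpha$ (default 0.05, the level used throughout the bundled
simulation designs).

**Outlier statistic.** On rejection, a model with *correlated* genetic
effects (unstructured $G_a$ and $G_p$) is fitted, and each remaining
interval $j$ on chromosome $k$ is scored by

$$ t^2_{kj} = \frac{\sum_f \tilde a_{kjf}' G_a^- \tilde a_{kjf}}
                   {\sum_f \mathrm{tr}\,(G_a^- \mathrm{var}(\tilde a_{kjf}))}, $$

summing over founders; the interval with the largest statistic becomes
the next putative QTL.  $G_a^-$ is a Moore–Penrose inverse with
singular values below $10^{-10}$ of the maximum truncated.  If the
correlated fit fails, the diagonal fit is used for the outlier
computation and the fallback is logged — multivariate variance models
are inherently fragile and a pragmatic fallback keeps the scan moving.

**Revised models.** A selected QTL's probability block $P_j$ leaves the
genome matrix and enters the model as its own random term.  In
multitrait mode the term is $(I_t \otimes P_j)a_{jt}$ with
$a_{jt} \sim N(0, \mathrm{diag}(\sigma^2_{js}) \otimes I_{n_f})$ — a
separate variance per trait ($t$ new parameters).  In multienvironment
mode two terms are added: a common founder effect
$(1_t \otimes P_j)a_j$, $a_j \sim N(0, \sigma^2_j I)$, and an
environment deviation $(I_t \otimes P_j)a_{jt}$,
$a_{jt} \sim N(0, \sigma^2_{jt} I_t \otimes I_{n_f})$ (2 new
parameters).  The common term induces correlation of the QTL effect
across environments; the deviation term carries any QTL-by-environment
interaction.  Trait-trait correlations *within* a QTL's effect are
deliberately not modelled: with only $n_f$ effects per trait there is
too little information, such fits routinely fail, and correlations are
undefined whenever a per-trait variance estimate is zero.  The diagonal
form is a compromise that works in practice.

**QTL-by-environment testing.** After a multienvironment scan, each
QTL's interaction variance is tested by a REML likelihood-ratio test of
$H_0\!: \sigma^2_{jt} = 0$, whose null is a point mass of one half at
zero plus half a $\chi^2_1$.  Model reduction is backward: all QTL are
tested, the least significant non-significant interaction is removed,
the model refitted, and the cycle repeated.  (The order is a package
choice; the tests themselves fix only the criterion, not a sequence.)

**Reporting.** For each QTL and trait the report gives the predicted
founder effects $\tilde a^*_{js}$ (for multienvironment QTL the common
plus deviation effect when the interaction is retained, the common
effect alone otherwise), the significance probability
$p_{js} = \Pr(\chi^2_{n_f-1} > c^2_{js})$ with
$c^2_{js} = \tilde a^{*\prime}_{js} V^-_{js} \tilde a^*_{js}$
(per-founder probabilities use 1 df), the score
$\mathrm{LOGP} = -\log_{10} p$, and the percentage of genetic variance

$$ PV_{js} = 100\, \frac{a^{*\prime}_{js} \mathrm{var}(\bar q_j) a^*_{js}}
  {\sum_j a^{*\prime}_{js}\mathrm{var}(\bar q_j)a^*_{js}
   + \sigma^2_{as}\,\bar p_{-l}'\bar p_{-l} + \sigma^2_{ps}}, $$

where $\mathrm{var}(\bar q_j) = \mathrm{diag}(\bar p_j) - \bar p_j \bar
p_j'$ uses the founder probabilities averaged over lines, and the
middle denominator term accounts for the non-selected intervals.  In
both modes $\sigma^2_{as}$ is taken from the diagonal of the final
fit's genome-term covariance, and estimates replace unknowns
throughout.  Reports round sizes to 3 decimals, probabilities to 4 and
LOGP to 1; full precision is retained internally and in the JSON/CSV
exports.

# Founder probabilities

`founder_posteriors()` runs a forward–backward hidden Markov model per
chromosome over the $n_f = 4$ founder-origin states of an inbred
line's haplotype, with per-marker rescaling against underflow
(posteriors agree with exhaustive path enumeration to $10^{-10}$ on
small chromosomes).

*Transitions.* For adjacent markers at distance $d$ cM, the Haldane
recombination fraction is $r = (1 - e^{-2d/100})/2$.  For a four-way
funnel RIL taken to fixation by selfing, the probability that the fixed
founder origins differ at the two loci is $R = 3r/(1+2r)$, splitting
equally over the three other founders, so each off-diagonal transition
probability is $r/(1+2r)$.  This combines the Haldane–Waddington
two-locus selfing result ($2r/(1+2r)$ for switching between the two
four-way-F1 homologs, which always changes founder pair) with the
single-meiosis mosaic within each two-way gamete (probability $r$ of a
within-pair switch).  The test suite verifies this formula by brute
force against the simulator's observed origin-switch frequencies.

*Emissions.* An observed allele consistent with a founder scores
$1-\varepsilon$, an inconsistent one $\varepsilon$ (default
$\varepsilon = 10^{-4}$); missing scores contribute a flat emission.
Founders sharing an allele split the emission mass implicitly — no
extra normalisation is applied.

*Interval averaging.* `interval_average()` replaces each chromosome's
$r_k$ marker blocks by $r_k - 1$ interval blocks, each the renormalised
mean of its flanking posteriors.  Scans accept marker-mode matrices
too, which simply substitutes $r_k$ for $r_k - 1$ columns per
chromosome.

Whether probability columns should be centred before forming $PP'$ is
genuinely open; `magicqtl` uses raw probabilities, keeping the row-sum
structure that the percent-variance formulas rely on.

# The REML engine

All models above reduce to balanced line-by-trait data with covariance
a sum of Kronecker products $T(\theta) \otimes B$, where $B$ is the
identity (polygenic), the genome kernel $PP'$ (supplied by its
eigendecomposition), or a low-rank founder block $W W'$ (a selected
QTL).  `fit_mvlmm()` exploits this:

* replicates are removed exactly by an orthonormal transform, leaving a
  line-means model plus within-line contrasts whose REML likelihood
  (constants included) matches a dense whole-data evaluation;
* the genome kernel's eigenbasis diagonalises the means covariance into
  $n_g$ blocks of size $t \times t$;
* selected-QTL blocks are handled by Woodbury / determinant-lemma
  identities, so a likelihood or analytic-gradient evaluation costs
  $O(n_g t^3 + n_g q^2)$ with $q$ the number of selected founder
  columns.

The residual log-likelihood is maximised by a bounded quasi-Newton
optimizer (`nlminb`) with analytic gradients, followed by a short
Newton polish (numerical Hessian of the analytic gradient) that
resolves the maximiser to near machine precision — balanced one-way
designs reproduce the closed-form ANOVA-REML identities to $10^{-8}$.
The estimates, not the iteration path, are the contract: the same
maximum is reached from perturbed starts (likelihoods agree to
$10^{-6}$), and small multivariate fits agree with a brute-force dense
maximiser to $10^{-4}$.

Numerical choices:

* variances are parameterised on the log scale and unstructured
  matrices by their log-Cholesky factors, so iterates stay positive
  (semi)definite by construction; a per-correlation hyperbolic-tangent
  parameterisation was rejected because it cannot guarantee positive
  definiteness for $t \ge 3$;
* each kernel is normalised to unit mean eigenvalue internally (undone
  on reporting) so optimizer bounds act on a common scale; the lower
  variance bound is $10^{-12}$ of the phenotypic variance, and
  parameters ending there are flagged as boundary estimates (their
  BLUPs and PEVs collapse to zero, and the fit agrees with the model
  that omits the term to $10^{-6}$);
* likelihood-ratio statistics that come out within $-10^{-6}$ of zero
  are clamped to zero (two separate maximisations); larger negative
  values raise a warning;
* non-convergent fits are retried from up to three jittered starts
  before an error is raised — an automated stand-in for the manual
  intervention that fragile multivariate fits sometimes need;
* fixed effects are trait/environment-specific intercepts, the only
  fixed structure the supported designs require; experiment-design
  terms beyond that (spatial trends, blocking factors) are out of
  scope.

At most one non-identity dense kernel is supported per fit (the genome
term); this covers every model the method needs, and two arbitrary
kernels would not be simultaneously diagonalisable.

# The simulator and what passing tests mean

`sim_magic()` generates the classic four-way funnel: each line draws
one recombined gamete from each two-way F1 (founder pairs 1/2 and
3/4 — the funnel is fixed, not randomised), then selfs by single-seed
descent.  Meiosis is Haldane (Poisson crossovers, no interference).
After the default six selfing generations about $(1/2)^6 \approx 1.6\%$
of loci remain heterozygous; these are resolved by keeping one homolog
per chromosome at random, matching the analysis assumption of a single
founder origin per locus.  Founder marker genotypes are biallelic with
allele frequency one half, drawn independently per marker (SNP-like),
with a fully informative option for validation.  One master seed
drives deterministic per-line substreams, so populations are
bit-reproducible.

The bundled study designs fix the conditions used throughout the
acceptance checks: 500 lines on seven 300-cM chromosomes with 201
equally spaced markers (1.5-cM spacing); three traits with means 9, 10
and 12; polygenic covariance $G_p$ with variances 0.5 and correlations
0.7 (traits 1–2) and 0.5 (with trait 3); unit residual error; two
replicates.  The power design adds four QTL of founder pattern
$(0.3, -0.3, -0.3, 0.3)$ at 141, 160, 174 and 207 cM on chromosomes
1–4: fully pleiotropic; sign-flipped in trait 3; expressed only in
trait 3; and absent in trait 3, respectively.  With uniform founder
probabilities each active QTL accounts for
$a'(\mathrm{diag}(p) - pp')a = 0.09$ of a per-trait genetic variance of
$0.77$, i.e. 11.7% (35.1% for the three active QTL of each trait).

The simulator emulates idealised conditions: balanced replication, no
missing phenotypes or genotypes, no spatial or design effects, no
selection or mortality, exchangeable founders, and a marker map dense
enough that interval averaging loses little information.  Real MAGIC
experiments violate most of these — partially replicated field designs,
spatially correlated residuals, founder-biased segregation,
multiallelic markers, missing data.  Passing the simulation-based
checks therefore demonstrates that the machinery is correct and
calibrated under its own assumptions, not that those assumptions hold
for any particular field data set.

# Problem sizes and runtime

The calibration studies are sized to run on a single CPU in minutes:
the null study uses 200 phenotype replicates on one simulated genome
set (100 in the test suite; type-I error and false-positive rate are
binomial/Poisson means over replicates, so Monte-Carlo error is
$\approx 0.015$–$0.02$, and occasional replicates where a diffuse
chance alignment of the polygenic draw with the genome kernel triggers
several selections dominate the false-positive mean); the power study
uses 50 replicates (detection proportions carry binomial error
$\approx 0.07$), with the acceptance *tests* additionally thinning the
map to 68 markers per chromosome while `scripts/acceptance.R` keeps
the full 201-marker density.  The genome set is simulated once and
shared across replicates — phenotypes are redrawn each time — mirroring
how the study conditions are defined.  A full scan replicate costs a
few seconds: each round is two diagonal fits (presence test), one
correlated fit and one back-transform over all remaining intervals.

# Known limitations

* Four founders only, one intercross plus selfing; no eight- or
  sixteen-founder funnels, no advanced intercross generations, no
  funnel randomisation.
* Balanced phenotypes with a common replicate count; no missing
  responses.
* No spatial residual models or general experiment-design random
  terms; no pedigree/relationship-matrix polygenic structure.
* Marker-mode and interval-mode probabilities from the built-in HMM
  only; three-point probability schemes are not implemented.
* Forward selection is greedy: closely linked QTL can shadow each
  other, and pleiotropy vs close linkage is not distinguished.
* Up to three traits/environments per fit; the dimension that the
  boundary-mixture test and the batched linear algebra are written for.
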