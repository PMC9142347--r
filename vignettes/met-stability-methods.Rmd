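---
title: "Models and methods for multi-environment trial stability analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for multi-environment trial stability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metstab)
```

## The setting

A breeding programme evaluates a set of genotypes in a series of
*environments* — location-year combinations — on replicated field trials,
and must decide which lines to advance. Two questions dominate: how much of
the genetic signal is stable across environments (the genotype main effect)
versus environment-specific (genotype-by-environment interaction, GEI), and
which individual lines combine good mean performance with *stable*
performance. `metstab` implements the standard analysis chain for this
setting: per-environment genotype means adjusted for design and spatial
field trends, a crossed variance decomposition across the whole series,
entry-mean heritability, joint-regression and ecovalence stability
statistics, a biplot view of GEI, comparison of candidate lines against a
commercial check, and mixed models for subjective evaluator panels
(professional bakers scoring dough and bread, tasters scoring sensory
traits). A synthetic-data generator with the same stochastic structure as
the analysis models makes every estimator testable by parameter recovery.

## Per-environment genotype means (BLUEs)

Within one environment the plot-level model is

$$y_{ijkl} = \mu + G_i + \beta_j + R_k + C_l + \varepsilon_{ijkl},$$

with genotype $G_i$ fixed and block $\beta_j$, field row $R_k$, field
column $C_l$ independent zero-mean Gaussian random effects. Row and column
are *post-blocking* controls for spatial trend: they are included only when
they improve the fit. The model is fitted by REML (lme4) and the reported
genotype values are estimated marginal means at population level (random
effects at zero), i.e. best linear unbiased estimates (BLUEs) with standard
errors from the fixed-effect covariance. Under a balanced complete RCBD
without spatial terms these reduce exactly to arithmetic genotype means;
in augmented designs, where most entries are unreplicated and only checks
repeat, the entries are adjusted through the block/row/column effects
estimated from the checks. Both behaviours are pinned against an explicit
dense GLS oracle in the tests. Incomplete blocks of alpha designs are
modelled through the same random block term.

Spatial-term choice (`select_spatial_terms`) fits all four row/column
inclusion combinations with identical fixed effects and compares
REML-based AIC, breaking ties (to 1e-9) toward the smaller model. A point
worth knowing: AIC's penalty of 2 per variance component is liberal at the
boundary. Because the null distribution of the restricted LRT for one
variance is the 50:50 chi-bar-square mixture, AIC admits a spurious
spatial term in roughly 15% of null trials. We keep AIC as the default —
it rarely costs more than a slightly overfitted covariance — but provide
`criterion = "lrt"`, a boundary-corrected restricted likelihood-ratio test
at `alpha = 0.05`, which holds the false-inclusion rate near 5% (about 95%
base-model selection under the null in our simulations, versus about 85%
for AIC). Detection power for a genuine row effect of residual magnitude
is essentially 1 at the default trial size under either mode.

## Variance decomposition and heritability

Across the series the all-random crossed model is

$$y = \mu + G + L + A + LA + \beta_{(LA)} + GL + GA + GLA + \varepsilon,$$

with $L$ locations, $A$ years, and blocks nested in location-years, fitted
by REML under the nonnegativity constraint; estimates at the zero boundary
are flagged rather than hidden. The genetic components are summarised as
shares of the *total genetic variance* $\sigma^2_G + \sigma^2_{GL} +
\sigma^2_{GA} + \sigma^2_{GLA}$ — non-genetic components never enter that
denominator. Reduced forms drop the location terms (single-location
series) or both location and year terms (single environment).

Broad-sense heritability on an entry-mean basis uses harmonic-mean
divisors so that unbalanced data — in particular the selection funnel,
where genotypes drop out year by year — are handled on the realized
incidence rather than nominal design counts:

$$H^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_{ga}/\bar n_a +
\sigma^2_{gl}/\bar n_l + \sigma^2_{gal}/\bar n_{al} +
\sigma^2_e/\bar n_{alr}}$$

where $\bar n_a, \bar n_l, \bar n_{al}, \bar n_{alr}$ are harmonic means,
across genotypes, of the number of years, locations, environments, and
plots in which each genotype was observed. A genotype with a zero count is
dropped with a report — a harmonic mean cannot absorb a zero. In the
single-environment balanced case with $r$ replicates this collapses to
$\sigma^2_g / (\sigma^2_g + \sigma^2_e/r)$, which the tests assert
exactly, along with monotonicity in every component.

## Stability statistics

**Finlay–Wilkinson joint regression.** Each genotype's BLUEs are regressed
by ordinary least squares on the *environment index*, the centred
per-environment mean of the BLUEs (two-stage form). The slope
$\beta_i$ is the sensitivity: near 0, static stability (the genotype
ignores the environment); near 1, dynamic stability (it tracks the
environment mean); above 1, hypersensitivity. The default classification
bands are (0.5, 0.8, 1.2). Per-genotype $R^2$ (squared correlation of
fitted and observed) measures how much of the genotype's GEI the linear
response explains. Two identifiability facts shape the tests: on a
complete table the estimated slopes always average exactly 1 (the index is
the genotype-mean of the data), so generating slopes are recoverable only
on the scale where they average 1; and when a table is incomplete the
index is computed from the genotypes present in every environment, with
per-genotype regressions re-centred on their own environments. Genotypes
seen in fewer than 3 environments are excluded with a report.

**Wricke's ecovalence.** The contribution of genotype $i$ to the
interaction sum of squares of the two-way table,

$$W_i = \sum_j (\hat G_{ij} - \bar G_{i\cdot} - \bar G_{\cdot j} +
\bar G_{\cdot\cdot})^2,$$

computed by double-centring. Note the sign of the grand mean: it is
*added back*. A published variant that subtracts all three terms does not
vanish on purely additive tables, contradicting the statistic's defining
property that a genotype with no interaction scores $W = 0$; the
double-centring form used here satisfies it, and the tests verify both the
additive-zero property and the identity $\sum_i W_i = SS_{GEI}$ against an
independent ANOVA oracle. $W$ is reported in squared trait units; display
scalings (such as $10^6$ for yield) belong to the report layer.

`drop_environments` supports the "no extremes" re-analysis: when a few
environments are exceptional (for instance unusually high-yielding
seasons), the stability statistics are recomputed without them and
reported side by side by `stability_table`.

## GGE biplots and which-won-where

Column-centring the BLUE table (subtracting each environment's mean)
leaves genotype main effect plus GEI — the quantity a within-environment
genotype ranking responds to. The SVD of the centred table gives genotype
scores $UD^f$ and environment loadings $VD^{1-f}$, symmetric $f = 0.5$ by
default; no scaling by environment standard deviation is applied unless
requested. A deterministic sign convention (dominant element of each
genotype axis positive) makes repeated fits identical. Winners are
computed on the *exact* centred matrix — the rank-2 polygon view familiar
from biplots is a visualisation device and is reported alongside for
comparison; the two coincide whenever the first two axes carry all the
variation. Environments sharing a winner form a mega-environment.

## Dunnett comparison against a check

Within one trial, every genotype is compared to a named check cultivar
with familywise error control through the joint $k$-variate $t$
distribution of the contrasts (two-sided; superior lines labelled A,
inferior B). The within-trial model is the design model without spatial
terms, with block as a fixed nuisance term — the exact multivariate-$t$
theory assumes a fixed-effects linear model, and for balanced blocks the
genotype contrasts are identical under either reading. The $t$ integrals
are evaluated by deterministic-seeded quadrature (abseps $10^{-4}$), so
p-values reproduce bit for bit; $k = 1$ uses the exact $t$ distribution.
The residual degrees of freedom are reported prominently because on-farm
trials with two replicates leave very few. Calibration is checked three
ways: reduction to the two-sided $t$ test at $k = 1$, agreement with a
$10^6$-draw Monte-Carlo max-$|t|$ oracle, and an empirical familywise
error of about 5% over 10,000 null simulations (`fwer_simulation`, which
also demonstrates the inflation of unadjusted comparisons).

## Evaluator score models

Baker panels score dough and bread stages on a 10-point scale; taster
panels score appearance, texture and flavour on a 1-5 scale. The model is
$y = \mu + G_i + \beta_j (+ \Upsilon_k) + \varepsilon$ with evaluator
$\beta_j$ and optional baking-stage $\Upsilon_k$ random; genotype BLUEs
come from the same estimated-marginal-means machinery. Scores are treated
as continuous; the generator clips simulated scores to the scale bounds
and reports the clipped fraction so recovery studies can confirm that
clipping was negligible at the chosen settings. With a single evaluator
the evaluator variance is unidentifiable and the fit falls back to fixed
effects with a warning — the BLUEs are then exactly the per-genotype
means.

## FHB scoring and selection filters

Head-row Fusarium head blight scoring follows the 0-5 spike scale:
incidence is the percentage of nonzero scores among the (default 20)
spikes, severity the mean of the per-score infected-spikelet percentages
over all spikes, and the index their product as a percentage. The default
score-to-percentage map `{0:0, 1:6.7, 2:13.3, 3:50, 4:75, 5:100}` reads
the scale anchors on a 15-spikelet spike ("one spikelet", "two
spikelets", "up to half", "more than half", "entire spike dead"); the
published protocol does not print its mapping, so the map is configurable.
Selection filters are deliberately strict at boundaries: "above the 50th
percentile" keeps values strictly above the type-7 interpolated median,
"below 15" is strict, and top-$n$ retains all boundary ties (reporting
them) rather than breaking them arbitrarily.

## The synthetic trial generator

`simulate_met` draws every effect family of the crossed model
independently from zero-mean Gaussians, each family from its own
deterministic substream of the master seed, so resizing one component
never perturbs another; the drawn effects are returned for recovery tests.
The defaults are the study conditions the package is calibrated to: 50
genotypes, 2 locations x 5 years, 3 replicate blocks, grand mean 2800
kg/ha, and yield variance components chosen to put 54% / 9% / 12% / 25% of
the total genetic variance on G / GL / GA / GLA at field-realistic
magnitudes. The absolute magnitudes are a synthetic choice — published
MET summaries typically report shares, not absolute components — and are
documented as such. The optional selection funnel (e.g. 50 to 42 to 24 to
16 genotypes over years) drops the lowest-ranked genotypes on their
running mean of the simulated trait, a truncation-selection stand-in for
multi-trait judgement calls that are not reproducible mechanically.

What the generator does **not** emulate: spatially correlated error beyond
independent row/column bands (no AR1xAR1), heterogeneous residual
variances per environment, non-Gaussian effects, marker or pedigree
structure, and informative missingness other than the funnel. Passing
recovery tests therefore demonstrate correctness of the estimators under
the stated model, not robustness to field pathologies outside it.

The companion generators mirror the downstream models exactly:
`simulate_fw` builds $y_{ij} = \mu + G_i + \beta_i E_j + \varepsilon$ with
centred environment effects, and `simulate_scores` builds the evaluator
model with scale clipping.

## Numerical choices and problem sizes

- REML fits delegate to lme4 with derivative checks disabled and
  small-sample design checks relaxed (augmented designs legitimately have
  as many random levels as plots). Optimizer return code -4
  (roundoff-limited, typical of perfect-fit boundaries) is accepted; the
  estimates are exact in the degenerate cases where it occurs.
- Variance estimates within $10^{-8} \times \hat\sigma^2_\varepsilon$ of
  zero are flagged as boundary estimates.
- Standard errors use the fixed-effect covariance at the REML optimum with
  no small-sample (Kenward-Roger) adjustment — a documented limitation,
  chosen for determinism and speed; degrees of freedom for the Dunnett
  test are the within-trial residual df.
- The quadrature for multivariate-$t$ probabilities uses absolute
  tolerance $10^{-4}$ with a fixed internal RNG seed: reproducible to far
  below any decision threshold used here.
- Ties: AIC ties resolve to fewer terms; top-$n$ selection retains
  boundary ties; winner ties in which-won-where resolve to the first
  genotype in sorted order.

The test suite sizes its simulations to run on one CPU in a few minutes
while keeping Monte-Carlo error well inside every asserted tolerance:
parameter-recovery studies use 200 replicates at the full study design
(1,500 plots) for the variance decomposition, 200 replicates for
Finlay-Wilkinson and score-model recovery, 60 replicates for the
boundary-detection study, and $10^6$ draws / $10^4$ simulated trials for
the Dunnett calibration.

## A worked miniature

```{r example}
sim <- simulate_met(met_sim_config(n_genotypes = 10, n_years = 3,
                                   n_replicates = 2, seed = 3))
blues <- blues_matrix(sim$plots, "yield_kg_ha", spatial = "none")
head(stability_table(blues), 4)
vc <- estimate_variance_components(sim$plots, "yield_kg_ha")
round(variance_proportions(vc), 2)
heritability(vc)$H2
```

## Known limitations

No AMMI analysis, no imputation of missing BLUE cells (incomplete tables
must be reduced explicitly), no spatial correlation models, no
heritability standard errors, no multi-trait selection index (the filters
are single-trait), and evaluator scores are modelled as continuous rather
than ordinal. These are scope decisions, not oversights; each has a
natural extension point in the corresponding module.
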