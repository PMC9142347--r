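# metstab

Statistical analysis of multi-environment plant-breeding trials (METs),
written for breeders and biometricians running small regional programmes —
the kind that evaluates a few dozen candidate lines against commercial
checks across a handful of locations and years and has to decide, every
season, which lines to advance.

## What it computes

Given plot-level field data (genotype, location, year, block, row, column,
trait values), the package runs the standard MET analysis chain:

- **Per-environment genotype BLUEs** from the mixed model
  *y = μ + G(fixed) + block + row + col + ε*, with row/column spatial
  terms included only when they improve a REML-based AIC
  (`estimate_blues`, `select_spatial_terms`).
- **Crossed variance decomposition** over the series,
  *y = μ + G + L + A + LA + block(LA) + GL + GA + GLA + ε* (all random,
  REML), with genetic components reported as shares of the total genetic
  variance σ²G + σ²GL + σ²GA + σ²GLA
  (`estimate_variance_components`, `variance_proportions`).
- **Entry-mean broad-sense heritability** with harmonic-mean divisors for
  unbalanced data:
  *H² = σ²g / (σ²g + σ²ga/n̄a + σ²gl/n̄l + σ²gal/n̄al + σ²e/n̄alr)*
  (`heritability`).
- **Stability statistics** on the genotype × environment BLUE table:
  Finlay–Wilkinson sensitivity β and per-genotype R² (two-stage joint
  regression on the environment index), and Wricke's ecovalence
  *Wᵢ = Σⱼ (Ĝᵢⱼ − Ḡᵢ. − Ḡ.ⱼ + Ḡ..)²*, each genotype's contribution to the
  interaction sum of squares (`finlay_wilkinson`, `wricke_ecovalence`,
  `stability_table`, with `drop_environments` for "no extremes"
  re-analyses).
- **GGE biplots**: SVD of the environment-centred table, biplot
  coordinates U·D^f / V·D^(1−f), and which-won-where mega-environment
  grouping (`gge`, `biplot_coords`, `which_won_where`).
- **Dunnett many-to-one comparison** of lines against a check at
  familywise level α through the joint multivariate-t of the contrasts,
  with A / B / ns labelling and the critical difference
  (`dunnett_test`, `fwer_simulation`).
- **Evaluator score models** for baker and taster panels,
  *score = μ + G(fixed) + evaluator + stage + ε* (`fit_score_model`).
- **FHB scoring** (incidence × severity index from 0–5 spike scores) and
  the strict percentile / threshold / top-n selection filters used to
  advance families (`fhb_scores`, `percentile_select`).
- A **synthetic trial generator** with exactly the stochastic structure of
  the analysis models, returning the drawn truth for parameter-recovery
  testing (`simulate_met`, `simulate_fw`, `simulate_scores`), and a
  one-call **pipeline** that runs every stage from a config and writes
  CSV tables plus a checksummed manifest (`run_pipeline`).

Everything returns plain S3 objects with `print`/`summary`/`coef`/`plot`
methods; mixed models are fitted with lme4 and genotype means are
estimated marginal means (emmeans).

## A worked example

Simulate a small trial series (10 genotypes, 2 locations × 3 years,
2 blocks), estimate BLUEs per environment, and summarise stability:

```r
library(metstab)
sim   <- simulate_met(met_sim_config(n_genotypes = 10, n_years = 3,
                                     n_replicates = 2, seed = 3))
blues <- blues_matrix(sim$plots, "yield_kg_ha", spatial = "none")
head(stability_table(blues), 4)
#>   genotype     mean     slope r_squared        w
#> 1      g01 2550.794 0.6432157 0.3912803 281318.7
#> 2      g02 2283.724 1.4228555 0.7144698 360484.8
#> 3      g03 1972.241 2.0574438 0.9511358 487390.4
#> 4      g04 2441.529 0.7373167 0.6337267 139834.3
```

`slope` is the Finlay–Wilkinson sensitivity (g01 under-responds to good
environments, g03 is hypersensitive), `r_squared` the predictability of
that response, and `w` Wricke's ecovalence in (kg/ha)² — g04 contributes
least to the interaction sum of squares, i.e. is the most stable of the
four. Decompose the variance and get heritability:

```r
vc <- estimate_variance_components(sim$plots, "yield_kg_ha")
round(variance_proportions(vc), 2)
#>    G   GL   GA  GLA
#> 0.30 0.14 0.23 0.33
heritability(vc)$H2
#> [1] 0.5367
```

At this small size only 30% of the genetic variance is the stable genotype
main effect. Finally, compare everything to a check within one trial:

```r
dunnett_test(sim$plots, "yield_kg_ha", "loc1", 2019, check = "g01")
#> Dunnett comparison vs check 'g01' (alpha = 0.05, residual df = 9)
#>    genotype mean se_mean     diff se_diff       t   p_unadj    p_adj label
#> 1       g01 2206   148.6     0.00      NA      NA        NA       NA    ns
#> 2       g02 1527   148.6  -679.80   210.2 -3.2350 0.0102400 0.056380    ns
#> 3       g03 1016   148.6 -1190.00   210.2 -5.6640 0.0003081 0.001905     B
#> ...
#> Critical difference: 696.9  (quantile  3.316 )
```

Genotype g03 is significantly inferior to the check after familywise
adjustment (label B); g02's unadjusted p of 0.01 does not survive it — the
reason the adjustment exists.

## Documentation

The methods vignette (`vignettes/met-stability-methods.Rmd`) derives each
model, states the assumptions, explains the numerical choices (AIC versus
boundary-corrected LRT for spatial terms, quadrature settings for the
multivariate-t, tie-breaking rules), and documents what the synthetic
generator does and does not emulate.
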