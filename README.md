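# cagedom

Dominance hierarchy analysis for group-housed laboratory mice from coded
home-cage behavior.

Male mice housed in groups form dominance hierarchies — usually despotic
ones, where a single alpha performs most of the aggression. Many proxies for
dominance are in circulation (tube tests, wound scoring, preputial gland
size, urinary darcin), but whether they measure the same construct as the
hierarchy actually expressed in the home cage is an empirical question.
`cagedom` implements the full analysis chain for answering it: from coded
behavioral event streams to directed sociomatrices, Glicko contest ratings,
per-mouse phenotype scores, and a convergent/discriminant validity analysis
built on mixed-model residualization and maximum-likelihood factor analysis.
A generative simulator of an entire cage study makes every stage testable
without video-coded data.

The package is aimed at behavioral biologists and biostatisticians working
with all-occurrence and instantaneous-scan observational data on group-housed
animals.

## What it computes

**Sociomatrix metrics.** Aggression events (winner = initiator) are tallied
into a directed frequency sociomatrix `M` with `M[i,j]` = wins of `i` over
`j`. From it:

- density = |{(i,j) : M[i,j] > 0}| / n(n−1) — how widely aggression is
  distributed;
- directional consistency DC = Σ(H−L) / Σ(H+L) over dyads, where H and L are
  the counts in each dyad's more- and less-frequent direction (1 = fully
  unidirectional);
- in-/out-strength = column/row sums per mouse.

**Glicko-1 ratings.** Each mouse carries a rating r (start 2200) and a
rating deviation RD (start 300). For a rating period with opponents j,
outcomes s_j ∈ {0,1}:

    g(RD) = 1 / sqrt(1 + 3 q² RD² / π²),          q = ln(10)/400
    E_j   = 1 / (1 + 10^(−g(RD_j)(r − r_j)/400))
    d²    = [q² Σ g(RD_j)² E_j (1 − E_j)]⁻¹
    r'    = r + q/(1/RD² + 1/d²) · Σ g(RD_j)(s_j − E_j)
    RD'   = sqrt[(1/RD² + 1/d²)⁻¹]

Two variants are reported as net change from baseline: **Glicko-Agg** (from
aggression contests) and **Glicko-Sub** (each submission is a contest won by
the mouse submitted to). The per-cage extremes of Glicko-Sub designate the
dominant and subordinate.

**Phenotype scores.** Pelt wound grids (PALS: severity 0–4 × %area × 0.25,
averaged over anterior/mid/posterior row bands), tube-test scores
(wins/competed, timeouts = loss for both), preputial gland : body length
ratio, scan-sampling time budgets, and proportion of scans observed alone.

**Validity pipeline.** Measures are standardized, residualized on
strain × group size with a random cage intercept, and factored (maximum
likelihood, varimax, eigenvalue > 1 rule, |loading| ≥ 0.45 membership).
Factor scores are regressed on the Glicko net changes (convergent validity);
the tube-test principal component is tested against open-field measures
(discriminant validity); submission responses within 5 s of a social
investigation are modeled by logistic regression with the six pairwise
strain × day contrasts at the Bonferroni threshold 0.05/6 ≈ 0.0083.

## Worked example

```r
library(cagedom)

study <- simulate_study(sim_config(seed = 42))   # 24 cages, 2 x 2 design
cage  <- study$cages[["C07"]]

M <- frequency_sociomatrix(contests_from_aggression(cage$events),
                           cage$meta$mouse_ids)
M
#>        C07_m1 C07_m2 C07_m3
#> C07_m1      0      0      0
#> C07_m2      9      0      9
#> C07_m3      0      1      0
sociomatrix_density(binarize(M))   # 0.5  — half the possible directed edges
directional_consistency(M)         # 0.895 — strongly unidirectional dyads

glicko_variants(cage$events, cage$meta$mouse_ids)$agg$states
#>   mouse   rating       rd n_contests net_change
#>  C07_m1 1858.510 175.0326          9  -341.4898
#>  C07_m2 2555.052 132.3771         19   355.0522
#>  C07_m3 1960.706 163.1464         10  -239.2942
```

Mouse `C07_m2` initiated (and therefore won) 18 of the cage's 19 observed
attacks: its rating climbs 355 points above the 2200 baseline while the two
victims go negative — the despot's signature.

```r
rep <- validity_analysis(study$measures)
rep$factor_solution
#> <factor_solution> 2 factor(s), n = 36 (6 subjects/variable)
#>                 Factor1 Factor2
#> darcin           -0.176   0.770
#> preputial_ratio  -0.003   0.986
#> posterior_pals   -0.183  -0.879
#> tube_r1           0.942  -0.131
#> tube_r2           0.931  -0.013
#> tube_r3           0.954   0.117
#> eigenvalues: 2.73 2.37  | % variance: 45.49 39.48
rep$glicko_correlation$r   # 0.966
```

The three tube-test rounds load together on one factor and the two
gland-derived dominance markers (darcin, preputial ratio) on another —
the tube test measures something separate from home-cage dominance, while
the two Glicko variants are nearly interchangeable (r = 0.97).

The same chain runs end to end, writing CSV/JSON reports:

```r
run_pipeline(pipeline_config(sim = sim_config(seed = 42), out_dir = "out"))
```

or from the shell via the CLI:

```sh
Rscript inst/cli/cagedom.R all --seed 42 --out out
Rscript inst/cli/cagedom.R simulate --seed 42 --out bundle   # CSV bundle only
```

## Documentation

`vignettes/cagedom-methods.Rmd` describes the statistical model, the
generative simulator and its assumptions, all tunable constants with their
defaults, and known limitations.
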