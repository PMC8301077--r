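---
title: "Methods: dominance inference and validity analysis in cagedom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dominance inference and validity analysis in cagedom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Group-housed male mice form dominance hierarchies that shape stress
physiology, immunity and welfare, yet most laboratory "dominance" measures
(tube tests, wound scores, gland morphometrics, urinary proteins) are
assayed outside the home cage. `cagedom` implements the analysis chain
needed to ask whether such proxies converge on the hierarchy the animals
actually express at home: coded behavioral events → contest streams →
sociomatrix statistics and Glicko ratings → phenotype scores → a factor
analytic validity assessment. Because hand-coded video is expensive and
rarely shareable, the package ships a generative model of a full cage study
so every stage is exercised by synthetic data with known ground truth.

# Data model and observational sampling

Events are rows `(day, t, actor, recipient, category)` with five ethogram
categories: mediated aggression (chasing, mounting, thrusts, resource
theft), escalated aggression (biting, fighting), submission (upright
posture, fleeing), allogrooming, and social investigation. The coding
convention that the first mouse to act submissively loses makes every
aggression event a decided contest won by its initiator; every submission
event, conversely, is a contest won by the mouse submitted to. These two
readings drive the two rating variants (Glicko-Agg, Glicko-Sub).

Observation follows all-occurrence sampling for 1 min in every 5 (the first
60 s of each 300-s block, a half-open window: an event at exactly `k*300` s
is observed) over two 24-h days (days 2 and 7 of co-housing). Instantaneous
scans every 5 min record each mouse's state (active / group sleep / solitary
sleep) and its cell on a 4 × 2 grid; solitary occupancy of a cell defines
"alone". Validation warns rather than rejects when events fall outside
sampled windows, so partially coded datasets load.

# Sociomatrix statistics

Density is the proportion of ordered pairs with at least one observed attack
(`n(n-1)` ordered pairs; an undirected variant over `n(n-1)/2` dyads exists
behind a flag but is not the default, because the matrices are directed).

Directional consistency is computed from the *frequency* matrix:
`DC = sum(H - L) / sum(H + L)` over dyads, H/L being the dyad's
larger/smaller directed count. A binary variant (`binary = TRUE`) is exposed
for auditing, but positivity alone collapses DC to a mutual-edge proportion
and contradicts the definition's "most frequent direction"; it is therefore
not the default. An all-zero matrix yields `NA` with a warning rather than
an arbitrary number.

Per-day matrices can be built, but the default pipeline pools the two
observation days by summation before computing metrics (day was not a
significant factor in the motivating analyses; the choice is switchable by
building per-day matrices explicitly).

# Glicko-1 ratings

The classic Glicko system is implemented from scratch (`glicko_g`,
`glicko_expected`, `glicko_update_period`, `glicko_rate`), not Glicko-2: the
2200-point default and the description of certainty growing with contests
and shrinking with inactivity match the classic system as popularized by the
R rating packages used in rodent dominance work. Constants and conventions:

| constant | default | why |
|---|---|---|
| initial rating | 2200 points | the convention reported with these data; net change is reported so the offset cancels |
| initial RD / RD ceiling | 300 / 300 points | fresh animals are maximally uncertain; ceiling caps idle inflation |
| q | ln(10)/400 | Glicko scale constant (fixed) |
| c | `sqrt((300² − 50²)/100)` ≈ 29.7 | calibrated so an RD of 50 returns to the ceiling after 100 idle periods; irrelevant at two observed days but defined for longer designs |
| rating period | one per observation day | the natural unit here; a per-event sequential mode exists for sensitivity analysis |

Within a period all updates use pre-period opponent states (simultaneous
update). Ties cannot occur — the coding rule always identifies a winner —
so outcomes are strictly {0, 1}; tube-test double losses never enter Glicko.
A mouse with no contests ends with net change exactly 0 and RD at the
ceiling. The engine is checked against an independent straight-line
transcription of the update equations kept in the test suite (agreement to
1e-9).

# Phenotype scores

**PALS.** Each pelt-grid cell scores `severity × area% × 0.25` (severity
0–4, area 0–100, so a cell maxes at 100). Regions are thirds of the grid's
rows from neck (anterior) to tail (posterior); on the 9 × 9 grid each band
averages 27 cells. The literature's phrasing also admits a 3 × 3 summary
grid ("three grid scores per region"); `pals_region_scores` accepts any row
count divisible by three, covering both readings without a separate code
path. The posterior average is the analysis value. The area term is kept on
its natural percent scale; a binned scale would only rescale loadings in the
downstream factor analysis.

**Tube tests.** Score = wins / trials competed, per round; a 2-min stalemate
counts in the denominator of both contestants and the numerator of neither.
Round-robin bookkeeping: `choose(n, 2) × 4` trials per round (40 for five
mice, 12 for three).

**Morphometrics.** Preputial ratio = combined gland mass (mg) / body length
(mm). Darcin enters as a standardized label-free quantitation value and may
be missing (non-urinating mice); missingness propagates to listwise deletion
in the factor analysis, never to imputation.

# The validity pipeline

1. **Standardize** each measure (mean 0, SD 1 over non-missing values;
   zero-variance input is an error, not a silent constant).
2. **Residualize** on strain, group size and their interaction with a random
   cage intercept (lme4), taking conditional residuals. Cage is nested in
   strain × group size, so when the random-effect variance is estimated at
   zero (singular fit) the model falls back — with a warning — to cage as a
   fixed factor, which absorbs the design through cage means. Constant
   design factors (e.g. a single-strain subset) are dropped from the fixed
   part automatically. Both modes are exposed because the distinction
   between "random intercept" and "nested factor syntax" in the motivating
   analysis is untestable from its description.
3. **Factor** the residuals: maximum likelihood (`stats::factanal`), factor
   count = number of correlation-matrix eigenvalues above 1.0, varimax
   rotation, regression (Thomson) scores — the score estimator is not
   stated in the motivating work, and regression scoring is the common
   default. Membership = |loading| ≥ 0.45. Each factor is oriented so its
   largest-magnitude loading is positive: with orthogonal rotation, sign and
   factor order are conventions, and only the membership pattern is treated
   as reproducible structure. Uniquenesses are bounded below at 0.005; a
   bound hit is reported as a Heywood warning rather than hidden.
4. **Convergent validity**: OLS of each Glicko net change on the factor
   scores with per-term F tests and partial eta squared.
5. **Discriminant validity**: the tube-round PCA's first component (the only
   one past the eigenvalue rule) regressed on open-field boli, center time
   and distance plus the design, with a random cage intercept. F tests use
   residual-based approximate denominator degrees of freedom; replicating
   JMP/SAS Satterthwaite output to the printed decimal is a non-goal.
6. **Sequence analysis**: every investigation is scored 1 if the
   investigated mouse submits within 5 s (same day, strict `t_inv < t_sub ≤
   t_inv + 5`), 0 otherwise; `responded ~ strain * day` by binomial GLM with
   all six pairwise cell contrasts on the log-odds scale, each compared to
   0.05/6 ≈ 0.0083 (comparing p to α/6 rather than multiplying p by 6 —
   equivalent decisions, cleaner reporting). Complete separation triggers a
   documented fallback: half a success and half a failure added per cell
   (an empirical-logit-style penalty; no penalized-GLM dependency is
   available in the supported environment).

The scanner deliberately ignores what *triggered* a submission — only the
submission's own direction is observable in the data model. Two
consequences: Glicko-Sub counts every submission regardless of trigger, and
the 5-s scan can credit an investigation with a submission actually
provoked by a nearby attack. The calibration tests therefore switch off
attack-triggered submissions when estimating the investigation-response
probability; on real coded data the same contamination exists and is
irreducible.

# The synthetic cage study

`sim_config()` states one world; its defaults are the package's standing
assumptions, set once and not revisited:

- **Design**: 6 cages per strain × group-size arm (24 cages), strains
  SJL / albinoB6, sizes 3 and 5, observation days {2, 7}.
- **Despotism** δ = 0.9: the alpha performs 90% of aggression; non-alpha
  aggression targets lower-ranked mice with probability 0.9, keeping dyads
  unidirectional (simulated DC ≈ 0.9, density ≈ 0.30–0.47 — low density,
  high DC, the despotic signature).
- **Rates** (continuous, per mouse-hour): aggression 0.5, investigation
  2.5, allogrooming 0.4. Under 1-in-5 sampling these yield ≈ 20 observed
  attacks and ≈ 100 observed investigations per cage over two days —
  matching the order of magnitude of the coded datasets that motivated the
  design (≈ 2,200 investigations study-wide).
- **Submission responses**: probability matrices by strain × day; after
  attack (0.5–0.75, higher for albinoB6 and day 7), after investigation
  (0.25 for SJL day 2, 0.10 elsewhere — the elevated-cell pattern the
  contrast analysis should detect). Latency ~ Uniform(0, 5 s) so the 5-s
  scanner's sensitivity is exact; an exponential option (mean 2.5 s, heavier
  tail) probes window misspecification. Responses that would cross midnight
  are dropped.
- **Investigation coupling** ρ = 0.8: investigation propensity is a
  0.8/0.2 mixture of the aggression propensity and an independent random
  trait. Note the *implied* count correlation exceeds 0.8 under despotic
  propensities (the mixture is on weights, not correlations); tests compare
  the empirical out-strength correlation against the ground-truth implied
  value, not against ρ itself.
- **Tube coupling** ρ_tube = 0: the Bradley–Terry tube latent is independent
  of home-cage dominance, which reproduces the two-factor separation
  ({darcin, preputial} vs {tube rounds}); setting ρ_tube = 0.9 merges the
  blocks, demonstrating the generator controls the headline structure.
- **Strain/rank effects** (SD units): darcin +1.5 and preputial +0.8 for
  albinoB6, wounding +1.2 for SJL; darcin and preputial increase by 1.0 per
  SD of within-cage dominance; posterior wounding accumulates with received
  attacks (victims are wounded). PALS grids are generated cell-wise with
  posterior > mid > anterior exposure and then scored through the same PALS
  functions the pipeline uses.
- **Cage variance** σ_cage = 0.4: a shared cage-level shift in darcin,
  preputial, wounding and the tube latent — CageID was a significant
  variance component in the motivating data, and without it every
  residualization degenerates to the fixed-cage fallback.
- **Open-field measures** independent of everything by default (the
  discriminant null); a coupled mode exists for power checks.
- **Scans**: per-mouse sticky Markov chains (persistence 0.7) whose
  stationary probabilities shift with dominance (more active, more solitary
  sleep); group sleepers share the nest cell, so time budget and
  proportion-alone carry the dominance signal the Budget-PC analysis
  expects.
- **Attrition and missingness**: the realized study world — 5 of 24 cages
  dropped before the validity stage (3 albinoB6-3, 1 albinoB6-5, 1 SJL-3),
  leaving 19 cages → 38 selected mice; exactly 2 selected mice missing
  darcin (the realized count) and 15% missingness elsewhere. This makes the
  6-subjects-per-variable gate (36/6) a property of the world, not a tuned
  output.

What the generator does **not** emulate: coder error and inter-observer
disagreement (observation is deterministic window thinning), spatial or
biomechanical realism, batch effects, within-week rank reversals, humane-
endpoint dynamics (attrition is a fixed design feature, not a response to
simulated aggression), and any quantitative claim about real strains —
labels map to effect *signs* only. A green recovery test therefore
establishes that the pipeline recovers the structure of a world with these
properties, not that the biological effect sizes are realistic.

# Numerical and testing choices

- Monte-Carlo suites fix their seeds; calibrated checks state their bands as
  ±2 Monte-Carlo SEs of the nominal rate.
- The convergent-power simulation calibrates its slope from the exact
  noncentral-F power function for nominal power 0.95 (not 0.90): asserting
  "≥ 90% of 200 replicates" at true power 0.90 would fail about half the
  time by construction; calibrating at 0.95 makes the bound a genuine test
  of the machinery with negligible false-failure probability.
- Engine-vs-oracle agreement is asserted to 1e-9 with idle inflation
  disabled (`c = 0`), isolating the one-period update from the inflation
  policy.
- Degenerate inputs error loudly (zero variance, empty rosters, unknown
  mice, unsorted contest streams) except where a missing value is the
  documented answer (all-zero DC, zero tube trials, zero scans).
- Selection ties (identical Glicko-Sub) break on Glicko-Agg, then roster
  order — deterministic, so the pipeline is bit-reproducible given a seed.

# Limitations

- Mixed-model p-values use residual-df approximations; they are adequate for
  the null/power calibrations tested but will not match Satterthwaite or
  Kenward–Roger output decimal for decimal.
- `factanal`'s ML fit differs in initialization from JMP's SMC-prior
  implementation; eigenvalues and loadings agree in structure, not to the
  fourth decimal, and only the ≥ 0.45 membership pattern is asserted
  anywhere.
- The submission-trigger ambiguity described above is inherent to the data
  model; Glicko-Sub is "all submissions", not "submissions attributable to a
  specific trigger class".
- With very sparse cages (no submissions at all) Glicko-Sub is flat zero and
  dominant/subordinate selection falls back to Glicko-Agg ordering.
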