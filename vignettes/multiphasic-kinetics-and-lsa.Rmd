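---
title: "Multiphasic enzyme kinetics and time-delayed association networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiphasic enzyme kinetics and time-delayed association networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eeanet)
```

## The problem

Heterotrophic marine bacteria access polymeric dissolved organic matter
through extracellular enzymes — leucine aminopeptidase (LAP),
beta-glucosidase (BG), alpha-glucosidase (AG). When hydrolysis rates are
assayed over a wide ladder of fluorogenic-substrate concentrations, the
response curve of a natural community is often *multiphasic*: a
high-affinity (HA) system saturating at micromolar substrate superimposed
on a low-affinity (LA) system with half-saturation constants tens to
hundreds of micromolar. A single Michaelis–Menten fit conflates the two and
badly misestimates both the affinity and the hydrolysis potential of the
community. `eeanet` resolves the systems by nested-model fitting, and then
asks how the resulting kinetic parameters co-vary — possibly with a time
lag — with phytoplankton blooms and bacterial community composition across
a monthly sampling campaign.

## The kinetic models

Four nested models of increasing complexity, with `S` in uM and `V` in
nM h^-1:

| model | equation | interpretation |
|---|---|---|
| M1 | $V = T_t S$ | one non-saturating system (first-order) |
| M2 | $V = \frac{V_{max} S}{K_m + S}$ | one saturating system |
| M3 | $V = \frac{V_{max,HA} S}{K_{m,HA} + S} + T_{t,LA} S$ | saturating HA + non-saturating LA |
| M4 | $V = \frac{V_{max,HA} S}{K_{m,HA} + S} + \frac{V_{max,LA} S}{K_{m,LA} + S}$ | two saturating systems |

$T_t$ is the first-order rate coefficient of a system assayed far below
saturation, equivalent to the ratio $V_{max}/K_m$; it is sometimes called a
"turnover time" although it is dimensionally a rate constant, and this
package carries it in h^-1. Because `S` is held in uM while `V` is held in
nM h^-1, the first-order terms include an explicit factor of 1000
(1 uM = 1000 nM); the factor lives in one place (`eval_model()`) and is
covered by a unit test, so $T_t$ never silently changes units.

Identifiability of M4 is enforced by construction: the two systems are
relabelled after every fit so that $K_{m,HA} < K_{m,LA}$. The high-affinity
label is a statement about the ordering of half-saturation constants, not
about which optimizer slot a system happened to land in.

## Fitting and model selection

`fit_model()` minimizes the residual sum of squares over the
replicate-level points (never replicate means — the small-sample AICc
correction needs the true number of observations) with bounded
Levenberg–Marquardt nonlinear least squares. Zero-substrate wells are
excluded: $V(0) = 0$ is structural in all four models, and background is
the business of the blanks.

Design choices that were genuinely open:

* **Multi-start grid.** $K_m$ starts at $\{\min S, \mathrm{med}\, S, \max
  S, 3\max S\}$ (for M4, all ordered pairs), $V_{max}$ at $\{\max V, 2\max
  V\}$, $T_t$ at the OLS slope through the origin. An optional `starts`
  argument appends seeded ±20% jitter. Nonlinear fits of multiphasic
  curves have real local optima; the grid spans the geometry the ladder
  can express.
* **Warm starts from nested submodels.** M3's pool includes the fitted M2
  embedded exactly ($T_{t,LA} = 0$); M4's pool includes the fitted M2
  ($V_{max,LA} = 0$) and the fitted M3 mapped to a large-$K_m$
  Michaelis–Menten term of equal initial slope. This makes the fitted RSS
  respect the nesting hierarchy (RSS$_{M4}$ ≤ RSS$_{M3}$ ≤ RSS$_{M2}$,
  RSS$_{M3}$ ≤ RSS$_{M1}$) within optimizer tolerance — a property the test
  suite asserts on random synthetic curves.
* **No upper bound on $K_m$.** Parameters are bounded below by zero and
  unbounded above. A finite $K_m$ cap looks prudent but removes M3's linear
  limit from the closure of M4's parameter space: when the data genuinely
  favour a non-saturating LA component, the capped M4 optimum sits at the
  boundary with a measurably *worse* RSS than M3, breaking the nesting
  property. Instead of constraining, any fitted $K_m$ above the highest
  assayed concentration is reported with an `extrapolated` flag — field
  campaigns do produce such estimates and they belong in the tables,
  flagged, not censored.
* **AICc convention.** The least-squares form
  $n \ln(RSS/n) + 2k + 2k(k+1)/(n-k-1)$ with $k$ = number of kinetic
  parameters + 1, counting the error variance. RSS is floored at machine
  epsilon so that interpolating fits on noiseless data remain comparable —
  all models reaching the floor are then ranked purely by parameter count,
  which is exactly the right tie-break. `select_model()` accepts a more
  complex model only when it lowers AICc; exact ties go to fewer
  parameters. The F-test alternative is deliberately not offered: with
  similar competing models it systematically prefers the simpler one even
  when the complex one is correct.
* **M1 in closed form.** The first-order model is linear through the
  origin; its least-squares solution is analytic and exact.

Single-system samples (M2 selected) report their saturating system under
the HA columns of the parameter table, with the LA columns absent. A lone
system has no partner to compare affinities against; the column placement
is a labelling convention, and the selected-model column always states
which structure was actually chosen.

Cell-specific rates divide $V_{max}$ by bacterial abundance:
1 nM h^-1 over 10^9 cells L^-1 is 1 amol cell^-1 h^-1. Campaign-level
HA-vs-LA contrasts use the paired Wilcoxon signed-rank test
(`compare_ha_la()`), exact for up to 30 informative pairs.

## From plates to rates

`compute_rates()` follows the assay arithmetic: subtract the time-matched
mean blank fluorescence, convert through the fluorophore standard curve
(MCA for peptidase substrates, MUF for glucosidase substrates), and take
the OLS slope of product concentration against incubation time — with
exactly two readings this reduces to the increase divided by the
incubation time. Rate estimates are invariant to any constant fluorescence
offset and to drift shared between sample and blank wells; both
invariances are tested. Negative fitted rates are flagged, never clipped:
they are information about the noise floor. The default incubation window
is 0–6 h, matching 3–6 h incubations read from time zero.

## Local similarity analysis

Monthly ecological series are short (here ~27–32 points), non-Gaussian and
episodically coupled: a bloom's degradation products reach the bacteria
after the bloom collapses, so the association may hold only over part of
the year and only at a lag. Local similarity analysis searches for the
best contiguous, possibly shifted, co-varying segment:

1. **Normalization.** Each series is replaced by normal scores
   $\Phi^{-1}(r_i/(n+1))$ of its ranks — robust to the heavy-tailed
   kinetic parameters. Plain z-scoring is available by flag.
2. **Dynamic program.** For every alignment offset $|d| \le D$ the
   Kadane-style recursion $P_{i,j} = \max(0, P_{i-1,j-1} + \hat x_i \hat
   y_j)$ (and its negative twin) finds the best positively and negatively
   co-varying run; the score is the best accumulated sum divided by $n$,
   signed. The implementation is vectorized over prefix sums and is tested
   for exact agreement with brute-force enumeration of every segment at
   every offset. The default delay cap is $D = 1$ sampling interval (one
   month). Convention: positive delay means the first variable *precedes*
   the second; delayed edges are exported leader-first.
3. **Significance.** Permutation p-values with add-one smoothing,
   $p = (1 + \#\{|LS_{perm}| \ge |LS_{obs}|\})/(n_{perm}+1)$, from
   whole-series permutations (default 1000), then Benjamini–Hochberg
   q-values across all pairs. Whole-series permutation ignores seasonal
   autocorrelation; see limitations.
4. **Ties.** Equal scores resolve toward smaller |delay|, then positive
   sign, then positive delay, so results are deterministic and
   orientation-stable.

Missing values: an isolated single-month gap is linearly interpolated in
the raw series before normalization; longer gaps make the pair fall back
to the longest contiguous stretch where both series are observed
(`n_effective` reports what was actually scored). Interpolating across long
gaps would fabricate exactly the kind of local runs the statistic rewards.

`build_network()` keeps pairs with $q \le 0.05$ (configurable) as edges —
signed, weighted by LS score, directed when delayed — and
`export_network()` writes SIF, GraphML (attribute-complete round trip) and
edge CSV for Cytoscape.

## What the synthetic generator emulates — and what it does not

`simulate_response_curve()` draws
$V_{obs} = V_{true}(1 + \varepsilon_{mult}) + \varepsilon_{add}$ with 5% CV
multiplicative noise and a 0.5 nM h^-1 additive floor by default:
fluorescence-derived rates scale roughly with signal, plus read noise near
the detection limit. The default ladder is the field design — 12 serial
half-dilutions from 400 uM (LAP) or 300 uM (glucosidases), 4 replicates.

`simulate_campaign()` realizes a 32-month monthly campaign with 5 random
dropout months (27 retained samples, mirroring a realistic cruise-gap
rate): a chlorophyll-like spring bloom and a cyanobacteria-like
late-summer bloom as annual Gaussian pulses (amplitude 3, width 1 month,
noise SD 0.5), two uncoupled bacterial-group series, and two
kinetic-parameter-like targets driven by the blooms — one positively at a
1-month lag, one negatively with no lag, both with coupling strength 1.2.
Pulse width matters: much wider pulses make lag-0 and lag-1 alignments
nearly indistinguishable, which is a property of the data, not of the
method.

The generator does **not** attempt mechanistic succession, nutrient
feedback, AR(1) persistence, or realistic bacterial-group compositional
constraints. Passing the planted-truth tests therefore shows that the
pipeline recovers couplings *of the planted kind* at campaign-realistic
length, noise and gap structure — not that every edge in a field network
is trustworthy.

## Problem sizes and numerical choices in the test suite

The suite simulates at the scales the claims are about: 200 curves for the
model-selection power check (M4 chosen in ≥ 94%), 100 curves for noisy
parameter recovery (median relative error < 20% per parameter at 5% CV,
using well-separated glucosidase-like parameters within the observed field
ranges), 50 curves for the RSS-nesting property, 1000 null pairs for
permutation-type-I calibration, and 20 campaign seeds for full-pipeline
planted-truth recovery. Levenberg–Marquardt tolerances are
`ftol = ptol = 1e-10` with at most 10^4 function evaluations per start.

## Known limitations

* When the true LA half-saturation constant lies beyond the assayed ladder
  (as parts of the observed LAP range do), its estimate is an extrapolation:
  median recovery error at 5% CV exceeds 20% there, which is a property of
  the design, not the optimizer. The `extrapolated` flags exist precisely
  to mark those estimates.
* Whole-series permutation nulls ignore within-series autocorrelation;
  strongly seasonal pairs can look locally similar for shared-seasonality
  reasons. Block or phase permutations are a possible extension.
* The delay search is capped at whole sampling intervals; sub-monthly
  dynamics alias into lag 0 or 1.
* AICc model selection is asymptotically, not exactly, calibrated; the
  eligibility rule (a model needs `n_params + 2` distinct substrate
  levels) keeps it away from the degenerate small-n regime.

## A minimal run

```{r example, eval = FALSE}
set.seed(1)
curves <- lapply(1:5, function(i) {
  simulate_response_curve(
    "M4", c(Vmax_HA = 20, Km_HA = 1, Vmax_LA = 200, Km_LA = 100),
    seed = i, sample_id = paste0("s", i), bacterial_abundance = 1e9)
})
kin <- run_kinetics(curves)
kin$parameters[, c("sample_id", "selected_model", "Km_HA_uM", "Km_LA_uM")]

sim <- simulate_campaign(campaign_truth(seed = 1))
out <- run_lsa(sim$table, config = run_config(seed = 1))
out$network
```
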