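# eeanet

Multiphasic extracellular enzyme kinetics and time-delayed association
networks for aquatic microbial ecology.

Natural bacterial communities hydrolyse polymeric organic matter with
extracellular enzymes (leucine aminopeptidase LAP, beta-glucosidase BG,
alpha-glucosidase AG). Assayed over a wide substrate ladder, their
hydrolysis-rate response curves are often *multiphasic*: a high-affinity
(HA) enzymatic system saturating at micromolar concentrations superimposed
on a low-affinity (LA) system with far higher half-saturation constants.
`eeanet` resolves the two systems and links their seasonal dynamics to
phytoplankton and bacterial community time series.

The package provides:

* **Nested kinetic models.** Four models of increasing complexity —
  first-order `V = Tt·S`, Michaelis–Menten `V = Vmax·S/(Km+S)`, and their
  two-isoenzyme combinations (MM + first-order; MM + MM) — fitted to
  replicate-level response curves by multi-start bounded
  Levenberg–Marquardt least squares and compared with the small-sample
  corrected Akaike criterion, AICc = n·ln(RSS/n) + 2k + 2k(k+1)/(n−k−1).
  A more complex model is accepted only when it lowers the AICc. Derived
  quantities include cell-specific Vmax (amol·cell⁻¹·h⁻¹ = Vmax/abundance)
  and paired Wilcoxon HA-vs-LA contrasts.
* **Assay processing.** Serial half-dilution ladder construction (12
  levels from 400 µM for LAP, 300 µM for glucosidases, 4 replicates),
  MUF/MCA standard curves, blank subtraction and rate estimation from
  plate-reader timecourses.
* **Local similarity analysis (LSA).** Rank-normalized series, a
  dynamic-programming search for the best contiguous co-varying segment
  allowing up to a 1-month delay, permutation p-values and
  Benjamini–Hochberg q-values across all variable pairs.
* **Network assembly** of significant associations (signed, weighted,
  directed when delayed) with SIF/GraphML/CSV export for Cytoscape.
* **Synthetic data** with recorded ground truth: noisy response curves
  from any of the four models, and seasonal monthly campaigns with
  bloom-like pulses, sampling gaps and planted lagged couplings.

## Worked example

Fit the four models to a simulated glucosidase curve (true model: two
saturating systems) and select by AICc:

```r
library(eeanet)
cv <- simulate_response_curve(
  "M4", c(Vmax_HA = 20, Km_HA = 1, Vmax_LA = 200, Km_LA = 100),
  seed = 42, sample_id = "feb12", bacterial_abundance = 1.5e9)
fits <- lapply(c("M1", "M2", "M3", "M4"), function(m) fit_model(cv, m))
sel <- select_model(fits)
for (f in fits) cat(sprintf("%s: AICc = %8.2f\n", f$model_id, f$AICc))
#> M1: AICc =   334.62
#> M2: AICc =   193.43
#> M3: AICc =   185.99
#> M4: AICc =   129.81
sel$estimates
#>     Vmax_HA       Km_HA     Vmax_LA       Km_LA
#>  16.2303009   0.6709767 206.4494933  92.2540890
```

The two-system model wins decisively (ΔAICc ≈ 56 against the next best)
and recovers the generating parameters: an HA system with sub-micromolar
Km and an LA system with roughly ten-fold higher Vmax and hundred-fold
higher Km. `kinetic_parameters(sel, cv)` adds cell-specific rates
(here sp.Vmax_HA ≈ 10.8, sp.Vmax_LA ≈ 138 amol·cell⁻¹·h⁻¹) and flags any
Km beyond the assayed range.

Link kinetic parameters to a simulated bloom campaign:

```r
sim <- simulate_campaign(campaign_truth(seed = 1))   # 32 months, 5 gaps
out <- run_lsa(sim$table, config = run_config(seed = 1))
out$network$edges
#>           var_x         var_y sign delay ls_score q_value directed
#> 1 cyanobacteria  BG_spVmax_HA   -1     0   -0.675 0.00749    FALSE
#> 2         chl_a LAP_spVmax_HA    1     1    0.501 0.00749     TRUE
```

Both planted couplings — a contemporaneous negative association with the
late-summer cyanobacteria pulse and a 1-month-delayed positive response to
the spring chlorophyll bloom (directed edge: chl a leads) — are recovered
at q < 0.01, and nothing else passes. A thin command-line front end over
the same functions lives at `inst/cli/eeanet.R`
(`simulate-curves`, `simulate-campaign`, `fit`, `lsa`, `all`).

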