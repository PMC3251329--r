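# fdopar

Reference-tissue Patlak quantitation of dynamic [¹⁸F]FDOPA PET in the
unilaterally 6-OHDA-lesioned (hemiparkinsonian) rat.

## What it is for

[¹⁸F]FDOPA is trapped in striatal dopaminergic terminals after transport
and decarboxylation, so its net influx constant **Kᵢ** indexes
presynaptic dopaminergic function. In the unilateral 6-OHDA rat model,
the within-animal ipsilateral/contralateral percentage **Kᵢ R/L** is a
noninvasive severity measure that can be compared against the
biochemical gold standard (striatal dopamine + metabolite content, also
as an R/L percentage) and against behavior (methamphetamine-induced
rotation counts). `fdopar` is for imaging scientists who need that chain
as tested, reproducible code:

* dynamic **frame schemes** (`build_framing("6x10,6x30,11x60,15x180,3x600")`
  → 41 frames / 90 min), decay correction (¹⁸F half-life 109.77 min) and
  **SUV** normalization;
* **VOI-mean TAC extraction** from 4D images + integer label masks
  (NIfTI-1 via RNifti);
* the **reference-tissue Patlak plot**: with the cerebellum (no
  trapping) replacing the arterial input,

  ```
  C_tissue(t) / C_ref(t)  =  Ki · ∫₀ᵗ C_ref(u) du / C_ref(t)  +  V
  ```

  fitted by OLS over frames with mid-times in the closed 10–60 min
  window; the slope is Kᵢ (1/min), the intercept V;
* the **statistical battery**: paired t (ipsi vs contra), one-way ANOVA
  with **Dunnett's** many-to-one comparisons against control (Monte
  Carlo adjusted p for unbalanced designs), and the three pairwise
  linear regressions among Kᵢ R/L, DA R/L, and log₁₀ rotations;
* a **synthetic generator** — compartmental TACs with known
  ground-truth Kᵢ = K₁k₃/(k₂+k₃), 4D phantoms, and lesion cohorts with
  configurable dose–severity and severity–DA/rotation links — so every
  stage is testable without animal data.

## Worked example

```r
library(fdopar)

## forward-simulate one animal and fit the Patlak plot
sch   <- build_framing("6x10,6x30,11x60,15x180,3x600")
pl    <- simulate_input_function(mid_times_min(sch))
cereb <- simulate_tissue_tac(pl, kinetic_params(0.4, 0.4, 0),    sch, "cerebellum")
stri  <- simulate_tissue_tac(pl, kinetic_params(0.08, 0.45, 0.11), sch, "striatum")
fit_patlak(patlak_transform(stri, cereb), c(10, 60))
#> Patlak fit [10-60 min, n = 20]: Ki = 0.01573 /min, V = 0.1525, R^2 = 1.0000
```

The fitted slope 0.01573/min recovers the configured macro-parameter
K₁k₃/(k₂+k₃) = 0.01571/min to 0.1%, inside the 15.7–16.7 × 10⁻³/min
range typical of intact rat striatum.

```r
## a full simulated study: 3 controls + 6 animals at 7/14/28 µg 6-OHDA
res <- run_all(run_config(seed = 1L))
head(res$cohort[, c("animal_id","dose_ug","ki_rl_percent","da_rl_percent","rotations")], 5)
#>   animal_id dose_ug ki_rl_percent da_rl_percent rotations
#> 1      R001       0      98.12064      91.43839         7
#> 2      R002       0      97.53859      74.77624         2
#> 3      R003       0      97.49311     100.00000         6
#> 4      R004       7      65.51464      69.27634        10
#> 5      R005       7      77.54791      69.14143         5

res$stats$anova_dunnett$ki_ipsi$dunnett$table   # dose effect on ipsilateral Ki (F = 69.57)
#>   group    mean_diff  statistic p_unadjusted   p_adjusted
#> 1     7 -0.003861591  -4.716700 1.990296e-04 4.300000e-04
#> 2    14 -0.007218481  -8.816938 9.478638e-08 9.478638e-08
#> 3    28 -0.010772842 -13.158375 2.427098e-10 2.427098e-10

res$stats$regressions$ki_vs_da$all
#> OLS: y = 1.221 x + -23.73, r = 0.956, p = 1.37e-11, n = 21
res$stats$regressions$ki_vs_logrot$all
#> OLS: y = -0.03197 x + 3.683, r = -0.842, p = 1.69e-06, n = 21
```

Reading the output: every dose group has significantly lower ipsilateral
Kᵢ than control after Dunnett adjustment; the Kᵢ asymmetry tracks the
monoamine asymmetry tightly (r = 0.956) with a regression that does
*not* pass through the origin (intercept −23.7: the biochemical deficit
runs deeper than the PET deficit); and Kᵢ R/L falls log-linearly with
rotational behavior. `run_all(cfg, out_dir)` additionally writes the
cohort, per-animal Patlak fits, and all statistical tables as TSV with a
provenance header (seed + config hash), and two runs with the same seed
are byte-identical.

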