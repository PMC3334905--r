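# cimplan

Experiment-planning calculus for **controlled in meso phase (CIMP)
crystallization** of membrane proteins: vapor-diffusion experiments in
which an aqueous protein drop hydrates a dry monoolein coating in a
96-well plate, and dehydration against a reservoir of screening solution
then drives the monoolein/water system to a chosen mesophase with the
protein partitioned into the lipid bilayer.

Two quantities decide the design of such an experiment, and both can be
computed before any plate is poured:

1. **The final hydration level.** The droplet shrinks by vapor diffusion
   until its precipitant concentration matches the reservoir, so its
   endpoint volume is fixed by the amount of precipitant added:
   `V_f = V_s / d` for a screen aliquot of volume `V_s` diluted `d`-fold
   relative to the reservoir. With an effective endpoint water density
   `phi` (ug water per nl of equilibrated droplet), the hydration level of
   the monoolein/water system is

   ```
   w = 100 * (phi * V_s / d) / (phi * V_s / d + M)      [wt% water]
   ```

   for `M` ug of monoolein. Choosing `d` therefore targets a mesophase on
   the monoolein/water isotherm (Lc, L-alpha, Ia3d, Pn3m, Pn3m + excess
   water). The constant `phi` is recovered from reported expected
   hydration levels by a minimax calibration (`calibrate_phi()`).

2. **The Nernst partitioning of the protein.** With partitioning constant
   `K = C_lip / C_aq` (molality of protein per kg monoolein over molality
   per kg total water), conservation of protein gives the incorporated
   fraction

   ```
   f = K * M / (K * M + W)
   ```

   so removing water (`W` down) forces the protein into the mesophase.
   `K` is estimated from a sealed depletion assay (`estimate_K()`): wells
   are incubated with protein solution for 24 h and the supernatant
   concentration measured; `f = 1 - C_sup / C_0` inverts to
   `K = f * W / ((1 - f) * M)`.

On top of this the package builds pH-by-precipitant grid screens,
additive mixes (e.g. 10% (v/v) additive content), dilution series that
target chosen phases, full 96-well plate layouts with per-well hydration
and phase predictions, robot-ready worklist CSVs, and a synthetic-assay
generator with known ground truth for end-to-end testing.

## Worked example

Calibrate `phi` from the reported expected hydration levels of the
standard experiment (132 ug monoolein, 450 + 450 nl), then plan:

```r
library(cimplan)

obs <- data.frame(dilution = c(1, 2, 4, 7), hydration = c(75, 60, 43, 30))
fit <- calibrate_phi(obs, screen_volume = 450, mo_mass = 132)
fit
#> <phi_calibration> phi = 0.8826 ug/nl, max |residual| = 0.071 points

expected_final_hydration(droplet_spec(450, 450, 4), fit$params, 132)
#> <equilibrium_result> V_f = 112.5 nl, water = 99.29 ug, hydration = 42.93 wt% (~43%)
```

A 1:4 dilution of the screen leaves a 112.5 nl droplet whose ~43 wt%
water puts the system in the Pn3m cubic phase. Which dilutions target
which phases:

```r
dilution_series_for_phases(c("Pn3m_excess_water", "Pn3m", "cubic/lamellar"),
                           450, 132, snap = TRUE)
#>               phase target_hydration dilution_factor predicted_hydration
#> 1 Pn3m_excess_water             72.0               1            75.00000
#> 2              Pn3m             40.5               4            42.85714
#> 3    cubic/lamellar             30.0               7            30.00000
```

— the classic undiluted / 1:4 / 1:7 trio. Estimate an apparent K from a
(here synthetic, K_true = 50) depletion assay:

```r
assay <- simulate_partition_assay(synthetic_assay_spec(K_true = 50, seed = 42))
estimate_K(assay)
#> <K_estimate> apparent K = 48.99 (median of 8 replicates)
unlist(bootstrap_K_interval(assay, seed = 42))[1:2]
#>    lower    upper
#> 46.30427 50.37346
```

And lay out a full grid-screen plate with its protein budget:

```r
plate <- plan_plate(16, build_grid_screen(4.5, 8.5, 0.5, 4.0, 8, 12),
                    dilutions = 4)
plate
#> <plate_layout> mo132 format: 96 condition(s), 16 ug/ul protein (7.2 ug/well)
#>   d = 4     -> 43% hydration, Pn3m
protein_consumption(plate)
#> [1] 691.2
write_worklist(export_worklist(plate), "plate.csv")  # 288 dispensing steps
```

## See also

The methods vignette (`vignettes/cimp-planning.Rmd`) documents the model
assumptions, the calibration, the default mesophase boundaries, the
noise model of the synthetic assays, and known limitations.
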