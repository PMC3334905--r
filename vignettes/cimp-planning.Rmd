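---
title: "Designing controlled in meso phase crystallization experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing controlled in meso phase crystallization experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cimplan)
```

## The experiment being modelled

In controlled in meso phase (CIMP) crystallization a 96-well plate is
precoated with dry monoolein (132 ug, 29 ug, or 100 ug on a hanging-drop
foil). A protein solution drop is dispensed onto the coating and the lipid
swells into a cubic mesophase over ~3 h. A screening-solution aliquot —
undiluted or diluted relative to the reservoir — is then added, the
reservoir wells are filled with undiluted screening solution, and the
sealed plate equilibrates by vapor diffusion at 22 °C. The droplet loses
water until its precipitant concentration matches the reservoir; the
dehydrating mesophase concentrates the membrane protein into the lipid
bilayer, where crystals can nucleate.

The package turns the quantities a planner controls (volumes, dilution
factor, lipid mass, screen composition) into the quantities that decide
the outcome (final hydration level, targeted mesophase, fraction of
protein incorporated), and back.

## The equilibration mass balance

Only the precipitant added with the screen aliquot survives at the
endpoint: a `V_s` nl aliquot diluted `d`-fold carries `V_s C_R / d` moles,
and the droplet shrinks until its concentration is the reservoir's `C_R`,
so

$$V_f = V_s / d.$$

This is independent of the protein volume (that water simply leaves
through the vapor phase) and of the absolute value of `C_R`. The water
mass of the endpoint droplet is $\phi V_f$, where $\phi$ (ug water per nl
of droplet) is below 1 because the equilibrated droplet is a concentrated
precipitant solution; $\phi$ absorbs the solute mass fraction. The final
hydration level of the water + monoolein system is then

$$w = \frac{100\,\phi V_s/d}{\phi V_s/d + M} \quad [\mathrm{wt\%\ water}].$$

`w` is strictly decreasing in `d` and increasing in `V_s`; in the limit of
infinite dilution the system dries toward the lamellar crystalline phase,
and as `M` vanishes it tends to pure water.

**Calibration of $\phi$.** How reported "expected hydration levels" were
computed is not stated anywhere we know of, so the package makes the
assumption explicit: a single constant $\phi$, fitted by minimizing the
maximum absolute residual against reported (dilution, hydration) pairs
(`calibrate_phi()`, brute-force grid at 0.001 resolution plus local
refinement; closed-form inversion for a single pair). The minimax
criterion was chosen because the reported levels are integer-rounded — a
least-squares fit would let one heavily rounded value drag the constant.
For the standard dilution series the fit gives:

```{r calibrate}
obs <- data.frame(dilution = c(1, 2, 4, 7), hydration = c(75, 60, 43, 30))
calibrate_phi(obs, screen_volume = 450, mo_mass = 132)
```

$\phi \approx 0.88$ reproduces all four integer levels (before rounding:
75.0, 60.0, 42.9, 30.0). The package default is 0.88; it is a
configuration parameter, not a constant, since a different precipitant
implies a different solute mass fraction.

**Initial hydration** uses a pre-equilibration water density of 1.0 ug/nl
(the starting droplet is dilute): 900 nl on 132 ug gives 87.2 → 87 wt%.
One narrative source rounds the same setup to "86% water"; the package
follows the 87% convention of the reported initial levels and notes the
discrepancy here rather than modelling an unstated specific-volume
correction. Reported hydration levels are rounded half-up to integer
percent throughout.

**Assumptions.** Only the endpoint is modelled — no equilibration
kinetics, no oil-barrier diffusion control, no temperature dependence.
Protein-solution solutes are assumed to contribute no precipitant to the
mass balance.

## The mesophase map

`phase_map()` partitions the hydration axis into the monoolein mesophase
sequence at 22 °C: Lc below 4 wt%, L-alpha to 30, Ia3d to 37, Pn3m to 44,
and Pn3m + excess water above. These defaults are calibrated to how the
standard dilution series behaves in practice — 75% and 60% are
excess-water conditions, 43% is cubic (Pn3m), and 30% sits on the
cubic/lamellar transition — not digitized from a published isotherm, whose
exact boundary readings are not printed anywhere usable. In particular the
L-alpha/Ia3d boundary is placed at 30 wt% so that the 1:7 condition is
tagged as the boundary condition it is observed to be. A value within 1.5
percentage points of a boundary carries the boundary's name as a tag
(`classify_phase()`); the tolerance reflects that a condition reported as
"cubic/lamellar" is a boundary condition, and that the real diagram shifts
with protein, detergent, salt and additives, so the map is a targeting aid
rather than ground truth. Custom maps can be supplied as JSON
(`read_phase_map()`).

The inverse problem — which dilution reaches a hydration target — is
closed-form (`dilution_for_hydration()`), and
`dilution_series_for_phases()` assembles a series per phase. The target
for a phase is the midpoint of its interval on the 0–100 axis (a boundary
target uses the boundary hydration itself); midpoints wetter than the
undiluted endpoint clamp to `d = 1`, and phases lying entirely above the
reachable range are skipped with a warning. Snapping to the practical
pipetting grid {1, 2, 4, 7} is off by default in the functions and
recovers the classic undiluted / 1:4 / 1:7 trio:

```{r series}
dilution_series_for_phases(c("Pn3m_excess_water", "Pn3m", "cubic/lamellar"),
                           450, 132, snap = TRUE)
```

## The partitioning model

The protein is assumed monomeric in both phases with a Nernst constant
$K = C_{lip}/C_{aq}$. The package takes $C_{lip}$ per kg of monoolein and
$C_{aq}$ per kg of **total** water — all water, including the water inside
the mesophase, counts toward the aqueous pool, which is how a supernatant
measurement that includes mesophase water is naturally interpreted. The
exact basis behind published incorporation curves is not recoverable from
a figure; the convention is isolated in `fraction_incorporated()` so an
alternative (per kg of hydrated lipid phase) could be swapped. Protein
conservation gives

$$f = \frac{KM}{KM + W}, \qquad
  \frac{C_{sup}}{C_0} = (1 - f)\,\frac{V_p\,d}{V_s}.$$

For $K = 0$ and equal volumes the concentration ratio equals `d` — the
ideally-diluted limit that bounds what any experiment can reach. At 40 wt%
water on the standard coating, $K = 25$ gives 97.4% incorporation and
$K = 0.1$ gives 13.0%, which is why the usable regime is quoted as roughly
$K > 5$ (over 90% incorporated below 40 wt% water) versus $K < 0.2$ (under
30%). The model-level tests check these thresholds at K = 25 and K = 0.1
rather than at the regime edges K = 5 and K = 0.2, where the
molality-basis convention shifts the curve by about as much as the margin
itself.

**K estimation** inverts a sealed 24-h depletion assay
(`estimate_K()`): no reservoir, no vapor loss, so `W` equals the applied
volume at 1 ug/nl. Per replicate $\hat f = 1 - C_{sup}/C_0$ and
$\hat K = \hat f W / ((1-\hat f) M)$; the summary is the median over
replicates, robust to the two failure modes that are flagged rather than
hidden: a fully depleted supernatant (K unbounded above, reported `Inf`)
and a supernatant reading above the sample concentration (negative
depletion within noise, reported as 0 with a warning).
`bootstrap_K_interval()` adds a percentile bootstrap over replicates,
deterministic given its seed.

## The synthetic-assay generator

`simulate_partition_assay()` forward-computes the supernatant
concentration from a known `K_true` and perturbs each replicate with
multiplicative lognormal noise of configurable CV (default 5%,
representative of a photometric concentration readout), parameterized to
unit mean so the noiseless limit is exact. Seeds are explicit arguments
everywhere; there is no hidden global random state. What the generator
emulates is the statistical structure the estimator assumes — independent
replicates, multiplicative measurement error, exact forward model
underneath. What it does not emulate: slow or incomplete incorporation
within 24 h, detergent partitioning, aggregation, pipetting volume error,
or baseline drift of the photometer. Passing parameter-recovery tests
(median estimate within 10% of truth at CV 5%, n = 8, over 200 seeds)
therefore validates the inference machinery, not the biochemical
assumption that the apparent K is a constant of the protein.

## Plates, worklists, pipeline

`plan_plate()` crosses screening solutions (grid screens via
`build_grid_screen()`, additive mixes via `with_additive()`, which
replaces a volume fraction — default 10% v/v — of the base by additive
stock and rescales all concentrations) with a dilution scheme, assigns
wells row-major A1–H12, and stamps every well with volumes, protein mass,
predicted hydration and phase, and the protocol timeline (3-h swelling,
22 °C, weekly inspection — metadata, not simulation). The three supported
formats are 132 ug (450 + 450 nl, 75 ul reservoir), 29 ug (100 + 100 nl;
no reservoir volume is separately documented for this format, so it
defaults to 75 ul, configurable) and the 100 ug hanging-drop foil
(300 + 300 nl, 50 ul).

`export_worklist()` emits one dispensing row per reagent per well in
protocol order (protein → seal/swell → diluted screen → reservoir) as
plain CSV with integer nanoliter volumes — the lowest common denominator
for liquid-handler software. Each row carries the condition descriptors,
which makes `import_worklist()` an exact inverse; the round trip is tested
to byte identity.

`run_pipeline()` ties the stages together from a JSON configuration
(schema in `inst/schema/run-config.schema.json`, validated field-by-field
in R): build screens, convert hydration targets to dilutions if asked,
plan the plate, optionally estimate K from an assay CSV. Reports carry no
timestamp, so identical configuration and seed give byte-identical output.

## Numerical choices and problem sizes

Hydration and dilution inversions are closed-form (round trips hold to
1e-9 relative). The phi calibration grid spans (0.5, 1.1] at 0.001 with
local refinement to 1e-8. Half-up integer rounding matches how hydration
levels are conventionally reported. The test suite runs everything at desk
scale: the stochastic recovery check uses 6 true K values × 200 seeds × 8
replicates, and bootstrap intervals use 2000 resamples — a few seconds in
total.

## Limitations

The calculus is an endpoint model with a single-solute mass balance; it
does not model equilibration kinetics, sponge phases, temperature, lipid
doping, or the shift of phase boundaries by screen chemistry — exactly the
effects that make the empirical map a default rather than a prediction.
The apparent K is treated as a constant of protein, lipid and buffer;
measured values for one well-studied membrane protein span an order of
magnitude (roughly 13–130) across conditions, so planning should use a
measured K for the actual sample where it matters.
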