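# bilayertools

Analysis toolkit for molecular-dynamics trajectories of lipid bilayers
exposed to small-molecule solutes, aimed at membrane biophysicists studying
how solvents and fermentation inhibitors perturb bacterial membranes (e.g.
hopanoid-containing *Zymomonas mobilis*-like model bilayers). It computes
the standard structural, dynamic and permeation observables of such
simulations, and ships a synthetic-trajectory generator with exactly known
ground truth so that every estimator is validated by parameter recovery
rather than by eyeball.

## What it computes

For a trajectory of a bilayer (normal along z) with per-frame periodic box:

- **Area per lipid**: `APL = <Lx·Ly> / n_lipids_per_leaflet` (Å²),
  straight from the periodic box.
- **Membrane thickness**: `|<z_P>_upper − <z_P>_lower|` (Å), the
  phosphate-to-phosphate distance along the membrane normal.
- **C–H order parameter**: `S_CH = ½⟨3cos²θ − 1⟩`, θ the angle between
  each acyl C–H bond and the normal, pooled over pairs, lipids and frames;
  reported as `−S_CH`.
- **Lateral diffusion**: the trajectory is cut into consecutive 10 ns
  segments; per segment an OLS fit of the lateral MSD of lipid phosphorus
  gives `D_xy = slope/4`; the result is the mean over segments with its
  SEM across segments, in Å²/ns and cm²/s (1 Å²/ns = 10⁻⁷ cm²/s).
- **Free-energy profiles**: solute center-of-mass z histograms are
  Boltzmann-inverted, `ΔG(z) = −RT ln(p/p₀)`, with `p₀` referenced to bulk
  water; profiles can be folded about the midplane and aggregated over the
  six independent leaflets of three replicas (mean ± SD per |z| bin).
- **Permeability**: complete leaflet-to-leaflet crossing events are counted
  by a three-state (bulk–interior–bulk) automaton and converted to
  `Pm = N / (2·A·Δt·C)` (cm/s), with the bulk concentration measured from
  the trajectory itself. The inhomogeneous solubility–diffusion closed form
  `Pm = [∫ exp(ΔG/RT)/D dz]⁻¹` is available as an independent oracle.
- **Lateral mixing**: a grouped lipid enrichment/depletion index over
  nearest neighbours (classes HOP / sat / MU / PU), where 1 means random
  mixing.

Replica aggregation follows the convention of reporting the mean of
replica means with the SEM across replicas (`aggregate_replicas()`), and
analyses discard the leading 20 % of each trajectory as equilibration by
default (`select_window()`).

## Worked example

```r
library(bilayertools)

comp <- load_composition(system.file("extdata", "composition_wildtype.csv",
                                     package = "bilayertools"))
leaflet_total(comp)
#> [1] 100

spec <- synthetic_spec(n_lipids_per_leaflet = 100, n_frames = 400,
                       n_solutes = 10, dt = 0.05,
                       pmf = pmf_spec("flat"), seed = 5)
run <- assemble_trajectory(spec)
w    <- select_window(run$traj, analysis_config())
leaf <- assign_leaflets(w)

area_per_lipid(w, comp)$mean
#> [1] 64.09326
membrane_thickness(w, leaf)$mean
#> [1] 39.2952
order_parameter(w)$mean           # -S_CH
#> [1] -0.1397745

cfg <- analysis_config(segment_length = 5)
estimate_dxy(segment_msd(w, leaf, cfg), cfg)
#> <diffusion_result> D_xy = 1.624 +/- 0.16 A^2/ns (1.624 x 10^-7 cm^2/s), 3 segments
```

The numbers recover the generator's stated world (APL 64 Å², thickness
39.3 Å, S = 0.14, D = 1.61 Å²/ns) within sampling error — which is exactly
what the test suite asserts systematically.

A config-driven pipeline (`run_pipeline("config.json")`, CLI wrapper in
`inst/cli/bilayertools.R`) orchestrates all stages and writes tidy CSV
outputs plus a JSON run manifest; `delta_report()` builds the
with/without-hopanoid Δ-property comparison.

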