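---
title: "Membrane bilayer analysis: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane bilayer analysis: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`bilayertools` analyses molecular-dynamics trajectories of flat lipid
bilayers with small-molecule solutes, and generates synthetic trajectories
with exactly known ground truth to validate every estimator by parameter
recovery. This vignette is the package's own account of the science: the
models, their assumptions, the tunable parameters, and the limits of what a
green test establishes.

## Geometry and shared conventions

The membrane normal is the z axis throughout; no instantaneous-normal
fitting is attempted, which is appropriate for flat bilayers but not for
vesicles or strongly undulating membranes. The bilayer midplane is defined
per frame as the mean z of all lipid phosphorus atoms — not the box centre —
so that whole-membrane drift along z cancels out of every z-referenced
quantity.

Leaflet membership is frozen at a reference frame (by default the first
analysis frame): a lipid is "upper" if its head marker sits above the
midplane there, and keeps that label even if it later crosses; such events
are logged as flips rather than reassigned. This matches the treatment of
leaflets as fixed populations when aggregating "six independent leaflets"
from three replicas. Lipids without phosphorus (hopanoids) participate
through a designated polar-end marker particle; the marker choice is a
package convention, since head-group assignment for tail-less lipids has no
universal rule.

Equilibration is removed as a *fraction* of the trajectory
(`equilibration_fraction`, default 0.2, i.e. the last 800 ns of a 1000 ns
production run) rather than an absolute time, so scaled-down test
trajectories exercise the identical code path. With `n` frames the leading
`floor(n * fraction)` are dropped; because `floor(n*f) < n` for any
`f < 1`, an empty window cannot arise from a valid fraction, and the guard
sits on the fraction itself.

Replica statistics follow the mean-of-replica-means convention: each
replica is reduced to its own mean first, and the reported uncertainty is
the standard error across replica means, never across pooled frames
(`aggregate_replicas()`). Pooled-frame SEMs would understate the error by
ignoring the strong temporal correlation within a replica.

## Structural metrics

*Area per lipid* is `Lx·Ly / n_leaflet` per frame. The denominator is the
full leaflet molecule count including hopanoids (100 for the packaged
compositions). The alternative — dividing by phospholipids only — would
inflate APL by 2x for the 50 % hopanoid leaflet; we follow the
overall-area convention and note that the choice is a label, not a model.

*Thickness* is the distance between mean phosphorus z of the two leaflets;
it is invariant under rigid translation and under relabelling of the
leaflets (absolute value).

*Order parameter*: `S_CH = 0.5 * <3 cos^2(theta) - 1>` with theta between
each acyl C–H bond vector and z, pooled over all tagged pairs, lipids and
frames; the headline number is `-S_CH` as conventionally plotted. Carbonyl
and head-group C–H bonds are excluded by the role specification at load
time. Per-pair means are kept as a secondary output for depth-resolved
(NMR-style) comparison. Zero-length bond vectors (a degenerate topology)
are skipped with a warning rather than poisoning the average.

## Lateral diffusion

The trajectory is divided into consecutive, non-overlapping segments of
`segment_length` (default 10 ns). Within each segment the lateral MSD of
phosphorus atoms is computed relative to the segment's first frame, and an
ordinary least-squares fit of MSD on lag over the full segment gives
`D = slope/4`. The headline value is the mean over segments, with SEM
across segments. Three numerical choices deserve note:

- The regression includes an intercept. Short-time displacement is not
  purely diffusive (bond vibrations, cage rattling in real data); an
  intercept absorbs that offset instead of biasing the slope.
- Lateral coordinates are unwrapped by minimum-image increments between
  consecutive frames; an increment exceeding half the box after folding
  means the sampling interval is too coarse to unwrap unambiguously and is
  a hard error, not a silent guess.
- Per-leaflet centre-of-mass drift is removed per frame (default on,
  toggleable). For `N` independent walkers this removes a `1/N` share of
  the signal, a bias well below the 5 % acceptance band at the tested
  sizes.

A per-segment log–log exponent flags non-diffusive transport
(`alpha > 1.5` marks ballistic-like segments). The unit identity
1 Å²/ns = 1e-7 cm²/s is applied exactly, never via a rounded constant.

## Partitioning and free-energy profiles

Solute centre-of-mass z positions (midplane-referenced) are histogrammed
with uniform bins (`bin_width_z`, default 1 Å — the histogram width is a
package default, chosen fine enough to resolve interfacial wells a few Å
wide yet coarse enough that well-sampled demo tracks occupy every bin).
Bins are laid out symmetrically about z = 0 so folding maps bins onto bins
exactly.

Boltzmann inversion uses `dG = -RT ln(p/p0)` with `R = 1.987204e-3`
kcal/(mol K). The reference `p0` is the *mean* probability over all bulk
bins (|z| beyond `bulk_cutoff_z`, by default thickness/2 + 10 Å, recomputed
per system and logged) rather than a single reference bin: averaging the
bulk plateau reduces reference noise without changing the expectation; a
single-bin mode is available for strict comparability. Zero-count bins are
masked as undefined — never clamped to an arbitrary large energy — and
barrier heights are reported over defined bins only.

Folding: each full-z profile contributes two one-sided leaflet profiles
(z > 0 and z < 0 mapped to |z|), so three replicas give six leaflets; the
folded output is the per-|z|-bin mean and standard deviation across
leaflets. The SD across leaflets and the SD across time frames answer
different questions (replica-to-replica variability vs temporal
fluctuation); the package reports the leaflet SD in the folded profile and
leaves frame-wise SDs to the per-frame series outputs, labelling both.

## Permeability

Crossing events are detected by a three-state automaton per solute: upper
bulk (z above the instantaneous mean upper phosphate plane plus
`crossing_margin`), interior, lower bulk. An event is a transition from one
bulk to the other, however long the interior dwell; re-entries count
nothing. The margin default (5 Å beyond the phosphate plane) places the
bulk boundary past the head-group region so that interfacial sorption is
not mistaken for a crossing; a margin reaching the water-slab midpoint is a
configuration error.

One subtlety is deliberate: under a periodic z box the two bulk slabs are
a single contiguous water compartment, connected through ±Lz/2. A solute
whose minimum-image step wraps through that boundary has moved through
water, not through the membrane, and is never counted. Ignoring this would
overcount crossings in any trajectory whose solutes explore the full water
slab.

The coefficient is `Pm = N / (2 A Δt C)`: `A` the time-averaged lateral
area, `Δt` the aggregate analyzed time (full per-replica trajectories by
default, matching event counting over complete production runs), `C` the
time-averaged bulk concentration counting whole solute centres in the bulk
slabs (no partial-volume weighting). With `N = 0` the point estimate is 0
and the one-crossing upper bound `1/(2AΔtC)` is reported instead of a
meaningless log10.

As an independent check, the inhomogeneous solubility–diffusion closed form
`Pm = [∫ exp(dG/RT)/D dz]^-1` (`pm_isd()`), integrated between the two
bulk boundaries, is computed by quadrature from the analytic PMF. The
counting estimate and the ISD value are two different routes to the same
quantity and are compared, never substituted for one another.

## Lateral mixing

The grouped enrichment index uses four classes: HOP (hopanoids, by head
group) and sat/MU/PU phospholipids (by tail class). Neighbours are
molecules of the same leaflet within a 12 Å lateral minimum-image cutoff of
the reference marker; 12 Å is a package default spanning the first
coordination shell at ~64 Å² per lipid (the upstream tool convention the
index follows does not state its cutoff; a Voronoi construction is the
main alternative and is out of scope). The index is the frame-averaged
fraction of class-j neighbours around class-i references divided by the
bulk fraction of j, with the reference excluded from its own bulk
denominator (`(N_j - δ_ij)/(N - 1)`). This self-exclusion makes the random
arrangement index exactly 1 in expectation, and the row identity
`Σ_j f_j|i E_ij = 1` holds by construction — both are asserted in tests.

On the classification itself: the packaged wild-type table resolves an
internal inconsistency in its source between lipid codes and long names by
following the codes, except for PYPE where the polyunsaturated reading is
required for the PU class to be non-empty (counts per leaflet: HOP 50,
sat 10, MU 36, PU 4). A species with any fully saturated chain is "sat",
all-monounsaturated is "MU", any polyunsaturated chain is "PU".

## The synthetic generator: a stated world

The generator emulates exactly the statistical structure the estimators
assume, with defaults set to the production conditions: 100 molecules per
leaflet, APL 64 Å² (per-frame SD 1 Å²), thickness 39.3 Å (per-lipid
phosphorus SD 0.5 Å), lipid D 1.61 Å²/ns, pooled order parameter 0.14,
300 K, and solutes started in the water phase. Components:

- **Lateral lipid tracks**: independent 2-D Brownian walks, per-step
  per-axis variance `2 D dt`, wrapped and unwrapped coordinates both kept.
- **Box and phosphates**: per-frame APL drawn `N(target, sd)` and converted
  to box lengths at fixed aspect ratio; per-lipid phosphorus z drawn about
  ±thickness/2. Frames are independent (no barostat autocorrelation).
- **Chain vectors**: a two-component mixture — a fixed-angle component
  (θ = 0 for S ≥ 0, θ = 90° for S < 0) and an isotropic component — with
  analytic weight `S / P2(θ0)`, so the target second Legendre moment is
  exact in expectation; no rejection sampling, azimuths uniform.
- **Solute tracks**: 1-D overdamped Langevin (Euler–Maruyama) in a
  specified PMF, `z' = z - (D/RT) dG' dt + sqrt(2 D dt) ξ`, periodic in z.
  The stationary density is `exp(-dG/RT)/Z`, which is what Boltzmann
  inversion must recover; the sidecar records the analytic PMF and the ISD
  permeability. Solute motion is 1-D because every downstream quantity
  here depends only on z statistics. A stability guard warns when the
  diffusive step exceeds one fifth of the PMF width.
- **Lateral types**: random mode assigns class labels by permutation
  matching the composition counts with uniform positions (the ideal-mixing
  null); segregated mode lays classes in disjoint strips separated by a
  gap, forcing cross-class indices to 0 below-gap cutoffs.

Every generator draws from a sub-stream derived from one master seed, so a
whole assembled trajectory (and its JSON ground-truth sidecar) is
bit-reproducible from the seed.

What the generator does **not** emulate — and hence what a green recovery
test does not establish: force-field realism, lipid internal dynamics and
chain correlations, solute–lipid chemistry, temporal correlation of box
fluctuations, position-dependent solute diffusivity, and any coupling
between solute concentration and the PMF. Recovery tests certify the
estimators, not the physics of any particular membrane.

## Numerical and design choices

- Trajectory I/O is implemented natively (PDB topology / multi-model PDB /
  CHARMM-style binary DCD with per-frame unit cells and the time step in
  the header) because no suitable reader ships with the supported
  dependency set; the DCD dialect was cross-validated against a reference
  MD analysis library during development. A missing unit cell in any frame
  is a hard error — APL is undefined without it.
- Frame spacing must be uniform within 1 % jitter; worse spacing is a
  non-uniform-sampling error rather than a silent resample.
- C–H pairing on file load is by nearest carbon within 1.3 Å at the first
  frame; synthetic topologies space carbons ≥ 3 Å apart so the pairing is
  unambiguous after coordinate round-trips.
- The MSD fit spans the full segment by default (the procedure's stated
  convention); a `lag_window` option exists for sensitivity analysis
  because the earliest lags are the most ballistic-contaminated in real
  data.
- Histogram boundary convention: bins are left-closed; a sample exactly on
  an edge belongs to the upper bin.
- The pipeline's mixing stage requires synthetic input, since loaded
  trajectories carry no species-to-class mapping in the supported topology
  formats.

## Known limitations

Single flat bilayer only (no curvature, no instantaneous normal); no
per-species APL decomposition; no finite-size (Saffman–Delbrück) or
rotational-diffusion corrections; no umbrella sampling / WHAM — equilibrium
occupancy inversion only, which needs well-sampled barriers; no
transition-path or Markov-state kinetics; enrichment analysis offers a
cutoff criterion only. Figure-derived barrier readings from visual
inspection of published profiles are treated as qualitative context, not as
numeric ground truth, anywhere in the tests.
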