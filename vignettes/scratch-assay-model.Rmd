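---
title: "The scratchsim model: rules, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The scratchsim model: rules, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`scratchsim` is an agent-based simulator of the 2-D scratch (wound-healing)
assay for glioblastoma cell lines whose motility and proliferation are
stimulated by an autocrine/paracrine ligand — the cleaved ectodomain of the
adhesion molecule L1CAM — acting through integrin (A) and FGFR (B) receptor
pathways that converge at FAK (C). This vignette is the package's own
account of the model: its assumptions, the parameters that matter, the
numerical choices, and what the simulation does and does not capture.

## The model

The world is a bounded, non-wrapping grid of patches. One tick is one
simulated minute (60 ticks = 1 h); one patch edge is `patch_scale`
micrometers (default 20, roughly one cell diameter). Cells and ligand
molecules live at continuous positions; a patch's cell/ligand count is the
number of agents rounding into it. Those counts are refreshed once per tick
and form the frozen density field every agent decision reads.

Biological assumptions carried over from the experimental system: no cell
death; all cells express the ligand precursor; uniform cell size; monolayer
cells are confined by crowding (and, for adherent lines, by intercellular
adhesion) but do not pile up; cells at a free edge cleave the precursor,
lose adhesion, and are maximally self-stimulated by their own released
ligand, so ligand density does not further modulate speed and there is no
chemotactic gradient response; released cells keep releasing.

### Initialization

`cell_capacity()` fills the area strictly left of the scratch line at a
near-confluent `confluent_density` (0.9 cells/patch). Cells are placed one
per patch (jittered within the patch) and get: pathway values `A`, `B`
drawn uniformly within `deviation_from_avg` of their inhibition-determined
ceilings, and a uniform-random position in the cell cycle, which makes the
expected initial phase occupancy proportional to the phase durations. Cells
in the column abutting the scratch line turn green: they are the released,
tracked cohort that the motility monitor reports, mirroring how edge cells
are tracked experimentally.

### Motility and the convergence point

Each pathway transmits a linear interpolation between the uninhibited rate
`u` and a base rate measured in single-knockout experiments:

* `cap_A = u - i_B (u - base_A)` — `base_A` is the speed through integrin
  *alone*, i.e. with FGFR fully blocked, so B-inhibition interpolates toward it;
* `cap_B = u - i_A (u - base_B)` — symmetrically;
* `cap_C = u - i_C (u - base_C)` — the convergence point degrades with its
  own inhibitor.

The effective motility is `mu = min(cap_A, cap_B, cap_C)`. A convergence
point can plausibly be modeled as taking the *maximum* of the upstream
responses or as being limited by the *minimum* of all three ceilings; the
two readings conflict once an upstream arm is blocked. We implement the
minimum-of-ceilings form because it is the only one consistent with the
definition of the base motilities (each is the measured speed with the
*other* receptor blocked) and with the knockout endpoint speeds: with B fully inhibited the reported speed is `base_A` (0.15
um/min), with A fully inhibited it is `base_B` (0.13), with C fully
inhibited it is `base_C` regardless of the upstream arms.

Per-cell fluctuation: each tick, with 50% probability, `A` and `B` each
move by an independent Uniform(-v, +v) increment (`v = deviation_from_avg`)
and are clamped to the symmetric window [cap - v, cap + v]. A cell's
signaling readout is `mu = min(caps) + (fluct_A + fluct_B)/2`; being
symmetric and zero-mean, the fluctuations spread the reported average
without biasing it. The readout may transiently dip below zero under heavy
inhibition with large `v`; the *realized* speed is `max(0, mu)`. Clamping
the readout itself at zero would inflate the reported mean under full
inhibition — precisely why the interface's `motility_check` switch (which
clamps the reported value at zero) defaults to off.

### Movement

Per tick and per cell, in order: (1) if the patch behind (west) holds more
than two cells the cell steps east to relieve the pile-up; else (2) if no
neighboring patch is below the crowding threshold (2 cells/patch) the cell
waits; else (3) with probability `randomness` it steps at a uniformly
random angle, otherwise toward the least dense of its 8 neighboring patches
(ties uniform at random). The step length is `sqrt(2) * mu * dt` patch
units with `dt = 1/(sqrt(2) * patch_scale)`, so the physical per-tick
displacement equals `mu` um/min exactly. Walls are impassable on three
sides; a cell reaching the rightmost column ends the run early.

### Cell cycle and proliferation

The mean inhibited fraction `a = (i_A + i_B + i_C)/3` drives proliferation:
the S-phase percentage interpolates linearly from `pct_S_base` (28) to
`pct_S_max_inhibition` (8), and the whole cycle stretches by
`1 / max(1 - a, prolif_floor)` so division slows under inhibition and stops
(20-fold stretch, with the default floor 0.05) at full inhibition. M phase
has a fixed duration of `m_phase_fraction` (5%) of the *uninhibited* cycle;
the non-S non-M remainder splits equally between G1 and G2 at zero
inhibition; the inhibition-induced change in S is absorbed by G1 when
`s_phase_to_g1` is on, else by G2. Phase boundaries are rounded to whole
ticks with the remainder assigned to G1, so spans always sum exactly to the
cycle total; a cycle of fewer than 5 ticks is rejected as degenerate. On
the last tick of the cycle the cell divides if an adjacent patch is below
the crowding threshold; the daughter takes the lighter parental color,
inherits the parent's pathway values and released state, and both restart
at cycle 0. A blocked division simply restarts the parent.

### Ligand release and movement

A cell strictly past the scratch line with fewer than two cells in the
patch ahead releases: blue/periwinkle turn red/orange and hatch exactly 4
molecules; thereafter each released, unblocked cell past the line sheds
1-4 molecules with 5% probability per tick. Molecules step `ligand_speed`
(0.25) patch units per tick, randomly with probability `l_randomness`
(default 0.2) and otherwise toward the neighboring patch with the most
cells, which keeps them clustered around the cells they stimulate. Ligands
never decay; `max_ligands` (default unbounded) caps pathological settings.

### Adhesion

When `cellular_adhesion` is on, links are rebuilt every tick between all
pairs of unreleased cells within `adhesion_radius` (1.5 patches). Each link
displaces both endpoints by `spring_constant * (distance - rest_length)`
along the connecting line, equal and opposite, with each cell's total
spring displacement capped at its per-tick step. Released cells carry no
links; a red cell that wanders back into the crowded monolayer (with
adhesion on) reverts to blue and re-links; green-lineage cells never
revert. Rebuilding is quadratic in the monolayer size, so adhesion runs are
much faster with the scratch line shifted left (the `adhesion-on` preset
uses x = -26).

## Monitors

`collect_frame()` reports, per tick: counts per color class, cleaved
(released) vs uncleaved cells, ligand count, phase counts and the realized
%S, the theoretical %S for the inhibition settings, and the reported
average motility — the mean signaling readout `mu` over the *original*
green cohort, daughters excluded, matching how tracked-cell velocities are
averaged experimentally. A separate `realized_speed` column gives the
cohort's mean kinematic displacement for users who want ground truth.
`interval_average_motility()` resamples the reported series at 1-, 5- or
10-minute intervals; for the unbiased reported series the three means agree
within Monte Carlo error, as they do for experimental tracking at different
imaging intervals.

A design note: we considered adding an independent per-frame noise draw on
the reported average (one reading of the interface's deviation control).
Frame-level noise of that magnitude would make the interval means disagree
by more than their Monte Carlo error and bias nothing else; the per-cell
fluctuation already yields the observed spread while keeping the cohort
mean centered, so the reported value carries no extra display noise. A
consequence worth knowing: the reported *cohort* average essentially never
goes negative (individual cells' readouts can), so runs with heavy
inhibition and large deviation will not show the occasional negative
average readings that single-trace displays can produce.

## Parameters at a glance

| parameter | default | units | meaning |
|---|---|---|---|
| `uninhibited_motility` | 0.23 | um/min | speed with all pathways open |
| `base_motility_A/B/C` | 0.15 / 0.13 / 0.13 | um/min | single-knockout speeds |
| `inhibition_A/B/C` | 0 | fraction | inhibited fraction per pathway |
| `pct_S_base`, `pct_S_max_inhibition` | 28, 8 | % | S-phase share at the two extremes |
| `doubling_time_hours` | 24 | h | uninhibited cycle length |
| `randomness` | 0.10 | fraction | random-walk vs density-directed steps |
| `deviation_from_avg` | 0.3 | um/min | fluctuation half-width |
| `l_randomness`, `ligand_speed` | 0.2, 0.25 | fraction, patches/tick | ligand motion |
| `scratch_line` | 0 | patch x | scratch position (world x range -32..32) |
| `time_scale_hours` | 24 | h | run length (1-72) |
| `world_width/height`, `patch_scale` | 65, 33, 20 | patches, um | geometry |
| `confluent_density`, `crowding_threshold` | 0.9, 2 | cells/patch | crowding model |
| `rest_length`, `spring_constant`, `adhesion_radius` | 1, 0.2, 1.5 | patches, -, patches | adhesion springs |
| `m_phase_fraction`, `prolif_floor` | 0.05, 0.05 | - | cycle bookkeeping |

Values with an experimental origin (motilities, S-phase percentages,
doubling time, deviation, randomness) are the T98G settings; the geometric
and bookkeeping constants are package choices, stated once here and
configurable. The `pct_decrease_A/B/C` controls are an equivalent
alternative parameterization of the base motilities
(`base = u (1 - pct/100)`); exactly one form may be supplied per pathway.

## Numerical and implementation choices

* **Synchronous vectorized ticks.** All agent decisions within a tick read
  the density field frozen at the tick's start (as the original go-loop's
  once-per-tick density update implies), so the update order of agents has
  no behavioral effect and the package updates all agents as vectors. Runs
  are bitwise-reproducible from `(params, seed)`.
* **Ties** (least-dense or most-dense neighbor) break uniformly at random.
* **Rounding**: phase boundaries round half-up with the remainder to G1;
  patch membership rounds to the nearest patch center.
* **Degenerate inputs**: a scratch line at the left edge yields a zero-cell
  world (warning, and the run halts on the extinction guard); cycles under
  5 ticks and negative phase spans are validation errors naming the field.
* **Determinism**: a single R RNG stream seeded at initialization; the CLI
  and all documented runs use explicit integer seeds, never wall-clock.

## What the simulation does and does not show

Test scenarios in this package run the full default world (65 x 33 patches,
950 cells, 24 h) for the endpoint checks and smaller worlds or shorter
horizons (1-6 h, scratch line shifted left) for structural properties;
those sizes give comfortable statistical margins for every documented
check. Passing them shows the rule set reproduces the configured endpoint
speeds, the interval-invariance of the reported average, S-phase occupancy
tracking its linear target, doubling-time demography, inhibition
monotonicity, and adhesion confinement — on simulated data generated by
these same rules. It does not validate the rules against new wet-lab
measurements, and several real-data features are deliberately outside the
model: chemotaxis up ligand gradients, receptor occupancy kinetics, ligand
decay, cell death and senescence, cell shape and size variation, and any
third dimension. The model is a 2-D culture abstraction; extending it to
paracrine-only responder populations or gradient-following cells would
require new rules, not new parameters.
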