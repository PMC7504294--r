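---
title: "Stochastic simulation of antibody labeling of CD4 receptors: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic simulation of antibody labeling of CD4 receptors: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mabsim)
```

## The scientific problem

Flow cytometry quantifies surface receptors by staining cells with
fluorophore-conjugated monoclonal antibodies (mAbs) and converting the
mean fluorescence intensity (MFI) into antibodies bound per cell
(ABC).  CD4^+^ T cells are the workhorse calibration system because
healthy donors carry a reasonably constant number of accessible CD4
receptors (~100,000 per cell).  Besides the mean, a cytometer reports
the coefficient of variation of the fluorescence signal (CV%, defined
as 100 x SD/mean).  Interpreting that CV% biologically requires
knowing how much variability the *labeling reaction itself*
generates: how much spread in ABC is intrinsic to the stochastic
binding kinetics, how much comes from cell-to-cell variation in
receptor number, and how much from cell-to-cell variation in binding
affinity.

`mabsim` answers this with an exact stochastic (kinetic Monte Carlo)
simulation of one cell's labeling reaction, repeated over a
population of cells with per-cell parameter heterogeneity.

## The model

### Compartments and species

Space around a spherical T cell (radius ~3.75 um) is partitioned into
three concentric shells, each 3.75 um thick:

* the **transition layer** (count `A_s`), in diffusive contact with the
  bulk suspension;
* the **boundary layer** (`A_b`);
* the **cell layer** (`A_c`), adjacent to the membrane.

On the surface, antibody can be nonspecifically **adsorbed** (`A_o`),
bound **monovalently** to one receptor (`AR`), or bound **bivalently**
across two receptors (`ARR`); `R` counts free receptors.  ABC, the
quantity a cytometer sees, is `AR + ARR` — each bound antibody carries
one label regardless of valence.

Five reversible steps (ten reaction channels) connect the states:

```
A_s <-> A_b <-> A_c <-> A_o ;  A_o + R <-> AR ;  AR + R <-> ARR
```

Diffusive transfer of one molecule between adjacent shells occurs at
rate `D/h^2`, with `D = 0.5e-10 m^2/s` the free-solution antibody
diffusion coefficient and `h` the thickness of the shell being left
(`D/h^2 = 3.56 /s` at the defaults; the table that defines the
cell-to-boundary rate uses an `h` symbol that is not defined
elsewhere, and all shells are equally thick, so the package uses
`D/h_c^2` — numerically immaterial).  Adsorption is perfect
(`k_on = D/h_c^2`: every arrival sticks) and desorption is
`k_off = 0.5 k_on`, which keeps the adsorbed pool ample (~6000 at
equilibrium, twice the cell-layer count) without depleting adsorption
sites; sites are treated as unlimited, so `A_o` has no capacity cap.
The four binding constants are stochastic rates in 1/s — per molecule
for the dissociations (`k_mn`, `k_bn`), per *pair* for the
associations (`k_mp`, `k_bp`), applied directly to counts or count
products with no volume conversion.

Two boundary conditions define the canonical scenarios:

* **Labeling**: `A_s` is pinned at 3000 molecules — the transition
  shell's content at a saturating bulk concentration of 1 umol/m^3
  (volume x concentration x Avogadro ~ 2,867, rounded to 3000).  The
  source channel fires at `k_2p * A_s` without depleting `A_s`.
* **Post-labeling wash**: the cell is resuspended in antibody-free
  buffer; `A_s = 0`, so the outermost hop drains molecules
  irreversibly to an effectively infinite bulk.

### The event loop

The engine is the classical direct-method stochastic simulation
algorithm.  At each step the ten propensities are computed
(`alpha_j = k_j x` reactant count or count product), the waiting time
is drawn as `tau = ln(1/u1) / sum(alpha)` with `u1` uniform on (0,1]
(an exact zero is resampled so `tau` stays finite), the channel is
the first whose cumulative propensity fraction exceeds a second
uniform `u2` (zero-propensity channels occupy zero-length segments
and can never fire), and the channel's column of the change matrix is
added to the count vector.  Counts are exact integers throughout, so
the conservation law `R + AR + 2*ARR = const` holds bit-exactly at
every event, and `sum(alpha) = 0` is recognised as an absorbing
state.

The loop is compiled (Rcpp); a pure-R reference loop
(`ssa_run(..., engine = "R")`) consumes the identical random-number
stream — including matching long-double accumulation of the
propensity sums — and reproduces the compiled trajectory bit for bit
under the same seed.  The suite verifies this equivalence, so the
fast path is validated against the transparent one on every run of
the tests.  A full labeling run generates about 2 x 10^6 events
(total propensity ~10^5 /s over tens of seconds), which the compiled
loop completes in well under a second.

Trajectories are recorded on a snapshot grid (default: 300 uniform
points; a logarithmic grid for the wash run, whose inter-event times
span from ~10^-10 s during the initial desorption churn to seconds in
the late dissociation era).  Per-event logs are opt-in because of
their size.  A `max_events` cap (default 10^8) guards against runaway
parameter sets and flags the trajectory as truncated.

## Canonical rate sets and scenarios

Binding-rate presets (1/s):

| preset          | k_mp   | k_mn  | k_bp           | k_bn  | regime |
|-----------------|--------|-------|----------------|-------|--------|
| `similar`       | 1e-4   | 1e-6  | 2e-6           | 1e-8  | comparable AR and ARR |
| `ar_dominant`   | 2e-4   | 1e-6  | 1e-7           | 1e-9  | mostly monovalent |
| `arr_dominant`  | 1e-4   | 1e-6  | 2e-4           | 1e-8  | mostly bivalent |
| `cluster_two_point` | 1e-4 | 1e-6 | {1e-7, 1e-6} per cell | 1e-9 | receptor clustering |
| `lognormal_kbp` | 1e-4   | 1e-6  | 10^N, N~N(-6.5,0.5) per cell | 1e-8 | continuous affinity spread |

The labeling run starts from a bare cell (`R = 100,000`, everything
else 0) and shows the canonical structure: layer populations climb
while binding consumes the incoming flux; once the receptors saturate
(`R = 0`), `AR` and `ARR` freeze and the transport layers relax to
their equilibrium (~3000 per shell, ~6000 adsorbed).  Bound receptors
then satisfy `AR + 2*ARR = 100,000` exactly — the conservation
identity, not an approximation.

### Choice of horizons

Two horizons matter and they are deliberately different:

* The single-run labeling scenario defaults to `t_end = 30 s`, the
  usual plotting horizon for the transport transient.
* Population ensembles default to `t_end = 60 s`.  The equilibrium
  readout is the final state of the run, and the readout must be taken
  *at saturation*: with the default rates the slowest canonical branch
  (`k_bp = 1e-7`) still carries ~7,500 free receptors at 30 s, and
  reading an unsaturated state biases both the means and the CV% of
  the population tables.  Every preset saturates well before 60 s, and
  because a real incubation lasts ~30 min while the state is frozen
  after saturation, any horizon past saturation reads the same
  stationary values.  (The suite verifies horizon-independence of the
  equilibrium readout implicitly: bound-receptor conservation is exact
  and the saturated state is absorbing up to slow AR/ARR exchange.)

The wash scenario continues from a labeled state for `3e4 s`.  Its
signature behaviour, which the suite asserts, is that ABC is
quasi-conserved (within a few tenths of a percent over two hours):
`AR` and `ARR` keep exchanging antibody between themselves while net
loss to the bulk is throttled by the slow dissociation rates.

## The population ensemble and CV%

An `ensemble_spec` draws per-cell parameters once, deterministically
from a master seed (receptor count, `k_bp`, and one independent
simulation seed per cell), so results are a pure function of the spec
regardless of execution order.  The canonical studies, in increasing
order of heterogeneity, are exposed as `preset_ensemble()`:

* `table4` — everything fixed: measures the *intrinsic* stochastic
  spread of ABC.  It is tiny (CV% ~ 0.1) because at saturation
  `AR + 2*ARR` is pinned exactly, which anticorrelates `AR` and `ARR`:
  the sum `AR + ARR` can fluctuate only as much as `ARR` alone.
* `table5_*` — receptor count `~ Normal(100,000, CV 6%)`: ABC tracks
  the receptor count nearly linearly, so the receptor CV% propagates
  into ABC with a transfer ratio slightly below 1 (the bivalent
  fraction grows with R).
* `table6`/`table7` — per-cell bivalent affinity (two-point or
  log-normal exponent): the monovalent/bivalent mix now differs
  between cells, and since all-monovalent binding yields ABC = R while
  all-bivalent yields ABC = R/2, affinity spread produces a much
  larger ABC CV% (~11) even though each cell's own reaction noise is
  negligible.

Design choices that were genuinely open:

* the two-point affinity model assigns the high value with probability
  0.5 (the split is exposed as a parameter);
* CV% uses the sample (n-1) standard deviation — visible at the ~2%
  level with 25 cells — and is computed from the same per-cell table
  for every column;
* truncated cell runs are kept with a warning by default (configurable
  to error), flagged per cell;
* 25 cells per ensemble is the canonical study size; the acceptance
  checks use it unchanged, which sets the sampling tolerance of a CV%
  estimate at roughly 14% relative (1 SE).

## The mean-field oracle

`ode_rhs()`/`mean_field_run()` integrate the deterministic mass-action
mirror of the ten propensities with a stiff solver (`deSolve::lsoda`;
rate scales span ~1e-8 to 1e5 1/s; relative tolerance 1e-8, receptor
conservation monitored to 1e-6 relative).  This is an engineering
validation tool, not part of the scientific claim: ensemble means of
the jump process should agree with the ODE at these molecule numbers,
and the suite asserts agreement within three standard errors at ten
checkpoints for all three binding presets (25 seeds each).  The ODE
carries no fluctuation information, so SD and CV% are never validated
against it.

## What the simulation does and does not emulate

The generator reproduces the idealised study conditions: a single
spherical cell in a quiescent, saturating antibody bath with purely
diffusive transport, unlimited adsorption sites, and at most two
sources of cell-to-cell heterogeneity.  Passing tests therefore
demonstrate correctness of the simulator and reproducibility of the
idealised population statistics — not agreement with any particular
wet-lab measurement.  Real samples add effects outside this model:
cell sedimentation and antibody depletion at low label concentrations,
hydrodynamic mixing, cell-size variation (touched only via the
desorption-rate sensitivity scan, which shows equilibrium ABC shifts
of at most ~1.5% for `k_off/k_on` between 0.4 and 0.6, shrinking as
the run is extended), receptor clustering geometry, and all
fluorescence-detection noise.  Mapping ABC to MFI and modelling the
detector are explicitly out of scope.

## Numerical notes and limitations

* Waiting times use `-log(u1)/total`; `u1 = 0` is resampled.  Channel
  selection uses strict cumulative comparison with a rounding guard
  that can never fire a zero-propensity channel.
* Snapshots record the state in force at each grid time (the last
  state before the first later event); the final state persists onto
  any remaining grid points after absorption or truncation.
* The plateau detector (`detect_equilibrium`) centres its tolerance
  band on the mean of the trailing observation window rather than the
  single last snapshot; with counts of ~3000 and Poisson-scale noise,
  an end-point-centred band fails stochastically.  With the default
  5% band and 5 s window, the transport layers of the default
  labeling run settle at ~30 s; figure-based readings of the same
  transient tend to call it a few seconds earlier, because the traces
  are within ~15% of the plateau well before they enter a 5% band.
* The model's intrinsic ABC spread at fixed conditions reads
  CV% ~ 0.11 at the printed rate constants (the suite tracks the
  published 0.08 and flags the difference); the published range
  69,050-69,300 for 25 replicates is consistent with the larger
  value.
* Per-pair association rates multiply count *products*, so propensity
  magnitudes reach ~10^4-10^5 /s; the compiled loop accumulates them
  in long double precision to keep the two engines bit-compatible.
* Scaled-down systems (e.g. `R0 = 2000`, `A_s = 100`) are used in the
  structural unit tests where only invariants matter; all population
  statistics and acceptance checks run at full scale
  (`R0 = 100,000`, `A_s = 3000`, 25 cells).
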