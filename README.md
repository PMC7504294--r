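# mabsim

Stochastic reaction–diffusion simulation of monoclonal-antibody (mAb)
labeling of CD4 receptors on T cells, and of the cell-to-cell
variability it imprints on the number of **antibodies bound per cell
(ABC)** — the quantity a calibrated flow cytometer reports through the
mean fluorescence intensity.

## Who this is for

Quantitative flow cytometry relies on CD4⁺ T cells as a counting
standard (~100,000 accessible CD4 receptors per cell).  The measured
fluorescence CV% of a labeled population mixes detector noise with
*biological* variability of the label load.  `mabsim` computes the
biological part from first principles: an exact Gillespie simulation
of one cell's labeling reaction, repeated over a population with
per-cell heterogeneity in receptor number and binding affinity.

## The model

Antibody reaches the cell through three concentric 3.75 µm shells
(transition → boundary → cell layer), adsorbs nonspecifically on the
surface, and binds receptors monovalently or bivalently:

    A_s ⇄ A_b ⇄ A_c ⇄ A_o,   A_o + R ⇄ AR,   AR + R ⇄ ARR

* Diffusive hops: rate `D/h² = 3.56 s⁻¹` per molecule
  (`D = 0.5e-10 m²/s`, `h = 3.75 µm`).
* Adsorption `k_on = D/h²` (perfect sticking), desorption
  `k_off = 0.5·k_on`.
* Binding constants (default "similar" preset): `k_mp = 1e-4`,
  `k_mn = 1e-6`, `k_bp = 2e-6`, `k_bn = 1e-8` s⁻¹ (per pair for the
  associations, applied directly to count products).
* During labeling the transition layer is pinned at `A_s = 3000`
  molecules (saturating bath); after the wash it is an empty sink.

The ten reaction channels are simulated with the direct-method
stochastic simulation algorithm — waiting time
`τ = ln(1/r₁)/Σαᵢ`, channel chosen with probability `αⱼ/Σαᵢ` — in a
compiled event loop that is bit-for-bit reproducible and verified
against a pure-R reference loop and a deterministic mean-field ODE
oracle.  Key invariants hold exactly: counts are integers and
`R + AR + 2·ARR` is conserved at every event, so at receptor
saturation `AR + 2·ARR` equals the initial receptor count exactly.
`ABC = AR + ARR`.

## Worked example

A full-scale labeling run (~2 × 10⁶ reaction events, well under a
second):

```r
library(mabsim)
tr <- run_scenario(labeling_scenario(t_end = 40), seed = 1)
tr
#> ssa_trajectory: 1.94142e+06 events over [0, 40] s (cpp engine)
#>   final: A_b = 2960  A_c = 2975  A_o = 5944  AR = 38352  ARR = 30824  R = 0  (ABC = 69176)
```

Reading the final state: the receptors have saturated (`R = 0`), so
bound receptors satisfy `AR + 2·ARR = 38352 + 2·30824 = 100000`
exactly; the three transport shells hold ≈3000 molecules each and the
adsorbed pool ≈6000 (= 2·A_c, the `k_on/k_off` balance); the cell
carries `ABC = 69176` labeled antibodies — between the all-monovalent
limit (100,000) and the all-bivalent limit (50,000) because both
binding modes coexist at these rates.

A population study — 25 cells whose bivalent affinity `k_bp` is
either 1e-7 (solitary receptors) or 1e-6 (clustered receptors) with
equal probability:

```r
res <- run_ensemble(preset_ensemble("table6", master_seed = 1))
res
#> mabsim_ensemble: 25 cells, t_end = 60 s, master seed 1
#>      R_init        AR       ARR    TotalA
#> mean  1e+05 72207.840 13896.040 86103.880
#> SD    0e+00 19066.849  9533.464  9533.386
#> CV%   0e+00    26.406    68.606    11.072
```

`AR` and `ARR` individually vary wildly between the two affinity
classes (CV% 26 and 69), but receptor conservation anticorrelates
them, so their sum — the measurable ABC — varies far less (CV% ≈ 11).
Comparing presets (`table4`: all fixed → CV% ≈ 0.1; `table5_*`:
receptor number ~ Normal(100,000, 6%) → CV% ≈ 4–6; `table6`/`table7`:
affinity heterogeneity → CV% ≈ 9–11) decomposes the measured
variability into intrinsic, receptor-driven and affinity-driven
contributions.

A command-line interface wraps the same functions:

```sh
exec/mabsim ensemble --preset table6 --seed 1 --out results/
exec/mabsim simulate --t-end 40 --events --out results/
```

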