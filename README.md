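# respdmd

Reduced-order modelling of pulsatile airway flow and inhaled-particle
deposition with exact dynamic mode decomposition (DMD).

Simulating aerosol transport in the respiratory tract with coupled CFD and
Lagrangian particle tracking costs tens of CPU-hours per breathing cycle.
Because respiration is driven by a near-sinusoidal inlet waveform, the
flow is close to linear in the Koopman sense, and a data-driven linear
propagator fitted to a handful of snapshot decks can reconstruct both the
velocity field and particle trajectories in minutes. This package is for
researchers in computational respiratory physiology and inhalation
dosimetry who want that surrogate as a tested, reusable pipeline — plus a
fully synthetic bifurcating-airway world so every stage runs and is
verifiable without access to proprietary CFD output.

## The method in brief

Snapshots $x_1,\dots,x_m \in \mathbb{R}^{3N}$ (all velocity components at
$N$ mesh nodes, or all coordinates of $N$ particles, per time step
$\Delta t$) are split into $X^- = [x_1 \cdots x_{m-1}]$ and
$X^+ = [x_2 \cdots x_m]$. With the rank-$r$ SVD $X^- \approx U_r \Sigma_r
V_r^\top$, exact DMD builds

$$\tilde A = U_r^\top X^+ V_r \Sigma_r^{-1},\qquad
\tilde A W = W \Lambda,\qquad
\Phi = X^+ V_r \Sigma_r^{-1} W,\qquad
b_0 = \Phi^\dagger x_1,$$

and reconstructs $x(t) = \Re(\Phi\, \Lambda^{t/\Delta t}\, b_0)$. For an
untrained flow rate $\dot v_\theta$ between two trained rates, the reduced
operators, POD bases and amplitudes are blended linearly with weight
$\theta = (\dot v_\theta - \dot v_2)/(\dot v_1 - \dot v_2)$ after aligning
the two SVD bases (sign/permutation/phase — see the methods vignette,
`vignettes/methods.Rmd`). Deposition agreement is measured by the
Bhattacharyya coefficient $\sum_i \sqrt{q_{1i} q_{2i}}$ over uniform radial
bins ($\Delta r = 0.01R$) of distance from the carina; field accuracy by
per-frame relative errors $\epsilon_k$, their mean (MRE) and maximum, full
field and per region (walls, outlets).

## Worked example

```r
library(respdmd)

geo  <- toy_airway_geometry()          # analytic Y-bifurcation point cloud
spec <- field_spec(geo)                # two-mode pulsatile velocity field
deck <- drop_trailing_low_energy(generate_flow_snapshots(spec, 50))
deck
#> <snapshot_set> kind=fluid  N=928 entities  Nt=144 frames  dt=0.015s  flow=50 L/min

model <- dmd_fit(build_pair(deck))     # full numerical rank by default
model
#> <dmd_model> r = 4 modes, state dim 2784, dt = 0.015s, flow = 50 L/min
#>   |lambda| in [1, 1]

recon <- reconstruct_deck(model, deck$times); recon$times <- deck$times
region_error_table(deck, recon)
#> <error_report> 144 frames, flow = 50 L/min
#>      region       MRE   max_eps max_cellwise n_excluded
#>  full_field 6.581e-12 1.218e-11    2.229e-10          0
#>        wall 6.565e-12 1.216e-11    2.218e-10          0
#>      outlet 6.966e-12 1.375e-11    1.494e-11          0
#>       inlet 7.006e-12 1.925e-11    1.928e-11          0
```

The deck is exactly linear (two oscillatory modes, four eigenvalues on the
unit circle), so reconstruction error is at roundoff — the stated-world
analogue of percent-level errors on real CFD fields. Interpolating the
reduced Koopman operator to an untrained rate:

```r
models <- lapply(c(40, 50, 60), function(v)
  dmd_fit(build_pair(drop_trailing_low_energy(generate_flow_snapshots(spec, v)))))
pset <- dmd_interpolate(models, 55)
pset
#> <pdmd_set> target 55 L/min from bracket (50, 60), theta = 0.500, r = 4
held <- drop_trailing_low_energy(generate_flow_snapshots(spec, 55))
ri <- reconstruct_interpolated(pset, held$times); ri$times <- held$times
mean_relative_error(snapshot_errors(held, ri))   # 3.15e-12 (percent)
```

(reusing the 50 L/min deck as-is would err by 9.09 %). The particle phase
— advect an aerosol ensemble, keep deposited trajectories, fit DMD, and
compare radial deposition PDFs:

```r
out <- run_phase1(run_config(seed = 1))
#> deposited 2991 of 6000; Bhattacharyya 0.916; median trajectory RMSE 2.5e-4 m
```

A coefficient of 0.92 means the reconstructed deposition density overlaps
92 % of the ground-truth mass over 100 radial bins; trajectory errors of a
quarter millimetre are a third of the bin width.

## Command line

`exec/respdmd` wires the stages into subcommands
(`simulate`, `fit`, `reconstruct`, `interpolate`, `evaluate`,
`deposition`, `phase1/2/3`), reading JSON configs (`read_run_config()`),
snapshot tables (TSV + JSON sidecar), model bundles (TSV arrays + JSON
manifest, bit-exact round trip) and writing optional legacy-VTK point
files for visualisation.

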