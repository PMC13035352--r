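---
title: "Reduced-order modelling of airway flow and aerosol deposition with DMD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-order modelling of airway flow and aerosol deposition with DMD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respdmd)
```

## The model

Pulsatile respiratory flow is driven by a sinusoidal inlet waveform
$\dot v(t) = \dot v_{\max}\sin(2\pi t/T)$ over a breathing cycle of period
$T$ (default 2.4 s, heavy-exercise conditions, sampled every
$\Delta t = 0.015$ s). Because the forcing is near-periodic, the
high-dimensional state — all velocity components at all mesh nodes, or all
coordinates of all tracked particles — evolves close to linearly from one
snapshot to the next, and a finite-rank approximation of the Koopman
operator captures it well. Dynamic mode decomposition (DMD) estimates that
operator from data alone.

Given $m$ snapshots $x_1,\dots,x_m \in \mathbb R^{3N}$ (each snapshot is a
$3\times N$ field flattened component-block-wise: all first components,
then all second, then all third), form the lagged and shifted matrices
$X^- = [x_1 \cdots x_{m-1}]$, $X^+ = [x_2 \cdots x_m]$ and seek the
best-fit propagator $x_{k+1} \approx A x_k$. With the thin SVD
$X^- = U\Sigma V^\top$ truncated at rank $r$:

* reduced operator: $\tilde A = U_r^\top X^+ V_r \Sigma_r^{-1}$,
* eigenpairs: $\tilde A W = W\Lambda$,
* exact DMD modes: $\Phi = X^+ V_r \Sigma_r^{-1} W$,
* amplitudes: $b_0 = \Phi^\dagger x_1$ (pseudoinverse; fitted to the first
  snapshot only — a least-squares fit over all snapshots is a known
  alternative and is deliberately not implemented),
* reconstruction: $x(t) = \Re\!\left(\Phi\,\Lambda^{t/\Delta t}\,b_0\right)$,
  with the principal complex logarithm defining non-integer powers.

The squared singular values measure modal energy; `choose_rank()` offers
energy-based truncation, while the default keeps the full numerical rank
(singular values below $10^{-12}\,\max\sigma$ count as zero), matching the
reference use of full-rank operators.

### Canonical eigen-order and normalisation

Eigenpairs are sorted by $|\arg\lambda|$ ascending (slow oscillations
first), then $|\lambda|$ descending, then positive frequency first; each
eigenvector has unit norm with its largest-magnitude entry made
real-positive. Any fixed convention would do for a single fit — the
spectrum and reconstruction are invariant — but parametric blending pairs
eigenpairs *across* fits positionally, so the convention is load-bearing
there.

## Parametric interpolation between flow rates

Models trained at two flow rates $\dot v_1 < \dot v_\theta < \dot v_2$ are
blended linearly in the reduced space with weight
$\theta = (\dot v_\theta - \dot v_2)/(\dot v_1 - \dot v_2)$:
$\tilde A_\theta = \theta\tilde A_1 + (1-\theta)\tilde A_2$, eigendecomposed
to $(\Lambda_\theta, W_\theta)$; the POD bases blend as
$U_\theta = \theta U_1 + (1-\theta)U_2$, the modes are
$\Phi_\theta = U_\theta W_\theta$, and the amplitudes blend entrywise. The
nearest bracketing pair of trained rates is used (ties toward the lower
rate); extrapolation is refused by default. $U_\theta$ is used exactly as
the blend produces it; an optional flag re-orthonormalises it by QR and
reports $\|U_\theta^\top U_\theta - I\|_F$.

Three consistency details make the printed equations well-defined in
floating point; all three leave each model's own reconstruction
bit-identical and only change the blend operands:

1. **Basis alignment.** SVD leaves every POD column's sign free, and
   near-degenerate singular values can swap order between fits.
   `align_models()` greedily matches each reference column to the
   remaining column of the other model with the largest absolute inner
   product, flips its sign to make that inner product positive, and applies
   the corresponding orthogonal similarity to $\Sigma_r$, $V_r$,
   $\tilde A$ and $W$ (eigenvalues, exact modes and amplitudes are
   invariant). Ambiguous pairings (two candidates within $10^{-6}$) emit a
   warning and keep canonical order.
2. **Amplitude phase.** The eigenvector phase convention is applied in each
   model's *own* basis at fit time, so after alignment the two models can
   still carry opposite-phase amplitudes for matched modes — the blend then
   cancels instead of interpolating (we observed ~100 % error from a single
   flipped dominant pair). Alignment therefore re-fixes each aligned
   eigenvector's phase and counter-rotates $\Phi$ and $b_0$.
3. **Mode family for the blend.** Each model's $b_0$ is fitted to its exact
   modes $\Phi = X^+V_r\Sigma_r^{-1}W$, but the interpolated reconstruction
   uses projected modes $U_\theta W_\theta$. When $X^+$ lies in the span of
   $U_r$ these differ exactly by a factor $\Lambda$ per column, so the
   implementation blends $\Lambda_j b_{0,j}$ instead of $b_{0,j}$. With the
   amplitudes as printed, interpolation at a trained rate would reproduce
   that model's deck shifted by one time step; with the correction it
   reproduces it exactly, which is what the endpoint-consistency criterion
   demands.

## The synthetic world

No public snapshot decks exist for the reference geometry, so the package
generates its own on an analytic Y-bifurcation point cloud
(`toy_airway_geometry()`): a parent tube descending onto the carina at the
origin, two daughters branching at ±35°, nodes on tube surfaces (wall),
interior rings (lumen), the parent top disk (inlet) and daughter end disks
(outlets). Default ~930 nodes, $R \approx 0.08$ m.

The velocity field is a sum of modes
$u(x,t) = \sum_j \mathrm{amp}_j(\dot v)\,p_j(x)\,
\sin(2\pi f_j t + \phi_j + \psi_j(x))$ with amplitudes linear in flow rate,
$\mathrm{amp}_j(\dot v) = a_j\,\dot v/\dot v_{\mathrm{ref}}$. Defaults: a
parabolic axial profile at the breathing fundamental ($a_1 = 0.35$ m/s) and
a weaker secondary-flow pattern at the first harmonic ($a_2 = 0.06$ m/s).
Choices that matter:

* **Per-node phase lag $\psi_j(x)$** (Womersley-like, growing along the
  airway). This is not decoration: a standing oscillation contributes a
  *single* spatial pattern, and no linear propagator can advance a
  one-dimensional sinusoid — the oscillation needs both quadratures in the
  snapshot span. With a non-constant lag each mode spans two independent
  quadratures and the deck follows exactly linear dynamics with
  eigenvalues $e^{\pm 2\pi i f_j \Delta t}$, which is what makes the deck a
  legitimate DMD oracle.
* **Amplitude scale.** 0.35 m/s gives a domain transit of ~0.4 s, a third
  of the inhalation. Physiologic tracheal speeds (~4 m/s at 50 L/min) would
  cross this desk-scale 0.11 m geometry in a single frame; the real airway
  tree is far longer, so the slow-down stands in for the missing path
  length.
* **Near-wall floor.** The axial profile is $1 - 0.92\rho^2$, leaving ~8 %
  of the peak at wall nodes, as vertex-interpolated finite-volume output
  does. Exact no-slip would make the wall-region relative error (the
  Table-2 analogue) a 0/0.
* **Trailing frames.** 160 frames cover the 2.4 s cycle; the last 16 are
  attenuated by $10^{-4}$, emulating the near-zero end-of-exhalation field.
  `drop_trailing_low_energy()` removes the maximal trailing run of frames
  below `threshold` (default $10^{-3}$) times the peak frame norm, capped
  at `max_drop` (default 16, the reference bookkeeping), and never touches
  interior frames. With measurement noise the tail norms sit at the noise
  floor, so the threshold must be raised above it (0.02 in the acceptance
  tests' noisy variant).

### Particles

Particles carry log-normal diameters (median 0.42 µm, GSD 3.5, density
4390 kg/m³ — an aerosolised iodine-131 surrogate) and are advected as
passive tracers by explicit Euler stepping at the snapshot spacing, with
nearest-node velocity lookup. 20 injector points are drawn uniformly over
the inner half of the inlet disk, each particle jittered within 1.5 mm of
its injector — without that spread all particles sharing an injector follow
one trajectory and the ensemble deck is rank-deficient. A particle deposits
when it comes within the capture radius (default half the median wall
inter-node spacing; a full spacing would swallow most of the daughter lumen
and deposit everything within ~10 frames) of a wall node, and is frozen
there; its final position is its deposition site. Outlet passage flags a
particle escaped. Deposited + escaped + suspended always partitions the
ensemble.

Unresolved turbulent dispersion is modelled as an isotropic AR(1)
displacement (stationary step 2×10⁻⁴ m, memory 0.97). Two non-obvious
findings from the in-repo stability study are baked into these defaults:

* **Dispersion must be temporally correlated.** White per-step noise puts
  white content into the trailing POD directions; the full-rank propagator
  fitted through it acquires an essentially random spectrum there, and for
  roughly half the seeds some $|\lambda| > 1.05$ mode turns the 143-step
  reconstruction into overflow. Correlated dispersion (eddies with a
  turnover time) is simultaneously more physical and keeps the spectrum
  near the unit circle. Purely Brownian amplitudes (~5×10⁻⁶ m/step for
  these particles) are too weak to give the deck full rank at all — the
  truncated fit then *forecasts* instead of interpolating and drifts.
* **Ensemble size regularises the fit.** At 2500 particles occasional seeds
  still produce mildly unstable spectra; at the default 6000 (~3400 of
  which deposit) the fitted spectral radius stayed within ~1.02 across all
  seeds studied, with Bhattacharyya overlap 0.90–0.98.

## Deposition statistics

Final positions of deposited particles are binned by Euclidean distance
from the carina reference point $p_0$ into uniform bins of width
$\Delta r = 0.01R$, normalised to densities $p_i = n_i/(N\Delta r)$ so
$\sum_i p_i\Delta r = 1$. $R$ defaults to the largest observed radius over
both ensembles being compared (raised, with a note, if positions overflow a
supplied value). Agreement is the Bhattacharyya coefficient on per-bin
masses, $\sum_i\sqrt{q_{1i}q_{2i}}$ with $q_i = p_i\Delta r$: 1 for
identical distributions, 0 for disjoint support, independent of bin width.
A published variant sums the raw density products without the square root;
it is not 1 for a perfect match and is provided only behind
`literal = TRUE`.

## Error metrics

Per-frame relative error
$\epsilon_k = \|x_k^{\mathrm{truth}} - x_k^{\mathrm{recon}}\|_2 /
\|x_k^{\mathrm{truth}}\|_2 \times 100\%$, summarised by its mean (MRE) and
maximum. Frames whose truth norm falls below the low-energy threshold
(shared with the trailing-discard rule) are excluded and counted rather
than allowed to produce huge ratios. Region tables recompute the same
statistics after restricting both decks to a mask (wall, outlet, inlet);
"maximum" is reported both as the largest $\epsilon_k$ and as the largest
per-entity-per-frame relative error (`max_cellwise`), since a worst single
cell and a worst frame are different questions.

## What a green test establishes — and what it does not

The synthetic decks are exactly linear by construction (finitely many
oscillatory modes, amplitudes affine in flow rate), so Phase-II
reconstruction and mid-rate interpolation are near-exact here; real CFD
fields are only approximately linear in the Koopman sense and their
reported reconstruction errors are percent-level, not $10^{-12}$. The
particle phase is the stochastic stress test: trajectories freeze at
individual deposition times and carry dispersion noise, and the full-rank
eigen-route must interpolate 143 steps of that — overlap ≥ 0.8 at the
canonical seed mirrors the qualitative "strong distributional agreement"
claim at desk scale, not the published figure. The advection model is a
passive-tracer stand-in: no inertia, no drag law, no two-way coupling, so
size-dependent deposition physics (impaction/sedimentation efficiency
curves) is out of scope, as is any deposition-fraction model.

## Numerical choices

* Numerical rank: $\sigma_j < 10^{-12}\max\sigma$ treated as zero; a
  requested rank above it is an error naming the attainable rank.
* Amplitudes and any pseudoinverse use SVD with the same relative cutoff.
* $\Lambda^{t/\Delta t}$ via principal branch; at integer steps this equals
  repeated multiplication to roundoff. A zero eigenvalue with negative time
  is a domain error.
* Ties in nearest-rate bracketing go to the lower rate; exact hits on a
  trained rate use that model as the $\theta = 1$ endpoint.
* Serialization writes doubles with 17 significant digits, which
  round-trips IEEE doubles bit-exactly; complex arrays store real and
  imaginary blocks side by side.

## Known limitations

* Full-rank exact DMD of stochastic trajectory decks is a root-finding
  problem in disguise; its spectrum is not guaranteed inside the closed
  unit disk. The defaults above make divergence rare, not impossible — a
  diverging reconstruction inflates the shared binning radius $R$ and can
  make the Bhattacharyya coefficient look *better*, so inspect `rmse`
  alongside the coefficient.
* The generator's parametric family varies only mode amplitudes with flow
  rate; real flows also shift mode *shapes* and frequencies, which is
  precisely where linear operator blending degrades (the reference reports
  ~20 % MRE over a 20 % parameter gap).
* No inlet-escape flag: during exhalation particles may drift above the
  inlet plane and are simply carried back; only outlet passage marks
  escape.
* `region_view` on a reconstructed deck relies on the truth deck's masks
  when the reconstruction lacks its own.
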