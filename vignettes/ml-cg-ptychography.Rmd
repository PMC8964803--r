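---
title: "Maximum-likelihood ptychographic reconstruction with a partitioned conjugate-gradient solver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-likelihood ptychographic reconstruction with a partitioned conjugate-gradient solver}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptycg)
```

## The model

Ptychography records, at each of $n$ overlapping scan positions, the
far-field diffraction intensity produced by a focused coherent probe $p$
(an $S \times S$ complex field, known and fixed here) passing through a
specimen described by a complex transmission image $\psi$ ($H \times W$).
The forward model is

$$ |\mathcal{G}\psi|^2 = |\mathcal{F}\mathcal{Q}\psi|^2 = d, $$

where $\mathcal{Q}$ extracts the $S \times S$ patch of $\psi$ under each
scan position and multiplies it elementwise by $p$, and $\mathcal{F}$ is an
independent two-dimensional discrete Fourier transform per patch. The
detector counts photons, a Poisson process, so the maximum-likelihood
estimate of $\psi$ minimizes (up to a $\psi$-independent constant) the
negative log-likelihood

$$ F(\psi) = \sum_{j=1}^{n} \left\{ |\mathcal{G}\psi|_j^2
   - 2\, d_j \log |\mathcal{G}\psi|_j \right\}, $$

whose gradient with respect to $\psi^*$ is

$$ \nabla_\psi F(\psi) = \mathcal{G}^H\!\left( \mathcal{G}\psi
   - \frac{d}{(\mathcal{G}\psi)^*} \right), \qquad
   \mathcal{G}^H = \mathcal{Q}^H \mathcal{F}^H . $$

The solver iterates $\psi_{m+1} = \psi_m + \gamma_m \eta_m$ with the
Dai–Yuan conjugate direction

$$ \eta_m = -\nabla F(\psi_m) + \alpha_m\, \eta_{m-1}, \qquad
   \alpha_m = \frac{\lVert \nabla F(\psi_m) \rVert_2^2}
   {\langle \eta_{m-1},\, \nabla F(\psi_m) - \nabla F(\psi_{m-1}) \rangle},
   \qquad \eta_0 = -\nabla F(\psi_0), $$

where $\langle a, b\rangle = \sum_i a_i^* b_i$ over the $H\cdot W$ pixels,
and a backtracking line search that starts at a large step $\gamma_0$ and
shrinks it geometrically until $F(\psi_m + \gamma_m \eta_m) \le F(\psi_m) +
\gamma_m t$ with $t = 0$: any step that does not increase the cost is
accepted, which makes the recorded cost sequence non-increasing whenever
the shrink cap is not reached. A plain gradient-descent solver with a
constant step is included for comparison ([pty_reconstruct_gd()]); it
needs a conservatively small step and converges more slowly.

### Conventions the formulas leave open

Several choices are not determined by the model above; the package fixes
them once:

* **Fourier normalization.** $\mathcal{F}$ is the *unitary* (orthonormal)
  DFT, so $\mathcal{F}^H$ is exactly the inverse transform and the adjoint
  identity $\langle \mathcal{G}x, y\rangle = \langle x, \mathcal{G}^H
  y\rangle$ holds to machine precision. Any other normalization rescales
  the cost and step lengths but not the minimizer.
* **Wirtinger convention.** $F$ is real-valued in the complex unknown;
  $\nabla_\psi F$ denotes $\partial F / \partial \psi^*$, so the
  first-order change of $F$ along $\eta$ is $2\,\mathrm{Re}\langle \nabla
  F, \eta\rangle$. The finite-difference tests check exactly this
  identity.
* **Real inner products in the direction update.** $\alpha_m$ must be real
  for $\eta_m$ to be a descent-compatible direction; the denominator uses
  $\mathrm{Re}\langle\cdot,\cdot\rangle$ and the numerator is a squared
  norm. If the denominator's magnitude falls below `eps_guard` the
  recursion restarts from steepest descent — standard practice for
  nonlinear CG.
* **Vanishing far-field amplitude.** $\log|\mathcal{G}\psi|$ and
  $d/(\mathcal{G}\psi)^*$ clamp $|\mathcal{G}\psi|$ below at `eps_guard`
  (default `1e-32`, far below any amplitude arising from unit-scale data);
  the elementwise division keeps the far-field phase. Pixels with $d = 0$
  contribute only the intensity term.
* **Coordinates.** Scan positions are 0-based `(row, col)` top-left
  corners of half-open $S \times S$ footprints that must lie fully inside
  the object; out-of-bounds positions are rejected, never clipped or
  wrapped. Sub-pixel positions are not supported.
* **Initialization.** $\psi_0 \equiv 1$ (unit transmission) by default; a
  seeded complex random perturbation is available (`init_mode =
  "random"`). All randomness in the package flows through explicit seeds,
  and repeated runs are bitwise identical on the serial path.
* **Precision.** Everything is double precision (R's native numeric type).

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_iters` | 128 | iteration count of a full-length run |
| `gamma0` | 1 | initial line-search step, reset every iteration (no warm start) |
| `shrink` | 0.5 | geometric step-shrink factor |
| `t` | 0 | line-search termination offset; 0 accepts any non-increase |
| `max_ls_steps` | 32 | shrink cap per line search (hitting it logs a warning) |
| `eps_guard` | 1e-32 | clamp on the far-field modulus |
| `stop_tol`, `stop_patience` | 0, 5 | optional plateau stop on the relative iterate 2-norm |

`gamma0 = 1` is deliberately large: for overlap-dominated scans the
accepted step settles around $1/(2\times\text{overlap})$, so the search
typically spends three to five shrinks per iteration, and resetting every
iteration keeps the step choice independent of history. Near full
convergence no strictly decreasing step may exist at floating-point
resolution; the line search then hits its cap and returns the last trial
step, which is why converged runs can emit cap warnings — the cost is flat
at that point, and the optional plateau stop (`stop_tol`) halts cleanly
before this regime.

## The partitioned solver

The diffraction stack dominates memory: $S^2 \cdot n \cdot
\text{bytes/value}$ ([pty_diffraction_bytes()]; a 512-pixel detector at
16K positions in 4-byte floats is exactly 16 GiB). Distributing patterns
over workers is therefore the natural decomposition. The obstacle is that
two stages of each CG iteration are global: the Dai–Yuan coefficient is a
matrices-to-scalar reduction over the complete gradient, and each line
search trial reduces the complete data volume to one scalar. Running the
monolithic algorithm independently per worker would produce different
$\alpha_m$ and $\gamma_m$ on every worker and lose equivalence.

[pty_reconstruct_partitioned()] therefore splits each iteration into four
stages over $P$ logical workers:

1. **GRAD** — each worker computes the gradient on its strip (plus halo)
   from its own patterns; embarrassingly parallel.
2. **DIR (gather–scatter)** — worker 0 (the master) gathers the owned
   gradient strips, which assemble the *exact* complete gradient, runs the
   Dai–Yuan recursion exactly as the monolithic solver, and scatters
   per-worker slices of $\eta_m$.
3. **LS (all-reduce)** — each trial step, workers sum the cost over their
   *owned* patterns only (halo duplicates excluded, so each pattern is
   counted exactly once, relying only on the associativity of addition);
   the partials are added in ascending worker order and the shrink loop
   runs on the global scalar, so all workers agree on $\gamma_m$.
4. **update + border exchange** — every worker applies $\psi \leftarrow
   \psi + \gamma_m \eta_m$ locally, then overwrites each stored pixel
   outside its owned strip with the owning neighbor's value.

Geometry: the object is cut into $P$ equal contiguous strips along its
longer axis (1-D decomposition; a 2-D grid would reduce halo volume for
very large $P$ but multiplies neighbor links and corner cases, and is left
as an extension point). Internally a wider-than-tall object is transposed
on entry and the result transposed back — the forward model commutes with
transposition because the 2-D DFT is separable. A pattern is owned by the
strip containing its footprint center (half-open intervals make boundary
assignment deterministic); the halo region is the strip dilated by the
full probe side $S$, which guarantees every footprint touching an owned
strip is locally available, and halo patterns are those whose footprint
intersects the halo region. Each worker stores $\psi$ over the footprint
closure of its pattern set so every local patch is extractable.

Because the scattered direction slices come from the exact master
direction and the step is global, worker-local $\psi$ never drifts: the
border exchange is bitwise idempotent (tested), owned gradient strips are
bitwise equal to the monolithic gradient's blocks (same values accumulated
in the same order), and the only difference from the monolithic solver is
the reassociated cost summation, which perturbs line-search scalars at the
level of machine rounding. Equivalence is therefore asserted within
`1e-6` relative over tens of iterations, not bitwise. Worker backends are
logical: `"serial"` (deterministic in-process loop) and `"process"`
(forked pool via the parallel package) share identical semantics; physical
transport — this execution model is how multi-GPU ptychography codes
distribute work, with NCCL/MPI moving the borders and reductions — is a
performance concern outside the correctness contract, and a `"device"`
backend is a declared extension point.

## Synthetic data

[pty_simulate()] builds $d = |\mathcal{G}\psi|^2$ from procedural ground
truths, so the full pipeline is testable with no external assets:

* [pty_star()] — a Siemens-star resolution target: binary radial spokes in
  an annulus, mapped to amplitude 0.6 / phase 0.8 rad on the spokes over a
  unit (vacuum) background. Star targets are the standard synthetic
  benchmark because the radially shrinking spoke period probes all spatial
  frequencies.
* [pty_texture()] — a smooth seeded random texture (low-pass-filtered
  Gaussian noise) standing in for photographic test objects; any
  user-supplied grayscale matrix can also be wrapped directly via
  [pty_dataset()].
* [pty_probe()] — disk (top-hat, default radius $S/4$) or Gaussian
  amplitude, optional quadratic phase, unit peak.
* [pty_scan()] — jittered raster grids; overlap requires `step < S`, and
  positions are clipped to keep footprints inside the object.
* Optional Poisson noise replaces intensities by seeded counts with mean
  `flux * d / max(d)`; the default experiments are noise-free, which makes
  the data exactly consistent (the gradient vanishes at the ground truth
  — a property the tests assert).

What the generator does *not* emulate: partial coherence, detector
point-spread and background, probe uncertainty (the probe is known
exactly), position errors, and sub-pixel scan geometry. Passing tests on
these data demonstrate the correctness of the operators, the optimizer and
the partitioned execution — not robustness to the systematic errors of
real beamline data, where probe retrieval and position refinement
(deliberate non-goals here) usually matter.

## Evaluation

The cost depends on $\psi$ only through $|\mathcal{G}\psi|$, so
reconstructions carry an arbitrary global phase. [pty_align_phase()]
removes it analytically ($\theta = \arg\langle \mathrm{ref}, \mathrm{est}
\rangle$ minimizes the residual norm), and quality metrics are computed on
*amplitude* images after alignment: [pty_ssim()] (Gaussian window, radius
7 px, $\sigma = 1.5$, standard stabilization constants, interior mean) and
[pty_psnr()] with the peak set to the reference amplitude maximum.
Convergence is tracked by the iterate difference 2-norm
$\lVert\psi_m - \psi_{m-1}\rVert_2$. Whether amplitude, phase or the
complex difference is scored is itself a convention; amplitude is used and
documented, and with near-exact reconstructions the choice is immaterial.

## A small worked run

```{r example, eval = FALSE}
obj <- pty_star(256)
probe <- pty_probe(64, "disk")
scan <- pty_scan(256, 256, 64, step = 14, jitter = 2, seed = 1)
ds <- pty_simulate(obj, probe, scan)

cfg <- pty_config(n_iters = 128, metrics_every = 8)
mono <- pty_reconstruct(ds, cfg = cfg)
part <- pty_reconstruct_partitioned(ds, P = 4, cfg = cfg)

max(abs(part$record$cost - mono$record$cost) / abs(mono$record$cost))
tail(mono$record[!is.na(mono$record$ssim), ], 3)
```

Problem sizes used by the shipped experiments (chosen as desk-scale
versions of the original beamline-scale runs, which used a $256^2$ probe
and 4K–16K patterns per view): equivalence and curve agreement on a
$256^2$ star with a $64^2$ disk probe and 196 patterns over 20 iterations;
reconstruction quality on a $512^2$ star with the same probe, step-16
jittered raster (841 patterns), CG run to the iterate-2-norm plateau with
a 512-iteration cap. On the latter, SSIM crosses 0.95 and PSNR 75 dB
within roughly 70–100 iterations and the converged PSNR exceeds 100 dB.

## Known limitations

* The probe must be known; there is no probe retrieval, no multi-mode
  probe, and no position refinement.
* Integer scan positions only; near-field propagation and 3-D
  (tomographic) ptychography are out of scope.
* The 1-D strip decomposition requires every strip to be at least $S$
  pixels wide, capping $P$ at `floor(min(H, W) / S)` in practice.
* The Poisson noise model is the plain counting model; detector readout
  noise and background are not modeled.
* Equivalence between worker counts is defined up to floating-point
  reassociation of the cost reduction (relative `1e-6` in double
  precision), not bitwise; within one worker count, serial-backend runs
  are bitwise reproducible.
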