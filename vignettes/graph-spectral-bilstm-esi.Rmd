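---
title: "Graph-spectral BiLSTM source imaging: model, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-spectral BiLSTM source imaging: model, simulator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Electrophysiological source imaging (ESI) reconstructs cortical current
sources from scalp EEG. The forward model is linear,

$$\mathbf{x}(t) = \mathbf{H}\,\mathbf{s}(t) + \boldsymbol\varepsilon(t),$$

with $\mathbf{x}(t) \in \mathbb{R}^n$ the EEG at $n$ electrodes,
$\mathbf{H} \in \mathbb{R}^{n \times m}$ the lead field, and
$\mathbf{s}(t) \in \mathbb{R}^m$ the amplitudes of $m$ candidate sources on a
cortical mesh. Because $n \ll m$ the inverse problem is ill-posed; recovering
*extended* activations (a patch of cortex rather than a point dipole) is
particularly hard for classical minimum-norm solvers, whose solutions are
over-diffuse.

This package implements a graph-spectral learning approach. The source mesh
is treated as an undirected graph $G = (V, \mathbf{A})$; its combinatorial
Laplacian $\mathbf{L} = \mathbf{D} - \mathbf{A}$ is eigendecomposed
$\mathbf{L} = \mathbf{U} \boldsymbol\Lambda \mathbf{U}^T$, and the
eigenvectors ordered by eigenvalue form a spatial frequency basis (the graph
Fourier transform, GFT). An eigenvector's *graph frequency* — the number of
edges across which it changes sign — grows with its eigenvalue, so the first
$k$ eigenvectors $\mathbf{U}_k$ span the spatially smooth subspace. An
extended patch is spatially smooth, so its GFT energy concentrates in this
low band (`test-simulator.R` checks ≥ 80% of the energy lands in the lowest
30% of the spectrum).

A bidirectional LSTM is trained to map the EEG sequence to the low-band
coefficient sequence $\tilde{\mathbf{s}}'(t) = \mathbf{U}_k^T \mathbf{s}(t)$,
and source maps are recovered by the truncated inverse transform
$\hat{\mathbf{s}} = \mathbf{U}_k \hat{\mathbf{s}}'$. Two things are gained:
the output layer shrinks from $m$ to $k$ units (a factor $m/k \approx 3.3$
at the defaults), and the reconstruction is automatically confined to the
spatially smooth subspace, which suits patch-like activations.

## The network

Each direction is a standard LSTM cell
($\sigma$ the logistic function, $*$ element-wise):

$$
\mathbf{f}_t = \sigma(\mathbf{W}_f[\mathbf{h}_{t-1}, \mathbf{x}_t] + \mathbf{b}_f),\quad
\mathbf{i}_t = \sigma(\cdot),\quad
\tilde{\mathbf{c}}_t = \tanh(\cdot),\quad
\mathbf{c}_t = \mathbf{f}_t * \mathbf{c}_{t-1} + \mathbf{i}_t * \tilde{\mathbf{c}}_t,
$$
$$
\mathbf{o}_t = \sigma(\cdot),\qquad
\mathbf{h}_t = \mathbf{o}_t * \tanh(\mathbf{c}_t),
$$

with the forward cell scanning $t = 1..T$ and the backward cell $t = T..1$.
The output at each time sample is an affine map of the concatenated hidden
states, $\mathbf{y}_t = g(\mathbf{W}_s[\mathbf{h}_t \oplus \mathbf{h}'_t] +
\mathbf{b}_s)$. Training minimizes the mean squared error between predicted
and true low-band coefficients with the Nadam optimizer
(Nesterov-accelerated adaptive moments); the parameters of the best
validation epoch are kept.

Design choices that were genuinely open:

* **Output activation.** A sigmoid output cannot represent signed, unbounded
  graph Fourier coefficients, so the default output activation is the
  identity; sigmoid is available as a configuration option
  (`output_activation = "sigmoid"`) for fidelity experiments with rescaled
  targets.
* **Hidden-size convention.** `hidden` is read as the *concatenated*
  bidirectional dimension (so `hidden = 256` means 128 units per
  direction), matching the dimension entering the output layer; a
  per-direction reading is selectable via `hidden_interpretation`.
* **Standardization.** Inputs are standardized per channel, fit on the
  training split only. Targets are centered per coefficient but scaled by a
  single pooled standard deviation (`target_scaling = "global"` in
  `gft_bilstm()`). Scaling every coefficient to unit variance
  (`"per_feature"`, the `prepare_targets()` default) makes the loss
  dominated by high-order coefficients whose energy is near the noise
  floor, and converges markedly slower; the global scale preserves each
  coefficient's natural share of signal energy.
* **Initialization.** Seeded Glorot-uniform weights, forget-gate biases at
  1 (the usual remember-by-default heuristic), zero output biases.
* **Optimization.** Nadam with constant learning rate $10^{-2}$, batch size
  32 trials, up to 40 epochs, early stopping with patience 12 on validation
  MSE. These values were selected by validation MSE on the simulated study
  (a cosine learning-rate decay was tried and gave no improvement). One
  trial (1 s, 100 samples) is one sequence; outputs are per time step.

The batched sequence scan and backpropagation-through-time live in compiled
code (`src/bilstm_core.cpp`); `lstm_cell_step()` is the plain-R reference
recurrence against which the batched path is tested, and all gradients are
verified against finite differences in the test suite.

## The simulator

The simulator emulates a patch-source EEG protocol:

* **Geometry.** An icosphere source space (default: subdivision 3, $m = 642$
  vertices at 75 mm) stands in for a cortical mesh. A realistic cortical
  surface with anatomically spaced sources is *not* reconstructed; the
  icosphere is an explicit substitute with the same vertex-count order and
  uniform mesh valence (5–6 neighbors).
* **Lead field.** Electrodes (default 64) are placed on a Fibonacci spiral
  over the upper hemisphere of a 92.5 mm scalp sphere, and each source is a
  unit current dipole oriented along the outward normal inside a
  homogeneous conducting sphere, using the closed-form Legendre-series sum
  for the surface potential. Columns are average-referenced. This is an
  analytic, dependency-free forward model; the imaging method itself is
  agnostic to how $\mathbf{H}$ was obtained.
* **Activations.** Each trial activates one (or more, disjoint) patch:
  a center vertex plus its level-1 mesh neighbors, neighbors at half the
  center amplitude (`neighbor_scale = 0.5`; the protocol only requires
  "lower"). The waveform is a stable 5th-order autoregressive process at
  100 Hz with poles giving damped 10 Hz and 23 Hz oscillations (spectral
  radius 0.95) — amplitudes are in arbitrary units, with the
  neighbor-to-center ratio the only shape constraint.
* **Noise.** Spatially and temporally white Gaussian sensor noise, rescaled
  so the realized $\mathrm{SNR} = 10\log_{10}(P_\mathrm{signal} /
  P_\mathrm{noise})$ is exact, with powers taken as mean squares over all
  channels and samples jointly.
* **Splits.** 70/15/15 train/validation/test by largest-remainder rounding,
  seeded. In single-source mode the default scaled-down protocol draws 600
  distinct centers of the 642 without replacement; passing
  `n_samples = NULL` activates every vertex in turn (the exhaustive
  protocol). Each sample stores one noisy EEG per requested SNR level so a
  single ground-truth dataset serves the whole SNR grid.

What the simulator does **not** emulate: realistic head geometry and
conductivity layers (BEM/FEM), free dipole orientations, correlated or
structured sensor noise (eye blinks, line noise), and moving sources.
Passing tests on this simulator therefore show that the pipeline recovers
smooth patch activations under its own stated conditions — not that it
matches clinical-grade forward modelling.

## Benchmarks and evaluation

The linear baselines are the classical Tikhonov minimum-norm kernel
$\mathbf{K} = \mathbf{H}^T(\mathbf{H}\mathbf{H}^T + \lambda^2\mathbf{I})^{-1}$
(MNE), its noise-normalized variant (dSPM: rows divided by
$\sqrt{(\mathbf{K}\mathbf{C}\mathbf{K}^T)_{ii}}$) and its
resolution-standardized variant (sLORETA: rows divided by
$\sqrt{(\mathbf{K}\mathbf{H})_{ii}}$). Regularization defaults to the
standard SNR heuristic $\lambda^2 = \mathrm{tr}(\mathbf{H}\mathbf{H}^T) /
(n \cdot 10^{\mathrm{SNR}/10})$. With identity covariances all three differ
only by positive per-row scaling.

Metrics:

* **AUC** — each vertex is scored by its maximum absolute reconstructed
  amplitude over time (the amplitude at the global energy peak is
  selectable), positives are all patch member vertices, and the AUC is the
  Mann–Whitney pairwise probability with ties at ½, averaged per trial.
* **Localization error (mm)** — at the energy-peak sample, the $P$
  strongest spatially distinct local maxima ($P$ = number of true centers,
  distinctness radius 2 mesh hops) are matched one-to-one to true centers
  greedily by increasing distance; LE is the mean matched distance. The
  multi-source matching protocol is this package's own convention — the
  single reported LE for two patches does not itself define one.
  Identically-zero estimates report the mesh diameter and a warning.

## Numerical conventions

* Eigenvector signs are fixed (largest-magnitude entry positive, ties by
  lowest index) so serialized bases and trained models reproduce across
  platforms. Within a degenerate eigenvalue the eigensolver's ordering is
  kept; graph-frequency values of tied eigenvectors can therefore differ
  between platforms' LAPACK builds — a documented limitation.
* A sign flip requires a *strictly* negative product across an edge: exact
  zeros contribute nothing.
* Dense symmetric eigendecomposition only; the paper-scale $m$ of a few
  thousand is comfortably dense-feasible (0.1 s at $m = 642$).
* All randomness flows from one integer seed through a counter-based
  derivation (`derive_seed`), so every stage is independently rerunnable.

## Problem sizes of the reference study

The packaged study (`simulation_study()`, also behind
`scripts/acceptance.R` and the heavyweight acceptance tests) uses $m = 642$,
$n = 64$, 600 trials (420/90/90), $k = \mathrm{round}(0.3\,m) = 193$
(mirroring the $k/m$ ratio 615/2052 of the full-scale protocol),
`hidden = 256`, and up to 40 training epochs per SNR level — sizes chosen as
a single-workstation study that preserves the structure of the full-scale
experiment. At these sizes one training takes a few minutes.

## Known limitations

* On the analytic spherical lead field the standardized linear solvers are
  strong: sLORETA's zero-localization-bias property is exact here, and its
  single-source AUC is correspondingly high — closer to the learned
  solver's than realistic-geometry studies report. Relative method rankings
  on this simulator should be read with that in mind.
* With two simultaneous patches and only 600 trials, the coefficient
  regression is generalization-limited: 420 training pairs sparsely cover
  the space of disjoint center pairs, and multi-source test AUC plateaus
  well below the single-source value even with much longer training. The
  exhaustive-coverage regime needs a dataset orders of magnitude larger.
* The per-feature/global target-scaling choice, the identity output
  activation, and the hidden-size convention are all configuration options;
  the defaults are the package's judgement calls, not uniquely determined
  by the method.
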