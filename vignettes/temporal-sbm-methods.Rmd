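---
title: "Temporal stochastic block models for developing neuronal cultures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal stochastic block models: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the science it implements: the
functional-network construction for multi-electrode array (MEA) recordings,
the temporal stochastic block model (T-SBM) and its static baseline, the
MCMC scheme, and the design choices made where the design was genuinely
open. Nothing here reports an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## From spike trains to functional networks

An MEA recording gives per-electrode spike timestamps for one device at one
day in vitro (DIV). Electrode activity is sparse, so correlating whole
recordings inflates correlations; instead correlation is measured inside
population bursts:

1. **Channel bursts** (`detect_channel_bursts()`): at least 4 spikes on one
   electrode within a sliding 100 ms window; overlapping qualifying windows
   merge, and the burst extent runs from its first to its last spike.
2. **Global bursts** (`detect_global_bursts()`): channel bursts starting on
   at least 4 distinct electrodes within 250 ms of the earliest (anchor)
   start. Scanning is greedy left-to-right over sorted start times; each
   channel burst joins at most one global burst. Anchoring to the earliest
   start (rather than demanding pairwise closeness) is a deliberate
   resolution of an ambiguity in the verbal definition: it is deterministic
   and oracle-checkable.
3. **Cross-correlation** (`cross_correlation_matrix()`): within each global
   burst, spikes are binned at 10 ms and the zero-lag Pearson correlation is
   taken per electrode pair; the matrix entry is the mean over the bursts
   where the pair had variance. Pearson-at-zero-lag on binned counts is the
   simplest estimator consistent with a correlation matrix in [-1, 1]; the
   bin width is configurable. Pairs never defined (electrodes silent in all
   bursts) are set to 0 rather than NA so graphs are always well formed.
4. **Thresholding** (`threshold_network()`): an edge joins two electrodes
   when their correlation is strictly above the threshold (default 0.20);
   equality yields no edge. `threshold_sweep()` reports average degree over
   a threshold grid, which is non-increasing by construction.

Limitations: the construction is undirected and lag-free; a community of
highly correlated electrodes says nothing about the direction or mechanism
of the coupling.

## The models

**Static multi-device SBM.** For networks \(A^{(1)},\dots,A^{(d)}\) on a
common electrode set, with \(k\) communities:

\[
\pi \sim \mathrm{Dirichlet}(\alpha),\quad
z_u^{(d)} \mid \pi \sim \mathrm{Categorical}(\pi),\quad
\eta_{ij} \sim \mathrm{Beta}(a,b),\quad
A_{uv}^{(d)} \sim \mathrm{Bernoulli}\!\left(\eta_{z_u^{(d)} z_v^{(d)}}\right).
\]

Edge probabilities are shared across devices; each node may sit in a
different community in each device (seeding variability), which is what
makes the shared \(\eta\) informative.

**T-SBM.** Community assignments are fixed over time; what changes is the
connection probability between communities, modelled on the logit scale as
a smooth function of DIV:

\[
\kappa_{\bullet}(t,t') = \sigma_\bullet^2
  \exp\!\left(-\frac{(t-t')^2}{2\ell_\bullet^2}\right) + \epsilon,
\qquad
x_{ij}(\cdot) \sim \mathcal{GP}(0, \kappa_{\mathrm{in}}\ \text{if}\ i=j,\
 \kappa_{\mathrm{out}}\ \text{otherwise}),
\]
\[
\beta_{ij} \sim N(0,1), \qquad
\eta_{ij}(t) = \mathrm{sigmoid}(\beta_{ij} + x_{ij}(t)), \qquad
A_{uv}^{(d)}(t) \sim \mathrm{Bernoulli}\!\left(\eta_{z_u^{(d)} z_v^{(d)}}(t)\right).
\]

All within-community pairs share one covariance (\(\kappa_{\mathrm{in}}\)),
all between-community pairs another (\(\kappa_{\mathrm{out}}\)); each pair
still has its own latent path and its own offset \(\beta_{ij}\). The
Gaussian process makes the model robust to irregularly spaced DIVs and
gives principled interpolation and extrapolation (`predict_eta()`).

**Nugget placement.** The kernel formula adds \(\epsilon\) as written above;
this package places it on the diagonal only (a jitter/noise term), because
a constant added to every kernel entry is a constant-kernel component that
is confounded with \(\beta\) and destroys positive-definiteness guarantees
as \(\epsilon\) grows. For the default \(\epsilon = 0.01\) the two readings
differ by at most 0.01 on off-diagonal entries. \(\epsilon\) is fixed, not
inferred.

## Priors

The tunable priors (`tsbm_priors()`), with units and defaults:

* `alpha = 1` — flat Dirichlet over community proportions.
* `sigma_scale = 0.5` — half-normal scale for \(\sigma_{\mathrm{in}}\),
  \(\sigma_{\mathrm{out}}\) (logit units). The latent process is meant to
  capture *temporal modulation around the pair-specific baseline*
  \(\beta_{ij}\). A near-constant latent path is indistinguishable from a
  shift of \(\beta\), and because a wider Gaussian prior assigns more mass
  to extreme levels, a generous output scale lets the latent path absorb
  the baseline and biases \(\beta\) toward zero while inflating
  \(\sigma\). Half-normal(0.5) keeps the output scale weakly informative —
  on the order of developmental swings on the logit scale — while smaller
  than typical baselines, preserving the decomposition.
* `ell_mean` — gamma prior (shape 2) for the length scales, centred at a
  third of the DIV-grid span (DIV units), hard-truncated below at the
  smallest DIV gap: a length scale shorter than the sampling interval would
  let the path wiggle invisibly between recordings.
* `eps = 0.01` — fixed nugget (logit-variance units); set it to 0 for exact
  interpolation identities.
* `beta_sd = 1` — the model's own \(N(0,1)\) offset prior.

## MCMC scheme

`fit_tsbm()` runs a compound sampler (defaults: 2 chains, warmup equal to
the number of kept draws):

* **Assignments `z`** — exact categorical Gibbs, one sweep per iteration;
  the full conditional for a node costs \(O(k^2 T)\) after pre-computing
  block edge counts. Gradient samplers cannot handle the discrete `z`,
  which is why the sampler is a compound of discrete and continuous
  updates.
* **Offsets and latent paths** — per community pair, the joint vector
  \((\beta_{ij}, v_{ij})\) has a standard-normal prior under the
  non-centred parameterisation \(x = L v\) (with \(L\) the Cholesky factor
  of the kernel Gram matrix), so it is updated by elliptical slice
  sampling: exact, tuning-free, and immune to the funnel at small
  \(\sigma\).
* **Ridge Gibbs move** — the map \((\beta, v) \mapsto \eta\) has a
  one-dimensional null space (a constant latent shift traded against
  \(\beta\)); along that line the likelihood is flat and the conditional
  prior is Gaussian, so it is sampled exactly. Without this move the
  sampler random-walks along the confounded ridge.
* **Kernel hyperparameters** — random-walk Metropolis on
  \((\log\sigma, \log\ell)\) with step-size adaptation during warmup
  (target acceptance ~0.3), plus a centred/non-centred swap move that
  rescales \(\sigma\) while holding every latent path fixed (re-whitening
  \(v\) under the new factor), walking the \(\sigma\)-versus-\(\|v\|\)
  ridge at constant likelihood.
* **Proportions `pi`** — conjugate Dirichlet.

**Initialisation and label modes.** Within a device, community labels are
exchangeable; across devices, permuting one device's labels changes the
likelihood only through differences among diagonal (and among off-diagonal)
entries of \(\eta\), so when those are similar the posterior has
near-degenerate *orientation* modes — an identifiability artifact of the
block-label symmetry, one step beyond classical global label switching.
The sampler works in the canonical cross-device-consistent representative:
chains start from k-means on each device's time-averaged adjacency rows,
with labels aligned across devices by node overlap; assignments are held
fixed for the first few warmup iterations so the continuous parameters can
adapt to the warm start (at the start \(\eta \equiv 1/2\), and a Gibbs sweep
under a non-informative \(\eta\) would randomise it); single-site sweeps
then preserve the orientation while genuinely misassigned nodes migrate
individually. Whole-device permutation moves were deliberately excluded:
at fixed \(\eta\) the per-device orientation objective is noise-dominated
when diagonal offsets are close, and such moves push chains into an
absorbing half-swapped configuration whose averaged \(\eta\) is strictly
worse. Global label switching across chains is handled post hoc by
`relabel_by_size()`, which aligns chains by modal-assignment overlap and
then orders communities by occupancy (or against a reference partition,
needed when community sizes tie).

**Convergence.** Split R-hat and a basic autocorrelation ESS are attached
for the continuous parameters; `relabel_by_size()` reports (never hides)
parameters exceeding R-hat 1.05. Chains are fully reproducible from
`(data, config, seed)`.

## Prediction and model comparison

`predict_eta()` draws, per posterior sample, the Gaussian-process
conditional of each latent path at the new DIVs given that sample's path
and kernel, then applies the link; with `eps = 0` the predictive mean at a
training DIV equals the in-sample posterior mean exactly. Points farther
than three posterior-mean length scales outside the grid revert to the
prior and are flagged. `predictive_loglik()` scores held-out networks by
log-mean-exp of the per-draw Bernoulli likelihood — the posterior
predictive mass — and works identically for the static baseline, whose
predictive \(\eta\) is time-free. `select_k()` fits a grid of maximum
community counts and picks the smallest whose occupied-community count
stays strictly below the cap, so the cap is demonstrably not binding.

## The synthetic validation scenario

`validation_scenario()` is the package's reference experiment and defines
the study conditions used by the acceptance script: 4 devices of 20 nodes,
two fixed communities of 10, DIV grid (11, 14, 18, 21, 25, 28, 31) — the
sampling pattern of a real multi-week culture study — with
\(\sigma = 0.25\), \(\ell = 3\), \(\epsilon = 0.01\) for both kernels and
offsets \(\beta_{11} = 0.5\), \(\beta_{12} = -2\), \(\beta_{22} = 0.7\).
This yields modular networks (within-community edge probability ~0.6-0.7,
cross ~0.12). Fits use 2 chains of 1000 post-warmup draws (scaled from a
5000-draw reference configuration; the posterior here is concentrated and
the extra draws change summaries at the third decimal). Two caveats the
generator makes explicit: a single simulation draws one latent path per
pair, so the recoverable level of each pair is \(\beta_{ij}\) plus that
draw's mean path value (standard deviation roughly 0.15-0.2 under these
kernels) — offset recovery is therefore assessed within that stochastic
band, and interval-coverage checks are posed on the identified quantity
\(\beta_{ij} + \bar{x}_{ij}\) rather than on the nominal offset alone; and
with two equal communities of 10, size-ordered
relabeling cannot orient the labels, so recovery summaries align labels to
the generative assignment.

What passing synthetic tests do *not* show: the generator emits exactly
exchangeable Bernoulli edges given \(\eta\); real MEA networks have degree
heterogeneity, spatial structure and thresholding artifacts that the block
model only approximates.

## Numerical choices

* Bernoulli log-masses are computed on the logit scale via
  `plogis(q, log.p = TRUE)` to avoid catastrophic cancellation at extreme
  probabilities.
* Gram matrices with `eps = 0` get a 1e-10 jitter only if Cholesky fails.
* Undefined correlations (zero-variance channels) are 0 by convention;
  degrees tie-less Spearman correlations are reported as `NA`.
* Trend classification collapses consecutive duplicate values first, making
  labels invariant to padding with repeated DIV columns; the isotonic fit
  must capture at least 90% of a curve's variance for an "increasing"
  label. The thresholds (0.05 / 0.2 / 0.3 / 0.5) quantify qualitative
  vocabulary and are all configurable via `trend_rules()`.
* Problem sizes in the test suite (devices, nodes, draws) are scaled to
  keep each property check sharp but cheap; the validation experiment runs
  at its stated full size.

## Known limitations

* Edges are binary and undirected; no lag-resolved or weighted extension.
* Community membership is fixed over time by design (allowing both
  \(\eta\) and `z` to vary is unidentifiable without extra constraints).
* The number of time points bounds how well \(\ell\) and \(\sigma\) can be
  separated; covariance posteriors are honestly wide on short grids.
* Orientation modes (which diagonal path a device's block follows) are
  genuinely unidentifiable when diagonal offsets coincide; the package
  reports the canonical consistent representative rather than mixing over
  orientations.
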