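---
title: "Brain network ictogenicity: models, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain network ictogenicity: models, calibration, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ictonet)
```

## The modelling problem

Epilepsy surgery aims to remove the brain tissue responsible for seizure
generation.  `ictonet` implements an *in silico* counterpart of that
question: place a dynamical node on every vertex of a brain network, let
each node rest just below a saddle-node-on-invariant-circle (SNIC)
bifurcation, drive the system with noise, and ask how much the network as a
whole spikes -- and how much less it would spike if a given node were
removed.

Two node models are available.

* **Wendling neural mass (WM).**  Ten first-order ODEs per node describing
  a pyramidal population interacting with one excitatory and two (slow,
  fast) inhibitory interneuron populations through a firing-rate sigmoid
  `S(v) = 2 e0 / (1 + exp(r (v0 - v)))`.  The node output is the aggregated
  pyramidal potential `z2 - z3 - z4` (mV).  Network input enters through
  the extrinsic drive `p`, which we make node- and time-dependent:
  mean `p0`, white noise, plus `1/N` times the firing-rate outputs of the
  in-neighbours scaled by the coupling `lambda`.
* **Canonical model (CM).**  The theta neuron
  `theta' = (1 - cos theta) + (1 + cos theta) I(t)` is the normal form of
  the SNIC; it is used here not as a single neuron but as the canonical
  representation of a neural mass near that bifurcation.  A node's output
  is `1 - cos(theta - theta_s)`, zero at the resting state `theta_s` and
  maximal half a rotation away; a spike is a full rotation.

Both models share one mechanism: below the bifurcation a node rests;
noise and network input can push it across, producing a large-amplitude
spike; recruitment through the coupling lets spiking reverberate through
the network.  Which nodes sustain that reverberation is a property of the
topology -- that is what the node-removal analysis measures.

## Parameter constants, and one deliberate deviation

The WM constants follow the standard parameterization (gains `A = 5`,
`B = 40`, `G = 20` mV; rates `a = 100`, `b = 50`, `g = 500` 1/s; sigmoid
`v0 = 6` mV, `e0 = 2.5` 1/s, `r = 0.56` 1/mV; `C1 = 135` with the usual
ratios), with one exception: the fast-somatic feedback connectivity is set
to `C7 = 0.8 C1`, the value of the original Wendling model, not `0.25 C1`.
With `0.25 C1` the SNIC sits at a critical input of `p_c = 91.66`, which is
incompatible with the published operating point of this framework (a
resting drive of `p0 = 94` at distance `p_c - p0 = 1.45`); with `0.8 C1`
the bifurcation sits at `p_c = 95.41` and both anchors are consistent.  All
constants are overridable through `wm_params()`.

`wm_critical_input()` locates `p_c` by reducing the ten-dimensional
equilibrium problem to a scalar fixed-point equation in the pyramidal
potential and bisecting (tolerance `1e-3`) on the constant input at which
the resting equilibrium pair is annihilated.  The value is cached per
parameter set.  For the CM the bifurcation is at `I_c = 0` exactly.

## Noise convention

The models are driven by Gaussian white noise, integrated with
Euler-Maruyama increments of standard deviation `sigma_eff * sqrt(dt)`.
The user-facing `sigma` is defined as the standard deviation of the
extrinsic noise *sampled at the model's reference interval* --
`0.015` dimensionless time units for the CM and `5e-3` s for the WM -- so
the effective intensity is `sigma * sqrt(tau_ref)`.  Two properties motivated
this convention:

1. results are invariant under refinement of the integration step (halving
   `dt` leaves the stationary statistics unchanged), and
2. at the standard operating point (`sigma* = 5`, see below) the dynamics
   are *intermittent*: nodes rest most of the time, noise occasionally
   seeds a spike, and coupling decides whether it recruits the network.
   A literal delta-correlated reading of `sigma` at these magnitudes makes
   every node rotate continuously even uncoupled, which destroys the whole
   BNI construction (the network is maximally "ictogenic" at zero
   coupling).  Far smaller references have the opposite failure: noise can
   seed collective reverberation but never extinguish it, so a network
   ignites once and stays on, BNI degenerates into a step function of the
   coupling, and node-removal scores lose all reliability.  The chosen
   references sit in the intermittent regime -- networks of 15-64 nodes
   switch between quiet and reverberating episodes many times per run, the
   uncoupled "floor" BNI stays small, and the calibrated couplings land
   near the published values (`BNI = 0.5` around `w*` of order 1 for
   15-node sparse random networks at `sigma* = 5`).

## Starred (scaled) parameters

Each model has three free parameters (distance to the bifurcation, noise,
coupling), but only two matter dynamically.  All user-facing sweeps use

* `sigma* = sigma / (T - x0)` -- noise relative to the distance to the
  bifurcation (`T` is `p_c` or `I_c`), and
* `lambda* = 2 e0 c lambda / (N sigma_p)` (WM) or
  `w* = 2 c w / (N sigma_I)` (CM) -- the average maximal input a node can
  receive from the network, relative to the noise (`c` is the mean
  degree).

`cm_from_starred()` / `wm_from_starred()` convert to raw parameters for a
given graph; the default `sigma* = 5` throughout matches the published
operating conditions.  Note that because the starred coupling is expressed
relative to `sigma`, its absolute scale inherits the noise convention
above; couplings are therefore always *calibrated* (below), never copied.

## Spike-epoch detection and BNI

`detect_spikes()` implements the published two-stage rule: the mean
absolute amplitude of the mean-removed output over a sliding 0.05 s window
is thresholded, local maxima above threshold are spikes, and 1 s windows
centred on spikes are merged into spiking epochs.  BNI is the mean over
nodes of the fraction of simulated time covered by epochs.

* **Threshold.**  Not stated in the published framework.  Default: the
  larger of (a) five times the rest-state standard deviation of an
  *uncoupled* node at the same distance and noise level (the subthreshold
  noise floor, estimated with iterative 6-sigma clipping so noise-driven
  spikes in the calibration run do not inflate it) and (b) half the
  windowed amplitude that a noiseless spike reaches.  The amplitude anchor
  matters for the theta model, whose one-sided heavy-tailed resting output
  otherwise lets sub-rotation noise bumps through as false spikes.  Cached
  per parameter set and overridable.
* **CM time scale.**  The CM's time unit is fixed only through the ratio
  of spike widths: both windows are multiplied by
  `cm_time_unit()` = FWHM(CM spike) / FWHM(WM spike), with both widths
  measured on noiseless nodes driven the same distance beyond the
  bifurcation.  At distance 1.2 the scale is about 5 CM units per second.

## Calibration and node ictogenicity

`calibrate_coupling()` bisects on the starred coupling until the
seed-averaged BNI is within `0.05` of the reference `BNI_pre` (default
`0.5`; `0.3`/`0.7` are supported for robustness checks).  Because the BNI
estimate is stochastic, the bisection returns the evaluation closest to the
target rather than the last midpoint.

`node_ictogenicity()` then removes one node at a time, re-simulates with
unchanged parameters, and reports `NI_i = (BNI_pre - BNI_post_i)/BNI_pre`.
Three choices deserve explanation:

* **Coupling prefactor.**  The `1/N` in the coupling is kept at the intact
  network size when nodes are removed.  Re-reading `N` as the reduced size
  would raise every surviving edge's gain by `N/(N-1)` per removal --
  a purely parametric perturbation that, on the steep part of the BNI
  curve, dwarfs the structural effect being measured.
* **Fraction mass.**  `BNI_post` is expressed over the intact node count,
  with the resected node contributing zero spiking time.  This makes the
  boundary identities exact: removing a node that never spiked and drives
  nothing leaves BNI unchanged (`NI = 0`), and removing all nodes gives
  `BNI = 0`.  Averaging only over survivors would instead hand every
  silent-node removal a spurious `-1/(N-1)` NI.
* **Noise seeds.**  Each node's noise stream is keyed by `(seed, node
  label)`, so streams stay attached to surviving nodes across resections.
  With `common_rng = TRUE` the pre- and all post-resection BNIs are
  evaluated under identical streams, turning NI into a common-random-number
  difference estimate with far smaller variance; this is used in all
  ensemble analyses.  The default (`common_rng = FALSE`) uses independent
  derived seeds per resection, which is unbiased but noisier.  Mixing a
  `bni_pre` measured under one seed set with posts measured under another
  turns seed-to-seed BNI differences into phantom NI -- the function
  therefore recomputes `bni_pre` under its own seeds unless told otherwise.

## Rank comparisons and regressions

`weighted_kendall()` compares two NI vectors with pair weights
`|a_i - a_j| * |b_i - b_j|`, so that pairs both rankings consider
well-separated dominate; exact ties are broken by a deterministic
index-proportional jitter of relative size `1e-12`.  `regress_ni()` fits
ordinary least squares of NI on each measure separately and on all jointly.
For ensemble summaries the package regresses each network realization
separately and averages the coefficients of determination across
realizations, rather than pooling nodes: each realization's NI-versus-
centrality relation is tight, but eigenvector centralities are normalized
to unit maximum per network and NI scales inherit each network's
calibration, so pooled scatters mix well-aligned lines with different
supports and understate the per-network relation substantially (pairs of
random networks with per-network R-squared above 0.9 can pool below 0.7).

## Functional networks from recordings

`epoch_networks()` reproduces the peri-ictal functional-inference chain:
median re-referencing; zero-phase order-4 Butterworth band-pass
(0.5--120 Hz) and notch (48--52 Hz); 8 s segments separated by 1 s gaps
(the published spacing is ambiguous between gap and stride; the gap
reading is the default and the spacing is configurable); 10 subsegments of
1024 samples spread with minimal equal overlap; 10 IAAFT surrogates per
channel (exact amplitude multiset, spectrum matched to relative tolerance
`1e-6` or 100 iterations); Pearson zero-lag correlations; two-sided
Mann-Whitney U tests of the 10 original against the 100 surrogate
subsegment correlations with Bonferroni-Holm control at 0.05; and the
surrogate-corrected matrix `C = s (rho_o - rho_surr)/(1 - rho_surr)`.
Signed correlations are used throughout; negative corrected weights are
possible and are by default dropped at the rich-club stage.

## Weighted rich clubs

`rich_club_profile()` computes `phi_w(k)` = (weight on edges internal to
the club of nodes with degree > k) / (sum of the equally many largest
weights in the network), normalizes by the mean over 100 null networks
(weight permutation followed by degree-preserving double-edge swaps, 10
attempts per edge, weights carried with the edges), and attaches a
one-sided permutation p-value per `k` (fraction of null coefficients at
least as large as the observed; the normalization cancels in this
comparison, so the raw coefficients are compared directly).  The "richest
club" is the membership above the `k` maximizing the normalized
coefficient, ties resolved toward smaller `k` (the more inclusive club).

## The synthetic recording generator

`synth_recording()` emulates what the functional-network chain needs from
iEEG and nothing more: channels with EEG-like autocorrelation (order-2
autoregressive noise band-passed to 1--40 Hz at 512 Hz), a planted "rich"
channel subset sharing a common latent signal, and epoch-dependent mixing
gains (defaults: 180/60/180 s pre/ictal/post epochs, gains 0.4/1.2/0.4),
giving analytic ground-truth correlations `g^2/(g^2+1)`.  It does not
emulate seizure waveform morphology, electrode artifacts, volume
conduction, or nonstationarity within an epoch, so passing tests certify
the inference chain's statistics, not its robustness to those features of
clinical data.

## Numerical choices and problem sizes

Integration uses Euler-Maruyama at `dt = 1e-4` s (WM; 20 steps per fastest
time constant) and `dt = 1e-3` (CM) by default, with output subsampled at
stride 20.  Simulated durations default to 200 s (WM) and 2000 units (CM),
discarding 2 s / 20 unit transients.  The ensemble analyses in the test
suite and the acceptance script run at desk scale -- CM durations of
250-400 units, 2-3 noise seeds per BNI evaluation, `dt = 4e-3`, and 1-2
network realizations per condition -- sizes chosen to keep a full run on
one core in the tens of minutes while leaving the reported statistics'
Monte-Carlo error inside the tolerances they are tested against (the
replicate-based reliability correction below accounts for what remains).
The graph generators default to the published study conditions (`N = 64`,
`c = 6`, scale-free exponents 2-3, small-world rewiring 0.5, rich clubs of
10 nodes with `p1 = 0.7`, `p2 = 0.2`).  The ensemble analyses operate at
the distance `I_c - I0 = 1.62`, the printed calibration cross-section of
the BNI surface; within-model consistency sweeps span distances 0.8-1.6.
For these pooled regressions the coupling is calibrated to `BNI = 0.5`
within `0.03` rather than the default `0.05`, so that per-network spread
of the realized `BNI_pre` does not masquerade as NI-scale heterogeneity
across pooled realizations.

## Known limitations

* The WM within-model analyses are computationally heavy; the package runs
  them at reduced ensemble sizes by default.
* Heterogeneous per-node parameters are supported by the simulators
  (vector `p0` / `I0`) but the calibration and starred conversions assume
  homogeneous nodes, as in the published framework.
* Directed functional networks and density-based richness parameters are
  out of scope for the rich-club module.
* The CM's absolute time unit is a convention fixed by the spike-width
  ratio; only window-based epoch logic depends on it.

## Desk-scale regression estimates

The ensemble regressions of NI on node measures are reported after a
measurement-error correction.  A desk-scale NI vector is a noisy estimate
(few noise seeds, short runs), and noise in the response attenuates every
R-squared by the NI reliability.  `regress_ni_reliable()` therefore
estimates NI twice under disjoint seed sets, estimates the reliability of
the replicate mean by Spearman-Brown from the replicate correlation, and
divides the observed R-squared by it (clamped to one; left uncorrected
with a warning when the replicates barely correlate).  The unit tests
validate the estimator against a synthetic oracle with known noise-free
R-squared.  The correction is applied uniformly -- including to the
directed-network regressions, where the claim is an upper bound.
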