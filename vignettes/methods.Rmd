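---
title: "Resolution effects in epileptogenic-network inversion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolution effects in epileptogenic-network inversion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the package addresses

Personalized whole-brain models of epilepsy estimate which brain regions can
start a seizure (the epileptogenic zone network, EZN) from stereotactic EEG
(SEEG) recordings. In practice the estimation is done with a *neural mass*
model (NMM): one point source per atlas region, coupled through a
structural connectome, with a simple inverse-square forward projection to
the electrode contacts. Real cortical tissue, however, is a continuous
sheet: a *neural field* model (NFM) discretized on the cortical surface
adds two ingredients the mass model lacks — short-range (mm) coupling
between neighbouring patches, and dipole sources whose orientation follows
the local surface normal, which matters a great deal for what a depth
electrode actually records.

This package rebuilds that comparison as a self-contained simulation study
on synthetic geometry. Seizures are simulated at high resolution (every
mesh vertex a source), projected to SEEG with the dipolar forward model,
and then inverted with the low-resolution mass model — the configuration a
clinical pipeline would use. Because the ground truth is known, the
recovered network can be scored exactly, and the two simplifications
(forward model, missing local coupling) can be separated by simulating each
configuration under four conditions:

* `lc_none` — mass model simulates, mass model inverts (control);
* `lc_0` — field model with local coupling switched off (isolates the
  forward-model effect: every vertex of a region then carries exactly the
  region trajectory);
* `lc_2`, `lc_4` — field model with increasing local coupling.

## Seizure dynamics: the 5D Epileptor

Every node carries the five-state Epileptor in its standard form: a fast
population `u1, u2` (fast discharges), a spike–wave population `q1, q2`,
and a slow permittivity variable `v` that moves the node in and out of the
ictal state. Time is in ms; `tau0 = 2857/2` sets the slow time scale. The
observable of a node is `q1 - u1`. An auxiliary sixth state `g` integrates
the exponential-kernel drive from `u1` to the spike–wave population
(`dg/dt = -g/tau12 + a12 u1 + ...`), which is the exact ODE form of the
printed convolution integral and costs O(1) memory.

A node's excitability `u0` decides its role. The uncoupled 2D reduction
(keep `u1` and `v`, substitute the `u2` nullcline) has its resting state on
the left branch of the cubic nullcline; the fixed point reaches the left
knee at

```
u0_c  =  u1_k - (1 - u1_k^3 - 2 u1_k^2 + I1)/4,   u1_k = -4/3 (trace-corrected)
```

which evaluates to −2.0620 (`critical_excitability()`; the `1/tau0` trace
term shifts the knee by ~2e-4). Above this value a node seizes on its own.
The study levels are −1.6 (EZ, seizes autonomously), −2.1 (propagation
zone, PZ: close enough to threshold that network input of about 0.15 in the
fast equation tips it over), and −3.6 (non-involved, NIZ: would need input
~6, far more than the couplings deliver). `verify_configuration()` checks
each catalogue entry behaves exactly so, and `adjust_global_coupling()`
finds the smallest global coupling in [1, 16] (integer grid, then
bisection) that recruits all PZ regions and no NIZ region.

Coupling enters twice. Long-range: a Heaviside firing rate of the
*region-mean* fast activity, weighted by the connectome and a global scale
`GCscaling`. Short-range (field mode only): a Laplacian-of-Gaussian kernel
over geodesic distance (sigma = cutoff/3, truncated at 10 mm, positive lobe
row-normalized to 1 so the local coupling scale is comparable across mesh
resolutions); one kernel serves all three local terms, whose thresholds
share `-1` except the spike–wave term. Subcortical nodes are point sources
with the local terms removed.

Integration is classic fixed-step RK4 (dt = 0.1 ms, 20000 samples = 2000
ms), deterministic and bitwise reproducible; every node starts at the
interictal equilibrium computed in closed form for `u0 = -3.6` (the
resting fixed point is available analytically through two cubics), so the
network begins far from onset. With local coupling off, vertices of a
region and the corresponding mass node then follow *identical*
trajectories — the design premise of condition `lc_0`, which the test suite
verifies to 1e-9.

## Synthetic geometry

The geometry generator replaces patient imaging at desk scale while keeping
the statistical shape of the real inputs:

* **Cortex**: an icosphere (subdivision 4 by default: 2562 vertices, radius
  70 mm) with per-vertex outward normals and areas (one third of incident
  triangle area) — the two quantities the dipolar forward model needs.
* **Parcellation**: farthest-point-sampled seeds grown by geodesic
  nearest-seed assignment, fragments repaired, giving ~20 contiguous,
  roughly equal-area regions; 4 subcortical point nodes sit on an interior
  shell, each its own region.
* **Connectome**: exponential distance rule `exp(-d/12 mm)` between region
  barycenters with multiplicative lognormal noise (sd 0.5), symmetrized,
  zero diagonal, max-normalized. The 12 mm decay makes the normalized
  weights span about four decades, as streamline-count connectomes do;
  with much longer decays every region couples strongly to every other and
  the Heaviside long-range drive injects visible fast-oscillation power
  into all non-involved regions, which real connectomes do not do.
* **Implantation**: 8 depth electrodes of 10 contacts (2 mm contacts, 1.5 mm
  gaps: centers exactly 3.5 mm apart), entering at the boundary between an
  adjacent region pair and descending obliquely so the array stays within a
  couple of centimetres of the surface. This emulates the clinical fact
  that electrodes are implanted *to test the EZ hypothesis*: on a sphere, a
  radially implanted electrode buries its deep contacts ~30 mm from all
  cortex and each electrode observes essentially one region, so the
  catalogue's eight single-EZ configurations are placed in the eight
  best-implanted regions (ranked by maximum absolute bipolar gain).
  Bipolar channels are adjacent-contact differences within an electrode.

Everything is reproducible bit-for-bit from the master seed; per-cell seeds
are derived by hashing the master seed with the configuration id and
condition label.

## Forward models and features

The field forward model treats the head as an infinite homogeneous
conductor: vertex `i` contributes `a_i/(4 pi sigma) Q_i . (r_k - x_i)/|r_k
- x_i|^3` at contact `k` (`Q_i` the unit normal, `a_i` the vertex area;
conductivity 1 in arbitrary units — downstream normalization removes the
scale). The mass forward model assumes for every vertex the orientation
that maximizes its gain (pointing at the contact), collapsing the dipole to
`a_j/(4 pi sigma |r_k - x_j|^2)` summed over the region's vertices — hence
mass gains always dominate the magnitude of summed field gains, with
equality exactly when all normals are forced toward the contact (verified
to 1e-12). Subcortical point sources use the inverse-square form with a
nominal area (the mean cortical region area) in both models. A guard
rejects contacts within 0.5 mm of a source.

SEEG data features follow the standard seizure-envelope recipe per bipolar
channel: high-pass at 50 Hz (zero-phase 2nd-order Butterworth), square,
50 ms moving average, log, low-pass at 5 Hz, normalize to [0, 1]. Two
implementation choices matter and are therefore worth stating:

* the log uses `log(p + eps)` with `eps` a fraction (1e-3) of the
  *recording-wide* maximum power, and the [0, 1] normalization is global
  across the montage (a per-contact option exists). Per-channel floors or
  per-contact normalization erase the cross-channel amplitude ordering —
  in a noiseless single-source simulation they make every channel's
  envelope identical — and that ordering is the spatial information the
  inversion uses;
* zero-phase filtering is done on mirror-padded signals and the outer
  100 ms of smoothed power is clamped: textbook `filtfilt` starts from zero
  state, and on log-scale signals the boundary transient would otherwise
  dominate the whole normalization.

The ictal window runs from the first up-crossing to the last down-crossing
of 0.1 on the across-contact maximum envelope, extended by half the ictal
duration on both sides, clipped to the recording, and linearly resampled to
512 samples.

## MAP inversion with the 2D reduction

The generative model for inversion is the 2D Epileptor reduction on the
region connectome, with a fast-synaptic Heaviside coupling on the
presynaptic node (the printed self-gating subscript is read as a typo, as
the full-model equation couples to the distant region's activity). Because
the reduction inherits the full model's time constants, its natural clock
is the same millisecond axis as the recording: it is Euler-integrated
(substep 0.1 ms, inside the stiff fast subsystem's stability limit) from
the same interictal initial state at recording time zero, and the predicted
observations are simply its states at the feature window's 512 sample
times. This removes any per-dataset step calibration and aligns the
model's autonomous onset latency, ictal duration, and (when present) the
second seizure with the data automatically.

The observation model maps the fast variable to the log-power feature
scale. Power mixes linearly across sources, and the power a bipolar
contact receives scales with its *squared* gain, so the prediction is

```
yhat_k(t) = amplitude * ( log( sum_j G2_kj exp(u1_j(t)) + phi )
                        - log( sum_j G2_kj exp(u1_init)  + phi ) ) + offset
```

with `G2` the squared, max-normalized bipolar mass gain and `phi =
exp(lfl)` a global floor that plays the same role as the dynamic-range
floor in the envelope extraction (it sets where weak channels stop
responding). The baseline shift makes all channels start on the common
floor the observed envelopes start on. A purely linear projection of
`u1` — the more obvious choice — cannot fit log-domain envelopes: its
cross-channel bump amplitudes scale with gain while observed log envelopes
scale with *log* gain, and fits collapse to a flat prediction.

Free parameters: one excitability per region (`u0 ~ N(-3.6, 1)`), the
global coupling (`~ N(1, 1)`), amplitude (`~ N(1, 1)`, kept positive),
offset (`~ N(0, 1)`), and the log floor (`~ N(-2, 2)`). Observation noise
is Gaussian with sd 0.1. The log posterior (prior kernels without
normalization constants) is maximized with L-BFGS-B using the exact
discrete adjoint gradient of the Euler scheme (the Heaviside is piecewise
constant, so its state-Jacobian contribution vanishes almost everywhere;
finite-difference agreement is tested to 1e-5), with an iteration cap of
200 (beyond it the objective changes only in its far decimals — most runs
end earlier in a line-search termination at a Heaviside kink). Initial
values are drawn from the priors with a per-seed RNG seed; the optimization
is run for many seeds because the posterior is multimodal — a seed whose
draw contains no supra-threshold region happily polishes the flat "no
seizure" optimum. The single-region catalogue uses 10 seeds per cell; the
EZ+PZ experiment keeps the full 50, since its three-region posterior basin
is reached by a much smaller fraction of prior draws. Seeds with goodness of fit
strictly above the third quartile (type-6 linear-interpolation quantile, so
50 distinct values select exactly 12) are kept; the simulation GOF is their
median, and per-region posterior summaries are the normalized histogram
(bin width 0.1 on [−6, 0]) and median of the selected modes. Goodness of
fit is `max(0, 1 - SS_res/SS_tot)` with `SS_tot` around per-contact means,
pooled over contacts.

## Scoring

EZ and PZ are pooled into one positive class against NIZ (no fixed
excitability boundary separates PZ from NIZ). For each simulation, 401
classification thresholds from −5 to −1 (step 0.01) are evaluated on the
posterior-median excitabilities; among thresholds with at least one
predicted positive, the precision-maximal one is chosen (ties broken by
recall, then by the larger threshold) — the conservative choice if
predicted positives are resection candidates, with the recall cost visible
in the reported F1. The sweep is verified against exhaustive evaluation.
Group summaries use Kruskal–Wallis tests across the four conditions and
paired Wilcoxon signed-rank tests against the control condition; the
gain-similarity analysis correlates the Pearson agreement of the (summed,
rectified, max-normalized) bipolar field gain with the bipolar mass gain of
the EZ region against the evaluation metrics, binned in 0.1-wide intervals.

## Problem sizes, runtime, and what the tests do and do not show

The default study runs eight single-region configurations under all four
conditions (10 inversion seeds per cell) and five EZ+PZ configurations
under the control condition (50 seeds), on the 2562-vertex sphere — about
a minute per cell on one CPU. At this scale the EZ is recovered perfectly
(median F1 = 1 in every condition, and for the EZ+PZ configurations) and
typical selected-seed GOF is about 0.7;
the full-scale study's GOF of 0.85 rides on richer real-geometry features
(folded cortex, 81924 vertices, clinically chosen implantations) that a
noiseless sphere does not reproduce — the 2D reduction cannot match the 5D
envelope's pre-onset drift and exact ictal shape, which caps the desk-scale
GOF near 0.75 regardless of optimization effort.

What the synthetic generator deliberately does not emulate: cortical
folding (and hence realistic dipole-orientation diversity and white-matter
contact placement), measurement noise, artifacts and line noise,
physiological interictal activity, subcortical surfaces, and conduction
delays. Passing tests therefore demonstrate the internal consistency of
the pipeline and the direction and mechanism of the resolution effects —
not clinical performance on real recordings.

## Numerical choices and degenerate inputs

* RK4 blow-up guard at |u1| > 1e3 aborts with a diagnostic; the 2D forward
  model returns a large finite penalty on divergence so line searches
  survive extreme prior draws.
* The equilibrium solver is closed-form (two cubics via `polyroot`); a
  residual above 1e-8 is an error.
* All-constant envelope channels are flagged degenerate and mapped to
  zeros; an envelope that never crosses the detection threshold raises a
  "no seizure detected" error and the cell is recorded as failed rather
  than silently skipped.
* Thresholds with zero predicted positives are excluded from the precision
  argmax; if no threshold predicts a positive, the report carries the
  largest threshold with empty-positive counts.
* Region means in the field model are unweighted vertex means (an
  area-weighted option is not provided; the regions are near-equal-area by
  construction).
* The half-size manipulation acts on the vertex-level excitability map
  only; the region-level (mass) map keeps the full-region value, which is
  what makes the control condition of half-size configurations well
  defined.
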