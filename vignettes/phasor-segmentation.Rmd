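---
title: "Phasor-based segmentation of TCSPC lifetime maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasor-based segmentation of TCSPC lifetime maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasorseg)
```

## The measurement and the model

A pulsed laser (repetition rate `f`, 20 MHz by default, so a 50 ns period)
excites a sample; a TCSPC card histograms photon arrival times into
`n_bins = 256` bins of `bin_width = 195 ps`, a 49.92 ns window inside one
excitation period. Scanning the probe across a surface yields one decay
histogram per pixel. The fluorescence decay of each pixel is a sum of
exponentials whose lifetimes are characteristic of the emitting material —
in paint mock-ups, mostly of the binder.

Rather than fitting every decay (slow, operator-dependent), each histogram
is reduced to its first-harmonic Fourier projection, the phasor

$$g = \frac{\sum_k c_k \cos(\omega t_k)}{\sum_k c_k},\qquad
  s = \frac{\sum_k c_k \sin(\omega t_k)}{\sum_k c_k},\qquad
  \omega = 2\pi f,$$

with bin-centre times $t_k = (k + \tfrac12)\Delta$. A mono-exponential
decay of lifetime $\tau$ maps to
$g = 1/(1+(\omega\tau)^2)$, $s = \omega\tau/(1+(\omega\tau)^2)$ — a point on
the universal semicircle $(g-\tfrac12)^2 + s^2 = \tfrac14$ — and its phase
lifetime $\tau_{\mathrm{phase}} = s/(2\pi f g)$ equals $\tau$. Mixtures fall
inside the semicircle and $\tau_{\mathrm{phase}}$ becomes an effective
lifetime.

Pixels whose histogram peaks at 100 counts or fewer are excluded before any
phasor is computed (strictly greater-than 100 is retained): low-count decays
produce phasor estimates noisy enough to bias the lifetime statistics.

## Mixture segmentation

The retained (g, s) points from a measurement spanning two materials form
two clusters. They are modelled as a K-component bivariate Gaussian mixture
$p(x) = \sum_{i=1}^{K} f_i\, \mathcal N(x;\mu_i,\Sigma_i)$ with full
covariances (phasor clusters are elliptical: shot noise scales differently
along and across the semicircle), fitted by expectation–maximization. K is
fixed at 2 by default because the intended measurements straddle the
interface of two known mixtures; automatic selection of K is out of scope.

Numerical choices, each of which was genuinely open:

* **Initialization.** Farthest-point seeding: the first centre is a seeded
  uniform draw from the data, each further centre the point farthest from
  all chosen centres; points are then hard-assigned to the nearest centre
  for the first M-step. Five restarts (consecutive derived seeds) are run
  and the best final log-likelihood kept. This is deterministic given the
  seed and robust to the very tight, well-separated clusters that
  noiseless or high-count simulations produce.
* **Regularization.** A ridge of 1e-10 is added to each covariance diagonal
  at every M-step. Noiseless simulated populations collapse to (nearly) a
  single phasor; without the ridge the covariance becomes singular and the
  likelihood diverges. The ridge is far below any physically meaningful
  variance (shot-noise variance at peak 500 is ~5e-5), so fitted parameters
  are unaffected at reporting precision; the single-component fit equals
  the sample moments up to exactly this ridge.
* **Convergence.** Relative log-likelihood change below 1e-8, at most 500
  iterations. The E/M updates guarantee a non-decreasing likelihood, which
  the tests assert on every fitted dataset.
* **Canonical order.** EM's component numbering is arbitrary, so components
  are renumbered by descending phase lifetime of their mean phasor
  (ties: descending fraction, then mean g). "Cluster 1" is therefore always
  the longest-lived population, and rendered colours (cluster 1 red,
  cluster 2 green) are stable across runs and seeds.
* **Hard edges.** Each phasor takes the cluster of its maximal posterior
  responsibility; an exact tie goes to the lower (longer-lived) index. The
  probability-blend rendering preserves the soft memberships instead,
  mixing palette colours channel-wise by responsibility.

Reciprocity — each phasor keeps its (row, col) back-reference — turns the
phasor-domain labels into a segmented image; unclassified (filtered) pixels
keep label 0 so outputs stay aligned with the acquisition grid. Cluster
statistics are the mean and population SD (n denominator; at n ≈ 1500 the
distinction from the n−1 form is negligible and no convention was imposed
by the problem) of the members' finite phase lifetimes.

## The simulator: what it emulates and what it does not

No public decay-map data exist for this instrument class, so the package
ships a generator used by every validation:

* Expected counts $\lambda_k = A\sum_i f_i e^{-t_k/\tau_i}/(1-e^{-T/\tau_i})$
  under periodic excitation (period $T = 1/f$); the wrap factor folds the
  tails of all previous pulses into the window and matters only for
  lifetimes approaching $T$ (for τ = 4.5 ns it changes bins by ~1.5e-5).
  $A$ scales the expected (not realized) peak to `target_peak`.
* Poisson counting noise per bin, seeded; per-pixel seeds are derived
  deterministically from (seed, row, col), so any sub-region of a map can
  be regenerated bit-identically.
* Two-population "interface" maps with a vertical boundary and ground-truth
  labels, the stand-in for a probe scanned across the junction of two paint
  mixtures. Default study conditions: lifetimes 3.7 ns vs 1.7 ns (the
  glue-like vs oil-like binder contrast), expected peak 500 counts, 50 × 60
  pixels = 3000 decays, matching a 3000-point acquisition session.

Deliberately **not** modelled: the instrument response function (excitation
pulses are picoseconds against nanosecond lifetimes; an optional Gaussian
IRF convolution exists for robustness checks but is off by default, and no
IRF deconvolution or reference-dye phasor calibration is applied — a
calibration hook would rotate/scale (g, s) but defaults to identity),
detector afterpulsing, dead time, dark counts, pile-up, spectral effects,
and the irregular geometry of freehand scans (maps are regular grids; a
real handheld acquisition visits points along an operator-chosen path).
Passing tests on simulated maps therefore demonstrate the correctness of
the transform, filter, clustering and mapping machinery — not robustness to
instrumental artefacts absent from the simulation.

## Discretization bias of the discrete phasor

The discrete sums over 195 ps bins approximate the continuous Fourier
integrals by the midpoint rule, which biases the recovered phase lifetime
of a noiseless mono-exponential by approximately $\Delta^2/(12\tau)$
($\Delta$ = bin width). At the default binning this is +1.3% at τ = 0.5 ns,
+0.1% at 1.7 ns, +0.03% at 3.7 ns; a characterization test pins the
measured bias to this law. The bias is intrinsic to the estimator — binning
the counts as per-bin integrals instead of point samples yields the
identical phasor, since the two differ by a constant factor per decay
component — so validations of transform *correctness* across the full
0.5–8 ns range use a finer 2048 × 24 ps validation configuration, where
recovery is better than 0.05% everywhere. Above τ ≈ 4 ns a second,
window-truncation effect (49.92 ns of a 50 ns period) dominates the bias
instead; both effects stay well below the shot-noise spread at realistic
count levels. Count quantization adds a third, peak-height-dependent
perturbation: at peak 500 it displaces noiseless phasors from the
semicircle by ~1e-3, so semicircle-geometry checks simulate at peak 1e5
where quantization is negligible against the 5e-4 discretization bound.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `rep_rate_hz` | 2e7 | Hz | laser repetition rate; sets ω and the 50 ns period |
| `n_bins`, `bin_width_s` | 256, 1.95e-10 | —, s | TCSPC card resolution; window must fit one period |
| `threshold` | 100 | counts | strict peak-count quality filter |
| `k` | 2 | — | two known mixtures at an interface |
| `target_peak` | 500 | counts | realistic high-quality acquisition, 5× the filter |
| `tol`, `max_iter`, `n_starts`, `ridge` | 1e-8, 500, 5, 1e-10 | — | EM numerics, above |
| `t_min_ns`, `t_max_ns` | 2.0, 4.5 | ns | lifetime colour ramp endpoints (blue → red) |

## Problem sizes used in validation

The shipped tests run on maps from 2 × 2 up to 50 × 60 pixels (the full
3000-decay interface experiment, executed once in the end-to-end recovery
test and by `scripts/acceptance.R`), mixture fits on 40–600 points, and
lifetime grids of 16–31 values — sizes at which every check completes in
seconds while exercising the same code paths as larger maps.

## Known limitations

* τ-phase is reported per pixel from a single harmonic; multi-harmonic
  fingerprinting and fitted multi-exponential decomposition are out of
  scope.
* Phasors with g ≤ 0 (not produced by physical non-negative decays at the
  first harmonic, but possible after background subtraction or on corrupt
  input) stay in the cloud for clustering but carry a missing lifetime and
  are excluded from cluster lifetime statistics.
* Exhaustive permutation scoring in `segmentation_accuracy()` targets small
  K (≤ 6); the pipeline's default is K = 2.
* The lifetime TIFF export uses a fixed-point encoding (sample =
  τ_ns / 100, 0 = missing) because the underlying TIFF writer stores
  scaled integer samples; the CSV export carries exact values.
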