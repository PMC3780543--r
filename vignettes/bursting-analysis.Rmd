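---
title: "Quantifying frequency-modulated transcriptional bursting with burstkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying frequency-modulated transcriptional bursting with burstkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstkit)
```

## The model

burstkit analyzes gene expression under the random telegraph model: a
promoter switches between an inactive and an active state with activation
rate $a$ and inactivation rate $b$ (both 1/min); while active it initiates
transcripts at rate $c$, and mRNA decays with first-order rate $d$. At
steady state the mean copy number is

$$\langle N \rangle \;=\; \frac{c}{d}\,\frac{a}{a+b},$$

the product of the active-state ceiling $c/d$ and the active fraction
$a/(a+b)$. Snapshot data (per-cell mRNA counts) identify only the
decay-normalized ratios $\alpha = a/d$, $\beta = b/d$, $\gamma = c/d$;
all distribution fitting therefore works in $(\alpha,\beta,\gamma)$ space
(`normalized_params()`).

The stationary copy-number distribution is

$$P(n) \;=\;
\frac{\Gamma(\alpha+n)\,\Gamma(\alpha+\beta)}
     {\Gamma(n+1)\,\Gamma(\alpha+\beta+n)\,\Gamma(\alpha)}\,
\gamma^{\,n}\, {}_1F_1(\alpha+n;\,\alpha+\beta+n;\,-\gamma).$$

**Numerical evaluation.** The confluent hypergeometric factor with a large
negative argument is an alternating series that overflows long before
$\gamma = 340$ (a realistic active-state ceiling for a strong reporter).
`telegraph_pmf()` applies the Kummer transformation
${}_1F_1(\alpha+n; \alpha+\beta+n; -\gamma) =
e^{-\gamma}\,{}_1F_1(\beta; \alpha+\beta+n; \gamma)$, whose series has
non-negative terms, and accumulates it in log space with a streaming
log-sum-exp (compiled code). Summation stops once past the term peak and 45
nats below the running maximum. The truncated tail mass is attached to the
result and a warning fires when it exceeds $10^{-6}$.

**Independent oracle.** `cme_oracle()` builds the truncated generator of
the joint (promoter state, copy number) chain with unit decay rate and
solves for its stationary null vector with a sparse LU factorization
(Matrix). It shares no code with the analytic path; the test suite requires
elementwise agreement within $10^{-6}$ over a 27-point parameter grid.

## Frequency modulation and the Hill correspondence

When ligand dose modulates only the activation rate, $a = k\cdot\text{dose}$,
the steady-state mean is *exactly* a Hill function of dose with coefficient
one:

$$\langle N\rangle(\text{dose}) =
\gamma\,\frac{\text{dose}}{\text{dose} + \beta/k},$$

so $A_\mathrm{max} = \gamma = c/d$ and $EC_{50} = \beta/k = b/k$
(`telegraph_hill_equiv()`; the identity is tested to machine precision).
A measured population dose response with $h \approx 1$ is the macroscopic
signature of pure burst-frequency modulation: the ligand changes how often
the gene fires, not how long it stays on or how fast it initiates.

## Fitting copy-number histograms

`fit_counts()` maximizes the multinomial log-likelihood of binned counts
(default bin width 100 mRNA; the last bin is open-ended so no probability
is lost to truncation). With one group all three parameters are free; with
a dose series $\beta$ and $\gamma$ are shared and each dose gets its own
$\alpha$ — the frequency-modulation hypothesis expressed as a constraint.

Choices that matter:

* **Optimizer.** Bounded quasi-Newton (`L-BFGS-B`) on log-parameters.
  Eight multi-starts: a method-of-moments center (active fractions from
  group means, $\gamma$ from the upper tail of the top group, $\beta$ from
  its Fano factor) plus Latin-hypercube perturbations of roughly
  $e^{\pm1.2}$. Multi-starts run at a coarse tolerance and the winner is
  polished tightly; near-ties are broken toward the smallest $\gamma$.
  The gradient is forward-difference but exploits separability: each
  $\alpha_g$ touches only its own dose's likelihood term.
* **Bounds.** $\alpha, \beta \in [10^{-3}, 10^{3}]$ and
  $\gamma \in [10^{-2}, 30\times\max(\text{count})]$. The $\gamma$ ceiling
  is substantive as well as numerical: the active-state ceiling cannot
  meaningfully exceed a modest multiple of the largest observed count, and
  series cost grows linearly with $\gamma$.
* **Degenerate data.** Poisson-distributed counts (no detectable
  bursting) drive the fit to a boundary — $\beta$ to its floor or
  $\alpha$ to its ceiling, both of which are the Poisson limit. Boundary
  contact is flagged in the result rather than hidden.
* **Uncertainty.** Parametric bootstrap (`n_boot`): counts resampled from
  the fitted distribution, refit from the fitted optimum, percentile
  intervals. Off by default because point recovery is the common use.

## Simulating the data the pipeline consumes

All simulation is exact Gillespie (compiled); frame-sampled quantities are
read off the exact event stream, never approximated by leaping.

* **Counts** (`simulate_counts()`): each cell starts inactive with zero
  transcripts and is evolved for $20/\min(a,b,d)$ time units before
  readout. Sampling the relaxed chain rather than the analytic PMF keeps
  the simulator an independent route: the chi-square agreement between the
  two is a real cross-check, not a tautology.
* **Traces** (`simulate_trace()`): the site intensity at a frame is the
  number of initiation events inside the trailing `nascent_dwell` window
  (one unit per nascent transcript) plus Gaussian noise. Presets:
  `steady` (initial state drawn from the stationary law), `induction`
  (starts inactive — the transient-induction experiment), `pulse` (one
  activity period, no re-activation — the single-pulse experiment), and
  `always_on` (a non-chromatinized, constitutively firing template).
* **Images** (`render_image()`): spots are 2-D Gaussians of fixed PSF
  width at sub-pixel positions over a flat background; optional elliptical
  nucleus/cell regions are painted and then smoothed (diffuse staining —
  sharp synthetic edges would masquerade as diffraction-limited structure);
  noise is Poisson shot noise on the expected image plus Gaussian read
  noise, the standard camera model. Coordinates are 0-based $(x, y)$ with
  $x$ the column and centers at pixel centers, everywhere.

What the generator does *not* emulate — and what passing tests therefore
do not certify about real data: photobleaching and focus drift, cell
division and movement, 3-D optics (images are born 2-D), diffusing
cytoplasmic mRNA, extrinsic (cell-to-cell) parameter variability, and a
stochastic elongation time (the nascent dwell is deterministic).

## Decoding transcription-site traces

`fit_hmm_decode()` fits a two-state Gaussian-emission hidden Markov model
per trace by Baum-Welch EM (k-means initialization, five restarts,
relative log-likelihood tolerance $10^{-8}$, 500-iteration cap), after
rescaling the trace by its (5th, 95th) percentile window. States are
labeled by emission mean (off = lower). The cited trace-fitting literature
uses a variational-Bayes flavor; plain EM is used here because nothing
downstream depends on VB-specific machinery — a deliberate, documented
simplification.

Three design points deserve emphasis:

* **Single-state guard.** A one-Gaussian model is fit alongside and
  preferred by AIC when the trace shows no evidence of two levels; such
  traces decode all-off when their raw mean sits at baseline (below three
  raw standard deviations), all-on otherwise. AIC rather than BIC: at 60
  frames, promoter flips inside a frame blend the two intensity levels,
  and the BIC penalty collapsed roughly a fifth of genuinely bursting
  traces in synthetic benchmarks; AIC keeps those while still collapsing
  featureless vehicle-control traces.
* **Viterbi vs. per-frame paths.** The Viterbi path (the contract answer
  for "the decoded state sequence") inherits the fitted self-transition
  probabilities and therefore suppresses single-frame excursions. For
  *dwell statistics* this is a bias, not a smoothing benefit: on synthetic
  truth with 36/35-min dwells sampled at 15-min frames, Viterbi-derived
  rates over-estimate dwells by ~50%. `fit_hmm_decode()` therefore also
  returns `path_midpoint` — each frame classified against the midpoint of
  the two fitted emission means — which the dwell pipeline uses.
* **Dwell estimation.** Run-length dwell means from a frame-sampled path
  are biased upward by quantization and by unobserved double flips between
  frames (naive recovery: ~51/50 min for a true 36/35). `fit_dwell_rates()`
  removes the bias exactly for a two-state Markov process: it estimates the
  per-frame transition matrix $P$ from pooled path transitions and maps it
  to continuous time through the matrix logarithm,
  $Q = \frac{\ln\lambda}{(\lambda-1)\,\Delta t}(P - I)$ with
  $\lambda = 1 - P_{01} - P_{10}$; mean dwells are the inverse rates. The
  estimate is valid only when $\lambda > 0$, i.e. when frames are fast
  enough that the chain does not fully mix between observations; the
  function flags violations instead of extrapolating. When pooling across
  traces, the pipeline uses only traces whose decode kept two states: a
  single-state decode has no transitions and would contribute pure
  self-transition dilution, and at kinetics where a burst is expected
  every hour or two, a 15-hour trace decoded with zero bursts is a decoder
  artifact rather than evidence. The literal
  dwell-set estimator (`fit_dwell_exponential()`, sample-mean MLE with an
  optional censored likelihood) is retained for dwell tables, where the
  censoring bookkeeping — boundary-touching runs only bound their dwell
  from below — is the point.

**Observability in the default trace study.** The live-cell design
(`run_config()` defaults, and the package's own validation experiments)
images every 15 min for 15 h and sets the nascent dwell equal to the frame
interval, so the trace integrates initiation over the whole interval. With
a much shorter visibility window most of the timeline is simply invisible
— with a 5-min window at 15-min frames even classification with generative
truth cannot recover the dwell kinetics. A window of one frame interval
corresponds physically to a slowly elongating or retained reporter
transcript; `trace_config()` itself defaults to a 5-min dwell for users
modeling faster reporters. The trace noise default (`noise_sd = 6` against
an on-level of $c \times$ window $= 30$) realizes an on-level-to-noise
ratio of 5.

The dose sweep in `run_trace_pipeline()` scales the activation rate as
$a = (1/\text{off mean}) \cdot \text{dose}/\text{ref\_dose}$, anchoring
the off-time at the saturating reference dose (50 µM by default) to the
measured value; the inactivation rate is dose-independent. This reproduces
the frequency-modulation signature: off-times fall with dose, on-times and
intensities per burst stay flat.

## Spot detection, segmentation, counting, tracking

* **Detection** (`localize_spots()`): difference-of-Gaussians band-pass
  ($\sigma$ and $1.6\sigma$), strict 8-neighbor maxima above
  median + 6 MAD of the filtered image, then iterative Gaussian-mask
  refinement with fixed PSF width until the center shifts $<10^{-3}$ px.
  The integrated intensity is the least-squares Gaussian amplitude times
  $2\pi\sigma^2$. Two guards suppress false positives that a global
  threshold cannot: a local signal-to-noise test (fitted peak amplitude
  against the MAD of the fit window's border — shot noise is stronger
  inside bright nuclei than the global background suggests) and, at the
  counting stage, gating of detections dimmer than 40% of the median spot
  intensity (the usual single-mRNA intensity gating). Detections within
  1 px merge, keeping the brighter.
* **Segmentation** (`segment()`): Otsu threshold (manual override
  supported, since real acquisitions are often thresholded by eye) →
  hole filling → connected components → area filter → removal of
  border-touching nuclei. Cells: a second Otsu pass on the
  sub-nuclear-threshold pixels separates cytoplasm from background, and
  the cell mask is partitioned among nucleus seeds by seeded region
  growing (`EBImage::propagate`), so each cell contains its nucleus.
* **Counting** (`count_and_classify()`): spots belong to the cell whose
  label contains their center; a transcription site is a nuclear spot at
  least twice the median single-spot intensity (an operational stand-in
  for by-eye brightness calls; configurable), optionally counted as
  intensity-equivalent mRNA units.
* **Tracking** (`track_ts()`): greedy nearest-neighbor linking within
  `max_jump`, gap closing up to `max_gap` frames, missed frames recorded
  as intensity 0 (darkness is off-state evidence). Candidate matches are
  taken in order of increasing displacement with ties to the earlier
  track — a greedy approximation to minimal total displacement, adequate
  for well-separated transcription sites (one per cell).

## Problem sizes, seeds, determinism

Every stochastic routine takes one integer seed, set once per top-level
call; repeated calls with the same seed are bit-identical. The package's
validation experiments use: 5000 cells/dose across six doses for joint
telegraph recovery; 500 traces of 60 frames for dwell and occupancy
recovery; 60 cells/dose for the Hill fits (the fixed-cell sample size of
the study design); 1000 rendered cells for the imaging-to-fitting
composition; $10^4$ cells per chi-square comparison of simulator and
analytic distribution. Where the full-scale experiment appears in the
acceptance script, unit tests run reduced replicates of the same property
(e.g. six joint-fit replicates at 3 × 1500 cells) so the default test run
stays fast.

## Known limitations

* Dwell-rate recovery requires $\lambda > 0$; at doses where the off-time
  falls below the frame interval the per-frame transition matrix carries
  little information and estimates degrade (flagged, not fixed).
* The binned likelihood treats cells as i.i.d.; extrinsic variability
  (e.g. volume, cell-cycle stage) will inflate the apparent $\beta$.
* The HMM assumes Gaussian emissions; the on-state intensity is really a
  Poisson mixture, absorbed into the state variance.
* `fit_counts()` assumes steady state; transient (time-resolved)
  distribution fitting is out of scope.
* Spot counting degrades when spot density approaches the diffraction
  limit (merged detections); the TS threshold rule is a heuristic.
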