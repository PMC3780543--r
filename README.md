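# burstkit

Tools for asking, quantitatively, *how* a transcriptional activator dose
changes gene output: by firing the gene more often (frequency modulation),
for longer (duration modulation), or harder (amplitude modulation).
burstkit is written for people analyzing single-molecule gene-expression
data — smFISH copy-number histograms across a ligand dose series, and
live-cell MS2-type transcription-site intensity movies — and for people
who want a fully synthetic, ground-truthed replica of such an experiment
to validate an analysis against.

## The model

The random telegraph model: a promoter switches between an inactive and an
active state with activation rate *a* and inactivation rate *b*; the
active gene initiates transcripts at rate *c*; mRNA decays at rate *d*.
At steady state

    ⟨N⟩ = (c/d) · a/(a+b),

and the full stationary copy-number distribution is the Poisson-beta form

    P(n) = [Γ(α+n) Γ(α+β) / (Γ(n+1) Γ(α+β+n) Γ(α))] · γⁿ · ₁F₁(α+n; α+β+n; −γ)

in the decay-normalized parameters α = a/d, β = b/d, γ = c/d (evaluated
stably in log space via the Kummer transformation; an independent
master-equation solver serves as a numerical oracle). If dose enters only
through the activation rate, a = k·dose, the mean dose response is exactly
a Hill curve with coefficient h = 1, A_max = γ and EC50 = b/k — so a
non-cooperative population dose response plus dose-invariant burst
duration and intensity is the signature of frequency modulation.

The package covers the full chain:

| step | functions |
|---|---|
| exact Gillespie simulation (counts, traces, dose series) | `simulate_counts`, `simulate_trace`, `simulate_dose_series` |
| analytic PMF, moments, master-equation oracle | `telegraph_pmf`, `telegraph_summary`, `cme_oracle` |
| binned joint maximum-likelihood fitting | `fit_counts` |
| Hill fitting and the telegraph correspondence | `fit_hill`, `hill_curve`, `telegraph_hill_equiv` |
| two-state HMM trace decoding and dwell analysis | `fit_hmm_decode`, `extract_dwells`, `fit_dwell_exponential`, `fit_dwell_rates` |
| synthetic images, spot localization, segmentation, counting, tracking | `render_image`, `localize_spots`, `segment`, `count_and_classify`, `track_ts` |
| end-to-end arcs | `run_dose_pipeline`, `run_trace_pipeline` |

## Worked example

Simulate a six-dose smFISH experiment (5000 cells per dose) in which only
the activation rate scales with dose, then fit every dose's copy-number
histogram jointly with shared β = b/d and γ = c/d:

```r
library(burstkit)

doses <- c(1.56, 3.125, 6.25, 12.5, 25, 50)                 # uM
dm  <- dose_map(doses, activation_scale = 1.5 / 9.6)        # EC50 = b/k = 9.6
tab <- simulate_dose_series(normalized_params(1, 1.5, 340), dm,
                            n_cells_per_dose = 5000, seed = 101)
fit_counts(tab, bin_width = 100)
#> Binned maximum-likelihood telegraph fit
#>   shared b/d = 1.491, c/d = 339.5 (bin width 100)
#>   per-group a/d:
#>     1.56: 0.2542
#>     3.125: 0.4899
#>     6.25: 0.9951
#>     12.5: 1.929
#>     25: 3.957
#>     50: 7.901
#>   log-likelihood -29372.80; converged: TRUE
```

The generative truth was β = 1.5, γ = 340, α rising linearly from 0.244 to
7.81: the joint fit recovers the shared burst parameters within ~1% and
the per-dose activation rates in order. The same means, fit with a
two-parameter Hill curve at 60 cells/dose (the fixed-cell sample size):

```r
ag <- aggregate(mrna_count ~ dose_uM,
                simulate_dose_series(normalized_params(1, 1.5, 190), dm, 60,
                                     seed = 21),
                function(x) c(m = mean(x), se = sd(x)/sqrt(length(x))))
fit_hill(ag$dose_uM, ag$mrna_count[, "m"], ag$mrna_count[, "se"], fix_h = 1)
#> Hill fit (h fixed): A_max = 184.2 (SE 5.79), EC50 = 8.528 (SE 0.937), h = 1
```

A_max estimates γ (here 190) and EC50 estimates b/k (here 9.6) — the
Hill↔telegraph correspondence in action. On the live-cell side,
`simulate_traces` + `fit_hmm_decode` + `fit_dwell_rates` recover mean
on/off dwell times from 15-min-interval transcription-site movies; see the
vignette (`vignettes/bursting-analysis.Rmd`) for the estimator details,
including why dwell rates are read off the decoded transition matrix
through a matrix logarithm rather than from raw run lengths.

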