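---
title: "Inter-departure time analysis of EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inter-departure time analysis of EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegtraffic)
```

## The model

`eegtraffic` treats a population of neurons under an electrode as a node in
a communication network that emits discrete units of information
("messages"). Peaks of band-limited EEG power reflect synchronous
post-synaptic activity; the troughs that separate successive peaks are
taken as the moments at which a unit of information departs the node. The
pipeline is:

1. **Time-frequency decomposition.** Each epoch is convolved with a complex
   Morlet wavelet at six scales whose pseudo-frequencies are 5–30 Hz in
   5 Hz steps; power is the squared modulus of the complex coefficients.
2. **Departure detection.** Troughs of the scalogram amplitude at each
   channel and scale are marked as departures, subject to a prominence
   threshold that suppresses insignificant dips.
3. **Interval statistics.** The positive delays between successive
   departures (inter-departure times, τ, in digitization intervals) are
   pooled across epochs per (subject, condition, channel, frequency) cell
   and fitted with the two-parameter Gamma distribution by maximum
   likelihood,
   \[
     f(x; k, \theta) = \frac{x^{k-1} e^{-x/\theta}}{\Gamma(k)\,\theta^{k}},
     \qquad \mathrm{CV} = k^{-1/2},
   \]
   with Weibull and other candidates available for goodness-of-fit
   ranking.
4. **Queueing interpretation.** A Gamma fit with shape \(k\) and scale
   \(\theta\) is read as an Erlang serial server: \(k\) exponential service
   stages at rate \(\mu = 1/\theta\). Serial stages give CV
   \(k^{-1/2} < 1\) (hypoexponential); parallel branching gives CV > 1
   (hyperexponential).
5. **Condition contrasts.** Shape and scale maps (channels × frequencies)
   are compared between paired conditions with mean-centered task PLS,
   assessed by permutation tests on the singular values and bootstrap
   standard errors of the element saliences.

## Wavelet parameterization

The mother wavelet is
\(\psi(u) = (\pi f_b)^{-1/2} e^{2\pi i f_c u} e^{-u^2/f_b}\) with center
frequency \(f_c = 1\) Hz. The scale \(a\) realizing an analysis frequency
\(f\) at digitization interval \(\Delta t\) follows the pseudo-frequency
relation \(f = f_c / (a\,\Delta t)\).

The envelope bandwidth is specified in the literature in seconds ("2 s"),
not as a toolbox parameter, so a convention had to be fixed: we take
\(f_b = 2\), which gives the mother envelope a ±1 SD width of exactly 2 s
and — at every scale — exactly two carrier cycles inside that central
window. This realizes the stated design trade-off (the narrowest envelope
that still holds two full cycles, maximizing temporal precision) with a
closed-form wavelet. `wavelet_spec(bandwidth =)` exposes the parameter; no
test in the package depends on its absolute value.

Convolution is computed by FFT with zero padding. The truncated wavelet's
half-width (4 envelope SDs, i.e. \(4a\) samples at scale \(a\)) is recorded
per scale as a cone of influence; departures inside it are artifacts of the
padded edges and are dropped by default (`drop_edge_events = TRUE`).
Signals shorter than four times the longest truncated wavelet are rejected.

## Departure detection

"Local minimum with a local neighborhood threshold" is formalized as
topographic prominence: a candidate trough with value \(v\) survives if, on
both sides, the series rises by at least
`threshold_ratio` × (max − min of the series) before reaching a sample
strictly deeper than \(v\). Runs of equal minimal values yield one event at
the run midpoint (rounded down); runs touching the series ends are
excluded. The implementation is a compiled single pass; an independent
brute-force oracle in the test suite reproduces its event sets exactly.

Two conventions matter and are worth stating explicitly:

* **Normalization series.** The threshold is a ratio of the range of the
  scalogram *amplitude* (the modulus, not its square). Trough locations are
  unchanged by the monotone square, but power ranges are dominated by a few
  extreme peaks, which would make the effective threshold much more
  aggressive and far less stable.
* **Epoch boundaries.** Intervals are differenced within epochs before
  pooling; no interval ever spans the gap between epochs.

**Threshold sensitivity.** Sweeping the prominence threshold over 2–10%
monotonically removes low-prominence events (event counts are
non-increasing in the threshold, a tested invariant). On noise-dominated
channel × scale series roughly a quarter of the events sit in that
prominence band, so the *scale* parameter of the downstream Gamma fit
shifts systematically by ~20% across the sweep while the *shape* parameter
— the functional form of the distribution — stays within ~10% at large
sample sizes. Analyses that compare conditions at a fixed threshold are
unaffected (the default is 5%), but absolute values of \(\theta\) should be
reported together with the threshold that produced them. This is a known
limitation of the prominence formalization, surfaced honestly by the
package's own stability test.

## Distribution fitting and ranking

The Gamma MLE solves the profile-likelihood equation
\(\log k - \psi(k) = \log \bar x - \overline{\log x}\) by a safeguarded
root search (bracket expansion around a moment-style start, `uniroot`
tolerance 1e-10), then sets \(\hat\theta = \bar x / \hat k\). The Weibull
shape solves its own profile equation the same way. Exponential, lognormal
and normal candidates have closed-form MLEs. Samples with fewer than
`min_n = 10` intervals are reported as missing, never fabricated;
zero-variance samples raise a degenerate-sample error because the shape
MLE diverges.

Goodness of fit uses the chi-square statistic on bins that are
equiprobable under the fitted distribution, so every bin has the same
expected count and the degrees-of-freedom adjustment
\(df = B - 1 - p\) (with \(p\) parameters estimated from the data) is
honest. The default bin count is \(\max(6, \lfloor n/50 \rfloor)\), capped
at 50, keeping expected counts near 50; the candidate ranking is stable
across \(B \in \{10, 20, 30\}\) (tested). Kolmogorov–Smirnov and
Anderson–Darling are deliberately not provided: their critical values do
not account for estimated parameters.

## PLS details

* **Centering.** The condition-mean matrix (conditions × elements) is
  centered column-wise by the grand mean of the condition means — the
  standard mean-centered task-PLS variant — and decomposed by SVD. Only the
  \(n_{conditions} - 1\) informative latent variables are returned; effect
  sizes are \(s_i^2 / \sum_j s_j^2\) over those.
* **Permutation scheme.** Each replication reassigns the order of
  conditions *within each participant* independently (sampling without
  replacement of that subject's labels), preserving the paired design. The
  p-value is the plain proportion of permuted singular values at the same
  LV position that equal or exceed the observed one; a
  `(b + 1) / (n + 1)` estimator is available via `plus_one = TRUE`.
* **Bootstrap.** Participants are resampled with replacement, the same
  resample applied to every condition block. Each bootstrap LV is
  sign-aligned to the original element saliences before standard errors
  accumulate; with two conditions the sign is the only indeterminacy. With
  more than two conditions, LV order swaps under resampling are not
  corrected (no Procrustes rotation) — a documented limitation.
* **Reliability cutoff.** The conventional two-sided 99% cutoff on
  bootstrap ratios is 2.57, which is \(\Phi^{-1}(0.995) = 2.5758\ldots\)
  *truncated* at two decimals (rounding would give 2.58).
  `bootstrap_ratio_cutoff()` reproduces the truncation convention.

## The synthetic generator

`synth_spec()` defaults emulate a resting-state pediatric protocol: 56
subjects, 128 channels at 500 Hz, two conditions alternating over eight
30 s epochs, of which the middle 20 s survive preprocessing (0.5–55 Hz
band-pass, 60 Hz notch, per-epoch demeaning).

Each channel is unit-SD 1/f Gaussian background plus band-limited
oscillations (defaults: 10 Hz at amplitude 6, 20 Hz at amplitude 2) whose
amplitude envelopes are renewal processes: burst onsets separated by
Gamma-distributed intervals (shape `burst_shape = 2`, mean 0.8 s), each
burst a raised-cosine bump two carrier periods wide. The alpha-dominant
amplitudes and sparse bursts were chosen so that envelope troughs are
resolvable at the wavelet's temporal resolution; under that condition the
renewal shape maps monotonically onto the downstream fitted \(\hat k\)
(verified: renewal shapes 2, 3, 4, 6 give \(\hat k \approx\) 6.3, 7.3,
7.7, 9.8 at the 10 Hz scale), which is what makes ground-truth recovery
testable. The condition effect multiplies the renewal shape by
\(1 + \texttt{effect\_magnitude}\) on designated channels — a change of
envelope *regularity*, not of band power, so detected condition
differences cannot be explained by power spectral density alone.

What the generator does **not** emulate: ocular/muscle artifacts and their
ICA cleaning, volume conduction and channel covariance, non-stationary
drifts, or any true physiology of message passing. Passing tests therefore
demonstrate that the pipeline recovers the statistical structure it
assumes, not that recorded EEG has that structure.

## Problem sizes and numerical choices

Simulation-based tests run at desk scale, chosen to keep the full suite
within a few minutes while leaving comfortable statistical margins:
detector–oracle equivalence on 1,000 series of length 500; Gamma recovery
over 200 replicates at n = 2,000 (plus single fits at n = 10,000);
CV convergence at n = 100,000; permutation calibration over 200 null
datasets of 12 subjects × 24 elements at 200 permutations; effect
recovery at 20 subjects with 500 permutations/bootstraps; end-to-end EEG
runs with up to 10 subjects × 8 channels. The full-size default study
(56 × 128) is configurable but not exercised by the tests.

Tie-breaks and degenerate inputs are all deterministic: plateau troughs
take the midpoint; equal chi-square statistics rank by fewer estimated
parameters, then name; identical condition means yield all-zero singular
values flagged `degenerate`; zero bootstrap SEs yield ±Inf ratios with a
warning. Every stochastic function takes an explicit seed and restores the
caller's RNG state.

## Limitations

* The scale parameter's sensitivity to the detection threshold (above).
* Plain EDF carries no condition labels; the package uses a text sidecar.
* The Erlang reading of Gamma fits is an interpretation, not an inference:
  a CV below 1 is *consistent with* serial stages, it does not identify
  them.
* Bootstrap sign alignment is per-LV only; salience reliability with more
  than two conditions should be interpreted with care.
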