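---
title: "Methods: from calcium movies and arena videos to condition comparisons"
author: "psiacx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from calcium movies and arena videos to condition comparisons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psiacx)
```

`psiacx` implements the analysis chain used in studies of psychedelic drug
effects on mouse auditory cortex: two-photon (2P) calcium-trace processing,
response-amplitude and noise-correlation statistics, widefield tonotopy,
video-based movement quantification, and a pooled bootstrap test that ties
the condition comparisons together. Because such studies rarely deposit raw
movies, the package ships seeded generators that emulate every input with
embedded ground truth; all claims the test suite makes are claims about
recovering that ground truth.

## Stimulus protocol

`make_tone_protocol()` builds a pure-tone set as a geometric series with
`tones_per_octave` tones per octave. The canonical protocol spans 2–45 kHz
at 2 tones/octave: ten tones, 2.00–45.25 kHz. The nominal upper bound is
admitted with a 1% tolerance (`endpoint_tol`), since the tenth tone of the
series (45.25 kHz) slightly exceeds the nominal 45 kHz endpoint but is part
of the ten-tone set. Each tone is presented 20 times, 0.5 s long at 70 dB
SPL, with inter-stimulus intervals drawn uniformly from {6, 7, 8} s; the
trial order is a seeded random permutation.

## Synthetic two-photon sessions

The generator (`synth_neural_config()`, `simulate_experiment()`) produces
per-trial evoked amplitudes

\[
a_{it} = g \, b_i \exp\!\left(-\frac{(\log_2 f_t - \log_2 \mathrm{BF}_i)^2}
{2 w^2}\right) + \sigma_\varepsilon\left(\sqrt{\rho}\, z_t +
\sqrt{1-\rho}\,\eta_{it}\right),
\]

with condition gain \(g\), per-neuron base amplitude \(b_i\) (log-normal,
median 0.3 ΔF/F, 30% spread), Gaussian log-frequency tuning of width
\(w\) octaves (default 1), and a shared unit-normal trial factor \(z_t\)
that gives every neuron pair an expected noise correlation \(\rho\). Best
frequencies are drawn from the protocol grid, which makes zero-noise BF
recovery an exact check rather than a rounding exercise.

Amplitudes are placed on the 30 Hz frame timebase by convolution with a
GCaMP6s-like kernel (`gcamp_kernel()`): a peak-normalized double
exponential, 0.18 s rise and 1.5 s decay, consistent with published
GCaMP6s timescales. The kernel is truncated at 4 s with a raised-cosine
taper over its last 0.5 s. The truncation is deliberate: with the shortest
inter-stimulus interval (6 s) and the 2 s baseline window, a transient
that dies within 4 s can never leak into the next trial's baseline, so the
noiseless recovery tests are exact to machine precision rather than "up to
kernel tails". Traces sit on a strictly positive baseline offset (default
1 arbitrary unit) so ΔF/F denominators are well defined, and the raw
somatic trace is contaminated as \(C_\mathrm{raw}(t) = C(t) + 0.7\,N(t)\)
with a slowly oscillating neuropil trace \(N\).

## Fluorescence processing

* `build_roi_masks()` — somatic annulus (default radii 2–6 px at the
  0.8 µm/px scale of a 16× objective; the radii are package defaults, not
  measured values) and a neuropil ring starting 3 px beyond it, 10 px
  wide. Somatic pixels claimed by two neurons are excluded from both;
  neuropil pixels never overlap any somatic set.
* `neuropil_correct()` — \(C(t) = C_\mathrm{raw}(t) - 0.7\,N(t)\).
* `qc_filter_cells()` — neurons kept only if the time-mean of the
  corrected trace is strictly positive (negative means indicate
  over-subtraction); a mean of exactly zero is dropped.
* `compute_dff()` — per trial, baseline \(\bar F\) is the mean over the
  2 s silent window before onset, and
  \(\Delta F/F = (F - \bar F)/\bar F\) out to 3 s after the tone. The 2 s
  baseline is a package choice: the shortest ISI (6 s) leaves neurons
  quiescent for at least that long. Window edges are half-open on the
  frame grid, `(onset, onset + w]`, rounded to the nearest frame.
* `response_amplitude()` — mean ΔF/F over the 1 s after onset.
* `sigma_normalize()` — each neuron's ΔF/F is divided by σ, the sample SD
  (denominator \(n-1\)) of its 1-s amplitudes across trials. Taking the
  SD over trial amplitudes (rather than over time) is the reading we
  adopt; after normalization, every retained neuron's amplitude SD is
  exactly 1, which the tests assert. Condition comparisons operate on
  these σ-normalized amplitudes.

## Tuning and noise correlations

`tuning_curve()` averages 1-s amplitudes within frequency; the best
frequency is the curve's argmax with exact ties broken to the lowest
frequency (deterministic and documented). `peak_normalize()` scales each
curve to unit peak, `group_average_ftc()` averages curves within BF
groups (up to 10 per condition), and `off_bf_ratio()` reports the mean
off-BF response as a percent of the BF response.

`noise_correlations()` subtracts each neuron's per-frequency mean
response, pools residuals over all trials, and computes the Pearson
correlation for each pair; the experiment-level statistic is the mean of
the upper triangle. Residuals are pooled raw, not z-scored per frequency
— with σ-normalized inputs the residual variance is already comparable
across frequencies, and the estimator is invariant to per-neuron affine
rescaling either way. The statistical unit for condition comparisons is
one mean per experiment; amplitude comparisons instead pool neurons
across experiments.

## Widefield tonotopy

`homomorphic_filter()` removes smooth multiplicative illumination:
log-transform, subtract a large-kernel Gaussian blur of the log image
(default sigma 50 px on 512 px frames), exponentiate. The blur is
implemented as a dense separable weight matrix with replicate padding
folded into the edge weights, so constant frames remain exactly constant
and the sigma may exceed the frame size. `pixel_dff()` applies the same
ΔF/F construction per pixel and averages over the repeats of each
frequency. `dff90_select()` keeps, per pixel, the frequencies whose
frequency-averaged trace peaks within 90% of that pixel's maximum peak —
we read "within 90% of the maximum" as ≥ 0.9 × max; the alternative
reading (≥ 10%) would select almost everything and could not support
frequency assignment. The per-pixel maximum (not a global scalar) is
used, since the output is a per-pixel frequency set. `tonotopic_map()`
assigns the median selected frequency on the octave axis; even-sized sets
take the geometric mean of the two middle tones (the octave-axis
midpoint).

The widefield generator lays the true BF out in contiguous monotone bands
along the gradient axis, one band per protocol tone. A banded (grid-valued)
truth map is the deliberate choice: the estimator can only return grid
tones or between-tone medians, so exact noiseless recovery — Spearman
correlation 1.0 against truth — is only a meaningful target when the truth
itself lives on the grid. The default pixel tuning width is 0.8 octaves,
narrow enough that a pixel's own tone beats its half-octave neighbours by
more than the 90% criterion in the noiseless limit.

## Behavior

`frame_difference()` forms \(V'(f) = V(f+1) - V(f)\);
`frame_energy()` sums |V′| over pixels — absolute values, because signed
differences of a brightness-conserving moving object cancel to nearly
zero. `movement_envelope()` takes the magnitude of the analytic signal
(FFT construction) of mean-removed D, smooths it with a zero-phase
order-2 Butterworth low-pass at 0.5 Hz (seconds-scale smoothing), restores
the mean and clamps at zero. `spatial_movement_map()` averages |V′| per
pixel within a time window and zeroes pixels below twice the standard
error of that pixel's |V′| across the whole video; compared maps are
normalized jointly to their common peak. `window_means()` averages M over
the 0–10 and 10–60 min windows, truncating (with a warning) when sessions
are shorter. `template_correlation()` bins M to the head-twitch template's
60 s bins and reports the Pearson correlation; 60 s is a package choice
for the bin width.

The video generator moves a Gaussian blob through a reflecting arena in
intermittent bouts (exponential on/off, mean 2 s each). Bout-gated
locomotion matters: a blob gliding at constant speed produces an almost
constant difference-energy trace, and the envelope of a constant is
uninformative; intermittent movement is both what mice do and what makes
the Hilbert envelope track activity. `truth_speed` records the programmed
profile speed (not the bout gating), so the control profile's truth is
exactly constant. Head twitches are rendered as ≤ 0.2 s bursts of
high-amplitude positional jitter with a decaying-rate profile that stops
at 10 min, emulating the reported head-twitch time-course; the behavioral
hypoactivity profile switches from 20 px/s to 3 px/s at a programmed
time.

## Bootstrap test

`bootstrap_mean_test()` implements the pooled bootstrap for a difference
of means: observed \(\Delta\mu = |\bar A - \bar B|\); pool \(A \cup B\);
draw \(A^*\) and \(B^*\), each of size \(\min(n, m)\), independently with
replacement from the pool, 10,000 times by default; \(p\) is the fraction
of replicates with \(\Delta\mu^* > \Delta\mu\), strictly. We follow the
strict-inequality rule literally and expose the smoothed
\((k+1)/(B+1)\) estimate as an off-by-default option. \(A^*\) and
\(B^*\) are drawn independently rather than as a joint permutation — that
is what drawing "with replacement from the null distribution" prescribes.
The pool is sorted before resampling so that `test(A, B)` and
`test(B, A)` consume identical random streams under the same seed.
`significance_level()` maps p to the strictest of the 5% / 1% / 0.01%
levels. Degenerate zero-variance pools return \(p = 0\) with a warning —
the literal outcome of the strict rule, flagged rather than hidden.

Under the null (both samples standard normal, \(n = m = 20\)), the
empirical rejection rate at the 5% level sits within [0.035, 0.065] over
2000 simulations, which the acceptance suite verifies.

## The reference study and problem sizes

`run_study()` wires the full design together: for each group and
condition it simulates a session, extracts and normalizes amplitudes,
computes tuning and noise correlations, then runs all pairwise bootstrap
comparisons (amplitudes and off-BF pooled over neurons, noise
correlations one mean per experiment, movement windows and template
correlations per mouse). A single top-level seed fans out to every
stochastic stage, so reports are bit-reproducible.

The reference configuration uses a treatment group with biphasic gain
(1, 1.4, 0.8 across Pre / Post 1 / Post 2) and a shared-noise step from
0.10 to 0.25 in the late session, against a control group with constant
parameters — calibration choices that mirror the qualitative pattern of
interest (early hyper-responsiveness, late suppression with increased
functional connectivity), not measured effect sizes. Defaults are 6
treatment and 3 control experiments of 100 neurons, and 5 behavior videos
per group at 64×64 px, 30 fps, 40 min.

The test and acceptance runs use deliberately scaled sizes so the whole
suite stays desk-sized: 40 neurons per experiment in study replicates,
widefield frames of 24×30 px with 10 repeats per tone, and behavior
groups of five 20-min videos at 24×24 px and 15 fps (hypoactivity onset
at 10 min; the nominal 10–60 min window truncates to the session with the
documented warning). These sizes are stated here as the package's own
choices; all statistical checks are rate- or tolerance-based at exactly
these sizes.

## Numerical conventions and degenerate inputs

* Frame grid: frame *f* samples time \((f-1)/\mathrm{rate}\); windows are
  half-open with edges rounded to the nearest frame.
* Nonpositive ΔF/F baselines: trial excluded (2P) or pixel undefined
  (widefield), with warnings.
* σ = 0 neurons, nonpositive FTC peaks or BF responses, zero-variance
  residuals, empty ΔF/F₉₀ sets: excluded and flagged; never silently
  imputed.
* BF ties: lowest frequency. Even median sets: octave-axis midpoint.
* Float TIFF output is affinely rescaled to [0, 1] with the range stored
  in a JSON sidecar (the TIFF writer clamps otherwise); round trips are
  exact to 32-bit float precision.

## What passing tests do and do not show

The generators embed exactly the structure the pipeline is designed to
measure: Gaussian log-frequency tuning, a single shared noise factor,
multiplicative illumination, a blob with programmed kinematics. Passing
recovery tests therefore demonstrates that the implementation measures
what it claims on data whose ground truth is known — not that real
cortical noise has one latent factor, that real illumination is
multiplicative and smooth, or that mouse movement is a bout-gated blob.
Two further limitations are worth stating. First, the off-BF percentage
is a ratio statistic whose small-sample bias depends on the
signal-to-noise ratio, so strong gain differences between conditions can
shift it slightly even when the underlying tuning shape is identical; the
stability checks therefore compare conditions generated with equal gain.
Second, the movement envelope's mean-restoration step compresses the
dynamic range of M (a 20:3 programmed speed ratio appears as roughly a
40% drop in M), which is a property of the published construction rather
than of the implementation.
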