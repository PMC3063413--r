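---
title: "fastkit: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fastkit: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it
implements: the signal models and their assumptions, the parameters
that matter, what the synthetic generators do and do not emulate, and
the numerical decisions taken where the methods leave room.

## The recording model

A recording is a continuous multichannel signal with a header
(channels, sampling rate, events, scores, an optional real-world start
clock with microsecond resolution) and a windowed data-access
contract: `read_window()` returns exactly the requested
channels × samples block in microvolts, and for file-backed recordings
reads only that window from disk. This is what makes hour-long,
multi-gigabyte files workable — nothing ever materialises the full
signal. Sample indexing is 0-based and all intervals are half-open
`[start, start + length)`, which makes `chunk()`/`append_recordings()`
round-trips exact by construction.

BrainVision import translates the `.vhdr`/`.vmrk` text headers only
and links the vendor `.eeg` binary in place; INT16 values are scaled
to µV by each channel's resolution at read time. Marker positions are
1-based in the vendor format and converted to 0-based onsets. The
internal format mirrors this design: a JSON header plus a raw
little-endian float32, channel-multiplexed binary; header-only edits
(scores, events) never rewrite the binary.

Rereferencing and filtering are *pure* transforms of blocks already
read — "on-display" semantics — so stored data are never modified by
exploration.

## Zero-phase filtering

All filters are order-4 Butterworth magnitudes applied with exactly
zero phase in the frequency domain (mirror-padded FFT multiplied by
the squared magnitude response — the transfer function of a
forward–backward application). Zero phase matters throughout: artefact
templates must not be shifted against the artefact, and slow-wave peak
latencies feed directly into the trajectory maps.

A deliberate consequence: the low-pass and high-pass branches at a
common cutoff satisfy `G_lp(f) + G_hp(f) = 1` *exactly*, so the
combined pulse-artefact method's two branches reconstruct the input
perfectly when no correction is applied, and their magnitude responses
cross exactly at the 4 Hz split.

## Gradient artefact (AAS)

Model: the MR gradient artefact is identical in every repetition time
(TR) — stationarity that in practice requires EEG/MR clock
synchronisation. The correction averages, for each volume epoch, the
`n_average_volumes = 30` nearest epochs into a template and subtracts
it. Parameters and defaults:

| parameter | default | unit | role |
|---|---|---|---|
| `n_average_volumes` | 30 | volumes | template window; larger = less EEG bias, slower drift tracking |
| `detect_window_s` | 1 | s | episode-detector tile length |
| `detect_channel` | first channel | — | channel screened by the detector |
| `detect_threshold_uv` | 350 | µV | mean absolute amplitude a tile must *strictly* exceed |
| `target_rate_hz` | 500 | Hz | output rate after anti-alias decimation |

Numerical choices: the template window is nearest-centred
(`floor((n−1)/2)` epochs before, the rest after) and *clamped* — not
shrunk — at episode edges, so every template averages exactly
`min(30, n_epochs)` epochs; tests verify this by probing with
delta-pattern epochs. Epoch length is the modal inter-trigger
interval; a shorter final epoch is corrected with the truncated
template. Trigger spacing jitter above one sample raises a warning
(unsynchronised clocks), but no slice-time realignment is attempted.

Intrinsic limit: the template contains 1/30 of the true EEG, so a
residual EEG bias of that order survives even exact periodicity;
tests assert exact cancellation (< 1e-6 µV) only for noise-free
periodic artefacts.

## Pulse artefact

The ballistocardiogram is beat-locked but varies from beat to beat — a
few tens of µV with main power near 1–2 Hz. Everything starts from QRS
detection on the ECG channel: 7–40 Hz band-pass, Teager energy
operator, smoothed and thresholded adaptively, then an RR-plausibility
pass that recovers beats in long gaps and prunes detections closer
than 0.4 of the median RR. The Teager operator makes detection
polarity-invariant. An estimated rate outside 30–180 bpm is a
detection failure, not a result.

Epochs span `[R − 0.25·RR, R + 0.75·RR)` of the median RR and are
truncated at the midpoint between beats only when neighbouring epochs
would overlap.

*Gaussian-mean*: per beat, the template is the Gaussian-weighted mean
(window 21 beats, σ = 5, weights renormalised after truncation at the
recording edges) of the surrounding epochs. Symmetric weighting tracks
slow amplitude drift better than a flat mean, which the tests check on
a linearly drifting artefact.

*OBS-PCA*: per channel, beat epochs are linearly time-normalised to
the median-RR grid, demeaned, and stacked; the optimal basis set is
the first `n_obs_components = 4` right singular vectors of that
(uncentred) matrix — the mean artefact waveform lands in the leading
component, as in the classical formulation. The basis is fitted to
each epoch by projection and the fit subtracted after inverse time
mapping. Component signs are fixed so each component's
largest-magnitude coefficient is positive (determinism); a
rank-deficient epoch matrix uses the available rank with a warning.

*Combined*: Gaussian-mean on the ≤ 4 Hz branch, OBS on the ≥ 4 Hz
branch, summed. The 4 Hz split reflects the empirical division of
labour between the two methods.

**Known limitation (quantified).** Per-epoch least-squares OBS removes
genuine EEG along with the artefact: fitting `k` data-derived
components to each one-RR epoch of band-limited EEG removes roughly
`(k / L_eff) · (1 + sqrt(L_eff / n_beats))²` of its variance, where
`L_eff ≈ 2 × bandwidth × RR` is the epoch's effective dimensionality.
For slow activity (0.5–2 Hz, `L_eff ≈ 3`) this is most of the band —
OBS visibly guts slow-wave-range EEG, which is exactly why the
combined method protects the low band with Gaussian-mean instead. The
test suite asserts the attainable bounds (high-band correlation
> 0.90 on a band-separated fixture; spectrum-ordering versus no
correction for the combined method only) rather than pretending OBS is
lossless.

## Sleep scoring and statistics

Stage codes follow the classical convention: 0 wake, 1–4 NREM, 5 REM,
6 movement time, −1 unscored; a score set is one scorer's per-window
codes plus artefact flags, and several scorers coexist per recording.
Statistics run over scoring windows fully inside `[FPL, OPL)` (the
lights-off/lights-on markers): time in bed, total sleep time (stages
1–5), efficiency, sleep latency (first stage-1–5 window after FPL — a
single-window onset criterion, chosen and documented here since the
convention is not fixed by the method), REM latency from onset,
per-stage durations and shares, and awakenings as maximal wake runs
after onset. Latencies undefined on a sleepless night are `NA`, never
0.

## Spectral analysis

Welch estimation: Hamming-tapered 4 s subwindows, 50 % overlap, PSD in
µV²/Hz scaled so the integral matches the variance (the test suite
checks Parseval within 10 % on white noise). The spectrogram's outer
window defaults to the scoring window length (else 30 s). Windows
overlapping movement-time stages, artefact-flagged windows, or
artefact/arousal events are *excluded*: stored as zero power for
format fidelity, but flagged in a mask that all statistics honour —
`band_power()` returns `NA` there, never 0/0. The `mongrain` scaling
divides band power by its mean over deep-sleep windows (stages {3, 4})
across the night.

## Slow waves

Detection runs on unweighted averages of four scalp regions (frontal,
central left, central right, parietal — extended 10–20 neighbourhoods
of Fz, C3, C4, Pz; configurable), band-passed 0.25–4 Hz. The five
criteria for a candidate delimited by a down- then an up-zero
crossing:

1. crossing separation within [0.25, 1.25] s — *inclusive*;
2. negative peak < −80 µV — *strict*;
3. peak-to-peak > 140 µV — *strict*;
4. maximum positive slope > 90 % of the maximum slope — *strict*,
   with the reference population defined as the candidates passing
   criteria 1–3 in the same episode and region (the population is not
   fixed by the method; this is the package's documented choice);
5. positive peak at most 2 s after the up crossing — *inclusive*.

Numerical choices: zero-crossing times are sub-sample (linear
interpolation; a sample exactly at zero is the crossing); boundary
comparisons carry a 1e-9 relative guard (1e-6 s on times) so waves
sitting exactly on a printed boundary behave as the printed inequality
dictates despite floating-point round-off. Peaks are reported at
sample resolution.

The trajectory: an electrode participates when its own band-passed
signal has a local minimum below −80 µV within ±0.3 s of the
region-average negative peak (the participation rule and window are
package choices — the method only requires "where the wave was
detected"); delays are negative-peak times relative to the earliest
participating electrode, which is the origin. Region streams seeing
the same physical wave (negative peaks within 0.5 s) are merged,
keeping the deepest peak and unioning the delay maps re-zeroed to the
new minimum. Peak-time noise grows with background level in the
detection band — on a quiet fixture delays are exact to ±1 sample,
which is what the tests assert.

## Synthetic data: what a green test establishes

The generators emulate: 1/f-shaped Gaussian background at 15 µV RMS
(the realistic scalp-EEG amplitude), a *strictly periodic* gradient
artefact (random smooth spline per seed, 5000 µV — > 40 dB over
background), a beat-locked pulse artefact (2–3 Gaussian bumps per
cardiac cycle, ~40 µV, lognormal per-beat amplitude jitter) plus a
morphologically plausible ECG, stage-structured sleep backgrounds with
stage-typical rhythms, and biphasic slow waves whose
criterion-relevant measurements are exact by construction (half-sine
lobes with zero crossings on sample instants).

They do **not** emulate: drifting or slice-locked gradient artefacts
(unsynchronised clocks), heart-rate variability and ectopy, artefact
topographies from a head model, non-Gaussian EEG microstructure, or
scorer disagreement. A green suite therefore establishes algorithmic
correctness against the stated models — not robustness to every
pathology of real recordings. Pulse-artefact tests use 3–5 minute
fixtures: with only ~60 beats the beat × time PCA overfits background
EEG and no implementation meets the documented preservation bounds;
recording length is part of the stated world, not a tuning knob.

## Degenerate inputs and errors

Every operation validates its domain: unknown channels and
out-of-range windows are errors with dedicated condition classes
(`fk_name_error`, `fk_bounds_error`, …); appending clock-overlapping
recordings is an error (the behaviour is otherwise undefined — no
crossfade is attempted); a flat ECG is a detection failure; `mongrain`
scaling without deep-sleep windows, statistics without FPL/OPL, and
empty stage selections all raise rather than return silent zeros.
Empty results that are legitimate (no scanning episode, no slow waves)
are empty lists, not errors.
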