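---
title: "Distinguishing distance-coding schemes in grid-cell firing on a circular track"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distinguishing distance-coding schemes in grid-cell firing on a circular track}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(gridtrack)
```

## The model and its assumptions

A grid cell confined to a circular track can organise its firing in four
ways: anchored to the track itself (allocentric), periodic in signed
cumulative distance (path integration), periodic in absolute travelled
distance, or periodic in elapsed time. On a circular track of outer radius
75 cm the reference circumference is `C = 2*pi*75 = 471.24` cm; a
path-integrated pattern with field distance Δ that does not divide `C`
precesses by `C mod Δ` on every lap, which is what the lap analysis
exploits. All analyses assume:

- head position tracked at a fixed rate (50 Hz by convention) with two
  markers 5 cm apart so heading is defined;
- distances measured as *angular* travelled distance converted with the
  fixed reference radius of 75 cm (so one physical lap always contributes
  exactly `C`, wherever on the 15 cm rim the animal runs), clockwise
  positive;
- spikes are timestamps of a sorted single unit; rates are
  occupancy-normalised.

The unwrap convention matters: using the animal's instantaneous radius
instead of the fixed 75 cm would make a lap's length depend on its radial
path (a mid-track lap would measure ~424 cm) and allocentric patterns would
spuriously precess. The fixed reference radius is exposed as `r_ref` in
`unwrap_cumulative_angle()`.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| map bin / smoothing `h` | 2.5 / 5 | cm | 2D quotient kernel rate maps |
| 1D bins | 10 (distance), 1 (time) | cm, s | linearized profiles |
| lap position bins | 47 (= C/47 ≈ 10.03 cm) | — | tile the circle exactly |
| jitter permutations | 400 per cell (50/cell pooled in studies) | — | regularity null |
| jitter noise range | [min ISI / 5, 0.5] | s | per-spike magnitude |
| shuffle percentiles | 95 (gridness), 99 (jitter, HD) | % | classification thresholds |
| DE hyper-parameters | pop 15·D, F = 0.8, CR = 0.9, 200 generations | — | model fitting |
| spectral bin | 2.5 | cm | PSD/one-peakness |
| theta band | 4–12 | Hz | LFP and intrinsic rhythm |

Lap rows require at least 2 s of occupancy and 10 occupied position bins:
a brief dip across a lap boundary covers a few tens of centimetres and is
not a usable lap. A lap is the region of the cumulative-distance axis
between consecutive multiples of `C`; all visits to that region contribute
to the same row, however often the animal re-enters it.

## The jitter null

The regularity statistic (mean of the first two autocorrelation peak
values) is tested against surrogates in which noise with per-spike
magnitude drawn uniformly between one fifth of the smallest interspike
interval and 500 ms (random sign) is added to the interspike intervals and
the train re-accumulated. Two properties motivated the interval
(cumulative) form over displacing each spike independently:

- independent displacements are bounded by 500 ms, i.e. a few centimetres
  at track running speeds, so they cannot destroy periodicity at
  field-distance scales — the "null" would be indistinguishable from the
  data;
- accumulating the noise makes the displacement diffuse along the train,
  destroying long-range alignment while leaving the local firing rate
  intact, which is exactly what "no regular field structure" means here.

The per-spike independent mode is retained as `mode = "independent"` for
comparison. In population studies the null statistics are pooled across
cells per reference frame and a single 99th-percentile threshold per frame
is used, mirroring how a population-level threshold is normally derived;
`jitter_null()` on a single cell uses 400 permutations.

## Lap-correction semantics

If the pattern is Δ-periodic in signed distance, the field set visible in
lap *k* equals the lap-0 set shifted by `-k·(C mod Δ)` (mod Δ). The
correction therefore rotates lap *k*'s positional row by `k·(C mod Δ)`,
with *k* the signed lap index, so counter-clockwise laps shift the other
way automatically. Two edge cases are handled exactly: when Δ divides `C`
to within 1e-9 the residual is treated as zero and the corrected
correlation equals the uncorrected one identically; when Δ is not larger
than one position bin the correction cannot be resolved and the function
falls back to the uncorrected value with `corrected = FALSE`.

The split-half control estimates Δ from the first temporal half of the
session only and applies the correction to the laps of the second half,
removing the circularity of estimating and evaluating on the same data.

## What the synthetic generator emulates — and what it does not

The trajectory generator reproduces the published summary behaviour of
rats foraging on the track: an Ornstein–Uhlenbeck running speed around
9.7 cm/s, Poisson direction reversals at 9.8/min, and a Poisson pause
process (0.13 Hz onsets, 3 s mean) chosen so a 10-min session covers
~40–46 m with ~80–120 reversals and ~3 lap segments — inside the published
per-animal ranges. Spikes are inhomogeneous-Poisson samples (thinning of a
piecewise-constant rate at the tracking rate) from periodic Gaussian field
profiles in the relevant coordinate; 2D cells use circular Gaussian bumps
on a triangular lattice. Study-scale allocentric cells receive irregular
anchored field layouts: a *regular* allocentric layout is also Δ-periodic
in signed distance and therefore genuinely ambiguous with path-integrated
coding — an identifiability limit of the design itself, not of the
classifier.

What the generator does not emulate: theta-phase dynamics of spiking,
conjunctive (grid × head-direction) tuning, slow drift of field positions,
electrode drift or sorting contamination, and realistic tracking noise.
Passing tests therefore demonstrate that the inferential machinery
recovers the truth under the stated generative assumptions, not that real
recordings would behave as cleanly.

## Numerical choices

- 2D autocorrelograms use the masked Pearson formula per lag, computed
  with FFT cross-correlations of the map, its square and its validity
  mask; lags with fewer than 20 overlapping valid bins are invalid, values
  are clipped to [-1, 1]. A literal per-lag Pearson oracle cross-checks
  the FFT path in the tests.
- Gridness uses the annulus between the central-peak extent (contiguous
  region ≥ 0.2 around the origin) and 1.3 × the median distance of the six
  innermost peaks (local maxima > 0.1 outside the centre, within the
  reliable two-thirds of the lag range); rotations are sampled by bilinear
  interpolation. A perfectly circular ridge discretises to only four local
  maxima, so four peaks suffice for a defined score (`min_peaks`).
- 1D autocorrelation peaks are interior local maxima above zero separated
  by at least two bins; the lag-1 shoulder of the central peak is never a
  field-distance peak.
- The one-peakness score uses the raw mean-subtracted periodogram at
  2.5 cm bins; the peak interval is bounded by the local minima flanking
  the global maximum (a half-maximum rule can be substituted). Smoothing
  or tapering was deliberately avoided: both concentrate the fake-track
  surrogates' lap-periodic fundamental and weaken the contrast.
- Fake-track surrogates are spike-count matched: Poisson trains are drawn
  from the shifted lattice rate scaled to the observed spike count, so
  observed and surrogate scores carry identical sampling noise. The
  discrimination degrades geometrically when the arena lattice spacing
  approaches the ring diameter (the slice then crosses fewer than two unit
  cells per lap and looks 1D-periodic); at the default 50 cm arena spacing
  and 150 cm track spacing the separation is comfortable. A lattice node
  exactly at the enclosure centre produces an atypical 6-fold-symmetric
  ring pattern, so study-scale slice cells use random spatial phases.
- Differential evolution is the classic DE/rand/1/bin with bound clipping
  and an early stop when the population objective spread collapses; the
  same seed gives bit-identical fits. Model amplitude is not a free
  parameter — the predicted profile integrates to the observed spike
  count. Two properties of the comb objective need care: (i) the predicted
  comb is integrated over each bin (pnorm differences), because a comb
  finer than the grid evaluated only at bin centres can alias into a
  spuriously good fit; (ii) the global basin is narrow (all fields must
  stay aligned across the session extent) and subharmonic combs at half
  the true spacing are local optima, so `fit_cell()` seeds the DE
  population with informed candidates (the profile's autocorrelation peak
  lag, its half and double, at the density argmax) and keeps the best of
  two restarts.
- Theta frequencies come from a zero-phase Butterworth band-pass (4–12 Hz)
  and the analytic-signal instantaneous frequency; the LFP peak is the
  mode of the 0.05 Hz histogram with bin centres on multiples of 0.05 Hz
  (so integer frequencies sit mid-bin), and the intrinsic spike-train
  frequency is the amplitude-weighted mean instantaneous frequency of the
  band-passed, envelope-subtracted autocorrelogram, with a theta index
  (band power / broadband power) flagging unmodulated trains. The 0.05
  detection threshold sits between the index distributions of
  homogeneous-Poisson trains (below ~0.025 at these rates and durations)
  and of clearly rhythmic trains (above ~0.13).
- Cue-card visibility uses the tangent construction (sight line from a
  card border tangent to the inner wall, intercepted with the mid-track
  circle), giving `2·(acos(r_in/r_mid) + acos(r_in/r_out)) + card width`
  of visible arc (~151° for the large track under this reading — the
  construction admits conventions differing by a few degrees, so it is
  verified against brute-force ray casting rather than a fixed figure).

## Problem sizes used in the shipped studies

The simulation studies run 4 × 50 cells on 600 s sessions with 50 pooled
jitter permutations per cell and frame and 1000 allocentric permutations
per cell; the slice-discrimination study runs 2 × 50 cells with a 10 × 10
phase-shift null; shuffle-calibration checks use 60 null-model cells
against thresholds pooled from 6 × 200 rotations (gridness) or 60 × 30
jitters. These sizes give stable percentile thresholds and binomial error
of a few percent on the reported rates.

## Known limitations

- Sessions in which the animal never completes two usable laps cannot
  support the lap analysis; such cells are flagged and excluded, as any
  lap-based analysis must.
- The travelled-distance and time schemes are close cousins when running
  speed is nearly constant; the generator's speed variability and pauses
  are what make them separable.
- The classifier's primary label resolves multiple flags by the largest
  threshold margin; cells genuinely coding in several frames are reduced
  to one label (the per-frame flags remain available).
- All statistics are computed per cell assuming independent spiking;
  bursting or strong theta modulation inflates the effective spike count
  and makes jitter nulls slightly anticonservative.
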