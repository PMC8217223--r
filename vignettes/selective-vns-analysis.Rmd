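---
title: "Methods: selective vagus nerve stimulation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selective vagus nerve stimulation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vagsel)
```

This vignette is the package's own account of the science it implements:
the models, the parameters that matter, the numerical conventions, what the
synthetic-data generator does and does not emulate, and the design choices
made where the procedure was genuinely open.

## The measurement problem

A four-contact cuff around the abdominal vagal trunk stimulates through one
of two bipolar contact pairs; a 4×8 penetrating microelectrode array (MEA,
400 µm pitch) in the nodose ganglion records the stimulus-evoked compound
action potentials (CAPs) of the recruited afferents. Because single-fiber
CAPs at the ganglion are small (under 10 µV peak to peak) against tens of
microvolts of background noise, detection rests on stimulus-triggered
averaging: a train of identical pulses (protocol: 120 pulses at 2 Hz) is
delivered, and the recording is averaged across windows aligned on each
pulse, attenuating stimulus-uncorrelated noise by √n.

Selectivity is the ability of the two cuff pairs to recruit different fiber
subpopulations, quantified channel-wise on the MEA; the functional readout
is gastric myoelectric activity recorded from serosal planar electrodes.

## CAP detection

Per channel, the detector:

1. **Blanks artifacts.** Samples exceeding 8 mV in absolute value (EMG
   transients, missing data packets) are replaced by the straight line
   joining the neighbouring clean samples; runs touching a recording edge
   extend the nearest clean value. Blanking is idempotent and applied to
   the raw signal before any averaging, because packet-loss artifacts are
   trial-local.
2. **Averages** windows running from the arrival latency of a 30 m/s fiber
   (the fastest class present; everything earlier is stimulus artifact) to
   498 ms post-stimulus (the slowest observable C fibers). With the default
   0.15 m cuff-to-ganglion distance the window is 5–498 ms. The distance is
   a per-recording scalar; all conduction velocities are conditioned on it.
3. **Smooths** with a sliding RMS window of 1 ms stepped at 0.1 ms, so the
   smoothed trace lives on a 0.1 ms grid.
4. **Thresholds** at `mean + gain · SD`, where mean and SD are those of the
   *baseline ensemble average*: windows of the analysis-window length drawn
   at random (seeded) from the signal after blanking a span 3 ms longer
   than the pulse width around each stimulus. The number of baseline
   windows defaults to the number of pulses, so the baseline average and
   the stimulus-triggered average have matched averaging depth — with
   unmatched depths the threshold would be referenced to the wrong noise
   scale. The default gain is 2.5, the midpoint of the usable 2.4–2.6
   range; `calibrate_gain()` reproduces the ROC procedure that selects the
   smallest gain with a false-positive rate under 10 % on labelled trials.
5. **Bins by conduction velocity.** The time axis is divided into 0.5 m/s
   CV bins ([v, v+0.5) in velocity ↔ (d/(v+0.5), d/v] in latency) and at
   most one response is reported per (channel, bin).

Two conventions deserve emphasis, because they define what "a detection"
is:

* **Latency convention.** A response's latency is the window-start time, on
  the RMS grid, of the first sample strictly above threshold. No sub-sample
  interpolation is attempted; the 0.1 ms grid is the measurement
  resolution. CV = distance / latency, and the 3 m/s C/Aδ boundary is
  assigned to Aδ (the class ranges 0–3 and 3–30 m/s overlap at the
  boundary; the choice is configurable).
* **Crossing = upward transition.** An event is registered where the
  smoothed trace crosses *from below* to above threshold. A single CAP
  whose RMS footprint straddles a CV-bin edge therefore yields one event,
  not one per bin it touches, and two CAPs whose footprints are not
  separated by a sub-threshold gap merge into one event.

The detector is validated by *oracle equivalence*: on noise-free synthetic
recordings, `detect_responses()` must return exactly the recruitment oracle
`ground_truth_responses()` — same channels, same CV bins — across the full
amplitude × pulse-width × cuff-pair grid. For that comparison the oracle
expresses each fiber's true arrival time on the same RMS grid with the same
window-start convention (pure integer arithmetic, no signal processing),
excludes fibers whose latency falls outside the analysis window (the window
defines the observable CV range: at 0.15 m, roughly 0.30–30 m/s), and
applies the same footprint-merge rule. The signal path under test — window
extraction, blanking, averaging, RMS, baseline statistics, thresholding —
is computed entirely from the simulated voltages.

## Threshold search

The response threshold per cuff pair and pulse width is found by bisection
on 0–3000 µA with a 20 µA target resolution. The first probe is at the
3000 µA ceiling, which settles the "no response" (NR) case in one trial;
otherwise the bracket (highest non-responding, lowest responding) is halved
— midpoints rounded to the 1 µA hardware lattice — until it is within
resolution, and the lowest responding amplitude is reported. At most
⌈log₂(3000/20)⌉ + 1 = 9 trials are needed. Because negatives only ever
raise the bracket floor and positives only lower its ceiling, the tested
amplitudes are always mutually consistent; the non-monotonicity warning in
`binary_search_threshold()` is therefore unreachable for a deterministic
predicate and retained purely defensively (a stochastic detector could
still trip it across repeated campaigns).

Aggregation over animals and cuff pairs (`mean_threshold_by_pulse_width()`)
is an arithmetic mean over testable entries, NR/NT excluded; the bundled
reference table reproduces the expected strength-duration trend (means of
about 1027, 307 and 248 µA at 0.1, 0.5 and 1.0 ms).

## Selectivity index

With T₁:₂, T₃:₄ the channels responding to each pair, T_S the shared
channels and T_R = T₁:₂ + T₃:₄ − T_S,

$$SI = \tfrac12\,\frac{T_R - T_S}{32} + \tfrac12\left(1 -
\frac{|T_{1:2} - T_{3:4}|}{T_R}\right).$$

The first term counts selectively driven channels; the second penalizes
imbalance between the pairs. Conventions adopted here: SI ≔ 0 when T_R = 0
(the balance term is 0/0; no responses means no selectivity), and the
balance term uses the raw per-pair counts including shared channels (the
literal reading of the definitions). `optimize_selectivity()` evaluates SI
over the Cartesian product of the amplitudes tested for each pair —
mirroring the post-hoc protocol, which reused the binary-search trials —
excludes combinations with more than 3 overlapping channels (>10 % of the
array), and breaks ties toward the lowest summed amplitude, then the lowest
pair-1:2 amplitude (less injected charge). Exhaustive enumeration over all
valid count triples at 32 channels confirms SI ∈ [0, 1] with SI = 1
exactly when recruitment is balanced, fully selective and array-wide.

## Somatotopy

For every responding channel, the Euclidean grid distance to the nearest
channel responding to the same pair and to the opposing pair. Channels
responding to both pairs are excluded as *sources* of cross-pair distances
(their cross distance is identically zero — a non-informative skew) but
remain in the same-pair lists and as neighbour targets; a pair's sole
responder has no same-pair distance and is skipped for that list.

The activation centroid of a pair is the 2-D mean of its responding
channels' grid coordinates; the separation between the two pairs' centroids
is compared between stimulation conditions with an exact Wilcoxon
signed-rank test (full 2ⁿ enumeration on average-ranked |differences|,
zeros dropped — at the study's sample sizes the attainable minima are
p = 0.25, 0.125, 0.0625 for n = 3, 4, 5, so exactness matters). A scalar
"mean distance from the array corner" centroid is retained behind
`method = "corner"` because protocols are sometimes written that way, but a
scalar cannot support a planar inter-centroid distance, so the 2-D centroid
is the default.

The generator's `clustering` knob spans the two regimes the analysis must
distinguish: 0 assigns fibers' channels uniformly (no somatotopy — same-pair
and cross-pair distance distributions coincide), 1 segregates the pairs'
preferred fibers into the left and right half-arrays (cross-pair distances
stochastically dominate). Tests verify both the null and the power side.

## Gastric myoelectric pipeline

Per planar electrode the four contact waveforms are averaged (independent
contact noise drops by half), then filtered with a zero-phase 4th-order
Butterworth low-pass at 2.5 Hz, decimated to 10 Hz by sample selection (the
2.5 Hz filter is the anti-alias stage), and filtered again with a
zero-phase 2nd-order low-pass at 0.3 Hz. Filtering is forward–backward
because the analysis is offline; this cancels group delay and squares the
magnitude response, so the effective attenuation is doubled — at the
9.6 cpm slow wave the chain passes |H₁|²|H₂|² ≈ 0.92 of the amplitude,
and a 2 Hz component is attenuated by far more than 40 dB. The filters are
implemented as cascaded bilinear-transformed second-order sections, which
stay numerically exact at cutoffs far below the sampling rate where the
expanded polynomial form degrades.

The 10 Hz signal is cut into 60 s segments with 54 s (90 %) overlap; each
segment is zero-padded so the FFT bin spacing equals 0.1 cpm (the padding
factor — 10× for 60 s segments — is derived from the bin width, not
hard-coded) and squared into power. Downstream summaries:

* **Dominant frequency**: median over segments of the highest-power bin in
  0–15 cpm (DC excluded; ties to the lower frequency). Significance is an
  assumption of this package, not a reconstruction: each segment's peak is
  tested against a white-noise null (periodogram ordinates exponential
  around the band mean, Bonferroni over the band's Rayleigh-resolution
  bins, α = 0.05), and the signal is flagged significant when most segments
  are. White noise passes this gate in well under 5 % of seeded runs.
* **Normogastric fraction**: power in 8–11 cpm over power in 0.5–15 cpm
  (DC excluded; the total band is another stated assumption). Spectra are
  averaged within an epoch before the fraction is taken. The fraction is
  invariant under amplitude scaling, and the whole pipeline is linear.
* **Epoch comparison**: baseline vs stimulation fractions, their ratio, and
  a per-segment 6–15 cpm band-power series for waterfall displays.

## The synthetic-data generator

The generator produces the statistical structure the analysis assumes —
and nothing more. Fibers carry a conduction velocity (C uniform on
0.3–3 m/s, Aδ on 3–30 m/s; C fibers dominate, matching the composition of
the abdominal vagus), a home MEA channel, a CAP amplitude of 4–8 µV, and a
Weiss-law threshold per cuff pair: I(PW) = rheobase · (1 + chronaxie/PW),
chosen over the exponential Lapicque form for its closed-form chronaxie;
preferred-pair rheobases are drawn from 100–600 µA and the other pair's
from 2–6× that (an `overlap` fraction of fibers gets near-equal rheobases,
so the pairs' recruitment overlaps partially, not exclusively). Recruitment
is a deterministic threshold crossing — consistent with the near-perfect
per-pulse reliability of supra-threshold responses — with latency jitter
defaulting to zero because the analysis operates on averages. Evoked CAPs
are a stereotyped ~2 ms biphasic template with a sharp onset; background
noise is white Gaussian, with optional mains interference, supra-8 mV
artifact excursions and packet-loss gaps to exercise blanking. GI sessions
are a sinusoidal slow wave (default 9.6 cpm, weak second harmonic) shared
by the four contacts of an electrode, plus common 1/f^1.5 drift and
independent white contact noise; from a configurable onset after
stimulation start, the slow-wave amplitude is multiplied by the suppression
factor. Serosal baselines are drift-dominated, which is why most noise
power sits below the normogastric band.

Deliberately absent: biophysical cable/axon models, volume conduction,
template variability across repeats, vago-vagal reflex delays (which in
real recordings can make fast fibers appear slow), and any vital-sign
channels. Passing tests therefore demonstrate that the *analysis* is
correct and sensitive under its stated assumptions — not that those
assumptions exhaust real nodose recordings.

## Problem sizes and numerical choices

The test suite and the acceptance script scale the protocol down to run in
minutes while preserving the quantities being checked: oracle-equivalence
trials use 3-pulse noise-free trains (averaging depth is irrelevant without
noise) with the 120-window baseline of the full protocol; noisy end-to-end
campaigns use 12-pulse trains with the background SD scaled so the
post-average SNR matches the 120-pulse, ~5 µV regime; GI sessions are
synthesized at 250 Hz (the pipeline accepts any rate with an integer
decimation to 10 Hz) over the protocol's 5 min baseline + 2 min
stimulation. Segregated-block somatotopy checks stimulate at 800 µA —
above every preferred-fiber threshold and below every non-preferred one in
the designed populations — so they probe the clean regime they are meant
to probe.

Other conventions: voltages are microvolts throughout (thresholds stated
in mV are converted at the boundary, avoiding silent 10³ errors); channel
indices are 1-based row-major over the 4×8 grid, and only relative geometry
enters any statistic; every stochastic stage takes an explicit seed, with
`split_seed()` fanning one study seed out to decorrelated stage seeds; the
end-to-end study writes byte-stable CSVs and a manifest with a
configuration digest.

## Known limitations

Ground-truth equivalence is exact only in the noise-free limit; with noise
the detected latency can shift by one RMS step, which near a bin edge moves
an event to the adjacent CV bin (and, near 3 m/s, can flip its fiber
class) — an intrinsic property of grid-quantized latency measurement, not
of the implementation. Response sets are nested across amplitude at the
channel level but not always at the CV-bin level: a newly recruited faster
fiber can merge with an existing footprint and absorb its transition. The
single-response-per-bin rule caps detectable responses per channel at the
number of bins; overlapping fibers on one channel within a bin are
unresolvable by design. The GI significance test and total-power band are
package assumptions (flagged above), and the centroid construction follows
the 2-D reading of an ambiguous verbal description, with the scalar variant
available behind a switch.
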