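---
title: "Detecting and characterizing ovine sleep spindles: methods and design choices"
author: "ovispindle authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterizing ovine sleep spindles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovispindle)
library(dplyr)
```

## The problem

Sleep spindles are transient 10-16 Hz bursts with a characteristic
waxing-waning envelope, prominent in non-REM (NREM) sleep and implicated in
memory consolidation. `ovispindle` implements an automated pipeline for
detecting and characterizing them in multichannel cortical EEG from sheep
(and comparable large-mammal recordings): detection by wavelet power-envelope
thresholding, topographic classification into local and simultaneous events,
coupling to the 0.5-2 Hz slow oscillation, sleep-cycle density profiles, and
a spectral-ratio state-space analysis that separates wake from NREM sleep.
Because no public sheep EEG accompanies the method, the package ships a
synthetic polysomnography generator with exact ground truth, so every stage
of the pipeline is testable end to end.

## The detection model

Recordings are assumed downsampled to 250 Hz and common-average referenced
([`downsample_recording()`], [`rereference_car()`]). Detection then proceeds
per channel:

1. **Envelope.** A complex Morlet wavelet transform is evaluated at center
   frequencies spanning the 5-16 Hz detection band in 0.5 Hz steps (23
   scales; 7 cycles per wavelet). Power (squared magnitude) is averaged
   across scales and smoothed with a 100 ms moving average. The wavelet
   count and smoothing window are exposed in `detection_config()`; 7 cycles
   balances time against frequency resolution at sigma-band frequencies, and
   100 ms stabilizes run detection without blurring sub-second events.
2. **Threshold.** A candidate is any maximal run of envelope samples above
   180% of the channel's mean envelope power in a designated *baseline*
   recording (`threshold_factor = 1.8`). Using a separate baseline night
   avoids first-night effects; when none is supplied the recording serves as
   its own baseline, with a warning.
3. **Boundaries.** Within each candidate the envelope peak is located and
   its prominence measured against the higher of the two minima separating
   it from neighboring candidate peaks (bounded by a +/- 6 s search window).
   Boundaries are the first samples, walking outward from the peak, where
   the envelope falls below a cutoff; adjacent spindles are therefore split,
   never merged. Two cutoff readings are implemented (see *Design
   choices*).
4. **Features.** Each event gets a Hanning-windowed power spectrum zero
   padded to 1024 bins (0.244 Hz resolution at 250 Hz); the peak frequency
   is the maximum-power bin inside the detection band, ties resolving to
   the lower frequency.
5. **Filters.** Events are rejected (and retained with a reason) when the
   duration falls outside 0.3-3 s, the peak frequency falls outside the
   detection band, the segment contains a voltage step exceeding 10 times
   its mean absolute sample-to-sample step (noise spike), or the 10-16 Hz
   zero-phase filtered trace contains fewer than three positive peaks.
   Downstream characterization uses the *classical* view
   (`classical_spindles()`): accepted events with peak frequency in
   10-16 Hz.

### Design choices in the detector

**Boundary cutoff.** The boundary rule "power dropped to below 80% of the
peak's prominence, or below 120% of the channel mean power" admits two
readings. Read as an absolute level (`boundary_rule = "prominence_fraction"`,
cutoff `0.8 x prominence` above zero), boundaries sit where the envelope
still holds 80% of its peak, so only the top fifth of each burst is kept:
detected durations collapse to ~0.2 of the physical event, sub-second
spindles fall below the 0.3 s duration floor, and recovery of injected
synthetic spindles drops to ~0.2 recall with boundary errors well above a
quarter second. Read as a *drop* (`"prominence_drop"`, cutoff
`peak - 0.8 x prominence`, floored at `1.2 x` channel mean), boundaries
enclose the full waxing-waning envelope; synthetic recovery then reaches
recall >= 0.95 with boundary errors under 0.25 s, and accepted durations are
compatible with the 0.3-3 s acceptance window being a meaningful filter.
The drop reading is therefore the default; both are available in
`detection_config()`.

**Spectral features and the slow oscillation.** A 0.3-1 s segment cannot
spectrally resolve a 1 Hz slow wave: the Hann mainlobe is several Hz wide,
so when a spindle rides a high-amplitude slow wave the slow wave's power
leaks across the whole 5-16 Hz search band and pins the "peak frequency" at
the lowest in-band bin. Since the quantity of interest is the peak frequency
*of the spindle*, the segment is zero-phase high-passed at the
detection-band low edge before windowing; content at and above 10 Hz is
unaffected.

**Other conventions.** "Mean variation in voltage" is read as the mean
absolute first difference of the raw segment — the simplest estimator
consistent with a voltage-step rule. The positive-peak filter operates on
the classical 10-16 Hz zero-phase (4th-order Butterworth, forward-backward)
trace; the band is configurable since the original description does not fix
it. Both the detection threshold and the 120%-of-mean boundary floor are
referenced to the baseline recording. Peak-bin ties resolve to the lowest
frequency, deterministically.

## Topography, coupling, macrostructure, state space

**Local vs simultaneous.** Accepted events overlapping in time (half-open
intervals) on different channels are *simultaneous*; the relation is
pairwise, with no transitive closure. Events of multiplicity exactly 2 enter
the pairwise connectivity matrix; events on >= 4 channels enter the global
matrix. Two normalizations are provided: by the total number of tallied
co-occurrences (unordered pair weights sum to 1) and per channel row (each
non-empty row sums to 1).

**Densities.** Events are assigned to hypnogram epochs by midpoint — an
unambiguous rule for events straddling epoch boundaries. Artifact-flagged
epochs are excluded from numerator and denominator alike; zero stage time
yields a missing density, never zero.

**Slow-wave coupling.** The channel trace is zero-phase band-passed at
0.5-2 Hz; within +/- 3 s of each spindle center the positive and negative
peaks nearest in time to the center give the slow-wave peak-to-peak
amplitude. The phase angle is the analytic-signal phase at the center
sample, with 0 at the slow-wave positive peak and +/- pi at the trough; an
analytic (Hilbert-type) representation is used because the source method
names a phase angle without defining its computation — this is a
package-level convention and is flagged as such. Windows clipped at the
recording edge are flagged; events with under 1 s of trace on either side
are excluded from coupling summaries.

**NREM substaging and sleep cycles.** Per-epoch delta power (0.5-4 Hz,
full-epoch Hanning spectra averaged over channels — the delta band bounds
are configurable since "delta" is quoted without bounds) splits NREM epochs
at 50% of the recording's maximum epoch delta power; epochs exactly at
threshold count as deep. A sleep cycle requires >= 30 s of contiguous wake,
then >= 2 min of contiguous NREM (any interior non-NREM epoch breaks the
run — the strict reading; a tolerance is not applied because the source is
silent on brief arousals), terminated by wake or by >= 1 min of REM.
Within-cycle profiles take the first three cycles of >= 18 min, split them
into 3 min periods, and normalize pooled spindle counts to proportions
summing to 1.

**State space.** Every 10 s wake/NREM epoch yields two band-power ratios
from full-epoch Hanning spectra: SSR1 = 6.5-9 / 0.5-9 Hz and SSR2 =
0.5-20 / 0.5-100 Hz. Band sums use bins whose centers fall in the half-open
interval `[low, high)`, so nesting guarantees ratios in [0, 1]. Ratios are
binned on a 41 x 41 grid of unit 0.025 covering [0, 1.025) — 1681 cells,
with the closed upper boundary at ratio 1 landing in the 41st bin — and
normalized per subject to total 1; combined maps sum per-subject maps so an
n-subject map totals n. Display contours sit at 2.5 and 5 times the
even-spread baseline `n_subjects / 1681`. The epoch transform is a single
full-epoch FFT (2500 samples at 250 Hz) rather than the 1024-bin spindle
FFT: a 10 s epoch supports 0.1 Hz resolution and the 0.5 Hz band edges
require it. Spindle-centered maps collate 10 s epochs centered on local
accepted spindles, with ratios from the channel-mean spectra or from the
spindle's own channel; spindles too close to the recording edge are skipped
and counted.

## The synthetic generator

`sim_config()` / `generate_study()` emulate a sheep polysomnography
segment: eight cortical channels (`A1-L ... P-R`) at 250 Hz with pink (1/f)
background of 0.02 mV standard deviation, values in millivolts throughout.
Stage-dependent components follow the vigilance timeline: NREM segments add
band-limited 0.5-2 Hz slow-wave activity (0.03 mV light / 0.08 mV deep, a
bimodal contrast the substaging rule must recover); wake segments attenuate
the 1/f background (x 0.6) and add 20-45 Hz low-voltage fast activity
(0.01 mV), emulating desynchronized wake EEG. Spindles are sinusoids under
a Hann (waxing-waning) envelope, 10-16 Hz, 0.5-1.5 s, injected at 2/min in
light and 4/min in deep NREM and 0.3/min in wake, with amplitude 5 times
the channel's mean classical-band background envelope; a quarter of events
span >= 4 channels and are centered on the positive peak of an injected
two-cycle slow wave of 0.05-0.15 mV — chosen to overlap the scale of real
ovine slow-wave peak-to-peak amplitudes and to make the
local-vs-simultaneous coupling contrast recoverable, not as a claim about
sheep physiology. Single-sample voltage spikes of 20 standard deviations
(0.1/min) exercise the artifact flags and the 10x noise-spike rule with
margin. One seed fixes the entire realization; the event table returned is
the exact injected truth.

What the generator does *not* emulate: true thalamocortical spindle
morphology (frequency chirp, asymmetric envelopes), inter-channel
correlation of the background, rumination artifacts, electrode drift, or
EMG/EOG signals. Passing recovery tests on this generator therefore
demonstrates the pipeline's internal correctness — thresholds, boundaries,
filters, normalizations and couplings behave as specified — not
field-ready performance on real sheep EEG.

## Numerical choices and degenerate inputs

Zero-phase filtering pads by reflection before forward-backward IIR passes
(plain forward-backward filtering with zero initial conditions corrupts
segment edges). Downsampling applies a zero-phase FIR low-pass
(Hamming-window design, cutoff at 90% of the target Nyquist, unity DC gain
enforced) before decimation; non-integer ratios interpolate linearly on the
filtered trace. Envelope computation pads by reflection and transforms on a
fast composite length. Flat candidates (zero prominence) are returned
unrefined and flagged; overlapping refined intervals on one channel are
merged with a warning; constant segments are never noise spikes (0 > 0 is
false); epochs with zero denominator band power yield undefined ratios and
are excluded from maps; empty stages yield missing, not zero, densities.
EDF output is 16-bit with per-channel physical scaling rounded outward to
the header's 8-character precision, so a write-read round trip is exact to
within one quantization step.

## Problem sizes in the shipped checks

The bundled validation suite runs the full pipeline on seeded synthetic
studies of 18-36 simulated minutes (8 channels at 250 Hz, around 90
injected spindles in the recovery study) — large enough for stable recall,
density and map statistics while keeping a complete run inside a few
minutes on a single core. Oracle-equivalence checks (boundary refinement,
nearest-extremum selection) each sweep 1000 randomized cases against
plain-loop brute-force implementations.

## Known limitations

The Morlet cycle count and the prominence reference of the original
MATLAB implementation are not published; both are configurable and the
defaults are stated above. Detection assumes an artifact-scored hypnogram
as input — no sleep scoring is performed beyond the delta-power NREM
substaging rule. Inferential statistics (stage comparisons, ANOVA-style
models) are deliberately out of scope: the package produces the event
tables and summaries on which such models can be fit with standard tools.
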