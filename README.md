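# ovispindle

Detection and characterization of sleep spindles in multichannel cortical
EEG, built around the automated pipeline developed for ovine
polysomnography. For sleep and comparative neurophysiology researchers who
need a reproducible, scriptable implementation of:

- **Spindle detection** by complex-Morlet wavelet power envelope over
  5–16 Hz: candidates where the envelope exceeds 180% of a baseline
  night's per-channel mean power, boundaries refined against the envelope
  peak's prominence (cutoff `peak − 0.8 × prominence`, floored at
  `1.2 ×` channel mean), Hanning/1024-bin spectral features, and the four
  acceptance filters (duration 0.3–3 s, in-band peak frequency, no
  >10× voltage-step noise spike, ≥3 positive peaks in the 10–16 Hz
  zero-phase filtered trace).
- **Topography**: local vs simultaneous events by pairwise temporal
  overlap, pairwise (multiplicity = 2) and global (≥4 channels)
  connectivity matrices under two normalizations.
- **Slow-wave coupling**: peak-to-peak amplitude of the 0.5–2 Hz trace
  from the positive/negative peaks nearest each spindle center within
  ±3 s, and an analytic-signal phase angle (0 = slow-wave peak).
- **Macrostructure**: delta-power NREM substaging at 50% of maximum epoch
  delta power, sleep-cycle segmentation (≥30 s wake → ≥2 min NREM →
  wake or ≥1 min REM), within-cycle and hourly density profiles.
- **State space**: per-10 s-epoch spectral ratios SSR1 = 6.5–9/0.5–9 Hz
  and SSR2 = 0.5–20/0.5–100 Hz, binned on a 41 × 41 grid of unit 0.025
  (1681 cells), per-subject proportional maps, combined maps and the
  2.5×/5× baseline display contours.
- **A synthetic polysomnography generator** with exact ground truth
  (stage-dependent 1/f + slow-wave background, Hann-enveloped spindle
  bursts, voltage spikes), so the whole pipeline is testable without any
  recordings.

Everything is tidyverse-native: recordings are `time` + channel tibbles,
events, hypnograms, couplings and maps are tibbles that pipe through
dplyr, with `tidy()`/`glance()` methods and ggplot2 `autoplot()`s.

## Worked example

```r
library(ovispindle)
library(dplyr)

# a seeded synthetic study: ~18 simulated minutes, 8 channels at 250 Hz
study <- generate_study(sim_config(seed = 11))
study
#> # Synthetic EEG study: 8 channels, 18.0 min, 45 ground-truth spindles (10 global)

events <- detect_spindles(study$recording)   # warns: recording is its own baseline
glance(events)
#> # A tibble: 1 × 6
#>   n_events n_accepted n_rejected n_channels mean_freq mean_duration
#>      <int>      <int>      <int>      <int>     <dbl>         <dbl>
#> 1     4548       1989       2559          8      9.79         0.446

# the classical 10-16 Hz view used for characterization
catalog <- events |> classical_spindles() |> annotate_simultaneity()
glance(catalog)
#> # A tibble: 1 × 5
#>   n_events n_local n_simultaneous n_global max_multiplicity
#>      <int>   <int>          <int>    <int>            <int>
#> 1      845     381            464       71                8

# recovery against the generator's ground truth
score_detection(catalog, study$truth)
#> Spindle detection score: recall 0.959 (94/98), precision 0.111
#>   boundary error 0.234 s onset / 0.230 s offset; |freq error| 0.180 Hz

# NREM spindle density, spindles per minute per channel
stage_density(catalog, study$hypnogram, stages_nrem()) |> head(3)
#> # A tibble: 3 × 4
#>   channel n_events minutes density
#>   <chr>      <dbl>   <dbl>   <dbl>
#> 1 A1-L         101    12.8    7.87
#> 2 A1-R          64    12.8    4.99
#> 3 A2-L          94    12.8    7.32
```

The recovery line reads: 94 of the 98 injected channel-events were matched
1-to-1 by an accepted detection within 0.5 s midpoint distance; matched
boundaries sit about 0.23 s from the injected Hann envelope's nominal
extent, and detected peak frequencies land within about 0.18 Hz of the
injected tone (the FFT bin width is 0.244 Hz). Precision is low by design
at the 180% threshold — real and synthetic background both cross it — which
is exactly why the duration/shape filters and the classical-band view
exist; detected NREM densities (5-8 per minute per channel here) include
that background event rate, just as the real recordings' densities do.

State-space separation of wake and NREM:

```r
ss  <- epoch_ssr(study$recording, study$hypnogram)
map <- build_density_map(ss)
autoplot(map)   # NREM mass near (0.007, 0.97); wake mass near (0.11, 0.29)
contour_levels(6)
#>        low       high
#> 0.00892326 0.01784652
```

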