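test_that("envelope power scales quadratically with amplitude", {
  cfg <- detection_config()
  rec1 <- sine_recording(12, dur = 6, amplitude = 1)
  rec2 <- sine_recording(12, dur = 6, amplitude = 2)
  env1 <- band_power_envelope(rec1, cfg)
  env2 <- band_power_envelope(rec2, cfg)
  interior <- 500:1000
  ratio <- mean(env2$ch1[interior]) / mean(env1$ch1[interior])
  expect_lt(abs(ratio - 4), 0.2)
  # silence maps to zero
  zero <- as_recording(matrix(0, 1000, 1), rate = 250)
  expect_equal(max(band_power_envelope(zero, cfg)$ch1), 0)
  # in-band signal beats silence everywhere in the interior
  expect_gt(min(env1$ch1[interior]), 0)
})

test_that("detection threshold is exactly the configured multiple of the baseline mean", {
  set.seed(31)
  env <- tibble::tibble(time = (0:999) / 250,
                        a = rexp(1000), b = runif(1000))
  thr <- baseline_threshold(env, detection_config())
  expect_equal(thr$threshold / thr$mean_power, c(1.8, 1.8))
  expect_equal(thr$mean_power, c(mean(env$a), mean(env$b)))
  const <- tibble::tibble(time = (0:99) / 250, a = rep(1, 100))
  expect_equal(baseline_threshold(const, detection_config())$threshold, 1.8)
  zero <- tibble::tibble(time = (0:99) / 250, a = rep(0, 100))
  expect_equal(baseline_threshold(zero, detection_config())$threshold, 0)
})

test_that("candidates are maximal supra-threshold runs", {
  env <- tibble::tibble(time = (0:4) / 1, a = c(0, 0, 5, 5, 0))
  attr(env, "rate") <- 1
  thr <- tibble::tibble(channel = "a", mean_power = 1, threshold = 1)
  cand <- detect_candidates(env, thr)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$start_idx, 3L)
  expect_equal(cand$end_idx, 4L)
  # sub-threshold gap of one sample splits runs
  env2 <- tibble::tibble(time = (0:6) / 1, a = c(0, 5, 5, 0.5, 5, 5, 0))
  attr(env2, "rate") <- 1
  expect_equal(nrow(detect_candidates(env2, thr)), 2)
  # nothing above threshold
  env3 <- tibble::tibble(time = (0:4) / 1, a = rep(0.5, 5))
  attr(env3, "rate") <- 1
  expect_equal(nrow(detect_candidates(env3, thr)), 0)
})

test_that("boundary refinement reproduces the analytic triangular case", {
  # triangular envelope rising 0 -> 10 over 1 s and back, channel mean 1;
  # under the absolute-level rule the cutoff is max(0.8 * 10, 1.2 * 1) = 8,
  # crossed at t = 0.8 s and t = 1.2 s
  rate <- 1000
  t <- (0:(2 * rate)) / rate
  env_v <- 10 * (1 - abs(t - 1))
  env <- tibble::tibble(time = t, a = env_v)
  attr(env, "rate") <- rate
  cand <- tibble::tibble(channel = "a", start = 0, end = 2,
                         start_idx = which(env_v > 1.8)[1],
                         end_idx = max(which(env_v > 1.8)))
  cm <- tibble::tibble(channel = "a", mean_power = 1)
  cfg <- detection_config(boundary_rule = "prominence_fraction")
  ref <- refine_boundaries(env, cand, cm, cfg)
  expect_lt(abs(ref$start - 0.8), 2 / rate)
  expect_lt(abs(ref$end - 1.2), 2 / rate)
  expect_lt(abs((ref$end - ref$start) - 0.4), 4 / rate)
  # drop rule: cutoff = 10 - 0.8 * 10 = 2, crossed at 0.2 s and 1.8 s
  ref2 <- refine_boundaries(env, cand, cm, detection_config())
  expect_lt(abs(ref2$start - 0.2), 2 / rate)
  expect_lt(abs(ref2$end - 1.8), 2 / rate)
})

test_that("rectangular envelopes keep their edges under refinement", {
  rate <- 100
  env_v <- c(rep(0, 100), rep(10, 50), rep(0, 100))
  env <- tibble::tibble(time = (seq_along(env_v) - 1) / rate, a = env_v)
  attr(env, "rate") <- rate
  cand <- tibble::tibble(channel = "a", start = 1, end = 1.5,
                         start_idx = 101L, end_idx = 150L)
  cm <- tibble::tibble(channel = "a", mean_power = 0.5)
  for (rule in c("prominence_drop", "prominence_fraction")) {
    ref <- refine_boundaries(env, cand, cm, detection_config(
      boundary_rule = rule))
    expect_equal(ref$start_idx, 101L)
    expect_equal(ref$end_idx, 150L)
  }
})

test_that("boundary refinement matches the brute-force outward scan", {
  set.seed(33)
  for (rule in c("prominence_drop", "prominence_fraction")) {
    cfg <- detection_config(boundary_rule = rule)
    for (k in 1:200) {
      n <- 400
      rate <- 100
      center <- runif(1, 0.3 * n, 0.7 * n)
      width <- runif(1, 10, 80)
      base <- runif(1, 0, 0.3)
      env_v <- base + runif(1, 1, 10) * exp(-((seq_len(n) - center)^2) /
                                              (2 * width^2)) +
        runif(n, 0, 0.05)
      ch_mean <- mean(env_v)
      thr <- 1.8 * ch_mean
      above <- env_v > thr
      if (!any(above)) next
      r <- rle(above)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- which(r$values)
      env <- tibble::tibble(time = (seq_len(n) - 1) / rate, a = env_v)
      attr(env, "rate") <- rate
      cand <- tibble::tibble(channel = "a",
                             start = (starts[runs] - 1) / rate,
                             end = ends[runs] / rate,
                             start_idx = starts[runs],
                             end_idx = ends[runs])
      cm <- tibble::tibble(channel = "a", mean_power = ch_mean)
      ref <- refine_boundaries(env, cand, cm, cfg)
      win <- round(2 * cfg$max_dur * rate)
      peaks <- ref$peak_idx
      for (i in seq_len(nrow(ref))) {
        lo <- max(1L, peaks[i] - win,
                  if (i > 1L) peaks[i - 1L] + 1L else 1L)
        hi <- min(n, peaks[i] + win,
                  if (i < nrow(ref)) peaks[i + 1L] - 1L else n)
        oc <- oracle_refine(env_v, cand$start_idx[i], cand$end_idx[i],
                            ch_mean, cfg, win_lo = lo, win_hi = hi)
        expect_identical(ref$start_idx[i], as.integer(oc$start))
        expect_identical(ref$end_idx[i], as.integer(oc$end))
      }
    }
  }
})

test_that("spectral peak matches a direct DFT oracle and the injected tone", {
  cfg <- detection_config()
  rate <- 250
  t <- (0:(rate - 1)) / rate
  x <- sin(2 * pi * 12 * t)
  sp <- spindle_spectrum(x, rate, cfg)
  expect_lt(abs(sp$peak_freq - 12), rate / 1024)
  expect_equal(sp$peak_freq,
               oracle_dft_peak(x, rate, 1024, cfg$detect_band))
  # two-tone mixture resolves to the stronger component
  x2 <- 2 * sin(2 * pi * 12 * t) + sin(2 * pi * 14 * t + 1)
  sp2 <- spindle_spectrum(x2, rate, cfg)
  expect_lt(abs(sp2$peak_freq - 12), rate / 1024)
  expect_equal(sp2$peak_freq,
               oracle_dft_peak(x2, rate, 1024, cfg$detect_band))
  # DC-only segment: in-band power is pure leakage, far below the DC bin
  spd <- spindle_spectrum(rep(2, 100), rate, cfg)
  expect_lt(spd$peak_power, 0.01 * max(spd$spectrum$power))
  expect_error(spindle_spectrum(1, rate, cfg), "2 samples")
})

test_that("the noise-spike rule flags single displaced samples only", {
  t <- seq(0, 1, by = 1 / 250)
  smooth <- sin(2 * pi * 12 * t)
  expect_false(is_noise_spike(smooth))
  expect_false(is_noise_spike(rep(1, 100)))
  # displace one sample so its step is 12x the segment's mean absolute step
  x <- smooth
  x[100] <- x[100] + 12 * mean(abs(diff(smooth)))
  expect_gt(max(abs(diff(x))) / mean(abs(diff(x))), 10)
  expect_true(is_noise_spike(x))
})

test_that("positive-peak counting matches the filtered-oscillation count", {
  rate <- 250
  t <- (0:(rate - 1)) / rate
  n <- count_positive_peaks(sin(2 * pi * 12 * t), rate)
  expect_gte(n, 10)
  expect_lte(n, 13)
  # half a cycle of the band-passed signal has a single peak
  expect_equal(count_positive_peaks(sin(pi * t), band = NULL), 1L)
  # a negative offset is removed by the zero-phase band-pass
  off <- sin(2 * pi * 12 * t) - 50
  filtered <- bandpass_filter(off, c(10, 16), rate)
  expect_equal(count_positive_peaks(off, rate),
               count_positive_peaks(filtered, band = NULL))
  expect_gte(count_positive_peaks(off, rate), 10)
})

test_that("too-short injected bursts are rejected for duration", {
  bg <- as_recording(matrix(rnorm(250 * 30, sd = 0.01), ncol = 1),
                     rate = 250, labels = "a")
  truth <- tibble::tibble(event = 1L, channels = "a", n_channels = 1L,
                          start = 15, duration = 0.2, freq = 12,
                          amplitude = 0.3, sw_amp = 0, sw_freq = 0)
  rec <- inject_events(bg, truth)
  ev <- detect_spindles(rec, baseline = bg)
  hits <- ev[ev$start < 15.5 & ev$end > 14.9, ]
  expect_gt(nrow(hits), 0)
  expect_false(any(hits$accepted))
  expect_true(any(grepl("duration", hits$reject_reason)))
})

test_that("every accepted event satisfies all acceptance filters", {
  rs <- recovery_study(seed = 1)
  ev <- rs$events
  cfg <- attr(ev, "config")
  acc <- ev[ev$accepted, ]
  expect_gt(nrow(acc), 0)
  expect_true(all(acc$duration >= cfg$min_dur & acc$duration <= cfg$max_dur))
  expect_true(all(acc$peak_freq >= cfg$detect_band[1] &
                    acc$peak_freq <= cfg$detect_band[2]))
  expect_true(all(acc$n_pos_peaks >= cfg$min_pos_peaks))
  expect_true(all(acc$reject_reason == ""))
  expect_true(all(acc$end > acc$start))
  expect_equal(acc$duration, acc$end - acc$start)
})

test_that("raising the threshold factor never increases accepted events", {
  cfg <- quick_cfg(seed = 35)
  study <- generate_study(cfg)
  rec <- slice_recording(study$recording, 60, 240)
  counts <- vapply(c(1.8, 2.5, 3.5), function(tf) {
    ev <- suppressWarnings(detect_spindles(
      rec, config = detection_config(threshold_factor = tf)))
    sum(ev$accepted)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detection is equivariant under time shifts", {
  set.seed(36)
  rate <- 250
  n <- rate * 40
  bg <- 0.01 * colored_noise_test(n)
  t <- (0:(round(1.0 * rate) - 1)) / rate
  burst <- 0.15 * sin(2 * pi * 12 * t) * (0.5 - 0.5 * cos(2 * pi *
                                                            t / max(t)))
  x <- bg
  i0 <- 15 * rate
  x[i0:(i0 + length(burst) - 1)] <- x[i0:(i0 + length(burst) - 1)] + burst
  shift <- 25L
  x_shift <- c(x[(n - shift + 1):n], x[1:(n - shift)])
  base <- as_recording(matrix(bg), rate = rate, labels = "a")
  r1 <- as_recording(matrix(x), rate = rate, labels = "a")
  r2 <- as_recording(matrix(x_shift), rate = rate, labels = "a")
  e1 <- detect_spindles(r1, baseline = base)
  e2 <- detect_spindles(r2, baseline = base)
  # the accepted event overlapping each (shifted) burst
  pick <- function(ev, lo, hi) {
    hit <- ev[ev$accepted & ev$end > lo & ev$start < hi, ]
    hit[which.max(hit$duration), ]
  }
  a1 <- pick(e1, 15, 16)
  a2 <- pick(e2, 15 + shift / rate, 16 + shift / rate)
  expect_equal(nrow(a1), 1)
  expect_equal(nrow(a2), 1)
  expect_lt(abs((a2$start - a1$start) - shift / rate), 2 / rate)
  expect_lt(abs((a2$end - a1$end) - shift / rate), 2 / rate)
})

test_that("the classical view keeps only in-band accepted events", {
  rs <- recovery_study(seed = 1)
  cl <- classical_spindles(rs$events)
  expect_true(all(cl$accepted))
  expect_true(all(cl$peak_freq >= 10 & cl$peak_freq <= 16))
})

test_that("event tables round-trip through CSV", {
  rs <- recovery_study(seed = 1)
  ev <- rs$events
  p <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, p)
  back <- read_events(p)
  expect_equal(back$start, ev$start)
  expect_equal(back$peak_freq, ev$peak_freq)
  expect_equal(back$accepted, ev$accepted)
})
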