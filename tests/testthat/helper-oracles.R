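# Independent brute-force oracles and small fixture builders.

# Plain-loop outward-scan boundary refinement for a single candidate run on
# an envelope vector. Independent of the vectorized implementation.
oracle_refine <- function(env, run_start, run_end, channel_mean, config,
                          win_lo = 1L, win_hi = length(env)) {
  peak <- run_start
  for (i in run_start:run_end) if (env[i] > env[peak]) peak <- i
  left_min <- env[peak]
  for (i in win_lo:peak) if (env[i] < left_min) left_min <- env[i]
  right_min <- env[peak]
  for (i in peak:win_hi) if (env[i] < right_min) right_min <- env[i]
  prom <- env[peak] - max(left_min, right_min)
  if (prom <= 0) return(list(start = run_start, end = run_end, flat = TRUE))
  lvl <- if (config$boundary_rule == "prominence_fraction") {
    config$boundary_prominence_frac * prom
  } else {
    env[peak] - config$boundary_prominence_frac * prom
  }
  cutoff <- max(lvl, config$boundary_mean_frac * channel_mean)
  s <- win_lo
  i <- peak
  while (i >= win_lo) {
    if (env[i] < cutoff) {
      s <- i + 1L
      break
    }
    i <- i - 1L
  }
  e <- win_hi
  i <- peak
  while (i <= win_hi) {
    if (env[i] < cutoff) {
      e <- i - 1L
      break
    }
    i <- i + 1L
  }
  list(start = s, end = e, flat = FALSE)
}

# Exhaustive nearest-extremum scan for the slow-wave peak-to-peak rule
# (strict local extrema; adequate for continuous-valued traces, where
# plateaus have probability zero).
oracle_nearest_p2p <- function(x, rate, center, window) {
  n <- length(x)
  t <- (seq_len(n) - 1L) / rate
  lo <- max(2L, which(t >= center - window)[1L])
  hi <- min(n - 1L, max(which(t <= center + window)))
  best_max <- NA_integer_
  best_min <- NA_integer_
  for (i in lo:hi) {
    if (x[i] > x[i - 1L] && x[i] > x[i + 1L]) {
      if (is.na(best_max) || abs(t[i] - center) < abs(t[best_max] - center))
        best_max <- i
    }
    if (x[i] < x[i - 1L] && x[i] < x[i + 1L]) {
      if (is.na(best_min) || abs(t[i] - center) < abs(t[best_min] - center))
        best_min <- i
    }
  }
  if (is.na(best_max) || is.na(best_min)) return(NA_real_)
  x[best_max] - x[best_min]
}

# Direct DFT (explicit summation) peak frequency within a band, for a
# Hanning-windowed zero-padded segment. O(n * bins) but independent of fft().
oracle_dft_peak <- function(x, rate, nfft, band) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
  xw <- x * w
  ks <- which((0:(nfft / 2)) * rate / nfft >= band[1] &
                (0:(nfft / 2)) * rate / nfft <= band[2]) - 1L
  pw <- vapply(ks, function(k) {
    ang <- -2 * pi * k * (seq_len(n) - 1L) / nfft
    Mod(sum(xw * complex(real = cos(ang), imaginary = sin(ang))))^2
  }, numeric(1))
  ks[which.max(pw)] * rate / nfft
}

# Independent sleep-cycle rule checker operating on the raw stage vector.
oracle_validate_cycle <- function(stages, epoch_len, cycle,
                                  min_wake = 30, min_nrem = 120,
                                  min_rem = 60) {
  wake <- c("W", "WU")
  nrem <- c("S1", "S2", "U1", "U2")
  s_ep <- cycle$start / epoch_len + 1L
  t_ep <- cycle$end / epoch_len + 1L
  if (s_ep < 2L || t_ep > length(stages)) return(FALSE)
  # preceding contiguous wake of at least min_wake
  w <- 0L
  i <- s_ep - 1L
  while (i >= 1L && stages[i] %in% wake) {
    w <- w + 1L
    i <- i - 1L
  }
  if (w * epoch_len < min_wake) return(FALSE)
  # NREM run from cycle start to terminator
  if (!all(stages[s_ep:(t_ep - 1L)] %in% nrem)) return(FALSE)
  if ((t_ep - s_ep) * epoch_len < min_nrem) return(FALSE)
  if (cycle$terminator == "wake") {
    stages[t_ep] %in% wake
  } else {
    r <- 0L
    i <- t_ep
    while (i <= length(stages) && stages[i] == "R") {
      r <- r + 1L
      i <- i + 1L
    }
    r * epoch_len >= min_rem
  }
}

# Unit-variance pink noise for fixtures (independent of the generator's
# internal implementation).
colored_noise_test <- function(n, alpha = 1) {
  w <- stats::fft(stats::rnorm(n))
  idx <- c(0, pmin(seq_len(n - 1L), n - seq_len(n - 1L)))
  s <- c(0, idx[-1L]^(-alpha / 2))
  x <- Re(stats::fft(w * s, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Small sine recording builder.
sine_recording <- function(freq, dur = 4, rate = 250, amplitude = 1,
                           n_channels = 1) {
  t <- (0:(round(dur * rate) - 1L)) / rate
  m <- matrix(rep(amplitude * sin(2 * pi * freq * t), n_channels),
              ncol = n_channels)
  as_recording(m, rate = rate)
}

# Short study configurations used across test files.
quick_cfg <- function(seed = 7, ...) {
  sim_config(stage_sequence = data.frame(
    stage = c("W", "S1", "S2", "R"), duration = c(60, 60, 180, 60)),
    seed = seed, ...)
}

# The larger seeded recovery study, computed once per test session.
.study_cache <- new.env(parent = emptyenv())

recovery_study <- function(seed = 1) {
  key <- paste0("study_", seed)
  if (is.null(.study_cache[[key]])) {
    cfg <- sim_config(stage_sequence = rbind(default_stage_sequence(),
                                             default_stage_sequence()),
                      seed = seed)
    study <- generate_study(cfg)
    events <- suppressWarnings(detect_spindles(study$recording))
    .study_cache[[key]] <- list(cfg = cfg, study = study, events = events)
  }
  .study_cache[[key]]
}
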