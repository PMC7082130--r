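test_that("NREM substaging splits at half the maximum delta power", {
  rate <- 250
  # two NREM epochs: strong vs weak 1 Hz oscillation, then a quiet wake epoch
  t <- (0:(10 * rate - 1)) / rate
  strong <- 1.0 * sin(2 * pi * 1 * t)
  weak <- 0.4 * sin(2 * pi * 1 * t)
  quiet <- rep(0.01, 10 * rate)
  rec <- as_recording(matrix(c(strong, weak, quiet)), rate = rate,
                      labels = "a")
  hyp <- as_hypnogram(c("S1", "S1", "W"))
  out <- substage_nrem(rec, hyp)
  expect_equal(out$stage, c("S2", "S1", "W"))
  # power ratio 1 : 0.16 -> epoch 2 below the 50% threshold
  expect_equal(attr(out, "delta_threshold"),
               0.5 * max(out$delta_power, na.rm = TRUE))
  # equal delta everywhere -> everything deep (>= convention)
  rec_eq <- as_recording(matrix(rep(strong, 3)), rate = rate, labels = "a")
  out_eq <- substage_nrem(rec_eq, as_hypnogram(c("S1", "S1", "S1")))
  expect_true(all(out_eq$stage == "S2"))
  expect_error(substage_nrem(rec, as_hypnogram(c("W", "W", "R"))),
               "no NREM")
})

test_that("substaging recovers the generator's deep/light labels", {
  cfg <- sim_config(stage_sequence = data.frame(
    stage = c("W", "S1", "S2", "S1", "S2"),
    duration = c(30, 120, 120, 120, 120)), seed = 61)
  study <- generate_study(cfg)
  blind <- as_hypnogram(ifelse(study$hypnogram$stage %in% stages_nrem(),
                               "S1", study$hypnogram$stage),
                        artifact = study$hypnogram$artifact)
  out <- substage_nrem(study$recording, blind)
  nrem <- study$hypnogram$stage %in% stages_nrem()
  agreement <- mean(out$stage[nrem] == study$hypnogram$stage[nrem])
  expect_gte(agreement, 0.9)
})

test_that("sleep cycles follow the wake/NREM/terminator rule", {
  # 40 s W -> 3 min NREM -> 90 s REM: one REM-terminated cycle
  h1 <- as_hypnogram(c(rep("W", 4), rep("S2", 18), rep("R", 9), "W"))
  c1 <- find_sleep_cycles(h1)
  expect_equal(nrow(c1), 1)
  expect_equal(c1$terminator, "rem")
  expect_equal(c1$start, 40)
  expect_equal(c1$end, 220)
  # insufficient preceding wake (20 s)
  h2 <- as_hypnogram(c(rep("W", 2), rep("S2", 18), rep("W", 4)))
  expect_equal(nrow(find_sleep_cycles(h2)), 0)
  # NREM run too short (90 s)
  h3 <- as_hypnogram(c(rep("W", 6), rep("S2", 9), rep("W", 4)))
  expect_equal(nrow(find_sleep_cycles(h3)), 0)
  # wake-terminated cycle
  h4 <- as_hypnogram(c(rep("W", 3), rep("S1", 13), rep("W", 3)))
  c4 <- find_sleep_cycles(h4)
  expect_equal(c4$terminator, "wake")
  # REM run shorter than 1 min does not terminate a cycle
  h5 <- as_hypnogram(c(rep("W", 3), rep("S2", 13), rep("R", 5), rep("S2", 4)))
  expect_equal(nrow(find_sleep_cycles(h5)), 0)
})

test_that("returned cycles revalidate against an independent rule checker", {
  set.seed(62)
  n_cycles_seen <- 0L
  for (k in 1:40) {
    # blocky random hypnograms: stages persist for geometric run lengths,
    # as real vigilance states do
    stages <- character(0)
    while (length(stages) < 120) {
      st <- sample(c("W", "WU", "S1", "S2", "U1", "U2", "R"), 1,
                   prob = c(0.25, 0.05, 0.2, 0.25, 0.05, 0.05, 0.15))
      stages <- c(stages, rep(st, 1L + rpois(1, 6)))
    }
    stages <- stages[1:120]
    hyp <- as_hypnogram(stages)
    cyc <- find_sleep_cycles(hyp)
    n_cycles_seen <- n_cycles_seen + nrow(cyc)
    for (i in seq_len(nrow(cyc))) {
      expect_true(oracle_validate_cycle(stages, 10, cyc[i, ]))
    }
  }
  expect_gt(n_cycles_seen, 10)
})

test_that("cycle density profiles are normalized proportions", {
  cyc <- tibble::tibble(start = 0, end = 1260, terminator = "wake")
  # all events in the first 3 min period
  ev <- tibble::tibble(channel = "a", start = seq(10, 150, by = 20),
                       end = seq(10, 150, by = 20) + 1, accepted = TRUE)
  prof <- cycle_density_profile(ev, cyc, min_cycle = 1080, n_cycles = 1)
  expect_equal(sum(prof$proportion), 1)
  expect_equal(prof$proportion[1], 1)
  expect_true(all(prof$proportion[-1] == 0))
  expect_equal(nrow(prof), 7)  # floor(1260 / 180)
  # evenly spaced events give equal proportions
  ev2 <- tibble::tibble(channel = "a",
                        start = seq(15, 1250, by = 10),
                        end = seq(15, 1250, by = 10) + 0.5, accepted = TRUE)
  prof2 <- cycle_density_profile(ev2, cyc, n_cycles = 1)
  expect_lt(diff(range(prof2$proportion)), 0.02)
  # too-short cycles are refused
  short <- tibble::tibble(start = 0, end = 600, terminator = "wake")
  expect_error(cycle_density_profile(ev, short), "minimum length")
  expect_warning(cycle_density_profile(ev, cyc, n_cycles = 3),
                 "qualifying")
})

test_that("hourly densities normalize by NREM minutes and skip NREM-free hours", {
  # hour 1: 30 min NREM; hour 2: all wake
  stages <- c(rep(c("S2", "W"), 180), rep("W", 360))
  hyp <- as_hypnogram(stages)
  ev <- tibble::tibble(channel = "a",
                       start = seq(2, 3598, length.out = 90), end = 0,
                       accepted = TRUE)
  # place each event midpoint inside an NREM epoch
  ep <- floor(seq(0, 179, length.out = 90)) * 2  # 0-based; odd 1-based = S2
  ev$start <- ep * 10 + 4
  ev$end <- ev$start + 1
  d <- hourly_density(ev, hyp)
  expect_equal(d$nrem_minutes[1], 30)
  expect_equal(d$density[1], 3)
  expect_true(is.na(d$density[2]))
})
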