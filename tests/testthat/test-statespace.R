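test_that("a pure in-band tone drives both ratios to one", {
  rate <- 250
  t <- (0:(100 * rate - 1)) / rate
  rec <- as_recording(cbind(a = sin(2 * pi * 7 * t)), rate = rate)
  hyp <- as_hypnogram(rep("W", 10))
  ss <- epoch_ssr(rec, hyp)
  expect_equal(nrow(ss), 10)
  expect_true(all(ss$ssr1 > 0.95))
  expect_true(all(ss$ssr2 > 0.99))
})

test_that("white-noise ratios match the flat-spectrum expectation", {
  set.seed(71)
  rate <- 250
  rec <- as_recording(matrix(rnorm(100 * 10 * rate)), rate = rate,
                      labels = "a")
  hyp <- as_hypnogram(rep("W", 100))
  ss <- epoch_ssr(rec, hyp)
  # flat spectrum: ssr1 -> 2.5/8.5, ssr2 -> 19.5/99.5
  expect_equal(mean(ss$ssr1), 2.5 / 8.5, tolerance = 0.02 / 0.294)
  expect_equal(mean(ss$ssr2), 19.5 / 99.5, tolerance = 0.05)
  expect_true(all(ss$ssr1 >= 0 & ss$ssr1 <= 1))
  expect_true(all(ss$ssr2 >= 0 & ss$ssr2 <= 1))
})

test_that("degenerate epochs are flagged undefined and excluded", {
  rec <- as_recording(matrix(0, 2500, 1), rate = 250, labels = "a")
  hyp <- as_hypnogram("W")
  ss <- epoch_ssr(rec, hyp)
  expect_true(is.na(ss$ssr1))
  expect_error(build_density_map(ss), "no epochs")
})

test_that("density maps bin on the 41 x 41 grid of unit 0.025", {
  e <- tibble::tibble(epoch = 1L, stage = "W", ssr1 = 0.5, ssr2 = 0.5)
  m <- build_density_map(e)
  expect_equal(nrow(m), 1681)
  expect_equal(sum(m$weight), 1)
  hot <- m[m$weight > 0, ]
  expect_equal(hot$ssr1_bin, 20)
  expect_equal(hot$ssr2_bin, 20)
  expect_equal(hot$weight, 1)
  # the closed upper boundary lands in the 41st cell
  e2 <- tibble::tibble(epoch = 1L, stage = "W", ssr1 = 1, ssr2 = 1)
  hot2 <- build_density_map(e2)
  hot2 <- hot2[hot2$weight > 0, ]
  expect_equal(hot2$ssr1_bin, 40)
  expect_equal(hot2$ssr2_bin, 40)
})

test_that("uniform ratios spread evenly over the grid", {
  set.seed(72)
  n <- 20000
  e <- tibble::tibble(epoch = seq_len(n), stage = "W",
                      ssr1 = runif(n), ssr2 = runif(n))
  m <- build_density_map(e)
  inner <- m[m$ssr1_bin < 40 & m$ssr2_bin < 40, ]
  expect_lt(max(abs(inner$weight - 1 / 1600)),
            6 * sqrt((1 / 1600) / n))
})

test_that("combining maps sums weights and subjects", {
  e1 <- tibble::tibble(epoch = 1:4, stage = "W",
                       ssr1 = c(0.1, 0.1, 0.5, 0.9),
                       ssr2 = c(0.2, 0.2, 0.5, 0.8))
  m1 <- build_density_map(e1)
  expect_identical(combine_maps(list(m1))$weight, m1$weight)
  both <- combine_maps(list(m1, m1))
  expect_equal(both$weight, 2 * m1$weight)
  expect_equal(sum(both$weight), 2)
  expect_equal(attr(both, "n_subjects"), 2L)
  six <- combine_maps(rep(list(m1), 6))
  expect_equal(sum(six$weight), 6)
  other <- build_density_map(e1, n_bins = 21L, unit = 0.05)
  expect_error(combine_maps(list(m1, other)), "different grids")
})

test_that("contour levels scale the even-spread baseline", {
  lev <- contour_levels(6)
  expect_equal(unname(lev["low"]), 2.5 * 6 / 1681)
  expect_equal(unname(lev["high"]), 5 * 6 / 1681)
  expect_equal(unname(contour_levels(1, low_mult = 1, high_mult = 1)),
               c(1 / 1681, 1 / 1681))
  expect_equal(unname(contour_levels(12)), 2 * unname(contour_levels(6)))
})

test_that("spindle-centered maps use local events and respect edges", {
  rs <- recovery_study(seed = 1)
  catl <- annotate_simultaneity(classical_spindles(rs$events))
  map_mean <- spindle_epoch_map(rs$study$recording, catl)
  expect_equal(sum(map_mean$weight), 1)
  expect_equal(nrow(map_mean), 1681)
  # no local spindles -> error
  none <- catl[0, ]
  expect_error(spindle_epoch_map(rs$study$recording, none), "no local")
  # single-channel recordings: channel-mean and spindle-channel agree
  ch <- catl$channel[which(catl$is_local)[1]]
  rec1 <- as_recording(
    recording_matrix(rs$study$recording)[, ch, drop = FALSE],
    rate = eeg_rate(rs$study$recording), labels = ch)
  cat1 <- catl[catl$is_local & catl$channel == ch, ]
  m_a <- spindle_epoch_map(rec1, cat1, source = "all_channels_mean")
  m_b <- spindle_epoch_map(rec1, cat1, source = "spindle_channel")
  expect_equal(m_a$weight, m_b$weight)
})

test_that("spindle-epoch density concentrates where NREM epochs live", {
  # spindles injected only in NREM: the spindle-centered map's mass must
  # fall inside the NREM region of the all-epoch map
  cfg <- sim_config(
    n_channels = 4,
    stage_sequence = data.frame(
      stage = c("W", "S1", "S2", "R", "S1", "S2"),
      duration = c(60, 120, 600, 60, 120, 600)),
    spindle_rate = c(W = 0, WU = 0, S1 = 2, S2 = 4, U1 = 2, U2 = 4, R = 0),
    seed = 91)
  study <- generate_study(cfg)
  ev <- suppressWarnings(detect_spindles(study$recording))
  catl <- annotate_simultaneity(classical_spindles(ev))
  ss <- epoch_ssr(study$recording, study$hypnogram)
  nrem_map <- build_density_map(ss[ss$stage %in% stages_nrem(), ])
  sp_map <- spindle_epoch_map(study$recording, catl)
  low <- contour_levels(1)["low"]
  nrem_cells <- paste(nrem_map$ssr1_bin, nrem_map$ssr2_bin)[
    nrem_map$weight >= low]
  in_mass <- sum(sp_map$weight[paste(sp_map$ssr1_bin, sp_map$ssr2_bin) %in%
                                 nrem_cells])
  expect_gte(in_mass, 0.9)
})
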