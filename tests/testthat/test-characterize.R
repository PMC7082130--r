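make_events <- function(channel, start, end) {
  tibble::tibble(channel = channel, start = start, end = end,
                 duration = end - start, peak_freq = 12, peak_power = 1,
                 mean_power = 1, n_pos_peaks = 5L, accepted = TRUE,
                 reject_reason = "")
}

test_that("simultaneity is pairwise overlap without transitive closure", {
  cat2 <- annotate_simultaneity(make_events(c("a", "b"), c(1, 1.5),
                                            c(2, 2.5)))
  expect_equal(cat2$multiplicity, c(2L, 2L))
  expect_false(any(cat2$is_local))

  cat_far <- annotate_simultaneity(make_events(c("a", "b"), c(0, 2),
                                               c(1, 3)))
  expect_true(all(cat_far$is_local))

  # chain: a-b and b-c overlap, a-c do not
  chain <- annotate_simultaneity(make_events(c("a", "b", "c"),
                                             c(0, 0.9, 1.8),
                                             c(1, 1.9, 2.8)))
  expect_equal(chain$multiplicity, c(2L, 3L, 2L))
  expect_equal(chain$partners[[2]], c("a", "c"))
  # partner relation is symmetric
  for (i in seq_len(nrow(chain))) {
    for (p in chain$partner_ids[[i]]) {
      expect_true(chain$id[i] %in% chain$partner_ids[[which(chain$id == p)]])
    }
  }
})

test_that("local plus simultaneous counts equal the catalog size", {
  rs <- recovery_study(seed = 1)
  catl <- annotate_simultaneity(classical_spindles(rs$events))
  g <- glance(catl)
  expect_equal(g$n_local + g$n_simultaneous, g$n_events)
})

test_that("pair connectivity concentrates on the only active pair", {
  ev <- make_events(rep(c("A1-L", "A1-R"), 10),
                    rep(seq(0, 90, by = 10), each = 2),
                    rep(seq(0, 90, by = 10), each = 2) + 1)
  catl <- annotate_simultaneity(ev)
  conn <- pair_connectivity(catl, "global",
                            channels = c("A1-L", "A1-R", "C-L"))
  m <- connectivity_matrix(conn)
  expect_equal(m["A1-L", "A1-R"], 1)
  expect_equal(sum(connectivity_matrix(conn, "count")), 20)
  expect_true(isSymmetric(m))
  # no multiplicity-2 events -> zero matrix
  lone <- annotate_simultaneity(make_events("a", 0, 1))
  expect_equal(sum(connectivity_matrix(pair_connectivity(lone))), 0)
})

test_that("row-normalized connectivity rows sum to one", {
  set.seed(41)
  n <- 60
  ev <- make_events(sample(c("a", "b", "c", "d"), n, replace = TRUE),
                    runif(n, 0, 200), 0)
  ev$end <- ev$start + runif(n, 0.3, 1.5)
  ev$duration <- ev$end - ev$start
  catl <- annotate_simultaneity(ev)
  conn <- pair_connectivity(catl, "per_channel_row")
  m <- connectivity_matrix(conn)
  rs <- rowSums(m)
  expect_true(all(abs(rs[rs > 0] - 1) < 1e-12))
  # global normalization sums to 1 over unordered pairs
  g <- connectivity_matrix(pair_connectivity(catl, "global"))
  if (sum(g) > 0) expect_equal(sum(g[upper.tri(g)]), 1)
})

test_that("global connectivity matches a brute-force recount", {
  set.seed(42)
  n <- 80
  ev <- make_events(sample(c("a", "b", "c", "d", "e"), n, replace = TRUE),
                    runif(n, 0, 120), 0)
  ev$end <- ev$start + runif(n, 0.3, 2)
  ev$duration <- ev$end - ev$start
  catl <- annotate_simultaneity(ev)
  conn <- global_connectivity(catl, min_channels = 4L)
  counts <- connectivity_matrix(conn, "count")
  # independent tally: loop over all event pairs
  brute <- counts * 0
  for (i in seq_len(nrow(catl) - 1)) {
    for (j in (i + 1):nrow(catl)) {
      overlap <- catl$start[i] < catl$end[j] & catl$start[j] < catl$end[i]
      if (overlap && catl$channel[i] != catl$channel[j] &&
          catl$multiplicity[i] >= 4 && catl$multiplicity[j] >= 4) {
        brute[catl$channel[i], catl$channel[j]] <-
          brute[catl$channel[i], catl$channel[j]] + 1
        brute[catl$channel[j], catl$channel[i]] <-
          brute[catl$channel[j], catl$channel[i]] + 1
      }
    }
  }
  expect_equal(counts, brute)
  # a min_channels above the montage size empties the matrix
  empty <- global_connectivity(catl, min_channels = 9L)
  expect_equal(sum(connectivity_matrix(empty, "count")), 0)
})

test_that("stage density divides counts by stage minutes, excluding artifacts", {
  hyp <- as_hypnogram(c(rep("S2", 12), rep("W", 6)))
  ev <- make_events(rep("a", 6), seq(5, 110, length.out = 6), 0)
  ev$end <- ev$start + 1
  ev$duration <- 1
  d <- stage_density(ev, hyp, stages_nrem(), by_channel = FALSE)
  expect_equal(d$density, 3)
  expect_equal(d$minutes, 2)
  # flag an epoch holding events as artifact: excluded from both sides
  hyp2 <- as_hypnogram(c(rep("S2", 12), rep("W", 6)),
                       artifact = c(TRUE, rep(FALSE, 17)))
  ev2 <- make_events(rep("a", 5), c(1, 3, 5, 12, 14), c(2, 4, 6, 13, 15))
  d2 <- stage_density(ev2, hyp2, stages_nrem(), by_channel = FALSE)
  expect_equal(d2$n_events, 2)  # the three events in artifact epoch 1 drop
  expect_equal(d2$minutes, 11 * 10 / 60)
  # zero stage time reports NA, not 0
  d3 <- stage_density(ev, hyp, "R", by_channel = FALSE)
  expect_true(is.na(d3$density))
})

test_that("NREM spindle density clearly exceeds wake density on synthetic data", {
  rs <- recovery_study(seed = 1)
  catl <- annotate_simultaneity(classical_spindles(rs$events))
  dn <- stage_density(catl, rs$study$hypnogram, stages_nrem(),
                      by_channel = FALSE)$density
  dw <- stage_density(catl, rs$study$hypnogram, stages_wake(),
                      by_channel = FALSE)$density
  expect_gt(dn, 2 * dw)
})

test_that("stage summaries aggregate event features per group and channel", {
  hyp <- as_hypnogram(rep("S2", 6))
  ev <- make_events("a", 10, 11)
  ev$peak_freq <- 12
  s <- stage_summary(ev, hyp)
  row <- s[s$group == "S2" & s$channel == "a", ]
  expect_equal(row$mean_freq, 12)
  expect_equal(row$mean_duration, 1)
  expect_equal(row$density, 1)
  # determinism: same inputs, same summary
  expect_identical(s, stage_summary(ev, hyp))
  # grouped form
  s2 <- stage_summary(ev, hyp, list(sleep = stages_nrem(),
                                    wake = stages_wake()))
  expect_true(is.na(s2$mean_freq[s2$group == "wake"]))
})
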