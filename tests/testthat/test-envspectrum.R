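test_that("window planner emits the full grid on clean single-state data", {
  ann <- clean_nrem(600)
  fw <- plan_windows(ann$mask, ann$stages, "NREM", "forward")
  expect_equal(nrow(fw), 26)            # floor((600-100)/20) + 1
  expect_true(all(fw$length == 100))
  expect_equal(fw$start, seq(0, 500, by = 20))

  # forward and backward passes agree (and pool to the same set)
  bw <- plan_windows(ann$mask, ann$stages, "NREM", "backward")
  expect_equal(sort(bw$start), fw$start)
  both <- plan_windows(ann$mask, ann$stages, "NREM", "both")
  expect_equal(nrow(both), 26)
})

test_that("windows shorten against an artifact and restart after it", {
  ann <- make_mask_and_stages(600, list(c(300, 304)),
                              list(list(stage = "N2", start = 0, end = 600)))
  fw <- plan_windows(ann$mask, ann$stages, "NREM", "forward")
  short <- fw[fw$length < 100, ]
  expect_equal(short$start, c(220, 240, 260, 280))
  expect_equal(short$length, c(80, 60, 40, 20))
  expect_equal(short$weight, short$length / 100)
  expect_equal(short$min_valid_freq, 1 / short$length)
  # full-length placement resumes at the first clean grid point after
  expect_equal(min(fw$start[fw$start >= 304 & fw$length == 100]), 320)
})

test_that("clean runs shorter than the minimum produce no windows", {
  # artifacts at [0,20) and [39,600): only [20,39) clean = 19 s
  ann <- make_mask_and_stages(600, list(c(0, 20), c(39, 600)),
                              list(list(stage = "N2", start = 0, end = 600)))
  expect_warning(pw <- plan_windows(ann$mask, ann$stages, "NREM"),
                 "no clean")
  expect_equal(nrow(pw), 0)
})

test_that("every emitted window is artifact-free and in-state", {
  set.seed(21)
  for (rep in 1:5) {
    cells <- runif(150) < 0.15
    stages <- sample(c("N2", "N3", "R", "W"), 30, replace = TRUE,
                     prob = c(0.5, 0.2, 0.2, 0.1))
    mask <- artifact_mask(cells)
    stg <- stage_annotation(stages)
    pw <- tryCatch(plan_windows(mask, stg, "NREM"),
                   warning = function(w) NULL)
    if (is.null(pw) || nrow(pw) == 0) next
    per_cell <- !cells & rep(stage_in_state(stages, "NREM"), each = 5)
    for (i in seq_len(nrow(pw))) {
      cidx <- (pw$start[i] / 4 + 1):((pw$start[i] + pw$length[i]) / 4)
      expect_true(all(per_cell[cidx]))
      expect_gte(pw$length[i], 20)
      expect_lte(pw$length[i], 100)
    }
  }
})

test_that("clean signal lost around one isolated artifact never exceeds 20 s", {
  for (art_start in c(96, 300, 301, 450)) {
    ann <- make_mask_and_stages(600, list(c(art_start, art_start + 4)),
                                list(list(stage = "N2", start = 0, end = 600)))
    pw <- plan_windows(ann$mask, ann$stages, "NREM", "both")
    expect_lte(uncovered_clean_seconds(pw, ann$mask, ann$stages, "NREM"), 20)
  }
})

test_that("single-window periodogram localizes an on-grid tone and tracks validity", {
  rate <- 50
  t <- (0:(100 * rate - 1)) / rate
  p <- window_psd(sin(2 * pi * 0.2 * t), rate)
  expect_equal(p$freq[which.max(p$density)], 0.2)
  expect_true(all(p$valid))
  expect_true(all(p$density >= 0))

  p50 <- window_psd(sin(2 * pi * 0.2 * t[1:(50 * rate)]), rate)
  expect_false(p50$valid[1])             # 0.01 Hz < 1/50
  expect_true(p50$valid[2])              # 0.02 Hz = 1/50
  expect_equal(p50$weight, 0.5)

  # constant segment: zero after detrending
  pc <- window_psd(rep(3, 100 * rate), rate)
  expect_equal(max(pc$density), 0, tolerance = 1e-20)

  expect_error(window_psd(c(rep(1, 100 * rate - 1), NA), rate), "non-finite")
  expect_error(window_psd(numeric(10 * rate), rate), "between 20 and 100")
})

test_that("aggregation is the validity-aware weighted mean", {
  # two identical full windows: idempotent
  d <- runif(400) + 0.1
  agg <- aggregate_psd(list(fake_window_psd(d, 100), fake_window_psd(d, 100)))
  expect_equal(agg$density, d)

  # worked example: (1.0*2 + 0.5*1) / 1.5 = 5/3 at shared valid bins
  agg2 <- aggregate_psd(list(fake_window_psd(rep(2, 400), 100),
                             fake_window_psd(rep(1, 400), 50)))
  expect_equal(agg2$density[2], 5 / 3)
  # 0.01 Hz bin: only the 100-s window is valid there
  expect_equal(agg2$density[1], 2)
  expect_equal(agg2$total_weight[1], 1)

  # a bin where no window is valid is flagged missing
  agg3 <- aggregate_psd(list(fake_window_psd(rep(1, 400), 50)))
  expect_true(is.na(agg3$density[1]))

  expect_error(aggregate_psd(list()), "at least one")
})

test_that("aggregation matches a brute-force loop oracle and is order-invariant", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    wp <- lapply(seq_len(n), function(i)
      fake_window_psd(runif(400), sample(seq(20, 100, by = 20), 1)))
    a <- aggregate_psd(wp)$density
    expect_equal(a, aggregate_oracle(wp), tolerance = 1e-12)
    perm <- sample(n)
    expect_equal(aggregate_psd(wp[perm])$density, a, tolerance = 1e-12)
  }
})

test_that("post-processing z-scores the analysis sub-grid exactly", {
  set.seed(41)
  agg <- aggregate_psd(list(fake_window_psd(exp(rnorm(400)), 100)))
  post <- postprocess_psd(agg)
  n <- length(post$z)
  expect_equal(n, 200)
  expect_lt(abs(mean(post$z)), 1e-9)
  pop_sd <- sqrt(mean((post$z - mean(post$z))^2))
  expect_equal(pop_sd, 1, tolerance = 1e-9)

  # flat density: degenerate z is an error
  flat <- aggregate_psd(list(fake_window_psd(rep(2, 400), 100)))
  expect_error(postprocess_psd(flat), "degenerate|flat")
})

test_that("artifact contamination does not move the envelope-spectrum peak", {
  rec <- make_fig_signal(sim_spec(duration = 600, seed = 13))
  clean <- clean_nrem(600)
  eps_clean <- envelope_spectrum(rec, clean$mask, clean$stages, "NREM",
                                 bands = demo_bands()["delta"])
  set.seed(14)
  art_cells <- sample(150, 30)           # 20% of 4-s cells artifactual
  dirty_mask <- artifact_mask(seq_len(150) %in% art_cells)
  eps_dirty <- envelope_spectrum(rec, dirty_mask, clean$stages, "NREM",
                                 bands = demo_bands()["delta"])
  f <- eps_clean$freq
  peak_clean <- f[f < 1][which.max(eps_clean$raw[1, 1, f < 1])]
  peak_dirty <- f[f < 1][which.max(eps_dirty$raw[1, 1, f < 1])]
  expect_equal(peak_dirty, peak_clean)
  expect_equal(peak_clean, 0.2)
})

test_that("requesting a state with no data errors through the planner", {
  ann <- clean_nrem(300)
  rec <- make_fig_signal(sim_spec(duration = 300, seed = 15))
  expect_warning(
    expect_error(envelope_spectrum(rec, ann$mask, ann$stages, "REM"),
                 "no usable windows"),
    "no clean")
})

test_that("abnormal-spectrum flagging marks gross outliers only", {
  set.seed(51)
  arr <- array(rnorm(60 * 2 * 100), c(60, 2, 100))
  flags <- flag_abnormal_spectra(arr)
  expect_false(any(flags))
  arr[3, 1, 1:30] <- 50                  # 30% of bins wildly deviant
  flags2 <- flag_abnormal_spectra(arr)
  expect_true(flags2[3, 1])
  expect_false(any(flags2[-3, ]))
})
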