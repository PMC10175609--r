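test_that("spike detection recovers ground truth at realistic noise", {
  amp <- 40
  truth <- spaced_spike_times(200, 20, seed = 2)
  tr <- gen_voltage_trace(truth, duration = 20, spike_amplitude = amp,
                          noise_sd = amp / 10, drift_amplitude = 5,
                          drift_period = 4, seed = 3)
  det <- detect_spikes(tr, threshold = amp / 2)
  matched <- vapply(truth, function(s) any(abs(det - s) <= 0.001), logical(1))
  expect_gte(mean(matched), 0.99)
  false_pos <- vapply(det, function(s) all(abs(truth - s) > 0.001), logical(1))
  expect_equal(sum(false_pos), 0)
})

test_that("spike detection handles degenerate traces and the refractory rule", {
  flat <- list(samples = rep(0, 5000), sample_rate = 10000, start_time = 0)
  expect_identical(detect_spikes(flat, threshold = 5), numeric(0))
  expect_error(detect_spikes(list(samples = numeric(0), sample_rate = 1e4),
                             threshold = 5), "empty")
  expect_error(detect_spikes(list(samples = c(0, NA), sample_rate = 1e4),
                             threshold = 5), "non-finite")
  # two waveform peaks 1 ms apart merge into one spike
  close_pair <- gen_voltage_trace(c(0.100, 0.101), duration = 0.3,
                                  noise_sd = 0, seed = 1)
  expect_length(detect_spikes(close_pair, threshold = 20), 1)
})

test_that("detection is invariant to a constant voltage offset", {
  truth <- spaced_spike_times(30, 3, seed = 4)
  tr <- gen_voltage_trace(truth, duration = 3, noise_sd = 3, seed = 5)
  shifted <- tr
  shifted$samples <- tr$samples + 25
  expect_identical(detect_spikes(tr, threshold = 20),
                   detect_spikes(shifted, threshold = 20))
})

test_that("trial segmentation discards adaptation and pools repeated series", {
  ev <- data.frame(
    direction = "forward",
    phase = c("adaptation", rep(c("motion", "stationary"), 3)),
    t_start = seq(0, 30, by = 5), t_end = seq(5, 35, by = 5),
    series_index = 1)
  seg <- segment_trials(ev)
  expect_equal(nrow(seg), 3)
  expect_equal(seg$trial_index, 1:3)

  two_series <- data.frame(
    direction = "forward",
    phase = c("adaptation", "motion", "stationary", "motion", "stationary",
              "adaptation", "motion", "stationary", "motion", "stationary"),
    t_start = seq(0, 45, by = 5), t_end = seq(5, 50, by = 5),
    series_index = rep(c(1, 2), each = 5))
  seg2 <- segment_trials(two_series)
  expect_equal(nrow(seg2), 4)
  expect_equal(seg2$trial_index, 1:4)  # treated as one series

  overlap <- data.frame(direction = "forward",
                        phase = c("motion", "stationary"),
                        t_start = c(0, 4), t_end = c(5, 9), series_index = 1)
  expect_error(segment_trials(overlap), "overlapping")
  orphan <- data.frame(direction = c("forward", "backward"),
                       phase = c("motion", "stationary"),
                       t_start = c(0, 5), t_end = c(5, 10), series_index = 1)
  expect_error(segment_trials(orphan), "not immediately followed")
})

test_that("bin counting uses half-open 2 ms bin occupancy over the first 5 s", {
  expect_equal(bin_counts(numeric(0), c(0, 5)), c(k = 0L, n = 2500L))
  expect_equal(bin_counts(c(0.0001, 0.0025, 0.0041), c(0, 5))[["k"]], 3L)
  expect_equal(bin_counts(c(0.0010, 0.0015), c(0, 5))[["k"]], 1L)  # same bin
  # spikes beyond the 5 s analysis span of a 6 s phase are ignored
  expect_equal(bin_counts(c(5.5), c(0, 6))[["k"]], 0L)
  expect_error(bin_counts(c(1), c(0, 4)), "shorter")
})

test_that("bin counting is invariant to uniform time translation", {
  set.seed(10)
  spikes <- sort(runif(60, 0, 5))
  base <- bin_counts(spikes, c(0, 5))
  for (shift in c(-3.2, 12.7, 100)) {
    expect_identical(bin_counts(spikes + shift, c(shift, shift + 5)), base)
  }
})

test_that("pooling sums counts and conserves per-trial records", {
  tr <- data.frame(direction = "forward",
                   k_motion = c(10, 20), n_motion = 2500,
                   k_stationary = c(5, 5), n_stationary = 2500)
  pooled <- pool_direction(tr)
  expect_equal(pooled$k_motion, 30)
  expect_equal(pooled$n_motion, 5000)
  expect_equal(pooled$k_stationary, 10)
  expect_equal(nrow(pooled$per_trial), 2)
  expect_equal(sum(pooled$per_trial$k_motion), pooled$k_motion)

  single <- pool_direction(tr[1, ])
  expect_equal(single$k_motion, tr$k_motion[1])
  expect_error(pool_direction(tr[0, ]), "no trials")
  mixed <- tr; mixed$direction <- c("forward", "backward")
  expect_error(pool_direction(mixed), "single motion direction")
})

test_that("a full recording processes into pooled per-direction counts", {
  truth_m <- spaced_spike_times(40, 4.8, seed = 6) + 5
  truth_s <- spaced_spike_times(10, 4.8, seed = 7) + 10
  tr <- gen_voltage_trace(c(truth_m, truth_s), duration = 15,
                          noise_sd = 2, seed = 8)
  ev <- data.frame(direction = "yaw_left",
                   phase = c("adaptation", "motion", "stationary"),
                   t_start = c(0, 5, 10), t_end = c(5, 10, 15), series_index = 1)
  res <- process_recording(tr, ev, threshold = 20, neuron_id = "u1")
  expect_named(res, "yaw_left")
  expect_equal(res$yaw_left$k_motion, 40)
  expect_equal(res$yaw_left$k_stationary, 10)
  expect_equal(res$yaw_left$n_motion, 2500)
})
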