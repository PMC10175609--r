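test_that("trial counts respect the Bernoulli-binomial generative model", {
  zero <- synthetic_neuron("z", "TL",
    rates = list(forward = list(r_motion = 0, r_stationary = 0)),
    n_trials = 4, seed = 1)
  tc <- gen_trial_counts(zero, "forward")
  expect_equal(nrow(tc), 4)
  expect_true(all(tc$k_motion == 0 & tc$k_stationary == 0))
  expect_true(all(tc$n_motion == 2500 & tc$n_stationary == 2500))

  certain <- synthetic_neuron("c", "TL",
    rates = list(forward = list(r_motion = 1, r_stationary = 0)),
    n_trials = 1, seed = 1)
  expect_equal(gen_trial_counts(certain, "forward")$k_motion, 2500)

  expect_error(gen_trial_counts(zero, "backward"), "not specified")
  expect_error(gen_trial_counts(zero, "sideways"), "unknown motion direction")
})

test_that("empirical bin-spike frequency converges to the specified rate", {
  nrn <- synthetic_neuron("mc", "CL1a",
    rates = list(forward = list(r_motion = 0.05, r_stationary = 0.03)),
    n_trials = 10000, seed = 99)
  tc <- gen_trial_counts(nrn, "forward")
  se <- sqrt(0.05 * 0.95 / (2500 * 10000))
  expect_lt(abs(mean(tc$k_motion) / 2500 - 0.05), 3 * se)
  expect_true(all(tc$k_motion >= 0 & tc$k_motion <= tc$n_motion))
})

test_that("generators are reproducible under a fixed seed", {
  nrn <- synthetic_neuron("r", "CL2",
    rates = list(yaw_left = list(r_motion = 0.08, r_stationary = 0.04)),
    n_trials = 5, seed = 7)
  expect_identical(gen_trial_counts(nrn, "yaw_left"),
                   gen_trial_counts(nrn, "yaw_left"))
  p1 <- gen_population(c(CL2 = 2, TL = 1), seed = 42)
  p2 <- gen_population(c(CL2 = 2, TL = 1), seed = 42)
  expect_identical(gen_counts_table(p1), gen_counts_table(p2))
  tr1 <- gen_voltage_trace(c(0.1), 0.5, noise_sd = 2, seed = 5)
  tr2 <- gen_voltage_trace(c(0.1), 0.5, noise_sd = 2, seed = 5)
  expect_identical(tr1$samples, tr2$samples)
})

test_that("voltage traces carry the requested spikes over drift and noise", {
  flat <- gen_voltage_trace(numeric(0), duration = 0.2, noise_sd = 0,
                            drift_amplitude = 0, seed = 1)
  expect_true(all(flat$samples == flat$samples[1]))

  tr <- gen_voltage_trace(seq(0.05, 0.95, by = 0.1), duration = 1,
                          noise_sd = 0, drift_amplitude = 0, seed = 1)
  x <- tr$samples
  n_max <- sum(x[2:(length(x) - 1)] > x[1:(length(x) - 2)] &
               x[2:(length(x) - 1)] > x[3:length(x)] &
               x[2:(length(x) - 1)] > x[1] + 1)
  expect_equal(n_max, 10)

  expect_error(gen_voltage_trace(c(2), duration = 1), "within")
  expect_error(gen_voltage_trace(c(0.1), duration = 1, sample_rate = 1000),
               "5 kHz")
})

test_that("populations include a mirrored yaw-selective CL2 pair and honor empty input", {
  expect_identical(gen_population(list()), list())
  pop <- gen_population(c(CL2 = 3), seed = 8)
  expect_length(pop, 3)
  r1 <- pop[[1]]$rates; r2 <- pop[[2]]$rates
  expect_gt(r1$yaw_right$r_motion, r1$yaw_right$r_stationary)
  expect_lt(r1$yaw_left$r_motion, r1$yaw_left$r_stationary)
  expect_gt(r2$yaw_left$r_motion, r2$yaw_left$r_stationary)
  expect_lt(r2$yaw_right$r_motion, r2$yaw_right$r_stationary)
  # the third neuron is unresponsive
  expect_equal(pop[[3]]$rates$yaw_left$r_motion,
               pop[[3]]$rates$yaw_left$r_stationary)
  expect_error(gen_population(c(XX = 1)), "unknown neuron class")
})

test_that("trajectories flatten segments and the preset has equal turn blocks", {
  expect_identical(gen_trajectory(list(list(command = "forward", n_steps = 3))),
                   rep("forward", 3))
  expect_error(gen_trajectory(list()), "at least one")
  expect_error(gen_trajectory(list(list(command = "forward", n_steps = 0))),
               "at least one step")
  expect_error(gen_trajectory(list(list(command = "spin", n_steps = 2))),
               "unknown command")
  preset <- trajectory_preset()
  expect_equal(sum(preset == "turn_right"), sum(preset == "turn_left"))
})

test_that("count tables round-trip through the delimited writer", {
  pop <- gen_population(c(CL2 = 2), seed = 3)
  counts <- gen_counts_table(pop)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_trial_counts(counts, f)
  expect_equal(read_trial_counts(f), counts)
  gt <- gen_ground_truth_table(pop)
  expect_true(all(c("r_motion", "r_stationary") %in% names(gt)))
  expect_true(all(gt$r_motion >= 0 & gt$r_motion <= 1))
})
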