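test_that("modulated connectivity shifts every bump by exactly one column", {
  for (variant in c("default", "noduli")) {
    fit <- cached_model(variant)
    X <- unclass(fit$targets)
    for (direction in c("left", "right")) {
      sh <- cached_shift(variant, direction)
      expect_true(all(sh$dM[!unclass(fit$mask)] == 0))  # no new synapse sites
      for (cc in 1:16) {
        moved <- as.integer(bump_position(compass_step(sh, X[, cc])))
        expected <- if (direction == "left") (cc %% 16) + 1 else ((cc - 2) %% 16) + 1
        expect_equal(moved, expected,
                     label = sprintf("%s/%s from column %d", variant, direction, cc))
      }
    }
  }
})

test_that("left-modulated dynamics move R1 to R2 and right turns wrap L8 to R8", {
  fit <- cached_model("default")
  X <- unclass(fit$targets)
  left <- cached_shift("default", "left")
  right <- cached_shift("default", "right")
  expect_equal(names(bump_position(compass_step(left, X[, column_position("R1")]))),
               "R2")
  expect_equal(names(bump_position(compass_step(right, X[, column_position("L8")]))),
               "R8")
})

test_that("right-turn modulation is the quadrant-rotated left-turn modulation", {
  left <- cached_shift("default", "left")$dM
  right <- cached_shift("default", "right")$dM
  rotated <- left
  for (r in list(1:16, 17:32)) for (cl in list(1:16, 17:32))
    rotated[r, cl] <- left[rev(r), rev(cl)]
  expect_lt(max(abs(right - rotated)), 1e-3)
})

test_that("feed-forward input cannot match the modulatory shift mechanism", {
  for (variant in c("default", "noduli")) {
    for (direction in c("left", "right")) {
      ff <- cached_feedforward(variant, direction)
      sh <- cached_shift(variant, direction)
      expect_gt(ff$loss, sh$loss)
      expect_gt(ff$loss / sh$loss, 2)  # not marginal: the mechanism fails outright
    }
  }
  # u = 0 recovers the maintenance matrix scored against shifted targets
  fit <- cached_model("default")
  ff <- cached_feedforward("default", "left")
  X <- unclass(fit$targets)
  s1 <- sapply(1:16, function(cc) (cc %% 16) + 1)
  X1 <- X[, s1]; X2 <- X1[, s1]
  loss0 <- sum((fit$M %*% X - X1)^2) + sum((fit$M %*% (fit$M %*% X) - X2)^2)
  expect_equal(ff$loss_zero_input, loss0)
  # the mechanism's failure is direction-symmetric
  ff_r <- cached_feedforward("default", "right")
  expect_equal(ff$loss, ff_r$loss, tolerance = 1e-4)
})

test_that("forward simulation keeps the bump still; turns move it one column per step", {
  fit <- cached_model("default")
  shifts <- list(left = cached_shift("default", "left"),
                 right = cached_shift("default", "right"))
  still <- simulate(fit, trajectory = rep("forward", 10), shifts = shifts,
                    start_column = "R3")
  expect_true(all(still$bump$cl1a_column == "R3"))
  expect_true(all(vapply(1:10, function(s) bump_displacement(still, s), 0L) == 0L))

  traj <- trajectory_preset()
  sim <- simulate(fit, trajectory = traj, shifts = shifts, start_column = "L4")
  disp <- vapply(seq_along(traj), function(s) bump_displacement(sim, s), 0L)
  expect_true(all(disp[traj == "forward"] == 0L))
  expect_true(all(disp[traj == "turn_left"] == 1L))
  expect_true(all(disp[traj == "turn_right"] == -1L))
  # CL1a and CL2 bumps coincide at every time point
  expect_equal(sim$bump$cl1a_position, sim$bump$cl2_position)
})

test_that("the equal-turn round trip returns the bump and crosses the PB ends", {
  fit <- cached_model("default")
  shifts <- list(left = cached_shift("default", "left"),
                 right = cached_shift("default", "right"))
  sim <- simulate(fit, shifts = shifts, start_column = "L4")
  pos <- sim$bump$cl1a_position
  expect_equal(pos[length(pos)], pos[1])  # net displacement zero
  steps <- cbind(pos[-length(pos)], pos[-1])
  expect_true(any(steps[, 1] == 1 & steps[, 2] == 16))  # L8 -> R8
  expect_true(any(steps[, 1] == 16 & steps[, 2] == 1))  # R8 -> L8
})

test_that("bump positions are invariant to amplitude renormalization", {
  fit <- cached_model("default")
  shifts <- list(left = cached_shift("default", "left"),
                 right = cached_shift("default", "right"))
  traj <- trajectory_preset(forward_steps = c(6, 5, 6), turn_steps = 9)  # 35 steps
  with_rn <- simulate(fit, trajectory = traj, shifts = shifts)
  without <- simulate(fit, trajectory = traj, shifts = shifts, renormalize = FALSE)
  expect_identical(with_rn$bump$cl1a_position, without$bump$cl1a_position)
  expect_identical(with_rn$bump$cl2_position, without$bump$cl2_position)
})

test_that("simulation validates commands and displacement steps", {
  fit <- cached_model("default")
  shifts <- list(left = cached_shift("default", "left"),
                 right = cached_shift("default", "right"))
  expect_error(simulate(fit, trajectory = c("forward", "hover"), shifts = shifts),
               "unknown command")
  sim <- simulate(fit, trajectory = rep("forward", 3), shifts = shifts)
  expect_error(bump_displacement(sim, 0), "must lie")
  expect_error(bump_displacement(sim, 4), "must lie")
})
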