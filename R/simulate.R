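#' Simulate a commanded heading trajectory on the compass network
#'
#' Iterates the network over a per-step command sequence: `forward` steps
#' apply the maintenance matrix `M`, turn steps apply the direction's
#' modulated matrix `M + dM`. After each step the state is (by default)
#' rescaled so its peak amplitude stays at 1 — the linear fixed points are
#' only approximate after finite optimization, and bump *position* is
#' invariant to this bookkeeping (rescaling by a positive factor cannot move
#' an argmax), which the test suite verifies.
#'
#' @param object A [fit_compass()] result.
#' @param nsim Number of response vectors (the dynamics are deterministic;
#'   values other than 1 are not meaningful and are rejected).
#' @param seed Unused (deterministic dynamics); present for the generic.
#' @param trajectory Per-step command vector from [gen_trajectory()] or
#'   [trajectory_preset()] (the default preset: forward, a right-turn
#'   block, forward, an equal left-turn block, forward).
#' @param shifts Named list with elements `left` and `right` holding
#'   [fit_shift()] results for this model; fitted on the fly when omitted.
#' @param start_column Initial bump column (label like `"L4"` or position
#'   1-16); the starting state is the corresponding bump target.
#' @param renormalize Rescale the state to unit peak amplitude after every
#'   step.
#' @param ... Ignored.
#' @return An object of class `compass_sim`: list with `commands`,
#'   `states` (32 x (steps + 1) matrix, including the initial state),
#'   `bump` (data frame: `step`, `command`, `cl1a_position`, `cl1a_column`,
#'   `cl2_position`, `cl2_column`), and `renormalize`.
#' @examples
#' \donttest{
#' fit <- fit_compass()
#' sim <- simulate(fit, trajectory = trajectory_preset())
#' sim$bump$cl1a_column
#' }
#' @export
simulate.compass_model <- function(object, nsim = 1, seed = NULL,
                                   trajectory = trajectory_preset(),
                                   shifts = NULL, start_column = "L4",
                                   renormalize = TRUE, ...) {
  if (!identical(nsim, 1) && !identical(nsim, 1L))
    stop("the compass dynamics are deterministic; nsim must be 1")
  bad <- setdiff(unique(trajectory), c("forward", "turn_left", "turn_right"))
  if (length(bad)) stop("unknown command(s): ", paste(bad, collapse = ", "))
  if (is.null(shifts))
    shifts <- list(left = fit_shift(object, "left"),
                   right = fit_shift(object, "right"))
  stopifnot(inherits(shifts$left, "compass_shift"),
            inherits(shifts$right, "compass_shift"))
  if (shifts$left$variant != object$variant || shifts$right$variant != object$variant)
    stop("shift modulations were fitted for a different model variant")

  start <- column_position(start_column)
  x <- unclass(object$targets)[, start]
  n_steps <- length(trajectory)
  states <- matrix(NA_real_, 32, n_steps + 1)
  states[, 1] <- x
  for (i in seq_len(n_steps)) {
    W <- switch(trajectory[i],
                forward = object$M,
                turn_left = shifts$left$M_effective,
                turn_right = shifts$right$M_effective)
    x <- drop(W %*% x)
    if (renormalize) x <- x / max(abs(x))
    states[, i + 1] <- x
  }
  pos1 <- apply(states, 2, function(s) as.integer(bump_position(s, "CL1a")))
  pos2 <- apply(states, 2, function(s) as.integer(bump_position(s, "CL2")))
  bump <- data.frame(step = 0:n_steps,
                     command = c(NA, trajectory),
                     cl1a_position = pos1, cl1a_column = pb_columns()[pos1],
                     cl2_position = pos2, cl2_column = pb_columns()[pos2])
  structure(list(commands = trajectory, states = states, bump = bump,
                 start_column = pb_columns()[start],
                 renormalize = renormalize, variant = object$variant),
            class = "compass_sim")
}

#' @export
print.compass_sim <- function(x, ...) {
  cat(sprintf("Compass simulation ('%s' variant): %d steps from column %s\n",
              x$variant, length(x$commands), x$start_column))
  cat(sprintf("  commands: %s\n",
              paste(rle(x$commands)$lengths, rle(x$commands)$values,
                    sep = "x", collapse = ", ")))
  cat(sprintf("  bump trace (CL1a): %s\n",
              paste(x$bump$cl1a_column, collapse = " ")))
  invisible(x)
}

#' Signed circular bump displacement at one simulation step
#'
#' Difference between consecutive CL1a bump positions, wrapped to the
#' signed circular range (-8, 8\]: `+1` is one column toward higher
#' position index (the left-turn direction), `-1` one column toward lower
#' index; the `L8 -> R8` wrap counts as `-1`.
#'
#' @param result A [simulate.compass_model()] result.
#' @param step Step number in `1 .. length(commands)`.
#' @return Signed integer displacement in columns.
#' @export
bump_displacement <- function(result, step) {
  stopifnot(inherits(result, "compass_sim"))
  n <- length(result$commands)
  if (step < 1 || step > n) stop("step must lie in 1..", n)
  d <- result$bump$cl1a_position[step + 1] - result$bump$cl1a_position[step]
  ((d + 7L) %% 16L) - 7L
}

#' Plot a compass simulation
#'
#' Three stacked panels: the commanded movement direction per step, then the
#' CL1a and CL2 population activities over time as column-by-time heatmaps,
#' revealing the single activity bump and its turn-induced traversal of the
#' PB (including wrapping between the lateral ends).
#'
#' @param x A `compass_sim`.
#' @param ... Ignored.
#' @export
plot.compass_sim <- function(x, ...) {
  old <- graphics::par(mfrow = c(3, 1), mar = c(3, 6, 2, 1))
  on.exit(graphics::par(old))
  steps <- seq_along(x$commands)
  code <- c(forward = 0, turn_right = -1, turn_left = 1)[x$commands]
  graphics::plot(steps, code, type = "s", yaxt = "n", xlab = "", ylab = "",
                 main = "Commanded movement", ylim = c(-1.2, 1.2))
  graphics::axis(2, at = c(-1, 0, 1), labels = c("right", "fwd", "left"), las = 1)
  pal <- grDevices::hcl.colors(101, "viridis")
  for (pop in c("CL1a", "CL2")) {
    rows <- if (pop == "CL1a") 1:16 else 17:32
    graphics::image(0:(ncol(x$states) - 1), 1:16, t(x$states[rows, ]),
                    col = pal, xlab = "time step", ylab = "",
                    main = paste(pop, "activity"), yaxt = "n")
    graphics::axis(2, at = c(1, 8, 9, 16), labels = pb_columns()[c(1, 8, 9, 16)],
                   las = 1)
  }
  invisible(x)
}
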