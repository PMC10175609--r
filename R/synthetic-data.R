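#' Specify a synthetic neuron with known ground-truth firing probabilities
#'
#' Defines the generative parameters for one simulated recording: per-bin
#' firing probabilities (probability of at least one spike in a 2 ms bin)
#' during motion and stationary phases for each tested motion direction.
#' Real recordings alternate 5 s motion and 5 s stationary phases, two to
#' five trials per direction; the generator reproduces that trial structure
#' with independent Bernoulli bins.
#'
#' @param neuron_id Character identifier.
#' @param class_label One of the recognized neuron classes
#'   (TL, CL1a, CL2, TB1, CPU1, CPU2, CPU5, CP1, CP2, PoU, TU).
#' @param rates Named list mapping direction labels (see
#'   [motion_directions()]) to lists with elements `r_motion` and
#'   `r_stationary`, both probabilities in \[0, 1\]. Each direction may
#'   appear at most once.
#' @param n_trials Trials per direction (>= 1; recordings used 2-5).
#' @param chirality `"left"`, `"right"`, or `"unknown"`.
#' @param seed Integer seed making all generated trials reproducible.
#' @return An object of class `synthetic_neuron`.
#' @examples
#' nrn <- synthetic_neuron("cl2_demo", "CL2",
#'   rates = list(yaw_right = list(r_motion = 0.10, r_stationary = 0.04)),
#'   n_trials = 3, seed = 1)
#' gen_trial_counts(nrn, "yaw_right")
#' @export
synthetic_neuron <- function(neuron_id, class_label, rates, n_trials = 3,
                             chirality = c("unknown", "left", "right"), seed = 1L) {
  chirality <- match.arg(chirality)
  if (!class_label %in% neuron_classes())
    stop("unknown neuron class '", class_label, "'")
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (is.null(names(rates)) || anyDuplicated(names(rates)))
    stop("rates must be a named list with every direction present at most once")
  for (d in names(rates)) {
    check_direction(d)
    r <- rates[[d]]
    if (is.null(r$r_motion) || is.null(r$r_stationary) ||
        r$r_motion < 0 || r$r_motion > 1 || r$r_stationary < 0 || r$r_stationary > 1)
      stop("rates for '", d, "' must provide r_motion and r_stationary in [0, 1]")
  }
  structure(list(neuron_id = as.character(neuron_id), class_label = class_label,
                 chirality = chirality, rates = rates,
                 n_trials = as.integer(n_trials), seed = as.integer(seed)),
            class = "synthetic_neuron")
}

#' @export
print.synthetic_neuron <- function(x, ...) {
  cat(sprintf("Synthetic %s neuron '%s' (chirality %s): %d trial(s) x %d direction(s), seed %d\n",
              x$class_label, x$neuron_id, x$chirality, x$n_trials,
              length(x$rates), x$seed))
  invisible(x)
}

# one deterministic sub-seed per (neuron seed, direction); kept < 2^31
direction_seed <- function(seed, direction) {
  (abs(seed) * 101L + match(direction, motion_directions()) * 7919L) %% 2147483647L
}

#' Generate trial-structured Bernoulli spike-bin counts
#'
#' Draws, for each trial, the number of occupied 2 ms bins during the 5 s
#' motion phase and the 5 s stationary phase as independent binomials with
#' the neuron's ground-truth per-bin probabilities: 2500 bins per phase.
#'
#' @param spec A [synthetic_neuron()].
#' @param direction Motion direction label; must be present in `spec$rates`.
#' @param bin_width,analysis_span Bin width and analysed phase length in
#'   seconds (defaults 2 ms and 5 s).
#' @return Data frame with one row per trial: `trial_index`, `k_motion`,
#'   `n_motion`, `k_stationary`, `n_stationary`.
#' @examples
#' nrn <- synthetic_neuron("n1", "CL1a",
#'   rates = list(forward = list(r_motion = 0.08, r_stationary = 0.03)), seed = 7)
#' gen_trial_counts(nrn, "forward")
#' @export
gen_trial_counts <- function(spec, direction, bin_width = 0.002, analysis_span = 5) {
  stopifnot(inherits(spec, "synthetic_neuron"))
  check_direction(direction)
  if (!direction %in% names(spec$rates))
    stop("direction '", direction, "' not specified for neuron '", spec$neuron_id, "'")
  r <- spec$rates[[direction]]
  n_bins <- round(analysis_span / bin_width)
  set.seed(direction_seed(spec$seed, direction))
  data.frame(trial_index = seq_len(spec$n_trials),
             k_motion = stats::rbinom(spec$n_trials, n_bins, r$r_motion),
             n_motion = n_bins,
             k_stationary = stats::rbinom(spec$n_trials, n_bins, r$r_stationary),
             n_stationary = n_bins)
}

#' Generate a synthetic intracellular voltage trace
#'
#' Superimposes a stereotyped biphasic spike waveform (1.5 ms, positive then
#' negative lobe) at each requested spike time on slow sinusoidal baseline
#' drift plus Gaussian noise. The waveform shape is a fixture convention;
#' only its detectability matters. Ground-truth spike times are retained in
#' the returned object so detector performance can be scored.
#'
#' @param spike_times Spike onset times in seconds, within `[0, duration]`.
#' @param duration Trace length in seconds.
#' @param sample_rate Sampling rate in Hz (>= 5000).
#' @param spike_amplitude Peak spike height in mV above baseline.
#' @param noise_sd Gaussian noise standard deviation in mV.
#' @param drift_amplitude Amplitude in mV of a slow sinusoidal baseline drift.
#' @param drift_period Drift period in seconds.
#' @param baseline Resting potential in mV.
#' @param seed Integer seed for the noise.
#' @return An object of class `voltage_trace`: list with `samples` (mV),
#'   `sample_rate`, `start_time`, and `spike_times` (ground truth).
#' @examples
#' tr <- gen_voltage_trace(c(0.1, 0.25), duration = 0.5, noise_sd = 0.5, seed = 1)
#' detect_spikes(tr, threshold = 20)
#' @export
gen_voltage_trace <- function(spike_times, duration, sample_rate = 10000,
                              spike_amplitude = 40, noise_sd = 1,
                              drift_amplitude = 0, drift_period = 2,
                              baseline = -60, seed = 1L) {
  if (sample_rate < 5000) stop("sample_rate must be >= 5 kHz")
  spike_times <- sort(as.numeric(spike_times))
  if (length(spike_times) && (min(spike_times) < 0 || max(spike_times) > duration))
    stop("spike times must lie within [0, duration]")
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  set.seed(as.integer(seed))
  x <- rep(baseline, n)
  if (drift_amplitude != 0) x <- x + drift_amplitude * sin(2 * pi * t / drift_period)
  if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
  wave_dur <- 0.0015
  n_wave <- round(wave_dur * sample_rate)
  wave <- spike_amplitude * sin(2 * pi * seq(0, by = 1 / sample_rate, length.out = n_wave) / wave_dur)
  for (ts in spike_times) {
    i0 <- round(ts * sample_rate) + 1L
    idx <- i0:min(i0 + n_wave - 1L, n)
    x[idx] <- x[idx] + wave[seq_along(idx)]
  }
  structure(list(samples = x, sample_rate = sample_rate, start_time = 0,
                 spike_times = spike_times),
            class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("Voltage trace: %d samples at %g Hz (%.3f s), %d ground-truth spike(s)\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate, length(x$spike_times)))
  invisible(x)
}

default_rate_profile <- function(baseline = 0.04) {
  stats::setNames(
    lapply(motion_directions(),
           function(d) list(r_motion = baseline, r_stationary = baseline)),
    motion_directions())
}

#' Generate a labelled population of synthetic neurons
#'
#' Builds one [synthetic_neuron()] per requested neuron, deterministically
#' from `seed`. Unless overridden through `rate_profiles`, neurons are
#' unresponsive (motion and stationary probabilities equal to `baseline_rate`),
#' except that the first two CL2 neurons (when at least two are requested)
#' form a direction-selective pair with mirrored yaw preferences: one is
#' excited by right yaw and suppressed by left yaw, the other the reverse,
#' emulating the mirror-symmetric yaw tuning observed in recordings.
#'
#' @param n_per_class Named integer vector/list: neurons per class label.
#' @param rate_profiles Optional named list (by class label) of rate maps as
#'   accepted by [synthetic_neuron()]; overrides the defaults for that class.
#' @param n_trials Trials per direction.
#' @param baseline_rate Default per-bin firing probability (both phases).
#' @param yaw_excited_rate,yaw_suppressed_rate Motion-phase probabilities for
#'   the preferred and anti-preferred yaw direction of the mirrored CL2 pair.
#' @param seed Integer seed.
#' @return List of `synthetic_neuron` objects.
#' @examples
#' pop <- gen_population(c(CL2 = 2, CL1a = 1), seed = 42)
#' sapply(pop, function(n) n$class_label)
#' @export
gen_population <- function(n_per_class, rate_profiles = NULL, n_trials = 3,
                           baseline_rate = 0.04, yaw_excited_rate = 0.10,
                           yaw_suppressed_rate = 0.015, seed = 1L) {
  n_per_class <- unlist(n_per_class)
  if (length(n_per_class) == 0) return(list())
  bad <- setdiff(names(n_per_class), neuron_classes())
  if (length(bad)) stop("unknown neuron class(es): ", paste(bad, collapse = ", "))
  pop <- list()
  idx <- 0L
  for (cls in names(n_per_class)) {
    for (i in seq_len(n_per_class[[cls]])) {
      idx <- idx + 1L
      rates <- if (!is.null(rate_profiles[[cls]])) rate_profiles[[cls]]
               else default_rate_profile(baseline_rate)
      chir <- "unknown"
      if (is.null(rate_profiles[[cls]]) && cls == "CL2" && i <= 2 && n_per_class[[cls]] >= 2) {
        # mirrored yaw-selective pair with opposite polarity
        pref <- if (i == 1) "yaw_right" else "yaw_left"
        anti <- if (i == 1) "yaw_left" else "yaw_right"
        rates[[pref]] <- list(r_motion = yaw_excited_rate, r_stationary = baseline_rate)
        rates[[anti]] <- list(r_motion = yaw_suppressed_rate, r_stationary = baseline_rate)
        chir <- if (i == 1) "right" else "left"
      }
      pop[[idx]] <- synthetic_neuron(
        neuron_id = sprintf("%s_%02d", cls, i), class_label = cls,
        rates = rates, n_trials = n_trials, chirality = chir,
        seed = (as.integer(seed) + idx * 104729L) %% 2147483647L)
    }
  }
  pop
}

#' Generate a discrete heading-command trajectory
#'
#' Flattens ordered `(command, n_steps)` segments into a per-step command
#' sequence with commands in `forward`, `turn_left`, `turn_right`.
#'
#' @param segments List of `list(command =, n_steps =)` entries (or a
#'   two-column data frame `command`, `n_steps`). Total steps must be >= 1.
#' @return Character vector of per-step commands.
#' @examples
#' gen_trajectory(list(list(command = "forward", n_steps = 3)))
#' @seealso [trajectory_preset()]
#' @export
gen_trajectory <- function(segments) {
  if (is.data.frame(segments))
    segments <- lapply(seq_len(nrow(segments)),
                       function(i) list(command = segments$command[i],
                                        n_steps = segments$n_steps[i]))
  if (length(segments) == 0) stop("trajectory must contain at least one segment")
  cmds <- unlist(lapply(segments, function(s) {
    if (!s$command %in% c("forward", "turn_left", "turn_right"))
      stop("unknown command '", s$command, "'")
    if (s$n_steps < 0) stop("n_steps must be >= 0")
    rep(s$command, s$n_steps)
  }))
  if (length(cmds) < 1) stop("trajectory must contain at least one step")
  cmds
}

#' Standard trajectory presets
#'
#' The `"roundtrip"` preset emulates the simulated walk used to demonstrate
#' heading integration: forward motion interrupted by a right-turn block
#' followed by a left-turn block of equal magnitude, so the final heading
#' (and hence the final compass-bump position) equals the initial one.
#'
#' @param name Preset name; currently `"roundtrip"`.
#' @param forward_steps Steps in each forward segment (length-3 vector or a
#'   single number recycled).
#' @param turn_steps Steps in each turn block (identical for both turns).
#' @return Character vector of per-step commands.
#' @examples
#' table(trajectory_preset())
#' @export
trajectory_preset <- function(name = "roundtrip", forward_steps = c(5, 4, 5),
                              turn_steps = 8) {
  if (!identical(name, "roundtrip")) stop("unknown preset '", name, "'")
  f <- rep(forward_steps, length.out = 3)
  gen_trajectory(list(
    list(command = "forward",    n_steps = f[1]),
    list(command = "turn_right", n_steps = turn_steps),
    list(command = "forward",    n_steps = f[2]),
    list(command = "turn_left",  n_steps = turn_steps),
    list(command = "forward",    n_steps = f[3])))
}

#' Tabulate and write trial counts for a synthetic population
#'
#' `gen_counts_table()` draws all trials for every neuron and direction of a
#' population into the canonical delimited schema; `write_trial_counts()` and
#' `read_trial_counts()` round-trip that schema as tab-separated text;
#' `gen_ground_truth_table()` tabulates the generating probabilities for
#' recovery tests.
#'
#' @param population List of [synthetic_neuron()] objects.
#' @param file Path of a tab-separated file.
#' @param counts Data frame in the canonical schema (columns `neuron_id`,
#'   `class_label`, `chirality`, `direction`, `trial_index`, `k_motion`,
#'   `n_motion`, `k_stationary`, `n_stationary`).
#' @return Data frames in the schemas described above.
#' @examples
#' pop <- gen_population(c(CL2 = 2), seed = 3)
#' head(gen_counts_table(pop))
#' @export
gen_counts_table <- function(population) {
  rows <- lapply(population, function(spec) {
    per_dir <- lapply(names(spec$rates), function(d) {
      tr <- gen_trial_counts(spec, d)
      cbind(data.frame(neuron_id = spec$neuron_id, class_label = spec$class_label,
                       chirality = spec$chirality, direction = d), tr)
    })
    do.call(rbind, per_dir)
  })
  do.call(rbind, rows)
}

#' @rdname gen_counts_table
#' @export
gen_ground_truth_table <- function(population) {
  rows <- lapply(population, function(spec) {
    data.frame(neuron_id = spec$neuron_id, class_label = spec$class_label,
               chirality = spec$chirality, direction = names(spec$rates),
               r_motion = vapply(spec$rates, function(r) r$r_motion, 0),
               r_stationary = vapply(spec$rates, function(r) r$r_stationary, 0),
               row.names = NULL)
  })
  do.call(rbind, rows)
}

counts_schema <- c("neuron_id", "class_label", "chirality", "direction",
                   "trial_index", "k_motion", "n_motion", "k_stationary",
                   "n_stationary")

#' @rdname gen_counts_table
#' @export
write_trial_counts <- function(counts, file) {
  missing_cols <- setdiff(counts_schema, names(counts))
  if (length(missing_cols))
    stop("counts table lacks column(s): ", paste(missing_cols, collapse = ", "))
  utils::write.table(counts[counts_schema], file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname gen_counts_table
#' @export
read_trial_counts <- function(file) {
  counts <- utils::read.table(file, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  missing_cols <- setdiff(counts_schema, names(counts))
  if (length(missing_cols))
    stop("counts table lacks column(s): ", paste(missing_cols, collapse = ", "))
  counts
}
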