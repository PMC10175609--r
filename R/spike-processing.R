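#' Detect spikes in an intracellular voltage trace
#'
#' Removes the slow baseline by subtracting a running median (default window
#' 500 ms, edge-replication padding at the trace boundaries) and marks an
#' event wherever the baseline-subtracted signal crosses the threshold
#' upward; within each suprathreshold run the sample of maximal deflection is
#' taken as the spike time. Events closer together than 2 ms — the
#' approximate refractory period of these neurons — are merged, keeping the
#' larger deflection.
#'
#' Applying the threshold to the median-subtracted signal (rather than the
#' raw voltage) makes a single manually chosen threshold workable under
#' baseline drift; adding a constant offset to the trace leaves the detected
#' spike times unchanged.
#'
#' @param trace A [gen_voltage_trace()] object, or any list with elements
#'   `samples` (mV), `sample_rate` (Hz), and optionally `start_time` (s).
#' @param threshold Detection threshold in mV on the baseline-subtracted
#'   signal (manually chosen; no automatic threshold).
#' @param median_window Running-median window width in seconds.
#' @param refractory Minimal spacing between distinct spikes in seconds.
#' @return Numeric vector of spike times in seconds.
#' @examples
#' tr <- gen_voltage_trace(c(0.1, 0.3), duration = 0.5, noise_sd = 0, seed = 1)
#' detect_spikes(tr, threshold = 20)
#' @export
detect_spikes <- function(trace, threshold, median_window = 0.5,
                          refractory = 0.002) {
  x <- trace$samples
  if (length(x) == 0) stop("empty voltage trace")
  if (!all(is.finite(x))) stop("voltage trace contains non-finite samples")
  if (median_window <= 0) stop("median_window must be positive")
  if (missing(threshold) || is.null(threshold)) stop("a detection threshold (mV) must be provided")
  rate <- trace$sample_rate
  t0 <- if (is.null(trace$start_time)) 0 else trace$start_time

  k <- round(median_window * rate)
  if (k %% 2 == 0) k <- k + 1
  k <- min(k, if (length(x) %% 2 == 1) length(x) else length(x) - 1)
  if (k >= 3) {
    half <- (k - 1) / 2
    padded <- c(rep(x[1], half), x, rep(x[length(x)], half))  # edge replication
    baseline <- stats::runmed(padded, k, endrule = "keep")[(half + 1):(half + length(x))]
  } else baseline <- x
  d <- x - baseline

  above <- d >= threshold
  if (!any(above)) return(numeric(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  peaks <- vapply(runs, function(i) {
    seg <- starts[i]:ends[i]
    seg[which.max(d[seg])]
  }, integer(1))
  amps <- d[peaks]

  # refractory merge: absorb events closer than `refractory`, keep the larger
  keep <- integer(0)
  for (i in seq_along(peaks)) {
    if (length(keep) && (peaks[i] - peaks[keep[length(keep)]]) / rate < refractory) {
      if (amps[i] > amps[keep[length(keep)]]) keep[length(keep)] <- i
    } else keep <- c(keep, i)
  }
  t0 + (peaks[keep] - 1) / rate
}

#' Segment a trial-event table into analysis windows
#'
#' Validates the phase structure of a recording session and returns one row
#' per trial with its motion and stationary windows. Adaptation phases (the
#' discarded stationary period preceding each stimulation series) are
#' excluded, and trials from repeated series of the same motion direction
#' are pooled as if they belonged to one series, in chronological order.
#'
#' @param events Data frame with columns `direction`, `phase` (one of
#'   `adaptation`, `motion`, `stationary`), `t_start`, `t_end` (seconds),
#'   and `series_index`. Phases must be time-ordered and non-overlapping,
#'   and every motion phase must be immediately followed by a stationary
#'   phase of the same direction.
#' @return Data frame with columns `direction`, `series_index`,
#'   `trial_index` (running index within the pooled direction),
#'   `motion_start`, `motion_end`, `stat_start`, `stat_end`.
#' @examples
#' ev <- data.frame(
#'   direction = "forward",
#'   phase = c("adaptation", "motion", "stationary", "motion", "stationary"),
#'   t_start = c(0, 5, 10, 15, 20), t_end = c(5, 10, 15, 20, 25),
#'   series_index = 1)
#' segment_trials(ev)
#' @export
segment_trials <- function(events) {
  need <- c("direction", "phase", "t_start", "t_end", "series_index")
  missing_cols <- setdiff(need, names(events))
  if (length(missing_cols))
    stop("event table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (!all(events$phase %in% c("adaptation", "motion", "stationary")))
    stop("phase must be one of adaptation, motion, stationary")
  events <- events[order(events$t_start), , drop = FALSE]
  if (any(events$t_end <= events$t_start))
    stop("every phase must have t_end > t_start")
  if (nrow(events) > 1 &&
      any(events$t_start[-1] < events$t_end[-nrow(events)] - 1e-9))
    stop("event table contains overlapping phases")

  mot <- which(events$phase == "motion")
  trials <- lapply(mot, function(i) {
    if (i == nrow(events) || events$phase[i + 1] != "stationary" ||
        events$direction[i + 1] != events$direction[i])
      stop("motion phase in row ", i,
           " is not immediately followed by a stationary phase of the same direction")
    data.frame(direction = events$direction[i],
               series_index = events$series_index[i],
               motion_start = events$t_start[i], motion_end = events$t_end[i],
               stat_start = events$t_start[i + 1], stat_end = events$t_end[i + 1])
  })
  out <- do.call(rbind, trials)
  if (is.null(out)) stop("event table contains no motion phase")
  out <- out[order(match(out$direction, motion_directions()), out$motion_start), ,
             drop = FALSE]
  out$trial_index <- stats::ave(seq_len(nrow(out)), out$direction,
                                FUN = seq_along)
  rownames(out) <- NULL
  out[c("direction", "series_index", "trial_index",
        "motion_start", "motion_end", "stat_start", "stat_end")]
}

#' Count occupied 2 ms bins in an analysis window
#'
#' Divides the first `analysis_span` seconds of the window into half-open
#' bins `[t, t + bin_width)` anchored at the window start and counts the
#' bins containing at least one spike (bin occupancy, not spike count:
#' several spikes inside one bin count once). Windows longer than the
#' analysis span are truncated to its first `analysis_span` seconds; shorter
#' windows are an error.
#'
#' @param spikes Numeric vector of spike times in seconds.
#' @param window Length-2 numeric `(t0, t1)` delimiting the phase.
#' @param bin_width Bin width in seconds (default 2 ms, the approximate
#'   refractory period).
#' @param analysis_span Analysed span in seconds (default 5 s).
#' @return Named integer vector `c(k = occupied bins, n = total bins)`.
#' @examples
#' bin_counts(c(0.0005, 0.0015, 0.004), window = c(0, 5))  # k = 2 of n = 2500
#' @export
bin_counts <- function(spikes, window, bin_width = 0.002, analysis_span = 5) {
  stopifnot(length(window) == 2)
  t0 <- window[1]; t1 <- window[2]
  if (t1 - t0 < analysis_span - 1e-9)
    stop(sprintf("window of %.3f s is shorter than the %.3f s analysis span",
                 t1 - t0, analysis_span))
  n <- round(analysis_span / bin_width)
  s <- spikes[spikes >= t0 & spikes < t0 + analysis_span]
  bins <- floor((s - t0) / bin_width)
  bins <- bins[bins >= 0 & bins < n]
  c(k = length(unique(bins)), n = as.integer(n))
}

#' Pool per-trial counts of one motion direction
#'
#' Sums spike-bin counts over the trials of one direction — the pooled data
#' are the analysis unit of the hypothesis comparison — while retaining the
#' per-trial quadruples for descriptive reports.
#'
#' @param trials Data frame with columns `k_motion`, `n_motion`,
#'   `k_stationary`, `n_stationary` (and optionally `direction`, which must
#'   then be constant, and `neuron_id`).
#' @return An object of class `trial_counts`: list with the pooled
#'   `k_motion`, `n_motion`, `k_stationary`, `n_stationary`, the `direction`
#'   and `neuron_id` (when present), and `per_trial` (the input rows).
#' @examples
#' tr <- data.frame(k_motion = c(10, 20), n_motion = 2500,
#'                  k_stationary = c(5, 5), n_stationary = 2500)
#' pool_direction(tr)
#' @export
pool_direction <- function(trials) {
  if (NROW(trials) == 0) stop("no trials to pool")
  need <- c("k_motion", "n_motion", "k_stationary", "n_stationary")
  missing_cols <- setdiff(need, names(trials))
  if (length(missing_cols))
    stop("trials lack column(s): ", paste(missing_cols, collapse = ", "))
  if ("direction" %in% names(trials) && length(unique(trials$direction)) > 1)
    stop("pool_direction expects trials of a single motion direction")
  structure(list(
    neuron_id = if ("neuron_id" %in% names(trials)) unique(trials$neuron_id)[1] else NA_character_,
    direction = if ("direction" %in% names(trials)) trials$direction[1] else NA_character_,
    k_motion = sum(trials$k_motion), n_motion = sum(trials$n_motion),
    k_stationary = sum(trials$k_stationary), n_stationary = sum(trials$n_stationary),
    per_trial = as.data.frame(trials)), class = "trial_counts")
}

#' @export
print.trial_counts <- function(x, ...) {
  cat(sprintf("Pooled counts%s%s: motion %d/%d bins, stationary %d/%d bins (%d trial(s))\n",
              if (!is.na(x$neuron_id)) paste0(" for ", x$neuron_id) else "",
              if (!is.na(x$direction)) paste0(" [", x$direction, "]") else "",
              x$k_motion, x$n_motion, x$k_stationary, x$n_stationary,
              nrow(x$per_trial)))
  invisible(x)
}

#' Process a voltage recording into pooled per-direction counts
#'
#' Convenience wrapper chaining [detect_spikes()], [segment_trials()],
#' [bin_counts()], and [pool_direction()]: the full path from a raw trace
#' plus trial-event table to the pooled Bernoulli counts consumed by
#' [hypothesis_posterior()].
#'
#' @inheritParams detect_spikes
#' @param events Trial-event table as accepted by [segment_trials()].
#' @param neuron_id Identifier attached to the output.
#' @param ... Passed on to [detect_spikes()].
#' @return Named list of [pool_direction()] results, one per direction.
#' @export
process_recording <- function(trace, events, threshold, neuron_id = NA_character_, ...) {
  spikes <- detect_spikes(trace, threshold = threshold, ...)
  trials <- segment_trials(events)
  out <- list()
  for (d in unique(trials$direction)) {
    tr <- trials[trials$direction == d, , drop = FALSE]
    per_trial <- do.call(rbind, lapply(seq_len(nrow(tr)), function(i) {
      m <- bin_counts(spikes, c(tr$motion_start[i], tr$motion_end[i]))
      s <- bin_counts(spikes, c(tr$stat_start[i], tr$stat_end[i]))
      data.frame(neuron_id = neuron_id, direction = d, trial_index = tr$trial_index[i],
                 k_motion = m[["k"]], n_motion = m[["n"]],
                 k_stationary = s[["k"]], n_stationary = s[["n"]])
    }))
    out[[d]] <- pool_direction(per_trial)
  }
  out
}
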