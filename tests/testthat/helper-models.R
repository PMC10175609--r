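# Fitted compass models are deterministic and reused across test files.
.fit_cache <- new.env(parent = emptyenv())

cached_model <- function(variant = "default", lambda = 0.15) {
  key <- sprintf("m_%s_%g", variant, lambda)
  if (is.null(.fit_cache[[key]]))
    .fit_cache[[key]] <- fit_compass(variant, lambda = lambda)
  .fit_cache[[key]]
}

cached_shift <- function(variant = "default", direction = "left") {
  key <- sprintf("s_%s_%s", variant, direction)
  if (is.null(.fit_cache[[key]]))
    .fit_cache[[key]] <- fit_shift(cached_model(variant), direction)
  .fit_cache[[key]]
}

cached_feedforward <- function(variant = "default", direction = "left") {
  key <- sprintf("f_%s_%s", variant, direction)
  if (is.null(.fit_cache[[key]]))
    .fit_cache[[key]] <- fit_feedforward(cached_model(variant), direction)
  .fit_cache[[key]]
}

# spike times on a jittered grid with guaranteed minimal spacing
spaced_spike_times <- function(n, duration, min_gap = 0.005, seed = 1) {
  set.seed(seed)
  grid <- seq(0.05, duration - 0.05, length.out = n)
  jitter_max <- (min(diff(grid)) - min_gap) / 2
  sort(grid + stats::runif(n, -jitter_max, jitter_max))
}
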