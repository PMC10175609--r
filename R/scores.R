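#' Score a table of trial counts for motion sensitivity and direction selectivity
#'
#' For every neuron and tested motion direction, pools the trials, computes
#' the three-hypothesis posterior, the Bayes factor for unequal rates, and
#' the motion sensitivity score; for every motion category in which both
#' opposing directions were tested, computes the absolute motion sensitivity
#' score, the direction selectivity score, and the expected absolute
#' direction selectivity score. Directions (or categories) a neuron was not
#' tested with are simply absent from the output and are excluded from the
#' corresponding cells when aggregating.
#'
#' @param counts Data frame in the canonical trial-count schema (see
#'   [gen_counts_table()]), one row per neuron, direction, and trial.
#' @param prior A [beta_prior()].
#' @param method Posterior computation method; see [hypothesis_posterior()].
#' @param bf_threshold Bayes-factor threshold flagging strong evidence for a
#'   firing-rate difference (default 10).
#' @return An object of class `selectivity_scores`: list with
#'   `directions` (per neuron x direction: pooled counts, posterior
#'   probabilities, `bf_uneq`, `strong_evidence`, `mss`),
#'   `categories` (per neuron x category: `amss`, `dss`, `adss`), the
#'   `posteriors` keyed `neuron_id.direction`, and the settings used.
#' @examples
#' pop <- gen_population(c(CL2 = 2), seed = 11)
#' sc <- score_neurons(gen_counts_table(pop))
#' sc$categories[sc$categories$category == "yaw", ]
#' @export
score_neurons <- function(counts, prior = beta_prior(),
                          method = c("quadrature", "closed_form_mix", "monte_carlo"),
                          bf_threshold = 10) {
  method <- match.arg(method)
  need <- c("neuron_id", "direction", "k_motion", "n_motion",
            "k_stationary", "n_stationary")
  missing_cols <- setdiff(need, names(counts))
  if (length(missing_cols))
    stop("counts table lacks column(s): ", paste(missing_cols, collapse = ", "))

  posteriors <- list()
  dir_rows <- list()
  for (id in unique(counts$neuron_id)) {
    sub <- counts[counts$neuron_id == id, , drop = FALSE]
    cls <- if ("class_label" %in% names(sub)) sub$class_label[1] else NA_character_
    for (d in unique(sub$direction)) {
      pooled <- pool_direction(sub[sub$direction == d, , drop = FALSE])
      post <- hypothesis_posterior(pooled, prior = prior, method = method)
      bf <- bayes_factor(post)
      posteriors[[paste(id, d, sep = ".")]] <- post
      dir_rows[[length(dir_rows) + 1L]] <- data.frame(
        neuron_id = id, class_label = cls, direction = d,
        k_motion = pooled$k_motion, n_motion = pooled$n_motion,
        k_stationary = pooled$k_stationary, n_stationary = pooled$n_stationary,
        p_less = post[["p_less"]], p_equal = post[["p_equal"]],
        p_greater = post[["p_greater"]],
        bf_uneq = bf, strong_evidence = bf >= bf_threshold,
        mss = mss(post))
    }
  }
  directions <- do.call(rbind, dir_rows)

  cat_rows <- list()
  for (id in unique(directions$neuron_id)) {
    cls <- directions$class_label[directions$neuron_id == id][1]
    for (cat_name in names(motion_categories())) {
      ab <- motion_categories()[[cat_name]]
      pa <- posteriors[[paste(id, ab[1], sep = ".")]]
      pb <- posteriors[[paste(id, ab[2], sep = ".")]]
      if (is.null(pa) || is.null(pb)) next  # category untested for this neuron
      cat_rows[[length(cat_rows) + 1L]] <- data.frame(
        neuron_id = id, class_label = cls, category = cat_name,
        amss = amss(pa, pb), dss = dss(pa, pb), adss = adss(pa, pb))
    }
  }
  categories <- if (length(cat_rows)) do.call(rbind, cat_rows) else
    data.frame(neuron_id = character(0), class_label = character(0),
               category = character(0), amss = numeric(0), dss = numeric(0),
               adss = numeric(0))

  structure(list(directions = directions, categories = categories,
                 posteriors = posteriors, prior = prior, method = method,
                 bf_threshold = bf_threshold),
            class = "selectivity_scores")
}

#' @export
print.selectivity_scores <- function(x, ...) {
  cat(sprintf("Selectivity scores for %d neuron(s): %d direction tests, %d category tests\n",
              length(unique(x$directions$neuron_id)), nrow(x$directions),
              nrow(x$categories)))
  cat(sprintf("  prior Beta(%g, %g), method '%s', %d test(s) with BF >= %g\n",
              x$prior$alpha, x$prior$beta, x$method,
              sum(x$directions$strong_evidence), x$bf_threshold))
  invisible(x)
}

#' Aggregate selectivity scores by neuron class
#'
#' Sums the posterior-weighted scores within each neuron class: MSS per
#' motion direction, and AMSS / DSS / ADSS per motion category, together
#' with the number of neurons tested in each cell — so the maximal
#' attainable magnitude of every cell equals its `n_tested`. Cells in which
#' no neuron of a class was tested are absent (untested), not zero.
#'
#' @param scores A [score_neurons()] result.
#' @param group_by Grouping column of the score tables (default
#'   `"class_label"`).
#' @return List of two data frames, `directions` (`group`, `direction`,
#'   `mss_sum`, `n_tested`, `n_strong`) and `categories` (`group`,
#'   `category`, `amss_sum`, `dss_sum`, `adss_sum`, `n_tested`).
#' @examples
#' pop <- gen_population(c(CL2 = 2, TL = 1), seed = 5)
#' aggregate_scores(score_neurons(gen_counts_table(pop)))
#' @export
aggregate_scores <- function(scores, group_by = "class_label") {
  stopifnot(inherits(scores, "selectivity_scores"))
  d <- scores$directions
  if (nrow(d) == 0) stop("no scored directions to aggregate")
  d$group <- d[[group_by]]
  directions <- do.call(rbind, lapply(split(d, list(d$group, d$direction), drop = TRUE),
    function(g) data.frame(group = g$group[1], direction = g$direction[1],
                           mss_sum = sum(g$mss), n_tested = nrow(g),
                           n_strong = sum(g$strong_evidence))))
  ct <- scores$categories
  categories <- if (nrow(ct)) {
    ct$group <- ct[[group_by]]
    do.call(rbind, lapply(split(ct, list(ct$group, ct$category), drop = TRUE),
      function(g) data.frame(group = g$group[1], category = g$category[1],
                             amss_sum = sum(g$amss), dss_sum = sum(g$dss),
                             adss_sum = sum(g$adss), n_tested = nrow(g))))
  } else data.frame(group = character(0), category = character(0),
                    amss_sum = numeric(0), dss_sum = numeric(0),
                    adss_sum = numeric(0), n_tested = integer(0))
  rownames(directions) <- rownames(categories) <- NULL
  list(directions = directions[order(directions$group, directions$direction), ],
       categories = categories[order(categories$group, categories$category), ])
}

#' Monte-Carlo power analysis of the motion-sensitivity test
#'
#' Estimates the probability that the Bayes factor reaches the
#' strong-evidence threshold for a given true effect (per-bin firing
#' probabilities `r_motion` vs `r_stationary`) and sample size, by repeated
#' simulation of pooled binomial data. A matched null run
#' (`r_motion = r_stationary = r_stationary`) estimates the false-positive
#' rate under identical sampling. Both fractions carry exact binomial
#' (Clopper-Pearson) 95% confidence intervals.
#'
#' @param r_motion,r_stationary True per-bin firing probabilities in \[0, 1\].
#' @param n_bins Bins per trial and phase (default 2500 = 5 s / 2 ms).
#' @param n_trials Trials pooled per phase.
#' @param prior A [beta_prior()].
#' @param bf_threshold Strong-evidence threshold on the Bayes factor.
#' @param n_reps Simulation replicates (>= 100).
#' @param seed Integer seed.
#' @param method Posterior method (the closed-form route is fastest).
#' @return An object of class `power_analysis`: list with `power`,
#'   `power_ci`, `null_rate`, `null_ci`, and the settings.
#' @examples
#' power_analysis(0.10, 0.02, n_trials = 3, n_reps = 100, seed = 1)
#' @export
power_analysis <- function(r_motion, r_stationary, n_bins = 2500, n_trials = 3,
                           prior = beta_prior(), bf_threshold = 10,
                           n_reps = 1000, seed = 1L,
                           method = "closed_form_mix") {
  stopifnot(r_motion >= 0, r_motion <= 1, r_stationary >= 0, r_stationary <= 1)
  if (n_reps < 100) stop("n_reps must be >= 100")
  n <- n_bins * n_trials
  detect_fraction <- function(rm, rs, seed_use) {
    set.seed(seed_use)
    km <- stats::rbinom(n_reps, n, rm)
    ks <- stats::rbinom(n_reps, n, rs)
    hits <- vapply(seq_len(n_reps), function(i) {
      post <- hypothesis_posterior(
        list(k_motion = km[i], n_motion = n, k_stationary = ks[i], n_stationary = n),
        prior = prior, method = method)
      bayes_factor(post) >= bf_threshold
    }, logical(1))
    mean(hits)
  }
  seed <- as.integer(seed)
  power <- detect_fraction(r_motion, r_stationary, seed)
  null_rate <- detect_fraction(r_stationary, r_stationary, seed + 1L)
  ci <- function(p) as.numeric(stats::binom.test(round(p * n_reps), n_reps)$conf.int)
  structure(list(power = power, power_ci = ci(power),
                 null_rate = null_rate, null_ci = ci(null_rate),
                 r_motion = r_motion, r_stationary = r_stationary,
                 n_bins = n_bins, n_trials = n_trials, n_reps = n_reps,
                 bf_threshold = bf_threshold, prior = prior, seed = seed),
            class = "power_analysis")
}

#' @export
print.power_analysis <- function(x, ...) {
  cat(sprintf("Power analysis (BF >= %g), %d reps, %d x %d bins per phase\n",
              x$bf_threshold, x$n_reps, x$n_trials, x$n_bins))
  cat(sprintf("  effect  r_m = %.4f vs r_s = %.4f: detection %.3f [%.3f, %.3f]\n",
              x$r_motion, x$r_stationary, x$power, x$power_ci[1], x$power_ci[2]))
  cat(sprintf("  null    r_m = r_s = %.4f:        detection %.3f [%.3f, %.3f]\n",
              x$r_stationary, x$null_rate, x$null_ci[1], x$null_ci[2]))
  invisible(x)
}
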