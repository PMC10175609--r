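#' Beta prior for per-bin firing probabilities
#'
#' The firing probability of a neuron within a 2 ms bin is modelled as a
#' Bernoulli parameter with a Beta prior. The default `beta_prior(1, 1)` is
#' the uniform (least-informative) choice; informative priors can be supplied
#' when prior knowledge about baseline compass-neuron activity is available.
#'
#' @param alpha,beta Positive shape parameters.
#' @return An object of class `beta_prior`.
#' @examples
#' beta_prior()        # uniform
#' beta_prior(2, 50)   # informative: low firing probability expected
#' @export
beta_prior <- function(alpha = 1, beta = 1) {
  stopifnot(is.numeric(alpha), is.numeric(beta), length(alpha) == 1, length(beta) == 1)
  if (!is.finite(alpha) || !is.finite(beta) || alpha <= 0 || beta <= 0)
    stop("Beta prior shapes must be strictly positive and finite")
  structure(list(alpha = alpha, beta = beta), class = "beta_prior")
}

#' @export
print.beta_prior <- function(x, ...) {
  cat(sprintf("Beta(%g, %g) prior on per-bin firing probability\n", x$alpha, x$beta))
  invisible(x)
}

# ---------------------------------------------------------------------------
# P(X < Y) for independent X ~ Beta(a1, b1), Y ~ Beta(a2, b2).
#
# Three routes:
#   * "quadrature":      1-D cumulative-distribution decomposition,
#                        P(X < Y) = int F_X(y) f_Y(y) dy, adaptive quadrature.
#   * "closed_form_mix": finite-sum identity, exact (in log space) when the
#                        relevant shape is a positive integer; requires
#                        integer a2 (falls back to quadrature otherwise).
#   * "monte_carlo":     empirical frequency over random draws.
#
# To make the data-swap symmetry of the hypothesis posterior exact in floating
# point, callers evaluate the probability in a canonical argument order and
# complement as needed (see beta_order_prob).
# ---------------------------------------------------------------------------

# log P(X < Y) by adaptive quadrature of the CDF decomposition. The two
# tails are integrated separately (lower.tail toggles which), so that a tiny
# ordering probability retains full relative accuracy instead of being the
# complement of a number near one.
beta_ltail_quadrature <- function(a1, b1, a2, b2, lower = TRUE) {
  # far-tail pbeta values may underflow to -Inf on the log scale, with a
  # warning from the bpser series; that saturation is the intended behavior
  lintegrand <- function(y) suppressWarnings(
    pbeta(y, a1, b1, lower.tail = lower, log.p = TRUE) +
      dbeta(y, a2, b2, log = TRUE))
  # rescale by an approximate peak of the integrand so tiny tails neither
  # underflow nor overflow
  probe <- seq(1e-9, 1 - 1e-9, length.out = 513)
  lpeak <- max(lintegrand(probe))
  if (!is.finite(lpeak)) return(-Inf)
  f <- function(y) exp(lintegrand(y) - lpeak)
  v <- stats::integrate(f, 0, 1, rel.tol = 1e-12, abs.tol = 0,
                        subdivisions = 1000L, stop.on.error = FALSE)$value
  if (v <= 0) return(-Inf)
  min(log(v) + lpeak, 0)
}

# log P(Y > X) = log sum_{j=0}^{a2-1} B(a1+j, b1+b2) / [(b2+j) B(1+j, b2) B(a1, b1)]
# (finite-sum identity, valid for integer a2 >= 1); summed in log space.
beta_ltail_sum <- function(a1, b1, a2, b2) {
  j <- 0:(a2 - 1)
  lt <- lbeta(a1 + j, b2 + b1) - log(b2 + j) - lbeta(1 + j, b2) - lbeta(a1, b1)
  m <- max(lt)
  min(m + log(sum(exp(lt - m))), 0)
}

is_whole <- function(x, tol = 1e-8) abs(x - round(x)) < tol

# The pair (log P(X < Y), log P(X > Y)), each tail evaluated directly for
# full relative accuracy, in a canonical argument order: the probability is
# always computed with the lexicographically smaller (a, b) pair first, so
# swapping the two distributions returns the exact reversed floating-point
# pair (making the data-swap symmetry of the posterior exact).
beta_order_logprob <- function(a1, b1, a2, b2, method, mc_draws = 1e6) {
  if (a1 == a2 && b1 == b2)  # identically distributed: each ordering has mass 1/2
    return(c(lt = log(0.5), gt = log(0.5)))
  swap <- (a1 > a2) || (a1 == a2 && b1 > b2)
  if (swap) { tmp <- c(a1, b1); a1 <- a2; b1 <- b2; a2 <- tmp[1]; b2 <- tmp[2] }
  pair <- switch(method,
    quadrature = c(beta_ltail_quadrature(a1, b1, a2, b2, lower = TRUE),
                   beta_ltail_quadrature(a1, b1, a2, b2, lower = FALSE)),
    closed_form_mix = {
      # P(X < Y) sums over integer a2; P(X > Y) = P(Y < X) sums over integer a1
      lt <- if (is_whole(a2)) beta_ltail_sum(a1, b1, round(a2), b2)
            else beta_ltail_quadrature(a1, b1, a2, b2, lower = TRUE)
      gt <- if (is_whole(a1)) beta_ltail_sum(a2, b2, round(a1), b1)
            else beta_ltail_quadrature(a1, b1, a2, b2, lower = FALSE)
      c(lt, gt)
    },
    monte_carlo = {
      p <- mean(stats::rbeta(mc_draws, a1, b1) < stats::rbeta(mc_draws, a2, b2))
      log(c(p, 1 - p))
    },
    stop("unknown method '", method, "'"))
  if (swap) c(lt = pair[2], gt = pair[1]) else c(lt = pair[1], gt = pair[2])
}

# ---------------------------------------------------------------------------

#' Posterior over the three firing-rate hypotheses
#'
#' Compares the per-bin firing probability \eqn{r_m} during the motion phase
#' with \eqn{r_s} during the stationary phase under a Bernoulli observation
#' model. Three hypotheses are entertained: \eqn{H(r_m < r_s)},
#' \eqn{H(r_m = r_s)}, and \eqn{H(r_m > r_s)}, with a uniform hypothesis
#' prior. Under equality a single shared rate carries the Beta prior; under
#' each ordering the joint independent Beta prior is truncated to the ordered
#' region and renormalized by the prior mass of that region (1/2 for a
#' symmetric prior; computed exactly otherwise). Marginal likelihoods are
#' evaluated in log space and normalized into posterior probabilities.
#'
#' @param counts Pooled Bernoulli counts: a list or one-row data frame with
#'   elements `k_motion`, `n_motion`, `k_stationary`, `n_stationary`
#'   (spike-bin counts and total 2 ms bins per phase), e.g. the output of
#'   [pool_direction()].
#' @param prior A [beta_prior()]; shared by both rates.
#' @param method How the ordered-region probability of two independent Beta
#'   distributions is computed: `"quadrature"` (adaptive 1-D integration of
#'   the CDF decomposition), `"closed_form_mix"` (exact log-space finite sum,
#'   available for integer shapes), or `"monte_carlo"`.
#' @param mc_draws Number of draws for `method = "monte_carlo"`.
#' @return An object of class `hypothesis_posterior`: a named numeric vector
#'   `(p_less, p_equal, p_greater)` summing to one, with attributes
#'   `log_marginals` (log marginal likelihood of each hypothesis, including
#'   the binomial coefficients), `prior`, `method`, and `counts`.
#' @examples
#' cts <- list(k_motion = 125, n_motion = 2500, k_stationary = 50, n_stationary = 2500)
#' hypothesis_posterior(cts)
#' @seealso [bayes_factor()], [mss()], [dss()], [score_neurons()]
#' @export
hypothesis_posterior <- function(counts, prior = beta_prior(),
                                 method = c("quadrature", "closed_form_mix", "monte_carlo"),
                                 mc_draws = 1e6) {
  method <- match.arg(method)
  stopifnot(inherits(prior, "beta_prior"))
  km <- as.numeric(counts$k_motion);     nm <- as.numeric(counts$n_motion)
  ks <- as.numeric(counts$k_stationary); ns <- as.numeric(counts$n_stationary)
  if (any(is.na(c(km, nm, ks, ns)))) stop("counts must provide k_motion, n_motion, k_stationary, n_stationary")
  if (nm == 0 || ns == 0) stop("no data: zero bins in a phase")
  if (km < 0 || ks < 0 || km > nm || ks > ns) stop("counts must satisfy 0 <= k <= n in each phase")

  a <- prior$alpha; b <- prior$beta
  am <- a + km; bm <- b + nm - km      # posterior shapes, motion rate
  as_ <- a + ks; bs_ <- b + ns - ks    # posterior shapes, stationary rate
  lc <- lchoose(nm, km) + lchoose(ns, ks)

  # H(==): shared rate r ~ Beta(a, b) over the pooled counts
  lml_eq <- lc + lbeta(a + (km + ks), b + ((nm - km) + (ns - ks))) - lbeta(a, b)

  # ordered hypotheses: independent-posterior region mass over prior region
  # mass; the two per-phase terms are added smaller-first so the value is
  # bitwise invariant under exchanging the motion and stationary data
  phase_terms <- sort(c(lbeta(am, bm) - lbeta(a, b),
                        lbeta(as_, bs_) - lbeta(a, b)))
  lml_indep <- lc + phase_terms[1] + phase_terms[2]
  lp_post <- beta_order_logprob(am, bm, as_, bs_, method, mc_draws)
  lp_prior <- log(0.5)  # identical priors on both rates: region mass exactly 1/2
  lml_lt <- lml_indep + lp_post[["lt"]] - lp_prior
  lml_gt <- lml_indep + lp_post[["gt"]] - lp_prior

  lml <- c(less = lml_lt, equal = lml_eq, greater = lml_gt)
  z <- exp(lml - max(lml))
  post <- z / sum(sort(z))  # sorted sum: normalization invariant to label permutation
  structure(c(p_less = unname(post[1]), p_equal = unname(post[2]),
              p_greater = unname(post[3])),
            log_marginals = lml, prior = prior, method = method,
            counts = list(k_motion = km, n_motion = nm,
                          k_stationary = ks, n_stationary = ns),
            class = "hypothesis_posterior")
}

#' @export
print.hypothesis_posterior <- function(x, digits = 4, ...) {
  cts <- attr(x, "counts")
  cat("Posterior over firing-rate hypotheses (motion vs stationary)\n")
  cat(sprintf("  data: k/n = %d/%d (motion), %d/%d (stationary)\n",
              cts$k_motion, cts$n_motion, cts$k_stationary, cts$n_stationary))
  cat(sprintf("  P(r_m < r_s) = %.*f   P(r_m = r_s) = %.*f   P(r_m > r_s) = %.*f\n",
              digits, x[["p_less"]], digits, x[["p_equal"]], digits, x[["p_greater"]]))
  bf <- bayes_factor(x)
  cat(sprintf("  BF(unequal) = %s%s\n",
              if (is.infinite(bf)) "Inf" else format(bf, digits = digits),
              if (bf >= 10) "  [strong evidence]" else ""))
  invisible(x)
}

as_posterior_probs <- function(post) {
  if (inherits(post, "hypothesis_posterior")) return(unclass(post)[1:3])
  p <- as.numeric(post)
  if (length(p) != 3 || any(p < 0) || abs(sum(p) - 1) > 1e-6)
    stop("a hypothesis posterior must be three non-negative probabilities summing to 1")
  names(p) <- c("p_less", "p_equal", "p_greater")
  p
}

#' Bayes factor for unequal firing rates
#'
#' \eqn{BF_{\neq} = (P(H_<|D) + P(H_>|D)) / P(H_=|D)} under the uniform
#' hypothesis prior. Values of 10 or more are conventionally read as strong
#' evidence for a firing-rate difference between the motion and stationary
#' phases. Returns `Inf` when the equality hypothesis has zero posterior
#' mass; infinite values sort above any finite Bayes factor.
#'
#' @param post A `hypothesis_posterior` (or a vector of the three
#'   probabilities in the order less, equal, greater).
#' @return A single non-negative number, possibly `Inf`.
#' @examples
#' bayes_factor(c(1/3, 1/3, 1/3))  # 2
#' bayes_factor(c(0.95, 0.05, 0))  # 19
#' @export
bayes_factor <- function(post) {
  p <- as_posterior_probs(post)
  if (p[["p_equal"]] == 0) return(Inf)
  (p[["p_less"]] + p[["p_greater"]]) / p[["p_equal"]]
}

#' Motion sensitivity score (MSS)
#'
#' Posterior-weighted score assigning +1 to \eqn{H(r_m > r_s)}, 0 to
#' equality, and -1 to \eqn{H(r_m < r_s)}; i.e.
#' \eqn{MSS = P(H_>|D) - P(H_<|D) \in [-1, 1]}. Summed across neurons of one
#' class, the maximal attainable magnitude equals the number of neurons.
#'
#' @inheritParams bayes_factor
#' @return A number in \[-1, 1\].
#' @examples
#' mss(c(0.2, 0.5, 0.3))  # 0.1
#' @export
mss <- function(post) {
  p <- as_posterior_probs(post)
  p[["p_greater"]] - p[["p_less"]]
}

#' Absolute motion sensitivity score (AMSS) for a motion category
#'
#' For the two opposing directions A and B of one motion category,
#' \eqn{AMSS = 1 - P(H_=^A|D)\,P(H_=^B|D) \in [0, 1]}: close to one whenever
#' at least one direction of the category shifts the firing probability away
#' from its stationary value, regardless of sign.
#'
#' @param post_A,post_B Hypothesis posteriors for the two opposing directions.
#' @return A number in \[0, 1\].
#' @examples
#' amss(c(0.25, 0.5, 0.25), c(0.25, 0.5, 0.25))  # 0.75
#' @export
amss <- function(post_A, post_B) {
  pA <- as_posterior_probs(post_A); pB <- as_posterior_probs(post_B)
  1 - pA[["p_equal"]] * pB[["p_equal"]]
}

#' Direction selectivity score (DSS) for a motion category
#'
#' Posterior-weighted score that is +1 when the firing probability does not
#' decrease for direction A and decreases for B, or increases for A and does
#' not change for B; -1 in the mirrored cases; 0 otherwise. With
#' \eqn{P_X(\ge) = P(H_>^X) + P(H_=^X)}, the expectation is
#' \deqn{DSS = [P_A(\ge) P_<^B + P_>^A P_=^B] - [P_<^A P_B(\ge) + P_=^A P_>^B].}
#' The two events inside each bracket are disjoint. \eqn{|DSS| \le AMSS}
#' always holds.
#'
#' @inheritParams amss
#' @return A number in \[-1, 1\].
#' @examples
#' dss(c(0, 0, 1), c(1, 0, 0))  # +1: A excites, B inhibits
#' @export
dss <- function(post_A, post_B) {
  pA <- as_posterior_probs(post_A); pB <- as_posterior_probs(post_B)
  plus  <- (pA[["p_greater"]] + pA[["p_equal"]]) * pB[["p_less"]] +
           pA[["p_greater"]] * pB[["p_equal"]]
  minus <- pA[["p_less"]] * (pB[["p_greater"]] + pB[["p_equal"]]) +
           pA[["p_equal"]] * pB[["p_greater"]]
  plus - minus
}

#' Expected absolute direction selectivity score (ADSS)
#'
#' \eqn{ADSS = P_>^A P_<^B + P_<^A P_>^B \in [0, 1]}: the posterior
#' probability that the two opposing directions of a category drive the
#' firing probability in opposite directions, disregarding which one excites.
#'
#' @inheritParams amss
#' @return A number in \[0, 1\].
#' @examples
#' adss(c(0.5, 0, 0.5), c(0.5, 0, 0.5))  # 0.5
#' @export
adss <- function(post_A, post_B) {
  pA <- as_posterior_probs(post_A); pB <- as_posterior_probs(post_B)
  pA[["p_greater"]] * pB[["p_less"]] + pA[["p_less"]] * pB[["p_greater"]]
}
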