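---
title: "Methods: Bayesian motion-sensitivity scoring and the CL1a-CL2 compass network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian motion-sensitivity scoring and the CL1a-CL2 compass network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cxcompass)
```

This vignette documents the statistical model, the network model, and the
numerical and design choices behind `cxcompass`. The package serves two
connected analyses of the insect central-complex heading system: deciding,
per neuron and motion direction, whether visual self-motion stimulation
changes the firing rate (and in which direction), and modeling how the
CL1a/CL2 columnar circuit of the protocerebral bridge (PB) can maintain and
shift a head-direction activity bump.

## 1. The Bernoulli-Beta three-hypothesis model

### Observation model

Stimulation alternates a 5 s motion phase and a 5 s stationary phase;
within each phase, spikes are reduced to occupancy of 2 ms bins — a bin
either contains a spike or it does not. The 2 ms width matches the
approximate refractory period of these neurons, so bin occupancy is close
to a Bernoulli process and the per-phase data collapse to counts $(k, n)$:
$k$ occupied bins out of $n = 2500$ per 5 s phase, pooled over the trials
of one direction. The analysis unit is the pooled count, not per-trial
posteriors; per-trial firing-rate differences are reported descriptively
alongside (`report_trials.tsv` in the pipeline output).

### Hypotheses and priors

Let $r_m$ and $r_s$ be the per-bin firing probabilities in the motion and
stationary phase. Three hypotheses partition the possibilities:
$H_<: r_m < r_s$, $H_=: r_m = r_s$, $H_>: r_m > r_s$, with a uniform prior
over hypotheses. Under $H_=$ a single shared rate carries a
$\mathrm{Beta}(\alpha, \beta)$ prior, giving the closed-form marginal
likelihood
$$P(D \mid H_=) = \binom{n_m}{k_m}\binom{n_s}{k_s}
  \frac{B(\alpha + k_m + k_s,\; \beta + n_m - k_m + n_s - k_s)}{B(\alpha, \beta)}.$$
Under each ordered hypothesis the two rates carry independent
$\mathrm{Beta}(\alpha, \beta)$ priors truncated to the ordered region and
renormalized by the prior mass of that region. Because both rates share
one prior, that mass is exactly $1/2$ by symmetry — the package exposes a
single prior for both rates, so no numerical prior-mass integral is ever
needed. The ordered marginal likelihood reduces to the independent-Beta
marginal times the posterior ordering probability
$P(\theta_m < \theta_s)$ of two independent Beta posteriors, divided by
$1/2$.

The default prior is the uniform $\mathrm{Beta}(1, 1)$ — the
least-informative choice; an informative prior (for instance
$\mathrm{Beta}(2, 50)$, encoding the expectation of low baseline firing)
can be supplied everywhere a prior is accepted and is recorded in the
pipeline's provenance dump.

### Computing the ordering probability

Three interchangeable routes compute $P(X < Y)$ for independent
$X \sim \mathrm{Beta}(a_1, b_1)$, $Y \sim \mathrm{Beta}(a_2, b_2)$:

* `quadrature` (default): adaptive 1-D integration of the CDF
  decomposition $\int F_X(y) f_Y(y)\,dy$. Both tails are integrated
  *separately* (the upper tail via `lower.tail = FALSE`), so a tiny
  ordering probability keeps full relative accuracy instead of degrading
  as $1 - (1 - \epsilon)$; the integrand is rescaled by its probed peak so
  extreme tails neither underflow nor overflow.
* `closed_form_mix`: an exact log-space finite-sum identity, available
  when the relevant shape is a positive integer (always the case with an
  integer-shaped prior and count data). This is the fastest route and is
  used in the Monte-Carlo power analysis.
* `monte_carlo`: the empirical frequency over random Beta draws, used as
  a cross-method oracle in the tests.

Two floating-point details make the posterior exactly
permutation-symmetric, which the tests assert bitwise: the ordering
probability is always evaluated in a canonical argument order (so swapping
the motion and stationary counts returns the exact reversed pair), and
order-dependent sums are either commutative two-term sums or explicitly
sorted before adding. When the two posterior Betas are identical the
ordering probabilities are set to exactly $1/2$ each, which is the exact
analytical value for continuous i.i.d. variables.

### Scores

From the posterior $(P_<, P_=, P_>)$ per neuron and direction:

* $BF_{\neq} = (P_< + P_>) / P_=$, with $BF_{\neq} \ge 10$ flagged as
  strong evidence for a firing-rate change; $P_= = 0$ yields an explicit
  `Inf` that sorts above all finite values.
* $MSS = P_> - P_< \in [-1, 1]$, the posterior-weighted sensitivity score.
* Per category (translation, yaw, lift, roll) with opposing directions
  $A$ and $B$: $AMSS = 1 - P_=^A P_=^B$,
  $DSS = [P_A(\ge) P_<^B + P_>^A P_=^B] - [P_<^A P_B(\ge) + P_=^A P_>^B]$
  where $P_X(\ge) = P_>^X + P_=^X$, and $ADSS = P_>^A P_<^B + P_<^A P_>^B$.
  The two events in each $DSS$ bracket are disjoint, and
  $|DSS| \le AMSS$ holds for every posterior pair (property-tested over
  $10^4$ random posteriors).

Scores are summed within neuron classes, so each cell's maximal magnitude
is the number of neurons tested in it; directions a neuron was never
tested with produce absent cells, not zeros.

### Power analysis

`power_analysis()` simulates pooled binomial data at given true rates and
reports the fraction of replicates with $BF_{\neq} \ge 10$, plus a matched
null run ($r_m = r_s$) as a false-positive estimate, both with exact
Clopper-Pearson 95% intervals. With the default geometry (3 trials
$\times$ 2500 bins) detection is essentially certain for a 0.02 → 0.10
per-bin effect, around 5% for 0.020 → 0.025, and strong evidence under the
null is rare (well under 5%) — the $BF \ge 10$ convention is conservative.
The test suite asserts monotonicity in effect size and in trial count at
1000 replicates.

## 2. Spike detection and trial reduction

Spikes are detected on the median-filtered residual: a running median
(500 ms window, edge-replication padding) estimates the baseline, and a
manually chosen threshold is applied to the *baseline-subtracted* signal.
Whether the original threshold was meant for the raw or the subtracted
voltage is not decidable from the description we follow; subtraction was
chosen because it makes one threshold workable under slow drift and makes
detection exactly invariant to a constant offset (tested). Suprathreshold
runs contribute their maximal-deflection sample as the spike time, and
events closer than 2 ms merge into the larger one (refractory rule).

Trial tables alternate motion and stationary phases; the stationary
adaptation phase that precedes each stimulation series is discarded, and
repeated series of the same direction are pooled in chronological order as
one series. Bins are half-open $[t, t + 2\,\mathrm{ms})$ anchored at phase
onset, zero-based, so boundary spikes are never double-counted; 6 s phases
are truncated to their first 5 s, matching the 5 s analysis window used
throughout.

## 3. What the synthetic data emulate — and what they do not

The generators reproduce the *structure* of the recordings: 5 s phases in
alternation, 2-5 trials per direction, eight directions in four opposed
categories, class-labelled populations including a mirrored
direction-selective CL2 pair with opposite yaw polarity, and voltage
traces with biphasic spikes (1.5 ms, an invented but detectable shape) on
drifting, noisy baselines. Firing-probability magnitudes are not reported
for the original recordings, so defaults are a package choice within a
plausible range for these neurons: baseline 0.04 per 2 ms bin (≈ 20 Hz
equivalent bin occupancy), excited 0.10, suppressed 0.015 — all
configurable.

Bins are drawn as independent Bernoulli variables because that is exactly
the observation model of the statistical analysis; real spike trains carry
serial correlation (bursting, adaptation) that the generator does not
emulate. Passing recovery tests on these data therefore validates the
inference machinery under its own assumptions, not robustness to model
misspecification. Real recordings also contain electrode artifacts and
non-stationary baselines richer than a sinusoidal drift.

## 4. The CL1a-CL2 compass network

### Geometry and mask

Sixteen PB columns are labelled `L8 ... L1, R1 ... R8` (positions 1-16);
state components 1-16 are CL1a neurons, 17-32 CL2 neurons, by column.
Dynamics are linear, $x_{t+1} = M x_t$, with $x$ the deviation from
baseline firing — the circuit is linearized around its operating point.
The mask admits synapses only where the reported arborizations overlap:
CL1a → CL2 strictly within one PB column (identity pattern); same-type
connections to self and adjacent columns (positions 1 and 16 are *not*
adjacent: the PB is open, with no anatomical ring closure); CL2 → CL1a in
the CBL over a five-column reach, realized as half-width-2 bands around
the same-column diagonal and around the mirror-column diagonal. The exact
CBL column permutation is rendered only graphically in the anatomical
literature; the two-band rule abstracts it, the half-width is a parameter,
and a custom mask matrix can be supplied. The `noduli` variant adds every
same-hemisphere CL2 → CL2 pair, standing for putative coupling through the
lower nodulus units.

### Targets and maintenance

Bump targets are cosines with one full period across the PB (a single
360° azimuth representation), one target per column, CL2 duplicating
CL1a: $\hat x_c(j) = \cos(2\pi (j - c)/16)$. Maintenance optimizes the
masked weights by L-BFGS from the fixed sign template (+0.5 excitatory on
CL1a → CL2 and same-type synapses, −0.5 on CL2 → CL1a); signs are
unconstrained during optimization, and the consistent
excitatory/inhibitory structure of the solution — all CL1a → CL2 synapses
excitatory, ipsilateral CL2 → CL1a excitatory, contralateral net
inhibitory — is an emergent outcome the tests check.

The objective is the summed squared deviation over all 16 targets, two
time steps, and 32 components, plus $\lambda \times$ the *mean* squared
free weight ($\lambda = 0.15$ by default, the midpoint of the robust
0.1-0.2 range; the mean keeps $\lambda$'s meaning independent of how many
synapses a mask variant admits). An alternative normalization that
averages the data-fit term as well was evaluated and rejected: with the
fit term averaged, the penalty dominates the trade-off and the
fixed-point residuals settle near $3 \times 10^{-2}$ per component,
which defeats the purpose of a maintenance network; with the summed fit
they reach $\approx 3 \times 10^{-5}$, comfortably inside the package's
$10^{-3}$ acceptance tolerance (a package choice — no tolerance is
inherited from the physiology).

Because the cosine targets span only a two-dimensional subspace per
population, 64 scalar fixed-point constraints face ~250 free weights, so
near-exact maintenance is well-posed rather than surprising.

On robustness: the *objective value* necessarily tracks $\lambda$ (the
penalty term is proportional to it, and the residual fit term scales like
$\lambda^2$), so raw loss is the wrong invariant to inspect across the
robust range. What is stable is the result: between $\lambda = 0.1$ and
$\lambda = 0.2$ the optimized connectivity changes by under $10^{-4}$
relative Frobenius norm and maintenance quality is preserved at both
endpoints. The tests assert exactly that.

### Shifts and the feed-forward control

For turning, the package optimizes an additive masked modulation
$\Delta M$ (same mask — no new synapse sites; same penalty form) against
targets shifted by one column per time step in the direction opposing the
turn: a left turn shifts the bump toward higher position index
(L8 → R8 direction), a right turn the reverse. Shifted targets wrap
cyclically between `L8` and `R8` even though the mask has no direct
adjacency there; the optimized network realizes the wrap through its
internal structure, and one application of each modulated matrix moves
all 16 bumps by exactly one column, wrap included (32 checks per
variant). An additive modulation is the minimal reading of a "modulatory
input"; re-optimizing the full matrix per direction would subsume it and
was not needed. The right-turn modulation equals the left-turn modulation
with every 16×16 quadrant rotated by 180°, to within optimization
tolerance — a consequence of the mirror symmetry of mask and targets.

The negative control optimizes a constant input $u$ under
$x_{t+1} = M x_t + u$ against the same shifted targets. Since $M$ holds
each target nearly fixed, a single $u$ would have to equal
$\hat x_{c+1} - \hat x_c$ for all $c$ at once; by the symmetry of the
cosine targets these difference vectors sum to zero, making $u = 0$ the
exact stationary point of the convex objective. The optimized feed-forward
loss accordingly exceeds the modulatory loss by four to five orders of
magnitude — the feed-forward mechanism fails outright, and the package
reports the ratio rather than just the verdict.

### Simulation

`simulate()` walks a command sequence (`forward`, `turn_left`,
`turn_right`), applying $M$ or $M + \Delta M_{dir}$ per step. After each
step the state is rescaled to unit peak amplitude by default: the linear
fixed points are approximate after finite optimization, so amplitude can
drift slowly over long runs, while bump *position* — the model's readout —
is provably invariant to positive rescaling; the suite verifies identical
bump traces with renormalization on and off over 35 steps. The default
demonstration trajectory (5 forward, 8 right, 4 forward, 8 left, 5
forward) makes the bump traverse the `L8`/`R8` boundary in both
directions and return exactly to its starting column; block lengths are
configurable and representative rather than a replica of any particular
published run, whose segment timing is not stated.

CL1a and CL2 bump positions coincide at every step of these simulations,
reflecting the duplicated targets. Degenerate states (no unique maximum)
raise an error from `bump_position()`; exact ties break toward the lower
position and are flagged.

## 5. Problem sizes and reproducibility

All optimizations are deterministic (fixed initialization, no random
restarts; seed-controlled restarts can be layered on top by the user), so
every model quantity is bit-reproducible. Data generation and power
analysis consume explicit integer seeds, and both pipelines write their
full configuration to `config.json`, labelling each default as mirroring
a reported value versus a package choice. The shipped test suite and
acceptance script use: 16-column networks (both variants, both turn
directions), a 2000-point Gauss-Legendre-per-axis grid oracle on 22 count
fixtures, $10^6$-draw Monte-Carlo cross-checks, $10^4$ random posteriors
for score properties, and 1000-replicate power curves — sizes chosen so
the whole analysis reruns in a few minutes on one CPU while leaving the
statistical assertions comfortably powered.

## 6. Known limitations

* The network is linear and discrete-time: it switches between stable
  states without making transition dynamics explicit, has no velocity
  dependence (one column per step regardless of turn speed), and omits
  the other central-complex cell classes (CL1b-d, TB1/TB2, TN, TB7) that
  likely close the ring and stabilize the compass in the animal.
* The Bernoulli observation model ignores serial spike-train correlation;
  the Bayes factors are exact under the model, not assumption-free.
* The CBL projection scheme is abstracted to the two-band rule; users
  with a specific column permutation should supply their own mask.
* The equality hypothesis is a measure-zero slice handled as a shared
  single rate with the same Beta prior (the standard spike-and-slab
  treatment); alternative diffuse-null formulations would shift Bayes
  factors quantitatively.
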