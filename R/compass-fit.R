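#' Linear network dynamics: one time step
#'
#' Applies the linear update `x[t+1] = M x[t]`. The firing-rate neurons and
#' synapses are linearized around their operating point, so the update has
#' no nonlinearity; states are deviations from baseline firing.
#'
#' @param M A `compass_model`, `compass_shift` (its effective matrix is
#'   used), or a 32 x 32 numeric matrix.
#' @param x Numeric state vector matching the matrix dimension.
#' @return The next state vector.
#' @examples
#' compass_step(diag(32), rnorm(32))
#' @export
compass_step <- function(M, x) {
  W <- effective_matrix(M)
  if (length(x) != ncol(W)) stop("state dimension does not match the connectivity matrix")
  drop(W %*% x)
}

effective_matrix <- function(M) {
  if (inherits(M, "compass_model")) return(M$M)
  if (inherits(M, "compass_shift")) return(M$M_effective)
  as.matrix(M)
}

init_weights <- function(mask) {
  # uniform initialization: +0.5 for excitatory (CL1a -> CL2 and same-type),
  # -0.5 for inhibitory (CL2 -> CL1a)
  M <- matrix(0, 32, 32)
  M[1:16, 1:16][mask[1:16, 1:16]] <- 0.5
  M[17:32, 17:32][mask[17:32, 17:32]] <- 0.5
  M[17:32, 1:16][mask[17:32, 1:16]] <- 0.5
  M[1:16, 17:32][mask[1:16, 17:32]] <- -0.5
  M
}

# two-step tracking objective and gradient over the masked free weights.
# loss(par) = sum_c sum_{t in 1,2} || Me^t x_c - target_t,c ||^2
#             + lambda * mean(par^2)
# where Me = base + par placed at mask positions. X1 and X2 are the step-1
# and step-2 target matrices (equal to X0 for maintenance).
masked_lbfgs <- function(mask, base, X0, X1, X2, lambda,
                         par0, control = list()) {
  idx <- which(mask)
  nf <- length(idx)
  assemble <- function(par) { W <- base; W[idx] <- W[idx] + par; W }
  objective <- function(par) {
    W <- assemble(par)
    Y <- W %*% X0
    sum((Y - X1)^2) + sum((W %*% Y - X2)^2) + lambda * sum(par^2) / nf
  }
  gradient <- function(par) {
    W <- assemble(par)
    Y <- W %*% X0
    E1 <- Y - X1
    E2 <- W %*% Y - X2
    G <- 2 * (E1 %*% t(X0)) + 2 * (E2 %*% t(Y) + t(W) %*% (E2 %*% t(X0)))
    G[idx] + 2 * lambda * par / nf
  }
  ctrl <- utils::modifyList(list(maxit = 10000L, factr = 10, pgtol = 1e-14),
                            control)
  fit <- stats::optim(par0, objective, gradient, method = "L-BFGS-B",
                      control = ctrl)
  if (fit$convergence != 0)
    warning("L-BFGS did not report convergence (code ", fit$convergence,
            "): ", fit$message)
  W <- assemble(fit$par)
  Y <- W %*% X0
  list(W = W, par = fit$par, loss = fit$value,
       fit_sse = sum((Y - X1)^2) + sum((W %*% Y - X2)^2),
       penalty = lambda * sum(fit$par^2) / nf,
       convergence = fit$convergence, counts = fit$counts)
}

#' Fit the compass network for head-direction maintenance
#'
#' Optimizes the masked synaptic weights of the CL1a-CL2 network so that
#' every compass-bump target is (approximately) a fixed point of the linear
#' dynamics over two time steps: the loss is the summed squared deviation
#' \eqn{\sum_c \sum_{t \in \{1,2\}} \|M^t \hat x_c - \hat x_c\|^2} plus a
#' weak quadratic penalty `lambda` on the mean squared free weight, which
#' pushes non-essential synapses to zero without biasing the maintained
#' states appreciably. Optimization uses L-BFGS from the fixed sign-template
#' initialization (+0.5 on CL1a -> CL2 and same-type synapses, -0.5 on
#' CL2 -> CL1a); signs are free during optimization — the consistent
#' excitatory/inhibitory structure of the solution is an outcome, not a
#' constraint.
#'
#' @param variant Connectivity variant, `"default"` or `"noduli"` (the
#'   latter additionally allows same-hemisphere CL2 -> CL2 synapses).
#' @param lambda Regularization weight (robust range about 0.1-0.2).
#' @param mask Optional [build_mask()] override.
#' @param targets Optional [make_targets()] override.
#' @param control Options passed to `stats::optim` (`maxit`, `factr`,
#'   `pgtol`).
#' @return An object of class `compass_model`: list with the optimized
#'   weight matrix `M` (exactly zero off-mask), `mask`, `targets`,
#'   `variant`, `lambda`, final `loss` with its `fit_sse` and `penalty`
#'   parts, `max_residual` (largest one-step per-component deviation over
#'   all targets), `convergence`, and optimizer `counts`.
#' @examples
#' \donttest{
#' fit <- fit_compass()
#' fit$max_residual     # targets are fixed points to ~1e-5
#' coef(fit)[1:4, 1:4]
#' }
#' @seealso [fit_shift()], [fit_feedforward()], [simulate.compass_model()]
#' @export
fit_compass <- function(variant = c("default", "noduli"), lambda = 0.15,
                        mask = NULL, targets = NULL, control = list()) {
  variant <- match.arg(variant)
  if (is.null(mask)) mask <- build_mask(variant)
  if (is.null(targets)) targets <- make_targets()
  X <- unclass(targets)
  m <- unclass(mask)
  base <- matrix(0, 32, 32)
  fit <- masked_lbfgs(m, base, X0 = X, X1 = X, X2 = X, lambda = lambda,
                      par0 = init_weights(m)[which(m)], control = control)
  M <- fit$W
  dimnames(M) <- dimnames(m)
  structure(list(M = M, mask = mask, targets = targets, variant = variant,
                 lambda = lambda, loss = fit$loss, fit_sse = fit$fit_sse,
                 penalty = fit$penalty,
                 max_residual = max(abs(M %*% X - X)),
                 convergence = fit$convergence, counts = fit$counts),
            class = "compass_model")
}

#' @export
print.compass_model <- function(x, ...) {
  cat(sprintf("Compass network ('%s' variant): 16 CL1a + 16 CL2 neurons, %d free synapses\n",
              x$variant, sum(x$mask)))
  cat(sprintf("  maintenance loss %.4g (fit %.3g + penalty %.3g, lambda = %g)\n",
              x$loss, x$fit_sse, x$penalty, x$lambda))
  cat(sprintf("  max one-step fixed-point residual over 16 bump targets: %.3g\n",
              x$max_residual))
  invisible(x)
}

#' @export
coef.compass_model <- function(object, ...) object$M

#' @export
residuals.compass_model <- function(object, steps = 1, ...) {
  X <- unclass(object$targets)
  Y <- X
  for (i in seq_len(steps)) Y <- object$M %*% Y
  Y - X
}

#' @export
summary.compass_model <- function(object, ...) {
  M <- object$M
  quad <- function(rows, cols) M[rows, cols]
  s <- list(
    variant = object$variant, lambda = object$lambda, loss = object$loss,
    max_residual_1step = object$max_residual,
    max_residual_2step = max(abs(M %*% (M %*% unclass(object$targets)) -
                                   unclass(object$targets))),
    cl1a_to_cl2_min = min(quad(17:32, 1:16)[unclass(object$mask)[17:32, 1:16]]),
    cl2_to_cl1a_range = range(quad(1:16, 17:32)[unclass(object$mask)[1:16, 17:32]]),
    weight_rms = sqrt(mean(M[unclass(object$mask)]^2)))
  class(s) <- "summary.compass_model"
  s
}

#' @export
print.summary.compass_model <- function(x, ...) {
  cat(sprintf("Compass network summary ('%s' variant, lambda = %g)\n", x$variant, x$lambda))
  cat(sprintf("  loss %.4g; fixed-point residuals: %.3g (1 step), %.3g (2 steps)\n",
              x$loss, x$max_residual_1step, x$max_residual_2step))
  cat(sprintf("  CL1a->CL2 minimum weight %.3g (positive = all excitatory)\n",
              x$cl1a_to_cl2_min))
  cat(sprintf("  CL2->CL1a weight range [%.3g, %.3g]; free-weight RMS %.3g\n",
              x$cl2_to_cl1a_range[1], x$cl2_to_cl1a_range[2], x$weight_rms))
  invisible(x)
}

#' Plot a connectivity or modulation matrix
#'
#' Heatmap of the 32 x 32 weight matrix in the conventional orientation
#' (source neuron on the x axis, target neuron on the y axis, CL1a before
#' CL2, columns ordered L8 ... R8). Values are clipped at `clip` for
#' display; excitation plots yellow, inhibition blue.
#'
#' @param x A `compass_model` or `compass_shift` (plots `M` or the
#'   modulation `dM` respectively) or a numeric matrix.
#' @param clip Display clipping value (default 0.7).
#' @param main Plot title.
#' @param ... Ignored.
#' @return Invisibly, the clipped matrix.
#' @export
plot.compass_model <- function(x, clip = 0.7, main = NULL, ...) {
  plot_weight_matrix(effective_matrix(x), clip = clip,
                     main = main %||% sprintf("Optimized connectivity ('%s')", x$variant))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

plot_weight_matrix <- function(W, clip = 0.7, main = "") {
  Wc <- pmin(pmax(W, -clip), clip)
  pal <- grDevices::colorRampPalette(c("#2166ac", "#f7f7f7", "#ffd92f"))(101)
  graphics::image(1:32, 1:32, t(Wc[32:1, ]), zlim = c(-clip, clip), col = pal,
                  axes = FALSE, xlab = "presynaptic", ylab = "postsynaptic",
                  main = main)
  at <- c(1, 8, 16, 17, 24, 32)
  lab <- c("CL1a L8", "CL1a L1", "CL1a R8", "CL2 L8", "CL2 L1", "CL2 R8")[c(1, 2, 3, 4, 5, 6)]
  graphics::axis(1, at = at, labels = lab, cex.axis = 0.6, las = 2)
  graphics::axis(2, at = 33 - at, labels = lab, cex.axis = 0.6, las = 2)
  graphics::box()
  invisible(Wc)
}

#' Fit a turn-dependent connectivity modulation that shifts the bump
#'
#' Starting from a maintenance-optimized network, optimizes an additive
#' modulation `dM` of the masked weights so that the modulated dynamics
#' `(M + dM)` move every compass-bump target to the adjacent PB column in
#' each of two time steps — in the direction opposing the turn: during a
#' left turn the bump shifts right (toward higher position index), and
#' vice versa. The shifted targets wrap cyclically between `L8` and `R8`
#' even though the mask has no direct 1 <-> 16 adjacency; the network must
#' realize the wrap through its internal structure. The modulation uses the
#' same anatomical mask (no new synapse sites) and the same quadratic
#' penalty form as maintenance.
#'
#' @param model A [fit_compass()] result.
#' @param direction Turn direction, `"left"` or `"right"`.
#' @param lambda_mod Penalty weight on the modulation (defaults to the
#'   model's `lambda`).
#' @param control Optimizer options, as in [fit_compass()].
#' @return An object of class `compass_shift`: list with the modulation
#'   `dM`, the effective matrix `M_effective = M + dM`, `direction`,
#'   `loss`, `fit_sse`, `penalty`, `variant`, and convergence info.
#' @examples
#' \donttest{
#' fit <- fit_compass()
#' sh <- fit_shift(fit, "left")
#' bump_position(compass_step(sh, fit$targets[, 9]))  # R1 -> R2
#' }
#' @export
fit_shift <- function(model, direction = c("left", "right"),
                      lambda_mod = model$lambda, control = list()) {
  stopifnot(inherits(model, "compass_model"))
  direction <- match.arg(direction)
  X <- unclass(model$targets)
  n_col <- ncol(X)
  s1 <- vapply(seq_len(n_col), shift_column, integer(1),
               direction = direction, n_columns = n_col)
  X1 <- X[, s1]
  X2 <- X1[, s1]
  m <- unclass(model$mask)
  fit <- masked_lbfgs(m, base = model$M, X0 = X, X1 = X1, X2 = X2,
                      lambda = lambda_mod, par0 = rep(0, sum(m)),
                      control = control)
  dM <- fit$W - model$M
  dimnames(dM) <- dimnames(model$M)
  structure(list(dM = dM, M_effective = fit$W, direction = direction,
                 loss = fit$loss, fit_sse = fit$fit_sse, penalty = fit$penalty,
                 lambda_mod = lambda_mod, variant = model$variant,
                 convergence = fit$convergence, counts = fit$counts),
            class = "compass_shift")
}

#' @export
print.compass_shift <- function(x, ...) {
  cat(sprintf("Connectivity modulation for %s turns ('%s' variant)\n",
              x$direction, x$variant))
  cat(sprintf("  shift loss %.4g (fit %.3g + penalty %.3g)\n",
              x$loss, x$fit_sse, x$penalty))
  invisible(x)
}

#' @export
plot.compass_shift <- function(x, clip = 0.7, main = NULL, what = c("dM", "effective"), ...) {
  what <- match.arg(what)
  W <- if (what == "dM") x$dM else x$M_effective
  plot_weight_matrix(W, clip = clip,
                     main = main %||% sprintf("%s modulation, %s turn",
                                              if (what == "dM") "Connectivity" else "Effective",
                                              x$direction))
}

#' Feed-forward control: constant input cannot shift the bump
#'
#' Optimizes a constant 32-component input vector `u` under the dynamics
#' `x[t+1] = M x[t] + u` against the same shifted targets used by
#' [fit_shift()]. Because the maintenance-optimized `M` holds every bump
#' target (approximately) fixed, a single constant input would have to
#' equal `x_{c+1} - x_c` for every column `c` simultaneously, which is
#' impossible; its optimized loss therefore stays far above the modulatory
#' loss — the purely feed-forward mechanism fails as a bump-shifting
#' mechanism, and this fit quantifies by how much.
#'
#' @inheritParams fit_shift
#' @param lambda_mod Penalty weight on the mean squared input component.
#' @return An object of class `compass_feedforward`: list with the input
#'   `u`, `direction`, `loss`, `fit_sse`, `penalty`, and for reference the
#'   loss of `u = 0` (`loss_zero_input`, the maintenance matrix scored
#'   against the shifted targets).
#' @examples
#' \donttest{
#' fit <- fit_compass()
#' ff <- fit_feedforward(fit, "left")
#' sh <- fit_shift(fit, "left")
#' ff$loss / sh$loss  # substantially > 1
#' }
#' @export
fit_feedforward <- function(model, direction = c("left", "right"),
                            lambda_mod = model$lambda, control = list()) {
  stopifnot(inherits(model, "compass_model"))
  direction <- match.arg(direction)
  X <- unclass(model$targets)
  n_col <- ncol(X)
  s1 <- vapply(seq_len(n_col), shift_column, integer(1),
               direction = direction, n_columns = n_col)
  X1 <- X[, s1]; X2 <- X1[, s1]
  M <- model$M
  loss_of <- function(u) {
    U <- matrix(u, nrow = 32, ncol = n_col)
    Y1 <- M %*% X + U
    Y2 <- M %*% Y1 + U
    sum((Y1 - X1)^2) + sum((Y2 - X2)^2)
  }
  objective <- function(u) loss_of(u) + lambda_mod * sum(u^2) / 32
  gradient <- function(u) {
    U <- matrix(u, nrow = 32, ncol = n_col)
    Y1 <- M %*% X + U
    E1 <- Y1 - X1
    E2 <- M %*% Y1 + U - X2
    drop(2 * rowSums(E1) + 2 * rowSums(E2 + t(M) %*% E2)) + 2 * lambda_mod * u / 32
  }
  ctrl <- utils::modifyList(list(maxit = 10000L, factr = 10, pgtol = 1e-14),
                            control)
  fit <- stats::optim(rep(0, 32), objective, gradient, method = "L-BFGS-B",
                      control = ctrl)
  structure(list(u = fit$par, direction = direction, loss = fit$value,
                 fit_sse = loss_of(fit$par),
                 penalty = lambda_mod * sum(fit$par^2) / 32,
                 loss_zero_input = loss_of(rep(0, 32)),
                 lambda_mod = lambda_mod, variant = model$variant,
                 convergence = fit$convergence),
            class = "compass_feedforward")
}

#' @export
print.compass_feedforward <- function(x, ...) {
  cat(sprintf("Feed-forward control for %s turns ('%s' variant)\n",
              x$direction, x$variant))
  cat(sprintf("  optimized input loss %.4g (zero-input baseline %.4g)\n",
              x$loss, x$loss_zero_input))
  invisible(x)
}
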