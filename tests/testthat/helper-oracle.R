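# Brute-force 2-D grid oracle for the three-hypothesis marginal likelihoods.
#
# The ordered-region integral over {r_x < r_y} is evaluated on a tensor
# Gauss-Legendre grid after substituting r_x = u * r_y (Jacobian r_y), which
# maps the triangular region onto the unit square so the product rule
# converges. This route never uses the CDF decomposition or the finite-sum
# identity employed by the package, so it is an independent check.

grid_region_lml <- function(kx, nx, ky, ny, alpha = 1, beta = 1, G = 1000) {
  gl <- pracma::gaussLegendre(G, 0, 1)
  lf <- outer(gl$x, gl$x, function(U, V)
    dbinom(kx, nx, U * V, log = TRUE) + dbeta(U * V, alpha, beta, log = TRUE) +
      dbinom(ky, ny, V, log = TRUE) + dbeta(V, alpha, beta, log = TRUE) + log(V))
  lw <- outer(log(gl$w), log(gl$w), "+")
  m <- max(lf)
  log(sum(exp(lf + lw - m))) + m
}

grid_posterior <- function(km, nm, ks, ns, alpha = 1, beta = 1, G = 1000) {
  lml <- c(
    less    = grid_region_lml(km, nm, ks, ns, alpha, beta, G) + log(2),
    equal   = lchoose(nm, km) + lchoose(ns, ks) +
      lbeta(alpha + km + ks, beta + (nm - km) + (ns - ks)) - lbeta(alpha, beta),
    greater = grid_region_lml(ks, ns, km, nm, alpha, beta, G) + log(2))
  z <- exp(lml - max(lml))
  list(lml = lml, post = z / sum(z))
}

# fixtures spanning strong, weak, null, sparse, and asymmetric-n regimes
oracle_fixtures <- function() {
  list(
    c(125, 2500,  50, 2500), c( 50, 2500, 125, 2500), c( 80, 2500,  85, 2500),
    c( 85, 2500,  80, 2500), c(100, 2500, 100, 2500), c(  0, 2500,   0, 2500),
    c(  0, 2500,   5, 2500), c(  5, 2500,   0, 2500), c(  1, 2500,   1, 2500),
    c(250, 5000, 180, 5000), c( 30, 7500,  60, 7500), c( 10,  500,  15,  500),
    c( 15,  500,  10,  500), c(  3,  100,  10,  100), c( 12,  200,  12,  200),
    c(400, 5000, 420, 5000), c( 60, 2500,  61, 2500), c(200, 2500,  40, 2500),
    c(  7, 1000,  70, 1000), c( 55, 2500,  45, 5000), c( 45, 5000,  55, 2500),
    c(150, 2500, 150, 2500))
}

as_counts <- function(f) list(k_motion = f[1], n_motion = f[2],
                              k_stationary = f[3], n_stationary = f[4])

# random valid hypothesis posteriors (uniform on the simplex)
random_posteriors <- function(n, seed = 1) {
  set.seed(seed)
  g <- matrix(stats::rexp(3 * n), ncol = 3)
  g / rowSums(g)
}
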