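test_that("the anatomical mask encodes the reported arborization rules", {
  m <- build_mask()
  # CL1a -> CL2 in the PB: strictly one column, the identity pattern
  expect_equal(unname(m[17:32, 1:16]), diag(16) == 1)
  # same-type recurrence: self plus adjacent columns, PB open (no 1<->16 wrap)
  expect_true(m["CL1a_L8", "CL1a_L7"] && m["CL1a_L8", "CL1a_L8"])
  expect_false(m["CL1a_L8", "CL1a_R8"])
  expect_false(m["CL2_L8", "CL2_R8"])
  # CL2 at L1 (position 8) reaches CL1a columns within +-2 of L1 and of R1
  reached <- which(m[1:16, 16 + 8])
  expect_equal(unname(reached), 6:11)
  # noduli variant: all same-hemisphere CL2 pairs, and only those, are added
  mn <- build_mask("noduli")
  expect_true(mn["CL2_L7", "CL2_L3"])
  expect_false(mn["CL2_R7", "CL2_L3"])
  expect_true(all(mn[1:16, ] == m[1:16, ]))  # CL1a rows unchanged
  added <- unclass(mn) & !unclass(m)
  expect_true(all(which(added, arr.ind = TRUE) > 16))
})

test_that("bump targets are duplicated cosines with one maximum per column", {
  X <- make_targets()
  expect_equal(dim(X), c(32, 16))
  for (cc in 1:16) {
    expect_equal(unname(which.max(X[1:16, cc])), cc)
    expect_equal(unname(X[1:16, cc]), unname(X[17:32, cc]))     # CL1a and CL2 targets equal
    expect_equal(sum(X[1:16, cc]), 0)           # full-period cosine
  }
  expect_equal(unname(which.max(make_targets()[1:16, 1])), 1)  # bump at L8
  expect_error(make_targets(3), ">= 4")
})

test_that("the linear step is a plain masked matrix-vector product", {
  x <- rnorm(32)
  expect_equal(compass_step(diag(32), x), x)
  expect_equal(compass_step(diag(32), rep(0, 32)), rep(0, 32))
  M <- matrix(rnorm(32 * 32), 32)
  expect_equal(compass_step(M, 3 * x), 3 * compass_step(M, x))
  expect_error(compass_step(M, rnorm(5)), "dimension")
})

test_that("maintenance optimization renders every target a two-step fixed point", {
  for (variant in c("default", "noduli")) {
    fit <- cached_model(variant)
    X <- unclass(fit$targets)
    expect_lt(max(abs(fit$M %*% X - X)), 1e-3)
    expect_lt(max(abs(fit$M %*% (fit$M %*% X) - X)), 2e-3)
    # mask closure: off-mask entries are exactly zero
    expect_true(all(fit$M[!unclass(fit$mask)] == 0))
  }
})

test_that("the optimized sign structure matches the reported polarity pattern", {
  fit <- cached_model("default")
  M <- fit$M
  mask <- unclass(fit$mask)
  # all CL1a -> CL2 synapses in the PB emerge excitatory
  expect_true(all(M[17:32, 1:16][mask[17:32, 1:16]] > 0))
  # CL2 -> CL1a: same-hemisphere (main-diagonal band) excitatory ...
  main_band <- outer(1:16, 1:16, function(i, j) abs(i - j) <= 2)
  anti_band <- outer(1:16, 1:16, function(i, j) abs(i - (17 - j)) <= 2)
  B <- M[1:16, 17:32]
  expect_true(all(B[main_band & mask[1:16, 17:32] & !anti_band] > 0))
  # ... and the contralateral (anti-diagonal) band net inhibitory
  expect_lt(sum(B[anti_band & mask[1:16, 17:32] & !main_band]), 0)
  # self-recurrence of CL1a neurons is excitatory
  expect_true(all(diag(M[1:16, 1:16]) > 0))
})

test_that("bump position reads the argmax with tie and degeneracy handling", {
  one_hot <- rep(0, 32); one_hot[5] <- 1; one_hot[21] <- 1
  expect_equal(as.integer(bump_position(one_hot)), 5L)
  expect_equal(names(bump_position(one_hot)), "L4")
  expect_equal(names(bump_position(one_hot, "CL2")), "L4")
  X <- make_targets()
  for (cc in c(1, 8, 16))
    expect_equal(as.integer(bump_position(X[, cc])), cc)
  expect_equal(bump_position(2 * X[, 3]), bump_position(X[, 3]))  # scale invariant
  expect_error(bump_position(rep(1, 32)), "degenerate")
  tie <- rep(0, 32); tie[c(4, 9)] <- 1
  expect_equal(as.integer(bump_position(tie)), 4L)   # broken toward lower index
  expect_true(attr(bump_position(tie), "degenerate"))
})

test_that("the optimized connectivity is robust across the regularization range", {
  fit_lo <- cached_model("default", lambda = 0.1)
  fit_hi <- cached_model("default", lambda = 0.2)
  X <- unclass(fit_lo$targets)
  expect_lt(max(abs(fit_lo$M %*% X - X)), 1e-3)
  expect_lt(max(abs(fit_hi$M %*% X - X)), 1e-3)
  rel_change <- norm(fit_hi$M - fit_lo$M, "F") / norm(fit_lo$M, "F")
  expect_lt(rel_change, 0.10)
})
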