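test_that("essential bases diagonalise the fluctuation covariance", {
  # static ensemble: all eigenvalues 0
  ref <- matrix(rnorm(30), 10)
  co <- array(NA_real_, c(4, 10, 3))
  for (f in 1:4) co[f, , ] <- ref
  e <- makeEnsemble(caTraceTopology(10), co)
  b <- essentialBasis(e, N = 5)
  expect_lt(max(b@values), 1e-20)

  # eigenvalue sum equals the total superposed variance
  eg <- genFluctuationEnsemble(ref, 0.03, 500, seed = 71,
                               topology = caTraceTopology(10))
  bg <- essentialBasis(eg, N = 30)
  # fit = TRUE default: recompute the superposed coordinates directly
  ms <- meanStructure(eg, 1:10)$mean
  Xs <- t(vapply(1:500, function(f) {
    fit <- kabsch(coords(eg)[f, , ], ms)
    as.vector(t(pepdyn:::.applyFit(coords(eg)[f, , ], fit)))
  }, numeric(30)))
  expect_equal(sum(bg@values), sum(diag(cov(Xs))), tolerance = 1e-10)

  expect_error(essentialBasis(eg, N = 31), "exceeds")
})

test_that("RMSIP obeys its algebraic identities", {
  set.seed(72)
  Q <- qr.Q(qr(matrix(rnorm(100 * 10), 100)))
  expect_equal(rmsip(Q, Q), 1, tolerance = 1e-12)

  A <- diag(12)[, 1:5]; B <- diag(12)[, 6:10]
  expect_equal(rmsip(A, B), 0)

  # invariant under a common orthogonal rotation
  R <- qr.Q(qr(matrix(rnorm(100 * 100), 100)))
  B2 <- qr.Q(qr(matrix(rnorm(100 * 10), 100)))
  expect_equal(rmsip(Q, B2), rmsip(R %*% Q, R %*% B2), tolerance = 1e-10)

  # bounded in [0, 1] for orthonormal inputs
  for (i in 1:20) {
    X <- qr.Q(qr(matrix(rnorm(40 * 6), 40)))
    Y <- qr.Q(qr(matrix(rnorm(40 * 6), 40)))
    v <- rmsip(X, Y)
    expect_gte(v, -1e-9); expect_lte(v, 1 + 1e-9)
  }
  expect_error(rmsip(Q, A), "dimensions differ")
})

test_that("random essential subspaces overlap at the sqrt(N/d) level", {
  set.seed(73)
  draws <- vapply(1:200, function(i) {
    A <- qr.Q(qr(matrix(rnorm(100 * 10), 100)))
    B <- qr.Q(qr(matrix(rnorm(100 * 10), 100)))
    rmsip(A, B)
  }, numeric(1))
  se <- sd(draws) / sqrt(200)
  expect_lt(abs(mean(draws) - sqrt(10 / 100)), 3 * se + 1e-3)
})

test_that("nRMSIP normalisation recovers stationary sampling", {
  ref <- matrix(rnorm(30), 10)
  L <- matrix(0, 30, 3)
  L[cbind(c(2, 15, 28), 1:3)] <- c(0.1, 0.08, 0.06)
  eA <- genFluctuationEnsemble(ref, L, 4000, seed = 74,
                               topology = caTraceTopology(10))
  v <- nrmsip(eA, eA, N = 3, fit = FALSE)
  expect_equal(v$nrmsip, 1, tolerance = 0.05)
  expect_equal(v$selfA, v$selfB)

  # deterministic orthogonal subspaces with perfect halves: nRMSIP 0
  co <- array(0, c(8, 4, 3))
  co[, 1, 1] <- rep(c(-1, 1), 4)               # only atom 1 x moves in A
  co2 <- array(0, c(8, 4, 3))
  co2[, 2, 2] <- rep(c(-1, 1), 4)              # only atom 2 y moves in B
  topo <- caTraceTopology(4)
  vAB <- nrmsip(makeEnsemble(topo, co), makeEnsemble(topo, co2),
                N = 1, fit = FALSE)
  expect_equal(vAB$nrmsip, 0)
  expect_equal(vAB$selfA, 1)
})

test_that("overlap matrices are symmetric with unit diagonal", {
  ref <- matrix(rnorm(30), 10)
  L <- matrix(0, 30, 2); L[1, 1] <- 0.08; L[17, 2] <- 0.05
  e1 <- genFluctuationEnsemble(ref, L, 400, seed = 75,
                               topology = caTraceTopology(10))
  e2 <- genFluctuationEnsemble(ref, L, 400, seed = 76,
                               topology = caTraceTopology(10))
  # the two short ensembles share their modes almost exactly, so the
  # cross-overlap can exceed the halves' self-consistency: the value above
  # 1 is flagged with a warning but reported unclipped
  expect_warning(om <- overlapMatrix(list(a = e1, b = e2), N = 2,
                                     fit = FALSE), "above 1")
  expect_equal(om$rmsip, t(om$rmsip), tolerance = 1e-12)
  expect_equal(diag(om$rmsip), c(a = 1, b = 1))
  expect_gt(om$nrmsip["a", "b"], 1)
  # entries equal pairwise calls
  b1 <- essentialBasis(e1, N = 2, fit = FALSE)
  b2 <- essentialBasis(e2, N = 2, fit = FALSE)
  expect_equal(om$rmsip["a", "b"], rmsip(b1, b2, 2))
  expect_equal(om$nrmsip["a", "b"],
               suppressWarnings(nrmsip(e1, e2, N = 2,
                                       fit = FALSE)$nrmsip))
  # two identical ensembles: off-diagonal overlap 1
  om2 <- overlapMatrix(list(e1, e1), N = 2, normalized = FALSE,
                       fit = FALSE)
  expect_equal(om2$rmsip[1, 2], 1, tolerance = 1e-12)
})

test_that("overlap classes split at the documented boundaries", {
  expect_equal(classifyOverlap(0.70), "[0.65, 0.75)")
  expect_equal(classifyOverlap(0.95), "[0.95, Inf)")
  expect_equal(classifyOverlap(0.649999), "below 0.65")
  expect_equal(classifyOverlap(c(0.65, 0.75, 0.85, 0.9999)),
               c("[0.65, 0.75)", "[0.75, 0.85)", "[0.85, 0.95)",
                 "[0.95, Inf)"))
  expect_error(classifyOverlap(-0.1))
})

test_that("shared versus orthogonal fluctuation spaces are separable", {
  ref <- matrix(rnorm(30), 10)
  L <- matrix(0, 30, 3)
  L[cbind(c(3, 12, 27), 1:3)] <- c(0.1, 0.08, 0.06)
  e1 <- genFluctuationEnsemble(ref, L, 4000, seed = 77,
                               topology = caTraceTopology(10))
  e2 <- genFluctuationEnsemble(ref, L, 4000, seed = 78,
                               topology = caTraceTopology(10))
  expect_gte(nrmsip(e1, e2, N = 3, fit = FALSE)$nrmsip, 0.95)

  Lo <- matrix(0, 30, 3)
  Lo[cbind(c(5, 19, 23), 1:3)] <- c(0.1, 0.08, 0.06)
  e3 <- genFluctuationEnsemble(ref, Lo, 4000, seed = 79,
                               topology = caTraceTopology(10))
  b1 <- essentialBasis(e1, N = 3, fit = FALSE)
  b3 <- essentialBasis(e3, N = 3, fit = FALSE)
  expect_lte(rmsip(b1, b3, 3), 0.2)
})
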