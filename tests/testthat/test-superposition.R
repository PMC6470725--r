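test_that("Kabsch fits remove rigid motions exactly", {
  set.seed(21)
  P <- matrix(rnorm(30), 10)
  k <- kabsch(P, P)
  expect_equal(k$rmsd, 0, tolerance = 1e-12)
  expect_equal(k$rotation, diag(3), tolerance = 1e-10)

  th <- 0.8
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Q <- P %*% Rz + matrix(c(1, -2, 3), 10, 3, byrow = TRUE)
  k2 <- kabsch(P, Q)
  expect_lt(k2$rmsd, 1e-10)
  expect_equal(crossprod(k2$rotation), diag(3), tolerance = 1e-10)
  expect_equal(det(k2$rotation), 1, tolerance = 1e-10)

  expect_error(kabsch(P[1:2, ], Q[1:2, ]), "3 points")
  coll <- cbind(1:5, 2 * (1:5), -1:3 * 0)
  expect_error(kabsch(coll, coll + 1), "collinear")
})

test_that("Kabsch RMSD matches an independent rotational search", {
  set.seed(22)
  P <- matrix(rnorm(30), 10)
  Q <- P
  Q[4, ] <- Q[4, ] + c(0.3, 0, 0)
  mine <- kabsch(P, Q)$rmsd

  # oracle: minimise RMSD over Euler angles by grid + Nelder-Mead refine
  rotmat <- function(a) {
    cx <- cos(a[1]); sx <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
    cz <- cos(a[3]); sz <- sin(a[3])
    Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
    Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    Rz %*% Ry %*% Rx
  }
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  f <- function(a) sqrt(mean(rowSums((Pc %*% rotmat(a) - Qc)^2)))
  grid <- as.matrix(expand.grid(a1 = seq(-pi, pi, length.out = 7),
                                a2 = seq(-pi / 2, pi / 2, length.out = 5),
                                a3 = seq(-pi, pi, length.out = 7)))
  vals <- apply(grid, 1, f)
  best <- stats::optim(grid[which.min(vals), ], f)$value
  expect_equal(mine, best, tolerance = 1e-5)

  # also agrees with the field-standard fitting routine (which reports
  # 3 decimals)
  expect_equal(mine,
               bio3d::rmsd(as.vector(t(P)), as.vector(t(Q)), fit = TRUE),
               tolerance = 0.01)
})

test_that("RMSD is symmetric and invariant to rigid motion of either input", {
  set.seed(23)
  for (i in 1:5) {
    P <- matrix(rnorm(24), 8)
    Q <- P + 0.1 * matrix(rnorm(24), 8)
    expect_equal(kabsch(P, Q)$rmsd, kabsch(Q, P)$rmsd, tolerance = 1e-12)
    th <- runif(1, 0, 2 * pi)
    Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
    expect_equal(kabsch(P %*% Rz + 5, Q)$rmsd, kabsch(P, Q)$rmsd,
                 tolerance = 1e-10)
    expect_equal(kabsch(P, Q %*% Rz - 2)$rmsd, kabsch(P, Q)$rmsd,
                 tolerance = 1e-10)
  }
})

test_that("rmsdSeries reports per-frame values with mean and SD", {
  ref <- matrix(rnorm(30), 10)
  co <- array(NA_real_, c(4, 10, 3))
  for (f in 1:4) co[f, , ] <- ref
  e <- makeEnsemble(caTraceTopology(10), co)
  r <- rmsdSeries(e, ref)
  expect_equal(r$rmsd, rep(0, 4), tolerance = 1e-10)

  # two-frame ensemble with a known displacement pattern: already centred
  # and rotationally aligned, so the RMSD has a closed form
  delta <- matrix(0, 10, 3)
  delta[, 1] <- c(rep(0.1, 5), rep(-0.1, 5))     # zero net translation
  co2 <- array(NA_real_, c(2, 10, 3))
  co2[1, , ] <- ref
  co2[2, , ] <- ref + delta
  e2 <- makeEnsemble(caTraceTopology(10), co2)
  r2 <- rmsdSeries(e2, ref)
  expect_equal(r2$rmsd[1], 0, tolerance = 1e-10)
  # optimal rotation can only lower it below the raw 0.1; bio3d agrees
  oracle <- bio3d::rmsd(as.vector(t(ref)), as.vector(t(ref + delta)),
                        fit = TRUE)
  expect_equal(r2$rmsd[2], oracle, tolerance = 0.01)
  expect_equal(r2$mean, mean(r2$rmsd))
  expect_error(rmsdSeries(e2, ref[1:4, ]), "selection mismatch")
})

test_that("the iterative mean structure is a fixed point", {
  ref <- matrix(rnorm(24), 8)
  co <- array(NA_real_, c(3, 8, 3))
  for (f in 1:3) co[f, , ] <- ref
  e <- makeEnsemble(caTraceTopology(8), co)
  m <- meanStructure(e, selection = 1:8)
  expect_true(m$converged)
  expect_equal(m$iterations, 1)
  expect_equal(m$mean, ref, tolerance = 1e-12, ignore_attr = TRUE)

  # symmetric two-frame ensemble about the reference; the fitted mean
  # matches the reference up to second order in the perturbation
  set.seed(31)
  delta <- 0.005 * matrix(rnorm(24), 8)
  co2 <- array(NA_real_, c(2, 8, 3))
  co2[1, , ] <- ref + delta
  co2[2, , ] <- ref - delta
  e2 <- makeEnsemble(caTraceTopology(8), co2)
  m2 <- meanStructure(e2, selection = 1:8)
  expect_lt(kabsch(m2$mean, ref)$rmsd, 1e-4)

  # Gaussian ensemble: sample mean near the generator reference
  eg <- genFluctuationEnsemble(ref, 0.02, 4000, seed = 32,
                               topology = caTraceTopology(8))
  mg <- meanStructure(eg, selection = 1:8)
  se <- 0.02 / sqrt(4000)
  expect_lt(kabsch(mg$mean, ref)$rmsd, 3 * se * sqrt(3))
})

test_that("RMSF recovers isotropic fluctuation magnitudes and rankings", {
  ref <- matrix(rnorm(60), 20)
  co <- array(NA_real_, c(3, 20, 3))
  for (f in 1:3) co[f, , ] <- ref
  expect_equal(unname(rmsf(makeEnsemble(caTraceTopology(20), co))),
               rep(0, 20), tolerance = 1e-10)

  # isotropic sigma = 0.05 nm: RMSF -> sigma * sqrt(3) (0.0866 nm); 100
  # atoms keep the rigid-body-fit variance loss below the 2% band
  nAt <- 100
  ref2 <- matrix(rnorm(3 * nAt), nAt)
  e <- genFluctuationEnsemble(ref2, 0.05, 10000, seed = 33,
                              topology = caTraceTopology(nAt))
  f <- rmsf(e, reference = "self")
  expect_equal(mean(f), 0.05 * sqrt(3), tolerance = 0.02)

  # a flexible segment must rank above the rest
  sds <- rep(0.02, 3 * 12); sds[(3 * 7 + 1):(3 * 9)] <- 0.1  # atoms 8-9
  e2 <- genFluctuationEnsemble(matrix(rnorm(36), 12), sds, 4000, seed = 34,
                               topology = caTraceTopology(12))
  f2 <- unname(rmsf(e2))
  expect_equal(sort(order(f2, decreasing = TRUE)[1:2]), c(8, 9))
})
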