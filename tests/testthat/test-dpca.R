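test_that("dihedral extraction covers the requested interior range", {
  # a 36-residue chain analysed over residues 2..35 gives 34 pairs
  d36 <- constantDihedralSeries(-70, -40, 36, nFrames = 2)
  ens <- rebuildChain(d36)
  dih <- extractDihedrals(ens, residues = 2:35)
  expect_equal(nResidues(dih), 34)
  expect_equal(dih@residues, 2:35)
  expect_error(extractDihedrals(ens, residues = 1:10), "neighbours")
})

test_that("the sin/cos encoding is an isometric circle embedding", {
  d <- new("DihedralSeries", phi = matrix(c(0, 1), 2, 1),
           psi = matrix(c(pi / 2, -2), 2, 1), residues = 2L)
  X <- dpcaEncode(d)
  expect_equal(X[1, ], c(cosphi.2 = 1, sinphi.2 = 0, cospsi.2 = 0,
                         sinpsi.2 = 1))
  expect_true(all(X >= -1 & X <= 1))
  # cos^2 + sin^2 = 1 per angle per frame
  expect_equal(X[, 1]^2 + X[, 2]^2, c(1, 1), tolerance = 1e-12)

  set.seed(61)
  dU <- new("DihedralSeries",
            phi = matrix(runif(20000, -pi, pi), 20000, 1),
            psi = matrix(runif(20000, -pi, pi), 20000, 1),
            residues = 2L)
  XU <- dpcaEncode(dU)
  expect_lt(max(abs(colMeans(XU))), 0.02)
  expect_equal(unname(apply(XU, 2, var)), rep(0.5, 4), tolerance = 0.03)
})

test_that("PCA matches a brute-force eigensolve and conserves variance", {
  set.seed(62)
  X <- matrix(rnorm(400 * 6), 400) %*% diag(c(3, 2, 1, 0.5, 0.2, 0.1))
  m <- dpca(X)
  oracle <- eigen(cov(X), symmetric = TRUE)
  expect_equal(m@values, pmax(oracle$values, 0), tolerance = 1e-8)
  for (j in 1:6)
    expect_equal(abs(sum(m@vectors[, j] * oracle$vectors[, j])), 1,
                 tolerance = 1e-8)
  expect_equal(sum(diag(cov(X))), sum(m@values), tolerance = 1e-10)

  # sign convention: largest-magnitude loading positive
  for (j in 1:6) expect_gt(m@vectors[which.max(abs(m@vectors[, j])), j], 0)

  # data on a line in 3-D: one nonzero eigenvalue equal to total variance
  t <- rnorm(100)
  line <- cbind(t, 2 * t, -t)
  ml <- dpca(line)
  expect_equal(ml@values[1], sum(diag(cov(line))), tolerance = 1e-10)
  expect_lt(ml@values[2], 1e-12)

  # zero variance: still a model, all eigenvalues 0
  mz <- dpca(matrix(1, 10, 3))
  expect_equal(mz@values, rep(0, 3))
})

test_that("dPCA is free of angular boundary artifacts", {
  set.seed(63)
  phi <- matrix(rnorm(2000, 3.0, 0.2), 2000, 1)    # straddles +pi wrap
  psi <- matrix(rnorm(2000, -3.0, 0.2), 2000, 1)
  d1 <- new("DihedralSeries", phi = pepdyn:::wrapAngle(phi),
            psi = pepdyn:::wrapAngle(psi), residues = 2L)
  shift <- 2.1
  d2 <- new("DihedralSeries", phi = pepdyn:::wrapAngle(phi + shift),
            psi = pepdyn:::wrapAngle(psi + shift), residues = 2L)
  v1 <- dpca(dpcaEncode(d1))@values
  v2 <- dpca(dpcaEncode(d2))@values
  expect_equal(v1, v2, tolerance = 1e-8)
})

test_that("free-energy landscapes implement the Boltzmann inversion", {
  proj <- rbind(matrix(0, 900, 2), matrix(1, 100, 2))
  g <- freeEnergyLandscape(proj, nBins = 4, temperature = 310)
  expect_equal(g@temperature, 310)
  occ <- which(!is.na(g@deltaG))
  expect_equal(length(occ), 2)
  expect_equal(min(g@deltaG[occ]), 0)            # modal bin exactly 0
  dd <- max(g@deltaG[occ])
  expect_equal(dd, GAS_CONSTANT_KJ * 310 * log(9), tolerance = 1e-9)
  # empty bins masked, not zero or large
  expect_true(all(is.na(g@deltaG[g@counts == 0])))
  # default temperature is 310 K
  expect_equal(freeEnergyLandscape(proj, nBins = 4)@temperature, 310)
})

test_that("k-means basins recover separated blobs with exact silhouettes", {
  set.seed(64)
  blob1 <- matrix(rnorm(300, 0, 0.2), 150, 2)
  blob2 <- matrix(rnorm(300, 5, 0.2), 150, 2)
  proj <- rbind(blob1, blob2)
  truth <- rep(1:2, each = 150)
  cl <- clusterLandscape(proj, kCandidates = 2:4, seed = 65)
  best <- cl$best
  expect_equal(best@k, 2L)
  # agreement up to relabeling (adjusted Rand index 1 for a perfect match)
  tab <- table(best@assignment, truth)
  expect_equal(sum(apply(tab, 1, max)), 300)

  # silhouette width equals a brute-force pairwise computation
  dmat <- as.matrix(dist(proj))
  silManual <- vapply(seq_len(300), function(i) {
    own <- best@assignment[i]
    a <- mean(dmat[i, best@assignment == own][-which(
      which(best@assignment == own) == i)])
    b <- min(vapply(setdiff(1:2, own), function(k)
      mean(dmat[i, best@assignment == k]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_equal(cl$diagnostics$silWidth[cl$diagnostics$k == 2],
               mean(silManual), tolerance = 1e-10)

  # SSE non-increasing in k on the same data
  expect_true(all(diff(cl$diagnostics$sse) <= 1e-8))
  expect_error(clusterLandscape(rbind(c(0, 0), c(1, 1)), kCandidates = 2),
               "distinct")
})

test_that("representative conformations sit in the lowest-energy bins", {
  set.seed(66)
  proj <- rbind(matrix(rnorm(3000, 0, 0.15), 1500, 2),
                matrix(rnorm(1000, 4, 0.15), 500, 2))
  g <- freeEnergyLandscape(proj, nBins = 12)
  cl <- clusterLandscape(proj, kCandidates = 2, seed = 67)
  reps <- representativeConformations(cl$models[["2"]], g, proj)
  expect_equal(nrow(reps), 2)
  expect_equal(reps$deltaG[1], 0)                 # majority basin floor
  expect_false(any(duplicated(reps$frame)))
  expect_true(all(reps$frame >= 1 & reps$frame <= 2000))
  expect_true(all(diff(reps$deltaG) >= 0))        # ordered by energy

  # single cluster: the representative comes from the modal bin
  g1 <- freeEnergyLandscape(proj[1:1500, ], nBins = 10)
  cl1 <- suppressWarnings(clusterLandscape(proj[1:1500, ], 2, seed = 68))
  one <- new("ClusterModel", k = 1L,
             assignment = rep(1L, 1500),
             centers = matrix(colMeans(proj[1:1500, ]), 1),
             sse = 0, silWidth = 0, silCoef = 0, seed = 1L)
  r1 <- representativeConformations(one, g1, proj[1:1500, ])
  expect_equal(r1$deltaG, 0)
})
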