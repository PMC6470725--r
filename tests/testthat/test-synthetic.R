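test_that("Markov dihedral generator honours the chain and the seed", {
  spec <- dihedralStateSpec(phiMean = c(-1, 1), psiMean = c(-2, 2),
                            kappa = 50, nResidues = 2)
  # absorbing chain started in state 1 stays there
  ch <- markovChainSpec(diag(2), initial = c(1, 0))
  sim <- genMarkovDihedrals(spec, ch, 200, seed = 1)
  expect_true(all(sim$states == 1))

  # bit-reproducible, and the caller's RNG stream is untouched
  set.seed(99); before <- rnorm(1)
  sim2 <- genMarkovDihedrals(spec, ch, 200, seed = 1)
  set.seed(99); expect_identical(before, rnorm(1))
  expect_identical(sim$dihedrals@phi, sim2$dihedrals@phi)

  expect_error(markovChainSpec(matrix(c(0.5, 0.5, 0.2, 0.7), 2,
                                      byrow = TRUE)), "sum to 1")
})

test_that("von Mises emissions have the right concentration tail mass", {
  spec <- dihedralStateSpec(phiMean = 0.5, psiMean = -2.5, kappa = 400,
                            nResidues = 1)
  ch <- markovChainSpec(matrix(1), initial = 1)
  sim <- genMarkovDihedrals(spec, ch, 20000, seed = 7)
  dphi <- pepdyn:::wrapAngle(sim$dihedrals@phi - 0.5)
  inside <- mean(abs(dphi) <= 0.15)
  # numeric-integration oracle for the von Mises tail mass (scaled Bessel
  # form keeps kappa = 400 finite)
  pInside <- integrate(function(x) exp(400 * (cos(x) - 1)) /
                         (2 * pi * besselI(400, 0, expon.scaled = TRUE)),
                       -0.15, 0.15)$value
  expect_gt(pInside, 0.99)
  expect_lt(abs(inside - pInside), 3 * sqrt(pInside * (1 - pInside) / 20000))
  expect_gt(inside, 0.99)
})

test_that("hidden-state occupancies converge to the stationary law", {
  spec <- dihedralStateSpec(phiMean = c(-1, 1), psiMean = c(-2, 2),
                            kappa = 5, nResidues = 1)
  # fast-mixing chain with stationary distribution (0.75, 0.25)
  P <- rbind(c(0.76, 0.24), c(0.72, 0.28))
  ch <- markovChainSpec(P)
  expect_equal(stationaryDistribution(P), c(0.75, 0.25), tolerance = 1e-12)
  n <- 20000
  sim <- genMarkovDihedrals(spec, ch, n, seed = 11)
  occ <- mean(sim$states == 1)
  se <- sqrt(0.75 * 0.25 / n)
  expect_lt(abs(occ - 0.75), 3 * se)

  # chi-square goodness of fit not rejected at alpha = 0.01 for n = 50,000
  sim2 <- genMarkovDihedrals(spec, ch, 50000, seed = 12)
  tab <- tabulate(sim2$states, 2)
  pval <- stats::chisq.test(tab, p = c(0.75, 0.25))$p.value
  expect_gt(pval, 0.01)
})

test_that("rebuilt chains round-trip their dihedrals and keep ideal geometry", {
  set.seed(5)
  d <- new("DihedralSeries",
           phi = matrix(runif(50 * 4, -pi, pi), 50, 4),
           psi = matrix(runif(50 * 4, -pi, pi), 50, 4),
           residues = 2:5)
  ens <- rebuildChain(d)
  back <- extractDihedrals(ens)
  expect_lt(max(abs(pepdyn:::wrapAngle(back@phi - d@phi))), 1e-6)
  expect_lt(max(abs(pepdyn:::wrapAngle(back@psi - d@psi))), 1e-6)

  # trans peptide: consecutive CA-CA distances ~ 0.38 nm in every frame
  ca <- selectAtoms(topology(ens), "name CA")
  for (f in c(1, 25, 50)) {
    cc <- coords(ens)[f, ca, ]
    expect_equal(sqrt(rowSums(diff(cc)^2)), rep(0.3804, 5),
                 tolerance = 1e-3)
  }

  # helix: canonical (-57, -47) everywhere
  helix <- makeHelixEnsemble(nRes = 12)
  dh <- extractDihedrals(helix)
  expect_equal(as.vector(dh@phi) * 180 / pi, rep(-57, 10), tolerance = 1e-6)
  expect_equal(as.vector(dh@psi) * 180 / pi, rep(-47, 10), tolerance = 1e-6)
})

test_that("fluctuation ensembles realise the prescribed covariance", {
  ref <- matrix(rnorm(30), 10)
  # zero covariance -> every frame equals the reference
  e0 <- genFluctuationEnsemble(ref, 0, 5, seed = 2)
  for (f in 1:5) expect_equal(e0@coords[f, , ], ref, ignore_attr = TRUE)

  # rank-2 factor -> exactly 2 nonzero eigenvalues, matching the spec
  L <- matrix(0, 30, 2)
  L[2, 1] <- 0.1; L[15, 2] <- 0.05
  e2 <- genFluctuationEnsemble(ref, L, 20000, seed = 3)
  b <- essentialBasis(e2, N = 6, fit = FALSE)
  expect_equal(sum(b@values > 1e-10), 2)
  expect_equal(b@values[1], 0.01, tolerance = 0.05)
  expect_equal(b@values[2], 0.0025, tolerance = 0.05)

  expect_error(genFluctuationEnsemble(ref, -0.1, 5, seed = 1), ">= 0")
  badCov <- diag(30); badCov[1, 1] <- -1
  expect_error(genFluctuationEnsemble(ref, badCov, 5, seed = 1),
               "positive semidefinite")
})

test_that("solvation scenes control local shell density", {
  centre <- matrix(c(1.5, 1.5, 1.5), 1)
  # multiplier 0: the tagged shell is empty
  s0 <- solvationSceneSpec(centre, c(3, 3, 3), bulkDensity = 33.4,
                           tagged = 1, multiplier = 0)
  e0 <- genSolvationFrames(s0, 10, seed = 4)
  expect_equal(shellProbability(e0, 1, 0.5, mode = "mean_count"), 0)

  # multiplier 1, no exclusion: indistinguishable from bulk
  s1 <- solvationSceneSpec(centre, c(3, 3, 3), bulkDensity = 33.4,
                           tagged = 1, multiplier = 1)
  e1 <- genSolvationFrames(s1, 80, seed = 5)
  expect_equal(shellProbability(e1, 1, 0.5, bulkDensity = 33.4), 1,
               tolerance = 0.08)

  # shell must fit inside the box
  expect_error(solvationSceneSpec(matrix(c(0.2, 1.5, 1.5), 1), c(3, 3, 3),
                                  tagged = 1), "overflows")
})

test_that("generator specs load from YAML configs", {
  path <- system.file("extdata", "two_state_demo.yaml", package = "pepdyn")
  gs <- readGeneratorSpec(path)
  expect_s3_class(gs$states, "DihedralStateSpec")
  expect_equal(gs$states$K, 2)
  expect_equal(gs$states$m, 6)
  expect_equal(gs$states$phiMean[1, 1], -57 * pi / 180)
  expect_equal(stationaryDistribution(gs$chain$P), c(0.75, 0.25),
               tolerance = 1e-12)
  sim <- genMarkovDihedrals(gs$states, gs$chain, 50, seed = 8)
  expect_equal(dim(sim$dihedrals@phi), c(50, 6))
})
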