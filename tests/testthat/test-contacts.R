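test_that("contact probabilities equal brute-force enumeration", {
  e <- makeContactOracleEnsemble(nFrames = 60, seed = 41)
  for (mode in c("SC-SC", "BB-BB")) {
    cm <- contactMap(e, mode, cutoff = 0.5)
    # oracle: direct all-pairs, all-frames heavy-atom loop
    a <- atoms(e)
    role <- if (mode == "BB-BB") "backbone" else "sidechain"
    res <- sort(unique(a$resid))
    for (i in seq_along(res)) for (j in seq_along(res)) {
      if (i >= j) next
      ai <- which(a$resid == res[i] & a$role == role & a$element != "H")
      aj <- which(a$resid == res[j] & a$role == role & a$element != "H")
      if (!length(ai) || !length(aj)) {
        expect_true(is.na(cm@map[i, j]))
        next
      }
      hits <- 0
      for (f in seq_len(nFrames(e))) {
        dmin <- Inf
        for (x in ai) for (y in aj)
          dmin <- min(dmin, sqrt(sum((coords(e)[f, x, ] -
                                        coords(e)[f, y, ])^2)))
        if (dmin <= 0.5) hits <- hits + 1
      }
      expect_identical(cm@map[i, j], hits / nFrames(e))
    }
    expect_identical(cm@map, t(cm@map))
  }
})

test_that("contact probability counts frames and respects monotonicity", {
  # two single-atom residues, 10 frames, 4 within the cutoff
  top <- caTraceTopology(2)
  co <- array(0, c(10, 2, 3))
  co[, 2, 1] <- c(rep(0.4, 4), rep(0.8, 6))
  e <- makeEnsemble(top, co)
  cm <- contactMap(e, "BB-BB", cutoff = 0.5)
  expect_equal(cm@map[1, 2], 0.4)

  # identical positions every frame -> probability 1
  co1 <- array(0, c(5, 2, 3))
  expect_equal(contactMap(makeEnsemble(top, co1), "BB-BB")@map[1, 2], 1)

  # shrinking the cutoff never increases any probability
  e2 <- makeContactOracleEnsemble(nFrames = 30, seed = 42)
  m1 <- contactMap(e2, "SC-SC", cutoff = 0.5)@map
  m2 <- contactMap(e2, "SC-SC", cutoff = 0.35)@map
  expect_true(all(m2 <= m1 + 1e-15, na.rm = TRUE))
})

test_that("geometric hydrogen bonds apply both distance and angle cuts", {
  # linear N-H...O at d(N, O) = 0.29 nm: bonded
  mkframe <- function(angleDeg) {
    # donor N at origin, H along +x, acceptor O placed so the deviation
    # from linearity at H equals angleDeg
    N <- c(0, 0, 0); H <- c(0.1, 0, 0)
    th <- angleDeg * pi / 180
    O <- H + 0.19 * c(cos(th), sin(th), 0)
    rbind(N, H, O)
  }
  top <- pepdyn:::.buildTopology(c("N", "H", "O"), c(1, 1, 2),
                                 c("ALA", "ALA", "ALA"), "A")
  lin <- makeEnsemble(top, mkframe(0))
  hb <- hbonds(lin)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$occupancy, 1)

  bent <- makeEnsemble(top, mkframe(40))
  expect_equal(nrow(hbonds(bent)), 0)

  # occupancy equals a brute-force frame count on a synthetic series
  co <- array(NA_real_, c(20, 3, 3))
  set.seed(43)
  for (f in 1:20) co[f, , ] <- mkframe(runif(1, 0, 60))
  e <- makeEnsemble(top, co)
  occ <- hbonds(e)
  manual <- 0
  for (f in 1:20) {
    dDA <- sqrt(sum((co[f, 1, ] - co[f, 3, ])^2))
    u <- co[f, 1, ] - co[f, 2, ]; v <- co[f, 3, ] - co[f, 2, ]
    dev <- pi - acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
    if (dDA <= 0.35 && dev <= 30 * pi / 180) manual <- manual + 1
  }
  if (manual == 0) expect_equal(nrow(occ), 0)
  else expect_equal(occ$occupancy, manual / 20)
})

test_that("CbetaHbeta center-of-mass statistics count contacts", {
  # two residues with controlled COM separation alternating 0.2 / 0.4 nm
  nm <- c("CB", "HB1", "HB2")
  top <- pepdyn:::.buildTopology(rep(c("CA", nm), 2),
                                 rep(1:2, each = 4),
                                 rep("ALA", 8), "A")
  co <- array(0, c(100, 8, 3))
  # atom order per residue: CA, CB, HB1, HB2; centre the CB/HB group so its
  # mass-weighted COM sits exactly at the residue anchor
  grp <- rbind(c(0, 0, 0), c(0, 0.05, 0.09), c(0, -0.05, 0.09))
  com <- colSums(grp * c(12.011, 1.008, 1.008)) / (12.011 + 2 * 1.008)
  for (f in 1:100) {
    co[f, 2:4, ] <- sweep(grp, 2, com)           # residue 1 COM at origin
    shift <- if (f %% 2) 0.2 else 0.4
    co[f, 6:8, ] <- sweep(grp, 2, com)
    co[f, 6:8, 1] <- co[f, 6:8, 1] + shift
  }
  e <- makeEnsemble(top, co)
  s <- cbetaComStat(e, c(1, 2), threshold = 0.26)
  expect_equal(s$D, 0.3, tolerance = 1e-12)
  expect_equal(s$rho, 0.5, tolerance = 1e-12)
  # sample SD of the alternating series is 0.1 * sqrt(n / (n - 1))
  expect_equal(s$sd, 0.1 * sqrt(100 / 99), tolerance = 1e-12)
  expect_equal(s$threshold, 0.26)

  # coincident COMs: D = 0, rho = 1
  co0 <- co; co0[, 6:8, ] <- co0[, 2:4, ]
  s0 <- cbetaComStat(makeEnsemble(top, co0), c(1, 2))
  expect_equal(s0$D, 0); expect_equal(s0$rho, 1)

  topNoB <- caTraceTopology(2)
  e2 <- makeEnsemble(topNoB, array(0, c(2, 2, 3)))
  expect_error(cbetaComStat(e2, c(1, 2)), "missing atom CB")
})

test_that("the one-sided CI95 threshold is the 95th percentile", {
  expect_equal(ci95Threshold(rep(0.23, 200)), 0.23)
  set.seed(44)
  x <- rnorm(200000, 0.23, 0.03)
  expect_equal(ci95Threshold(x), 0.23 + qnorm(0.95) * 0.03,
               tolerance = 0.005 / (0.23 + qnorm(0.95) * 0.03))
  u <- runif(200000, 0.2, 0.3)
  expect_equal(ci95Threshold(u), 0.295, tolerance = 0.002)
  expect_error(ci95Threshold(rnorm(50)), "100")
})
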