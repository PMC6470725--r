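# Fixtures built in code: tiny PDB/GRO texts and canonical synthetic
# ensembles (ideal helix, antiparallel hairpin, extended chain).

RT310 <- pepdyn::GAS_CONSTANT_KJ * 310

pdbLine <- function(serial, name, resname, resid, x, y, z, chain = "A",
                    element = substr(name, 1, 1)) {
  sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          resname, chain, resid, x, y, z, element)
}

# A 3-residue Gly-Abu-Gly peptide, coordinates in Angstroms.
writeTriPeptidePDB <- function(path) {
  lines <- c(
    pdbLine(1, "N",   "GLY", 1, 1.70, 0.00, 0.00),
    pdbLine(2, "CA",  "GLY", 1, 3.10, 0.20, 0.10),
    pdbLine(3, "C",   "GLY", 1, 4.00, 1.10, 0.90),
    pdbLine(4, "O",   "GLY", 1, 3.60, 2.20, 1.20),
    pdbLine(5, "N",   "ABU", 2, 5.20, 0.60, 1.30),
    pdbLine(6, "CA",  "ABU", 2, 6.20, 1.40, 2.00),
    pdbLine(7, "C",   "ABU", 2, 7.50, 0.60, 2.20),
    pdbLine(8, "O",   "ABU", 2, 7.60, -0.60, 2.00),
    pdbLine(9, "CB",  "ABU", 2, 6.50, 2.70, 1.30),
    pdbLine(10, "HB1", "ABU", 2, 7.10, 3.30, 2.00, element = "H"),
    pdbLine(11, "HB2", "ABU", 2, 5.60, 3.20, 1.00, element = "H"),
    pdbLine(12, "CG",  "ABU", 2, 7.20, 2.50, 0.00),
    pdbLine(13, "N",   "GLY", 3, 8.50, 1.30, 2.60),
    pdbLine(14, "CA",  "GLY", 3, 9.80, 0.70, 2.90),
    pdbLine(15, "C",   "GLY", 3, 10.80, 1.80, 3.20),
    pdbLine(16, "O",   "GLY", 3, 10.50, 3.00, 3.10),
    "END")
  writeLines(lines, path)
  path
}

# constant-dihedral single-frame series over `n` residues total
constantDihedralSeries <- function(phiDeg, psiDeg, nRes, nFrames = 1) {
  m <- nRes - 2
  new("DihedralSeries",
      phi = matrix(phiDeg * pi / 180, nFrames, m),
      psi = matrix(psiDeg * pi / 180, nFrames, m),
      residues = seq(2L, nRes - 1L))
}

makeHelixEnsemble <- function(nRes = 12, nFrames = 1) {
  pepdyn::rebuildChain(constantDihedralSeries(-57, -47, nRes, nFrames))
}

makeExtendedEnsemble <- function(nRes = 10, nFrames = 1) {
  pepdyn::rebuildChain(constantDihedralSeries(-139, 135, nRes, nFrames))
}

# antiparallel beta-hairpin: two (-139, 135) strands joined by a type II'
# turn; strand residues acquire E labels under Kabsch-Sander assignment
makeHairpinEnsemble <- function(nFrames = 1) {
  phi <- c(rep(-139, 3), 60, -80, rep(-139, 3)) * pi / 180
  psi <- c(rep(135, 3), -120, 0, rep(135, 3)) * pi / 180
  d <- new("DihedralSeries",
           phi = matrix(phi, nFrames, 8, byrow = TRUE),
           psi = matrix(psi, nFrames, 8, byrow = TRUE),
           residues = 2:9)
  pepdyn::rebuildChain(d)
}

# the frozen two-state study conditions: antipodal von Mises states (equal
# encoded covariance), stationary distribution (0.75, 0.25)
twoStateStudySpec <- function(m = 6, kappa = 200) {
  s1 <- c(-57, -47) * pi / 180
  s2 <- pepdyn:::wrapAngle(s1 + pi)
  list(
    states = pepdyn::dihedralStateSpec(
      phiMean = matrix(c(rep(s1[1], m), rep(s2[1], m)), 2, m, byrow = TRUE),
      psiMean = matrix(c(rep(s1[2], m), rep(s2[2], m)), 2, m, byrow = TRUE),
      kappa = kappa),
    chain = pepdyn::markovChainSpec(rbind(c(0.85, 0.15), c(0.45, 0.55))))
}

# small ensemble with hand-placed coordinates for brute-force contact and
# hydrogen-bond oracles: 5 CA-trace residues with CB/HB pseudo-atoms moved
# randomly per frame (seeded)
makeContactOracleEnsemble <- function(nFrames = 100, seed = 123) {
  set.seed(seed)
  d <- new("DihedralSeries",
           phi = matrix(stats::runif(nFrames * 3, -pi, pi), nFrames, 3),
           psi = matrix(stats::runif(nFrames * 3, -pi, pi), nFrames, 3),
           residues = 2:4)
  pepdyn::rebuildChain(d)
}

expect_allequal <- function(a, b, tol = 1e-12) {
  testthat::expect_lt(max(abs(a - b)), tol)
}
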