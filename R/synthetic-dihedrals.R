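# Ground-truth dihedral ensembles: Markov-switching von Mises emissions and
# NeRF reconstruction of a poly-Ala backbone (optionally with Cbeta/Hbeta
# pseudo-atoms) so the dihedral ground truth also exists in Cartesian form.

#' Specify per-state von Mises dihedral emissions
#'
#' @param phiMean,psiMean K x m matrices (or vectors recycled across
#'   residues) of state means in radians, in (-pi, pi].
#' @param kappa concentration parameter(s), >= 0; scalar, per-state vector or
#'   K x m matrix.
#' @param nResidues number of residues m.
#' @return A \code{DihedralStateSpec} list (validated).
#' @export
dihedralStateSpec <- function(phiMean, psiMean, kappa, nResidues = NULL) {
  toMat <- function(x, K, m) {
    if (is.matrix(x)) x else matrix(x, K, m, byrow = FALSE)
  }
  K <- if (is.matrix(phiMean)) nrow(phiMean) else length(phiMean)
  m <- nResidues %||% if (is.matrix(phiMean)) ncol(phiMean) else 1L
  phiMean <- toMat(phiMean, K, m); psiMean <- toMat(psiMean, K, m)
  kappa <- toMat(kappa, K, m)
  if (any(kappa < 0)) stop("kappa must be >= 0", call. = FALSE)
  if (any(c(phiMean, psiMean) <= -pi | c(phiMean, psiMean) > pi))
    stop("state means must lie in (-pi, pi]", call. = FALSE)
  structure(list(phiMean = phiMean, psiMean = psiMean, kappa = kappa,
                 K = K, m = m), class = "DihedralStateSpec")
}

#' Specify a discrete-time Markov chain
#'
#' @param transition K x K row-stochastic matrix.
#' @param initial initial state distribution (default: stationary).
#' @return A \code{MarkovChainSpec} list (validated).
#' @export
markovChainSpec <- function(transition, initial = NULL) {
  P <- as.matrix(transition)
  if (nrow(P) != ncol(P)) stop("transition matrix must be square", call. = FALSE)
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-12))
    stop("transition matrix rows must be non-negative and sum to 1 (1e-12)",
         call. = FALSE)
  if (is.null(initial)) initial <- stationaryDistribution(P)
  if (any(initial < 0) || abs(sum(initial) - 1) > 1e-12)
    stop("initial distribution must be a probability vector", call. = FALSE)
  structure(list(P = P, initial = as.numeric(initial), K = nrow(P)),
            class = "MarkovChainSpec")
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Left eigenvector of the transition matrix for eigenvalue 1, normalised to
#' sum to one.
#'
#' @param P K x K row-stochastic matrix.
#' @return Numeric vector of stationary probabilities.
#' @export
stationaryDistribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

# von Mises sampler, Best & Fisher (1979) wrapped-Cauchy rejection.
rvonmises <- function(n, mu, kappa) {
  out <- numeric(n)
  small <- kappa < 1e-8
  out[small] <- runif(sum(small), -pi, pi)
  idx <- which(!small)
  if (length(idx)) {
    k <- kappa[idx]
    a <- 1 + sqrt(1 + 4 * k^2)
    b <- (a - sqrt(2 * a)) / (2 * k)
    r <- (1 + b^2) / (2 * b)
    todo <- seq_along(idx)
    theta <- numeric(length(idx))
    while (length(todo)) {
      u1 <- runif(length(todo)); u2 <- runif(length(todo))
      u3 <- runif(length(todo))
      z <- cos(pi * u1)
      f <- (1 + r[todo] * z) / (r[todo] + z)
      c0 <- k[todo] * (r[todo] - f)
      ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
      theta[todo[ok]] <- sign(u3[ok] - 0.5) * acos(pmin(1, pmax(-1, f[ok])))
      todo <- todo[!ok]
    }
    out[idx] <- theta + mu[idx]
  }
  out[small] <- out[small] + mu[small]
  wrapAngle(out)
}

#' Simulate Markov-switching von Mises dihedral series
#'
#' Hidden states evolve as a discrete Markov chain; given the state, each
#' residue's (phi, psi) is drawn independently from von Mises distributions
#' centred on the state means. The true state path is returned for recovery
#' tests.
#'
#' @param states a \code{DihedralStateSpec}.
#' @param chain a \code{MarkovChainSpec} with matching state count.
#' @param nFrames number of frames (>= 1).
#' @param seed integer seed; the call uses one private RNG stream.
#' @param residues residue numbers for the series columns (default 2..m+1,
#'   i.e. interior residues of an (m+2)-residue chain).
#' @return List with \code{dihedrals} (a \code{DihedralSeries}) and
#'   \code{states} (integer vector of true hidden states, 1-based).
#' @export
genMarkovDihedrals <- function(states, chain, nFrames, seed,
                               residues = NULL) {
  stopifnot(inherits(states, "DihedralStateSpec"),
            inherits(chain, "MarkovChainSpec"), nFrames >= 1)
  if (states$K != chain$K) stop("state counts differ", call. = FALSE)
  m <- states$m
  residues <- as.integer(residues %||% seq(2L, m + 1L))
  oldseed <- .saveSeed()
  on.exit(.restoreSeed(oldseed), add = TRUE)
  set.seed(as.integer(seed))
  path <- integer(nFrames)
  path[1] <- sample.int(chain$K, 1, prob = chain$initial)
  if (nFrames > 1) for (f in 2:nFrames)
    path[f] <- sample.int(chain$K, 1, prob = chain$P[path[f - 1], ])
  phi <- matrix(NA_real_, nFrames, m)
  psi <- matrix(NA_real_, nFrames, m)
  for (r in seq_len(m)) {
    phi[, r] <- rvonmises(nFrames, states$phiMean[path, r],
                          states$kappa[path, r])
    psi[, r] <- rvonmises(nFrames, states$psiMean[path, r],
                          states$kappa[path, r])
  }
  d <- new("DihedralSeries", phi = phi, psi = psi, residues = residues)
  list(dihedrals = d, states = path)
}

# Private RNG stream helpers: generators take an explicit seed and leave the
# caller's global RNG state untouched.
.saveSeed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restoreSeed <- function(s) {
  if (is.null(s)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", s, envir = globalenv())
}

#' Ideal backbone geometry for chain reconstruction
#'
#' Bond lengths (nm) and angles (radians) of a standard trans peptide unit.
#'
#' @return Named list of lengths and angles.
#' @export
idealBackboneGeometry <- function() {
  list(bNCA = 0.1458, bCAC = 0.1525, bCN = 0.1329, bCO = 0.1231,
       bNH = 0.0997, bCACB = 0.1530, bCBHB = 0.1090,
       aNCAC = 111.2 * pi / 180, aCACN = 116.2 * pi / 180,
       aCNCA = 121.7 * pi / 180, aCACO = 120.5 * pi / 180,
       aNCACB = 110.4 * pi / 180, omega = pi)
}

#' Rebuild a Cartesian backbone from dihedral series
#'
#' Natural-extension (NeRF) construction of a poly-Ala-like backbone (N, H,
#' CA, C, O per residue; amide H on residues 2..n placed anti to the
#' preceding carbonyl, DSSP's convention) with optional CB/HB1/HB2
#' pseudo-atoms so sidechain contact statistics have targets. omega is fixed
#' at 180 degrees. Extracting dihedrals from the result returns the inputs.
#'
#' @param d a \code{DihedralSeries}; columns are the interior residues of a
#'   chain with \code{max(residues) + 1} residues in total.
#' @param geometry bond lengths/angles, see \code{\link{idealBackboneGeometry}}.
#' @param withCB add CB, HB1, HB2 pseudo-atoms to every residue.
#' @param resnames residue names (default "ALA", recycled).
#' @param dt frame spacing (ns) for the returned ensemble.
#' @return A \code{ConformationalEnsemble}.
#' @export
rebuildChain <- function(d, geometry = idealBackboneGeometry(),
                         withCB = TRUE, resnames = "ALA", dt = 1) {
  g <- geometry
  resFirst <- min(d@residues) - 1L
  resLast <- max(d@residues) + 1L
  nres <- resLast - resFirst + 1L
  if (!identical(d@residues, seq(resFirst + 1L, resLast - 1L)))
    stop("dihedral residue range must be contiguous", call. = FALSE)
  nf <- nFrames(d)
  resnames <- rep_len(toupper(resnames), nres)
  # column r holds the angle of residue r; the series covers the interior
  # residues, terminal phi/psi default to extended (180 deg)
  phi <- cbind(rep(pi, nf), d@phi, rep(pi, nf))
  psi <- cbind(rep(pi, nf), d@psi, rep(pi, nf))
  N <- CA <- C <- O <- vector("list", nres)
  # residue 1 in a canonical frame
  N[[1]] <- matrix(rep(c(0, 0, 0), each = nf), nf)
  CA[[1]] <- matrix(rep(c(g$bNCA, 0, 0), each = nf), nf)
  C[[1]] <- matrix(rep(c(g$bNCA - g$bCAC * cos(g$aNCAC),
                         g$bCAC * sin(g$aNCAC), 0), each = nf), nf)
  for (r in 2:nres) {
    N[[r]] <- placeAtom(N[[r - 1]], CA[[r - 1]], C[[r - 1]],
                        g$bCN, g$aCACN, psi[, r - 1])
    CA[[r]] <- placeAtom(CA[[r - 1]], C[[r - 1]], N[[r]],
                         g$bNCA, g$aCNCA, rep(g$omega, nf))
    C[[r]] <- placeAtom(C[[r - 1]], N[[r]], CA[[r]],
                        g$bCAC, g$aNCAC, phi[, r])
  }
  for (r in seq_len(nres)) {
    # carbonyl O trans to the next amide N (or to psi = 180 at the terminus)
    O[[r]] <- placeAtom(N[[r]], CA[[r]], C[[r]], g$bCO, g$aCACO,
                        wrapAngle(psi[, r] + pi))
  }
  name <- character(0); resid <- integer(0); resn <- character(0)
  coordList <- list()
  addAtom <- function(nm, r, xyz) {
    name <<- c(name, nm); resid <<- c(resid, r)
    resn <<- c(resn, resnames[r - resFirst + 1L])
    coordList[[length(coordList) + 1L]] <<- xyz
  }
  for (r in seq_len(nres)) {
    rr <- resFirst + r - 1L
    addAtom("N", rr, N[[r]])
    if (r > 1) {
      H <- N[[r]] + g$bNH * .rowunit(C[[r - 1]] - O[[r - 1]])
      addAtom("H", rr, H)
    }
    addAtom("CA", rr, CA[[r]])
    if (withCB) {
      CB <- placeAtom(C[[r]], N[[r]], CA[[r]], g$bCACB, g$aNCACB,
                      rep(122.5 * pi / 180, nf))
      addAtom("CB", rr, CB)
      HB1 <- placeAtom(N[[r]], CA[[r]], CB, g$bCBHB, 109.5 * pi / 180,
                       rep(pi / 3, nf))
      HB2 <- placeAtom(N[[r]], CA[[r]], CB, g$bCBHB, 109.5 * pi / 180,
                       rep(-pi / 3, nf))
      addAtom("HB1", rr, HB1)
      addAtom("HB2", rr, HB2)
    }
    addAtom("C", rr, C[[r]])
    addAtom("O", rr, O[[r]])
  }
  natom <- length(name)
  co <- array(NA_real_, c(nf, natom, 3))
  for (i in seq_len(natom)) co[, i, ] <- coordList[[i]]
  top <- .buildTopology(name, resid - min(resid) + 1L, resn, chain = "A")
  # keep author numbering if the series started above 1
  top@atoms$resid <- resid
  makeEnsemble(top, co, dt = dt)
}

#' Read generator parameters from a YAML/JSON config
#'
#' The file provides the state emissions (degrees) and the switching chain:
#' \preformatted{
#' states:
#'   phiMeanDeg: [[-57, -57], [123, 123]]   # K x m
#'   psiMeanDeg: [[-47, -47], [133, 133]]
#'   kappa: 200
#' chain:
#'   transition: [[0.85, 0.15], [0.45, 0.55]]
#' }
#'
#' @param path YAML (or JSON) file.
#' @return List with \code{states} (a \code{DihedralStateSpec}) and
#'   \code{chain} (a \code{MarkovChainSpec}).
#' @export
readGeneratorSpec <- function(path) {
  y <- yaml::read_yaml(path)
  toMat <- function(x) if (is.list(x)) do.call(rbind, x) else rbind(x)
  phi <- toMat(y$states$phiMeanDeg) * pi / 180
  psi <- toMat(y$states$psiMeanDeg) * pi / 180
  states <- dihedralStateSpec(phiMean = wrapAngle(phi),
                              psiMean = wrapAngle(psi),
                              kappa = y$states$kappa)
  chain <- markovChainSpec(toMat(y$chain$transition),
                           initial = y$chain$initial)
  list(states = states, chain = chain)
}
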