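# Cartesian ensembles fluctuating about a reference with a prescribed
# covariance: the ground truth for RMSF and essential-subspace recovery.

#' Generate an ensemble with prescribed Gaussian fluctuations
#'
#' Frames are drawn as \code{reference + L z}, \code{z ~ N(0, I)}, where
#' \code{L} is a factor of the requested covariance of the flattened (3n)
#' coordinate vector. The sample mean converges to the reference and the
#' sample covariance to the specification as the frame count grows.
#'
#' @param reference n x 3 matrix of mean coordinates (nm), or a
#'   \code{MolecularTopology}-bearing list from \code{\link{readStructure}}.
#' @param covariance one of: a scalar sigma (isotropic per-coordinate SD,
#'   nm); a length-3n vector of per-coordinate SDs; a 3n x r factor matrix
#'   \code{L} (low-rank spec, covariance = L Lt); or a full 3n x 3n positive
#'   semidefinite covariance matrix (nm^2).
#' @param nFrames number of frames.
#' @param seed integer seed (private RNG stream).
#' @param topology optional \code{MolecularTopology}; default: a chain of CA
#'   pseudo-atoms, one residue per atom.
#' @param dt frame spacing, ns.
#' @return A \code{ConformationalEnsemble}.
#' @export
genFluctuationEnsemble <- function(reference, covariance, nFrames, seed,
                                   topology = NULL, dt = 1) {
  ref <- .as3(reference)
  n <- nrow(ref)
  d <- 3L * n
  L <- .covFactor(covariance, d)
  oldseed <- .saveSeed()
  on.exit(.restoreSeed(oldseed), add = TRUE)
  set.seed(as.integer(seed))
  if (is.null(topology)) topology <- caTraceTopology(n)
  flatRef <- as.vector(t(ref))                  # x1 y1 z1 x2 ...
  co <- array(NA_real_, c(nFrames, n, 3))
  Z <- matrix(rnorm(nFrames * ncol(L)), ncol(L), nFrames)
  X <- flatRef + L %*% Z                        # d x frames
  for (f in seq_len(nFrames))
    co[f, , ] <- matrix(X[, f], ncol = 3, byrow = TRUE)
  makeEnsemble(topology, co, dt = dt)
}

# Resolve the covariance specification into a d x r factor L (cov = L Lt).
.covFactor <- function(covariance, d) {
  if (is.matrix(covariance)) {
    if (nrow(covariance) == d && ncol(covariance) == d &&
        isSymmetric(unname(covariance), tol = 1e-10)) {
      e <- eigen(covariance, symmetric = TRUE)
      if (min(e$values) < -1e-10 * max(abs(e$values)))
        stop("covariance must be positive semidefinite", call. = FALSE)
      pos <- e$values > 1e-14 * max(e$values, 0)
      e$vectors[, pos, drop = FALSE] %*%
        diag(sqrt(e$values[pos]), sum(pos))
    } else if (nrow(covariance) == d) {
      covariance                                 # low-rank factor
    } else stop("covariance factor must have 3n rows", call. = FALSE)
  } else if (length(covariance) == 1) {
    if (covariance < 0) stop("sigma must be >= 0", call. = FALSE)
    diag(rep(covariance, d), d)
  } else if (length(covariance) == d) {
    if (any(covariance < 0)) stop("SDs must be >= 0", call. = FALSE)
    diag(as.numeric(covariance), d)
  } else stop("unrecognised covariance specification", call. = FALSE)
}

#' CA-trace pseudo-topology
#'
#' One CA atom per residue; used for generated Cartesian ensembles where
#' only the trace matters.
#'
#' @param n residue count.
#' @param resnames residue names, recycled (default ALA).
#' @return A \code{MolecularTopology}.
#' @export
caTraceTopology <- function(n, resnames = "ALA") {
  .buildTopology(rep("CA", n), seq_len(n), rep_len(toupper(resnames), n),
                 chain = "A")
}
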