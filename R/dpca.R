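# Dihedral principal component analysis: phi/psi extraction, sin/cos
# encoding, covariance eigendecomposition and projection.

#' Extract backbone phi/psi series from an ensemble
#'
#' Standard torsions phi = (C[i-1], N, CA, C) and psi = (N, CA, C, N[i+1]),
#' IUPAC sign convention, for the requested residue range (which must have
#' flanking residues on both sides, so the defaults are residues 2..n-1).
#'
#' @param e a \code{ConformationalEnsemble} with backbone N, CA, C.
#' @param residues residue range (default: all interior residues, i.e.
#'   2..n-1 for an n-residue chain — residues 2 to 35 for the 36-residue
#'   peptides these analyses were designed around).
#' @return A \code{DihedralSeries}.
#' @export
extractDihedrals <- function(e, residues = NULL) {
  a <- atoms(e)
  pep <- a$role %in% c("backbone", "sidechain")
  allRes <- sort(unique(a$resid[pep]))
  residues <- as.integer(residues %||% allRes[c(-1, -length(allRes))])
  if (!all((residues - 1) %in% allRes) || !all((residues + 1) %in% allRes))
    stop("residue range must have neighbours on both sides", call. = FALSE)
  need <- function(r, nm) {
    i <- which(a$resid == r & a$name == nm)
    if (!length(i)) stop("residue ", r, " is missing backbone atom ", nm,
                         call. = FALSE)
    i[1]
  }
  nf <- nFrames(e)
  phi <- psi <- matrix(NA_real_, nf, length(residues))
  for (k in seq_along(residues)) {
    r <- residues[k]
    Cm <- e@coords[, need(r - 1, "C"), , drop = FALSE][, 1, ]
    N <- e@coords[, need(r, "N"), , drop = FALSE][, 1, ]
    CA <- e@coords[, need(r, "CA"), , drop = FALSE][, 1, ]
    C <- e@coords[, need(r, "C"), , drop = FALSE][, 1, ]
    Np <- e@coords[, need(r + 1, "N"), , drop = FALSE][, 1, ]
    phi[, k] <- dihedralAngle(.as3(Cm), .as3(N), .as3(CA), .as3(C))
    psi[, k] <- dihedralAngle(.as3(N), .as3(CA), .as3(C), .as3(Np))
  }
  new("DihedralSeries", phi = phi, psi = psi, residues = residues)
}

#' Sin/cos encoding of a dihedral series
#'
#' Per residue, the ordered block (cos phi, sin phi, cos psi, sin psi); the
#' encoding removes the angular periodicity so ordinary PCA applies.
#'
#' @param d a \code{DihedralSeries}.
#' @return frames x 4m numeric matrix with entries in [-1, 1].
#' @export
dpcaEncode <- function(d) {
  m <- nResidues(d)
  X <- matrix(NA_real_, nFrames(d), 4 * m)
  for (k in seq_len(m)) {
    X[, 4 * k - 3] <- cos(d@phi[, k])
    X[, 4 * k - 2] <- sin(d@phi[, k])
    X[, 4 * k - 1] <- cos(d@psi[, k])
    X[, 4 * k] <- sin(d@psi[, k])
  }
  colnames(X) <- as.vector(t(outer(d@residues,
                                   c("cosphi", "sinphi", "cospsi", "sinpsi"),
                                   function(r, s) paste0(s, ".", r))))
  X
}

#' Principal component analysis by covariance eigendecomposition
#'
#' Columns are centred; the covariance matrix is eigendecomposed. The sign
#' of each eigenvector is fixed so its largest-magnitude loading is
#' positive, making projections reproducible.
#'
#' @param X frames x p data matrix (>= 2 frames).
#' @param k number of components to keep (default all).
#' @return A \code{DPCAModel}.
#' @export
dpca <- function(X, k = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 frames", call. = FALSE)
  mu <- colMeans(X)
  S <- cov(X)
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  k <- k %||% ncol(X)
  V <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  new("DPCAModel", center = mu, vectors = V, values = vals[seq_len(k)])
}

#' Project data onto principal components
#'
#' @param model a \code{DPCAModel}.
#' @param X frames x p matrix (same encoding as the training data).
#' @param k number of components (default 2).
#' @return frames x k matrix of scores.
#' @export
dpcaProject <- function(model, X, k = 2) {
  X <- as.matrix(X)
  k <- min(k, ncol(model@vectors))
  sweep(X, 2, model@center) %*% model@vectors[, seq_len(k), drop = FALSE]
}
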