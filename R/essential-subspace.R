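# Essential-dynamics subspaces of CA fluctuations and the RMSIP / nRMSIP
# overlap statistics with their four-class interpretation.

#' Essential basis of CA-coordinate fluctuations
#'
#' Frames are superposed on their iterative mean over the selection; the
#' covariance of the flattened (3n) CA coordinates is eigendecomposed and
#' the top N eigenvectors returned. Weights are uniform (CA-trace
#' convention).
#'
#' @param e a \code{ConformationalEnsemble} (>= 2 frames).
#' @param selection atom indices (default all CA atoms).
#' @param N eigenvector count (default 10); must not exceed 3n.
#' @param fit superpose frames on their iterative mean first (default TRUE;
#'   set FALSE for ensembles generated in a common reference frame, where
#'   refitting would mix the prescribed fluctuation modes with rigid-body
#'   ones).
#' @return An \code{EssentialBasis}.
#' @export
essentialBasis <- function(e, selection = NULL, N = 10, fit = TRUE) {
  selection <- unname(selection %||% .caIndices(topology(e)))
  nf <- nFrames(e)
  if (nf < 2) stop("need at least 2 frames", call. = FALSE)
  d <- 3L * length(selection)
  if (N > d) stop("N (", N, ") exceeds the dimension 3 * n_CA = ", d,
                  call. = FALSE)
  X <- matrix(NA_real_, nf, d)
  if (fit) {
    ref <- meanStructure(e, selection)$mean
    for (f in seq_len(nf)) {
      ft <- kabsch(e@coords[f, selection, ], ref)
      X[f, ] <- as.vector(t(.applyFit(e@coords[f, selection, ], ft)))
    }
  } else {
    for (f in seq_len(nf))
      X[f, ] <- as.vector(t(e@coords[f, selection, ]))
  }
  S <- cov(X)
  eg <- eigen(S, symmetric = TRUE)
  V <- eg$vectors[, seq_len(N), drop = FALSE]
  for (j in seq_len(N)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  new("EssentialBasis", vectors = V, values = pmax(eg$values[seq_len(N)], 0),
      selection = as.integer(selection), frames = as.integer(nf))
}

#' Root-mean-square inner product of two essential bases
#'
#' RMSIP = sqrt( (1/N) sum_i sum_j (eta_i^A . eta_j^B)^2 ) over the first N
#' eigenvectors of each basis; 1 for identical subspaces, 0 for orthogonal
#' ones.
#'
#' @param A,B \code{EssentialBasis} objects (or bare d x N matrices with
#'   orthonormal columns) in the same dimension d.
#' @param N number of eigenvectors to compare (default: all available in
#'   both).
#' @return RMSIP in [0, 1].
#' @export
rmsip <- function(A, B, N = NULL) {
  VA <- if (is(A, "EssentialBasis")) A@vectors else as.matrix(A)
  VB <- if (is(B, "EssentialBasis")) B@vectors else as.matrix(B)
  if (nrow(VA) != nrow(VB))
    stop("basis dimensions differ: ", nrow(VA), " vs ", nrow(VB),
         call. = FALSE)
  N <- N %||% min(ncol(VA), ncol(VB))
  if (N > ncol(VA) || N > ncol(VB))
    stop("N exceeds available eigenvectors", call. = FALSE)
  M <- crossprod(VA[, seq_len(N), drop = FALSE],
                 VB[, seq_len(N), drop = FALSE])
  sqrt(sum(M^2) / N)
}

# split an ensemble into temporal halves (floor/ceil)
.halves <- function(e) {
  nf <- nFrames(e)
  h1 <- seq_len(floor(nf / 2))
  h2 <- setdiff(seq_len(nf), h1)
  sub <- function(idx) makeEnsemble(topology(e),
                                    e@coords[idx, , , drop = FALSE],
                                    times = e@times[idx], box = e@box)
  list(sub(h1), sub(h2))
}

#' Normalised RMSIP between two ensembles
#'
#' nRMSIP = RMSIP(A, B) / sqrt(RMSIP(A1, A2) * RMSIP(B1, B2)), where A1/A2
#' and B1/B2 are the first and second temporal halves of each trajectory,
#' each half superposed on its own mean. The normalisation corrects the raw
#' overlap for finite-sampling self-consistency; values can exceed 1 when
#' the cross-overlap beats the self-consistency (flagged with a warning,
#' not clipped).
#'
#' @param eA,eB \code{ConformationalEnsemble}s (>= 4 frames each).
#' @param selection atom indices common to both (default all CA atoms).
#' @param N eigenvector count.
#' @param fit superpose frames before the covariance (see
#'   \code{\link{essentialBasis}}).
#' @return List with \code{nrmsip}, \code{rmsip}, \code{selfA},
#'   \code{selfB}.
#' @export
nrmsip <- function(eA, eB, selection = NULL, N = 10, fit = TRUE) {
  if (nFrames(eA) < 4 || nFrames(eB) < 4)
    stop("need at least 4 frames per ensemble", call. = FALSE)
  selection <- unname(selection %||% .caIndices(topology(eA)))
  bA <- essentialBasis(eA, selection, N, fit)
  bB <- essentialBasis(eB, selection, N, fit)
  hA <- .halves(eA); hB <- .halves(eB)
  selfA <- rmsip(essentialBasis(hA[[1]], selection, N, fit),
                 essentialBasis(hA[[2]], selection, N, fit), N)
  selfB <- rmsip(essentialBasis(hB[[1]], selection, N, fit),
                 essentialBasis(hB[[2]], selection, N, fit), N)
  if (selfA * selfB <= 1e-12)
    stop("zero self-overlap: sampling has not converged", call. = FALSE)
  cross <- rmsip(bA, bB, N)
  val <- cross / sqrt(selfA * selfB)
  if (val > 1)
    warning("nRMSIP above 1: cross-overlap exceeds self-consistency")
  list(nrmsip = val, rmsip = cross, selfA = selfA, selfB = selfB)
}

#' Pairwise RMSIP / nRMSIP overlap matrix
#'
#' @param ensembles named list of \code{ConformationalEnsemble}s with a
#'   common CA dimension.
#' @param selection atom indices (default all CA atoms of the first).
#' @param N eigenvector count.
#' @param normalized also compute nRMSIP (default TRUE).
#' @param fit superpose frames before the covariance (see
#'   \code{\link{essentialBasis}}).
#' @return List with symmetric matrices \code{rmsip} (diagonal 1) and, if
#'   requested, \code{nrmsip}.
#' @export
overlapMatrix <- function(ensembles, selection = NULL, N = 10,
                          normalized = TRUE, fit = TRUE) {
  if (length(ensembles) < 2) stop("need at least 2 ensembles", call. = FALSE)
  selection <- unname(selection %||% .caIndices(topology(ensembles[[1]])))
  nn <- length(ensembles)
  nm <- names(ensembles) %||% paste0("E", seq_len(nn))
  bases <- lapply(ensembles, essentialBasis, selection = selection, N = N,
                  fit = fit)
  R <- diag(1, nn); dimnames(R) <- list(nm, nm)
  Nrm <- R
  for (i in seq_len(nn - 1)) for (j in (i + 1):nn) {
    R[i, j] <- R[j, i] <- rmsip(bases[[i]], bases[[j]], N)
    if (normalized) {
      v <- nrmsip(ensembles[[i]], ensembles[[j]], selection, N, fit)$nrmsip
      Nrm[i, j] <- Nrm[j, i] <- v
    }
  }
  out <- list(rmsip = R)
  if (normalized) out$nrmsip <- Nrm
  out
}

#' Classify an overlap value into the four reporting classes
#'
#' Classes: below 0.65; [0.65, 0.75); [0.75, 0.85); [0.85, 0.95);
#' [0.95, Inf).
#'
#' @param value nRMSIP (or RMSIP) value(s), >= 0.
#' @return Character class label(s).
#' @export
classifyOverlap <- function(value) {
  stopifnot(all(value >= 0))
  cut(value, breaks = c(-Inf, 0.65, 0.75, 0.85, 0.95, Inf), right = FALSE,
      labels = c("below 0.65", "[0.65, 0.75)", "[0.75, 0.85)",
                 "[0.85, 0.95)", "[0.95, Inf)")) |> as.character()
}
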