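# Least-squares superposition and fluctuation statistics on the CA trace.

#' Kabsch superposition of two point sets
#'
#' Finds the proper rotation and translation minimising the (optionally
#' weighted) RMSD between \code{P} and \code{Q}; reflections are excluded.
#' The fit maps P onto Q: \code{sweep(P, 2, cP) \%*\% rotation + cQ}.
#'
#' @param P,Q n x 3 coordinate matrices (nm), n >= 3, non-collinear.
#' @param weights optional non-negative weights (default uniform).
#' @return List with \code{rotation} (3 x 3, det +1), \code{translation}
#'   (the vector added after rotating centred P), \code{rmsd} (nm) and the
#'   centroids \code{centerP}, \code{centerQ}.
#' @export
kabsch <- function(P, Q, weights = NULL) {
  P <- .as3(P); Q <- .as3(Q)
  n <- nrow(P)
  if (n != nrow(Q)) stop("point counts differ", call. = FALSE)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (any(w < 0) || sum(w) <= 0) stop("invalid weights", call. = FALSE)
  w <- w / sum(w)
  cP <- colSums(P * w); cQ <- colSums(Q * w)
  Pc <- sweep(P, 2, cP); Qc <- sweep(Q, 2, cQ)
  if (sum(svd(sqrt(w) * Pc)$d > 1e-10 * max(1, max(abs(Pc)))) < 2)
    stop("degenerate geometry: points are (nearly) collinear", call. = FALSE)
  A <- crossprod(Pc * w, Qc)                 # 3 x 3
  s <- svd(A)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- Pc %*% R
  rmsd <- sqrt(sum(w * rowSums((fitted - Qc)^2)))
  list(rotation = R, translation = cQ, centerP = cP, centerQ = cQ,
       rmsd = rmsd)
}

# Apply a kabsch fit: superpose P onto the target frame.
.applyFit <- function(P, fit) {
  sweep(.as3(P), 2, fit$centerP) %*% fit$rotation +
    matrix(fit$translation, nrow(.as3(P)), 3, byrow = TRUE)
}

#' Per-frame RMSD against a fixed reference
#'
#' Each frame is least-squares superposed onto the reference over the
#' selection before the RMSD is measured.
#'
#' @param e a \code{ConformationalEnsemble}.
#' @param reference atoms x 3 reference coordinates (full topology) or a
#'   matrix matching the selection.
#' @param selection atom indices (default: all CA atoms).
#' @return List with \code{rmsd} (per-frame, nm), \code{mean}, \code{sd}.
#' @export
rmsdSeries <- function(e, reference, selection = NULL) {
  selection <- selection %||% unname(.caIndices(topology(e)))
  if (!length(selection)) stop("empty selection", call. = FALSE)
  ref <- .as3(reference)
  refSel <- if (nrow(ref) == nAtoms(e)) ref[selection, , drop = FALSE] else ref
  if (nrow(refSel) != length(selection))
    stop("selection mismatch: reference has ", nrow(refSel),
         " points for ", length(selection), " selected atoms", call. = FALSE)
  r <- vapply(seq_len(nFrames(e)), function(f) {
    kabsch(e@coords[f, selection, ], refSel)$rmsd
  }, numeric(1))
  list(rmsd = r, mean = mean(r), sd = if (length(r) > 1) sd(r) else 0)
}

#' Iterative mean structure
#'
#' Alternates between superposing every frame on the current mean and
#' recomputing the arithmetic mean, until the mean moves less than
#' \code{tol} (RMSD, nm) or \code{maxIter} is reached.
#'
#' @param e a \code{ConformationalEnsemble}.
#' @param selection atom indices used for fitting and averaging (default all
#'   CA atoms).
#' @param tol convergence threshold on the mean shift, nm.
#' @param maxIter iteration cap; non-convergence warns and returns the best
#'   iterate.
#' @return List with \code{mean} (selection x 3 matrix, nm),
#'   \code{converged}, \code{iterations}.
#' @export
meanStructure <- function(e, selection = NULL, tol = 1e-6, maxIter = 50) {
  selection <- selection %||% unname(.caIndices(topology(e)))
  nf <- nFrames(e)
  if (nf < 2) stop("need at least 2 frames", call. = FALSE)
  m <- e@coords[1, selection, ]
  converged <- FALSE
  it <- 0
  while (it < maxIter) {
    it <- it + 1
    acc <- matrix(0, length(selection), 3)
    for (f in seq_len(nf)) {
      fit <- kabsch(e@coords[f, selection, ], m)
      acc <- acc + .applyFit(e@coords[f, selection, ], fit)
    }
    newM <- acc / nf
    shift <- sqrt(mean(rowSums((newM - m)^2)))
    m <- newM
    if (shift < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("mean structure did not converge in ", maxIter, " iterations")
  list(mean = m, converged = converged, iterations = it)
}

#' Per-residue CA root-mean-square fluctuation
#'
#' Every frame is superposed (over the CA selection) on the reference, then
#' RMSF_i = sqrt(mean |r_i - rbar_i|^2) about the superposed ensemble mean.
#' The reference is either the ensemble's own iterative mean
#' (\code{reference = "self"}) or external coordinates, e.g. another
#' peptide's time-average (positional residue correspondence).
#'
#' @param e a \code{ConformationalEnsemble}.
#' @param reference "self" or a matrix of reference coordinates (selection
#'   x 3 or full-topology x 3).
#' @param selection atom indices (default: all CA atoms).
#' @return Named numeric vector of per-residue RMSF (nm).
#' @export
rmsf <- function(e, reference = "self", selection = NULL) {
  selection <- selection %||% .caIndices(topology(e))
  sel <- unname(selection)
  if (identical(reference, "self")) {
    ref <- meanStructure(e, sel)$mean
  } else {
    ref <- .as3(reference)
    if (nrow(ref) == nAtoms(e)) ref <- ref[sel, , drop = FALSE]
    if (nrow(ref) != length(sel))
      stop("reference/selection mismatch", call. = FALSE)
  }
  nf <- nFrames(e)
  sup <- array(NA_real_, c(nf, length(sel), 3))
  for (f in seq_len(nf)) {
    fit <- kabsch(e@coords[f, sel, ], ref)
    sup[f, , ] <- .applyFit(e@coords[f, sel, ], fit)
  }
  mbar <- apply(sup, c(2, 3), mean)
  dev2 <- vapply(seq_along(sel), function(i) {
    mean(rowSums(sweep(sup[, i, , drop = TRUE], 2, mbar[i, ])^2))
  }, numeric(1))
  stats::setNames(sqrt(dev2), names(selection))
}
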