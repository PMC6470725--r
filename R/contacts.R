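# Residue contact probabilities, geometric hydrogen bonds, and the
# CbetaHbeta(1,2) center-of-mass contact statistic.

#' Residue-residue contact-probability map
#'
#' A pair of residues is in contact in a frame when the minimum distance
#' between their heavy atoms of the requested role is at or below the
#' cutoff; the map holds the fraction of frames in contact. Backbone atoms
#' are N, CA, C, O; sidechain is every other heavy atom. Residues lacking
#' atoms of the role (e.g. Gly sidechains) get NA rows, not zeros.
#'
#' @param e a \code{ConformationalEnsemble}.
#' @param mode "BB-BB" or "SC-SC".
#' @param cutoff contact distance, nm (default 0.5).
#' @return A \code{ContactMap}.
#' @export
contactMap <- function(e, mode = c("SC-SC", "BB-BB"), cutoff = 0.5) {
  mode <- match.arg(mode)
  a <- atoms(e)
  role <- if (mode == "BB-BB") "backbone" else "sidechain"
  pep <- a$role %in% c("backbone", "sidechain")
  res <- sort(unique(a$resid[pep]))
  n <- length(res)
  idx <- lapply(res, function(r)
    which(a$resid == r & a$role == role & a$element != "H"))
  have <- lengths(idx) > 0
  nf <- nFrames(e)
  prob <- matrix(NA_real_, n, n, dimnames = list(res, res))
  for (i in seq_len(n)) {
    if (!have[i]) next
    prob[i, i] <- 1
    if (i == n) next
    for (j in (i + 1):n) {
      if (!have[j]) next
      hits <- 0L
      for (f in seq_len(nf)) {
        dmin <- .pairMinDist(.as3(e@coords[f, idx[[i]], ]),
                             .as3(e@coords[f, idx[[j]], ]))
        if (dmin <= cutoff) hits <- hits + 1L
      }
      prob[i, j] <- prob[j, i] <- hits / nf
    }
  }
  new("ContactMap", map = prob, mode = mode, cutoff = cutoff)
}

# minimum distance between two point sets (matrices m x 3, k x 3)
.pairMinDist <- function(A, B) {
  A <- .as3(A); B <- .as3(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

#' Geometric hydrogen bonds with per-pair occupancy
#'
#' A donor-hydrogen-acceptor triple is bonded in a frame when the
#' donor-acceptor distance is at most \code{rCut} and the deviation from
#' linearity at the hydrogen is at most \code{angCut}. Donors are N/O atoms
#' with an attached hydrogen (same residue, within 0.12 nm in the first
#' frame); acceptors are N/O atoms. Occupancy is the fraction of frames
#' bonded; only pairs with non-zero occupancy are returned.
#'
#' @param e a \code{ConformationalEnsemble}.
#' @param rCut donor-acceptor cutoff, nm (default 0.35).
#' @param angCut allowed deviation from linearity, degrees (default 30).
#' @param angleAtHydrogen if TRUE (default) the angle criterion is
#'   180 - angle(D-H-A) <= angCut; if FALSE it is angle(H-D-A) <= angCut.
#' @return data.frame with donor/acceptor atom indices, residue indices and
#'   occupancy, sorted by decreasing occupancy.
#' @export
hbonds <- function(e, rCut = 0.35, angCut = 30, angleAtHydrogen = TRUE) {
  a <- atoms(e)
  pep <- which(a$role %in% c("backbone", "sidechain"))
  heavyDA <- pep[a$element[pep] %in% c("N", "O")]
  hyd <- pep[a$element[pep] == "H"]
  # attach hydrogens to their donor heavy atom by first-frame proximity
  donors <- list()
  for (h in hyd) {
    same <- heavyDA[a$resid[heavyDA] == a$resid[h]]
    if (!length(same)) next
    d <- sqrt(rowSums(sweep(.as3(e@coords[1, same, ]), 2,
                            e@coords[1, h, ])^2))
    if (min(d) <= 0.12)
      donors[[length(donors) + 1L]] <- c(D = same[which.min(d)], H = h)
  }
  if (!length(donors)) {
    warning("no donors with attached hydrogens found")
    return(data.frame())
  }
  donors <- do.call(rbind, donors)
  nf <- nFrames(e)
  out <- list()
  cosCut <- cos(angCut * pi / 180)
  for (k in seq_len(nrow(donors))) {
    D <- donors[k, "D"]; H <- donors[k, "H"]
    acc <- setdiff(heavyDA, D)
    cnt <- integer(length(acc))
    for (f in seq_len(nf)) {
      pd <- e@coords[f, D, ]; ph <- e@coords[f, H, ]
      pa <- .as3(e@coords[f, acc, ])
      dDA <- sqrt(rowSums(sweep(pa, 2, pd)^2))
      ok <- dDA <= rCut
      if (any(ok)) {
        if (angleAtHydrogen) {
          u <- .rowunit(matrix(pd - ph, sum(ok), 3, byrow = TRUE))
          v <- .rowunit(pa[ok, , drop = FALSE] -
                          matrix(ph, sum(ok), 3, byrow = TRUE))
          # deviation from linearity at H: angle between H->D and H->A is
          # 180 - dev; dev <= angCut  <=>  cos(angle) <= -cos(angCut)
          ok2 <- .rowdot(u, v) <= -cosCut
        } else {
          u <- .rowunit(matrix(ph - pd, sum(ok), 3, byrow = TRUE))
          v <- .rowunit(pa[ok, , drop = FALSE] -
                          matrix(pd, sum(ok), 3, byrow = TRUE))
          ok2 <- .rowdot(u, v) >= cosCut
        }
        cnt[which(ok)[ok2]] <- cnt[which(ok)[ok2]] + 1L
      }
    }
    pos <- which(cnt > 0)
    if (length(pos))
      out[[length(out) + 1L]] <- data.frame(
        donor = D, hydrogen = H, acceptor = acc[pos],
        donorResid = a$resid[D], acceptorResid = a$resid[acc[pos]],
        occupancy = cnt[pos] / nf)
  }
  if (!length(out)) return(data.frame())
  res <- do.call(rbind, out)
  res[order(-res$occupancy, res$donor, res$acceptor), ]
}

#' CbetaHbeta(1,2) center-of-mass contact statistic
#'
#' Per frame, the distance between the mass-weighted centers of
#' {CB, HB1, HB2} of the two residues (masses C 12.011, H 1.008); reports
#' the mean and SD of the distance and the probability of contact at or
#' below the threshold (default 0.26 nm, the one-sided CI95 of the
#' disulfide-bonded reference dipeptide's distance distribution).
#'
#' @param e a \code{ConformationalEnsemble}.
#' @param pair length-2 vector of residue indices.
#' @param threshold contact distance, nm.
#' @return List with \code{pair}, \code{distances} (per frame, nm),
#'   \code{D} (mean), \code{sd}, \code{rho} (contact probability) and
#'   \code{threshold}.
#' @export
cbetaComStat <- function(e, pair, threshold = 0.26) {
  stopifnot(length(pair) == 2)
  a <- atoms(e)
  masses <- c(CB = 12.011, HB1 = 1.008, HB2 = 1.008)
  comIdx <- lapply(pair, function(r) {
    i <- vapply(names(masses), function(nm) {
      j <- which(a$resid == r & a$name == nm)
      if (!length(j))
        stop("residue ", r, " is missing atom ", nm, call. = FALSE)
      j[1]
    }, integer(1))
    i
  })
  w <- masses / sum(masses)
  nf <- nFrames(e)
  dist <- vapply(seq_len(nf), function(f) {
    c1 <- colSums(e@coords[f, comIdx[[1]], ] * w)
    c2 <- colSums(e@coords[f, comIdx[[2]], ] * w)
    sqrt(sum((c1 - c2)^2))
  }, numeric(1))
  list(pair = pair, distances = dist, D = mean(dist),
       sd = if (nf > 1) sd(dist) else 0,
       rho = mean(dist <= threshold), threshold = threshold)
}

#' One-sided 95% contact threshold from reference distances
#'
#' Upper 95th percentile of an empirical center-of-mass distance
#' distribution measured on a bonded reference system; distances at or
#' below this threshold count as contact.
#'
#' @param referenceDistances numeric vector, >= 100 samples.
#' @return Threshold in the input units (nm).
#' @export
ci95Threshold <- function(referenceDistances) {
  if (length(referenceDistances) < 100)
    stop("need at least 100 reference samples", call. = FALSE)
  unname(quantile(referenceDistances, 0.95, type = 7))
}
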