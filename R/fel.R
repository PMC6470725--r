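# Free-energy landscape over the first two dihedral principal components,
# k-means basin identification and lowest-energy conformer extraction.

#' Universal gas constant in kJ/(mol K)
#' @export
GAS_CONSTANT_KJ <- 8.31446261815324e-3

#' Free-energy landscape from a 2-D projection
#'
#' Bins the (dPC1, dPC2) scores on a regular grid over the bounding box
#' (expanded by 1%) and converts occupation probabilities rho to
#' Delta G = -R T log(rho / rho_max), kJ/mol. The modal bin is exactly 0;
#' empty bins are masked NA, never reported as high energy.
#'
#' @param proj frames x 2 matrix of projections.
#' @param nBins bins per axis (default 100; scalar or length 2).
#' @param temperature Kelvin (default 310, the simulation temperature the
#'   landscape convention was defined at).
#' @param expand fractional bounding-box expansion (default 0.01).
#' @param breaks optional list(x, y) of explicit bin edges.
#' @return A \code{FELGrid}.
#' @export
freeEnergyLandscape <- function(proj, nBins = 100, temperature = 310,
                                expand = 0.01, breaks = NULL) {
  proj <- as.matrix(proj)
  stopifnot(ncol(proj) == 2, nrow(proj) >= 1)
  nBins <- rep_len(nBins, 2)
  if (any(nBins < 2)) stop("need at least 2 bins per axis", call. = FALSE)
  if (is.null(breaks)) {
    pad <- function(v, n) {
      r <- range(v)
      w <- diff(r)
      if (w == 0) w <- max(abs(r[1]), 1e-6)
      seq(r[1] - expand * w, r[2] + expand * w, length.out = n + 1)
    }
    xb <- pad(proj[, 1], nBins[1]); yb <- pad(proj[, 2], nBins[2])
  } else { xb <- breaks$x; yb <- breaks$y }
  ix <- findInterval(proj[, 1], xb, rightmost.closed = TRUE)
  iy <- findInterval(proj[, 2], yb, rightmost.closed = TRUE)
  ok <- ix >= 1 & ix <= length(xb) - 1 & iy >= 1 & iy <= length(yb) - 1
  counts <- matrix(0L, length(xb) - 1, length(yb) - 1)
  tab <- table(factor(ix[ok], levels = seq_len(nrow(counts))),
               factor(iy[ok], levels = seq_len(ncol(counts))))
  counts[] <- as.integer(tab)
  rho <- counts / sum(counts)
  rhoMax <- max(rho)
  dG <- matrix(NA_real_, nrow(counts), ncol(counts))
  occ <- counts > 0
  dG[occ] <- -GAS_CONSTANT_KJ * temperature * log(rho[occ] / rhoMax)
  new("FELGrid", xbreaks = xb, ybreaks = yb, counts = counts, deltaG = dG,
      temperature = temperature)
}

#' Count free-energy basins below a level
#'
#' Connected components (4-neighbour) of occupied bins with Delta G at or
#' below \code{level}; separated components correspond to basins divided by
#' a saddle above the level.
#'
#' @param grid a \code{FELGrid}.
#' @param level kJ/mol (default 2).
#' @return Integer basin count; the component label matrix is attached as
#'   attribute \code{"labels"}.
#' @export
felBasins <- function(grid, level = 2) {
  low <- !is.na(grid@deltaG) & grid@deltaG <= level
  lab <- matrix(0L, nrow(low), ncol(low))
  comp <- 0L
  for (s in which(low)) {
    if (lab[s] != 0L) next
    comp <- comp + 1L
    queue <- s
    lab[s] <- comp
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      i <- (cur - 1L) %% nrow(low) + 1L
      j <- (cur - 1L) %/% nrow(low) + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1 && ii <= nrow(low) && jj >= 1 && jj <= ncol(low)) {
          nxt <- (jj - 1L) * nrow(low) + ii
          if (low[nxt] && lab[nxt] == 0L) { lab[nxt] <- comp; queue <- c(queue, nxt) }
        }
      }
    }
  }
  structure(comp, labels = lab)
}

#' k-means clustering of a landscape projection
#'
#' k-means (k-means++-style multiple restarts via \code{stats::kmeans} with
#' \code{nstart}) for each candidate k, with SSE and silhouette diagnostics;
#' the returned selection defaults to the k with maximum average silhouette
#' width, overridable by the caller.
#'
#' @param proj frames x 2 projection matrix.
#' @param kCandidates integer vector of candidate cluster counts.
#' @param seed integer seed for the restarts (private RNG stream).
#' @param nstart restarts per k (default 50).
#' @return List with \code{models} (one \code{ClusterModel} per k),
#'   \code{diagnostics} (data.frame k, sse, silWidth, silCoef) and
#'   \code{best} (the maximum-silhouette model).
#' @export
clusterLandscape <- function(proj, kCandidates = 2:6, seed = 1,
                             nstart = 50) {
  proj <- as.matrix(proj)
  nUnique <- nrow(unique(proj))
  if (any(kCandidates >= nUnique))
    stop("k must be below the number of distinct points (", nUnique, ")",
         call. = FALSE)
  if (any(kCandidates < 2)) stop("k candidates must be >= 2", call. = FALSE)
  oldseed <- .saveSeed()
  on.exit(.restoreSeed(oldseed), add = TRUE)
  set.seed(as.integer(seed))
  # silhouettes on a subsample when frames are many (pairwise distances)
  silIdx <- if (nrow(proj) > 4000) sample.int(nrow(proj), 4000) else
    seq_len(nrow(proj))
  dsub <- stats::dist(proj[silIdx, , drop = FALSE])
  models <- list()
  diag <- data.frame()
  for (k in kCandidates) {
    km <- kmeans(proj, centers = k, nstart = nstart, iter.max = 100)
    sil <- cluster::silhouette(km$cluster[silIdx], dsub)
    sw <- summary(sil)$avg.width
    perCl <- summary(sil)$clus.avg.widths
    mod <- new("ClusterModel", k = as.integer(k),
               assignment = as.integer(km$cluster),
               centers = km$centers, sse = km$tot.withinss,
               silWidth = sw, silCoef = max(perCl),
               seed = as.integer(seed))
    models[[as.character(k)]] <- mod
    diag <- rbind(diag, data.frame(k = k, sse = km$tot.withinss,
                                   silWidth = sw, silCoef = max(perCl)))
  }
  best <- models[[as.character(diag$k[which.max(diag$silWidth)])]]
  list(models = models, diagnostics = diag, best = best)
}

# Delta G of the bin each frame falls in.
.frameBinDG <- function(grid, proj) {
  ix <- findInterval(proj[, 1], grid@xbreaks, rightmost.closed = TRUE)
  iy <- findInterval(proj[, 2], grid@ybreaks, rightmost.closed = TRUE)
  ix <- pmin(pmax(ix, 1L), nrow(grid@counts))
  iy <- pmin(pmax(iy, 1L), ncol(grid@counts))
  grid@deltaG[cbind(ix, iy)]
}

#' Lowest-energy representative conformations per cluster
#'
#' For each cluster, finds its minimum-Delta G occupied bin and returns the
#' member frame nearest that bin's center; clusters are ordered from lowest
#' to highest minimum Delta G.
#'
#' @param clusters a \code{ClusterModel}.
#' @param grid a \code{FELGrid} built from the same projection.
#' @param proj the frames x 2 projection both were built from.
#' @return data.frame (one row per cluster, ordered by energy) with
#'   \code{cluster}, \code{frame}, \code{deltaG}, \code{dPC1}, \code{dPC2}.
#' @export
representativeConformations <- function(clusters, grid, proj) {
  proj <- as.matrix(proj)
  stopifnot(length(clusters@assignment) == nrow(proj))
  dgFrame <- .frameBinDG(grid, proj)
  xmid <- (grid@xbreaks[-1] + grid@xbreaks[-length(grid@xbreaks)]) / 2
  ymid <- (grid@ybreaks[-1] + grid@ybreaks[-length(grid@ybreaks)]) / 2
  rows <- list()
  for (cl in seq_len(clusters@k)) {
    memb <- which(clusters@assignment == cl)
    if (!length(memb)) {
      warning("cluster ", cl, " is empty; skipped")
      next
    }
    dgMin <- min(dgFrame[memb])
    cand <- memb[dgFrame[memb] == dgMin]
    ix <- findInterval(proj[cand[1], 1], grid@xbreaks,
                       rightmost.closed = TRUE)
    iy <- findInterval(proj[cand[1], 2], grid@ybreaks,
                       rightmost.closed = TRUE)
    centre <- c(xmid[ix], ymid[iy])
    d <- sqrt(rowSums(sweep(proj[cand, , drop = FALSE], 2, centre)^2))
    f <- cand[which.min(d)]
    rows[[length(rows) + 1L]] <- data.frame(
      cluster = cl, frame = f, deltaG = dgMin,
      dPC1 = proj[f, 1], dPC2 = proj[f, 2])
  }
  out <- do.call(rbind, rows)
  out[order(out$deltaG), , drop = FALSE]
}
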