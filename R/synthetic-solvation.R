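# Solvated scenes with controlled local water density around tagged atoms:
# ground truth for radial-distribution and hydration-shell statistics.
# Waters are single-site oxygen pseudo-atoms (residue SOL).

#' Specify a solvation scene
#'
#' @param solute n x 3 matrix of solute coordinates (nm).
#' @param box box lengths, numeric(3), nm.
#' @param bulkDensity bulk water number density, nm^-3 (default 33.4, liquid
#'   water at ambient conditions).
#' @param tagged indices of solute atoms whose hydration shell is controlled.
#' @param multiplier per-tagged-atom local density multiplier (recycled).
#' @param exclusionRadius no water closer than this to any solute atom (nm).
#' @param shellRadius controlled-shell outer radius (nm; default 0.5, the
#'   hydration-shell radius used in the analyses).
#' @return A \code{SolvationSceneSpec} list (validated).
#' @export
solvationSceneSpec <- function(solute, box, bulkDensity = 33.4,
                               tagged = integer(0), multiplier = 1,
                               exclusionRadius = 0, shellRadius = 0.5) {
  solute <- .as3(solute)
  stopifnot(length(box) == 3, all(box > 0))
  if (bulkDensity < 0 || any(multiplier < 0) || exclusionRadius < 0)
    stop("densities and radii must be >= 0", call. = FALSE)
  if (exclusionRadius >= shellRadius && length(tagged))
    stop("exclusion radius must be below the shell radius", call. = FALSE)
  if (length(tagged)) {
    lo <- apply(solute[tagged, , drop = FALSE], 1, min) - shellRadius
    hi <- sweep(-solute[tagged, , drop = FALSE], 2, box, "+") - shellRadius
    if (min(lo) < 0 || min(hi) < 0)
      stop("tagged hydration shell overflows the box", call. = FALSE)
  }
  structure(list(solute = solute, box = as.numeric(box),
                 bulkDensity = bulkDensity, tagged = as.integer(tagged),
                 multiplier = rep_len(multiplier, length(tagged)),
                 exclusionRadius = exclusionRadius,
                 shellRadius = shellRadius),
            class = "SolvationSceneSpec")
}

#' Generate solvated frames with controlled shell densities
#'
#' Waters are placed uniformly at the bulk density outside the exclusion
#' radius of the solute; within each tagged atom's shell (exclusion radius to
#' shell radius) the density is the bulk density times that atom's
#' multiplier. The total water count is fixed across frames (multinomial
#' allocation over regions) so the ensemble has a constant atom count;
#' positions are redrawn every frame.
#'
#' @param spec a \code{SolvationSceneSpec}.
#' @param nFrames number of frames.
#' @param seed integer seed (private RNG stream).
#' @param soluteNames atom names for the solute atoms (default CA).
#' @return A \code{ConformationalEnsemble} whose topology tags waters with
#'   the solvent role; the box is recorded.
#' @export
genSolvationFrames <- function(spec, nFrames, seed, soluteNames = "CA") {
  stopifnot(inherits(spec, "SolvationSceneSpec"))
  ns <- nrow(spec$solute)
  Vbox <- prod(spec$box)
  rsh <- spec$shellRadius; rex <- spec$exclusionRadius
  Vshell <- 4 / 3 * pi * (rsh^3 - rex^3)
  nt <- length(spec$tagged)
  if (nt > 1) {
    dd <- as.matrix(stats::dist(spec$solute[spec$tagged, , drop = FALSE]))
    if (min(dd[upper.tri(dd)]) < 2 * rsh)
      stop("tagged shells overlap; shell densities would be ambiguous",
           call. = FALSE)
  }
  # expected counts per region at the requested densities
  inAnyShell <- function(p) {
    if (!nt) return(rep(FALSE, nrow(p)))
    hit <- rep(FALSE, nrow(p))
    for (t in seq_len(nt)) {
      d <- sqrt(rowSums(sweep(p, 2, spec$solute[spec$tagged[t], ])^2))
      hit <- hit | (d <= rsh)
    }
    hit
  }
  nearSolute <- function(p) {
    if (rex <= 0) return(rep(FALSE, nrow(p)))
    hit <- rep(FALSE, nrow(p))
    for (i in seq_len(ns)) {
      d <- sqrt(rowSums(sweep(p, 2, spec$solute[i, ])^2))
      hit <- hit | (d < rex)
    }
    hit
  }
  # bulk volume: box minus tagged shells minus (approximately) the exclusion
  # volume of untagged solute atoms; estimated analytically for speed
  Vex <- if (rex > 0) (ns - nt) * 4 / 3 * pi * rex^3 else 0
  Vbulk <- max(Vbox - nt * 4 / 3 * pi * rsh^3 - Vex, 0)
  expBulk <- spec$bulkDensity * Vbulk
  expShell <- spec$bulkDensity * spec$multiplier * Vshell
  nw <- max(1L, round(expBulk + sum(expShell)))
  probs <- c(expBulk, expShell) / (expBulk + sum(expShell))

  oldseed <- .saveSeed()
  on.exit(.restoreSeed(oldseed), add = TRUE)
  set.seed(as.integer(seed))

  sampleBulk <- function(k) {
    out <- matrix(NA_real_, 0, 3)
    while (nrow(out) < k) {
      cand <- cbind(runif(2 * k, 0, spec$box[1]), runif(2 * k, 0, spec$box[2]),
                    runif(2 * k, 0, spec$box[3]))
      ok <- !inAnyShell(cand) & !nearSolute(cand)
      out <- rbind(out, cand[ok, , drop = FALSE])
    }
    out[seq_len(k), , drop = FALSE]
  }
  sampleShell <- function(k, centre) {
    u <- runif(k)
    r <- (u * (rsh^3 - rex^3) + rex^3)^(1 / 3)
    dir <- matrix(rnorm(3 * k), k)
    sweep(r * .rowunit(dir), 2, centre, "+")
  }

  natom <- ns + nw
  co <- array(NA_real_, c(nFrames, natom, 3))
  for (f in seq_len(nFrames)) {
    # total count is fixed; the region split is redrawn so per-region means
    # converge to density x volume over frames
    alloc <- as.vector(stats::rmultinom(1, nw, probs))
    co[f, seq_len(ns), ] <- spec$solute
    pos <- sampleBulk(alloc[1])
    if (nt) for (t in seq_len(nt)) if (alloc[1 + t] > 0)
      pos <- rbind(pos, sampleShell(alloc[1 + t],
                                    spec$solute[spec$tagged[t], ]))
    co[f, ns + seq_len(nw), ] <- pos
  }
  top <- .buildTopology(
    c(rep_len(soluteNames, ns), rep("O", nw)),
    c(seq_len(ns), ns + seq_len(nw)),
    c(rep("ALA", ns), rep("SOL", nw)), chain = "A")
  makeEnsemble(top, co, box = spec$box)
}
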