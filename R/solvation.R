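# Solvent-accessible surface area (Shrake-Rupley), rSASA normalisation and
# hydration-shell water statistics.

#' Lee & Richards atomic radii
#'
#' Van der Waals radii (nm) per element as used for solvent-accessible
#' surface area; user-overridable in \code{\link{sasa}}.
#'
#' @return Named numeric vector of radii (nm).
#' @export
leeRichardsRadii <- function() {
  c(C = 0.170, N = 0.155, O = 0.152, S = 0.180, H = 0.120, P = 0.180)
}

#' Maximal per-residue SASA reference values (mSASA)
#'
#' Reference maxima (nm^2) measured on capped Ala-Xaa-Ala model peptides
#' (Cys as the disulfide-bonded dimer): Cys 0.758, Ser 1.219, Abu 1.347.
#'
#' @return Named numeric vector (nm^2).
#' @export
defaultMSASA <- function() {
  c(CYS = 0.758, SER = 1.219, ABU = 1.347)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Deterministic golden-spiral test points on each heavy atom's solvent-
#' expanded sphere (radius + probe); points outside every neighbouring
#' sphere are accessible. Areas are summed per residue; for an ensemble the
#' per-frame areas are averaged.
#'
#' @param x a \code{ConformationalEnsemble}, or an atoms x 3 coordinate
#'   matrix (then \code{elements} and \code{resid} must be given).
#' @param radii named per-element radii, nm (default
#'   \code{\link{leeRichardsRadii}}).
#' @param probe probe radius, nm (default 0.14, water).
#' @param nPoints test points per sphere (default 1000).
#' @param elements,resid element symbols and residue indices when \code{x}
#'   is a bare matrix.
#' @param includeHydrogens count hydrogens as spheres (default FALSE:
#'   heavy-atom surface).
#' @return Named numeric vector of per-residue SASA (nm^2).
#' @export
sasa <- function(x, radii = leeRichardsRadii(), probe = 0.14,
                 nPoints = 1000, elements = NULL, resid = NULL,
                 includeHydrogens = FALSE) {
  if (is(x, "ConformationalEnsemble")) {
    a <- atoms(x)
    keep <- which(a$role %in% c("backbone", "sidechain"))
    if (!includeHydrogens) keep <- keep[a$element[keep] != "H"]
    el <- a$element[keep]; rs <- a$resid[keep]
    acc <- NULL
    for (f in seq_len(nFrames(x))) {
      v <- .sasaFrame(.as3(x@coords[f, keep, ]), el, rs, radii, probe,
                      nPoints)
      acc <- if (is.null(acc)) v else acc + v
    }
    return(acc / nFrames(x))
  }
  xyz <- .as3(x)
  if (is.null(elements)) stop("elements required for bare coordinates",
                              call. = FALSE)
  if (is.null(resid)) resid <- seq_len(nrow(xyz))
  if (!includeHydrogens) {
    keep <- elements != "H"
    xyz <- xyz[keep, , drop = FALSE]
    resid <- resid[keep]; elements <- elements[keep]
  }
  .sasaFrame(xyz, elements, resid, radii, probe, nPoints)
}

.sasaFrame <- function(xyz, elements, resid, radii, probe, nPoints) {
  miss <- setdiff(unique(elements), names(radii))
  if (length(miss))
    stop("no atomic radius for element(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  r <- unname(radii[elements]) + probe
  n <- nrow(xyz)
  pts <- sphereGrid(nPoints)
  areaAtom <- numeric(n)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    neigh <- which(seq_len(n) != i & d2[i, ] < (r[i] + r)^2)
    p <- sweep(pts * r[i], 2, xyz[i, ], "+")
    if (length(neigh)) {
      free <- rep(TRUE, nPoints)
      for (j in neigh) {
        dj2 <- rowSums(sweep(p, 2, xyz[j, ])^2)
        free <- free & dj2 >= r[j]^2
        if (!any(free)) break
      }
      frac <- mean(free)
    } else frac <- 1
    areaAtom[i] <- 4 * pi * r[i]^2 * frac
  }
  out <- tapply(areaAtom, resid, sum)
  stats::setNames(as.numeric(out), names(out))
}

#' Relative solvent-accessible surface area
#'
#' SASA divided by the residue type's maximal SASA (mSASA). Values above 1
#' are possible (conformations more exposed than the reference peptide) and
#' are flagged with a warning, not clipped.
#'
#' @param sasaValue SASA in nm^2 (vectorised).
#' @param residueType 3-letter code with an mSASA entry (CYS, SER, ABU by
#'   default).
#' @param msasa reference table, user-overridable.
#' @return Dimensionless ratio(s).
#' @export
rsasa <- function(sasaValue, residueType, msasa = defaultMSASA()) {
  residueType <- toupper(residueType)
  if (!all(residueType %in% names(msasa)))
    stop("no mSASA reference for residue type: ",
         paste(setdiff(residueType, names(msasa)), collapse = ", "),
         call. = FALSE)
  out <- sasaValue / unname(msasa[residueType])
  if (any(out > 1 + 1e-9))
    warning("rSASA above 1: more exposed than the reference peptide")
  out
}

# water oxygen atom indices
.waterIdx <- function(top) {
  a <- top@atoms
  which(a$role == "solvent" & a$element == "O")
}

#' Radial distribution function of water around selected centers
#'
#' g(r) per shell: observed water-oxygen density around the centers divided
#' by the bulk density (water count over box volume unless given).
#'
#' @param e a \code{ConformationalEnsemble} with solvent and a box.
#' @param centers atom indices used as RDF centers.
#' @param rMax outer radius, nm.
#' @param dr bin width, nm.
#' @param bulkDensity override bulk number density (nm^-3).
#' @return List with \code{edges}, \code{mid}, \code{g}, \code{counts}
#'   (mean per frame per center) and \code{bulkDensity}.
#' @export
rdf <- function(e, centers, rMax = 1.0, dr = 0.02, bulkDensity = NULL) {
  wat <- .waterIdx(topology(e))
  if (!length(wat)) stop("ensemble has no solvent", call. = FALSE)
  if (is.null(bulkDensity)) {
    if (!length(e@box)) stop("need a box to infer bulk density", call. = FALSE)
    bulkDensity <- length(wat) / prod(e@box)
  }
  edges <- seq(0, rMax, by = dr)
  if (edges[length(edges)] < rMax) edges <- c(edges, rMax)
  nb <- length(edges) - 1
  cnt <- numeric(nb)
  nf <- nFrames(e)
  for (f in seq_len(nf)) {
    W <- .as3(e@coords[f, wat, ])
    for (cIdx in centers) {
      d <- sqrt(rowSums(sweep(W, 2, e@coords[f, cIdx, ])^2))
      h <- findInterval(d, edges, rightmost.closed = TRUE)
      h <- h[h >= 1 & h <= nb]
      if (length(h)) cnt <- cnt + tabulate(h, nb)
    }
  }
  cnt <- cnt / (nf * length(centers))
  vol <- 4 / 3 * pi * diff(edges^3)
  list(edges = edges, mid = (edges[-1] + edges[-length(edges)]) / 2,
       g = cnt / (vol * bulkDensity), counts = cnt,
       bulkDensity = bulkDensity)
}

#' Hydration-shell water probability
#'
#' Default mode ("shell_occupancy_norm"): the mean number of water oxygens
#' within \code{rCut} of the center, divided by the bulk-density expectation
#' for the same shell volume — the integral of the radial distribution
#' function over the shell. Mode "mean_count" reports the raw mean count.
#'
#' @param e a \code{ConformationalEnsemble} with solvent.
#' @param center a single atom index.
#' @param rCut shell radius, nm (default 0.5).
#' @param mode "shell_occupancy_norm" or "mean_count".
#' @param bulkDensity override the box-derived bulk density (nm^-3).
#' @return Probability (default mode) or mean count.
#' @export
shellProbability <- function(e, center, rCut = 0.5,
                             mode = c("shell_occupancy_norm", "mean_count"),
                             bulkDensity = NULL) {
  mode <- match.arg(mode)
  wat <- .waterIdx(topology(e))
  if (!length(wat)) stop("ensemble has no solvent", call. = FALSE)
  if (length(e@box) && rCut > min(e@box) / 2)
    stop("rCut exceeds half the smallest box dimension", call. = FALSE)
  nf <- nFrames(e)
  cnt <- vapply(seq_len(nf), function(f) {
    W <- .as3(e@coords[f, wat, ])
    sum(rowSums(sweep(W, 2, e@coords[f, center, ])^2) <= rCut^2)
  }, numeric(1))
  m <- mean(cnt)
  if (mode == "mean_count") return(m)
  if (is.null(bulkDensity)) {
    if (!length(e@box)) stop("need a box to infer bulk density", call. = FALSE)
    bulkDensity <- length(wat) / prod(e@box)
  }
  m / (bulkDensity * 4 / 3 * pi * rCut^3)
}
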