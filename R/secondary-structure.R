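# Kabsch-Sander hydrogen bonds and DSSP-style secondary structure.
#
# The electrostatic H-bond model evaluates
#   E = 0.084 * (1/rON + 1/rCH - 1/rOH - 1/rCN) * 332  kcal/mol
# with distances in Angstroms (coordinates held in nm are converted); a bond
# is declared when E < -0.5 kcal/mol. Eight states H, G, I, E, B, T, S, C
# are assigned per frame with priority H > E > B > G > I > T > S.

KS_BOND_CUTOFF <- -0.5   # kcal/mol

#' Kabsch-Sander hydrogen-bond energy
#'
#' @param C,O carbonyl carbon and oxygen of the acceptor residue (nm);
#'   length-3 vectors or n x 3 matrices (vectorised).
#' @param N,H amide nitrogen and hydrogen of the donor residue (nm).
#' @return Energy in kcal/mol (vectorised).
#' @export
ksHbondEnergy <- function(C, O, N, H) {
  C <- .as3(C); O <- .as3(O); N <- .as3(N); H <- .as3(H)
  ang <- function(a, b) 10 * .rownorm(a - b)   # nm -> Angstrom
  rON <- ang(O, N); rCH <- ang(C, H); rOH <- ang(O, H); rCN <- ang(C, N)
  if (any(c(rON, rCH, rOH, rCN) < 1e-9))
    stop("coincident atoms in hydrogen-bond energy", call. = FALSE)
  0.084 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN) * 332
}

# Backbone atom coordinates per residue for one frame: list of matrices
# (residues x 3) for N, H, CA, C, O; H rows may be NA (first residue, Pro).
.backboneFrame <- function(e, frame) {
  a <- atoms(e)
  pep <- a$role %in% c("backbone", "sidechain")
  res <- sort(unique(a$resid[pep]))
  pick <- function(nm, required = TRUE) {
    m <- matrix(NA_real_, length(res), 3)
    for (i in seq_along(res)) {
      j <- which(a$resid == res[i] & a$name %in% nm)
      if (length(j)) m[i, ] <- e@coords[frame, j[1], ]
      else if (required)
        stop("residue ", res[i], " is missing backbone atom ",
             nm[1], call. = FALSE)
    }
    m
  }
  list(res = res,
       N = pick("N"), CA = pick("CA"), C = pick("C"), O = pick("O"),
       H = pick(c("H", "HN"), required = FALSE),
       isPro = vapply(res, function(r)
         a$resname[match(r, a$resid)] == "PRO", logical(1)))
}

# n x n logical matrix: hb[a, d] TRUE when CO of residue a accepts an H bond
# from NH of residue d (E < -0.5 kcal/mol). Donors without H are skipped.
.ksHbondMatrix <- function(bb) {
  n <- length(bb$res)
  hb <- matrix(FALSE, n, n)
  donors <- which(!is.na(bb$H[, 1]) & !bb$isPro)
  for (d in donors) {
    acc <- setdiff(seq_len(n), d)
    # 0.9 nm CA-CA prefilter (Kabsch-Sander speed cutoff)
    ca <- sqrt(rowSums(sweep(bb$CA[acc, , drop = FALSE], 2, bb$CA[d, ])^2))
    acc <- acc[ca < 0.9]
    if (!length(acc)) next
    Eacc <- ksHbondEnergy(bb$C[acc, , drop = FALSE], bb$O[acc, , drop = FALSE],
                          matrix(bb$N[d, ], length(acc), 3, byrow = TRUE),
                          matrix(bb$H[d, ], length(acc), 3, byrow = TRUE))
    hb[acc[Eacc < KS_BOND_CUTOFF], d] <- TRUE
  }
  hb
}

# Single-frame DSSP labels from the bond matrix and CA trace.
.dsspFrame <- function(bb) {
  n <- length(bb$res)
  hb <- .ksHbondMatrix(bb)
  turn3 <- turn4 <- turn5 <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (i + 3 <= n) turn3[i] <- hb[i, i + 3]
    if (i + 4 <= n) turn4[i] <- hb[i, i + 4]
    if (i + 5 <= n) turn5[i] <- hb[i, i + 5]
  }
  lab <- rep("C", n)
  # minimal helices: turns at i-1 and i -> residues i..i+nlen-1
  helixMask <- function(flag, nlen) {
    m <- rep(FALSE, n)
    for (i in which(flag)) if (i > 1 && flag[i - 1])
      m[i:min(n, i + nlen - 1)] <- TRUE
    m
  }
  h4 <- helixMask(turn4, 4)
  h3 <- helixMask(turn3, 3)
  h5 <- helixMask(turn5, 5)
  # bridges
  bridge <- matrix(FALSE, n, n)
  for (i in 2:(n - 1)) for (j in 2:(n - 1)) {
    if (abs(i - j) < 3) next
    par <- (hb[i - 1, j] && hb[j, i + 1]) || (hb[j - 1, i] && hb[i, j + 1])
    anti <- (hb[i, j] && hb[j, i]) || (hb[i - 1, j + 1] && hb[j - 1, i + 1])
    if (par || anti) bridge[i, j] <- TRUE
  }
  bridgeRes <- which(apply(bridge, 1, any))
  # a bridge extends to a ladder (E) when an adjacent residue also bridges
  # with an adjacent partner; isolated bridges stay B
  inLadder <- rep(FALSE, n)
  for (i in bridgeRes) for (j in which(bridge[i, ])) {
    neigh <- FALSE
    for (di in c(-1L, 1L)) for (dj in c(-1L, 0L, 1L)) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= n && jj >= 1 && jj <= n && bridge[ii, jj])
        neigh <- TRUE
    }
    if (neigh) inLadder[i] <- TRUE
  }
  # turn state: residues strictly inside any n-turn
  turnMask <- rep(FALSE, n)
  for (i in which(turn3)) turnMask[(i + 1):(i + 2)] <- TRUE
  for (i in which(turn4)) turnMask[(i + 1):(i + 3)] <- TRUE
  for (i in which(turn5)) turnMask[(i + 1):(i + 4)] <- TRUE
  turnMask <- turnMask[seq_len(n)]
  # bend: CA kink above 70 degrees
  bendMask <- rep(FALSE, n)
  if (n >= 5) for (i in 3:(n - 2)) {
    u <- bb$CA[i, ] - bb$CA[i - 2, ]
    v <- bb$CA[i + 2, ] - bb$CA[i, ]
    ang <- acos(pmin(1, pmax(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
    bendMask[i] <- ang > 70 * pi / 180
  }
  # priority H > E > B > G > I > T > S, fill only unassigned
  put <- function(lab, mask, code) { lab[mask & lab == "C"] <- code; lab }
  isBridge <- rep(FALSE, n); isBridge[bridgeRes] <- TRUE
  lab <- put(lab, h4, "H")
  lab <- put(lab, inLadder, "E")
  lab <- put(lab, isBridge & !inLadder, "B")
  lab <- put(lab, h3, "G")
  lab <- put(lab, h5, "I")
  lab <- put(lab, turnMask, "T")
  lab <- put(lab, bendMask, "S")
  lab
}

#' Default reduction of DSSP labels to reported classes
#'
#' H -> alpha-helix; E, B -> beta-sheet; T, S -> beta-turn/bend; G, I, C ->
#' coil. The pooling of T with S and the exclusion of 3-10 helix from the
#' helix class are the package defaults and can be overridden.
#'
#' @return Named character vector over the 8 DSSP labels.
#' @export
defaultSSReduction <- function() {
  c(H = "alpha-helix", G = "coil", I = "coil",
    E = "beta-sheet", B = "beta-sheet",
    T = "beta-turn/bend", S = "beta-turn/bend", C = "coil")
}

#' Assign DSSP-style secondary structure per frame
#'
#' Kabsch-Sander hydrogen bonds drive the standard pattern assignment:
#' consecutive n-turns give helices (G/H/I), bridge patterns give B/E, other
#' turns T, CA kinks above 70 degrees S, else coil. Backbone N, H, C, O must
#' be present (Pro needs no H; the chain's first residue needs no H).
#'
#' @param e a \code{ConformationalEnsemble}.
#' @param reduction label reduction map (see
#'   \code{\link{defaultSSReduction}}).
#' @return A \code{SecondaryStructureTrace}.
#' @export
assignSecondaryStructure <- function(e, reduction = defaultSSReduction()) {
  nf <- nFrames(e)
  bb1 <- .backboneFrame(e, 1)
  n <- length(bb1$res)
  noH <- which(is.na(bb1$H[, 1]) & !bb1$isPro)
  noH <- setdiff(noH, 1L)      # chain start has no amide H by construction
  if (length(noH))
    stop("residue ", bb1$res[noH[1]], " is missing its amide hydrogen",
         call. = FALSE)
  labels <- matrix("C", nf, n)
  for (f in seq_len(nf)) {
    bb <- if (f == 1) bb1 else .backboneFrame(e, f)
    labels[f, ] <- .dsspFrame(bb)
  }
  colnames(labels) <- bb1$res
  new("SecondaryStructureTrace", labels = labels, reduction = reduction)
}

#' Secondary-structure class fractions
#'
#' Fraction of residue-frame cells assigned to each reduced class; with
#' \code{perResidue = TRUE}, fractions are computed per residue over frames.
#' Classes (including coil) always sum to 1.
#'
#' @param trace a \code{SecondaryStructureTrace}.
#' @param perResidue return a residues x classes matrix instead of a global
#'   vector.
#' @return Named numeric vector of fractions, or a matrix when
#'   \code{perResidue}.
#' @export
ssFractions <- function(trace, perResidue = FALSE) {
  classes <- unique(unname(trace@reduction))
  red <- matrix(trace@reduction[trace@labels], nrow(trace@labels))
  if (perResidue) {
    out <- sapply(classes, function(cl) colMeans(red == cl))
    rownames(out) <- colnames(trace@labels)
    out
  } else {
    stats::setNames(vapply(classes, function(cl) mean(red == cl),
                           numeric(1)), classes)
  }
}
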