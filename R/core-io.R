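# Structure / ensemble I/O and trajectory preprocessing.
#
# PDB parsing and writing are delegated to bio3d; GRO is parsed here (fixed
# columns, coordinates already in nm). Coordinates are stored in nm: PDB
# Angstroms are divided by 10 on the way in and multiplied back on the way
# out. Multi-model PDB is the trajectory interchange format.

KNOWN_RESNAMES <- c(AMINO3, WATER_RESNAMES, ION_RESNAMES)

.assignRoles <- function(name, resname) {
  role <- rep("sidechain", length(name))
  role[resname %in% WATER_RESNAMES] <- "solvent"
  role[resname %in% ION_RESNAMES] <- "ion"
  pep <- !(resname %in% c(WATER_RESNAMES, ION_RESNAMES))
  role[pep & name %in% BACKBONE_NAMES] <- "backbone"
  role
}

.guessElement <- function(name, given = NULL) {
  el <- toupper(sub("^[0-9]*", "", name))
  out <- substr(el, 1, 1)
  two <- substr(el, 1, 2)
  out[two %in% c("CL", "NA", "MG", "ZN", "FE", "BR")] <- two[
    two %in% c("CL", "NA", "MG", "ZN", "FE", "BR")]
  if (!is.null(given)) {
    ok <- !is.na(given) & nzchar(trimws(given))
    out[ok] <- trimws(given)[ok]
  }
  out
}

.checkResnames <- function(resname) {
  unknown <- setdiff(unique(resname), KNOWN_RESNAMES)
  if (length(unknown))
    stop("unknown residue name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
}

# Build a validated topology from parallel atom vectors.
.buildTopology <- function(name, resid, resname, chain, element = NULL,
                           disulfidePairs = NULL) {
  .checkResnames(resname)
  atoms <- data.frame(
    name = name,
    element = .guessElement(name, element),
    resid = as.integer(resid),
    resname = resname,
    chain = chain,
    role = .assignRoles(name, resname),
    stringsAsFactors = FALSE)
  dp <- if (is.null(disulfidePairs)) matrix(integer(0), ncol = 2) else
    matrix(as.integer(disulfidePairs), ncol = 2)
  new("MolecularTopology", atoms = atoms, disulfidePairs = dp)
}

#' Construct a conformational ensemble from raw pieces
#'
#' @param topology a \code{MolecularTopology}.
#' @param coords frames x atoms x 3 array in nm (a single atoms x 3 matrix is
#'   promoted to one frame).
#' @param times frame times in ns; defaults to \code{dt * (1:frames)}.
#' @param dt native frame spacing in ns used when \code{times} is NULL.
#' @param box optional periodic cell lengths, nm.
#' @return A \code{ConformationalEnsemble}.
#' @export
makeEnsemble <- function(topology, coords, times = NULL, dt = 1,
                         box = numeric(0)) {
  if (is.matrix(coords)) coords <- array(coords, c(1, dim(coords)))
  if (is.null(times)) times <- dt * seq_len(dim(coords)[1])
  new("ConformationalEnsemble", topology = topology, coords = coords,
      times = as.numeric(times), box = as.numeric(box))
}

.preScanPDB <- function(lines) {
  rec <- grepl("^(ATOM|HETATM)", lines)
  for (i in which(rec)) {
    l <- lines[i]
    xyz <- suppressWarnings(as.numeric(c(substr(l, 31, 38), substr(l, 39, 46),
                                         substr(l, 47, 54))))
    if (nchar(l) < 54 || any(is.na(xyz)))
      stop("malformed PDB record at line ", i, ": ", trimws(l), call. = FALSE)
  }
  invisible(TRUE)
}

.topologyFromBio3d <- function(pdb) {
  a <- pdb$atom
  # re-index residues 1-based and contiguous per chain, preserving order
  key <- paste(a$chain, a$resno, a$insert)
  resid <- as.integer(factor(key, levels = unique(key)))
  dis <- .findDisulfides(a, resid)
  .buildTopology(trimws(a$elety), resid, trimws(a$resid), a$chain,
                 element = a$elesy, disulfidePairs = dis)
}

# SG-SG pairs within 0.23 nm in the first model -> disulfide bond.
.findDisulfides <- function(atom, resid) {
  sg <- which(trimws(atom$resid) == "CYS" & trimws(atom$elety) == "SG")
  if (length(sg) < 2) return(NULL)
  xyz <- as.matrix(atom[sg, c("x", "y", "z")]) / 10
  pairs <- NULL
  for (i in seq_along(sg)[-length(sg)]) for (j in (i + 1):length(sg)) {
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= 0.23)
      pairs <- rbind(pairs, c(resid[sg[i]], resid[sg[j]]))
  }
  pairs
}

#' Read a molecular structure (PDB or GRO)
#'
#' Parses a structure file into a topology plus first-frame coordinates.
#' Coordinates are returned in nm (PDB Angstroms are divided by 10). Residue
#' roles (backbone/sidechain/solvent/ion) are assigned from atom and residue
#' names; the non-standard residue ABU (alpha-aminobutyric acid) is accepted.
#'
#' @param path file path.
#' @param format "pdb" or "gro"; default guessed from the extension.
#' @return A list with \code{topology} (\code{MolecularTopology}),
#'   \code{coords} (atoms x 3 matrix, nm, first model), \code{nModels}
#'   (model count for multi-model PDB) and \code{box} (numeric(3) or
#'   numeric(0)).
#' @export
readStructure <- function(path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "pdb"
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "pdb") {
    .preScanPDB(readLines(path, warn = FALSE))
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    top <- .topologyFromBio3d(pdb)
    nmod <- nrow(pdb$xyz)
    xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE) / 10
    list(topology = top, coords = xyz, nModels = nmod, box = numeric(0))
  } else {
    .readGRO(path)
  }
}

.readGRO <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("malformed GRO record at line 2: atom count", call. = FALSE)
  if (length(lines) < n + 3) stop("truncated GRO file: expected ", n,
                                  " atom lines", call. = FALSE)
  al <- lines[3:(n + 2)]
  num <- function(s) suppressWarnings(as.numeric(s))
  x <- num(substr(al, 21, 28)); y <- num(substr(al, 29, 36))
  z <- num(substr(al, 37, 44))
  bad <- which(is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stop("malformed GRO record at line ", bad[1] + 2, ": ",
         trimws(al[bad[1]]), call. = FALSE)
  resno <- as.integer(substr(al, 1, 5))
  resname <- toupper(trimws(substr(al, 6, 10)))
  name <- trimws(substr(al, 11, 15))
  resid <- as.integer(factor(resno, levels = unique(resno)))
  top <- .buildTopology(name, resid, resname, chain = "A")
  box <- num(strsplit(trimws(lines[n + 3]), "\\s+")[[1]])[1:3]
  list(topology = top, coords = cbind(x, y, z, deparse.level = 0),
       nModels = 1L, box = box)
}

#' Read a conformational ensemble from a multi-model PDB
#'
#' @param path multi-model PDB file.
#' @param topology optional \code{MolecularTopology} to validate against; an
#'   atom-count mismatch is an error reporting expected and found counts.
#' @param dt frame spacing in ns used to synthesise times (default 1 ns);
#'   ignored when \code{times} is given.
#' @param times optional explicit frame times (ns).
#' @param box optional periodic cell (nm); when present, bonded backbone
#'   pairs are checked and a broken (wrapped) molecule raises an error.
#' @return A \code{ConformationalEnsemble}.
#' @export
readEnsemble <- function(path, topology = NULL, dt = 1, times = NULL,
                         box = numeric(0)) {
  .preScanPDB(readLines(path, warn = FALSE))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  top <- .topologyFromBio3d(pdb)
  if (!is.null(topology)) {
    if (nAtoms(topology) != nAtoms(top))
      stop(sprintf("atom-count mismatch: topology expects %d atoms, file has %d",
                   nAtoms(topology), nAtoms(top)), call. = FALSE)
    top <- topology
  }
  nf <- nrow(pdb$xyz)
  co <- array(NA_real_, c(nf, nAtoms(top), 3))
  for (f in seq_len(nf))
    co[f, , ] <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE) / 10
  e <- makeEnsemble(top, co, times = times, dt = dt, box = box)
  if (length(box)) .checkWholeMolecule(e)
  e
}

# Bonded heavy-atom pairs (N-CA, CA-C intra-residue; C-N peptide) must stay
# below 0.25 nm when a periodic box is declared; re-imaging is out of scope.
.checkWholeMolecule <- function(e, maxBond = 0.25) {
  a <- atoms(e)
  pep <- which(a$role %in% c("backbone", "sidechain"))
  res <- sort(unique(a$resid[pep]))
  idx <- function(r, nm) {
    i <- which(a$resid == r & a$name == nm)
    if (length(i)) i[1] else NA_integer_
  }
  pairs <- NULL
  for (r in res) {
    pairs <- rbind(pairs, c(idx(r, "N"), idx(r, "CA")),
                   c(idx(r, "CA"), idx(r, "C")),
                   c(idx(r, "C"), idx(r + 1, "N")))
  }
  pairs <- pairs[stats::complete.cases(pairs), , drop = FALSE]
  for (f in seq_len(nFrames(e))) {
    d <- sqrt(rowSums((e@coords[f, pairs[, 1], , drop = FALSE] -
                       e@coords[f, pairs[, 2], , drop = FALSE])^2))
    if (any(d > maxBond))
      stop("broken molecule across the periodic box in frame ", f,
           " (bonded pair at ", sprintf("%.3f", max(d)),
           " nm); re-imaging is out of scope", call. = FALSE)
  }
  invisible(TRUE)
}

#' Write an ensemble as a multi-model PDB
#'
#' @param e a \code{ConformationalEnsemble} (nm; written as Angstroms).
#' @param path output file.
#' @param frames optional frame subset.
#' @return \code{path}, invisibly.
#' @export
writeEnsemblePDB <- function(e, path, frames = seq_len(nFrames(e))) {
  a <- atoms(e)
  xyz <- matrix(NA_real_, length(frames), nAtoms(e) * 3)
  for (i in seq_along(frames))
    xyz[i, ] <- as.vector(t(e@coords[frames[i], , ])) * 10
  bio3d::write.pdb(file = path, xyz = xyz, resno = a$resid, resid = a$resname,
                   elety = a$name, chain = a$chain,
                   elesy = a$element)
  invisible(path)
}

#' Discard equilibration and stride-subsample an ensemble
#'
#' Frames with time at or before \code{discard} are removed and the remainder
#' is subsampled at \code{stride} (which must be an integer multiple of the
#' native frame spacing). Applying the same preprocessing twice is a no-op.
#'
#' @param e a \code{ConformationalEnsemble} with uniform frame spacing.
#' @param discard equilibration time to drop, ns (frames with t <= discard).
#' @param stride analysis sampling interval, ns.
#' @return The preprocessed \code{ConformationalEnsemble}.
#' @export
preprocessEnsemble <- function(e, discard = 0, stride = NULL) {
  stopifnot(discard >= 0)
  t <- frameTimes(e)
  if (length(t) > 1) {
    dt <- diff(t)
    if (max(dt) - min(dt) > 1e-6 * mean(dt))
      stop("non-uniform frame spacing; cannot stride", call. = FALSE)
    dt <- mean(dt)
  } else dt <- stride %||% 1
  if (is.null(stride)) stride <- dt
  stopifnot(stride > 0)
  step <- round(stride / dt)
  if (abs(step - stride / dt) > 1e-6)
    stop("stride must be an integer multiple of the native frame spacing (",
         signif(dt, 6), " ns)", call. = FALSE)
  keep <- which(t > discard + 1e-9)
  if (!length(keep))
    stop("discard (", discard, " ns) removes every frame", call. = FALSE)
  keep <- keep[seq(1L, length(keep), by = step)]
  makeEnsemble(topology(e), e@coords[keep, , , drop = FALSE],
               times = t[keep], box = e@box)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
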