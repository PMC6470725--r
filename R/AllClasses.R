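# Central S4 containers. Units: nm, ns, kJ/mol throughout (Kabsch-Sander
# hydrogen-bond energies are kept in kcal/mol, the DSSP convention).

BACKBONE_NAMES <- c("N", "CA", "C", "O", "H", "HN", "OXT")
WATER_RESNAMES <- c("HOH", "SOL", "WAT", "TIP3")
ION_RESNAMES   <- c("NA", "CL", "K", "MG", "CA2", "ZN", "SOD", "CLA")
AMINO3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
            "TYR", "VAL", "ABU")

#' MolecularTopology: atoms, residues and disulfide connectivity
#'
#' Ordered atom records (name, element, 1-based residue index, residue name,
#' chain, role) plus the residue-pair list of disulfide bonds. Roles partition
#' atoms into backbone / sidechain / solvent / ion; backbone means the
#' peptide-unit atoms N, CA, C, O (plus amide H/HN and OXT).
#'
#' @slot atoms data.frame with columns \code{name}, \code{element},
#'   \code{resid} (integer, 1-based), \code{resname} (3-letter code, ABU
#'   accepted), \code{chain}, \code{role}.
#' @slot disulfidePairs integer matrix with two columns of residue indices;
#'   both members must be CYS residues.
#' @export
setClass("MolecularTopology",
  representation(atoms = "data.frame", disulfidePairs = "matrix"),
  prototype(disulfidePairs = matrix(integer(0), ncol = 2)))

setValidity("MolecularTopology", function(object) {
  a <- object@atoms
  need <- c("name", "element", "resid", "resname", "chain", "role")
  if (!all(need %in% names(a)))
    return(paste("atom table must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) == 0) return("empty atom table")
  if (!all(a$role %in% c("backbone", "sidechain", "solvent", "ion")))
    return("roles must be backbone/sidechain/solvent/ion")
  pep <- a$role %in% c("backbone", "sidechain")
  bb <- pep & a$name %in% BACKBONE_NAMES
  if (any(a$role[bb] != "backbone"))
    return("backbone-named peptide atoms must carry the backbone role")
  if (any(a$role[pep & !bb] != "sidechain"))
    return("non-backbone peptide atoms must carry the sidechain role")
  dp <- object@disulfidePairs
  if (ncol(dp) != 2) return("disulfidePairs must have 2 columns")
  if (nrow(dp) > 0) {
    resnames <- vapply(seq_len(nrow(dp)), function(i) {
      all(a$resname[a$resid %in% dp[i, ]] == "CYS")
    }, logical(1))
    if (!all(resnames)) return("disulfide pairs must reference CYS residues")
  }
  TRUE
})

#' ConformationalEnsemble: frames x atoms x 3 coordinates with times
#'
#' @slot topology a \code{MolecularTopology}.
#' @slot coords numeric array (frames, atoms, 3), nm, all finite.
#' @slot times numeric, ns per frame, strictly increasing.
#' @slot box optional periodic cell lengths (nm), numeric(3) or numeric(0).
#' @export
setClass("ConformationalEnsemble",
  representation(topology = "MolecularTopology", coords = "array",
                 times = "numeric", box = "numeric"),
  prototype(box = numeric(0)))

setValidity("ConformationalEnsemble", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3 || d[3] != 3)
    return("coords must be a frames x atoms x 3 array")
  if (d[2] != nrow(object@topology@atoms))
    return(sprintf("coordinate atom count (%d) does not match topology (%d)",
                   d[2], nrow(object@topology@atoms)))
  if (!all(is.finite(object@coords))) return("coordinates must be finite")
  if (length(object@times) != d[1])
    return("times length must equal frame count")
  if (d[1] > 1 && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  if (!length(object@box) %in% c(0L, 3L))
    return("box must be numeric(0) or numeric(3)")
  TRUE
})

#' DihedralSeries: per-frame, per-residue backbone (phi, psi) angles
#'
#' Angles in radians in (-pi, pi]. phi is undefined for the first residue of
#' a chain and psi for the last; the residue index range stored here excludes
#' them.
#'
#' @slot phi,psi numeric matrices frames x residues (radians).
#' @slot residues integer vector of author (1-based) residue numbers, one per
#'   column of \code{phi}/\code{psi}.
#' @export
setClass("DihedralSeries",
  representation(phi = "matrix", psi = "matrix", residues = "integer"))

setValidity("DihedralSeries", function(object) {
  if (!identical(dim(object@phi), dim(object@psi)))
    return("phi and psi must have identical dimensions")
  if (ncol(object@phi) != length(object@residues))
    return("residue index length must match angle columns")
  ang <- c(object@phi, object@psi)
  if (any(ang <= -pi - 1e-9 | ang > pi + 1e-9))
    return("angles must lie in (-pi, pi]")
  TRUE
})

#' SecondaryStructureTrace: per-frame DSSP labels and their reduction
#'
#' Labels are the eight DSSP states H, G, I, E, B, T, S, C. The reduction map
#' pools them into the reported classes (alpha-helix, beta-sheet,
#' beta-turn/bend, coil) and is configurable.
#'
#' @slot labels character matrix frames x residues.
#' @slot reduction named character vector mapping each of the 8 labels to a
#'   reduced class name.
#' @export
setClass("SecondaryStructureTrace",
  representation(labels = "matrix", reduction = "character"))

setValidity("SecondaryStructureTrace", function(object) {
  lab <- unique(as.vector(object@labels))
  if (!all(lab %in% names(object@reduction)))
    return("all labels must be covered by the reduction map")
  if (!all(c("H", "G", "I", "E", "B", "T", "S", "C") %in%
           names(object@reduction)))
    return("reduction map must cover the 8 DSSP labels")
  TRUE
})

#' ContactMap: residue-residue contact probabilities
#'
#' @slot map symmetric numeric matrix of contact probabilities in [0,1];
#'   diagonal 1; entries NA where a residue has no atoms of the requested
#'   role (e.g. Gly sidechains).
#' @slot mode "BB-BB" or "SC-SC".
#' @slot cutoff heavy-atom distance cutoff in nm.
#' @export
setClass("ContactMap",
  representation(map = "matrix", mode = "character", cutoff = "numeric"))

setValidity("ContactMap", function(object) {
  m <- object@map
  if (nrow(m) != ncol(m)) return("map must be square")
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-12, check.attributes = FALSE)))
    return("map must be symmetric")
  v <- m[!is.na(m)]
  if (any(v < -1e-12 | v > 1 + 1e-12)) return("probabilities must be in [0,1]")
  TRUE
})

#' DPCAModel: principal components of sin/cos-encoded dihedrals
#'
#' @slot center mean vector (length p).
#' @slot vectors p x K matrix of orthonormal eigenvector columns.
#' @slot values eigenvalues, non-increasing, >= 0 (within round-off).
#' @export
setClass("DPCAModel",
  representation(center = "numeric", vectors = "matrix", values = "numeric"))

setValidity("DPCAModel", function(object) {
  V <- object@vectors
  if (nrow(V) != length(object@center)) return("center/vectors mismatch")
  g <- crossprod(V)
  if (max(abs(g - diag(ncol(V)))) > 1e-8)
    return("eigenvector columns must be orthonormal")
  if (is.unsorted(rev(object@values), strictly = FALSE))
    return("eigenvalues must be non-increasing")
  TRUE
})

#' FELGrid: free-energy landscape over a 2-D projection
#'
#' Per-bin occupation probabilities rho(x, y) converted to free energies
#' Delta G = -R T log(rho / rho_max) in kJ/mol. Empty bins are masked (NA),
#' never reported as zero or as a large energy; the modal bin is exactly 0.
#'
#' @slot xbreaks,ybreaks bin edges along the two components.
#' @slot counts integer matrix of per-bin frame counts.
#' @slot deltaG numeric matrix (kJ/mol); NA on empty bins; min 0.
#' @slot temperature Kelvin.
#' @export
setClass("FELGrid",
  representation(xbreaks = "numeric", ybreaks = "numeric", counts = "matrix",
                 deltaG = "matrix", temperature = "numeric"))

setValidity("FELGrid", function(object) {
  if (!identical(dim(object@counts), dim(object@deltaG)))
    return("counts and deltaG must share dimensions")
  if (nrow(object@counts) != length(object@xbreaks) - 1 ||
      ncol(object@counts) != length(object@ybreaks) - 1)
    return("grid dimensions must match bin edges")
  occ <- object@counts > 0
  if (any(is.na(object@deltaG[occ]))) return("occupied bins must have deltaG")
  if (any(!is.na(object@deltaG[!occ]))) return("empty bins must be masked NA")
  if (any(occ) && abs(min(object@deltaG[occ])) > 1e-12)
    return("minimum deltaG over occupied bins must be exactly 0")
  TRUE
})

#' ClusterModel: k-means partition of a 2-D projection
#'
#' @slot k number of clusters.
#' @slot assignment integer vector, one entry per frame, values in 1..k.
#' @slot centers k x 2 matrix of centroids in (dPC1, dPC2).
#' @slot sse total within-cluster sum of squared errors.
#' @slot silWidth average silhouette width.
#' @slot silCoef silhouette coefficient (max per-cluster mean width).
#' @slot seed RNG seed used for the restarts.
#' @export
setClass("ClusterModel",
  representation(k = "integer", assignment = "integer", centers = "matrix",
                 sse = "numeric", silWidth = "numeric", silCoef = "numeric",
                 seed = "integer"))

setValidity("ClusterModel", function(object) {
  if (any(object@assignment < 1L | object@assignment > object@k))
    return("assignments must lie in 1..k")
  if (nrow(object@centers) != object@k) return("one centroid per cluster")
  TRUE
})

#' EssentialBasis: top eigenvectors of a Calpha-coordinate covariance
#'
#' @slot vectors d x N matrix, orthonormal columns, d = 3 * n_Calpha.
#' @slot values eigenvalues in nm^2, non-increasing.
#' @slot selection integer atom indices the basis was computed on.
#' @slot frames number of frames used.
#' @export
setClass("EssentialBasis",
  representation(vectors = "matrix", values = "numeric",
                 selection = "integer", frames = "integer"))

setValidity("EssentialBasis", function(object) {
  V <- object@vectors
  if (max(abs(crossprod(V) - diag(ncol(V)))) > 1e-8)
    return("basis columns must be orthonormal")
  if (any(object@values < -1e-10)) return("eigenvalues must be >= 0")
  if (is.unsorted(rev(object@values))) return("eigenvalues must be sorted")
  TRUE
})

## ---- accessors ------------------------------------------------------------

#' @rdname nFrames
#' @export
setMethod("nFrames", "ConformationalEnsemble", function(x) dim(x@coords)[1])
#' @rdname nFrames
#' @export
setMethod("nFrames", "DihedralSeries", function(x) nrow(x@phi))
#' @rdname nFrames
#' @export
setMethod("nFrames", "SecondaryStructureTrace", function(x) nrow(x@labels))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "MolecularTopology", function(x) nrow(x@atoms))
#' @rdname nAtoms
#' @export
setMethod("nAtoms", "ConformationalEnsemble", function(x) dim(x@coords)[2])

#' @rdname nResidues
#' @export
setMethod("nResidues", "MolecularTopology",
          function(x) length(unique(x@atoms$resid[
            x@atoms$role %in% c("backbone", "sidechain")])))
#' @rdname nResidues
#' @export
setMethod("nResidues", "ConformationalEnsemble",
          function(x) nResidues(x@topology))
#' @rdname nResidues
#' @export
setMethod("nResidues", "DihedralSeries", function(x) length(x@residues))
#' @rdname nResidues
#' @export
setMethod("nResidues", "SecondaryStructureTrace", function(x) ncol(x@labels))

#' @rdname atoms
#' @export
setMethod("atoms", "MolecularTopology", function(x) x@atoms)
#' @rdname atoms
#' @export
setMethod("atoms", "ConformationalEnsemble", function(x) x@topology@atoms)

#' @rdname topology
#' @export
setMethod("topology", "ConformationalEnsemble", function(x) x@topology)

#' @rdname coords
#' @export
setMethod("coords", "ConformationalEnsemble", function(x) x@coords)

#' @rdname frameTimes
#' @export
setMethod("frameTimes", "ConformationalEnsemble", function(x) x@times)

## ---- show methods ---------------------------------------------------------

setMethod("show", "MolecularTopology", function(object) {
  a <- object@atoms
  cat("MolecularTopology:", nrow(a), "atoms,",
      nResidues(object), "peptide residues\n")
  tab <- table(a$role)
  cat("  roles:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if (nrow(object@disulfidePairs))
    cat("  disulfides:", paste(apply(object@disulfidePairs, 1, paste,
                                     collapse = "-"), collapse = ", "), "\n")
})

setMethod("show", "ConformationalEnsemble", function(object) {
  cat("ConformationalEnsemble:", nFrames(object), "frames x",
      nAtoms(object), "atoms\n")
  t <- object@times
  cat(sprintf("  time %.4g..%.4g ns", t[1], t[length(t)]))
  if (length(object@box)) cat(sprintf("; box %.3g x %.3g x %.3g nm",
                                      object@box[1], object@box[2],
                                      object@box[3]))
  cat("\n")
})

setMethod("show", "DihedralSeries", function(object) {
  cat("DihedralSeries:", nFrames(object), "frames, residues",
      object@residues[1], "..", object@residues[length(object@residues)], "\n")
})

setMethod("show", "FELGrid", function(object) {
  occ <- sum(object@counts > 0)
  cat(sprintf("FELGrid: %d x %d bins, %d occupied, T = %g K, max dG = %.2f kJ/mol\n",
              nrow(object@counts), ncol(object@counts), occ,
              object@temperature, max(object@deltaG, na.rm = TRUE)))
})

setMethod("show", "EssentialBasis", function(object) {
  cat(sprintf("EssentialBasis: %d vectors in d = %d (from %d frames)\n",
              ncol(object@vectors), nrow(object@vectors), object@frames))
})

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel: k = %d, SSE = %.4g, avg silhouette = %.3f\n",
              object@k, object@sse, object@silWidth))
})

setMethod("show", "ContactMap", function(object) {
  cat(sprintf("ContactMap (%s, cutoff %.2f nm): %d residues\n",
              object@mode, object@cutoff, nrow(object@map)))
})

setMethod("show", "SecondaryStructureTrace", function(object) {
  cat("SecondaryStructureTrace:", nFrames(object), "frames x",
      nResidues(object), "residues\n")
})

setMethod("show", "DPCAModel", function(object) {
  cat(sprintf("DPCAModel: p = %d, %d components, top eigenvalues: %s\n",
              length(object@center), ncol(object@vectors),
              paste(signif(head(object@values, 3), 3), collapse = ", ")))
})
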