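#' @import methods
#' @importFrom stats setNames sd quantile kmeans rnorm runif cov var
#' @importFrom utils write.csv head tail
NULL

#' Number of frames in an ensemble-like object
#'
#' @param x an object holding per-frame data.
#' @return Integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Number of atoms
#'
#' @param x a topology or ensemble.
#' @return Integer atom count.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Number of residues
#'
#' @param x a topology, ensemble or per-residue trace.
#' @return Integer residue count.
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' Atom table of a topology-bearing object
#'
#' @param x a \code{MolecularTopology} or \code{ConformationalEnsemble}.
#' @return A data.frame with one row per atom (name, element, residue index,
#'   residue name, chain, role).
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' Topology of an ensemble
#'
#' @param x a \code{ConformationalEnsemble}.
#' @return The \code{MolecularTopology}.
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' Coordinate array of an ensemble
#'
#' @param x a \code{ConformationalEnsemble}.
#' @return Numeric array frames x atoms x 3, in nm.
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' Frame times
#'
#' @param x a \code{ConformationalEnsemble}.
#' @return Numeric vector of frame times in ns, strictly increasing.
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
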