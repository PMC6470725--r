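# Atom selections: residue ranges plus role filters, either as arguments or
# as a compact expression like "resid 2-35 and backbone".

#' Select atom indices from a topology
#'
#' Filters may be passed as arguments or as a selection expression of
#' space-separated clauses joined with \code{and}: \code{"resid 2-35"},
#' \code{"name CA"}, \code{"backbone"}, \code{"sidechain"}, \code{"protein"},
#' \code{"solvent"}, \code{"heavy"}.
#'
#' @param x a \code{MolecularTopology} or \code{ConformationalEnsemble}.
#' @param expr optional selection expression.
#' @param resid optional integer vector of residue indices.
#' @param role optional subset of backbone/sidechain/solvent/ion.
#' @param name optional atom-name subset.
#' @param heavyOnly drop hydrogens if TRUE.
#' @return Sorted integer vector of atom indices.
#' @export
selectAtoms <- function(x, expr = NULL, resid = NULL, role = NULL,
                        name = NULL, heavyOnly = FALSE) {
  a <- if (is(x, "ConformationalEnsemble")) atoms(x) else x@atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(expr)) {
    for (clause in strsplit(expr, "\\s+and\\s+")[[1]]) {
      toks <- strsplit(trimws(clause), "\\s+")[[1]]
      keep <- keep & switch(toks[1],
        resid = {
          parts <- unlist(strsplit(paste(toks[-1], collapse = ","), ","))
          ids <- unlist(lapply(parts[nzchar(parts)], function(p) {
            if (grepl("-", p)) {
              ab <- as.integer(strsplit(p, "-")[[1]])
              seq(ab[1], ab[2])
            } else as.integer(p)
          }))
          a$resid %in% ids
        },
        name = a$name %in% toks[-1],
        backbone = a$role == "backbone",
        sidechain = a$role == "sidechain",
        protein = a$role %in% c("backbone", "sidechain"),
        solvent = a$role == "solvent",
        heavy = a$element != "H",
        stop("unknown selection clause: ", clause, call. = FALSE))
    }
  }
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  if (!is.null(role)) keep <- keep & a$role %in% role
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (heavyOnly) keep <- keep & a$element != "H"
  which(keep)
}

# Calpha indices ordered by residue, with an error when one is missing.
.caIndices <- function(top, resid = NULL) {
  a <- top@atoms
  pep <- a$role %in% c("backbone", "sidechain")
  res <- sort(unique(a$resid[pep]))
  if (!is.null(resid)) res <- intersect(res, resid)
  idx <- vapply(res, function(r) {
    i <- which(a$resid == r & a$name == "CA")
    if (!length(i)) stop("residue ", r, " has no CA atom", call. = FALSE)
    i[1]
  }, integer(1))
  stats::setNames(idx, res)
}
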