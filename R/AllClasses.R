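#' @import methods
NULL

.ATOM_COLS <- c("serial", "atom", "element", "resname", "resseq",
                "chain", "x", "y", "z", "occ", "b")

#' StructureModel: one predicted enzyme-substrate complex
#'
#' Holds the atoms of a single two-chain coordinate model together with the
#' role assignment (which chain is the protease, which the candidate
#' propeptide substrate) and a free-text pair label such as \code{"MC9--PP3"}.
#' Atoms are stored as a data.frame with one row per atom and columns
#' \code{serial}, \code{atom} (atom name, e.g. \code{"SG"}, \code{"CA"}),
#' \code{element}, \code{resname} (3-letter code), \code{resseq} (residue
#' number as in the source file), \code{chain}, \code{x}, \code{y}, \code{z}
#' (Angstrom), \code{occ} and \code{b}.
#'
#' @slot atoms data.frame of atoms, in file order.
#' @slot enzymeChain single-character chain id of the protease chain.
#' @slot substrateChain single-character chain id of the substrate chain.
#' @slot label free-text pair identifier.
#' @aliases StructureModel
#' @exportClass StructureModel
setClass("StructureModel",
         representation(atoms = "data.frame",
                        enzymeChain = "character",
                        substrateChain = "character",
                        label = "character"))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  msgs <- character()
  missing_cols <- setdiff(.ATOM_COLS, names(a))
  if (length(missing_cols))
    msgs <- c(msgs, paste("atoms lacks columns:",
                          paste(missing_cols, collapse = ", ")))
  if (length(object@enzymeChain) != 1L || length(object@substrateChain) != 1L)
    msgs <- c(msgs, "enzymeChain and substrateChain must be single strings")
  else {
    if (identical(object@enzymeChain, object@substrateChain))
      msgs <- c(msgs, "enzyme and substrate chain ids must differ")
    if (!length(missing_cols)) {
      if (!any(a$chain == object@enzymeChain))
        msgs <- c(msgs, sprintf("no atoms on enzyme chain '%s'",
                                object@enzymeChain))
      if (!any(a$chain == object@substrateChain))
        msgs <- c(msgs, sprintf("no atoms on substrate chain '%s'",
                                object@substrateChain))
      if (nrow(a) && !all(is.finite(c(a$x, a$y, a$z))))
        msgs <- c(msgs, "non-finite atom coordinates")
      if (nrow(a) && any(!nzchar(a$element)))
        msgs <- c(msgs, "empty element symbols")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a StructureModel
#'
#' @param atoms data.frame of atoms (see \linkS4class{StructureModel}).
#' @param enzymeChain,substrateChain chain ids taking the enzyme and
#'   substrate roles; must both occur in \code{atoms$chain} and differ.
#' @param label optional pair label.
#' @return A \linkS4class{StructureModel}.
#' @export
StructureModel <- function(atoms, enzymeChain, substrateChain,
                           label = "complex") {
  atoms <- as.data.frame(atoms)[, .ATOM_COLS]
  rownames(atoms) <- NULL
  new("StructureModel", atoms = atoms,
      enzymeChain = as.character(enzymeChain),
      substrateChain = as.character(substrateChain),
      label = as.character(label))
}

#' @describeIn StructureModel accessor for the atom table.
#' @param object,x a \code{StructureModel}.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname StructureModel
#' @export
setMethod("atoms", "StructureModel", function(x) x@atoms)

#' @rdname StructureModel
#' @export
setGeneric("enzymeChain", function(x) standardGeneric("enzymeChain"))

#' @rdname StructureModel
#' @export
setMethod("enzymeChain", "StructureModel", function(x) x@enzymeChain)

#' @rdname StructureModel
#' @export
setGeneric("substrateChain", function(x) standardGeneric("substrateChain"))

#' @rdname StructureModel
#' @export
setMethod("substrateChain", "StructureModel", function(x) x@substrateChain)

#' @rdname StructureModel
#' @export
setGeneric("modelLabel", function(x) standardGeneric("modelLabel"))

#' @rdname StructureModel
#' @export
setMethod("modelLabel", "StructureModel", function(x) x@label)

#' Atoms of one role-tagged chain
#'
#' @param model a \linkS4class{StructureModel}.
#' @param role \code{"enzyme"} or \code{"substrate"}.
#' @return data.frame of the atoms on that chain.
#' @export
chainAtoms <- function(model, role = c("enzyme", "substrate")) {
  role <- match.arg(role)
  ch <- if (role == "enzyme") model@enzymeChain else model@substrateChain
  model@atoms[model@atoms$chain == ch, , drop = FALSE]
}

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  cat("StructureModel '", object@label, "': ", nrow(a), " atoms\n", sep = "")
  cat("  enzyme chain ", object@enzymeChain, " (",
      sum(a$chain == object@enzymeChain), " atoms), substrate chain ",
      object@substrateChain, " (",
      sum(a$chain == object@substrateChain), " atoms)\n", sep = "")
})

#' PredictionMatrix: enzymes x substrates screen decisions
#'
#' Grid of screening outcomes for a batch of predicted complexes, one cell
#' per (enzyme, substrate) pair holding the three filter metrics and the
#' accept/reject decision.
#'
#' @slot enzymes ordered enzyme labels (rows).
#' @slot substrates ordered substrate labels (columns).
#' @slot cells named list keyed \code{"<enzyme>|<substrate>"}; each element
#'   is a list with components \code{metrics} and \code{decision} (and
#'   optionally \code{error} for pairs that failed to process).
#' @exportClass PredictionMatrix
setClass("PredictionMatrix",
         representation(enzymes = "character",
                        substrates = "character",
                        cells = "list"))

setValidity("PredictionMatrix", function(object) {
  if (!length(object@cells)) return(TRUE)
  keys <- names(object@cells)
  if (is.null(keys))
    return("cells must be a named list")
  if (anyDuplicated(keys))
    return("duplicate (enzyme, substrate) pair")
  parts <- strsplit(keys, "|", fixed = TRUE)
  ok <- vapply(parts, function(p)
    length(p) == 2L && p[1] %in% object@enzymes && p[2] %in% object@substrates,
    logical(1))
  if (length(ok) && !all(ok))
    return("cell keys must be '<enzyme>|<substrate>' over the declared labels")
  TRUE
})

#' Verdict grid of a PredictionMatrix
#'
#' @param pm a \linkS4class{PredictionMatrix}.
#' @return character matrix (enzymes x substrates) of
#'   \code{"predicted-substrate"} / \code{"rejected"}, \code{"error"} for
#'   failed pairs, \code{NA} for missing pairs.
#' @export
verdictMatrix <- function(pm) {
  m <- matrix(NA_character_, length(pm@enzymes), length(pm@substrates),
              dimnames = list(pm@enzymes, pm@substrates))
  for (key in names(pm@cells)) {
    p <- strsplit(key, "|", fixed = TRUE)[[1]]
    cell <- pm@cells[[key]]
    m[p[1], p[2]] <- if (!is.null(cell$error)) "error" else
      cell$decision$verdict
  }
  m
}

#' Long-format metrics of a PredictionMatrix
#'
#' @param pm a \linkS4class{PredictionMatrix}.
#' @return data.frame with one row per screened pair: labels, the three
#'   filter metrics, verdict and failing filter.
#' @export
metricsTable <- function(pm) {
  rows <- lapply(names(pm@cells), function(key) {
    p <- strsplit(key, "|", fixed = TRUE)[[1]]
    cell <- pm@cells[[key]]
    if (!is.null(cell$error))
      return(data.frame(enzyme = p[1], substrate = p[2], clash_count = NA,
                        bsa = NA, min_distance = NA, verdict = "error",
                        failed_filter = NA_character_))
    m <- cell$metrics
    data.frame(enzyme = p[1], substrate = p[2],
               clash_count = m$clash_count, bsa = m$bsa,
               min_distance = m$min_distance,
               verdict = cell$decision$verdict,
               failed_filter = cell$decision$failed_filter)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

setMethod("show", "PredictionMatrix", function(object) {
  cat("PredictionMatrix: ", length(object@enzymes), " enzymes x ",
      length(object@substrates), " substrates, ",
      length(object@cells), " screened pairs\n", sep = "")
  if (length(object@cells)) print(verdictMatrix(object))
})

#' PartitionResult: per-gene dependence classification
#'
#' Assignment of every differentially expressed gene to one dependence class
#' (a cell of the WT / atmc4-1 / atmc9-1 significance Venn), a Pep1
#' responsiveness status and a marker group.
#'
#' @slot assignments data.frame with columns \code{gene_id}, \code{class},
#'   \code{pep1_status} (\code{pep_plus} / \code{pep_minus} /
#'   \code{not_applicable}) and \code{marker_group}.
#' @slot pepPlusMode \code{"pep1_only"} or \code{"pep1_or_propep1"}, or
#'   \code{"unavailable"} when no Pep1 contrast was supplied.
#' @exportClass PartitionResult
setClass("PartitionResult",
         representation(assignments = "data.frame",
                        pepPlusMode = "character"))

setValidity("PartitionResult", function(object) {
  a <- object@assignments
  need <- c("gene_id", "class", "pep1_status", "marker_group")
  if (!all(need %in% names(a)))
    return(paste("assignments needs columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(a$gene_id))
    return("duplicate gene_id in assignments")
  if (!all(a$class %in% DEPENDENCE_CLASSES))
    return("unknown dependence class")
  if (!all(a$pep1_status %in% c("pep_plus", "pep_minus", "not_applicable")))
    return("unknown pep1_status")
  if (!all(a$marker_group %in% MARKER_GROUPS))
    return("unknown marker group")
  TRUE
})

#' @rdname PartitionResult-class
#' @param x a \code{PartitionResult}.
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))

#' @rdname PartitionResult-class
#' @export
setMethod("assignments", "PartitionResult", function(x) x@assignments)

setMethod("show", "PartitionResult", function(object) {
  a <- object@assignments
  cat("PartitionResult: ", nrow(a), " genes (pep_plus mode: ",
      object@pepPlusMode, ")\n", sep = "")
  if (nrow(a)) print(table(factor(a$class, levels = DEPENDENCE_CLASSES)))
})
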