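#' Van der Waals radii table
#'
#' Bondi-style van der Waals radii used by the clash and SASA computations.
#' The default table ships as a two-column text file
#' (\code{extdata/vdw_radii.tsv}) covering C, N, O, S, P and H; elements not
#' in the table fall back to the default radius.
#'
#' @param path optional path to a two-column (element, radius) table;
#'   defaults to the file shipped with the package.
#' @param default radius (Angstrom) for elements absent from the table.
#' @return An object of class \code{RadiiTable}: a named numeric vector of
#'   radii with a \code{default} attribute.
#' @export
defaultRadii <- function(path = system.file("extdata", "vdw_radii.tsv",
                                            package = "MCwound"),
                         default = 1.70) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("element", "radius") %in% names(tab)))
    .stop("mcwoundFormatError", "radii table needs columns element, radius")
  r <- tab$radius
  names(r) <- toupper(tab$element)
  if (any(r <= 0) || default <= 0)
    .stop("mcwoundFormatError", "van der Waals radii must be positive")
  structure(r, default = default, class = "RadiiTable")
}

#' Look up van der Waals radii for element symbols
#'
#' @param radii a \code{RadiiTable} from \code{\link{defaultRadii}}.
#' @param elements character vector of element symbols.
#' @return numeric vector of radii (Angstrom), using the table's default for
#'   unknown elements.
#' @export
radiusFor <- function(radii, elements) {
  r <- unname(radii[toupper(elements)])
  r[is.na(r)] <- attr(radii, "default")
  r
}

# Element from a PDB atom name when columns 77-78 are blank: first
# alphabetic character (AlphaFold-style models use plain C/N/O/S names).
.elementFromName <- function(name) {
  stripped <- gsub("[^A-Za-z]", "", name)
  toupper(substr(stripped, 1L, 1L))
}

#' Read a predicted complex from a PDB file
#'
#' Parses ATOM/HETATM records (wwPDB fixed columns, via \pkg{bio3d}),
#' drops waters (HOH) and alternate locations other than \code{' '}/\code{'A'},
#' and tags the two named chains with their enzyme/substrate roles. Elements
#' come from columns 77-78 when present, otherwise from the atom name.
#' Residue numbering is kept exactly as in the file.
#'
#' @param path PDB file.
#' @param enzymeChain,substrateChain chain ids carrying the two roles.
#' @param label pair label; defaults to the file name without extension.
#' @return A \linkS4class{StructureModel} with atoms in file order.
#' @export
readStructure <- function(path, enzymeChain, substrateChain, label = NULL) {
  if (!file.exists(path))
    .stop("mcwoundFormatError", "no such file: %s", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, rm.alt = TRUE, verbose = FALSE),
    error = function(e) .stop("mcwoundFormatError",
                              "cannot parse PDB file %s: %s",
                              path, conditionMessage(e)))
  a <- pdb$atom
  a <- a[a$resid != "HOH", , drop = FALSE]
  if (!nrow(a))
    .stop("mcwoundFormatError", "no non-water ATOM/HETATM records in %s", path)
  elem <- a$elesy
  blank <- is.na(elem) | !nzchar(trimws(elem))
  elem[blank] <- .elementFromName(a$elety[blank])
  atoms <- data.frame(serial = a$eleno,
                      atom = trimws(a$elety),
                      element = toupper(trimws(elem)),
                      resname = trimws(a$resid),
                      resseq = a$resno,
                      chain = as.character(a$chain),
                      x = a$x, y = a$y, z = a$z,
                      occ = ifelse(is.na(a$o), 1, a$o),
                      b = ifelse(is.na(a$b), 0, a$b),
                      stringsAsFactors = FALSE)
  for (ch in unique(c(enzymeChain, substrateChain)))
    if (!any(atoms$chain == ch))
      .stop("mcwoundChainError", "chain '%s' absent from %s", ch, path)
  if (is.null(label))
    label <- sub("\\.[^.]*$", "", basename(path))
  StructureModel(atoms, enzymeChain, substrateChain, label)
}

#' Write a StructureModel as a PDB file
#'
#' Emits standard ATOM records with 8.3 fixed-point coordinates, a TER
#' record between chains (each TER consumes one serial, per PDB convention)
#' and a terminal END. If any serial would exceed 99,999 the whole model is
#' renumbered from 1 with a warning (generated fixtures never get that
#' large).
#'
#' @param model a \linkS4class{StructureModel}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeStructure <- function(model, path) {
  a <- atoms(model)
  serial <- a$serial
  nTer <- length(unique(a$chain))  # TER records consume serials too
  if (any(serial + nTer > 99999L)) {
    warning("atom serials exceed 99999; renumbering model from 1")
    serial <- seq_len(nrow(a))
  }
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)),
                   eleno = serial,
                   elety = a$atom,
                   resid = a$resname,
                   resno = a$resseq,
                   chain = a$chain,
                   o = a$occ, b = a$b,
                   elesy = a$element,
                   chainter = TRUE, end = TRUE)
  invisible(path)
}

#' Excise an inter-domain linker from a protein sequence
#'
#' Type II metacaspase zymogens carry a linker between the p20 and p10
#' domains that can occlude the catalytic site in predicted structures; the
#' screen therefore deletes the linker residues before structure prediction.
#' Positions are 1-based and inclusive. The linker ranges are inputs (they
#' differ per enzyme and are not hard-coded).
#'
#' @param sequence amino-acid string.
#' @param startRes,endRes first and last residue of the linker
#'   (1 <= startRes <= endRes <= nchar(sequence)).
#' @return the sequence with positions \code{startRes..endRes} removed.
#' @export
exciseLinker <- function(sequence, startRes, endRes) {
  n <- nchar(sequence)
  if (!(startRes >= 1 && startRes <= endRes && endRes <= n))
    .stop("mcwoundRangeError",
          "linker range %d..%d outside sequence of length %d",
          startRes, endRes, n)
  out <- paste0(substr(sequence, 1L, startRes - 1L),
                substr(sequence, endRes + 1L, n))
  if (!nzchar(out))
    .stop("mcwoundRangeError", "linker excision would remove entire sequence")
  out
}

#' Specify the catalytic atom of an enzyme
#'
#' Names the active-site cysteine thiol sulfur (atom \code{"SG"}; residue
#' C139 in AtMC4, or the equivalent in the other metacaspases) that the
#' proximity filter measures from.
#'
#' @param chain chain id.
#' @param resSeq residue number (file numbering).
#' @param atomName atom name, default \code{"SG"}.
#' @return a \code{catalyticSite} list.
#' @export
catalyticSite <- function(chain, resSeq, atomName = "SG") {
  structure(list(chain = as.character(chain), resSeq = as.integer(resSeq),
                 atomName = as.character(atomName)),
            class = "catalyticSite")
}

#' Locate a uniquely specified atom in a model
#'
#' @param model a \linkS4class{StructureModel}.
#' @param site a \code{\link{catalyticSite}}.
#' @return one-row data.frame: the matching atom.
#' @export
locateAtom <- function(model, site) {
  a <- atoms(model)
  hit <- a$chain == site$chain & a$resseq == site$resSeq &
    a$atom == site$atomName
  n <- sum(hit)
  if (n == 0L)
    .stop("mcwoundSiteError",
          "catalytic atom %s not found at chain %s residue %d",
          site$atomName, site$chain, site$resSeq)
  if (n > 1L)
    .stop("mcwoundSiteError",
          "catalytic atom %s at chain %s residue %d is ambiguous (%d matches)",
          site$atomName, site$chain, site$resSeq, n)
  a[hit, , drop = FALSE]
}
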