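#' Independent oracles for fixture ground truth
#'
#' Deliberately naive reference computations used to stamp synthetic
#' fixtures with their true metrics. They share no code with the production
#' paths they check: the clash oracle enumerates all inter-chain pairs from
#' a full distance matrix, the minimum-distance oracle is an exhaustive
#' scan, and the interface-area oracle runs the quadrature at four times the
#' production density.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param radii a \code{RadiiTable}.
#' @param overlapThreshold clash overlap threshold, Angstrom.
#' @return \code{oracleClashCount}: integer inter-chain clash count.
#' @name oracles
#' @export
oracleClashCount <- function(model, radii = defaultRadii(),
                             overlapThreshold = 0.4) {
  enz <- chainAtoms(model, "enzyme")
  sub <- chainAtoms(model, "substrate")
  enz <- enz[!(enz$element %in% c("H", "D")), , drop = FALSE]
  sub <- sub[!(sub$element %in% c("H", "D")), , drop = FALSE]
  re <- radiusFor(radii, enz$element)
  rs <- radiusFor(radii, sub$element)
  d <- sqrt(outer(enz$x, sub$x, "-")^2 +
            outer(enz$y, sub$y, "-")^2 +
            outer(enz$z, sub$z, "-")^2)
  sum(outer(re, rs, "+") - d >= overlapThreshold)
}

#' @rdname oracles
#' @param site a \code{\link{catalyticSite}}.
#' @return \code{oracleMinDistance}: minimum catalytic-atom-to-substrate
#'   heavy-atom distance, Angstrom.
#' @export
oracleMinDistance <- function(model, site) {
  cat_atom <- locateAtom(model, site)
  sub <- chainAtoms(model, "substrate")
  sub <- sub[!(sub$element %in% c("H", "D")), , drop = FALSE]
  best <- Inf
  for (i in seq_len(nrow(sub))) {
    d <- sqrt((sub$x[i] - cat_atom$x)^2 + (sub$y[i] - cat_atom$y)^2 +
              (sub$z[i] - cat_atom$z)^2)
    if (d < best) best <- d
  }
  best
}

#' @rdname oracles
#' @param probe probe radius, Angstrom.
#' @param nPoints the production quadrature density; the oracle uses
#'   4 times this many points.
#' @return \code{oracleBsa}: buried interface area at high quadrature
#'   density, Angstrom^2.
#' @export
oracleBsa <- function(model, radii = defaultRadii(), probe = 1.4,
                      nPoints = 960) {
  buriedInterfaceArea(model, radii, probe, nPoints = 4L * nPoints)
}
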