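#' Deterministic quasi-uniform points on the unit sphere
#'
#' Golden-spiral (Fibonacci) construction; fully deterministic, so every
#' SASA value in the package is exactly reproducible. Points are fixed in
#' the model's coordinate frame: rotating a structure changes SASA only at
#' the quadrature-noise level.
#'
#' @param n number of points (>= 1).
#' @return n x 3 matrix of unit vectors.
#' @export
spherePoints <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    .stop("mcwoundRangeError", "n must be a single integer >= 1")
  n <- as.integer(n)
  k <- seq_len(n)
  z <- 1 - (2 * k - 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (k - 1) * pi * (3 - sqrt(5))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# Heavy-atom filter shared by all metrics (predicted models lack hydrogens,
# but robustness is cheap).
.dropH <- function(a, includeHydrogens) {
  if (includeHydrogens) a else a[!(a$element %in% c("H", "D")), , drop = FALSE]
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over the van der Waals surface: each atom's sphere is
#' expanded by the probe radius and sampled with \code{nPoints} deterministic
#' quadrature points; the accessible fraction (points not inside any other
#' expanded sphere) times \eqn{4\pi(r+p)^2} is its SASA.
#'
#' @param atomTable data.frame of atoms (as in \code{\link{atoms}}).
#' @param radii a \code{RadiiTable}.
#' @param probe probe radius, Angstrom (water: 1.4).
#' @param nPoints quadrature points per atom.
#' @param includeHydrogens keep H atoms? Default drops them.
#' @return list with \code{per_atom_area} (named by atom serial, Angstrom^2),
#'   \code{total_area}, \code{probe_radius}, \code{n_points}.
#' @export
computeSasa <- function(atomTable, radii = defaultRadii(), probe = 1.4,
                        nPoints = 960, includeHydrogens = FALSE) {
  a <- .dropH(as.data.frame(atomTable), includeHydrogens)
  n <- nrow(a)
  if (!n)
    .stop("mcwoundRangeError", "no atoms left after hydrogen filtering")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rext <- radiusFor(radii, a$element) + probe
  dirs <- spherePoints(nPoints)
  area <- numeric(n)
  # neighbour lists from the full pairwise distance matrix; models here are
  # small (hundreds of atoms), so O(n^2) memory is fine
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rext[i] + rext)^2)
    nb <- nb[nb != i]
    if (!length(nb)) {
      area[i] <- 4 * pi * rext[i]^2
      next
    }
    pts <- dirs * rext[i]
    pts <- sweep(pts, 2, xyz[i, ], "+")
    free <- rep(TRUE, nPoints)
    for (j in nb) {
      if (!any(free)) break
      dx <- pts[free, 1] - xyz[j, 1]
      dy <- pts[free, 2] - xyz[j, 2]
      dz <- pts[free, 3] - xyz[j, 3]
      free[free] <- dx * dx + dy * dy + dz * dz >= rext[j]^2
    }
    area[i] <- mean(free) * 4 * pi * rext[i]^2
  }
  names(area) <- a$serial
  list(per_atom_area = area, total_area = sum(area),
       probe_radius = probe, n_points = nPoints)
}

#' Buried interface area of a two-chain complex
#'
#' BSA = (SASA(enzyme alone) + SASA(substrate alone) - SASA(complex)) / 2,
#' the PISA-style single-interface convention; \code{halve = FALSE} gives the
#' total buried area instead. Small negative values from quadrature noise
#' clamp to 0.
#'
#' @param model a \linkS4class{StructureModel}.
#' @inheritParams computeSasa
#' @param halve report one interface's area (default) or the summed burial.
#' @return buried area, Angstrom^2.
#' @export
buriedInterfaceArea <- function(model, radii = defaultRadii(), probe = 1.4,
                                nPoints = 960, includeHydrogens = FALSE,
                                halve = TRUE) {
  enz <- chainAtoms(model, "enzyme")
  sub <- chainAtoms(model, "substrate")
  sasaE <- computeSasa(enz, radii, probe, nPoints, includeHydrogens)$total_area
  sasaS <- computeSasa(sub, radii, probe, nPoints, includeHydrogens)$total_area
  sasaC <- computeSasa(atoms(model), radii, probe, nPoints,
                       includeHydrogens)$total_area
  bsa <- sasaE + sasaS - sasaC
  if (halve) bsa <- bsa / 2
  max(bsa, 0)
}

# integer cell keys for the uniform spatial grid
.gridKeys <- function(xyz, cell) {
  g <- floor(xyz / cell)
  paste(g[, 1], g[, 2], g[, 3], sep = ",")
}

#' Count steric clashes across the enzyme-substrate interface
#'
#' A clash is an unordered inter-chain heavy-atom pair whose van der Waals
#' spheres interpenetrate by at least \code{overlapThreshold} (MolProbity's
#' 0.4 Angstrom convention), i.e. \eqn{(r_i + r_j) - d_{ij} \ge} threshold.
#' Intra-chain pairs are ignored: the screen asks about contacts with the
#' enzyme, not about internal model quality. A uniform spatial grid restricts
#' candidate pairs; the result is identical to exhaustive pairwise
#' evaluation. Both the raw count (which feeds the filter) and a per-1000-atom
#' normalised score are reported.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param radii a \code{RadiiTable}.
#' @param overlapThreshold minimum overlap (Angstrom) to call a clash.
#' @param includeHydrogens keep H atoms? Default drops them.
#' @return list with \code{clash_count}, \code{pairs} (data.frame: serials
#'   and overlap, Angstrom), \code{overlap_threshold},
#'   \code{per_1000_atoms}.
#' @export
countClashes <- function(model, radii = defaultRadii(),
                         overlapThreshold = 0.4, includeHydrogens = FALSE) {
  enz <- .dropH(chainAtoms(model, "enzyme"), includeHydrogens)
  sub <- .dropH(chainAtoms(model, "substrate"), includeHydrogens)
  if (!nrow(enz) || !nrow(sub))
    .stop("mcwoundRangeError", "both chains must have heavy atoms")
  re <- radiusFor(radii, enz$element)
  rs <- radiusFor(radii, sub$element)
  xyzE <- as.matrix(enz[, c("x", "y", "z")])
  xyzS <- as.matrix(sub[, c("x", "y", "z")])
  # largest centre distance that can still clash
  cutoff <- max(re) + max(rs) - overlapThreshold
  keysS <- .gridKeys(xyzS, cutoff)
  bins <- split(seq_len(nrow(sub)), keysS)
  gE <- floor(xyzE / cutoff)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out_i <- integer(0); out_j <- integer(0); out_ov <- numeric(0)
  for (i in seq_len(nrow(enz))) {
    neigh <- sweep(offsets, 2, gE[i, ], "+")
    keys <- paste(neigh[, 1], neigh[, 2], neigh[, 3], sep = ",")
    js <- unlist(bins[keys], use.names = FALSE)
    if (!length(js)) next
    dx <- xyzS[js, 1] - xyzE[i, 1]
    dy <- xyzS[js, 2] - xyzE[i, 2]
    dz <- xyzS[js, 3] - xyzE[i, 3]
    ov <- (re[i] + rs[js]) - sqrt(dx * dx + dy * dy + dz * dz)
    hit <- ov >= overlapThreshold
    if (any(hit)) {
      out_i <- c(out_i, rep.int(i, sum(hit)))
      out_j <- c(out_j, js[hit])
      out_ov <- c(out_ov, ov[hit])
    }
  }
  pairs <- data.frame(serial_enzyme = enz$serial[out_i],
                      serial_substrate = sub$serial[out_j],
                      overlap = out_ov)
  pairs <- pairs[order(pairs$serial_enzyme, pairs$serial_substrate), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  list(clash_count = nrow(pairs), pairs = pairs,
       overlap_threshold = overlapThreshold,
       per_1000_atoms = 1000 * nrow(pairs) / (nrow(enz) + nrow(sub)))
}

#' Catalytic-site geometry of a complex
#'
#' Measures the proximity filter quantity (minimum distance from the
#' catalytic thiol SG to any substrate heavy atom) and ranks candidate P1
#' cleavage sites: all substrate Arg/Lys residues with a main-chain carbonyl
#' O, ordered by SG-to-O distance (shorter is better; metacaspases cleave
#' after Arg/Lys, and the refinement prioritises a short SG-carbonyl
#' distance), ties broken by residue number.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param site a \code{\link{catalyticSite}} resolving on the enzyme chain.
#' @param includeHydrogens keep substrate H atoms in the minimum-distance
#'   scan? Default drops them.
#' @return list with \code{min_distance} (Angstrom), \code{nearest_atom}
#'   (substrate atom serial) and \code{site_candidates} (data.frame:
#'   \code{resseq}, \code{resname}, \code{distance}).
#' @export
catalyticGeometry <- function(model, site, includeHydrogens = FALSE) {
  cat_atom <- locateAtom(model, site)
  sub <- .dropH(chainAtoms(model, "substrate"), includeHydrogens)
  if (!nrow(sub))
    .stop("mcwoundRangeError", "substrate chain has no heavy atoms")
  sg <- as.numeric(cat_atom[1, c("x", "y", "z")])
  d <- sqrt((sub$x - sg[1])^2 + (sub$y - sg[2])^2 + (sub$z - sg[3])^2)
  imin <- which.min(d)
  cand <- sub[sub$resname %in% c("ARG", "LYS") & sub$atom == "O", ,
              drop = FALSE]
  if (nrow(cand)) {
    cd <- sqrt((cand$x - sg[1])^2 + (cand$y - sg[2])^2 + (cand$z - sg[3])^2)
    ord <- order(cd, cand$resseq)
    candidates <- data.frame(resseq = cand$resseq[ord],
                             resname = cand$resname[ord],
                             distance = cd[ord])
  } else {
    candidates <- data.frame(resseq = integer(0), resname = character(0),
                             distance = numeric(0))
  }
  rownames(candidates) <- NULL
  list(min_distance = d[imin], nearest_atom = sub$serial[imin],
       site_candidates = candidates)
}
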