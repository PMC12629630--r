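#' Filter thresholds for the substrate screen
#'
#' The screen's three cutoffs: at most 50 inter-chain clashes, at least
#' 500 Angstrom^2 of buried interface (removing loosely bound pairs), and a
#' catalytic SG-to-substrate distance under 4.5 Angstrom. Boundaries are
#' applied exactly as stated: reject if clashes > 50, if BSA < 500, or if
#' distance >= 4.5.
#'
#' @param maxClashes maximum tolerated inter-chain clash count.
#' @param minInterface minimum buried interface area, Angstrom^2.
#' @param maxCatalyticDistance exclusive upper bound on the SG-substrate
#'   minimum distance, Angstrom.
#' @return a \code{filterThresholds} list.
#' @export
filterThresholds <- function(maxClashes = 50, minInterface = 500,
                             maxCatalyticDistance = 4.5) {
  if (maxClashes <= 0 || minInterface <= 0 || maxCatalyticDistance <= 0)
    .stop("mcwoundRangeError", "all filter thresholds must be positive")
  structure(list(maxClashes = maxClashes, minInterface = minInterface,
                 maxCatalyticDistance = maxCatalyticDistance),
            class = "filterThresholds")
}

#' Apply the three screening filters to one pair's metrics
#'
#' Filters are checked in order (1 clash, 2 interface, 3 distance) and the
#' first violated one is recorded; a pair passing all three is a predicted
#' substrate.
#'
#' @param metrics list with \code{clash_count}, \code{bsa},
#'   \code{min_distance} (see \code{\link{screenPair}}).
#' @param thresholds a \code{\link{filterThresholds}}.
#' @return list with \code{verdict} (\code{"predicted-substrate"} /
#'   \code{"rejected"}) and \code{failed_filter} (\code{"none"},
#'   \code{"clash"}, \code{"interface"} or \code{"distance"}).
#' @export
applyFilters <- function(metrics, thresholds = filterThresholds()) {
  failed <- if (metrics$clash_count > thresholds$maxClashes) "clash"
  else if (metrics$bsa < thresholds$minInterface) "interface"
  else if (metrics$min_distance >= thresholds$maxCatalyticDistance) "distance"
  else "none"
  list(verdict = if (failed == "none") "predicted-substrate" else "rejected",
       failed_filter = failed)
}

#' Screen one predicted enzyme-substrate complex
#'
#' Computes all three filter metrics unconditionally (downstream users need
#' the full metric vector even for rejected pairs; only the verdict
#' short-circuits), attaches the best-ranked Arg/Lys cleavage-site candidate
#' if any, and applies the filters.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param site the enzyme's \code{\link{catalyticSite}}.
#' @param thresholds a \code{\link{filterThresholds}}.
#' @inheritParams computeSasa
#' @return list with \code{metrics} (clash_count, per_1000_atoms, bsa,
#'   min_distance, best_site, site_candidates) and \code{decision}
#'   (see \code{\link{applyFilters}}).
#' @export
screenPair <- function(model, site, thresholds = filterThresholds(),
                       radii = defaultRadii(), probe = 1.4, nPoints = 960) {
  clash <- countClashes(model, radii)
  bsa <- buriedInterfaceArea(model, radii, probe, nPoints)
  geom <- catalyticGeometry(model, site)
  best <- if (nrow(geom$site_candidates))
    as.list(geom$site_candidates[1, ]) else NULL
  metrics <- list(clash_count = clash$clash_count,
                  per_1000_atoms = clash$per_1000_atoms,
                  bsa = bsa,
                  min_distance = geom$min_distance,
                  best_site = best,
                  site_candidates = geom$site_candidates)
  list(metrics = metrics, decision = applyFilters(metrics, thresholds))
}

#' Screen a batch of complexes into a prediction matrix
#'
#' Each model is screened independently (verdicts are a pure function of
#' per-pair metrics) and placed in the enzymes x substrates grid by its
#' label, expected as \code{"<enzyme>__<substrate>"}. A model that fails to
#' process is recorded as an error cell; the rest of the batch is unaffected.
#'
#' @param models list of \linkS4class{StructureModel}s whose labels parse as
#'   \code{enzyme__substrate}.
#' @param sites named list of \code{\link{catalyticSite}}s, keyed by enzyme
#'   label.
#' @param thresholds a \code{\link{filterThresholds}}.
#' @inheritParams computeSasa
#' @return a \linkS4class{PredictionMatrix}.
#' @export
screenBatch <- function(models, sites, thresholds = filterThresholds(),
                        radii = defaultRadii(), probe = 1.4, nPoints = 960) {
  labels <- vapply(models, modelLabel, character(1))
  parts <- strsplit(labels, "__", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 2L
  if (any(bad))
    .stop("mcwoundFormatError",
          "labels not of the form '<enzyme>__<substrate>': %s",
          paste(labels[bad], collapse = ", "))
  enzymes <- unique(vapply(parts, `[`, character(1), 1L))
  substrates <- unique(vapply(parts, `[`, character(1), 2L))
  keys <- vapply(parts, paste, character(1), collapse = "|")
  if (anyDuplicated(keys))
    .stop("mcwoundFormatError", "duplicate enzyme-substrate pair: %s",
          paste(unique(keys[duplicated(keys)]), collapse = ", "))
  cells <- vector("list", length(models))
  names(cells) <- keys
  for (k in seq_along(models)) {
    enz <- parts[[k]][1]
    if (is.null(sites[[enz]]))
      .stop("mcwoundFormatError", "no catalytic site configured for enzyme %s",
            enz)
    cells[[k]] <- tryCatch(
      screenPair(models[[k]], sites[[enz]], thresholds, radii, probe,
                 nPoints),
      error = function(e) list(error = conditionMessage(e)))
  }
  new("PredictionMatrix", enzymes = enzymes, substrates = substrates,
      cells = cells)
}

#' Serialise a PredictionMatrix to disk
#'
#' Writes \code{matrix.tsv} (the verdict grid, rows = enzymes) and
#' \code{metrics.json} (full per-pair metrics, decisions and ranked cleavage
#' sites). Outputs are deterministic: identical inputs give byte-identical
#' files.
#'
#' @param pm a \linkS4class{PredictionMatrix}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeScreenResults <- function(pm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vm <- verdictMatrix(pm)
  df <- data.frame(enzyme = rownames(vm), vm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, file.path(dir, "matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  json <- lapply(names(pm@cells), function(key) {
    p <- strsplit(key, "|", fixed = TRUE)[[1]]
    cell <- pm@cells[[key]]
    out <- list(enzyme = p[1], substrate = p[2])
    if (!is.null(cell$error)) return(c(out, list(error = cell$error)))
    m <- cell$metrics
    c(out, list(clash_count = m$clash_count,
                per_1000_atoms = m$per_1000_atoms,
                bsa = m$bsa,
                min_distance = m$min_distance,
                best_site = m$best_site,
                candidates = m$site_candidates,
                verdict = cell$decision$verdict,
                failed_filter = cell$decision$failed_filter))
  })
  .writeJson(json, file.path(dir, "metrics.json"))
  invisible(dir)
}
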