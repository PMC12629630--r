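#' Validate a screening run configuration
#'
#' Accepts a YAML file path or a list. Recognised keys: \code{thresholds}
#' (\code{max_clashes}, \code{min_interface}, \code{max_catalytic_distance}),
#' \code{probe}, \code{n_points}, \code{radii_file},
#' \code{enzyme_chain}, \code{substrate_chain} and \code{catalytic_sites}
#' (per enzyme label: \code{chain}, \code{res_seq}, \code{atom_name}).
#' Unknown keys are rejected rather than silently ignored. All screen
#' constants default to the study values (50 clashes, 500 Angstrom^2,
#' 4.5 Angstrom, probe 1.4, 960 quadrature points) but are overridable, so
#' sensitivity analyses are one setting away.
#'
#' @param config list or YAML path; \code{NULL} for all defaults.
#' @return validated config list with all defaults filled in.
#' @export
readRunConfig <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  known <- c("thresholds", "probe", "n_points", "radii_file",
             "enzyme_chain", "substrate_chain", "catalytic_sites")
  extra <- setdiff(names(config), known)
  if (length(extra))
    .stop("mcwoundConfigError", "unknown config key(s): %s",
          paste(extra, collapse = ", "))
  th <- config$thresholds
  if (!is.null(th)) {
    extraTh <- setdiff(names(th), c("max_clashes", "min_interface",
                                    "max_catalytic_distance"))
    if (length(extraTh))
      .stop("mcwoundConfigError", "unknown threshold key(s): %s",
            paste(extraTh, collapse = ", "))
  }
  thresholds <- tryCatch(
    filterThresholds(
      maxClashes = th$max_clashes %||% 50,
      minInterface = th$min_interface %||% 500,
      maxCatalyticDistance = th$max_catalytic_distance %||% 4.5),
    error = function(e) .stop("mcwoundConfigError", "%s",
                              conditionMessage(e)))
  radii <- if (is.null(config$radii_file)) defaultRadii()
  else defaultRadii(config$radii_file)
  sites <- lapply(config$catalytic_sites, function(s)
    catalyticSite(s$chain %||% "A", s$res_seq %||% 1L,
                  s$atom_name %||% "SG"))
  list(thresholds = thresholds,
       probe = config$probe %||% 1.4,
       nPoints = config$n_points %||% 960,
       radii = radii,
       enzymeChain = config$enzyme_chain %||% "A",
       substrateChain = config$substrate_chain %||% "B",
       sites = sites)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Screen a directory of predicted complexes
#'
#' Reads every \code{<enzyme>__<substrate>.pdb} in \code{inputDir}, screens
#' each pair, and writes \code{matrix.tsv}, \code{metrics.json} and a
#' per-pair log (\code{screen_log.tsv}, with metric values and timing) to
#' \code{outDir}. A file that fails to parse is flagged as an error cell;
#' the remaining pairs are processed. An empty directory yields an empty
#' matrix with valid output files. Outputs are deterministic.
#'
#' @param inputDir directory of pair-labelled PDB files.
#' @param outDir output directory.
#' @param config screening configuration (see \code{\link{readRunConfig}});
#'   must name a catalytic site for every enzyme label present.
#' @return invisibly, a list with the \linkS4class{PredictionMatrix}
#'   (\code{matrix}), the per-pair log (\code{log}) and \code{n_failed}.
#' @export
runScreen <- function(inputDir, outDir, config = NULL) {
  cfg <- readRunConfig(config)
  files <- sort(list.files(inputDir, pattern = "\\.pdb$", full.names = TRUE))
  labels <- sub("\\.pdb$", "", basename(files))
  bad <- !grepl("^[^_]+(_[^_]+)*__.+$", labels) |
    lengths(regmatches(labels, gregexpr("__", labels, fixed = TRUE))) != 1L
  if (any(bad))
    .stop("mcwoundFormatError",
          "file name(s) not of the form <enzyme>__<substrate>.pdb: %s",
          paste(basename(files)[bad], collapse = ", "))
  parts <- strsplit(labels, "__", fixed = TRUE)
  enzymes <- unique(vapply(parts, `[`, character(1), 1L))
  substrates <- unique(vapply(parts, `[`, character(1), 2L))
  keys <- vapply(parts, paste, character(1), collapse = "|")
  if (anyDuplicated(keys))
    .stop("mcwoundFormatError", "duplicate pair among input files: %s",
          paste(unique(keys[duplicated(keys)]), collapse = ", "))
  cells <- list()
  logRows <- list()
  for (i in seq_along(files)) {
    enz <- parts[[i]][1]
    t0 <- proc.time()[["elapsed"]]
    cell <- tryCatch({
      model <- readStructure(files[i], cfg$enzymeChain, cfg$substrateChain,
                             label = labels[i])
      site <- cfg$sites[[enz]]
      if (is.null(site))
        .stop("mcwoundConfigError",
              "no catalytic site configured for enzyme %s", enz)
      screenPair(model, site, cfg$thresholds, cfg$radii, cfg$probe,
                 cfg$nPoints)
    }, error = function(e) list(error = conditionMessage(e)))
    elapsed <- proc.time()[["elapsed"]] - t0
    cells[[keys[i]]] <- cell
    logRows[[i]] <- if (is.null(cell$error))
      data.frame(pair = labels[i], status = "ok",
                 clash_count = cell$metrics$clash_count,
                 bsa = round(cell$metrics$bsa, 3),
                 min_distance = round(cell$metrics$min_distance, 3),
                 verdict = cell$decision$verdict,
                 seconds = round(elapsed, 2))
    else
      data.frame(pair = labels[i], status = "error", clash_count = NA,
                 bsa = NA, min_distance = NA, verdict = "error",
                 seconds = round(elapsed, 2))
  }
  pm <- new("PredictionMatrix", enzymes = enzymes, substrates = substrates,
            cells = cells)
  writeScreenResults(pm, outDir)
  logTab <- if (length(logRows))
    do.call(rbind, c(logRows, list(make.row.names = FALSE)))
  else data.frame(pair = character(0), status = character(0),
                  clash_count = numeric(0), bsa = numeric(0),
                  min_distance = numeric(0), verdict = character(0),
                  seconds = numeric(0))
  utils::write.table(logTab, file.path(outDir, "screen_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!length(files))
    warning("no .pdb files found in ", inputDir, "; wrote an empty matrix")
  nFailed <- sum(logTab$status == "error")
  invisible(list(matrix = pm, log = logTab, n_failed = nFailed))
}

#' Classify contrast tables listed in a manifest
#'
#' The manifest (YAML path, or a data.frame/list with \code{file},
#' \code{genotype}, \code{treatment} per entry) maps each TSV to its
#' contrast. The three wound contrasts (WT, atmc4-1, atmc9-1) are required;
#' the Pep1 and Propep1+wound contrasts are optional and, when absent,
#' Pep1-dependent features are disabled with a message. Writes
#' \code{partition.tsv} and \code{summary.json} to \code{outDir}.
#'
#' @param manifest manifest as above; file paths are resolved relative to
#'   the manifest's directory (or to \code{baseDir} for non-path manifests).
#' @param outDir output directory.
#' @param rule a \code{\link{significanceRule}}.
#' @param pepPlusMode see \code{\link{classifyDependence}}.
#' @param baseDir base directory for relative file paths.
#' @return invisibly, the \linkS4class{PartitionResult}.
#' @export
runClassify <- function(manifest, outDir, rule = significanceRule(),
                        pepPlusMode = "pep1_only", baseDir = ".") {
  if (is.character(manifest)) {
    baseDir <- dirname(manifest)
    manifest <- yaml::read_yaml(manifest)$contrasts
  }
  if (is.data.frame(manifest))
    manifest <- lapply(seq_len(nrow(manifest)), function(i)
      as.list(manifest[i, ]))
  if (!length(manifest))
    .stop("mcwoundConfigError", "empty manifest")
  tables <- list()
  for (entry in manifest) {
    if (is.null(entry$file) || is.null(entry$genotype) ||
        is.null(entry$treatment))
      .stop("mcwoundConfigError",
            "manifest entries need file, genotype, treatment")
    path <- if (file.exists(entry$file)) entry$file
    else file.path(baseDir, entry$file)
    key <- .contrastKey(entry$genotype, entry$treatment)
    tables[[key]] <- readContrastTable(path, entry$genotype, entry$treatment)
  }
  optional <- setdiff(c(.contrastKey("WT", "Pep1"),
                        .contrastKey("WT", "Propep1+wound")),
                      names(tables))
  if (length(optional))
    message("optional contrast(s) absent, Pep1 features degrade: ",
            paste(optional, collapse = ", "))
  partition <- classifyDependence(tables, rule, pepPlusMode)
  writePartition(partition, outDir)
  invisible(partition)
}

#' Generate fixture trees from the command line path
#'
#' \code{kind = "structures"} writes the four-fixture verdict suite as
#' \code{SYN-MC__<label>.pdb} files plus \code{truth.json} and a ready-made
#' \code{config.yaml}; the synthetic enzyme label is prefixed \code{SYN-} to
#' mark it as a constructed stand-in, not a real metacaspase model.
#' \code{kind = "degs"} writes simulated contrast tables, truth labels and
#' a manifest (see \code{\link{writeDeTables}}).
#'
#' @param kind \code{"structures"} or \code{"degs"}.
#' @param outDir output directory.
#' @param seed integer seed.
#' @param ... passed to \code{\link{makeVerdictSuite}} or
#'   \code{\link{generateDeTables}}.
#' @return \code{outDir}, invisibly.
#' @export
runSimulate <- function(kind = c("structures", "degs"), outDir, seed = 1,
                        ...) {
  kind <- match.arg(kind)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (kind == "structures") {
    suite <- makeVerdictSuite(seed = seed, ...)
    truth <- list()
    for (label in names(suite)) {
      fx <- suite[[label]]
      slug <- gsub("-", "", label)
      writeStructure(fx$model,
                     file.path(outDir, sprintf("SYN-MC__%s.pdb", slug)))
      truth[[slug]] <- fx$truth
    }
    .writeJson(truth, file.path(outDir, "truth.json"))
    yaml::write_yaml(
      list(catalytic_sites = list(`SYN-MC` = list(chain = "A", res_seq = 1L,
                                                  atom_name = "SG"))),
      file.path(outDir, "config.yaml"))
  } else {
    sim <- generateDeTables(seed = seed, ...)
    writeDeTables(sim, outDir)
  }
  message("simulated ", kind, " written to ", outDir, " (seed ", seed, ")")
  invisible(outDir)
}
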