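# Run expr with a private RNG stream; the caller's .Random.seed is untouched.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Two parallel slab chains in the y-z plane, facing each other across a gap
# along x. Enzyme (chain A): residue 1 is a CYS whose CA/SG sit at the slab
# edge, positioned by sgMode; residues 2.. are single-CA "ALA" scaffold
# atoms. Substrate (chain B): one CA plus one main-chain O per residue.
# Not physically realistic proteins -- geometric scaffolds with just enough
# PDB semantics for every screen operation to run.
.buildSlabComplex <- function(nSideEnz, nSideSub, gap,
                              sgMode = c("edge", "back"),
                              spacing = 3.5, jitter = 0, seed = 1,
                              placeArgLys = TRUE, label = "fixture") {
  sgMode <- match.arg(sgMode)
  gridYZ <- function(nSide) {
    idx <- seq_len(nSide) - (nSide + 1) / 2
    as.matrix(expand.grid(y = idx * spacing, z = idx * spacing))
  }
  eyz <- gridYZ(nSideEnz)
  syz <- gridYZ(nSideSub)
  yEdge <- max(eyz[, 1])
  sg <- switch(sgMode,
               edge = c(0, yEdge + 2.0, 0),
               back = c(-2.5, yEdge + 2.0, 0))
  sgCA <- sg + c(-1.6, 0.8, 0)
  nE <- nrow(eyz)
  enz <- data.frame(
    serial = seq_len(nE + 2L),
    atom = c("CA", "SG", rep("CA", nE)),
    element = c("C", "S", rep("C", nE)),
    resname = c("CYS", "CYS", rep("ALA", nE)),
    resseq = c(1L, 1L, seq_len(nE) + 1L),
    chain = "A",
    x = c(sgCA[1], sg[1], rep(0, nE)),
    y = c(sgCA[2], sg[2], eyz[, 1]),
    z = c(sgCA[3], sg[3], eyz[, 2]),
    occ = 1, b = 0, stringsAsFactors = FALSE)
  nS <- nrow(syz)
  resnames <- if (placeArgLys) rep(c("LYS", "ARG"), length.out = nS)
  else rep("GLY", nS)
  sub <- data.frame(
    serial = nE + 2L + seq_len(2L * nS),
    atom = rep(c("CA", "O"), nS),
    element = rep(c("C", "O"), nS),
    resname = rep(resnames, each = 2L),
    resseq = rep(seq_len(nS), each = 2L),
    chain = "B",
    x = gap,
    y = rep(syz[, 1], each = 2L) + rep(c(0, 1.4), nS),
    z = rep(syz[, 2], each = 2L),
    occ = 1, b = 0, stringsAsFactors = FALSE)
  a <- rbind(enz, sub)
  if (jitter > 0)
    a[, c("x", "y", "z")] <- .withSeed(seed, {
      a[, c("x", "y", "z")] +
        matrix(stats::rnorm(3L * nrow(a), sd = jitter), ncol = 3)
    })
  StructureModel(a, "A", "B", label)
}

.fixtureTruth <- function(model, site, thresholds, radii, probe, nPoints) {
  clash <- oracleClashCount(model, radii)
  bsa <- oracleBsa(model, radii, probe, nPoints)
  dist <- oracleMinDistance(model, site)
  failed <- if (clash > thresholds$maxClashes) "clash"
  else if (bsa < thresholds$minInterface) "interface"
  else if (dist >= thresholds$maxCatalyticDistance) "distance"
  else "none"
  list(clash_count = clash, bsa = bsa, min_distance = dist,
       verdict = if (failed == "none") "predicted-substrate" else "rejected",
       failed_filter = failed)
}

#' Generate one toy enzyme-peptide complex with known truth
#'
#' Builds a two-slab scaffold complex (see the package vignette for the
#' geometry) whose clash, interface and catalytic-distance properties are
#' controlled by the centroid separation, and stamps it with ground-truth
#' metrics from the independent oracles -- never from the production code
#' path. Deterministic for a fixed seed.
#'
#' @param nEnzymeAtoms,nSubstrateAtoms approximate atom counts per chain
#'   (rounded up to the nearest square slab).
#' @param separation signed x-offset between chain centroids, Angstrom.
#' @param jitter Gaussian coordinate noise, Angstrom.
#' @param placeArgLys give the substrate LYS/ARG residues (with main-chain
#'   O atoms) rather than GLY.
#' @param seed integer seed.
#' @param thresholds a \code{\link{filterThresholds}} used only to stamp the
#'   designed verdict.
#' @inheritParams computeSasa
#' @return list with \code{model} (\linkS4class{StructureModel}),
#'   \code{site} (the catalytic SG specification) and \code{truth}
#'   (oracle clash count, BSA, min distance, designed verdict).
#' @export
generateComplexFixture <- function(nEnzymeAtoms = 25, nSubstrateAtoms = 25,
                                   separation = 3.3, jitter = 0.05,
                                   placeArgLys = TRUE, seed = 1,
                                   thresholds = filterThresholds(),
                                   radii = defaultRadii(), probe = 1.4,
                                   nPoints = 960) {
  if (nEnzymeAtoms < 1 || nSubstrateAtoms < 1 || jitter < 0)
    .stop("mcwoundRangeError", "invalid fixture parameters")
  model <- .buildSlabComplex(ceiling(sqrt(nEnzymeAtoms)),
                             ceiling(sqrt(nSubstrateAtoms)),
                             gap = separation, sgMode = "edge",
                             jitter = jitter, seed = seed,
                             placeArgLys = placeArgLys,
                             label = sprintf("fixture_sep%.1f", separation))
  site <- catalyticSite("A", 1L, "SG")
  list(model = model, site = site,
       truth = .fixtureTruth(model, site, thresholds, radii, probe, nPoints))
}

#' Oracle-validated verdict suite
#'
#' Emits four labelled fixtures, one per screening outcome: \code{pass},
#' \code{fail-clash}, \code{fail-interface} and \code{fail-distance}. Each
#' fixture is validated against the independent oracles before emission
#' (the pass fixture must show contact without >= 0.4 Angstrom overlaps,
#' oracle BSA at or above the interface cutoff, and the catalytic SG within
#' the distance cutoff); geometries that fail validation are re-tuned by a
#' bounded deterministic search over the inter-slab gap and slab size.
#'
#' @param seed integer seed (controls the small coordinate jitter).
#' @param thresholds a \code{\link{filterThresholds}}.
#' @inheritParams computeSasa
#' @return named list of fixtures (\code{model}, \code{site}, \code{truth}),
#'   with names \code{pass}, \code{fail-clash}, \code{fail-interface},
#'   \code{fail-distance}.
#' @export
makeVerdictSuite <- function(seed = 1, thresholds = filterThresholds(),
                             radii = defaultRadii(), probe = 1.4,
                             nPoints = 960) {
  site <- catalyticSite("A", 1L, "SG")
  jit <- 0.05
  tune <- function(label, grid, ok) {
    for (i in seq_len(nrow(grid))) {
      model <- .buildSlabComplex(grid$nE[i], grid$nS[i], grid$gap[i],
                                 sgMode = grid$sg[i], jitter = jit,
                                 seed = seed + i, label = label)
      truth <- .fixtureTruth(model, site, thresholds, radii, probe, nPoints)
      if (ok(truth)) return(list(model = model, site = site, truth = truth))
    }
    .stop("mcwoundTuningError",
          "could not tune fixture '%s' within %d attempts (last: %d clashes, %.1f A^2, %.2f A)",
          label, nrow(grid), truth$clash_count, truth$bsa, truth$min_distance)
  }
  margin <- 0.9  # oracle margin so production quadrature agrees
  pass <- tune("pass",
               expand.grid(nE = c(7L, 8L, 9L), nS = c(7L, 8L, 9L),
                           gap = c(3.3, 3.2, 3.4), sg = "edge",
                           stringsAsFactors = FALSE),
               function(t) t$clash_count == 0 &&
                 t$bsa >= thresholds$minInterface / margin &&
                 t$min_distance <= margin * thresholds$maxCatalyticDistance)
  failClash <- tune("fail-clash",
                    expand.grid(nE = 8L, nS = 8L, gap = c(2.0, 1.5, 1.0),
                                sg = "edge", stringsAsFactors = FALSE),
                    function(t) t$failed_filter == "clash" &&
                      t$clash_count >= thresholds$maxClashes / margin)
  failInterface <- tune("fail-interface",
                        expand.grid(nE = 5L, nS = 5L, gap = 100,
                                    sg = "edge", stringsAsFactors = FALSE),
                        function(t) t$failed_filter == "interface" &&
                          t$clash_count == 0 && t$bsa == 0)
  failDistance <- tune("fail-distance",
                       expand.grid(nE = c(7L, 8L, 9L), nS = c(7L, 8L, 9L),
                                   gap = c(3.3, 3.2, 3.4), sg = "back",
                                   stringsAsFactors = FALSE),
                       function(t) t$failed_filter == "distance" &&
                         t$min_distance >=
                           thresholds$maxCatalyticDistance / margin)
  list("pass" = pass, "fail-clash" = failClash,
       "fail-interface" = failInterface, "fail-distance" = failDistance)
}

# which wound contrasts each dependence class is induced in
.CLASS_PLAN <- list(
  MC4_SPECIFIC      = c(WT = TRUE,  m4 = FALSE, m9 = TRUE),
  MC9_SPECIFIC      = c(WT = TRUE,  m4 = TRUE,  m9 = FALSE),
  CO_DEPENDENT      = c(WT = TRUE,  m4 = FALSE, m9 = FALSE),
  MC_INDEPENDENT    = c(WT = TRUE,  m4 = TRUE,  m9 = TRUE),
  MC9_REPRESSED     = c(WT = FALSE, m4 = FALSE, m9 = TRUE),
  MC4_ONLY_MUTANT   = c(WT = FALSE, m4 = TRUE,  m9 = FALSE),
  BOTH_MUTANTS_ONLY = c(WT = FALSE, m4 = TRUE,  m9 = TRUE))

#' Default planted design for the DE generator
#'
#' Ten genes per dependence class; the four WT-significant classes are
#' additionally split into ten Pep1-responsive and ten unresponsive genes,
#' so every marker group is populated.
#'
#' @param nPerCell genes per (class, Pep1 status) cell.
#' @return data.frame with columns \code{class}, \code{pep_status},
#'   \code{n}.
#' @export
defaultDesign <- function(nPerCell = 10L) {
  wt <- c("MC4_SPECIFIC", "MC9_SPECIFIC", "CO_DEPENDENT", "MC_INDEPENDENT")
  mut <- c("MC9_REPRESSED", "MC4_ONLY_MUTANT", "BOTH_MUTANTS_ONLY")
  rbind(
    expand.grid(class = wt, pep_status = c("pep_plus", "pep_minus"),
                stringsAsFactors = FALSE),
    data.frame(class = mut, pep_status = "not_applicable"),
    make.row.names = FALSE) -> d
  d$n <- nPerCell
  d
}

#' Simulate differential-expression contrast tables with planted classes
#'
#' Emulates the statistical structure the dependence classifier consumes:
#' per-contrast log2 fold changes and adjusted p values where planted genes
#' are strongly induced (large positive log2FC, tiny padj) in exactly the
#' contrasts their class prescribes, and everything else is null
#' (near-zero log2FC, padj near 1). Adjusted p values are planted directly:
#' the count-level model and the BH adjustment are upstream of this package.
#' Deterministic for a fixed seed.
#'
#' @param design data.frame with columns \code{class}, \code{pep_status},
#'   \code{n} (see \code{\link{defaultDesign}}).
#' @param nNull number of pure-null genes.
#' @param inducedLfcMean,inducedLfcSd log2FC distribution of induced genes;
#'   the mean must clear the rule's cutoff.
#' @param nullLfcSd log2FC spread of null genes.
#' @param inducedPadj,nullPadj planted adjusted p values.
#' @param seed integer seed.
#' @param rule the \code{\link{significanceRule}} the tables are built to be
#'   classified under (used for validation only).
#' @return list with \code{tables} (named contrast data.frames for
#'   WT/atmc4-1/atmc9-1 x wound/Pep1) and \code{truth} (data.frame:
#'   gene_id, class, pep1_status, marker_group).
#' @export
generateDeTables <- function(design = defaultDesign(), nNull = 1000L,
                             inducedLfcMean = 4, inducedLfcSd = 0.25,
                             nullLfcSd = 0.1, inducedPadj = 1e-6,
                             nullPadj = 0.99, seed = 1,
                             rule = significanceRule()) {
  if (any(design$n < 0) || nNull < 0)
    .stop("mcwoundRangeError", "gene counts must be non-negative")
  if (inducedLfcMean <= rule$lfcCutoff)
    .stop("mcwoundRangeError",
          "inducedLfcMean (%.2f) must exceed the rule's lfcCutoff (%.2f)",
          inducedLfcMean, rule$lfcCutoff)
  if (!all(design$class %in% names(.CLASS_PLAN)))
    .stop("mcwoundRangeError", "unknown class in design")
  design <- design[design$n > 0, , drop = FALSE]
  cls <- rep(design$class, design$n)
  pep <- rep(design$pep_status, design$n)
  # Pep1 status only means something for WT-significant genes
  wt_sig <- vapply(cls, function(k) .CLASS_PLAN[[k]][["WT"]], logical(1))
  pep[!wt_sig] <- "not_applicable"
  cls <- c(cls, rep("NOT_DEG", nNull))
  pep <- c(pep, rep("not_applicable", nNull))
  n <- length(cls)
  ids <- sprintf("GENE%05d", seq_len(n))
  truth <- data.frame(gene_id = ids, class = cls, pep1_status = pep,
                      marker_group = assignMarkerGroup(cls, pep),
                      stringsAsFactors = FALSE)
  genos <- c(WT = "WT", m4 = "atmc4-1", m9 = "atmc9-1")
  tables <- .withSeed(seed, {
    out <- list()
    for (g in names(genos)) {
      for (trt in c("wound", "Pep1")) {
        induced <- if (trt == "wound")
          vapply(cls, function(k)
            k != "NOT_DEG" && .CLASS_PLAN[[k]][[g]], logical(1))
        else
          g == "WT" & pep == "pep_plus"
        lfc <- ifelse(induced,
                      stats::rnorm(n, inducedLfcMean, inducedLfcSd),
                      stats::rnorm(n, 0, nullLfcSd))
        out[[.contrastKey(genos[[g]], trt)]] <-
          data.frame(gene_id = ids, log2fc = lfc,
                     padj = ifelse(induced, inducedPadj, nullPadj),
                     stringsAsFactors = FALSE)
      }
    }
    out
  })
  list(tables = tables, truth = truth)
}

#' Write simulated DE tables, truth labels and a manifest
#'
#' Writes each contrast as a TSV in the dialect
#' \code{\link{readContrastTable}} reads (columns gene_id, log2FoldChange,
#' padj), the planted truth as \code{truth_labels.tsv}, and a
#' \code{manifest.yaml} mapping each file to its (genotype, treatment) so
#' \code{\link{runClassify}} can consume the directory directly.
#'
#' @param sim output of \code{\link{generateDeTables}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeDeTables <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  for (key in names(sim$tables)) {
    parts <- strsplit(key, "_", fixed = TRUE)[[1]]
    genotype <- parts[1]
    treatment <- paste(parts[-1], collapse = "_")
    fname <- paste0(gsub("[^A-Za-z0-9.+-]", "-", key), ".tsv")
    tab <- sim$tables[[key]]
    utils::write.table(
      data.frame(gene_id = tab$gene_id, log2FoldChange = tab$log2fc,
                 padj = tab$padj),
      file.path(dir, fname), sep = "\t", quote = FALSE, row.names = FALSE)
    manifest[[length(manifest) + 1L]] <-
      list(file = fname, genotype = genotype, treatment = treatment)
  }
  utils::write.table(sim$truth, file.path(dir, "truth_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(contrasts = manifest),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}
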