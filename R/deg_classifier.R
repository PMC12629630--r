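#' Dependence classes and marker groups
#'
#' \code{DEPENDENCE_CLASSES} are the eight cells of the three-way
#' significance Venn over the WT, atmc4-1 and atmc9-1 contrasts (plus
#' \code{NOT_DEG}): a gene induced in WT and in atmc9-1 but not in atmc4-1
#' depends specifically on AtMC4 (\code{MC4_SPECIFIC}); one induced in WT
#' but in neither mutant needs both proteases (\code{CO_DEPENDENT}); one
#' induced only in atmc9-1 is normally repressed by AtMC9
#' (\code{MC9_REPRESSED}); and so on. \code{MARKER_GROUPS} crosses the two
#' wound-induced AtMC4-dependent classes with Pep1 responsiveness:
#' Group 1 = MC4-specific, Pep1-responsive (e.g. ACS8, WRKY48);
#' Group 2 = co-dependent, Pep1-responsive (e.g. PDF1.4, NHL10);
#' Groups 3/4 = the Pep1-unresponsive counterparts (e.g. WOX5, AtMC7).
#'
#' @name dependenceClasses
#' @export
DEPENDENCE_CLASSES <- c("MC4_SPECIFIC", "MC9_SPECIFIC", "CO_DEPENDENT",
                        "MC_INDEPENDENT", "MC9_REPRESSED", "MC4_ONLY_MUTANT",
                        "BOTH_MUTANTS_ONLY", "NOT_DEG")

#' @rdname dependenceClasses
#' @export
MARKER_GROUPS <- c("GROUP1", "GROUP2", "GROUP3", "GROUP4", "NONE")

#' Significance rule for calling DEGs
#'
#' The study's default calls a gene differentially expressed at
#' |log2 fold change| > 2 with BH-adjusted p (FDR) < 0.05; the
#' high-stringency analyses use log2FC > 3. Inequalities are strict, as
#' printed.
#'
#' @param lfcCutoff positive log2 fold-change cutoff (2 or 3 in the study).
#' @param padjCutoff adjusted-p cutoff in (0, 1).
#' @param direction \code{"up"} (log2FC > cutoff) or \code{"down"}
#'   (log2FC < -cutoff).
#' @return a \code{significanceRule} list.
#' @export
significanceRule <- function(lfcCutoff = 2, padjCutoff = 0.05,
                             direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (lfcCutoff <= 0)
    .stop("mcwoundRangeError", "lfcCutoff must be positive")
  if (padjCutoff <= 0 || padjCutoff >= 1)
    .stop("mcwoundRangeError", "padjCutoff must lie in (0, 1)")
  structure(list(lfcCutoff = lfcCutoff, padjCutoff = padjCutoff,
                 direction = direction), class = "significanceRule")
}

#' Read one differential-expression contrast table
#'
#' Expects a TSV with columns \code{gene_id}, \code{log2FoldChange} (alias
#' \code{log2fc}, \code{log2FC}) and \code{padj} (alias \code{FDR},
#' \code{adj_p}), the summary format DESeq2-style upstream analyses emit.
#' Missing adjusted p values are kept as NA (genes dropped by independent
#' filtering) and never treated as significant.
#'
#' @param path TSV file.
#' @param genotype,treatment optional annotations stored as attributes.
#' @return data.frame with columns \code{gene_id}, \code{log2fc},
#'   \code{padj}.
#' @export
readContrastTable <- function(path, genotype = NA_character_,
                              treatment = NA_character_) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  pick <- function(aliases) {
    hit <- intersect(aliases, names(tab))
    if (!length(hit))
      .stop("mcwoundFormatError", "%s: no column among %s", path,
            paste(aliases, collapse = "/"))
    tab[[hit[1]]]
  }
  out <- data.frame(gene_id = as.character(pick("gene_id")),
                    log2fc = as.numeric(pick(c("log2FoldChange", "log2fc",
                                               "log2FC", "lfc"))),
                    padj = as.numeric(pick(c("padj", "FDR", "adj_p"))),
                    stringsAsFactors = FALSE)
  if (any(!nzchar(out$gene_id)))
    .stop("mcwoundFormatError", "%s: empty gene_id", path)
  if (anyDuplicated(out$gene_id))
    .stop("mcwoundFormatError", "%s: duplicated gene_id", path)
  attr(out, "genotype") <- genotype
  attr(out, "treatment") <- treatment
  out
}

#' Genes passing a significance rule in one contrast
#'
#' @param table contrast data.frame (see \code{\link{readContrastTable}}).
#' @param rule a \code{\link{significanceRule}}.
#' @return character vector of gene ids.
#' @export
significantSet <- function(table, rule = significanceRule()) {
  ok_p <- !is.na(table$padj) & table$padj < rule$padjCutoff
  ok_fc <- if (rule$direction == "up") table$log2fc > rule$lfcCutoff
  else table$log2fc < -rule$lfcCutoff
  table$gene_id[ok_p & ok_fc]
}

#' Assign genes to the three-way significance Venn cells
#'
#' Set algebra over the WT, atmc4-1 and atmc9-1 significant sets: each gene
#' in the union lands in exactly one of the seven non-empty Venn cells;
#' genes outside the union are \code{NOT_DEG}. "Depends on AtMC4" is
#' operationalised as significant in WT but not in atmc4-1 under the same
#' rule (no fold-change-ratio test).
#'
#' @param wtSet,m4Set,m9Set character vectors of significant gene ids in the
#'   WT, atmc4-1 and atmc9-1 contrasts.
#' @param universe optional vector of all gene ids; genes in it but outside
#'   the union are reported as \code{NOT_DEG}.
#' @return named character vector: gene id -> dependence class.
#' @export
vennPartition <- function(wtSet, m4Set, m9Set, universe = NULL) {
  genes <- unique(c(wtSet, m4Set, m9Set, universe))
  wt <- genes %in% wtSet
  m4 <- genes %in% m4Set
  m9 <- genes %in% m9Set
  cls <- rep("NOT_DEG", length(genes))
  cls[wt & !m4 & m9] <- "MC4_SPECIFIC"
  cls[wt & m4 & !m9] <- "MC9_SPECIFIC"
  cls[wt & !m4 & !m9] <- "CO_DEPENDENT"
  cls[wt & m4 & m9] <- "MC_INDEPENDENT"
  cls[!wt & !m4 & m9] <- "MC9_REPRESSED"
  cls[!wt & m4 & !m9] <- "MC4_ONLY_MUTANT"
  cls[!wt & m4 & m9] <- "BOTH_MUTANTS_ONLY"
  names(cls) <- genes
  cls
}

#' Split an AtMC4-dependent gene set by Pep1 responsiveness
#'
#' Intersects the AtMC4-dependent wound-induced DEGs with the genes induced
#' by direct Pep1 treatment in WT: the intersection (pep_plus) is the part
#' of the wound response routed through Propep1 cleavage to Pep1; the
#' remainder (pep_minus) implicates other AtMC4 substrates.
#'
#' @param mc4Dependent character vector of AtMC4-dependent gene ids.
#' @param pep1Wt character vector of Pep1-induced gene ids in WT.
#' @return list with disjoint \code{pep_plus} and \code{pep_minus} covering
#'   \code{mc4Dependent}.
#' @export
pep1Split <- function(mc4Dependent, pep1Wt) {
  mc4Dependent <- unique(mc4Dependent)
  list(pep_plus = intersect(mc4Dependent, pep1Wt),
       pep_minus = setdiff(mc4Dependent, pep1Wt))
}

#' Genes de-repressed in a mutant
#'
#' Genes significant in the mutant contrast but not in WT, implying the
#' missing protease normally suppresses them (e.g. the Pep1-induced sets
#' revealed in atmc4-1 and atmc9-1).
#'
#' @param wtSet,mutantSet character vectors of significant gene ids.
#' @return character vector: \code{mutantSet} minus \code{wtSet}.
#' @export
derepressedSet <- function(wtSet, mutantSet) {
  setdiff(mutantSet, wtSet)
}

#' Map (dependence class, Pep1 status) to a marker group
#'
#' @param cls dependence class (vectorised).
#' @param pep1Status \code{"pep_plus"}, \code{"pep_minus"} or
#'   \code{"not_applicable"} (vectorised).
#' @return marker group: GROUP1..GROUP4 or NONE.
#' @export
assignMarkerGroup <- function(cls, pep1Status) {
  out <- rep("NONE", length(cls))
  out[cls == "MC4_SPECIFIC" & pep1Status == "pep_plus"] <- "GROUP1"
  out[cls == "CO_DEPENDENT" & pep1Status == "pep_plus"] <- "GROUP2"
  out[cls == "MC4_SPECIFIC" & pep1Status == "pep_minus"] <- "GROUP3"
  out[cls == "CO_DEPENDENT" & pep1Status == "pep_minus"] <- "GROUP4"
  out
}

# canonical key for a contrast table within a named list
.contrastKey <- function(genotype, treatment) paste(genotype, treatment,
                                                    sep = "_")

#' Full dependence classification across genotypes
#'
#' Runs the whole partition: significant sets from the WT/atmc4-1/atmc9-1
#' wound contrasts, Venn dependence classes, Pep1 status for WT-significant
#' genes and marker groups. \code{pepPlusMode = "pep1_only"} (default) takes
#' the Pep1-induced set from the WT Pep1-infiltration contrast alone;
#' \code{"pep1_or_propep1"} unions it with the WT Propep1+wound contrast.
#' Without a Pep1 contrast, Pep1 status is \code{not_applicable} everywhere
#' and all marker groups are \code{NONE}.
#'
#' @param tables named list of contrast data.frames; names are
#'   \code{"<genotype>_<treatment>"} with genotypes \code{WT},
#'   \code{atmc4-1}, \code{atmc9-1} and treatments \code{wound},
#'   \code{Pep1}, \code{Propep1+wound}, \code{water}, \code{flg22}. The
#'   three wound contrasts are required.
#' @param rule a \code{\link{significanceRule}} applied to every contrast.
#' @param pepPlusMode \code{"pep1_only"} or \code{"pep1_or_propep1"}.
#' @return a \linkS4class{PartitionResult}.
#' @export
classifyDependence <- function(tables, rule = significanceRule(),
                               pepPlusMode = c("pep1_only",
                                               "pep1_or_propep1")) {
  pepPlusMode <- match.arg(pepPlusMode)
  need <- c(.contrastKey("WT", "wound"), .contrastKey("atmc4-1", "wound"),
            .contrastKey("atmc9-1", "wound"))
  missing <- setdiff(need, names(tables))
  if (length(missing))
    .stop("mcwoundConfigError", "missing required contrast table(s): %s",
          paste(missing, collapse = ", "))
  wt <- significantSet(tables[[need[1]]], rule)
  m4 <- significantSet(tables[[need[2]]], rule)
  m9 <- significantSet(tables[[need[3]]], rule)
  cls <- vennPartition(wt, m4, m9)
  pepKey <- .contrastKey("WT", "Pep1")
  propepKey <- .contrastKey("WT", "Propep1+wound")
  havePep <- pepKey %in% names(tables)
  if (havePep) {
    pepSet <- significantSet(tables[[pepKey]], rule)
    if (pepPlusMode == "pep1_or_propep1" && propepKey %in% names(tables))
      pepSet <- union(pepSet, significantSet(tables[[propepKey]], rule))
    wt_sig <- cls %in% c("MC4_SPECIFIC", "MC9_SPECIFIC", "CO_DEPENDENT",
                         "MC_INDEPENDENT")
    pep <- rep("not_applicable", length(cls))
    pep[wt_sig] <- ifelse(names(cls)[wt_sig] %in% pepSet,
                          "pep_plus", "pep_minus")
  } else {
    pep <- rep("not_applicable", length(cls))
  }
  a <- data.frame(gene_id = names(cls), class = unname(cls),
                  pep1_status = pep,
                  marker_group = assignMarkerGroup(unname(cls), pep),
                  stringsAsFactors = FALSE)
  a <- a[order(a$gene_id), , drop = FALSE]
  rownames(a) <- NULL
  new("PartitionResult", assignments = a,
      pepPlusMode = if (havePep) pepPlusMode else "unavailable")
}

#' Summarise a partition
#'
#' Per-class and per-marker-group counts, the AtMC4-dependent total
#' (MC4-specific plus co-dependent), its Pep1-responsive subset, and the
#' Pep1-responsive percentage both at full precision and rounded half-up to
#' the nearest integer percent (the study's reporting convention: 128 of
#' 377 prints as 34\%). Percentages of an empty denominator are NULL.
#'
#' @param partition a \linkS4class{PartitionResult}.
#' @return list with \code{class_counts}, \code{marker_counts},
#'   \code{n_mc4_dependent}, \code{n_pep_plus}, \code{pep_plus_pct},
#'   \code{pep_plus_pct_rounded}, \code{class_pct}.
#' @export
summarizePartition <- function(partition) {
  a <- assignments(partition)
  classCounts <- as.list(table(factor(a$class, levels = DEPENDENCE_CLASSES)))
  classCounts <- lapply(classCounts, as.integer)
  markerCounts <- as.list(table(factor(a$marker_group,
                                       levels = MARKER_GROUPS)))
  markerCounts <- lapply(markerCounts, as.integer)
  mc4dep <- a$class %in% c("MC4_SPECIFIC", "CO_DEPENDENT")
  nMc4 <- sum(mc4dep)
  nPep <- sum(mc4dep & a$pep1_status == "pep_plus")
  pct <- if (nMc4 > 0) 100 * nPep / nMc4 else NULL
  nDeg <- sum(a$class != "NOT_DEG")
  classPct <- if (nDeg > 0)
    lapply(classCounts[setdiff(DEPENDENCE_CLASSES, "NOT_DEG")],
           function(k) 100 * k / nDeg) else NULL
  list(class_counts = classCounts,
       marker_counts = markerCounts,
       n_mc4_dependent = nMc4,
       n_pep_plus = nPep,
       pep_plus_pct = pct,
       pep_plus_pct_rounded = if (is.null(pct)) NULL else roundHalfUp(pct),
       class_pct = classPct)
}

#' Serialise a partition to disk
#'
#' Writes \code{partition.tsv} (gene_id, class, pep1_status, marker_group,
#' sorted by gene id) and \code{summary.json}
#' (\code{\link{summarizePartition}} output). Deterministic: identical
#' inputs give byte-identical files.
#'
#' @param partition a \linkS4class{PartitionResult}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writePartition <- function(partition, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(assignments(partition), file.path(dir, "partition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .writeJson(summarizePartition(partition), file.path(dir, "summary.json"))
  invisible(dir)
}
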