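test_that("significantSet applies strict thresholds and drops missing padj", {
  tab <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                    log2fc = c(3.5, 2.0, 4.0, -3.0, 2.5),
                    padj = c(0.01, 0.01, NA, 0.01, 0.05))
  up <- significantSet(tab, significanceRule(2, 0.05, "up"))
  expect_setequal(up, "a")  # b: lfc not > 2; c: padj missing; e: padj not < .05
  down <- significantSet(tab, significanceRule(2, 0.05, "down"))
  expect_setequal(down, "d")
  expect_length(intersect(up, down), 0L)
})

test_that("contrast tables read with DESeq2-style column aliases", {
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "a.tsv")
  write.table(data.frame(gene_id = c("g1", "g2"),
                         log2FoldChange = c(4, 0), padj = c(1e-6, 0.9)),
              p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- file.path(dir, "b.tsv")
  write.table(data.frame(gene_id = "g1", log2fc = 4, FDR = 1e-6),
              p2, sep = "\t", quote = FALSE, row.names = FALSE)
  t1 <- readContrastTable(p1)
  expect_identical(names(t1), c("gene_id", "log2fc", "padj"))
  t2 <- readContrastTable(p2)
  expect_equal(t2$padj, 1e-6)
  p3 <- file.path(dir, "c.tsv")
  write.table(data.frame(gene = "g1", lfc = 1), p3, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(readContrastTable(p3), class = "mcwoundFormatError")
})

test_that("vennPartition assigns the worked four-gene example", {
  cls <- vennPartition(wtSet = c("a", "b", "c", "d"),
                       m4Set = c("c", "d"), m9Set = c("b", "d"))
  expect_identical(cls[["a"]], "CO_DEPENDENT")
  expect_identical(cls[["b"]], "MC4_SPECIFIC")
  expect_identical(cls[["c"]], "MC9_SPECIFIC")
  expect_identical(cls[["d"]], "MC_INDEPENDENT")
  # induced only in the atmc9-1 background
  expect_identical(vennPartition(character(0), character(0), "x")[["x"]],
                   "MC9_REPRESSED")
  # all sets equal: everything is MC-independent
  cls3 <- vennPartition(c("p", "q"), c("p", "q"), c("p", "q"))
  expect_true(all(cls3 == "MC_INDEPENDENT"))
  # universe genes outside the union are NOT_DEG
  cls4 <- vennPartition("a", character(0), character(0),
                        universe = c("a", "z"))
  expect_identical(cls4[["z"]], "NOT_DEG")
})

test_that("venn cells are disjoint and exhaustive on random triples", {
  set.seed(7)
  genes <- sprintf("g%02d", 1:30)
  for (i in 1:200) {
    wt <- sample(genes, sample(0:30, 1))
    m4 <- sample(genes, sample(0:30, 1))
    m9 <- sample(genes, sample(0:30, 1))
    cls <- vennPartition(wt, m4, m9)
    uni <- union(union(wt, m4), m9)
    expect_setequal(names(cls), uni)
    expect_true(all(cls != "NOT_DEG"))
    expect_identical(anyDuplicated(names(cls)), 0L)
    # membership pattern is reconstructible from the class
    plan <- list(MC4_SPECIFIC = c(TRUE, FALSE, TRUE),
                 MC9_SPECIFIC = c(TRUE, TRUE, FALSE),
                 CO_DEPENDENT = c(TRUE, FALSE, FALSE),
                 MC_INDEPENDENT = c(TRUE, TRUE, TRUE),
                 MC9_REPRESSED = c(FALSE, FALSE, TRUE),
                 MC4_ONLY_MUTANT = c(FALSE, TRUE, FALSE),
                 BOTH_MUTANTS_ONLY = c(FALSE, TRUE, TRUE))
    for (g in names(cls))
      expect_identical(plan[[cls[[g]]]],
                       c(g %in% wt, g %in% m4, g %in% m9))
  }
})

test_that("pep1Split partitions its first argument", {
  expect_identical(pep1Split(c("x", "y"), c("y", "z")),
                   list(pep_plus = "y", pep_minus = "x"))
  expect_identical(pep1Split(character(0), c("a")),
                   list(pep_plus = character(0), pep_minus = character(0)))
  s <- c("a", "b")
  expect_identical(pep1Split(s, s),
                   list(pep_plus = s, pep_minus = character(0)))
  set.seed(3)
  genes <- sprintf("g%02d", 1:30)
  for (i in 1:100) {
    dep <- sample(genes, sample(0:30, 1))
    pep <- sample(genes, sample(0:30, 1))
    sp <- pep1Split(dep, pep)
    expect_length(intersect(sp$pep_plus, sp$pep_minus), 0L)
    expect_setequal(c(sp$pep_plus, sp$pep_minus), dep)
  }
})

test_that("derepressedSet is the mutant-only complement", {
  expect_setequal(derepressedSet("a", c("a", "b")), "b")
  expect_length(derepressedSet(c("a", "b"), c("a", "b")), 0L)
  expect_setequal(derepressedSet(c("x"), c("a", "b")), c("a", "b"))
})

test_that("marker groups map dependence class x Pep1 status", {
  expect_identical(assignMarkerGroup("MC4_SPECIFIC", "pep_plus"), "GROUP1")
  expect_identical(assignMarkerGroup("CO_DEPENDENT", "pep_plus"), "GROUP2")
  expect_identical(assignMarkerGroup("MC4_SPECIFIC", "pep_minus"), "GROUP3")
  expect_identical(assignMarkerGroup("CO_DEPENDENT", "pep_minus"), "GROUP4")
  expect_identical(assignMarkerGroup("MC9_REPRESSED", "pep_plus"), "NONE")
  expect_identical(assignMarkerGroup("MC_INDEPENDENT", "pep_minus"), "NONE")
})

test_that("summaries count classes and reproduce the 34% rounding", {
  # a 377-gene MC4-dependent set with 128 Pep1-responsive members
  n <- 377
  a <- data.frame(gene_id = sprintf("g%03d", 1:n),
                  class = "MC4_SPECIFIC",
                  pep1_status = rep(c("pep_plus", "pep_minus"),
                                    c(128, n - 128)),
                  stringsAsFactors = FALSE)
  a$marker_group <- assignMarkerGroup(a$class, a$pep1_status)
  pr <- new("PartitionResult", assignments = a, pepPlusMode = "pep1_only")
  s <- summarizePartition(pr)
  expect_identical(s$n_mc4_dependent, 377L)
  expect_identical(s$n_pep_plus, 128L)
  expect_equal(s$pep_plus_pct, 100 * 128 / 377)
  expect_identical(s$pep_plus_pct_rounded, 34)
  expect_identical(s$marker_counts$GROUP1, 128L)
  expect_identical(s$marker_counts$GROUP3, 377L - 128L)
})

test_that("empty partitions report null percentages", {
  a <- data.frame(gene_id = character(0), class = character(0),
                  pep1_status = character(0), marker_group = character(0))
  s <- summarizePartition(new("PartitionResult", assignments = a,
                              pepPlusMode = "pep1_only"))
  expect_identical(s$class_counts$MC4_SPECIFIC, 0L)
  expect_null(s$pep_plus_pct)
  expect_null(s$class_pct)
})

test_that("summary counts are invariant under gene-id relabeling", {
  sim <- generateDeTables(seed = 10)
  p1 <- classifyDependence(sim$tables)
  relabel <- lapply(sim$tables, function(t) {
    t$gene_id <- paste0("X", t$gene_id)
    t[rev(seq_len(nrow(t))), , drop = FALSE]
  })
  p2 <- classifyDependence(relabel)
  expect_identical(summarizePartition(p1)$class_counts,
                   summarizePartition(p2)$class_counts)
})

test_that("classifyDependence requires the three wound contrasts", {
  sim <- generateDeTables(seed = 1)
  tabs <- sim$tables
  tabs[["atmc9-1_wound"]] <- NULL
  expect_error(classifyDependence(tabs), class = "mcwoundConfigError")
})

test_that("without a Pep1 contrast, Pep1 features degrade to NONE", {
  sim <- generateDeTables(seed = 1)
  tabs <- sim$tables[c("WT_wound", "atmc4-1_wound", "atmc9-1_wound")]
  p <- classifyDependence(tabs)
  a <- assignments(p)
  expect_true(all(a$pep1_status == "not_applicable"))
  expect_true(all(a$marker_group == "NONE"))
  expect_identical(p@pepPlusMode, "unavailable")
})

test_that("pep1_or_propep1 mode widens the Pep1-responsive set", {
  sim <- generateDeTables(seed = 6)
  tabs <- sim$tables
  # a propep1 contrast that adds one otherwise pep_minus gene
  minusGene <- sim$truth$gene_id[sim$truth$class == "MC4_SPECIFIC" &
                                   sim$truth$pep1_status == "pep_minus"][1]
  tabs[["WT_Propep1+wound"]] <-
    data.frame(gene_id = minusGene, log2fc = 5, padj = 1e-8)
  pOnly <- assignments(classifyDependence(tabs, pepPlusMode = "pep1_only"))
  pUnion <- assignments(classifyDependence(tabs,
                                           pepPlusMode = "pep1_or_propep1"))
  expect_identical(pOnly$pep1_status[pOnly$gene_id == minusGene],
                   "pep_minus")
  expect_identical(pUnion$pep1_status[pUnion$gene_id == minusGene],
                   "pep_plus")
})
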