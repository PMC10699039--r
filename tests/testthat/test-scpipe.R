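## Single-cell stage: QC, normalization, HVG, clustering grid, cell cycle,
## lineage assignment, differential expression.

test_that("QC removes exactly the threshold violators", {
  ## 30 genes x 12 cells; plant one violation of each criterion
  set.seed(1)
  counts <- matrix(rpois(30 * 12, 60), 30, 12)
  rownames(counts) <- c(sprintf("G%02d", 1:28), "MT-A", "RARE")
  colnames(counts) <- sprintf("c%02d", 1:12)
  counts["RARE", ] <- 0
  counts["RARE", 1:4] <- 1                      # detected in 4 cells < 5
  counts["MT-A", ] <- 10
  counts[, 1] <- 0; counts[1:10, 1] <- 99       # 990 UMIs < 1000
  counts["MT-A", 2] <- 900                      # mito fraction > 20%
  sce <- makeSCE(counts)
  res <- qcFilter(sce, qcConfig(minGenes = 5))
  expect_false("RARE" %in% rownames(res$sce))
  expect_false(any(c("c01", "c02") %in% colnames(res$sce)))
  expect_equal(res$report$removed_genes, 1)
  expect_equal(res$report$removed_low_umi, 1)
  expect_equal(res$report$removed_high_mito, 1)
  ## a clean matrix passes unchanged
  clean <- makeSCE(matrix(rpois(30 * 8, 80), 30, 8,
                          dimnames = list(sprintf("G%02d", 1:30),
                                          sprintf("k%02d", 1:8))))
  res2 <- qcFilter(clean, qcConfig(minGenes = 10))
  expect_identical(dim(res2$sce), dim(clean))
  expect_error(qcFilter(clean, qcConfig(minUmi = 1e9)), "removed")
})

test_that("QC is idempotent on generated data", {
  cohort <- generateScCohort(smallScConfig(seed = 2, n = 600, patients = 1))
  once <- qcFilter(cohort[[1]]$counts)
  twice <- qcFilter(once$sce)
  expect_identical(dim(once$sce), dim(twice$sce))
  expect_equal(twice$report$removed_genes + twice$report$removed_low_umi +
               twice$report$removed_low_genes + twice$report$removed_high_mito,
               0)
})

test_that("log-normalization formula and scale invariance", {
  counts <- matrix(0, 3, 2, dimnames = list(c("a", "b", "c"), c("x", "y")))
  counts[, 1] <- c(100, 9900, 0)
  counts[, 2] <- c(200, 19800, 0)               # cell y = 2x
  sce <- logNormalize(makeSCE(counts))
  ln <- as.matrix(assay(sce, "logcounts"))
  expect_equal(ln["a", "x"], log(101))
  expect_equal(ln["c", "x"], 0)
  expect_equal(ln[, "x"], ln[, "y"])            # doubling leaves it unchanged
  zero <- makeSCE(matrix(0, 2, 2))
  expect_error(logNormalize(zero), "zero-total")
})

test_that("variance-stabilized HVG ranks planted overdispersed genes high", {
  ## overdispersed genes via tiny NB size
  genes <- TILprofiler:::.defaultGeneUniverse()
  od <- sprintf("FILLER%03d", 1:10)
  cohort <- generateScCohort(scSimConfig(
    nPatients = 1, cellsPerPatient = 1000, seed = 5,
    dispersionOverride = setNames(rep(0.05, 10), od)))
  sce <- cohort[[1]]$counts
  hv <- selectHVG(sce, n = nrow(sce) %/% 10)    # top decile
  expect_gte(sum(od %in% hv), 9)
  ## constant gene is never selected while variable genes exist
  counts <- matrix(rpois(40 * 30, 5), 40, 30)
  counts[1, ] <- 7
  rownames(counts) <- sprintf("G%02d", 1:40)
  sce2 <- makeSCE(counts)
  expect_false("G01" %in% selectHVG(sce2, n = 20))
  expect_warning(all40 <- selectHVG(sce2, n = 3000), "available")
  expect_length(all40, 40)
})

test_that("clustering grid recovers well-separated planted populations", {
  ## three strong programs, 60 informative genes
  set.seed(6)
  n <- 240
  truth <- rep(1:3, each = n / 3)
  mu <- matrix(0.2, 90, n)
  for (kk in 1:3) mu[(kk - 1) * 20 + 1:20, truth == kk] <- 6
  mu[61:90, ] <- 30                              # housekeeping
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 2), nrow(mu))
  rownames(counts) <- sprintf("G%02d", seq_len(nrow(counts)))
  sce <- logNormalize(makeSCE(counts))
  hvg <- selectHVG(sce, n = 60)
  res <- reduceAndCluster(sce, hvg, dimsGrid = c(3, 5, 7),
                          resGrid = seq(0.2, 0.8, 0.2), seed = 3)
  expect_gte(mclust::adjustedRandIndex(res$labels, truth), 0.9)
  ## identical partitions at adjacent resolutions give stability 1
  expect_true(any(res$report$stability == 1))
  expect_warning(
    reduceAndCluster(sce, hvg, dimsGrid = c(3, 500),
                     resGrid = c(0.4, 0.5), seed = 1),
    "dropping")
})

test_that("cell-cycle scoring calls a planted G2M program", {
  set.seed(8)
  counts <- matrix(rpois(200 * 150, 3), 200, 150,
                   dimnames = list(sprintf("G%03d", 1:200),
                                   sprintf("c%03d", 1:150)))
  g2m <- sprintf("G%03d", 1:10)
  s <- sprintf("G%03d", 11:20)
  planted <- 1:50
  counts[g2m, planted] <- matrix(rpois(10 * 50, 3 * 4), 10)  # +2 log2 units
  sce <- logNormalize(makeSCE(counts))
  cc <- scoreCellCycle(sce, s, g2m, seed = 1)
  expect_gte(mean(cc$phase[planted] == "G2M"), 0.95)
  ## determinism
  cc2 <- scoreCellCycle(sce, s, g2m, seed = 1)
  expect_identical(cc, cc2)
  expect_error(scoreCellCycle(sce, c("NOPE1", "NOPE2"), g2m), "missing")
  ## an all-zero cell scores ~0 on both sets and falls to G1
  counts0 <- cbind(counts, zero = 0)
  counts0[21, "zero"] <- 1      # keep the library nonzero for normalization
  sce0 <- logNormalize(makeSCE(counts0))
  cc0 <- scoreCellCycle(sce0, s, g2m, seed = 1)
  expect_identical(cc0["zero", "phase"], "G1")
})

test_that("lineage assignment follows canonical markers", {
  cohort <- generateScCohort(smallScConfig(seed = 9, n = 1500, patients = 1))
  el <- cohort[[1]]
  sce <- logNormalize(el$counts)
  clusters <- setNames(el$truth$cluster, el$truth$barcode)
  lin <- assignLineage(clusters, sce)
  expect_identical(unname(lin["CD4.Treg"]), "Treg")
  expect_identical(unname(lin[c("CD8.EM", "CD8.exhausted", "CD8.cytotoxic")]),
                   rep("CD8", 3))
  ## exactly one cluster earns the Treg label in the default cohort
  expect_equal(sum(lin == "Treg"), 1)
  ## a cluster expressing only CD8A/CD8B among markers is CD8
  counts <- matrix(1, 6, 40, dimnames = list(
    c("CD8A", "CD8B", "CD4", "IL7R", "FOXP3", "IL2RA"), NULL))
  counts[c("CD4", "IL7R", "FOXP3", "IL2RA"), 1:20] <- 0
  counts[c("CD8A", "CD8B"), 21:40] <- 0
  sce2 <- logNormalize(makeSCE(counts))
  expect_warning(
    lin2 <- assignLineage(rep(c("a", "b"), each = 20), sce2,
                          foxp3Fraction = 0.99),
    "tie")
  expect_identical(unname(lin2["a"]), "CD8")
})

test_that("differential expression recovers planted effects with filters", {
  set.seed(10)
  n <- 50
  counts <- matrix(rnbinom(300 * 2 * n, mu = 2, size = 2), 300,
                   dimnames = list(sprintf("G%03d", 1:300), NULL))
  counts["G001", 1:n] <- rnbinom(n, mu = 8, size = 2)    # 4-fold up in A
  sce <- logNormalize(makeSCE(counts))
  de <- differentialExpression(sce, seq_len(n), n + seq_len(n))
  expect_true("G001" %in% de$gene)
  expect_gt(de$avg_log2FC[de$gene == "G001"], 0)
  ## all reported genes satisfy the printed filters
  expect_true(all(abs(de$avg_log2FC) >= 0.58))
  expect_true(all(pmax(de$pct.1, de$pct.2) >= 0.25))
  expect_true(all(de$p_val_adj < 0.05))
  ## antisymmetry
  deR <- differentialExpression(sce, n + seq_len(n), seq_len(n))
  shared <- intersect(de$gene, deR$gene)
  expect_equal(de$avg_log2FC[match(shared, de$gene)],
               -deR$avg_log2FC[match(shared, deR$gene)])
  expect_equal(de$p_val[match(shared, de$gene)],
               deR$p_val[match(shared, deR$gene)])
  expect_error(differentialExpression(sce, 1:10, 5:20), "overlap")
  expect_error(differentialExpression(sce, 1:2, 3:10), ">= 3")
})

test_that("duplicated identical groups yield no differential genes", {
  set.seed(11)
  counts <- matrix(rnbinom(100 * 30, mu = 3, size = 2), 100)
  rownames(counts) <- sprintf("G%03d", 1:100)
  dup <- cbind(counts, counts)
  colnames(dup) <- sprintf("c%03d", 1:60)
  sce <- logNormalize(makeSCE(dup))
  de <- differentialExpression(sce, 1:30, 31:60)
  expect_equal(nrow(de), 0)
})

test_that("differential expression agrees with an independent implementation", {
  skip_if_not_installed("Seurat")
  set.seed(12)
  n <- 40
  counts <- matrix(rnbinom(120 * 2 * n, mu = 3, size = 2), 120,
                   dimnames = list(sprintf("G%03d", 1:120),
                                   sprintf("c%03d", 1:(2 * n))))
  counts[1:5, 1:n] <- matrix(rnbinom(5 * n, mu = 12, size = 2), 5)
  sce <- logNormalize(makeSCE(counts))
  mine <- differentialExpression(sce, seq_len(n), n + seq_len(n),
                                 alpha = 1, allResults = TRUE)
  so <- suppressWarnings(Seurat::CreateSeuratObject(counts))
  so <- suppressWarnings(Seurat::NormalizeData(so, verbose = FALSE))
  grp <- factor(rep(c("A", "B"), each = n))
  names(grp) <- colnames(counts)
  Seurat::Idents(so) <- grp
  ref <- suppressWarnings(Seurat::FindMarkers(
    so, ident.1 = "A", ident.2 = "B",
    logfc.threshold = 0.58, min.pct = 0.25, verbose = FALSE))
  shared <- intersect(mine$gene, rownames(ref))
  expect_gt(length(shared), 0)
  ## the reference scales its fold-change pseudocount per cell, so small
  ## absolute deviations are expected
  expect_equal(mine$avg_log2FC[match(shared, mine$gene)],
               ref[shared, "avg_log2FC"], tolerance = 0.02)
  expect_equal(mine$p_val[match(shared, mine$gene)],
               ref[shared, "p_val"], tolerance = 0.02)
})
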