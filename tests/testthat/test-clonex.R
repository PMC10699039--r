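## Clonality x checkpoint-expression stratification.

## A small cohort with hand-set expression for the panel genes:
## patients with clonotyped cells, explicit HE/LE structure.
buildPanelSCE <- function(expr, patient = "P01") {
  genes <- icpGenes()
  stopifnot(nrow(expr) == length(genes))
  counts <- rbind(expr, HK = 50)
  rownames(counts) <- c(genes, "HK01")
  sce <- makeSCE(counts, patient = patient)
  logNormalize(sce)
}

test_that("per-patient medians follow the definition", {
  expr <- matrix(0, 10, 3)
  expr[1, ] <- c(0, 1, 2)
  sce <- buildPanelSCE(expr)
  med <- icpMedians(sce, clonotyped = rep(TRUE, 3))
  ## median of normalized values of counts (0, 1, 2)
  ln <- as.matrix(assay(sce, "logcounts"))
  expect_equal(med["P01", "IL2RA"], median(ln["IL2RA", ]))
  ## genes expressed in under half the cells have median 0
  expect_equal(unname(med["P01", "CD28"]), 0)
  ## invariant to cell order
  med2 <- icpMedians(sce[, 3:1], clonotyped = rep(TRUE, 3))
  expect_equal(med, med2)
  expect_warning(icpMedians(sce, rep(TRUE, 3), panel = c("IL2RA", "NOPE")),
                 "absent")
})

test_that("majority rule classifies cells by indicator count", {
  ## all medians zero; a cell expressing 6 of 10 panel genes is HE,
  ## a zero cell is LE
  expr <- matrix(0, 10, 21)
  expr[1:6, 1] <- 5
  expr[1:4, 2] <- 5
  sce <- buildPanelSCE(expr)
  med <- icpMedians(sce, clonotyped = rep(TRUE, 21))
  expect_true(all(med == 0))
  cls <- classifyExpression(sce, med)
  expect_identical(unname(cls[1]), "HE")   # 6 of 10 indicators
  expect_identical(unname(cls[2]), "LE")   # 4 of 10
  expect_identical(unname(cls[3]), "LE")   # zero expression
})

test_that("planted high-checkpoint cells are nearly all HE", {
  set.seed(20)
  n <- 400
  expr <- matrix(rbinom(10 * n, 1, 0.2) * rpois(10 * n, 3), 10, n)
  planted <- 1:100
  expr[sample(1:10, 8), planted] <- rpois(8 * 100, 4) + 1  # 8 of 10 expressed
  sce <- buildPanelSCE(expr)
  med <- icpMedians(sce, clonotyped = rep(TRUE, n))
  cls <- classifyExpression(sce, med)
  expect_gte(mean(cls[planted] == "HE"), 0.95)
})

test_that("compartments join clonality and expression and sum to 100", {
  cohort <- generateScCohort(smallScConfig(seed = 23, n = 1500, patients = 2))
  pieces <- cohortPieces(cohort)
  cells <- as.data.frame(clonotypeCells(pieces$ct))
  clonotyped <- cells$barcode[!is.na(cells$clonotype_id)]
  med <- icpMedians(pieces$sce, clonotyped)
  he <- classifyExpression(pieces$sce, med)
  comp <- compartmentalize(he, pieces$ct, pieces$clusters, defaultLineageMap)
  ## definition: HC cell + HE state -> HC_HE
  d <- comp$cells
  expect_true(all(d$compartment ==
                  paste(d$clonality, d$expression, sep = "_")))
  ## compositions sum to 100 per cluster, compartments partition cells
  expect_equal(unname(rowSums(comp$byCluster)),
               rep(100, nrow(comp$byCluster)))
  expect_equal(nrow(d), sum(cells$clonality %in% c("HC", "LC")))
  ## the planted association concentrates HC_HE CD4 cells in the Treg cluster
  expect_gte(comp$tregShareHCHE, 75)
})

test_that("checkpoint burden counts detected panel genes", {
  expr <- matrix(0, 10, 2)
  expr[c(1, 5, 6), 1] <- c(3, 1, 7)   # IL2RA, CTLA4, ICOS detected
  sce <- buildPanelSCE(expr)
  contigs <- makeContigs(list(colnames(sce)[1:2]))
  ct <- suppressMessages(callClonotypes(contigs, "P01",
                                        barcodes = colnames(sce)))
  bur <- icpBurden(sce, ct, setNames(rep("k1", 2), colnames(sce)))
  expect_equal(unname(bur$burden[1]), 3)
  expect_equal(unname(bur$burden[2]), 0)
  expect_true(all(bur$burden <= 10))
})

test_that("burden shift between HC and LC Tregs matches the NB expectation", {
  ## Treg-enriched cohort for power; seed-averaged
  props <- c(CD8.EM = 0.2, CD8.exhausted = 0.1, CD8.cytotoxic = 0.1,
             CD4.EM = 0.05, CD4.TFH = 0.05, CD4.Treg = 0.5)
  cfg <- NULL
  shifts <- vapply(1:3, function(s) {
    cfg <<- smallScConfig(seed = 500 + s, n = 2000, patients = 1,
                          clusterProps = props)
    cohort <- generateScCohort(cfg)
    pieces <- cohortPieces(cohort)
    bur <- icpBurden(pieces$sce, pieces$ct, pieces$clusters)
    row <- bur$byCluster[bur$byCluster$cluster == "CD4.Treg", ]
    expect_lt(row$p_adj[1], 0.01)
    row$mean_HC - row$mean_LC
  }, numeric(1))
  ## analytic expectation: detection probability difference summed over
  ## the panel, 1 - (size / (size + mu))^size per gene, integrated over
  ## the log-normal library-size factor
  genes <- icpGenes()
  progs <- TILprofiler:::.defaultClusterPrograms()$CD4.Treg
  base <- cfg$baseMeans[genes]
  fold <- ifelse(genes %in% names(progs), 2^progs[genes], 1)
  muLC <- base * fold
  muHC <- muLC * 2^cfg$plantedIcpEffect
  size <- cfg$nbDispersion
  lib <- exp(qnorm(ppoints(2001)) * cfg$libSd)
  det <- function(mu) mean(1 - (size / (size + outer(lib, mu)))^size) * length(mu)
  expected <- det(muHC) - det(muLC)
  expect_gt(expected, 0.8)   # the default effect plants a shift near one
  expect_lt(abs(mean(shifts) - expected), 0.2)
})

test_that("LC/HC differential map recovers the planted fold change", {
  cohort <- generateScCohort(smallScConfig(seed = 31, n = 2000, patients = 2))
  pieces <- cohortPieces(cohort)
  dif <- lcHcDifferential(pieces$sce, pieces$ct, pieces$clusters)
  ## planted twofold effect on ENTPD1 in the Treg cluster
  expect_lt(abs(dif["CD4.Treg", "ENTPD1"] - 1), 0.3)
  ## identical expression of HC and LC cells gives zero
  expr <- matrix(3, 10, 40)
  sce <- buildPanelSCE(expr)
  bcs <- colnames(sce)
  contigs <- makeContigs(c(list(bcs[1:20]), as.list(bcs[21:40])))
  ct <- suppressMessages(callClonotypes(contigs, "P01", barcodes = bcs))
  d0 <- lcHcDifferential(sce, ct, setNames(rep("k1", 40), bcs), minCells = 5)
  expect_true(all(d0["k1", ] == 0))
  ## a cluster with no LC cells anywhere is missing
  ctHC <- suppressMessages(callClonotypes(makeContigs(list(bcs[1:40])),
                                          "P01", barcodes = bcs))
  dNA <- lcHcDifferential(sce, ctHC, setNames(rep("k1", 40), bcs),
                          minCells = 5)
  expect_true(all(is.na(dNA["k1", ])))
})

test_that("null planted effect centres the differential map at zero", {
  meds <- vapply(1:5, function(s) {
    cohort <- generateScCohort(scSimConfig(
      nPatients = 1, cellsPerPatient = 1500, plantedIcpEffect = 0,
      seed = 300 + s))
    pieces <- cohortPieces(cohort)
    dif <- lcHcDifferential(pieces$sce, pieces$ct, pieces$clusters,
                            minCells = 5)
    median(dif, na.rm = TRUE)
  }, numeric(1))
  expect_lt(max(abs(meds)), 0.15)
})

test_that("HE fraction is balanced under exchangeable expression", {
  set.seed(40)
  for (rep in 1:3) {
    expr <- matrix(rpois(10 * 300, 2), 10, 300)   # iid columns
    sce <- buildPanelSCE(expr)
    med <- icpMedians(sce, clonotyped = rep(TRUE, 300))
    cls <- classifyExpression(sce, med)
    he <- mean(cls == "HE")
    expect_gte(he, 0.2); expect_lte(he, 0.8)
  }
})

test_that("clonex outputs are invariant under cell reordering", {
  cohort <- generateScCohort(smallScConfig(seed = 33, n = 800, patients = 1))
  pieces <- cohortPieces(cohort)
  cells <- as.data.frame(clonotypeCells(pieces$ct))
  clonotyped <- cells$barcode[!is.na(cells$clonotype_id)]
  med1 <- icpMedians(pieces$sce, clonotyped)
  he1 <- classifyExpression(pieces$sce, med1)
  perm <- sample(ncol(pieces$sce))
  sceP <- pieces$sce[, perm]
  med2 <- icpMedians(sceP, clonotyped)
  he2 <- classifyExpression(sceP, med2)
  expect_equal(med1, med2)
  expect_equal(he1[names(he2)], he2)
  comp1 <- compartmentalize(he1, pieces$ct, pieces$clusters,
                            defaultLineageMap)
  comp2 <- compartmentalize(he2, pieces$ct, pieces$clusters,
                            defaultLineageMap)
  expect_equal(comp1$byCluster, comp2$byCluster)
  expect_equal(comp1$tregShareHCHE, comp2$tregShareHCHE)
})
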