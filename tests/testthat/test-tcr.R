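## Clonotype calling, repertoire metrics, cross-cluster sharing.

test_that("clonotype keys group identical productive chain sets", {
  contigs <- makeContigs(list(c("bc1", "bc2"),          # clone of 2
                              c("bc3", "bc4", "bc5"),   # clone of 3
                              "bc6"))                   # singleton
  ct <- callClonotypes(contigs, patient = "P1")
  d <- as.data.frame(clonotypeCells(ct))
  expect_equal(d$clonotype_id[d$barcode == "bc1"],
               d$clonotype_id[d$barcode == "bc2"])
  expect_equal(d$clone_size[d$barcode == "bc1"], 2)
  expect_equal(d$clonality[d$barcode == "bc1"], "LC")
  expect_equal(d$clonality[d$barcode == "bc3"], "HC")
  expect_equal(d$size_class[d$barcode == "bc3"], "3-10")
  expect_equal(d$size_class[d$barcode == "bc6"], "1")
})

test_that("a shared beta chain alone does not merge strict clonotypes", {
  contigs <- makeContigs(list("bc1", "bc2"))
  ## give bc2 the TRB of bc1 but keep its own TRA
  trb1 <- contigs$chain == "TRB" & contigs$barcode == "bc1"
  trb2 <- contigs$chain == "TRB" & contigs$barcode == "bc2"
  contigs[trb2, c("v_gene", "j_gene", "cdr3", "cdr3_nt")] <-
    contigs[trb1, c("v_gene", "j_gene", "cdr3", "cdr3_nt")]
  ct <- callClonotypes(contigs, patient = "P1")
  d <- as.data.frame(clonotypeCells(ct))
  expect_false(d$clonotype_id[1] == d$clonotype_id[2])
  ## under the beta-only key they do merge
  ctB <- callClonotypes(contigs, patient = "P1", keyMode = "beta")
  dB <- as.data.frame(clonotypeCells(ctB))
  expect_equal(dB$clonotype_id[1], dB$clonotype_id[2])
})

test_that("malformed chains and unmatched barcodes are dropped with a note", {
  contigs <- makeContigs(list("bc1", "bc2"))
  contigs$chain[1] <- "IGH"
  expect_message(callClonotypes(contigs, "P1"), "malformed chain")
  expect_message(
    ct <- callClonotypes(contigs[-1, ], "P1", barcodes = c("bc1", "bc9")),
    "without matching cell")
  d <- as.data.frame(clonotypeCells(ct))
  expect_setequal(d$barcode, c("bc1", "bc9"))
  expect_equal(d$clonality[d$barcode == "bc9"], "none")
})

test_that("cells without productive contigs get no clonotype", {
  contigs <- makeContigs(list("bc1", "bc2"))
  contigs$productive[contigs$barcode == "bc2"] <- "false"
  ct <- callClonotypes(contigs, "P1")
  d <- as.data.frame(clonotypeCells(ct))
  expect_true(is.na(d$clonotype_id[d$barcode == "bc2"]))
  expect_equal(d$clonality[d$barcode == "bc2"], "none")
  expect_equal(d$n_productive_chains[d$barcode == "bc1"], 2)
})

test_that("clonotype calling is invariant to contig row order", {
  cohort <- generateScCohort(smallScConfig(seed = 3, n = 500, patients = 1))
  contigs <- cohort[[1]]$contigs
  ct1 <- callClonotypes(contigs, "P01")
  set.seed(1)
  ct2 <- callClonotypes(contigs[sample(nrow(contigs)), ], "P01")
  d1 <- as.data.frame(clonotypeCells(ct1))
  d2 <- as.data.frame(clonotypeCells(ct2))
  d2 <- d2[match(d1$barcode, d2$barcode), ]
  expect_equal(d1$clone_size, d2$clone_size)
  ## same partition into clonotypes (ids may be numbered differently)
  expect_equal(mclust::adjustedRandIndex(d1$clonotype_id[!is.na(d1$clonotype_id)],
                                         d2$clonotype_id[!is.na(d2$clonotype_id)]),
               1)
})

test_that("repertoire metrics count clones and expanded cells by definition", {
  ## clone sizes {1,1,2,2,3,3,3}: 7 cells, 3/7 expanded
  contigs <- makeContigs(list("c1", "c2", c("c3", "c4"), c("c5", "c6", "c7")))
  ct <- callClonotypes(contigs, "P1")
  clusters <- setNames(rep("k1", 7), paste0("c", 1:7))
  met <- repertoireMetrics(ct, clusters,
                           lineages = c(k1 = "CD8"))
  expect_equal(met$byCluster$n_clonotypes, 4)
  expect_equal(met$byCluster$pct_productive, 100)
  expect_equal(unname(met$expandedByLineage["CD8"]), 100 * 3 / 7)
  ## all singletons: diversity = n cells, no expansion
  contigs2 <- makeContigs(as.list(paste0("s", 1:5)))
  ct2 <- callClonotypes(contigs2, "P2")
  met2 <- repertoireMetrics(ct2, setNames(rep("k1", 5), paste0("s", 1:5)),
                            lineages = c(k1 = "CD4"))
  expect_equal(met2$byCluster$n_clonotypes, 5)
  expect_equal(unname(met2$expandedByLineage["CD4"]), 0)
  ## size classes partition the clonotyped cells
  expect_equal(sum(met$sizeClassCounts$n_cells), 7)
})

test_that("sharing fraction counts clonotypes spanning clusters", {
  ## 10 clonotypes, one spans two clusters
  bcs <- paste0("b", 1:11)
  contigs <- makeContigs(c(as.list(bcs[1:9]), list(bcs[10:11])))
  ct <- callClonotypes(contigs, "P1")
  clusters <- setNames(c(rep("k1", 10), "k2"), bcs)
  sh <- clonotypeSharing(ct, clusters)
  expect_equal(sh$pooled, 10)
  expect_equal(sh$perPatient$n_shared, 1)
  expect_equal(nrow(sh$flows), 1)
  expect_equal(sh$flows$n_cells_a + sh$flows$n_cells_b, 2)
  ## clonotypes confined to one cluster share nothing
  sh0 <- clonotypeSharing(ct, setNames(c(rep("k1", 5), rep("k2", 6)), bcs))
  expect_equal(sh0$pooled, 0)
  ## relabeling clusters leaves the sharing fraction unchanged
  relab <- c(k1 = "A", k2 = "B")
  shR <- clonotypeSharing(ct, setNames(relab[clusters], names(clusters)))
  expect_equal(shR$pooled, sh$pooled)
})

test_that("clonotype identifiers never span patients", {
  cohort <- generateScCohort(smallScConfig(seed = 4, n = 400, patients = 2))
  pieces <- cohortPieces(cohort)
  d <- as.data.frame(clonotypeCells(pieces$ct))
  tab <- unique(d[!is.na(d$clonotype_id), c("clonotype_id", "patient")])
  expect_false(anyDuplicated(tab$clonotype_id) > 0)
})
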