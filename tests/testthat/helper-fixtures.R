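## Shared fixture builders. Everything is generated in code at test time.

suppressPackageStartupMessages({
  library(Matrix)
  library(SummarizedExperiment)
  library(SingleCellExperiment)
})

## A tiny FlowSample with explicit values (cells x markers).
makeFlowSample <- function(values, sampleId = "toy") {
  FlowSample(values, sampleId = sampleId)
}

## A FlowSample row for hand-built gating cases: one named cell with the
## 15 standard markers, high = 1000, low = 10 by default.
flowCell <- function(high = character(0), low = NULL) {
  markers <- c(lineageMarkers(), icpProteins())
  if (is.null(low)) low <- setdiff(markers, high)
  v <- setNames(rep(10, length(markers)), markers)
  v[high] <- 1000
  v
}

## SingleCellExperiment from a dense genes x cells matrix.
makeSCE <- function(counts, patient = "P01") {
  counts <- as(Matrix(as.matrix(counts), sparse = TRUE), "CsparseMatrix")
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("%s_c%03d", patient, seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("G%03d", seq_len(nrow(counts)))
  SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(barcode = colnames(counts),
                                   patient = patient,
                                   row.names = colnames(counts)))
}

## A minimal contig table: one productive TRA+TRB pair per cell, shared
## within each clone group.
makeContigs <- function(barcodesByClone) {
  rows <- list()
  for (i in seq_along(barcodesByClone)) {
    for (bc in barcodesByClone[[i]]) {
      rows[[length(rows) + 1]] <- data.frame(
        barcode = bc, chain = c("TRA", "TRB"),
        v_gene = c(paste0("TRAV", i), paste0("TRBV", i)),
        j_gene = c(paste0("TRAJ", i), paste0("TRBJ", i)),
        cdr3 = c(paste0("CAV", i, "F"), paste0("CAS", i, "F")),
        cdr3_nt = c(strrep("TGC", 5 + i), strrep("GCA", 5 + i)),
        productive = "true", stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

## Small sc cohort for fast downstream tests.
smallScConfig <- function(seed = 1, n = 1200, patients = 2, ...) {
  scSimConfig(nPatients = patients, cellsPerPatient = n, seed = seed, ...)
}

## Truth-labeled cluster vector (named by barcode) from a cohort element.
truthClusters <- function(cohort) {
  tr <- do.call(rbind, lapply(cohort, `[[`, "truth"))
  setNames(tr$cluster, tr$barcode)
}

defaultLineageMap <- c(CD8.EM = "CD8", CD8.exhausted = "CD8",
                       CD8.cytotoxic = "CD8", CD4.EM = "CD4",
                       CD4.TFH = "CD4", CD4.Treg = "Treg")

## Clonotype tables + merged normalized matrix for a cohort.
cohortPieces <- function(cohort) {
  tabs <- lapply(cohort, function(el)
    suppressMessages(callClonotypes(el$contigs, el$truth$patient[1],
                                    colnames(el$counts))))
  ct <- combineClonotypes(tabs)
  sce <- logNormalize(mergePatients(lapply(cohort, `[[`, "counts")))
  list(ct = ct, sce = sce, clusters = truthClusters(cohort))
}
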