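## Readers and writers for the standard interchange formats: MatrixMarket
## counts with barcodes/features sidecars (10x convention, genes x cells),
## 10x-style filtered-contig CSV, flow CSV (one row per cell), TSV tables
## and truth JSON.

#' Write a count matrix as MatrixMarket + sidecars
#'
#' Writes `matrix.mtx` (coordinate format, 1-based indices, genes x
#' cells), `features.tsv` and `barcodes.tsv` into `dir`.
#'
#' @param sce a SingleCellExperiment with a `counts` assay (or a sparse
#'   genes x cells matrix).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCountsMTX <- function(sce, dir) {
  counts <- if (is(sce, "SummarizedExperiment")) assay(sce, "counts") else sce
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  utils::write.table(
    data.frame(id = rownames(counts), name = rownames(counts),
               type = "Gene Expression"),
    file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a MatrixMarket count directory
#'
#' Reads `matrix.mtx` + `features.tsv` + `barcodes.tsv` (1-based indices
#' per the MatrixMarket standard). Duplicate gene symbols are summed.
#'
#' @param dir directory containing the three files.
#' @param patient patient identifier stored in `colData`.
#' @return a [SingleCellExperiment::SingleCellExperiment] with a `counts`
#'   assay.
#' @export
readCountsMTX <- function(dir, patient = basename(dir)) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) stop("no matrix.mtx in ", dir)
  header <- readLines(mtx, n = 1)
  if (!startsWith(header, "%%MatrixMarket"))
    stop("malformed MatrixMarket header at line 1 of ", mtx)
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  feats <- utils::read.table(file.path(dir, "features.tsv"), sep = "\t",
                             stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  if (nrow(feats) != nrow(m) || length(barcodes) != ncol(m))
    stop("sidecar dimensions do not match the matrix")
  sym <- feats[[min(2, ncol(feats))]]
  if (anyDuplicated(sym)) {
    agg <- methods::as(Matrix::sparseMatrix(
      i = match(sym, unique(sym)), j = seq_along(sym), x = 1,
      dims = c(length(unique(sym)), length(sym))), "CsparseMatrix")
    m <- agg %*% m
    sym <- unique(sym)
  }
  rownames(m) <- sym
  colnames(m) <- barcodes
  SingleCellExperiment(
    assays = list(counts = m),
    colData = DataFrame(barcode = barcodes, patient = patient,
                        row.names = barcodes))
}

#' Contig annotation CSV IO
#'
#' 10x `filtered_contig_annotations.csv` conventions; unknown extra
#' columns are preserved on read and ignored downstream.
#'
#' @param path CSV path.
#' @return data.frame of contig rows.
#' @export
readContigCSV <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname readContigCSV
#' @param contigs contig data.frame.
#' @export
writeContigCSV <- function(contigs, path) {
  utils::write.csv(contigs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Flow CSV IO
#'
#' One row per cell, one column per marker, header = marker names.
#'
#' @param path CSV path.
#' @param sampleId sample identifier for the constructed object.
#' @return [FlowSample-class] (read) or `path` invisibly (write).
#' @export
readFlowCSV <- function(path, sampleId = sub("[.]csv$", "", basename(path))) {
  vals <- as.matrix(utils::read.csv(path, check.names = FALSE))
  FlowSample(vals, sampleId = sampleId)
}

#' @rdname readFlowCSV
#' @param m a FlowSample.
#' @export
writeFlowCSV <- function(m, path) {
  utils::write.csv(as.data.frame(fluorescence(m)), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Concatenate per-patient count objects
#'
#' Column-binds per-patient SingleCellExperiments (no batch correction;
#' genes must agree).
#'
#' @param sces list of SingleCellExperiments with `counts` and a
#'   `patient` column in `colData`.
#' @return one merged SingleCellExperiment.
#' @export
mergePatients <- function(sces) {
  mats <- lapply(sces, function(s) assay(s, "counts"))
  genes <- rownames(mats[[1]])
  if (!all(vapply(mats, function(m) identical(rownames(m), genes),
                  logical(1))))
    stop("gene sets differ between patients")
  counts <- Reduce(Matrix::cbind2, mats)
  bcs <- unlist(lapply(mats, colnames), use.names = FALSE)
  pats <- rep(vapply(sces, function(s) as.character(colData(s)$patient[1]),
                     character(1)),
              vapply(mats, ncol, integer(1)))
  colnames(counts) <- bcs
  SingleCellExperiment(
    assays = list(counts = counts),
    colData = DataFrame(barcode = bcs, patient = pats, row.names = bcs))
}

#' TSV table IO
#'
#' @param x data.frame (or matrix with row names kept in the first
#'   column).
#' @param path TSV path.
#' @export
writeTSV <- function(x, path) {
  if (is.matrix(x)) x <- data.frame(id = rownames(x), x, check.names = FALSE)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTSV
#' @export
readTSV <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}
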