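#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
#' @importFrom SingleCellExperiment SingleCellExperiment
NULL

## Checkpoint panel: surface protein name and the gene symbol measured in
## scRNA-seq. Order is the display order used throughout.
.ICP_PROTEINS <- c("CD25", "CD28", "CD39", "4-1BB", "CTLA-4",
                   "ICOS", "OX40", "PD-1", "PD-L1", "TIGIT")
.ICP_GENES    <- c("IL2RA", "CD28", "ENTPD1", "TNFRSF9", "CTLA4",
                   "ICOS", "TNFRSF4", "PDCD1", "CD274", "TIGIT")
.LINEAGE_MARKERS <- c("CD45", "CD3", "CD4", "CD8", "FoxP3")
.T_SUBSETS <- c("CD8", "CD4FoxP3neg", "CD4FoxP3pos", "DP", "DN")

#' Immune-checkpoint panel
#'
#' The default 10-checkpoint panel: surface protein names as used on a
#' cytometry panel and the corresponding gene symbols quantified by
#' scRNA-seq.
#'
#' @return A data.frame with columns `protein` and `gene`.
#' @export
#' @examples
#' icpPanel()
icpPanel <- function() {
  data.frame(protein = .ICP_PROTEINS, gene = .ICP_GENES,
             stringsAsFactors = FALSE)
}

#' @rdname icpPanel
#' @export
icpGenes <- function() .ICP_GENES

#' @rdname icpPanel
#' @export
icpProteins <- function() .ICP_PROTEINS

#' @rdname icpPanel
#' @export
lineageMarkers <- function() .LINEAGE_MARKERS

# ---------------------------------------------------------------------------
# FlowSample: one stained sample, markers x cells, with marker roles.
# ---------------------------------------------------------------------------

#' FlowSample class
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one flow-cytometry
#' sample. Rows are markers (fluorescence, arbitrary units; values may be
#' negative after compensation), columns are cells. `rowData(x)$role` marks
#' each marker as `"lineage"` or `"icp"`; `metadata(x)$sample_id` names the
#' sample and `metadata(x)$panel` gives the ordered checkpoint panel.
#'
#' @export
setClass("FlowSample", contains = "SummarizedExperiment")

setValidity("FlowSample", function(object) {
  msg <- NULL
  if (!"fluorescence" %in% names(assays(object)))
    msg <- c(msg, "assay 'fluorescence' is required")
  else if (anyNA(assay(object, "fluorescence")))
    msg <- c(msg, "fluorescence values must not contain NA")
  if (!"role" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData must contain a 'role' column")
  else if (!all(rowData(object)$role %in% c("lineage", "icp")))
    msg <- c(msg, "marker roles must be 'lineage' or 'icp'")
  panel <- metadata(object)$panel
  if (is.null(panel))
    msg <- c(msg, "metadata(x)$panel (ordered checkpoint list) is required")
  else if (!all(panel %in% rownames(object)))
    msg <- c(msg, "panel markers must all be rows of the sample")
  if (is.null(metadata(object)$sample_id))
    msg <- c(msg, "metadata(x)$sample_id is required")
  if (is.null(msg)) TRUE else msg
})

#' Construct a FlowSample
#'
#' @param values numeric cells x markers matrix (column names are marker
#'   names) or markers x cells if `cellsAsRows = FALSE`.
#' @param sampleId sample identifier.
#' @param markerRoles named character vector mapping marker to
#'   `"lineage"`/`"icp"`. Defaults to the standard panel: CD45/CD3/CD4/CD8/
#'   FoxP3 as lineage, everything else as checkpoint.
#' @param panel ordered checkpoint list; defaults to the 10-ICP panel
#'   intersected with the available markers.
#' @param cellsAsRows are the input rows cells (default) or markers?
#' @return A [FlowSample-class] object.
#' @export
FlowSample <- function(values, sampleId, markerRoles = NULL, panel = NULL,
                       cellsAsRows = TRUE) {
  values <- as.matrix(values)
  if (cellsAsRows) values <- t(values)
  markers <- rownames(values)
  if (is.null(markers)) stop("marker names are required")
  if (is.null(markerRoles)) {
    markerRoles <- ifelse(markers %in% .LINEAGE_MARKERS, "lineage", "icp")
    names(markerRoles) <- markers
  }
  if (is.null(panel)) panel <- intersect(.ICP_PROTEINS, markers)
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("cell%05d", seq_len(ncol(values)))
  se <- SummarizedExperiment(
    assays = list(fluorescence = values),
    rowData = DataFrame(role = unname(markerRoles[markers])),
    metadata = list(sample_id = sampleId, panel = panel))
  new("FlowSample", se)
}

#' @describeIn FlowSample cells x markers fluorescence matrix.
#' @param x a FlowSample.
#' @export
fluorescence <- function(x) t(assay(x, "fluorescence"))

#' @describeIn FlowSample marker role map.
#' @export
markerRoles <- function(x) {
  r <- rowData(x)$role
  names(r) <- rownames(x)
  r
}

#' @describeIn FlowSample the ordered checkpoint panel of the sample.
#' @export
samplePanel <- function(x) metadata(x)$panel

#' @describeIn FlowSample the sample identifier.
#' @export
sampleId <- function(x) metadata(x)$sample_id

setMethod("show", "FlowSample", function(object) {
  cat("FlowSample '", sampleId(object), "': ", ncol(object), " cells, ",
      nrow(object), " markers (", sum(rowData(object)$role == "lineage"),
      " lineage, ", sum(rowData(object)$role == "icp"), " checkpoint)\n",
      sep = "")
})

# ---------------------------------------------------------------------------
# ClonotypeTable: per-cell clonotype assignment for one or more patients.
# ---------------------------------------------------------------------------

#' ClonotypeTable class
#'
#' Per-cell clonotype assignment. One row per cell: `barcode`, `patient`,
#' `clonotype_id` (patient-scoped, `NA` for cells with no productive TCR),
#' `n_productive_chains`, `clone_size` (number of cells of the patient
#' sharing the clonotype), `clonality` (`"HC"` for clones of >= 3 cells,
#' `"LC"` for <= 2, `"none"` without a clonotype) and `size_class`.
#'
#' @slot cells a [S4Vectors::DataFrame] with the columns above.
#' @slot droppedBarcodes number of contig barcodes dropped because they did
#'   not match the expression matrix.
#' @export
setClass("ClonotypeTable",
         representation(cells = "DataFrame", droppedBarcodes = "integer"))

setValidity("ClonotypeTable", function(object) {
  d <- object@cells
  need <- c("barcode", "patient", "clonotype_id", "n_productive_chains",
            "clone_size", "clonality", "size_class")
  if (!all(need %in% colnames(d)))
    return(paste("missing columns:", paste(setdiff(need, colnames(d)), collapse = ", ")))
  has <- !is.na(d$clonotype_id)
  msg <- NULL
  if (any(d$clone_size[has] < 1)) msg <- c(msg, "clone_size must be >= 1")
  if (!all(d$clonality[has] == ifelse(d$clone_size[has] >= 3, "HC", "LC")))
    msg <- c(msg, "clonality must be HC iff clone_size >= 3")
  if (!all(d$clonality[!has] == "none"))
    msg <- c(msg, "cells without clonotype must have clonality 'none'")
  ## clonotype identifiers are patient-scoped, never shared across patients
  tab <- unique(data.frame(id = d$clonotype_id[has], p = d$patient[has]))
  if (anyDuplicated(tab$id))
    msg <- c(msg, "a clonotype_id occurs in more than one patient")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn ClonotypeTable per-cell table as a DataFrame.
#' @param x a ClonotypeTable.
#' @export
clonotypeCells <- function(x) x@cells

setMethod("show", "ClonotypeTable", function(object) {
  d <- object@cells
  has <- !is.na(d$clonotype_id)
  cat("ClonotypeTable: ", nrow(d), " cells / ",
      length(unique(d$patient)), " patient(s); ",
      length(unique(d$clonotype_id[has])), " clonotypes; ",
      sum(d$clonality == "HC"), " HC cells, ",
      sum(d$clonality == "LC"), " LC cells",
      if (object@droppedBarcodes > 0)
        paste0(" (", object@droppedBarcodes, " unmatched contig barcodes dropped)"),
      "\n", sep = "")
})
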