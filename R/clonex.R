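## Clonality x checkpoint-expression stratification: per-patient per-gene
## medians, HE/LE classification, the four compartments, per-cell
## checkpoint burden, and the LC-vs-HC differential checkpoint map.

#' Per-patient checkpoint medians
#'
#' Median log-normalized expression of each panel checkpoint gene over all
#' clonotyped T cells of each patient. Panel genes absent from the matrix
#' are dropped with a warning; patients without clonotyped cells are
#' omitted.
#'
#' @param sce a SingleCellExperiment with `logcounts` and a `patient`
#'   column in `colData`.
#' @param clonotyped logical per cell (or barcodes) marking cells with a
#'   clonotype.
#' @param panel checkpoint gene symbols (default the 10-gene panel).
#' @return patients x genes numeric matrix of medians.
#' @export
icpMedians <- function(sce, clonotyped, panel = icpGenes()) {
  x <- assay(sce, "logcounts")
  miss <- setdiff(panel, rownames(x))
  if (length(miss) > 0) {
    warning("panel gene(s) absent and dropped: ", paste(miss, collapse = ", "))
    panel <- setdiff(panel, miss)
  }
  if (length(panel) == 0) stop("no panel genes present")
  if (is.character(clonotyped)) clonotyped <- colnames(sce) %in% clonotyped
  pats <- as.character(colData(sce)$patient)
  keepPats <- unique(pats[clonotyped])
  med <- t(vapply(keepPats, function(p) {
    cols <- clonotyped & pats == p
    apply(as.matrix(x[panel, cols, drop = FALSE]), 1, median)
  }, numeric(length(panel))))
  rownames(med) <- keepPats
  colnames(med) <- panel
  med
}

#' Per-cell HE/LE expression class
#'
#' For each cell, each panel checkpoint yields an indicator: expression
#' strictly above the cell's patient median for that checkpoint. Under the
#' default majority rule a cell is `HE` when at least
#' `ceiling(panel_size / 2)` indicators hold (5 of 10 on the default
#' panel); the alternative rule compares the cell's mean panel score to
#' the patient median of that mean.
#'
#' @param sce a SingleCellExperiment with `logcounts` and `patient` in
#'   `colData`.
#' @param medians patients x genes matrix from [icpMedians].
#' @param rule `"majority"` (default) or `"meanScore"`.
#' @param cutoff indicator count required for HE under the majority rule
#'   (default `ceiling(ncol(medians) / 2)`).
#' @return character vector `"HE"`/`"LE"` per cell (`NA` for cells of
#'   patients without medians), named by barcode.
#' @export
classifyExpression <- function(sce, medians, rule = c("majority", "meanScore"),
                               cutoff = NULL) {
  rule <- match.arg(rule)
  panel <- colnames(medians)
  x <- as.matrix(assay(sce, "logcounts")[panel, , drop = FALSE])
  pats <- as.character(colData(sce)$patient)
  out <- rep(NA_character_, ncol(x))
  names(out) <- colnames(x)
  if (rule == "majority") {
    if (is.null(cutoff)) cutoff <- ceiling(length(panel) / 2)
    for (p in rownames(medians)) {
      cols <- pats == p
      ind <- x[, cols, drop = FALSE] > medians[p, ]
      out[cols] <- ifelse(colSums(ind) >= cutoff, "HE", "LE")
    }
  } else {
    score <- colMeans(x)
    for (p in rownames(medians)) {
      cols <- pats == p
      out[cols] <- ifelse(score[cols] > median(score[cols]), "HE", "LE")
    }
  }
  out
}

#' Clonality x expression compartments
#'
#' Joins the per-cell clonality class (HC/LC) with the HE/LE expression
#' class into the four compartments HC_HE, HC_LE, LC_HE and LC_LE. Only
#' clonotyped cells are labeled. Returns per-cluster (and per-lineage)
#' compartment compositions in percent, and the share of HC_HE cells from
#' CD4-lineage clusters that fall in the FoxP3+ (Treg) cluster.
#'
#' @param exprClass per-cell HE/LE from [classifyExpression] (named by
#'   barcode).
#' @param ct a [ClonotypeTable-class].
#' @param clusters named cluster label per cell.
#' @param lineages optional named map cluster -> lineage (`"CD8"`, `"CD4"`,
#'   `"Treg"`); Treg counts as CD4 lineage for the share statistic.
#' @return list with `cells` (barcode, patient, cluster, clonality,
#'   expression, compartment), `byCluster` and `byLineage` composition
#'   matrices (rows sum to 100), and `tregShareHCHE` (percent, `NA`
#'   without lineage map or HC_HE CD4 cells).
#' @export
compartmentalize <- function(exprClass, ct, clusters, lineages = NULL) {
  d <- as.data.frame(clonotypeCells(ct))
  d$cluster <- unname(clusters[d$barcode])
  d$expression <- unname(exprClass[d$barcode])
  d <- d[d$clonality %in% c("HC", "LC") & !is.na(d$expression), ,
         drop = FALSE]
  d$compartment <- paste(d$clonality, d$expression, sep = "_")
  lev <- c("HC_HE", "HC_LE", "LC_HE", "LC_LE")
  comp <- factor(d$compartment, levels = lev)
  byCluster <- 100 * prop.table(table(cluster = d$cluster, comp), 1)
  out <- list(cells = d[, c("barcode", "patient", "cluster", "clonality",
                            "expression", "compartment")],
              byCluster = unclass(byCluster))
  if (!is.null(lineages)) {
    d$lineage <- unname(lineages[d$cluster])
    byLineage <- 100 * prop.table(table(lineage = d$lineage, comp), 1)
    out$byLineage <- unclass(byLineage)
    cd4 <- d$lineage %in% c("CD4", "Treg")
    hche <- d$compartment == "HC_HE" & cd4
    out$tregShareHCHE <- if (any(hche))
      100 * mean(d$lineage[hche] == "Treg") else NA_real_
  }
  out
}

#' Per-cell checkpoint burden
#'
#' The number of panel checkpoint genes detected (`count > 0`) in each
#' cell, with per-cluster mean and standard deviation for HC and LC cells
#' and a two-sided Mann-Whitney test per cluster (Benjamini-Hochberg
#' adjusted across clusters; skipped where a cluster lacks one class).
#'
#' @param sce a SingleCellExperiment with `counts`.
#' @param ct a [ClonotypeTable-class].
#' @param clusters named cluster label per cell.
#' @param panel checkpoint gene symbols (default the 10-gene panel).
#' @return list with `burden` (integer per cell, named by barcode) and
#'   `byCluster` (cluster, n_HC, n_LC, mean_HC, sd_HC, mean_LC, sd_LC,
#'   p, p_adj).
#' @export
icpBurden <- function(sce, ct, clusters, panel = icpGenes()) {
  counts <- assay(sce, "counts")
  panel <- intersect(panel, rownames(counts))
  if (length(panel) == 0) stop("no panel genes present")
  burden <- Matrix::colSums(counts[panel, , drop = FALSE] > 0)
  d <- as.data.frame(clonotypeCells(ct))
  d$cluster <- unname(clusters[d$barcode])
  d$burden <- unname(burden[d$barcode])
  d <- d[d$clonality %in% c("HC", "LC"), , drop = FALSE]
  rows <- lapply(split(d, d$cluster), function(g) {
    hc <- g$burden[g$clonality == "HC"]
    lc <- g$burden[g$clonality == "LC"]
    p <- if (length(hc) >= 1 && length(lc) >= 1)
      mannWhitney(hc, lc)$p else NA_real_
    data.frame(cluster = g$cluster[1], n_HC = length(hc), n_LC = length(lc),
               mean_HC = mean(hc), sd_HC = sd(hc),
               mean_LC = mean(lc), sd_LC = sd(lc), p = p,
               stringsAsFactors = FALSE)
  })
  byCluster <- do.call(rbind, rows)
  rownames(byCluster) <- NULL
  tested <- !is.na(byCluster$p)
  byCluster$p_adj <- NA_real_
  byCluster$p_adj[tested] <- bhAdjust(byCluster$p[tested])
  list(burden = burden, byCluster = byCluster)
}

#' LC-vs-HC differential checkpoint map
#'
#' For every (patient, cluster) contributing at least `minCells` cells in
#' both clonality classes, the per-checkpoint log2 fold-change of HC over
#' LC cells (`log2(mean(expm1) + 1)` difference on log-normalized data);
#' the reported map entry is the median over contributing patients, `NA`
#' where no patient contributes.
#'
#' @param sce a SingleCellExperiment with `logcounts` and `patient` in
#'   `colData`.
#' @param ct a [ClonotypeTable-class].
#' @param clusters named cluster label per cell.
#' @param panel checkpoint gene symbols.
#' @param minCells minimal HC and LC cells per (patient, cluster) (10).
#' @param mode `"medianOfFC"` (default: median across patients of the
#'   per-patient log2 fold-changes) or `"log2OfMedianRatio"` (log2 of the
#'   ratio of cross-patient median means).
#' @return clusters x checkpoints numeric matrix.
#' @export
lcHcDifferential <- function(sce, ct, clusters, panel = icpGenes(),
                             minCells = 10,
                             mode = c("medianOfFC", "log2OfMedianRatio")) {
  mode <- match.arg(mode)
  x <- assay(sce, "logcounts")
  panel <- intersect(panel, rownames(x))
  d <- as.data.frame(clonotypeCells(ct))
  d$cluster <- unname(clusters[d$barcode])
  d <- d[d$clonality %in% c("HC", "LC"), , drop = FALSE]
  cls <- sort(unique(d$cluster))
  out <- matrix(NA_real_, length(cls), length(panel),
                dimnames = list(cls, panel))
  groupMeans <- function(bcs)
    Matrix::rowMeans(expm1(x[panel, bcs, drop = FALSE]))
  for (cc in cls) {
    gc <- d[d$cluster == cc, , drop = FALSE]
    if (mode == "medianOfFC") {
      fcs <- lapply(split(gc, gc$patient), function(g) {
        hc <- g$barcode[g$clonality == "HC"]
        lc <- g$barcode[g$clonality == "LC"]
        if (length(hc) < minCells || length(lc) < minCells) return(NULL)
        log2(groupMeans(hc) + 1) - log2(groupMeans(lc) + 1)
      })
      fcs <- do.call(rbind, fcs[!vapply(fcs, is.null, logical(1))])
      if (!is.null(fcs) && nrow(fcs) > 0)
        out[cc, ] <- apply(fcs, 2, median)
    } else {
      ms <- lapply(c(HC = "HC", LC = "LC"), function(cls2) {
        byPat <- lapply(split(gc, gc$patient), function(g) {
          bcs <- g$barcode[g$clonality == cls2]
          other <- g$barcode[g$clonality == setdiff(c("HC", "LC"), cls2)]
          if (length(bcs) < minCells || length(other) < minCells) return(NULL)
          groupMeans(bcs)
        })
        byPat <- do.call(rbind, byPat[!vapply(byPat, is.null, logical(1))])
        if (is.null(byPat) || nrow(byPat) == 0) return(NULL)
        apply(byPat, 2, median)
      })
      if (!is.null(ms$HC) && !is.null(ms$LC))
        out[cc, ] <- log2(ms$HC + 1) - log2(ms$LC + 1)
    }
  }
  out
}
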