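## scRNA-seq stage: QC filtering, log-normalization, variance-stabilized
## HVG selection, grid-based dimension reduction + graph clustering with a
## stability report, cell-cycle scoring, lineage assignment and filtered
## Wilcoxon differential expression.

#' @importFrom cluster silhouette
#' @importFrom mclust adjustedRandIndex Mclust mclustBIC
NULL

#' Quality-control configuration
#'
#' @param minCellsPerGene genes detected in fewer cells are removed (5).
#' @param minUmi cells with fewer total UMIs are removed (1000).
#' @param minGenes cells with fewer detected genes are removed (200).
#' @param maxMitoFrac cells with a higher mitochondrial fraction are
#'   removed (0.20).
#' @param mitoPrefix gene-symbol prefix identifying mitochondrial
#'   transcripts ("MT-").
#' @return an object of class `QCConfig`.
#' @export
qcConfig <- function(minCellsPerGene = 5, minUmi = 1000, minGenes = 200,
                     maxMitoFrac = 0.20, mitoPrefix = "MT-") {
  stopifnot(minCellsPerGene > 0, minUmi > 0, minGenes > 0,
            maxMitoFrac > 0, maxMitoFrac <= 1)
  structure(list(minCellsPerGene = minCellsPerGene, minUmi = minUmi,
                 minGenes = minGenes, maxMitoFrac = maxMitoFrac,
                 mitoPrefix = mitoPrefix), class = "QCConfig")
}

#' Quality-control filtering
#'
#' Removes genes detected in fewer than `minCellsPerGene` cells (computed
#' on the input cells), then removes cells with fewer than `minUmi` UMIs,
#' fewer than `minGenes` detected genes, or a mitochondrial fraction above
#' `maxMitoFrac` (all computed on the gene-filtered matrix).
#'
#' @param sce a [SingleCellExperiment::SingleCellExperiment] with a
#'   `counts` assay.
#' @param qc a [qcConfig] object.
#' @return list with `sce` (filtered) and `report` (removed counts per
#'   criterion).
#' @export
qcFilter <- function(sce, qc = qcConfig()) {
  counts <- assay(sce, "counts")
  if (ncol(counts) == 0 || nrow(counts) == 0) stop("empty count matrix")
  detectedIn <- Matrix::rowSums(counts > 0)
  keepGene <- detectedIn >= qc$minCellsPerGene
  counts2 <- counts[keepGene, , drop = FALSE]
  umi <- Matrix::colSums(counts2)
  ngene <- Matrix::colSums(counts2 > 0)
  mitoGenes <- startsWith(rownames(counts2), qc$mitoPrefix)
  mito <- if (any(mitoGenes))
    Matrix::colSums(counts2[mitoGenes, , drop = FALSE]) / pmax(umi, 1)
  else rep(0, ncol(counts2))
  lowUmi <- umi < qc$minUmi
  lowGenes <- ngene < qc$minGenes
  highMito <- mito > qc$maxMitoFrac
  keepCell <- !(lowUmi | lowGenes | highMito)
  report <- list(genes_in = nrow(counts), cells_in = ncol(counts),
                 removed_genes = sum(!keepGene),
                 removed_low_umi = sum(lowUmi),
                 removed_low_genes = sum(lowGenes),
                 removed_high_mito = sum(highMito),
                 genes_out = sum(keepGene), cells_out = sum(keepCell))
  if (!any(keepCell) || !any(keepGene))
    stop("all cells or genes removed by QC; report: ",
         paste(names(report), unlist(report), sep = "=", collapse = ", "))
  list(sce = sce[keepGene, keepCell], report = report)
}

#' Log-normalization
#'
#' Per-cell library-size normalization to `scale` counts followed by
#' `log(1 + x)`, stored as a `logcounts` assay.
#'
#' @param sce a SingleCellExperiment with a `counts` assay.
#' @param scale library-size target (default 1e4).
#' @return the SingleCellExperiment with an added `logcounts` assay.
#' @export
logNormalize <- function(sce, scale = 1e4) {
  counts <- assay(sce, "counts")
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) stop("zero-total cell encountered (run QC first)")
  norm <- counts %*% Diagonal(x = scale / totals)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  SummarizedExperiment::assay(sce, "logcounts") <- norm
  sce
}

#' Highly variable gene selection (variance-stabilizing)
#'
#' Ranks genes by standardized variance: a local regression of
#' log10(variance) on log10(mean) of the raw counts yields an expected
#' standard deviation per gene; counts are standardized with it, clipped at
#' `sqrt(n_cells)`, and the variance of the clipped values is the score.
#' Ties resolve by gene order.
#'
#' @param sce a SingleCellExperiment with a `counts` assay.
#' @param n number of genes to select (default 3000).
#' @param loessSpan span of the mean-variance trend fit (default 0.3).
#' @return character vector of selected gene names (all genes, with a
#'   warning, if fewer than `n` are available).
#' @export
selectHVG <- function(sce, n = 3000, loessSpan = 0.3) {
  counts <- assay(sce, "counts")
  nc <- ncol(counts)
  if (nc < 2) stop("need at least 2 cells")
  mu <- Matrix::rowMeans(counts)
  ex2 <- Matrix::rowMeans(counts^2)
  v <- (ex2 - mu^2) * nc / (nc - 1)
  use <- v > 0 & mu > 0
  fit <- loess(log10(v[use]) ~ log10(mu[use]), span = loessSpan)
  sdExp <- rep(NA_real_, length(mu))
  sdExp[use] <- sqrt(10^predict(fit))
  clipMax <- sqrt(nc)
  stdvar <- rep(0, length(mu))
  cc <- methods::as(counts, "TsparseMatrix")
  byGene <- split(cc@x, factor(cc@i, levels = seq_len(nrow(counts)) - 1L))
  for (g in which(use)) {
    z0 <- pmin((0 - mu[g]) / sdExp[g], clipMax)
    znz <- pmin((byGene[[g]] - mu[g]) / sdExp[g], clipMax)
    nnz <- length(znz)
    s1 <- sum(znz) + (nc - nnz) * z0
    s2 <- sum(znz^2) + (nc - nnz) * z0^2
    stdvar[g] <- (s2 - s1^2 / nc) / (nc - 1)
  }
  names(stdvar) <- rownames(counts)
  if (n > length(stdvar)) {
    warning("requested ", n, " genes but only ", length(stdvar),
            " available; returning all")
    n <- length(stdvar)
  }
  names(sort(stdvar, decreasing = TRUE, method = "radix")[seq_len(n)])
}

## Centered (and unit-scaled) truncated SVD embedding of cells x genes.
.truncatedEmbedding <- function(x, maxDim) {
  xs <- scale(x)                       # genes with zero variance -> NaN
  xs[, !is.finite(colSums(xs))] <- 0
  n <- nrow(xs); p <- ncol(xs)
  maxDim <- min(maxDim, n - 1L, p)
  if (p <= n) {
    eg <- eigen(crossprod(xs), symmetric = TRUE)
    d <- sqrt(pmax(eg$values[seq_len(maxDim)], 0))
    emb <- xs %*% eg$vectors[, seq_len(maxDim), drop = FALSE]
  } else {
    eg <- eigen(tcrossprod(xs), symmetric = TRUE)
    emb <- eg$vectors[, seq_len(maxDim), drop = FALSE] %*%
      diag(sqrt(pmax(eg$values[seq_len(maxDim)], 0)), maxDim)
  }
  emb
}

## Mean silhouette width of a partition on an embedding (-1 when the
## partition is a single cluster).
.meanSilhouette <- function(emb, labels) {
  if (length(unique(labels)) < 2) return(-1)
  sil <- cluster::silhouette(as.integer(factor(labels)), dist(emb))
  mean(sil[, "sil_width"])
}

#' Dimension-reduction and clustering grid
#'
#' Explores reduced spaces of 3 to 49 dimensions (step 2) of a centered
#' truncated SVD on the highly variable genes, and for each space runs
#' graph clustering (kNN k = 20, Jaccard weights, Louvain modularity) over
#' resolutions 0.1 to 1.2 (step 0.1). Stability of each combination is the
#' mean adjusted Rand index against the partitions at neighbouring
#' resolutions; the chosen combination maximizes the mean silhouette width
#' subject to stability at or above `stabilityFloor`.
#'
#' @param sce a SingleCellExperiment with `logcounts`.
#' @param hvg highly variable genes from [selectHVG].
#' @param dimsGrid candidate dimensionalities (default `seq(3, 49, 2)`;
#'   values at or above `min(n_cells, n_hvg)` are dropped with a warning).
#' @param resGrid candidate Louvain resolutions (default
#'   `seq(0.1, 1.2, 0.1)`).
#' @param k nearest neighbours of the cell graph (default 20).
#' @param seed RNG seed.
#' @param stabilityFloor minimal acceptable stability (default 0.5).
#' @param regressCovariates optional cells x covariates matrix (e.g. G2M
#'   score, mitochondrial fraction) residualized out of each gene before
#'   the embedding.
#' @return list with `labels`, `dims`, `resolution`, `embedding` (at the
#'   chosen dimensionality), and `report` (one row per grid combination:
#'   dims, resolution, n_clusters, silhouette, stability).
#' @export
reduceAndCluster <- function(sce, hvg, dimsGrid = seq(3, 49, 2),
                             resGrid = seq(0.1, 1.2, 0.1), k = 20,
                             seed = 1, stabilityFloor = 0.5,
                             regressCovariates = NULL) {
  x <- Matrix::t(assay(sce, "logcounts")[hvg, , drop = FALSE])
  x <- as.matrix(x)
  if (!is.null(regressCovariates)) {
    cov <- as.matrix(regressCovariates)
    x <- stats::resid(stats::lm(x ~ cov))
  }
  lim <- min(nrow(x), ncol(x))
  drop <- dimsGrid >= lim
  if (any(drop)) {
    warning("dropping dimensionalities >= ", lim, ": ",
            paste(dimsGrid[drop], collapse = ", "))
    dimsGrid <- dimsGrid[!drop]
  }
  if (length(dimsGrid) == 0) stop("no usable dimensionalities")
  embFull <- .truncatedEmbedding(x, max(dimsGrid))
  report <- list()
  labelsByCombo <- list()
  for (d in dimsGrid) {
    emb <- embFull[, seq_len(d), drop = FALSE]
    g <- knnJaccardGraph(emb, k = min(k, nrow(emb) - 1))
    parts <- lapply(resGrid, function(r)
      louvainCluster(g, seed = seed, resolution = r)$membership)
    for (i in seq_along(resGrid)) {
      neigh <- c(i - 1, i + 1)
      neigh <- neigh[neigh >= 1 & neigh <= length(resGrid)]
      stab <- mean(vapply(neigh, function(j)
        mclust::adjustedRandIndex(parts[[i]], parts[[j]]), numeric(1)))
      sil <- .meanSilhouette(emb, parts[[i]])
      key <- sprintf("d%02d_r%.1f", d, resGrid[i])
      labelsByCombo[[key]] <- parts[[i]]
      report[[key]] <- data.frame(dims = d, resolution = resGrid[i],
                                  n_clusters = length(unique(parts[[i]])),
                                  silhouette = sil, stability = stab)
    }
  }
  report <- do.call(rbind, report)
  ok <- report$stability >= stabilityFloor
  if (!any(ok)) {
    warning("no grid combination reached stability ", stabilityFloor,
            "; choosing best silhouette overall")
    ok <- rep(TRUE, nrow(report))
  }
  best <- rownames(report)[ok][which.max(report$silhouette[ok])]
  list(labels = labelsByCombo[[best]],
       dims = report[best, "dims"],
       resolution = report[best, "resolution"],
       embedding = embFull[, seq_len(report[best, "dims"]), drop = FALSE],
       report = report)
}

#' Cell-cycle scoring
#'
#' Module scores for S and G2M gene sets: mean expression of the set minus
#' the mean of a control set drawn (seeded) from expression-matched bins —
#' genes are ranked by average expression, cut into `nBins` bins, and
#' `ctrlPerBin` control genes are sampled from the bin of each set gene.
#' Phase is the argmax of the two scores when positive, otherwise G1.
#'
#' @param sce a SingleCellExperiment with `logcounts`.
#' @param sGenes,g2mGenes gene sets (non-empty after intersection with the
#'   matrix, else an error naming the missing set).
#' @param seed RNG seed for control sampling.
#' @param nBins number of expression bins (default 24).
#' @param ctrlPerBin control genes per bin (default 100).
#' @return data.frame with `s_score`, `g2m_score`, `phase` per cell.
#' @export
scoreCellCycle <- function(sce, sGenes, g2mGenes, seed = 1, nBins = 24,
                           ctrlPerBin = 100) {
  x <- assay(sce, "logcounts")
  sets <- list(S = intersect(sGenes, rownames(x)),
               G2M = intersect(g2mGenes, rownames(x)))
  for (nm in names(sets))
    if (length(sets[[nm]]) == 0)
      stop("no ", nm, " genes present in the matrix; missing: ",
           paste(utils::head(if (nm == "S") sGenes else g2mGenes, 5),
                 collapse = ", "))
  avg <- Matrix::rowMeans(x)
  bins <- cut(rank(avg, ties.method = "first"), breaks = nBins,
              labels = FALSE)
  names(bins) <- rownames(x)
  set.seed(seed)
  scores <- lapply(sets, function(set) {
    ctrl <- unique(unlist(lapply(set, function(g) {
      pool <- names(bins)[bins == bins[[g]]]
      pool <- setdiff(pool, g)
      sample(pool, min(ctrlPerBin, length(pool)))
    })))
    Matrix::colMeans(x[set, , drop = FALSE]) -
      Matrix::colMeans(x[ctrl, , drop = FALSE])
  })
  s <- scores$S; g2m <- scores$G2M
  phase <- ifelse(pmax(s, g2m) <= 0, "G1", ifelse(s >= g2m, "S", "G2M"))
  data.frame(s_score = s, g2m_score = g2m, phase = phase,
             row.names = colnames(x), stringsAsFactors = FALSE)
}

#' Default lineage marker sets
#'
#' Canonical gene sets used to assign clusters to T-cell lineages.
#' @return named list of gene vectors.
#' @export
defaultLineageMarkers <- function() {
  list(CD8 = c("CD8A", "CD8B"),
       CD4 = c("CD4", "IL7R"),
       Treg = c("FOXP3", "IL2RA"))
}

#' Assign clusters to T-cell lineages
#'
#' Per cluster and lineage, the mean expression of the lineage's canonical
#' marker set is z-scored across clusters; the cluster label is the argmax.
#' A `Treg` call additionally requires FOXP3 detected (count > 0) in more
#' than `foxp3Fraction` of the cluster's cells; failing that, the cluster
#' falls back to the next-best lineage. Ties break deterministically by
#' lineage order, with a warning.
#'
#' @param labels cluster label per cell.
#' @param sce a SingleCellExperiment with `logcounts` (and `counts` for the
#'   FOXP3 detection check).
#' @param markerSets named list of lineage gene sets (genes missing from
#'   the matrix are dropped with a warning).
#' @param foxp3Fraction detection fraction required for a Treg call (0.3).
#' @return named character vector: cluster -> lineage.
#' @export
assignLineage <- function(labels, sce, markerSets = defaultLineageMarkers(),
                          foxp3Fraction = 0.3) {
  x <- assay(sce, "logcounts")
  if (length(labels) != ncol(x)) stop("clustering must cover all cells")
  markerSets <- lapply(markerSets, function(gs) {
    miss <- setdiff(gs, rownames(x))
    if (length(miss) > 0)
      warning("missing lineage markers dropped: ", paste(miss, collapse = ", "))
    intersect(gs, rownames(x))
  })
  if (any(vapply(markerSets, length, integer(1)) == 0))
    stop("a lineage marker set is empty after intersection")
  labels <- factor(labels)
  cl <- levels(labels)
  score <- sapply(markerSets, function(gs) {
    m <- Matrix::colMeans(x[gs, , drop = FALSE])
    tapply(m, labels, mean)
  })
  score <- matrix(score, nrow = length(cl),
                  dimnames = list(cl, names(markerSets)))
  z <- scale(score)
  z[, !is.finite(colSums(z))] <- 0
  counts <- assay(sce, "counts")
  foxp3Det <- if ("FOXP3" %in% rownames(counts))
    tapply(counts["FOXP3", ] > 0, labels, mean) else setNames(rep(0, length(cl)), cl)
  out <- character(length(cl)); names(out) <- cl
  for (ci in cl) {
    ord <- order(-z[ci, ], seq_along(markerSets))   # ties by lineage order
    if (sum(z[ci, ] == max(z[ci, ])) > 1)
      warning("lineage tie in cluster ", ci, "; broken by lineage order")
    pick <- names(markerSets)[ord]
    if (pick[1] == "Treg" && foxp3Det[[ci]] <= foxp3Fraction)
      pick <- pick[-1]
    out[ci] <- pick[1]
  }
  out
}

#' Filtered Wilcoxon differential expression
#'
#' Two-group differential expression on log-normalized data. Per gene the
#' average log2 fold-change is
#' `log2(mean(expm1(A)) + 1) - log2(mean(expm1(B)) + 1)` and the percent
#' of expressing cells (`count > 0`) is computed per group; genes passing
#' `|avg_log2FC| >= log2fcMin` and `max(pct) >= minPct` are tested with a
#' two-sided Wilcoxon rank-sum test (tie-corrected), adjusted by
#' Benjamini-Hochberg over the tested genes, and reported when
#' `p_adj < alpha`.
#'
#' @param sce a SingleCellExperiment with `counts` and `logcounts`.
#' @param cellsA,cellsB disjoint cell (column) selections, each >= 3 cells.
#' @param log2fcMin fold-change filter (default 0.58, i.e. 1.5-fold).
#' @param minPct expressing-fraction filter (default 0.25).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param allResults return all tested genes instead of only the
#'   significant ones.
#' @return data.frame with `gene`, `avg_log2FC`, `pct.1`, `pct.2`,
#'   `p_val`, `p_val_adj`, ordered by `p_val`.
#' @export
differentialExpression <- function(sce, cellsA, cellsB, log2fcMin = 0.58,
                                   minPct = 0.25, alpha = 0.05,
                                   allResults = FALSE) {
  idx <- function(cells) {
    if (is.character(cells)) match(cells, colnames(sce)) else as.integer(cells)
  }
  a <- idx(cellsA); b <- idx(cellsB)
  if (anyNA(a) || anyNA(b)) stop("unknown cells")
  if (length(intersect(a, b)) > 0) stop("groups overlap")
  if (length(a) < 3 || length(b) < 3) stop("both groups need >= 3 cells")
  counts <- assay(sce, "counts")
  ln <- assay(sce, "logcounts")
  pct1 <- Matrix::rowMeans(counts[, a, drop = FALSE] > 0)
  pct2 <- Matrix::rowMeans(counts[, b, drop = FALSE] > 0)
  meanA <- Matrix::rowMeans(expm1(ln[, a, drop = FALSE]))
  meanB <- Matrix::rowMeans(expm1(ln[, b, drop = FALSE]))
  lfc <- log2(meanA + 1) - log2(meanB + 1)
  test <- abs(lfc) >= log2fcMin & pmax(pct1, pct2) >= minPct
  genes <- rownames(counts)[test]
  if (length(genes) == 0)
    return(data.frame(gene = character(0), avg_log2FC = numeric(0),
                      pct.1 = numeric(0), pct.2 = numeric(0),
                      p_val = numeric(0), p_val_adj = numeric(0)))
  lnA <- as.matrix(ln[genes, a, drop = FALSE])
  lnB <- as.matrix(ln[genes, b, drop = FALSE])
  p <- vapply(seq_along(genes), function(i)
    mannWhitney(lnA[i, ], lnB[i, ])$p, numeric(1))
  res <- data.frame(gene = genes, avg_log2FC = unname(lfc[genes]),
                    pct.1 = unname(pct1[genes]), pct.2 = unname(pct2[genes]),
                    p_val = p, p_val_adj = bhAdjust(p),
                    stringsAsFactors = FALSE)
  if (!allResults) res <- res[res$p_val_adj < alpha, , drop = FALSE]
  res <- res[order(res$p_val), , drop = FALSE]
  rownames(res) <- NULL
  res
}
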