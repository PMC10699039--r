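#' @importFrom Matrix sparseMatrix t tcrossprod readMM writeMM Diagonal
#'   colSums rowSums
#' @importFrom igraph graph_from_data_frame E membership modularity
#'   cluster_louvain vcount ecount as_data_frame make_empty_graph
NULL

## Blockwise Euclidean k-nearest-neighbour search. Ties are broken by cell
## index (stable order after sort), self always excluded.
.knnIndices <- function(x, k, block = 512L) {
  n <- nrow(x)
  if (k >= n) stop("k must be smaller than the number of cells")
  sq <- rowSums(x^2)
  idx <- matrix(0L, n, k)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    ## squared distances block x n
    d2 <- outer(sq[rows], sq, "+") - 2 * x[rows, , drop = FALSE] %*% t(x)
    for (j in seq_along(rows)) {
      d <- d2[j, ]
      d[rows[j]] <- Inf
      idx[rows[j], ] <- order(d)[seq_len(k)]
    }
  }
  idx
}

#' kNN graph with Jaccard edge weights
#'
#' Builds the PhenoGraph-style cell graph: Euclidean k-nearest neighbours
#' per cell (self excluded from the search, ties by index), an undirected
#' edge wherever either cell lists the other as a neighbour, and edge
#' weight equal to the Jaccard overlap of the two closed neighbourhoods
#' (cell plus its k neighbours): two coincident cells with the same
#' neighbours get weight 1. Zero-weight edges are dropped.
#'
#' @param x numeric cells x features matrix (typically logicle-transformed
#'   fluorescence or a reduced-dimension embedding).
#' @param k number of nearest neighbours (default 30).
#' @return an undirected weighted [igraph::graph] with one vertex per cell
#'   (named by row index) and Jaccard weights in `(0, 1]`.
#' @export
knnJaccardGraph <- function(x, k = 30) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k >= n) stop("k must be smaller than the number of cells")
  nn <- .knnIndices(x, k)
  A <- sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn),
                    x = 1, dims = c(n, n))
  U <- (A + Matrix::t(A)) > 0       # candidate edges: j in kNN(i) or i in kNN(j)
  N <- A + Diagonal(n)              # closed neighbourhood {i} + kNN(i)
  inter <- tcrossprod(N)
  Usum <- methods::as(methods::as(U, "generalMatrix"), "TsparseMatrix")
  ii <- Usum@i + 1L; jj <- Usum@j + 1L
  keep <- ii < jj
  ii <- ii[keep]; jj <- jj[keep]
  ov <- inter[cbind(ii, jj)]
  w <- ov / (2 * (k + 1) - ov)
  pos <- w > 0
  edges <- data.frame(from = ii[pos], to = jj[pos], weight = w[pos])
  g <- graph_from_data_frame(edges, directed = FALSE,
                             vertices = data.frame(name = seq_len(n)))
  g
}

#' Louvain community detection
#'
#' Weighted Louvain modularity optimization on a cell graph. Randomization
#' is confined to the node visiting order drawn from the seeded RNG, so the
#' partition is reproducible for a fixed seed.
#'
#' @param g an undirected weighted [igraph::graph].
#' @param seed integer RNG seed.
#' @param resolution resolution parameter of the modularity objective
#'   (default 1).
#' @return list with `membership` (integer labels, one per vertex) and
#'   `modularity` (weighted modularity of the returned partition).
#' @export
louvainCluster <- function(g, seed = 1, resolution = 1) {
  if (vcount(g) == 0) stop("empty graph")
  set.seed(seed)
  cl <- cluster_louvain(g, weights = E(g)$weight, resolution = resolution)
  mem <- as.integer(membership(cl))
  list(membership = mem,
       modularity = modularity(g, mem, weights = E(g)$weight,
                               resolution = resolution))
}

#' Cluster summaries for flow data
#'
#' Per-cluster mean marker intensity, min-max normalized per marker across
#' clusters (as displayed on cluster heatmaps), plus the per-sample cluster
#' abundance in percent (summing to 100 within each sample).
#'
#' @param x cells x markers matrix used for clustering (or raw intensities).
#' @param labels cluster label per cell.
#' @param sampleIds sample identifier per cell.
#' @return list with `profile` (clusters x markers, values in `[0, 1]`) and
#'   `abundance` (samples x clusters, percentages).
#' @export
summarizeClusters <- function(x, labels, sampleIds = NULL) {
  x <- as.matrix(x)
  if (length(labels) != nrow(x)) stop("labels must cover all cells")
  labels <- factor(labels)
  means <- apply(x, 2, function(col) tapply(col, labels, mean))
  if (nlevels(labels) == 1) means <- matrix(means, nrow = 1,
                                            dimnames = list(levels(labels), colnames(x)))
  norm <- apply(means, 2, function(m) {
    rng <- max(m) - min(m)
    if (rng <= 0) rep(0, length(m)) else (m - min(m)) / rng
  })
  if (nlevels(labels) == 1) norm <- matrix(norm, nrow = 1,
                                           dimnames = dimnames(means))
  rownames(norm) <- levels(labels)
  abundance <- NULL
  if (!is.null(sampleIds)) {
    tab <- table(factor(sampleIds), labels)
    abundance <- sweep(unclass(tab), 1, rowSums(tab), "/") * 100
  }
  list(profile = norm, abundance = abundance)
}

#' PhenoGraph-style clustering of a flow sample cohort
#'
#' The unsupervised recipe applied to pooled cells: per-marker auto-logicle
#' transformation, kNN graph (k = 30) with Jaccard weights, Louvain
#' communities, then cluster summaries. The marker set defaults to the 12
#' channels driving checkpoint co-expression structure: the 10 checkpoints
#' plus CD4 and CD8.
#'
#' @param samples list of [FlowSample-class] objects.
#' @param markers markers to cluster on (default: panel checkpoints + CD4,
#'   CD8 of the first sample).
#' @param k nearest neighbours (default 30).
#' @param seed RNG seed.
#' @param resolution Louvain resolution (default 1).
#' @param umap also compute a UMAP embedding (n_neighbors = 30,
#'   min_dist = 0.1) via the uwot package if available.
#' @return list with `labels` (per pooled cell), `sample` (sample id per
#'   cell), `modularity`, `summary` (see [summarizeClusters]), `transformed`
#'   (pooled transformed matrix), `graph`, and optionally `embedding`.
#' @export
clusterFlowCohort <- function(samples, markers = NULL, k = 30, seed = 1,
                              resolution = 1, umap = FALSE) {
  if (inherits(samples, "FlowSample")) samples <- list(samples)
  if (is.null(markers))
    markers <- c(samplePanel(samples[[1]]), "CD4", "CD8")
  mats <- lapply(samples, function(s) fluorescence(s)[, markers, drop = FALSE])
  sample_of <- rep(vapply(samples, sampleId, character(1)),
                   vapply(mats, nrow, integer(1)))
  pooled <- do.call(rbind, mats)
  trans <- pooled
  for (m in markers) {
    p <- autoLogicleParams(pooled[, m])
    trans[, m] <- logicleTransform(pooled[, m], p)
  }
  g <- knnJaccardGraph(trans, k = k)
  cl <- louvainCluster(g, seed = seed, resolution = resolution)
  out <- list(labels = cl$membership, sample = sample_of,
              modularity = cl$modularity,
              summary = summarizeClusters(trans, cl$membership, sample_of),
              transformed = trans, graph = g)
  if (umap && requireNamespace("uwot", quietly = TRUE)) {
    set.seed(seed)
    out$embedding <- uwot::umap(trans, n_neighbors = 30, min_dist = 0.1)
  }
  out
}
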