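## Synthetic cohort generators with known ground truth. The flow generator
## draws per-cell log-normal fluorescence with subset-specific positivity;
## the single-cell generator draws sparse negative-binomial UMI counts with
## cluster marker programs, patient-private clonotypes under zero-truncated
## geometric clone-size laws, and a planted association between clonal
## expansion and checkpoint expression in the FoxP3+ cluster.

#' Default checkpoint positivity probabilities
#'
#' Subset x checkpoint positivity probabilities used by the flow
#' generator: strongly Treg-skewed (e.g. CD39 at 0.822 of CD4+FoxP3+
#' cells), with CD25/CD39 rates on CD4 subsets chosen so that about two
#' thirds of CD25+CD39+ CD4 cells are FoxP3+.
#'
#' @return numeric matrix (rows CD8, CD4FoxP3neg, CD4FoxP3pos, DP, DN,
#'   nonT; columns the 10 checkpoints).
#' @export
defaultIcpPositivity <- function() .defaultIcpPositivity()

.defaultIcpPositivity <- function() {
  m <- rbind(
    CD8         = c(0.15, 0.40, 0.250, 0.06, 0.05, 0.10, 0.05, 0.45, 0.06, 0.35),
    CD4FoxP3neg = c(0.35, 0.80, 0.245, 0.05, 0.12, 0.30, 0.15, 0.35, 0.05, 0.25),
    CD4FoxP3pos = c(0.85, 0.90, 0.822, 0.30, 0.70, 0.60, 0.50, 0.50, 0.15, 0.70),
    DP          = c(0.30, 0.60, 0.300, 0.10, 0.15, 0.20, 0.15, 0.40, 0.05, 0.30),
    DN          = c(0.10, 0.30, 0.150, 0.05, 0.05, 0.10, 0.05, 0.30, 0.05, 0.20),
    nonT        = c(0.05, 0.05, 0.100, 0.02, 0.02, 0.03, 0.02, 0.10, 0.10, 0.05))
  colnames(m) <- .ICP_PROTEINS
  m
}

#' Flow cohort simulation configuration
#'
#' Defaults reproduce the cohort medians the analysis assumes: CD8 36.5%,
#' CD4+FoxP3- 38.6% and CD4+FoxP3+ 9.5% of T-cells (the remainder split
#' between double-positive and double-negative T-cells), and Treg-skewed
#' checkpoint positivity (e.g. CD39 at 82.2% of Tregs). Fluorescence is
#' log-normal per marker around `posMean`/`negMean` with meanlog dispersion
#' `noiseSd`, plus Gaussian background of sd `bgSd` (producing the negative
#' events expected after compensation).
#'
#' @param nSamples number of samples.
#' @param cellsPerSample cells per sample.
#' @param nonTFrac fraction of non-T contaminant cells.
#' @param subsetProps named fractions over CD8 / CD4FoxP3neg / CD4FoxP3pos /
#'   DP / DN, summing to 1 (within T-cells).
#' @param icpPositivity subset x checkpoint positivity probability matrix
#'   (rows CD8, CD4FoxP3neg, CD4FoxP3pos, DP, DN, nonT).
#' @param posMean,negMean location of the positive/negative log-normal
#'   populations (arbitrary fluorescence units).
#' @param noiseSd log-scale dispersion of both populations.
#' @param bgSd additive Gaussian background sd.
#' @param seed integer RNG seed.
#' @return an object of class `FlowSimConfig`.
#' @export
flowSimConfig <- function(nSamples = 10, cellsPerSample = 5000,
                          nonTFrac = 0.2,
                          subsetProps = c(CD8 = 0.365, CD4FoxP3neg = 0.386,
                                          CD4FoxP3pos = 0.095, DP = 0.030,
                                          DN = 0.124),
                          icpPositivity = .defaultIcpPositivity(),
                          posMean = 1000, negMean = 15,
                          noiseSd = 0.45, bgSd = 6, seed = 1) {
  if (abs(sum(subsetProps) - 1) > 1e-9)
    stop("subsetProps must sum to 1")
  if (!all(names(subsetProps) == .T_SUBSETS))
    stop("subsetProps must be named ", paste(.T_SUBSETS, collapse = "/"))
  if (nonTFrac < 0 || nonTFrac >= 1) stop("nonTFrac must be in [0, 1)")
  if (any(icpPositivity < 0 | icpPositivity > 1))
    stop("positivity probabilities must lie in [0, 1]")
  if (!all(rownames(icpPositivity) == c(.T_SUBSETS, "nonT")))
    stop("icpPositivity rows must be ", paste(c(.T_SUBSETS, "nonT"), collapse = "/"))
  stopifnot(posMean > 0, negMean > 0, noiseSd > 0, bgSd >= 0)
  structure(list(nSamples = nSamples, cellsPerSample = cellsPerSample,
                 nonTFrac = nonTFrac, subsetProps = subsetProps,
                 icpPositivity = icpPositivity, posMean = posMean,
                 negMean = negMean, noiseSd = noiseSd, bgSd = bgSd,
                 seed = as.integer(seed)),
            class = "FlowSimConfig")
}

## Lineage-marker positivity implied by each subset label.
.lineageTruth <- function(subset) {
  switch(subset,
    CD8         = c(CD45 = 1, CD3 = 1, CD4 = 0, CD8 = 1, FoxP3 = 0),
    CD4FoxP3neg = c(CD45 = 1, CD3 = 1, CD4 = 1, CD8 = 0, FoxP3 = 0),
    CD4FoxP3pos = c(CD45 = 1, CD3 = 1, CD4 = 1, CD8 = 0, FoxP3 = 1),
    DP          = c(CD45 = 1, CD3 = 1, CD4 = 1, CD8 = 1, FoxP3 = 0),
    DN          = c(CD45 = 1, CD3 = 1, CD4 = 0, CD8 = 0, FoxP3 = 0),
    nonT        = c(CD45 = NA, CD3 = 0, CD4 = 0, CD8 = 0, FoxP3 = 0))
}

#' Gating thresholds matching a simulation configuration
#'
#' The log-space midpoint between the positive and negative population
#' means, `sqrt(posMean * negMean)`, for every marker.
#'
#' @param config a `FlowSimConfig`.
#' @return named numeric vector of cutoffs (one per marker).
#' @export
trueGates <- function(config) {
  cut <- sqrt(config$posMean * config$negMean)
  setNames(rep(cut, length(c(.LINEAGE_MARKERS, .ICP_PROTEINS))),
           c(.LINEAGE_MARKERS, .ICP_PROTEINS))
}

#' Derive gating cutoffs from observed fluorescence
#'
#' Fits a two-component Gaussian mixture to log-shifted values and returns
#' the midpoint of the component means in log space — the valley between
#' the negative and positive log-normal modes.
#'
#' @param values numeric fluorescence values for one marker.
#' @return a single cutoff in the original units.
#' @export
deriveGate <- function(values) {
  lx <- log(pmax(values, 0.5))
  fit <- mclust::Mclust(lx, G = 2, modelNames = "E", verbose = FALSE)
  exp(mean(fit$parameters$mean))
}

#' Generate a synthetic flow-cytometry cohort
#'
#' One sample per element: a [FlowSample-class] (15 markers: CD45, CD3,
#' CD4, CD8, FoxP3 plus the 10-checkpoint panel) and the ground truth
#' (per-cell subset label and the planted positivity draws).
#'
#' @param config a [flowSimConfig] object.
#' @return list of length `nSamples`; each element has `$sample`
#'   (FlowSample) and `$truth` (data.frame with `cell`, `subset`).
#' @export
generateFlowCohort <- function(config = flowSimConfig()) {
  stopifnot(inherits(config, "FlowSimConfig"))
  set.seed(config$seed)
  markers <- c(.LINEAGE_MARKERS, .ICP_PROTEINS)
  lapply(seq_len(config$nSamples), function(s) {
    n <- config$cellsPerSample
    isT <- runif(n) >= config$nonTFrac
    subset <- character(n)
    subset[!isT] <- "nonT"
    subset[isT] <- sample(.T_SUBSETS, sum(isT), replace = TRUE,
                          prob = config$subsetProps)
    pos <- matrix(0, n, length(markers), dimnames = list(NULL, markers))
    for (ss in unique(subset)) {
      rows <- subset == ss
      lin <- .lineageTruth(ss)
      for (m in .LINEAGE_MARKERS) {
        p <- lin[[m]]
        if (is.na(p)) p <- 0.6   # nonT: mixed CD45+ leukocytes and CD45- debris
        pos[rows, m] <- rbinom(sum(rows), 1, p)
      }
      for (m in .ICP_PROTEINS)
        pos[rows, m] <- rbinom(sum(rows), 1, config$icpPositivity[ss, m])
    }
    mu <- ifelse(pos == 1, log(config$posMean), log(config$negMean))
    vals <- matrix(rlnorm(n * length(markers), meanlog = mu,
                          sdlog = config$noiseSd) +
                   rnorm(n * length(markers), sd = config$bgSd),
                   n, length(markers), dimnames = list(NULL, markers))
    cellIds <- sprintf("S%02d_cell%05d", s, seq_len(n))
    rownames(vals) <- cellIds
    fs <- FlowSample(vals, sampleId = sprintf("S%02d", s))
    list(sample = fs,
         truth = data.frame(cell = cellIds, subset = subset,
                            stringsAsFactors = FALSE))
  })
}

# ---------------------------------------------------------------------------
# Single-cell RNA + TCR cohort
# ---------------------------------------------------------------------------

## Clone-size law: cell-level fraction of cells in clones >= 3 for a
## zero-truncated geometric with success p is 1 - p^2 (3 - 2p). The default
## success parameters solve that expression for the expansion fractions the
## analysis assumes (72.2% of CD8 cells, 23.7% of CD4 cells).
.P_GEOM_CD8 <- 0.34724772
.P_GEOM_CD4 <- 0.68358299

.DEFAULT_CLUSTERS <- c("CD8.EM", "CD8.exhausted", "CD8.cytotoxic",
                       "CD4.EM", "CD4.TFH", "CD4.Treg")

## Co-regulated transcriptional module accompanying each cluster's
## canonical markers (real cluster programs span dozens of genes).
.moduleGenes <- function(cluster, n = 15)
  sprintf("MOD.%s.%02d", cluster, seq_len(n))

.defaultGeneUniverse <- function(nFiller = 260) {
  core <- c("CD3D", "CD3E", "CD3G", "TRAC", "CD2", "B2M", "ACTB", "GAPDH")
  lineage <- c("CD8A", "CD8B", "CD4", "IL7R", "FOXP3")
  program <- c("GZMK", "GZMB", "PRF1", "NKG7", "GNLY", "STAT4",
               "HAVCR2", "LAG3", "TOX", "CCR7", "SELL", "TCF7",
               "CXCL13", "BCL6", "IKZF2", "MKI67", "TOP2A")
  modules <- unlist(lapply(.DEFAULT_CLUSTERS, .moduleGenes))
  mito <- c("MT-CO1", "MT-CO2", "MT-ND1", "MT-ND4", "MT-CYB")
  hk <- sprintf("HK%02d", 1:20)
  filler <- sprintf("FILLER%03d", seq_len(nFiller))
  unique(c(core, lineage, .ICP_GENES, program, modules, mito, hk, filler))
}

.defaultBaseMeans <- function(genes) {
  mu <- setNames(rep(0.06, length(genes)), genes)
  mu[c("CD3D", "CD3E", "CD3G", "TRAC", "CD2")] <- 3
  mu[c("B2M", "ACTB", "GAPDH")] <- 40
  mu[grep("^HK", genes)] <- 60
  mu[grep("^MT-", genes)] <- 22
  mu[grep("^FILLER", genes)] <- 2
  mu[grep("^MOD\\.", genes)] <- 0.3
  mu[.ICP_GENES] <- 0.12
  mu[c("CD8A", "CD8B", "CD4", "FOXP3")] <- 0.15
  mu["CD28"] <- 0.8     # CD28 broadly expressed on T cells
  mu["PDCD1"] <- 0.10
  mu["IL7R"] <- 1
  mu
}

.defaultClusterPrograms <- function() {
  progs <- list(
    CD8.EM        = c(CD8A = 3, CD8B = 3, GZMK = 2, STAT4 = 2, IL7R = 1.5),
    CD8.exhausted = c(CD8A = 3, CD8B = 3, PDCD1 = 3, HAVCR2 = 2, LAG3 = 2,
                      TOX = 2, TIGIT = 2.5, ENTPD1 = 1.5),
    CD8.cytotoxic = c(CD8A = 3, CD8B = 3, GZMB = 2.5, PRF1 = 2.5,
                      NKG7 = 2.5, GNLY = 2.5),
    CD4.EM        = c(CD4 = 3, IL7R = 2, CCR7 = 1.5, SELL = 1.5, TCF7 = 1.5),
    CD4.TFH       = c(CD4 = 3, CXCL13 = 3, BCL6 = 1.5, ICOS = 1,
                      ENTPD1 = 1, CTLA4 = 1),
    CD4.Treg      = c(CD4 = 3, FOXP3 = 4, IKZF2 = 2,
                      IL2RA = 3.5, CD28 = 2, ENTPD1 = 3.5, TNFRSF9 = 3.5,
                      CTLA4 = 3.5, ICOS = 3.5, TNFRSF4 = 3.5, TIGIT = 3.5))
  for (cc in names(progs))
    progs[[cc]] <- c(progs[[cc]], setNames(rep(2.5, 15), .moduleGenes(cc)))
  progs
}

#' Single-cell cohort simulation configuration
#'
#' Emulates the structure of a droplet scRNA-seq + TCR cohort of
#' tumor-infiltrating T cells: six clusters spanning the CD8 and CD4
#' lineages (one FoxP3+ regulatory cluster with a broad checkpoint
#' program), sparse negative-binomial UMI counts, patient-private
#' clonotypes drawn from zero-truncated geometric clone-size laws with more
#' expansion in the CD8 lineage, and a planted log2 effect of clonal
#' expansion on checkpoint genes in the FoxP3+ cluster.
#'
#' @param nPatients number of patients (default 5).
#' @param cellsPerPatient cells per patient (default 2000).
#' @param clusterProps named cluster proportions summing to 1.
#' @param clusterLineage named map cluster -> `"CD8"`/`"CD4"` lineage (the
#'   FoxP3+ cluster belongs to the CD4 lineage).
#' @param markerPrograms named list: per cluster, named vector of log2
#'   fold-changes applied to the base means.
#' @param baseMeans named per-gene negative-binomial base means; defaults
#'   give roughly 2500 UMIs and 230 detected genes per cell with a ~5%
#'   mitochondrial fraction.
#' @param nbDispersion negative-binomial size parameter (default 1.5);
#'   a named vector `dispersionOverride` replaces it for specific genes.
#' @param dispersionOverride optional named per-gene size overrides.
#' @param cloneSizeP named success parameters of the zero-truncated
#'   geometric clone-size law per lineage.
#' @param pProductive probability that a T cell yields a productive TCR
#'   (default 0.84).
#' @param shareFrac target fraction of clonotypes observed in more than
#'   one cluster (default 0.054). Clones are assigned within cluster
#'   pools (sizes drawn from the lineage's law) and sharing is planted by
#'   swapping single members between same-lineage clones of different
#'   clusters, which preserves clone sizes and lineage expansion rates.
#' @param plantedIcpEffect log2 fold-change added to checkpoint genes in
#'   expanded (clone size >= 3) FoxP3+ cluster cells (default 1).
#' @param libSd log-normal sd of the per-cell library size factor.
#' @param seed integer RNG seed.
#' @return an object of class `ScSimConfig`.
#' @export
scSimConfig <- function(nPatients = 5, cellsPerPatient = 2000,
                        clusterProps = c(CD8.EM = 0.28, CD8.exhausted = 0.15,
                                         CD8.cytotoxic = 0.12, CD4.EM = 0.25,
                                         CD4.TFH = 0.05, CD4.Treg = 0.15),
                        clusterLineage = c(CD8.EM = "CD8",
                                           CD8.exhausted = "CD8",
                                           CD8.cytotoxic = "CD8",
                                           CD4.EM = "CD4", CD4.TFH = "CD4",
                                           CD4.Treg = "CD4"),
                        markerPrograms = .defaultClusterPrograms(),
                        baseMeans = NULL,
                        nbDispersion = 1.5,
                        dispersionOverride = NULL,
                        cloneSizeP = c(CD8 = .P_GEOM_CD8, CD4 = .P_GEOM_CD4),
                        pProductive = 0.84,
                        shareFrac = 0.054,
                        plantedIcpEffect = 1,
                        libSd = 0.25, seed = 1) {
  if (length(clusterProps) == 0) stop("empty cluster set")
  if (abs(sum(clusterProps) - 1) > 1e-9)
    stop("clusterProps must sum to 1")
  if (!all(names(clusterProps) %in% names(clusterLineage)))
    stop("every cluster needs a lineage")
  if (!all(names(clusterProps) %in% names(markerPrograms)))
    stop("every cluster needs a marker program (possibly empty)")
  if (nbDispersion <= 0) stop("negative-binomial dispersion must be > 0")
  if (any(cloneSizeP <= 0 | cloneSizeP >= 1))
    stop("clone-size law parameters must lie in (0, 1)")
  if (pProductive < 0 || pProductive > 1)
    stop("pProductive must lie in [0, 1]")
  if (shareFrac < 0 || shareFrac > 1)
    stop("shareFrac must lie in [0, 1]")
  if (is.null(baseMeans)) baseMeans <- .defaultBaseMeans(.defaultGeneUniverse())
  structure(list(nPatients = nPatients, cellsPerPatient = cellsPerPatient,
                 clusterProps = clusterProps, clusterLineage = clusterLineage,
                 markerPrograms = markerPrograms, baseMeans = baseMeans,
                 nbDispersion = nbDispersion,
                 dispersionOverride = dispersionOverride,
                 cloneSizeP = cloneSizeP, pProductive = pProductive,
                 shareFrac = shareFrac,
                 plantedIcpEffect = plantedIcpEffect,
                 libSd = libSd, seed = as.integer(seed)),
            class = "ScSimConfig")
}

.ztGeom <- function(n, p) 1L + rgeom(n, p)

.randomCdr3nt <- function(n) {
  len <- 3L * sample(10:15, n, replace = TRUE)
  vapply(len, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1))
}

.randomCdr3aa <- function(nt) {
  aa <- c("A","R","N","D","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")
  vapply(nchar(nt) / 3, function(l)
    paste0("C", paste(sample(aa, l - 2, replace = TRUE), collapse = ""), "F"),
    character(1))
}

## Assign productive cells of one (patient, lineage) pool to clones by
## drawing sizes from the zero-truncated geometric until cells run out.
.assignClones <- function(cells, p) {
  out <- integer(length(cells))
  remaining <- sample(cells)          # random order
  clone <- 0L
  while (length(remaining) > 0) {
    clone <- clone + 1L
    s <- min(.ztGeom(1L, p), length(remaining))
    out[remaining[seq_len(s)]] <- clone
    remaining <- remaining[-seq_len(s)]
  }
  out
}

#' Generate a synthetic scRNA-seq + TCR cohort
#'
#' One element per patient: a [SingleCellExperiment::SingleCellExperiment]
#' with sparse UMI counts (genes x cells), a 10x-style filtered-contig
#' annotation table, and the ground truth (cluster, lineage, clonotype and
#' planted effect per cell). Clonotype identifiers are patient-scoped and
#' never reused across patients.
#'
#' @param config a [scSimConfig] object.
#' @return list of length `nPatients`; each element has `$counts`
#'   (SingleCellExperiment), `$contigs` (data.frame) and `$truth`
#'   (data.frame).
#' @export
generateScCohort <- function(config = scSimConfig()) {
  stopifnot(inherits(config, "ScSimConfig"))
  set.seed(config$seed)
  genes <- names(config$baseMeans)
  icpInMatrix <- intersect(.ICP_GENES, genes)
  clusters <- names(config$clusterProps)
  size <- setNames(rep(config$nbDispersion, length(genes)), genes)
  if (!is.null(config$dispersionOverride))
    size[names(config$dispersionOverride)] <- config$dispersionOverride
  lapply(seq_len(config$nPatients), function(pi) {
    pid <- sprintf("P%02d", pi)
    n <- config$cellsPerPatient
    cl <- sample(clusters, n, replace = TRUE, prob = config$clusterProps)
    lineage <- unname(config$clusterLineage[cl])
    barcodes <- sprintf("%s_cell%04d", pid, seq_len(n))

    ## --- clonotypes -----------------------------------------------------
    ## Clones live within cluster pools; sizes follow the lineage's law.
    productive <- runif(n) < config$pProductive
    cloneId <- rep(NA_character_, n)
    counter <- 0L
    for (cc in unique(cl)) {
      pool <- which(cl == cc & productive)
      if (length(pool) == 0) next
      lin <- config$clusterLineage[[cc]]
      asg <- .assignClones(seq_along(pool), config$cloneSizeP[[lin]])
      cloneId[pool] <- sprintf("%s_CT%05d", pid, counter + asg)
      counter <- counter + max(asg)
    }
    has <- !is.na(cloneId)
    ## plant cross-cluster sharing: swap one member between same-lineage
    ## clones of different clusters (sizes and expansion rates unchanged)
    if (config$shareFrac > 0) {
      sizes <- table(cloneId[has])
      cloneCluster <- tapply(cl[has], cloneId[has], `[`, 1)
      cloneLin <- unname(config$clusterLineage[cloneCluster])
      eligible <- names(sizes)[sizes >= 2]
      nSwaps <- floor(config$shareFrac * length(sizes) / 2)
      for (i in seq_len(nSwaps)) {
        if (length(eligible) < 2) break
        a <- sample(eligible, 1)
        mates <- eligible[cloneLin[match(eligible, names(sizes))] ==
                            cloneLin[match(a, names(sizes))] &
                          cloneCluster[match(eligible, names(sizes))] !=
                            cloneCluster[match(a, names(sizes))]]
        mates <- setdiff(mates, a)
        if (length(mates) == 0) { eligible <- setdiff(eligible, a); next }
        b <- if (length(mates) == 1) mates else sample(mates, 1)
        ia <- which(cloneId == a)[1]
        ib <- which(cloneId == b)[1]
        cloneId[ia] <- b
        cloneId[ib] <- a
        eligible <- setdiff(eligible, c(a, b))
      }
    }
    cloneSize <- rep(NA_integer_, n)
    cloneSize[has] <- as.integer(table(cloneId[has])[cloneId[has]])

    ## --- counts ---------------------------------------------------------
    lib <- rlnorm(n, 0, config$libSd)
    expanded <- has & cloneSize >= 3
    mu <- matrix(config$baseMeans, length(genes), n,
                 dimnames = list(genes, barcodes))
    for (cc in clusters) {
      prog <- config$markerPrograms[[cc]]
      prog <- prog[names(prog) %in% genes]
      if (length(prog) == 0) next
      cols <- cl == cc
      if (!any(cols)) next
      mu[names(prog), cols] <- mu[names(prog), cols] * 2^prog
    }
    ## planted expansion effect on checkpoint genes in the FoxP3+ cluster
    tregCols <- cl == "CD4.Treg" & expanded
    if (any(tregCols) && config$plantedIcpEffect != 0)
      mu[icpInMatrix, tregCols] <-
        mu[icpInMatrix, tregCols] * 2^config$plantedIcpEffect
    mu <- sweep(mu, 2, lib, "*")
    counts <- matrix(rnbinom(length(mu), mu = mu, size = size),
                     length(genes), n, dimnames = dimnames(mu))
    sce <- SingleCellExperiment(
      assays = list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                         "CsparseMatrix")),
      colData = DataFrame(barcode = barcodes, patient = pid,
                          row.names = barcodes))

    ## --- contigs --------------------------------------------------------
    uc <- unique(cloneId[has])
    vA <- sample(sprintf("TRAV%d", 1:8), length(uc), replace = TRUE)
    jA <- sample(sprintf("TRAJ%d", 1:6), length(uc), replace = TRUE)
    vB <- sample(sprintf("TRBV%d", 2:9), length(uc), replace = TRUE)
    jB <- sample(sprintf("TRBJ%d", 1:5), length(uc), replace = TRUE)
    ntA <- .randomCdr3nt(length(uc)); aaA <- .randomCdr3aa(ntA)
    ntB <- .randomCdr3nt(length(uc)); aaB <- .randomCdr3aa(ntB)
    names(vA) <- names(jA) <- names(vB) <- names(jB) <- uc
    names(ntA) <- names(aaA) <- names(ntB) <- names(aaB) <- uc
    pb <- barcodes[has]; pc <- cloneId[has]
    contigs <- data.frame(
      barcode = rep(pb, each = 2),
      is_cell = "true", high_confidence = "true",
      contig_id = paste0(rep(pb, each = 2), "_contig_", rep(1:2, length(pb))),
      chain = rep(c("TRA", "TRB"), length(pb)),
      v_gene = as.vector(rbind(vA[pc], vB[pc])),
      d_gene = "None",
      j_gene = as.vector(rbind(jA[pc], jB[pc])),
      c_gene = rep(c("TRAC", "TRBC1"), length(pb)),
      full_length = "true", productive = "true",
      cdr3 = as.vector(rbind(aaA[pc], aaB[pc])),
      cdr3_nt = as.vector(rbind(ntA[pc], ntB[pc])),
      reads = 1000L, umis = 4L,
      raw_clonotype_id = rep(pc, each = 2),
      stringsAsFactors = FALSE)
    ## some unproductive cells still yield a single non-productive contig
    np <- which(!productive)
    np <- np[runif(length(np)) < 0.5]
    if (length(np) > 0) {
      nt <- .randomCdr3nt(length(np))
      contigs <- rbind(contigs, data.frame(
        barcode = barcodes[np], is_cell = "true", high_confidence = "true",
        contig_id = paste0(barcodes[np], "_contig_1"), chain = "TRB",
        v_gene = sample(sprintf("TRBV%d", 2:9), length(np), replace = TRUE),
        d_gene = "None",
        j_gene = sample(sprintf("TRBJ%d", 1:5), length(np), replace = TRUE),
        c_gene = "TRBC1", full_length = "false", productive = "false",
        cdr3 = .randomCdr3aa(nt), cdr3_nt = nt, reads = 120L, umis = 1L,
        raw_clonotype_id = "None", stringsAsFactors = FALSE))
    }
    contigs <- contigs[order(contigs$barcode, contigs$contig_id), ]
    rownames(contigs) <- NULL

    truth <- data.frame(barcode = barcodes, patient = pid, cluster = cl,
                        lineage = lineage, productive = productive,
                        clonotype_id = cloneId, clone_size = cloneSize,
                        expanded = !is.na(cloneSize) & cloneSize >= 3,
                        planted_icp_boost = as.numeric(tregCols) *
                          config$plantedIcpEffect,
                        stringsAsFactors = FALSE)
    list(counts = sce, contigs = contigs, truth = truth)
  })
}
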