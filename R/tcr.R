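## Clonotype calling from contig annotations, repertoire metrics and
## cross-cluster clonotype sharing.

#' Call clonotypes from contig annotations
#'
#' Groups cells into clonotypes from their productive TCR contigs. The
#' default (strict) clonotype key is the sorted multiset of
#' `(chain, v_gene, j_gene, cdr3_nt)` over a cell's productive contigs;
#' identical keys within a patient share a patient-scoped clonotype
#' identifier, and keys are never compared across patients. Cells with no
#' productive contig receive no clonotype (`clonality = "none"`).
#'
#' @param contigs data.frame with 10x-style columns `barcode`, `chain`
#'   (TRA/TRB; other values rejected with a message), `v_gene`, `j_gene`,
#'   `cdr3`, `cdr3_nt`, `productive`.
#' @param patient patient identifier (scopes the clonotype ids).
#' @param barcodes optional cell barcodes of the expression matrix; contig
#'   barcodes not present are dropped (count recorded), and listed cells
#'   without contigs appear with clonality `none`.
#' @param keyMode `"strict"` (chain + V/J genes + CDR3 nucleotide, the
#'   default), `"nt"` (chain + CDR3 nucleotide), `"aa"` (chain + CDR3
#'   amino acid) or `"beta"` (TRB chain only, strict fields).
#' @param sizeBreaks clone-size class boundaries; default classes
#'   1, 2, 3-10, 11-100, >100.
#' @return a [ClonotypeTable-class].
#' @export
callClonotypes <- function(contigs, patient, barcodes = NULL,
                           keyMode = c("strict", "nt", "aa", "beta"),
                           sizeBreaks = c(1, 2, 10, 100, Inf)) {
  keyMode <- match.arg(keyMode)
  need <- c("barcode", "chain", "v_gene", "j_gene", "cdr3", "cdr3_nt",
            "productive")
  miss <- setdiff(need, colnames(contigs))
  if (length(miss) > 0)
    stop("contig table lacks column(s): ", paste(miss, collapse = ", "))
  badChain <- !contigs$chain %in% c("TRA", "TRB")
  if (any(badChain)) {
    message(sum(badChain), " contig row(s) with malformed chain rejected")
    contigs <- contigs[!badChain, , drop = FALSE]
  }
  dropped <- 0L
  if (!is.null(barcodes)) {
    unmatched <- !contigs$barcode %in% barcodes
    dropped <- length(unique(contigs$barcode[unmatched]))
    if (dropped > 0)
      message(dropped, " contig barcode(s) without matching cell dropped")
    contigs <- contigs[!unmatched, , drop = FALSE]
  }
  prod <- tolower(as.character(contigs$productive)) %in% c("true", "t", "1")
  pc <- contigs[prod, , drop = FALSE]
  if (keyMode == "beta") pc <- pc[pc$chain == "TRB", , drop = FALSE]
  piece <- switch(keyMode,
    strict = , beta = paste(pc$chain, pc$v_gene, pc$j_gene, pc$cdr3_nt,
                            sep = ":"),
    nt = paste(pc$chain, pc$cdr3_nt, sep = ":"),
    aa = paste(pc$chain, pc$cdr3, sep = ":"))
  keys <- tapply(piece, pc$barcode, function(p)
    paste(sort(p), collapse = ";"))
  nChains <- table(contigs$barcode[prod])
  allBC <- if (is.null(barcodes)) unique(contigs$barcode) else barcodes
  key <- unname(keys[allBC])
  ids <- rep(NA_character_, length(allBC))
  hasKey <- !is.na(key)
  if (any(hasKey)) {
    firstSeen <- match(key[hasKey], unique(key[hasKey]))
    ids[hasKey] <- sprintf("%s_CT%05d", patient, firstSeen)
  }
  size <- rep(NA_integer_, length(allBC))
  if (any(hasKey))
    size[hasKey] <- as.integer(table(ids[hasKey])[ids[hasKey]])
  clonality <- ifelse(is.na(ids), "none", ifelse(size >= 3, "HC", "LC"))
  labs <- c(as.character(sizeBreaks[1]),
            vapply(seq_len(length(sizeBreaks) - 2), function(i) {
              lo <- sizeBreaks[i] + 1; hi <- sizeBreaks[i + 1]
              if (lo == hi) as.character(lo) else paste0(lo, "-", hi)
            }, character(1)),
            paste0(">", sizeBreaks[length(sizeBreaks) - 1]))
  sizeClass <- rep(NA_character_, length(allBC))
  sizeClass[hasKey] <- labs[findInterval(size[hasKey],
                                         c(sizeBreaks[1], sizeBreaks + 1))]
  nch <- integer(length(allBC))
  inTab <- allBC %in% names(nChains)
  nch[inTab] <- as.integer(nChains[allBC[inTab]])
  new("ClonotypeTable",
      cells = DataFrame(barcode = allBC, patient = patient,
                        clonotype_id = ids, n_productive_chains = nch,
                        clone_size = size, clonality = clonality,
                        size_class = sizeClass),
      droppedBarcodes = dropped)
}

#' Combine per-patient clonotype tables
#'
#' @param ... ClonotypeTable objects (or a single list of them).
#' @return one [ClonotypeTable-class] covering all patients.
#' @export
combineClonotypes <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1 && is.list(tabs[[1]]) &&
      !is(tabs[[1]], "ClonotypeTable")) tabs <- tabs[[1]]
  cells <- do.call(rbind, lapply(tabs, clonotypeCells))
  new("ClonotypeTable", cells = cells,
      droppedBarcodes = sum(vapply(tabs, function(t) t@droppedBarcodes,
                                   integer(1))))
}

#' Repertoire metrics
#'
#' Per patient and cluster: unique clonotype count, percent of cells with a
#' productive TCR, and the clone-size-class composition of cells. Per
#' lineage: the percent of clonotyped cells belonging to expanded clones
#' (clone size >= 3).
#'
#' @param ct a [ClonotypeTable-class].
#' @param clusters named (by barcode) or aligned cluster label per cell.
#' @param lineages optional named map cluster -> lineage (e.g. `"CD8"`,
#'   `"CD4"`); lineage metrics are skipped when absent.
#' @return list with `byCluster` (data.frame), `sizeClassCounts`
#'   (patient x cluster x class cell counts, long form) and
#'   `expandedByLineage` (percent of clonotyped cells in expanded clones).
#' @export
repertoireMetrics <- function(ct, clusters, lineages = NULL) {
  d <- as.data.frame(clonotypeCells(ct))
  if (!is.null(names(clusters))) clusters <- clusters[d$barcode]
  if (length(clusters) != nrow(d)) stop("cluster labels must cover all cells")
  d$cluster <- as.character(clusters)
  has <- !is.na(d$clonotype_id)
  byCluster <- do.call(rbind, lapply(split(d, list(d$patient, d$cluster),
                                           drop = TRUE), function(g) {
    data.frame(patient = g$patient[1], cluster = g$cluster[1],
               n_cells = nrow(g),
               n_clonotypes = length(unique(g$clonotype_id[!is.na(g$clonotype_id)])),
               pct_productive = 100 * mean(!is.na(g$clonotype_id)),
               stringsAsFactors = FALSE)
  }))
  rownames(byCluster) <- NULL
  scc <- as.data.frame(table(patient = d$patient[has],
                             cluster = d$cluster[has],
                             size_class = d$size_class[has]),
                       stringsAsFactors = FALSE)
  names(scc)[4] <- "n_cells"
  out <- list(byCluster = byCluster, sizeClassCounts = scc)
  if (!is.null(lineages)) {
    d$lineage <- unname(lineages[d$cluster])
    dl <- d[has & !is.na(d$lineage), , drop = FALSE]
    out$expandedByLineage <- vapply(split(dl, dl$lineage), function(g)
      100 * mean(g$clone_size >= 3), numeric(1))
  }
  out
}

#' Clonotype sharing between clusters
#'
#' The fraction of clonotypes observed in two or more clusters, per patient
#' and pooled over patients (sharing is never counted across patients), and
#' a pairwise flow table for Sankey-style export.
#'
#' @param ct a [ClonotypeTable-class].
#' @param clusters named (by barcode) or aligned cluster label per cell.
#' @return list with `perPatient` (data.frame patient, n_clonotypes,
#'   n_shared, pct_shared), `pooled` (percent over all clonotypes) and
#'   `flows` (clonotype, cluster_a, cluster_b, n_cells_a, n_cells_b).
#' @export
clonotypeSharing <- function(ct, clusters) {
  d <- as.data.frame(clonotypeCells(ct))
  if (!is.null(names(clusters))) clusters <- clusters[d$barcode]
  if (length(clusters) != nrow(d)) stop("cluster labels must cover all cells")
  d$cluster <- as.character(clusters)
  d <- d[!is.na(d$clonotype_id), , drop = FALSE]
  if (length(unique(d$cluster)) < 2) stop("need at least two clusters")
  perClone <- split(d$cluster, d$clonotype_id)
  nClusters <- vapply(perClone, function(cl) length(unique(cl)), integer(1))
  clonePatient <- vapply(split(d$patient, d$clonotype_id), `[`, character(1), 1)
  perPatient <- do.call(rbind, lapply(split(names(perClone), clonePatient),
                                      function(ids) {
    data.frame(patient = clonePatient[[ids[1]]],
               n_clonotypes = length(ids),
               n_shared = sum(nClusters[ids] >= 2),
               pct_shared = 100 * mean(nClusters[ids] >= 2),
               stringsAsFactors = FALSE)
  }))
  rownames(perPatient) <- NULL
  shared <- names(perClone)[nClusters >= 2]
  flows <- do.call(rbind, lapply(shared, function(id) {
    tab <- table(perClone[[id]])
    cls <- names(tab)
    pairs <- utils::combn(cls, 2)
    data.frame(clonotype = id, cluster_a = pairs[1, ],
               cluster_b = pairs[2, ],
               n_cells_a = as.integer(tab[pairs[1, ]]),
               n_cells_b = as.integer(tab[pairs[2, ]]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(flows))
    flows <- data.frame(clonotype = character(0), cluster_a = character(0),
                        cluster_b = character(0), n_cells_a = integer(0),
                        n_cells_b = integer(0))
  list(perPatient = perPatient,
       pooled = 100 * mean(nClusters >= 2),
       flows = flows)
}
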