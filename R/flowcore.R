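## Supervised flow-cytometry analysis: hierarchical subset gating,
## checkpoint positivity and MFI per subset, the Treg/Tconv MFI-ratio
## summary, and pairwise co-positivity.

#' Hierarchical subset gating
#'
#' Assigns each cell of a sample to a T-cell subset by threshold gating:
#' CD45+ then CD3+ cells are T cells, split by CD4/CD8 into CD8
#' (CD8+CD4-), DP (CD4+CD8+), DN (CD4-CD8-) and CD4+CD8- cells, the
#' latter split by FoxP3 into CD4FoxP3pos / CD4FoxP3neg. Cells failing the
#' CD45 or CD3 gate are labeled `nonT` regardless of other markers.
#'
#' @param m a [FlowSample-class].
#' @param gates named numeric cutoffs; must include CD45, CD3, CD4, CD8
#'   and FoxP3 (same units as the fluorescence values).
#' @return character vector of per-cell labels (`CD8`, `CD4FoxP3neg`,
#'   `CD4FoxP3pos`, `DP`, `DN`, `nonT`), named by cell.
#' @export
assignSubsets <- function(m, gates) {
  need <- .LINEAGE_MARKERS
  missing <- setdiff(need, names(gates))
  if (length(missing) > 0)
    stop("missing gating threshold(s) for: ", paste(missing, collapse = ", "))
  if (any(!is.finite(unlist(gates[need])))) stop("gating cutoffs must be finite")
  x <- fluorescence(m)
  missingM <- setdiff(need, colnames(x))
  if (length(missingM) > 0)
    stop("sample lacks gating marker(s): ", paste(missingM, collapse = ", "))
  isT <- x[, "CD45"] > gates[["CD45"]] & x[, "CD3"] > gates[["CD3"]]
  cd4 <- x[, "CD4"] > gates[["CD4"]]
  cd8 <- x[, "CD8"] > gates[["CD8"]]
  foxp3 <- x[, "FoxP3"] > gates[["FoxP3"]]
  out <- rep("nonT", nrow(x))
  out[isT & cd8 & !cd4] <- "CD8"
  out[isT & cd4 & !cd8 & foxp3] <- "CD4FoxP3pos"
  out[isT & cd4 & !cd8 & !foxp3] <- "CD4FoxP3neg"
  out[isT & cd4 & cd8] <- "DP"
  out[isT & !cd4 & !cd8] <- "DN"
  names(out) <- rownames(x)
  out
}

#' Per-subset checkpoint profile
#'
#' For each reported subset (CD8, CD4FoxP3neg, CD4FoxP3pos): the percent of
#' subset cells positive for each panel checkpoint (threshold gating) and
#' the mean fluorescence intensity (arithmetic mean of the untransformed
#' values), plus the subset's share of T cells. Subsets without cells are
#' omitted with a warning.
#'
#' @param m a [FlowSample-class].
#' @param labels per-cell subset labels from [assignSubsets].
#' @param gates named positivity cutoffs covering the panel checkpoints.
#' @param subsets subsets to report (default the three main T subsets).
#' @return data.frame with columns `sample_id`, `subset`,
#'   `subset_fraction_of_T`, `icp`, `percent_positive`, `mfi`.
#' @export
icpProfile <- function(m, labels, gates,
                       subsets = c("CD8", "CD4FoxP3neg", "CD4FoxP3pos")) {
  x <- fluorescence(m)
  panel <- samplePanel(m)
  missing <- setdiff(panel, names(gates))
  if (length(missing) > 0)
    stop("missing positivity cutoff(s) for: ", paste(missing, collapse = ", "))
  tcells <- labels != "nonT"
  nT <- sum(tcells)
  out <- list()
  for (ss in subsets) {
    rows <- labels == ss
    if (!any(rows)) {
      warning("subset ", ss, " has no cells in sample ", sampleId(m),
              "; omitted")
      next
    }
    pp <- vapply(panel, function(icp)
      100 * mean(x[rows, icp] > gates[[icp]]), numeric(1))
    mfi <- vapply(panel, function(icp) mean(x[rows, icp]), numeric(1))
    out[[ss]] <- data.frame(
      sample_id = sampleId(m), subset = ss,
      subset_fraction_of_T = 100 * sum(rows) / nT,
      icp = panel, percent_positive = unname(pp), mfi = unname(mfi),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Treg / Tconv MFI ratio per checkpoint
#'
#' For each checkpoint, the ratio of the cohort median of the CD4+FoxP3+
#' MFI over the cohort median of the CD4+FoxP3- MFI (medians taken across
#' samples of the per-sample mean fluorescence).
#'
#' @param profiles row-bound [icpProfile] output across the cohort.
#' @return named numeric vector of ratios, one per checkpoint (`Inf` with a
#'   warning when a denominator median is zero).
#' @export
mfiRatio <- function(profiles) {
  treg <- profiles[profiles$subset == "CD4FoxP3pos", ]
  tconv <- profiles[profiles$subset == "CD4FoxP3neg", ]
  if (nrow(treg) == 0 || nrow(tconv) == 0)
    stop("need at least one sample with both CD4 subsets")
  icps <- unique(profiles$icp)
  vapply(icps, function(icp) {
    num <- median(treg$mfi[treg$icp == icp])
    den <- median(tconv$mfi[tconv$icp == icp])
    if (den == 0) {
      warning("zero denominator median for ", icp, "; ratio reported as Inf")
      return(Inf)
    }
    num / den
  }, numeric(1))
}

#' Checkpoint co-positivity
#'
#' Within a chosen subset, the percent of cells positive for both of two
#' checkpoints; and among all CD4+ cells (FoxP3+ or FoxP3-) double-positive
#' for the pair, the percent that are FoxP3+ — the surrogate-gating summary
#' for identifying Tregs without intracellular FoxP3 staining.
#'
#' @param m a [FlowSample-class].
#' @param labels per-cell subset labels from [assignSubsets].
#' @param icpA,icpB the two panel checkpoints.
#' @param gates named positivity cutoffs.
#' @param subset subset for the double-positive percentage (default
#'   CD4FoxP3pos).
#' @return list with `percent_double_positive` (within `subset`) and
#'   `percent_foxp3_of_cd4_dp` (`NA` when no CD4+ double-positive cells).
#' @export
coPositivity <- function(m, labels, icpA, icpB, gates,
                         subset = "CD4FoxP3pos") {
  panel <- samplePanel(m)
  if (!all(c(icpA, icpB) %in% panel))
    stop("both checkpoints must be in the sample panel")
  x <- fluorescence(m)
  dp <- x[, icpA] > gates[[icpA]] & x[, icpB] > gates[[icpB]]
  rows <- labels == subset
  pctDP <- if (any(rows)) 100 * mean(dp[rows]) else NA_real_
  cd4 <- labels %in% c("CD4FoxP3neg", "CD4FoxP3pos")
  cd4dp <- cd4 & dp
  pctFoxp3 <- if (any(cd4dp))
    100 * mean(labels[cd4dp] == "CD4FoxP3pos") else NA_real_
  list(percent_double_positive = pctDP,
       percent_foxp3_of_cd4_dp = pctFoxp3)
}
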