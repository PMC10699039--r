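## Configuration validation and end-to-end orchestration of the stages:
## simulate -> flow (supervised + unsupervised) -> sc -> tcr -> clonex.
## All randomness flows through stage-scoped seeds derived from the one
## global seed, so toggling a stage does not shift another stage's draws.

.STAGE_SEED_OFFSET <- c(simulate = 11L, flow = 23L, cluster = 37L,
                        sc = 41L, tcr = 53L, clonex = 67L)

#' Default run configuration
#'
#' Nested list of all stage parameters with the standard defaults
#' (PhenoGraph k = 30, 3000 highly variable genes, dimension grid 3-49
#' step 2, resolution grid 0.1-1.2 step 0.1, the QC and differential
#' expression thresholds, majority HE rule).
#'
#' @return a named list (class `RunConfig`).
#' @export
defaultRunConfig <- function() {
  structure(list(
    seed = 1L,
    outdir = "til_run",
    stages = list(simulate = TRUE, flow = TRUE, cluster = TRUE,
                  sc = TRUE, tcr = TRUE, clonex = TRUE),
    flow_sim = list(n_samples = 4L, cells_per_sample = 3000L),
    sc_sim = list(n_patients = 2L, cells_per_patient = 2000L),
    cluster = list(k = 30L, resolution = 1, max_cells = 4000L,
                   umap = FALSE),
    sc = list(min_cells_per_gene = 5L, min_umi = 1000L, min_genes = 200L,
              max_mito_frac = 0.2, hvg = 3000L,
              dims_grid = seq(3, 49, 2), res_grid = seq(0.1, 1.2, 0.1),
              knn = 20L, stability_floor = 0.5),
    de = list(log2fc = 0.58, min_pct = 0.25, alpha = 0.05),
    tcr = list(key_mode = "strict"),
    clonex = list(rule = "majority", min_cells = 10L)
  ), class = "RunConfig")
}

.mergeConfig <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste(path, key, sep = ".")
    if (!key %in% names(defaults))
      stop("unknown configuration key: ", full)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop("configuration key ", full, " must be a mapping")
      defaults[[key]] <- .mergeConfig(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Validate a run configuration
#'
#' Reads a YAML file (or accepts a list), fills defaults, rejects unknown
#' keys by name, and checks value ranges. Validation is idempotent:
#' re-validating a validated configuration returns it unchanged.
#'
#' @param config YAML path, a list of overrides, or `NULL` for pure
#'   defaults.
#' @return a validated `RunConfig` list.
#' @export
validateConfig <- function(config = NULL) {
  user <- if (is.null(config)) list()
  else if (is.character(config)) {
    out <- yaml::read_yaml(config)
    if (is.null(out)) list() else out
  } else as.list(config)
  class(user) <- NULL
  cfg <- .mergeConfig(unclass(defaultRunConfig()), user)
  with(cfg, {
    stopifnot(is.numeric(seed), length(seed) == 1)
    if (cluster$k < 1) stop("cluster$k must be >= 1")
    if (sc$hvg < 1) stop("sc$hvg must be >= 1")
    if (de$min_pct < 0 || de$min_pct > 1) stop("de$min_pct must be in [0,1]")
    if (!tcr$key_mode %in% c("strict", "nt", "aa", "beta"))
      stop("unknown tcr$key_mode")
    if (!clonex$rule %in% c("majority", "meanScore"))
      stop("unknown clonex$rule")
  })
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "RunConfig")
}

.stageSeed <- function(config, stage)
  (config$seed + .STAGE_SEED_OFFSET[[stage]]) %% .Machine$integer.max

#' Run the full pipeline
#'
#' Executes the enabled stages in dependency order (simulate -> flow /
#' cluster / sc -> tcr -> clonex), writes every stage's outputs as TSV /
#' CSV / MTX under `outdir`, and returns a manifest recording seeds,
#' package version, input hashes and output paths. A rerun with the same
#' configuration reproduces byte-identical outputs.
#'
#' @param config a validated `RunConfig` (see [validateConfig]).
#' @return the manifest (named list), invisibly; also written as
#'   `manifest.json` in `outdir`.
#' @export
runPipeline <- function(config = validateConfig()) {
  config <- validateConfig(unclass(config))
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("TILprofiler")),
                   r_version = R.version.string,
                   seed = config$seed, stage_seeds = as.list(.STAGE_SEED_OFFSET + config$seed),
                   outputs = list())
  addOut <- function(path) manifest$outputs[[length(manifest$outputs) + 1]] <<- path
  st <- config$stages
  if (!st$simulate)
    stop("stage 'simulate' is required as the data source of this run")
  if (st$clonex && !(st$tcr && st$sc))
    stop("stage 'clonex' requires stages 'tcr' and 'sc'")
  if (st$tcr && !st$sc)
    stop("stage 'tcr' requires stage 'sc' (barcode matching)")

  ## --- simulate --------------------------------------------------------
  fcfg <- flowSimConfig(nSamples = config$flow_sim$n_samples,
                        cellsPerSample = config$flow_sim$cells_per_sample,
                        seed = .stageSeed(config, "simulate"))
  flowCohort <- generateFlowCohort(fcfg)
  scfg <- scSimConfig(nPatients = config$sc_sim$n_patients,
                      cellsPerPatient = config$sc_sim$cells_per_patient,
                      seed = .stageSeed(config, "simulate") + 1L)
  scCohort <- generateScCohort(scfg)
  simdir <- file.path(out, "sim")
  dir.create(simdir, showWarnings = FALSE)
  for (el in flowCohort) {
    p <- file.path(simdir, paste0("flow_", sampleId(el$sample), ".csv"))
    writeFlowCSV(el$sample, p); addOut(p)
  }
  for (el in scCohort) {
    pid <- el$truth$patient[1]
    d <- file.path(simdir, pid)
    writeCountsMTX(el$counts, d); addOut(d)
    p <- file.path(simdir, paste0(pid, "_filtered_contig_annotations.csv"))
    writeContigCSV(el$contigs, p); addOut(p)
    p <- file.path(simdir, paste0(pid, "_truth.tsv"))
    writeTSV(el$truth, p); addOut(p)
  }

  ## --- flow (supervised) ----------------------------------------------
  if (st$flow) {
    gates <- trueGates(fcfg)
    profiles <- do.call(rbind, lapply(flowCohort, function(el) {
      icpProfile(el$sample, assignSubsets(el$sample, gates), gates)
    }))
    p <- file.path(out, "flow_profiles.tsv"); writeTSV(profiles, p); addOut(p)
    ratios <- mfiRatio(profiles)
    p <- file.path(out, "flow_mfi_ratio.tsv")
    writeTSV(data.frame(icp = names(ratios), ratio = ratios), p); addOut(p)
  }

  ## --- flow (unsupervised) ---------------------------------------------
  if (st$cluster) {
    gates <- trueGates(fcfg)
    tcellMats <- lapply(flowCohort, function(el) {
      lab <- assignSubsets(el$sample, gates)
      el$sample[, lab != "nonT"]
    })
    pooledN <- sum(vapply(tcellMats, ncol, integer(1)))
    if (pooledN > config$cluster$max_cells) {
      set.seed(.stageSeed(config, "cluster"))
      keepFrac <- config$cluster$max_cells / pooledN
      tcellMats <- lapply(tcellMats, function(s)
        s[, runif(ncol(s)) < keepFrac])
    }
    cres <- clusterFlowCohort(tcellMats, k = config$cluster$k,
                              seed = .stageSeed(config, "cluster"),
                              resolution = config$cluster$resolution,
                              umap = config$cluster$umap)
    p <- file.path(out, "flow_cluster_labels.tsv")
    writeTSV(data.frame(cell = rownames(cres$transformed),
                        sample = cres$sample, cluster = cres$labels), p)
    addOut(p)
    p <- file.path(out, "flow_cluster_profile.tsv")
    writeTSV(cres$summary$profile, p); addOut(p)
    p <- file.path(out, "flow_cluster_abundance.tsv")
    writeTSV(cres$summary$abundance, p); addOut(p)
    p <- file.path(out, "flow_graph_edges.tsv")
    writeTSV(igraph::as_data_frame(cres$graph), p); addOut(p)
    if (!is.null(cres$embedding)) {
      p <- file.path(out, "flow_umap.tsv")
      writeTSV(data.frame(cell = rownames(cres$transformed),
                          umap1 = cres$embedding[, 1],
                          umap2 = cres$embedding[, 2]), p); addOut(p)
    }
  }

  ## --- sc ---------------------------------------------------------------
  scResults <- NULL
  if (st$sc) {
    ## concatenation without batch correction; per-patient truth retained
    merged <- mergePatients(lapply(scCohort, function(el) el$counts))
    qc <- qcFilter(merged, qcConfig(
      minCellsPerGene = config$sc$min_cells_per_gene,
      minUmi = config$sc$min_umi, minGenes = config$sc$min_genes,
      maxMitoFrac = config$sc$max_mito_frac))
    sce <- logNormalize(qc$sce)
    hvg <- selectHVG(sce, n = min(config$sc$hvg, nrow(sce)))
    rc <- reduceAndCluster(sce, hvg,
                           dimsGrid = config$sc$dims_grid,
                           resGrid = config$sc$res_grid,
                           k = config$sc$knn,
                           seed = .stageSeed(config, "sc"),
                           stabilityFloor = config$sc$stability_floor)
    clusters <- setNames(paste0("sc", rc$labels), colnames(sce))
    lineage <- assignLineage(clusters, sce)
    scResults <- list(sce = sce, clusters = clusters, lineage = lineage,
                      qcReport = qc$report, choice = rc)
    p <- file.path(out, "sc_qc_report.json")
    jsonlite::write_json(qc$report, p, auto_unbox = TRUE); addOut(p)
    p <- file.path(out, "sc_clusters.tsv")
    writeTSV(data.frame(barcode = colnames(sce),
                        patient = colData(sce)$patient,
                        cluster = clusters,
                        lineage = unname(lineage[clusters])), p); addOut(p)
    p <- file.path(out, "sc_grid_report.tsv")
    writeTSV(rc$report, p); addOut(p)
  }

  ## --- tcr --------------------------------------------------------------
  ct <- NULL
  if (st$tcr) {
    tabs <- lapply(scCohort, function(el) {
      pid <- el$truth$patient[1]
      bcs <- intersect(colnames(scResults$sce),
                       colnames(el$counts))
      callClonotypes(el$contigs, patient = pid, barcodes = bcs,
                     keyMode = config$tcr$key_mode)
    })
    ct <- combineClonotypes(tabs)
    p <- file.path(out, "clonotypes.tsv")
    writeTSV(as.data.frame(clonotypeCells(ct)), p); addOut(p)
    mets <- repertoireMetrics(ct, scResults$clusters, scResults$lineage)
    p <- file.path(out, "repertoire_by_cluster.tsv")
    writeTSV(mets$byCluster, p); addOut(p)
    p <- file.path(out, "repertoire_size_classes.tsv")
    writeTSV(mets$sizeClassCounts, p); addOut(p)
    sh <- clonotypeSharing(ct, scResults$clusters)
    p <- file.path(out, "clonotype_sharing.tsv")
    writeTSV(sh$perPatient, p); addOut(p)
    p <- file.path(out, "clonotype_flows.tsv")
    writeTSV(sh$flows, p); addOut(p)
  }

  ## --- clonex -----------------------------------------------------------
  if (st$clonex) {
    sce <- scResults$sce
    cells <- clonotypeCells(ct)
    clonotyped <- cells$barcode[!is.na(cells$clonotype_id)]
    med <- icpMedians(sce, clonotyped)
    he <- classifyExpression(sce, med, rule = config$clonex$rule)
    comp <- compartmentalize(he, ct, scResults$clusters,
                             scResults$lineage)
    p <- file.path(out, "compartments.tsv")
    writeTSV(comp$cells, p); addOut(p)
    p <- file.path(out, "compartments_by_cluster.tsv")
    writeTSV(comp$byCluster, p); addOut(p)
    bur <- icpBurden(sce, ct, scResults$clusters)
    p <- file.path(out, "icp_burden_by_cluster.tsv")
    writeTSV(bur$byCluster, p); addOut(p)
    dif <- lcHcDifferential(sce, ct, scResults$clusters,
                            minCells = config$clonex$min_cells)
    p <- file.path(out, "lc_hc_differential.tsv")
    writeTSV(dif, p); addOut(p)
  }

  manifest$input_hashes <- as.list(tools::md5sum(
    list.files(simdir, recursive = TRUE, full.names = TRUE)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
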