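#' Run a pipeline stage (or the whole chain) with file-based artifacts
#'
#' Thin orchestration layer tying the analysis stages into reproducible,
#' file-based workflows. Each stage reads its inputs from \code{out_dir}
#' (or the configured paths), writes versioned TSV/JSON artifacts back, and
#' records a run manifest (configuration, seed, input checksums, timing).
#' \code{"all"} chains simulate, preprocess, diffexp, network, modules,
#' preserve and bottleneck in order.
#'
#' Configuration is a YAML or JSON file (or an R list) with optional
#' sections \code{sim}, \code{preprocess}, \code{network},
#' \code{preservation}, \code{bottleneck}, \code{diffexp}, \code{paths} and
#' \code{filter}; anything omitted uses the package defaults. The
#' \code{filter} section selects samples declaratively, e.g.
#' \code{filter: {diagnosis: [CTL, PD, PDD, DLB]}}, and \code{diffexp}
#' supports a trait stratification such as CERAD 0-1 versus 2-3 via
#' \code{stratify: {column: cerad, low: [0, 1], high: [2, 3]}}.
#'
#' @param command one of simulate, preprocess, diffexp, network, modules,
#'   preserve, bottleneck, all.
#' @param config a list, or path to a YAML/JSON configuration file.
#' @param out_dir artifact directory (created if needed).
#' @param seed integer seed propagated to every stochastic stage.
#' @return invisibly, a list of the stage result objects.
#' @export
runPipeline <- function(command = c("simulate", "preprocess", "diffexp",
                                    "network", "modules", "preserve",
                                    "bottleneck", "all"),
                        config = NULL, out_dir = "wpcna_out", seed = 1L) {
  command <- match.arg(command)
  cfg <- .loadPipelineConfig(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- if (command == "all")
    c("simulate", "preprocess", "diffexp", "network", "modules",
      "preserve", "bottleneck")
  else command
  results <- list()
  for (st in stages) {
    t0 <- Sys.time()
    results[[st]] <- switch(st,
      simulate = .stageSimulate(cfg, out_dir, seed),
      preprocess = .stagePreprocess(cfg, out_dir, seed),
      diffexp = .stageDiffexp(cfg, out_dir),
      network = .stageNetwork(cfg, out_dir),
      modules = .stageModules(cfg, out_dir),
      preserve = .stagePreserve(cfg, out_dir, seed),
      bottleneck = .stageBottleneck(cfg, out_dir)
    )
    .writeManifest(st, cfg, out_dir, seed, t0)
  }
  invisible(results)
}

.loadPipelineConfig <- function(config) {
  if (is.null(config)) return(list())
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON file")
  config
}

.writeManifest <- function(stage, cfg, out_dir, seed, t0) {
  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("manifest_", files)]
  manifest <- list(
    stage = stage,
    seed = seed,
    config = cfg,
    package_version = as.character(packageVersion("wpcna")),
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    checksums = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

.applySampleFilter <- function(x, samples, filter) {
  if (is.null(filter)) return(list(x = x, samples = samples))
  keep <- rep(TRUE, nrow(samples))
  for (col in names(filter))
    keep <- keep & samples[[col]] %in% filter[[col]]
  list(x = x[, samples$sample_id[keep], drop = FALSE],
       samples = samples[keep, , drop = FALSE])
}

# coerce configuration fields arriving from YAML/JSON (lists, unnamed
# arrays) back into the vectors and matrices simConfig expects
.sanitizeSimArgs <- function(args) {
  vec_fields <- c("module_sizes", "groups", "bottleneck_targets",
                  "bottleneck_weights", "covariate_effects",
                  "loading_range")
  for (nm in intersect(names(args), vec_fields))
    args[[nm]] <- unlist(args[[nm]])
  if (!is.null(args$groups) && is.null(names(args$groups)))
    stop("config field 'groups' must be a named mapping, e.g. ",
         "groups: {CTL: 47, PD: 33, PDD: 47, DLB: 11}")
  if (!is.null(args$group_effects)) {
    ge <- args$group_effects
    if (!is.matrix(ge)) ge <- do.call(rbind, lapply(ge, unlist))
    dimnames(ge) <- list(paste0("M", seq_len(nrow(ge))), names(args$groups))
    args$group_effects <- ge
  }
  if (!is.null(args$trait_loadings)) {
    tl <- args$trait_loadings
    if (!is.matrix(tl)) tl <- do.call(rbind, lapply(tl, unlist))
    dimnames(tl) <- list(paste0("M", seq_len(nrow(tl))),
                         c("cerad", "braak", "lb_score"))
    args$trait_loadings <- tl
  }
  args[intersect(names(args), names(formals(simConfig)))]
}

.stageSimulate <- function(cfg, out_dir, seed) {
  args <- .sanitizeSimArgs(cfg$sim %||% list())
  args$seed <- args$seed %||% seed
  sc <- do.call(simConfig, args)
  se <- simulateCohort(sc)
  truth <- metadata(se)$truth
  writeAbundance(assay(se, "log2"), file.path(out_dir, "abundance.tsv"))
  writeSampleTable(as.data.frame(colData(se)),
                   file.path(out_dir, "samples.tsv"))
  writeTruthJSON(truth, file.path(out_dir, "truth.json"))
  writeGMT(simulateMarkerSets(truth, seed = .subSeed(seed, 3L)),
           file.path(out_dir, "markers.gmt"))
  se
}

.stagePreprocess <- function(cfg, out_dir, seed) {
  paths <- cfg$paths %||% list()
  x <- readAbundance(paths$matrix %||% file.path(out_dir, "abundance.tsv"))
  samples <- readSampleTable(paths$samples %||%
                               file.path(out_dir, "samples.tsv"))
  fl <- .applySampleFilter(x, samples, cfg$filter)
  se <- SummarizedExperiment(assays = list(log2 = fl$x),
                             colData = DataFrame(fl$samples))
  args <- cfg$preprocess %||% list()
  args$se <- se
  args$seed <- args$seed %||% seed
  out <- do.call(preprocessCohort, args)
  writeAbundance(assay(out, "log2"), file.path(out_dir, "cleaned.tsv"))
  writeSampleTable(as.data.frame(colData(out)),
                   file.path(out_dir, "cleaned_samples.tsv"))
  jsonlite::write_json(metadata(out)$preprocess,
                       file.path(out_dir, "preprocess_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  out
}

.readCleaned <- function(cfg, out_dir) {
  x <- readAbundance(file.path(out_dir, "cleaned.tsv"))
  samples <- readSampleTable(file.path(out_dir, "cleaned_samples.tsv"))
  list(x = x, samples = samples[colnames(x), , drop = FALSE])
}

.stageDiffexp <- function(cfg, out_dir) {
  cl <- .readCleaned(cfg, out_dir)
  res <- anovaTukey(cl$x, cl$samples$diagnosis)
  write.table(res, file.path(out_dir, "diffexp_anova.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  strat <- cfg$diffexp$stratify %||%
    list(column = "cerad", low = c(0, 1), high = c(2, 3))
  v <- cl$samples[[strat$column]]
  grp <- ifelse(v %in% strat$low, "low",
                ifelse(v %in% strat$high, "high", NA))
  keep <- !is.na(grp)
  tt <- NULL
  if (sum(keep) >= 4L && length(unique(grp[keep])) == 2L) {
    tt <- twoGroupTest(cl$x[, keep, drop = FALSE],
                       factor(grp[keep], levels = c("low", "high")))
    write.table(tt, file.path(out_dir, "diffexp_stratified.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(anova = res, stratified = tt)
}

.stageNetwork <- function(cfg, out_dir) {
  cl <- .readCleaned(cfg, out_dir)
  args <- cfg$network %||% list()
  args$x <- cl$x
  net <- do.call(buildNetwork, args)
  kt <- kmeTable(net)
  write.table(kt, file.path(out_dir, "module_labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(module = rownames(eigenproteins(net)),
                         eigenproteins(net), check.names = FALSE),
              file.path(out_dir, "eigenproteins.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(protein = rownames(net@kme), net@kme,
                         check.names = FALSE),
              file.path(out_dir, "kme_matrix.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  saveRDS(net, file.path(out_dir, "network.rds"))
  net
}

.stageModules <- function(cfg, out_dir) {
  net <- readRDS(file.path(out_dir, "network.rds"))
  cl <- .readCleaned(cfg, out_dir)
  traits <- cl$samples[, intersect(c("cerad", "braak", "lb_score", "age"),
                                   colnames(cl$samples)), drop = FALSE]
  mt <- moduleTraitCorrelation(eigenproteins(net), traits,
                               diagnosis = cl$samples$diagnosis)
  write.table(mt, file.path(out_dir, "module_traits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  hubs <- callHubs(moduleLabels(net), net@kme,
                   connectivity = rowSums(adjacencyMatrix(net)) - 1)
  write.table(hubs, file.path(out_dir, "hubs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  enr <- NULL
  gmt_path <- cfg$paths$gene_sets %||% file.path(out_dir, "markers.gmt")
  if (file.exists(gmt_path)) {
    enr <- fisherEnrichment(moduleLabels(net), readGMT(gmt_path))
    write.table(enr, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(traits = mt, hubs = hubs, enrichment = enr)
}

.stagePreserve <- function(cfg, out_dir, seed) {
  net <- readRDS(file.path(out_dir, "network.rds"))
  cl <- .readCleaned(cfg, out_dir)
  pcfg <- cfg$preservation %||% list()
  truth_path <- file.path(out_dir, "truth.json")
  if (!is.null(pcfg$test_matrix)) {
    test_x <- readAbundance(pcfg$test_matrix)
    test_samples <- readSampleTable(pcfg$test_samples)
  } else if (file.exists(truth_path)) {
    # replication cohort drawn from the planted truth
    se <- .stageReplication(out_dir, seed)
    test_x <- assay(se, "log2")[, !colData(se)$is_gis]
    test_samples <- as.data.frame(colData(se))[!colData(se)$is_gis, ]
  } else stop("preserve stage needs a test cohort (test_matrix) or a ",
              "simulated truth")
  pres <- modulePreservation(cl$x, moduleLabels(net), test_x,
                             beta = net@config$beta,
                             n_perm = pcfg$n_perm %||% 200L,
                             seed = .subSeed(seed, 7L))
  write.table(pres, file.path(out_dir, "preservation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  syn <- syntheticEigenproteins(moduleLabels(net), net@kme, test_x,
                                test_samples$diagnosis)
  write.table(syn, file.path(out_dir, "synthetic_eigenproteins.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  list(preservation = pres, synthetic = syn)
}

.stageReplication <- function(out_dir, seed) {
  tr <- jsonlite::read_json(file.path(out_dir, "truth.json"),
                            simplifyVector = TRUE)
  # rebuild the SimTruth from the serialised artifact
  cfg <- do.call(simConfig, .sanitizeSimArgs(tr$config))
  ge <- cfg$group_effects
  ms <- as.matrix(tr$module_scores)
  rownames(ms) <- rownames(ge)
  truth <- new("SimTruth",
               membership = unlist(tr$membership),
               moduleScores = ms,
               loadings = unlist(tr$loadings),
               bottleneckId = tr$bottleneck_id,
               bottleneckWeights = unlist(tr$bottleneck_weights),
               groupEffects = ge,
               traitTable = as.data.frame(tr$trait_table),
               config = unclass(cfg))
  simulateReplication(truth, seed = .subSeed(seed, 5L))
}

.stageBottleneck <- function(cfg, out_dir) {
  net <- readRDS(file.path(out_dir, "network.rds"))
  bcfg <- cfg$bottleneck %||% list()
  module_set <- bcfg$module_set %||% head(sort(unique(
    moduleLabels(net)[moduleLabels(net) > 0L])), 4L)
  source_module <- bcfg$source_module %||% module_set[1L]
  res <- bottleneckAnalysis(net, module_set, source_module,
                            path_mode = bcfg$path_mode %||% "unweighted",
                            normalized = bcfg$normalized %||% TRUE)
  write.table(res, file.path(out_dir, "bottleneck_ranks.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  graph <- thresholdEdges(tomSubgraph(tomMatrix(net), moduleLabels(net),
                                      module_set))
  writeEdgeList(graph, file.path(out_dir, "bottleneck_edges.tsv"))
  writeGraphML(graph, file.path(out_dir, "bottleneck_graph.graphml"))
  res
}
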