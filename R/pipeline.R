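## End-to-end pipeline: simulate -> map introgressions -> phenotype
## indices -> differential expression -> overlap, with a reproducibility
## manifest.

.pipelineDefaults <- function() {
  list(simulate = list(genome = genomeSpec(), mosaic = mosaicConfig(),
                       divergence = divergenceModel(),
                       expression = expressionDesign(),
                       treatment = saltTreatment(),
                       lines = defaultPhenoPanel(),
                       nReplicates = 3L, noiseSd = 0.08),
       map = mapperConfig(),
       phenotype = list(checkLine = "OLESA"),
       dge = dgeConfig(),
       overlap = list())
}

#' Pipeline configuration
#'
#' Stage-keyed parameter groups with the module defaults; unknown stage or
#' parameter names are rejected.
#'
#' @param ... named stage overrides, e.g.
#'   `simulate = list(noiseSd = 0.1)` or `map = mapperConfig(threshold = 8)`.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(...) {
  cfg <- .pipelineDefaults()
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown pipeline stage(s): ", paste(bad, collapse = ", "))
  for (st in names(over)) {
    o <- over[[st]]
    if (inherits(o, c("MapperConfig", "DGEConfig"))) { cfg[[st]] <- o; next }
    badKey <- setdiff(names(o), names(cfg[[st]]))
    if (length(badKey))
      stop(sprintf("unknown key(s) in stage '%s': %s", st,
                   paste(badKey, collapse = ", ")))
    cfg[[st]][names(o)] <- o
  }
  structure(cfg, class = "PipelineConfig")
}

#' Run the full pipeline
#'
#' Executes simulate, map-introgressions, phenotype, dge and overlap in
#' order, writing each stage's artifacts under `outdir` and a
#' `manifest.json` recording the package version, seed, completed stages
#' and md5 digests of every output. Reruns with the same configuration and
#' seed reproduce identical artifacts. Any stage failure aborts with a
#' stage-named error.
#'
#' @param config a [pipelineConfig()].
#' @param outdir output directory (created if needed).
#' @param seed integer master seed; per-stage seeds are derived from it.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config = pipelineConfig(), outdir, seed = 1L) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(outdir, f)
  stages <- character()
  runStage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    stages <<- c(stages, name)
    res
  }

  sim <- runStage("simulate", function() {
    sc <- config$simulate
    truth <- simulateTruthLine(sc$genome, sc$mosaic, seed = .stageSeed(seed, 1L))
    prof <- simulateVariantProfiles(truth$annotation, truth$labels,
                                    sc$divergence, seed = .stageSeed(seed, 2L))
    expr <- simulateExpression(sc$expression, seed = .stageSeed(seed, 3L))
    phen <- simulatePhenotypes(sc$lines, sc$treatment, sc$nReplicates,
                               sc$noiseSd, seed = .stageSeed(seed, 4L))
    writeGff3(truth$annotation, pth("annotation.gff3"))
    writeVariantProfiles(prof, pth("variant_profiles.tsv"))
    writeTruthJson(truth, pth("truth.json"), degTruth = expr$truth)
    counts <- SummarizedExperiment::assay(expr$se, "counts")
    writeCountsTsv(counts, pth("counts.tsv"))
    writeTsv(as.data.frame(SummarizedExperiment::colData(expr$se)),
             pth("samples.tsv"))
    writeTsv(as.data.frame(SummarizedExperiment::rowData(expr$se)),
             pth("gene_lengths.tsv"))
    writeTsv(phen$pheno, pth("phenotypes.tsv"))
    writeTsv(phen$ions, pth("ions.tsv"))
    list(truth = truth, expr = expr, phen = phen)
  })

  runStage("map-introgressions", function() {
    prof <- readVariantProfiles(pth("variant_profiles.tsv"))
    calls <- classifyTranscripts(prof, config$map)
    report <- callBlocks(calls, config$map)
    writeBlocksBed(report, pth("blocks.bed"))
    inv <- do.call(rbind, lapply(seq_along(blocks(report)), function(i)
      data.frame(block_id = blocks(report)$block_id[i],
                 transcript_id = blocks(report)$members[[i]])))
    writeTsv(inv %||% data.frame(block_id = character(0),
                                 transcript_id = character(0)),
             pth("block_genes.tsv"))
    tot <- geneTotals(report)
    jsonlite::write_json(list(perChromosome = tot$perChromosome,
                              totalGenes = tot$totalGenes,
                              dispersed = dispersedTranscripts(report)),
                         pth("introgression_report.json"),
                         auto_unbox = TRUE, digits = NA)
    report
  })

  runStage("phenotype", function() {
    ph <- readTsv(pth("phenotypes.tsv"))
    idx <- toleranceIndexTable(ph, checkLine = config$phenotype$checkLine)
    writeTsv(idx$relative, pth("tolerance_index.tsv"))
    writeTsv(idx$el, pth("electrolyte_leakage.tsv"))
    writeTsv(idx$ses, pth("ses_distribution.tsv"))
    ions <- readTsv(pth("ions.tsv"))
    writeTsv(naKSummary(ions, checkLine = config$phenotype$checkLine),
             pth("na_k_ratio.tsv"))
    idx
  })

  degs <- runStage("dge", function() {
    counts <- readCountsTsv(pth("counts.tsv"))
    meta <- readTsv(pth("samples.tsv"))
    lens <- readTsv(pth("gene_lengths.tsv"))
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = counts),
      colData = S4Vectors::DataFrame(meta, row.names = meta$sample_id),
      rowData = S4Vectors::DataFrame(lens))
    out <- lapply(c("IL", "parent"), function(g) {
      tab <- runDge(se, g, config$dge)
      writeTsv(tab, pth(sprintf("deg_%s_salt_vs_control.tsv", g)))
      tab
    })
    names(out) <- c("IL", "parent")
    out
  })

  runStage("overlap", function() {
    s <- overlapSummary(
      upA = degs$IL$gene_id[degs$IL$call == "up"],
      downA = degs$IL$gene_id[degs$IL$call == "down"],
      upB = degs$parent$gene_id[degs$parent$call == "up"],
      downB = degs$parent$gene_id[degs$parent$call == "down"])
    jsonlite::write_json(unclass(s), pth("overlap_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    writeTsv(data.frame(n_A = s$nA, n_B = s$nB, common_up = s$commonUp,
                        common_down = s$commonDown, union_size = s$unionSize,
                        pct_common = round(s$pctCommon, 1)),
             pth("overlap_summary.tsv"))
    s
  })

  outputs <- setdiff(list.files(outdir), "manifest.json")
  manifest <- list(
    package = "introgmap",
    version = as.character(utils::packageVersion("introgmap")),
    seed = seed,
    stages = stages,
    outputs = as.list(tools::md5sum(file.path(outdir, sort(outputs)))))
  names(manifest$outputs) <- sort(outputs)
  jsonlite::write_json(manifest, pth("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
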