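#' @include AllClasses.R simulate.R targetCalling.R compendium.R enrichment.R
#' @include nullModel.R similarity.R diversity.R io.R
NULL

#' Run the full synthetic annotation pipeline
#'
#' Executes the seven stages end to end on synthetic data: simulate the gene
#' space and compendium with planted structure, generate binding signals and
#' call targets TIP-style, merge the called (high-throughput) edges with a
#' low-throughput evidence subset, annotate TFs with target functions,
#' run the randomized-compendium null model, build the TF-pair similarity
#' and discordance tables, and compute diversity profiles with the
#' pleiotropy-regulator association. Every stage writes its artifact into
#' \code{outDir} and a \code{manifest.json} records the package version,
#' seed, thresholds and an md5 digest per output, so a rerun with the same
#' seed is byte-identical.
#'
#' @param config a [SimulationConfig-class]; its seed drives all randomness.
#' @param outDir output directory (created if needed).
#' @param tgFdr FDR for target calling (default 0.01).
#' @param associationFdr FDR for TF-function associations (default 0.05).
#' @param neighborFdr FDR for TF-neighbor detection (default 0.01).
#' @param pFlavor p-value flavor for the null model ("gtest" or "fisher").
#' @param cutoffs p-value cutoffs for the empirical FDR table.
#' @param lowThroughputFrac fraction of each TF's true target set replayed
#'   as low-throughput literature evidence (default 0.2).
#' @return invisibly, a list with the in-memory stage results and
#'   \code{manifest}.
#' @export
runPipeline <- function(config, outDir,
                        tgFdr = 0.01, associationFdr = 0.05,
                        neighborFdr = 0.01, pFlavor = "gtest",
                        cutoffs = c(0.001, 0.0001),
                        lowThroughputFrac = 0.2) {
  stopifnot(is(config, "SimulationConfig"))
  for (thr in c(tgFdr, associationFdr, neighborFdr))
    if (thr <= 0 || thr >= 1) stop("FDR thresholds must lie in (0, 1)")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stageFiles <- list()
  runStage <- function(name, code) {
    message("[", name, "] seed=", config@seed,
            " tgFdr=", tgFdr, " associationFdr=", associationFdr)
    tryCatch(code, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # 1. simulate
  sim <- runStage("simulate", {
    sp <- generateGeneSpace(config)
    cmp <- generateCompendium(config, sp$genes, sp$collections)
    writeGeneTable(sp$genes, file.path(outDir, "gene_table.tsv"))
    for (nm in names(sp$collections))
      writeGMT(geneSets(sp$collections[[nm]]),
               file.path(outDir, paste0("collection_", nm, ".gmt")))
    writeReportTSV(cmp$truth, file.path(outDir, "planted_truth.tsv"))
    c(sp, cmp)
  })
  stageFiles$simulate <- c("gene_table.tsv", "planted_truth.tsv",
                           paste0("collection_", names(sim$collections),
                                  ".gmt"))

  # 2. call targets from binding signals
  called <- runStage("call-targets", {
    trueSets <- tgSets(sim$compendium)
    edges <- lapply(sim$tfs, function(tf) {
      bp <- generateBindingSignals(config, tf, sim$genes$gene_id,
                                   trueSets[[tf]] %||% character())
      res <- tipTargets(bp, fdrThreshold = tgFdr)
      if (!any(res$called)) return(NULL)
      data.frame(tf = tf, tg = res$gene_id[res$called],
                 evidence = "other_high_throughput",
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, edges)
  })
  calledCmp <- Compendium(called)
  writeCompendiumGMT(calledCmp, file.path(outDir, "called_targets.gmt"))
  stageFiles$call_targets <- "called_targets.gmt"

  # 3. merge with low-throughput evidence
  merged <- runStage("merge", {
    truthEdges <- edgeTable(sim$compendium)
    lowIdx <- withSubstream(config@seed, "low_throughput",
                            sample(nrow(truthEdges),
                                   round(lowThroughputFrac *
                                         nrow(truthEdges))))
    low <- truthEdges[sort(lowIdx), , drop = FALSE]
    low$evidence <- "low_throughput"
    mergeSources(list(edgeTable(calledCmp), low))
  })
  writeCompendiumGMT(merged, file.path(outDir, "compendium.gmt"))
  stageFiles$merge <- "compendium.gmt"

  # 4. annotate target functions
  assoc <- runStage("annotate", {
    annotateTFs(merged, sim$collections, sim$genes, fdr = associationFdr)
  })
  writeReportTSV(assoc, file.path(outDir, "associations.tsv"))
  stageFiles$annotate <- "associations.tsv"

  # 5. randomized-compendium null model
  null <- runStage("nullfdr", {
    nullModelAnalysis(merged, sim$collections, sim$genes,
                      seed = substreamSeed(config@seed, "null_model"),
                      pFlavor = pFlavor, cutoffs = cutoffs,
                      fdr = associationFdr)
  })
  nullOut <- cbind(null$fdrTable,
                   nUpper = null$pairing$nUpper,
                   nLower = null$pairing$nLower,
                   nTied = null$pairing$nTied,
                   trueEstimate = null$trueEstimate)
  writeReportTSV(nullOut, file.path(outDir, "null_fdr.tsv"))
  stageFiles$nullfdr <- "null_fdr.tsv"

  # 6. similarity and discordance
  simOut <- runStage("similarity", {
    pairs <- tfPairTable(merged, assoc, sim$collections, sim$genes,
                         neighborFdr = neighborFdr,
                         targetFunFdr = associationFdr)
    disc <- discordanceAnalysis(pairs)
    writeReportTSV(pairs, file.path(outDir, "tf_pairs.tsv"))
    writeReportTSV(disc$strata, file.path(outDir, "discordance.tsv"))
    list(pairs = pairs, discordance = disc)
  })
  stageFiles$similarity <- c("tf_pairs.tsv", "discordance.tsv")

  # 7. diversity and pleiotropy
  div <- runStage("diversity", {
    prof <- diversityProfiles(merged, assoc, sim$collections, sim$genes)
    assocTest <- tryCatch(
      pleiotropyAssociation(prof, "pi_TargetFun", "pi_Reg",
                            covariates = "n_TG"),
      error = function(e) NULL)
    writeReportTSV(prof, file.path(outDir, "diversity.tsv"))
    if (!is.null(assocTest))
      writeReportTSV(data.frame(response = "pi_TargetFun",
                                predictor = "pi_Reg", covariates = "n_TG",
                                estimate = assocTest$estimate,
                                t = assocTest$t, p = assocTest$p,
                                spearman_rho = assocTest$spearmanRho,
                                spearman_p = assocTest$spearmanP,
                                n = assocTest$n),
                     file.path(outDir, "pleiotropy.tsv"))
    list(profiles = prof, association = assocTest)
  })
  stageFiles$diversity <- c("diversity.tsv",
                            if (!is.null(div$association)) "pleiotropy.tsv")

  manifest <- list(
    package = "tfanno",
    version = as.character(utils::packageVersion("tfanno")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config@seed,
    thresholds = list(tg_fdr = tgFdr, association_fdr = associationFdr,
                      neighbor_fdr = neighborFdr),
    p_flavor = pFlavor,
    stages = lapply(stageFiles, function(files)
      as.list(tools::md5sum(file.path(outDir, files)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(sim = sim, called = calledCmp, merged = merged,
                 associations = assoc, null = null, similarity = simOut,
                 diversity = div, manifest = manifest))
}
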