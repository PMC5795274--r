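test_that("fixed seed gives bit-identical gene space, compendium and signals", {
  cfg <- smallConfig(seed = 7)
  a <- generateGeneSpace(cfg)
  b <- generateGeneSpace(cfg)
  expect_identical(a, b)
  ca <- generateCompendium(cfg, a$genes, a$collections)
  cb <- generateCompendium(cfg, b$genes, b$collections)
  expect_identical(edgeTable(ca$compendium), edgeTable(cb$compendium))
  sa <- generateBindingSignals(cfg, "T", a$genes$gene_id[1:50],
                               a$genes$gene_id[1:5])
  sb <- generateBindingSignals(cfg, "T", a$genes$gene_id[1:50],
                               a$genes$gene_id[1:5])
  expect_identical(signalMatrix(sa), signalMatrix(sb))
})

test_that("zero terms yields empty collections but a full gene table", {
  cfg <- simulationConfig(seed = 2, nGenes = 100,
                          sources = data.frame(name = "S", type = "curated",
                                               nTerms = 0L, minSize = 3L,
                                               maxSize = 10L))
  sp <- generateGeneSpace(cfg)
  expect_equal(nrow(sp$genes), 100L)
  expect_length(geneSets(sp$collections$S), 0L)
  expect_false(any(sp$genes$S))
})

test_that("membership flags agree with the emitted sets", {
  sp <- generateGeneSpace(smallConfig(seed = 5, nGenes = 200L))
  for (nm in names(sp$collections)) {
    annotated <- sort(unique(unlist(geneSets(sp$collections[[nm]]))))
    expect_setequal(sp$genes$gene_id[sp$genes[[nm]]], annotated)
  }
  # union of annotated genes equals genes with >= 1 membership flag
  flagged <- sp$genes$gene_id[Reduce(`|`, sp$genes[names(sp$collections)])]
  union <- unique(unlist(lapply(sp$collections,
                                function(cl) unlist(geneSets(cl)))))
  expect_setequal(flagged, union)
})

test_that("curated sources annotate only coding genes", {
  sp <- generateGeneSpace(smallConfig(seed = 9))
  coding <- sp$genes$gene_id[sp$genes$is_coding]
  for (nm in names(sp$collections)) {
    cl <- sp$collections[[nm]]
    if (collectionType(cl) == "curated")
      expect_true(all(unlist(geneSets(cl)) %in% coding))
    expect_true(all(unlist(geneSets(cl)) %in% sp$genes$gene_id))
  }
})

test_that("degenerate rates make the TG set exactly the planted term", {
  sc <- smallScenario(seed = 3, targetRateInTerm = 1, backgroundRate = 0,
                      nPlantedLinks = 1L)
  expect_equal(nrow(sc$truth), 1L)
  tf <- sc$truth$tf[1]
  members <- geneSets(sc$collections[[sc$truth$source[1]]])[[sc$truth$term[1]]]
  expect_setequal(tgSets(sc$compendium)[[tf]], members)
  # all other TFs have no targets at all
  expect_setequal(tfIds(sc$compendium), tf)
})

test_that("equal rates leave approximately uniform enrichment p-values", {
  cfg <- simulationConfig(seed = 8, targetRateInTerm = 0.2,
                          backgroundRate = 0.2)
  sp <- generateGeneSpace(cfg)
  cmp <- generateCompendium(cfg, sp$genes, sp$collections)
  a <- annotateTFs(cmp$compendium, sp$collections, sp$genes)
  p <- a$p_gtest[!is.na(a$p_gtest)]
  p500 <- withr::with_seed(1, sample(p, 500))
  ks <- suppressWarnings(stats::ks.test(p500, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
  expect_gt(mean(p500), 0.4)
  expect_lt(mean(p500), 0.6)
  expect_equal(sum(a$significant), 0)
})

test_that("binding peaks land on the TSS bin and lift target row sums", {
  cfg <- simulationConfig(seed = 4, noiseSd = 0)
  genes <- sprintf("g%04d", 1:20)
  bp <- generateBindingSignals(cfg, "T", genes, genes[3])
  m <- signalMatrix(bp)
  expect_equal(ncol(m), 60L)
  expect_equal(unname(which.max(m[3, ])), 31L)      # bin containing the TSS
  expect_true(all(m[-3, ] == 0))
  # zero peak and zero noise -> all-zero matrix
  cfg0 <- simulationConfig(seed = 4, noiseSd = 0, peakHeight = 0)
  expect_true(all(signalMatrix(
    generateBindingSignals(cfg0, "T", genes, genes[3])) == 0))
  # with noise, target rows dominate in total signal
  cfgN <- simulationConfig(seed = 6, nGenes = 1000L)
  ids <- sprintf("g%04d", 1:1000)
  targets <- withr::with_seed(2, sample(ids, 50))
  mN <- signalMatrix(generateBindingSignals(cfgN, "T", ids, targets))
  expect_gt(mean(rowSums(mN[ids %in% targets, ])),
            mean(rowSums(mN[!ids %in% targets, ])))
  expect_true(all(mN >= 0))
})

test_that("generator rejects invalid configurations", {
  expect_error(simulationConfig(nGenes = 20,
                                sources = data.frame(name = "S",
                                                     type = "curated",
                                                     nTerms = 2L,
                                                     minSize = 5L,
                                                     maxSize = 50L)),
               "exceed")
  expect_error(simulationConfig(backgroundRate = 0.5,
                                targetRateInTerm = 0.1))
  expect_error(simulationConfig(windowBp = 6000, binBp = 70), "divisible")
  expect_error(generateBindingSignals(smallConfig(), "T", character(),
                                      character()), "empty")
  expect_error(generateBindingSignals(smallConfig(), "T", "g1", "g1",
                                      windowBp = 300L, binBp = 100L),
               "4 bins")
})

test_that("emitted sets live in the gene space and survive a GMT round trip", {
  sp <- generateGeneSpace(smallConfig(seed = 13))
  path <- withr::local_tempfile(fileext = ".gmt")
  for (nm in names(sp$collections)) {
    sets <- geneSets(sp$collections[[nm]])
    writeGMT(sets, path)
    back <- readGMT(path)
    expect_identical(lapply(back, identity)[names(sets)],
                     lapply(sets, identity))
  }
})
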