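# Shared fixtures: small, fast study configurations built in code.

# Reduced gene space for module-level tests (the full default scenario is
# exercised in the acceptance suite).
smallConfig <- function(seed = 11, nGenes = 600L, nPlantedLinks = 12L,
                        ...) {
  simulationConfig(
    seed = seed, nGenes = nGenes, nTFs = 8L,
    sources = data.frame(
      name = c("OMIM", "GWAS", "Reactome"),
      type = c("curated", "machine", "curated"),
      nTerms = c(8L, 8L, 10L), minSize = 8L, maxSize = 40L,
      stringsAsFactors = FALSE),
    nPlantedLinks = nPlantedLinks, ...)
}

# A gene space + compendium bundle under the small configuration.
smallScenario <- function(seed = 11, ...) {
  cfg <- smallConfig(seed = seed, ...)
  sp <- generateGeneSpace(cfg)
  cmp <- generateCompendium(cfg, sp$genes, sp$collections)
  list(config = cfg, genes = sp$genes, collections = sp$collections,
       compendium = cmp$compendium, truth = cmp$truth, tfs = cmp$tfs)
}

# Planted-vs-recovered keys for association tables.
linkKey <- function(d) paste(d$tf, d$source, d$term, sep = "/")

# Random 2x2 tables with all margins positive.
randomTables <- function(n, maxCell = 30L, seed = 1) {
  withr::with_seed(seed, replicate(n, {
    repeat {
      tab <- c(n11 = sample.int(maxCell, 1), n10 = sample.int(maxCell, 1),
               n01 = sample.int(maxCell, 1), n00 = sample.int(maxCell, 1))
      m <- matrix(tab, 2, byrow = TRUE)
      if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(tab)
    }
  }, simplify = FALSE))
}

# Expand a 2x2 table into the two 0/1 indicator vectors it summarises.
expandIndicators <- function(tab) {
  list(x = rep(c(1, 1, 0, 0), tab), y = rep(c(1, 0, 1, 0), tab))
}
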