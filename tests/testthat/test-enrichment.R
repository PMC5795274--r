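test_that("gene universes follow the coding / literature-rich rules", {
  genes <- data.frame(
    gene_id = sprintf("g%02d", 1:10),
    is_coding = c(rep(TRUE, 6), rep(FALSE, 4)),
    OMIM = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE,
             FALSE),
    GWAS = rep(FALSE, 10))
  attr(genes, "sourceTypes") <- c(OMIM = "curated", GWAS = "machine")
  expect_length(buildUniverse(genes, "coding"), 6L)
  lr <- buildUniverse(genes, "literature_rich")
  expect_length(lr, 3L)                      # 3 coding genes annotated
  expect_false("g07" %in% lr)                # annotated non-coding purged
  expect_true(all(lr %in% buildUniverse(genes, "coding")))
  expect_error(buildUniverse(genes[genes$is_coding == FALSE, ], "coding"),
               "empty")
})

test_that("contingency tables are restricted to the universe", {
  expect_equal(buildContingency(c("a", "b"), c("b", "c"),
                                c("a", "b", "c", "d")),
               c(n11 = 1L, n10 = 1L, n01 = 1L, n00 = 1L))
  # enlarging the universe only grows n00
  expect_equal(buildContingency(c("a", "b"), c("b", "c"),
                                c("a", "b", "c", "d", "e", "f")),
               c(n11 = 1L, n10 = 1L, n01 = 1L, n00 = 3L))
  expect_equal(buildContingency(c("x", "y"), c("b", "c"),
                                c("a", "b", "c", "d"))[["n11"]], 0L)
  expect_equal(sum(buildContingency(letters[1:3], letters[2:5],
                                    letters[1:10])), 10L)
})

test_that("Fisher's exact test matches the hypergeometric oracle", {
  # printed Table 2 low-TG stratum p-value
  expect_equal(fisherTest(c(n11 = 117, n10 = 212, n01 = 11704,
                            n00 = 30669), "greater"), 0.001, tolerance = 0.05)
  # hypergeometric enumeration at the point of independence: P(X >= 1) = 5/6
  expect_equal(fisherTest(c(n11 = 1, n10 = 1, n01 = 1, n00 = 1), "greater"),
               5 / 6)
  # closed form: perfect split, P = 1 / C(10, 5)
  expect_equal(fisherTest(c(n11 = 5, n10 = 0, n01 = 0, n00 = 5), "greater"),
               1 / choose(10, 5))
  # agrees with stats::fisher.test one-sided on random tables
  for (tab in randomTables(25, seed = 3)) {
    m <- matrix(tab, 2, byrow = TRUE)
    expect_equal(fisherTest(tab, "greater"),
                 stats::fisher.test(m, alternative = "greater")$p.value,
                 tolerance = 1e-12)
    expect_equal(fisherTest(tab, "two.sided"),
                 stats::fisher.test(m)$p.value, tolerance = 1e-12)
  }
})

test_that("G-test follows 2 sum O ln(O/E) with a 1-df chi-square null", {
  g <- gTest(c(n11 = 20, n10 = 10, n01 = 10, n00 = 20))
  expect_equal(g$G, 6.80, tolerance = 1e-2)
  expect_equal(g$p, 0.0091, tolerance = 1e-2)
  ind <- gTest(c(n11 = 10, n10 = 20, n01 = 10, n00 = 20))
  expect_equal(ind$G, 0, tolerance = 1e-12)
  expect_equal(ind$p, 1)
  expect_error(gTest(c(n11 = 0, n10 = 0, n01 = 3, n00 = 5)), "zero margin")
  # a fast approximation to Fisher's exact test at large cell counts:
  # the bulk of tables agree within 2x, none stray beyond 3x
  tabs <- withr::with_seed(4, replicate(100, c(
    n11 = sample(20:60, 1), n10 = sample(20:60, 1),
    n01 = sample(20:60, 1), n00 = sample(20:60, 1)), simplify = FALSE))
  ratio <- vapply(tabs, function(tab)
    gTest(tab)$p / fisherTest(tab, "two.sided"), numeric(1))
  expect_gte(mean(ratio < 2 & ratio > 0.5), 0.9)
  expect_true(all(ratio < 3 & ratio > 1 / 3))
})

test_that("phi equals the Pearson correlation of the indicator vectors", {
  expect_equal(phiCoefficient(c(n11 = 7, n10 = 0, n01 = 0, n00 = 7)), 1)
  expect_equal(phiCoefficient(c(n11 = 1, n10 = 1, n01 = 1, n00 = 1)), 0)
  expect_equal(phiCoefficient(c(n11 = 5866, n10 = 5339, n01 = 6568,
                                n00 = 55763)), 0.401, tolerance = 1e-3)
  for (tab in randomTables(1000, maxCell = 30L, seed = 7)) {
    iv <- expandIndicators(tab)
    expect_lt(abs(phiCoefficient(tab) - stats::cor(iv$x, iv$y)), 1e-12)
  }
  # symmetry: swapping the two variables (n10 <-> n01) leaves phi unchanged
  for (tab in randomTables(50, seed = 8)) {
    swapped <- tab[c("n11", "n01", "n10", "n00")]
    names(swapped) <- c("n11", "n10", "n01", "n00")
    expect_equal(phiCoefficient(tab), phiCoefficient(swapped))
  }
  expect_error(phiCoefficient(c(n11 = 0, n10 = 0, n01 = 2, n00 = 2)),
               "zero margin")
})

test_that("odds ratio applies the pseudo-count only at zero cells", {
  o <- oddsRatio(c(n11 = 6, n10 = 3, n01 = 2, n00 = 4))
  expect_equal(o$or, 4)
  expect_equal(o$log2or, 2)
  z <- oddsRatio(c(n11 = 5, n10 = 0, n01 = 2, n00 = 4))
  expect_true(is.infinite(z$or))
  expect_equal(z$log2or, log2((5.5 * 4.5) / (0.5 * 2.5)))
})

test_that("BH q-values follow the step-up procedure", {
  expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bhFDR(rep(0.2, 5)), rep(0.2, 5))
  p <- withr::with_seed(2, stats::runif(50))
  q <- bhFDR(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(bhFDR(c(0.5, 1.2)), "0, 1")
})

test_that("universe inflation strictly increases the odds ratio", {
  for (tab in randomTables(100, seed = 10)) {
    if (tab[["n11"]] == 0 || tab[["n10"]] == 0 || tab[["n01"]] == 0) next
    grown <- tab + c(0, 0, 0, 25)
    expect_gt(oddsRatio(grown)$or, oddsRatio(tab)$or)
  }
})

test_that("a single strongly planted link is the top association", {
  sc <- smallScenario(seed = 23, nPlantedLinks = 1L,
                      targetRateInTerm = 0.9, backgroundRate = 0.02)
  a <- annotateTFs(sc$compendium, sc$collections, sc$genes)
  top <- a[which.min(a$p_greater), ]
  expect_equal(linkKey(top), linkKey(sc$truth))
})

test_that("annotation respects the universe policy and label equivariance", {
  sc <- smallScenario(seed = 14)
  a <- annotateTFs(sc$compendium, sc$collections, sc$genes)
  # q-values computed within each source
  for (s in unique(a$source))
    expect_equal(a$q[a$source == s],
                 bhFDR(a$p_two_sided[a$source == s]))
  # every record's table sums to its universe
  lr <- length(buildUniverse(sc$genes, "literature_rich"))
  co <- length(buildUniverse(sc$genes, "coding"))
  tot <- a$n11 + a$n10 + a$n01 + a$n00
  expect_true(all(tot[a$source == "GWAS"] == co))
  expect_true(all(tot[a$source != "GWAS"] == lr))
  # consistent relabeling of genes leaves all p-values unchanged
  map <- stats::setNames(sprintf("X%06d", seq_len(nrow(sc$genes))),
                         sc$genes$gene_id)
  genes2 <- sc$genes
  genes2$gene_id <- unname(map[genes2$gene_id])
  attr(genes2, "sourceTypes") <- attr(sc$genes, "sourceTypes")
  coll2 <- lapply(sc$collections, function(cl)
    annotationCollection(collectionName(cl), collectionType(cl),
                         lapply(geneSets(cl), function(s) unname(map[s]))))
  e2 <- edgeTable(sc$compendium)
  e2$tg <- unname(map[e2$tg])
  e2$tf <- unname(map[e2$tf])
  a2 <- annotateTFs(Compendium(e2), coll2, genes2)
  expect_equal(sort(a2$p_two_sided), sort(a$p_two_sided))
  expect_error(annotateTFs(sc$compendium, sc$collections, sc$genes,
                           universePolicy = c(curated = "literature_rich")),
               "no entry")
})

test_that("planted links are recovered with high precision and recall", {
  sc <- smallScenario(seed = 51)
  a <- annotateTFs(sc$compendium, sc$collections, sc$genes, fdr = 0.05)
  sig <- a[a$significant & a$direction == "positive", ]
  expect_gte(mean(linkKey(sc$truth) %in% linkKey(sig)), 0.8)
  expect_gte(mean(linkKey(sig) %in% linkKey(sc$truth)), 0.9)
})

test_that("association p-values rank true links with high AUC", {
  sc <- smallScenario(seed = 77)
  a <- annotateTFs(sc$compendium, sc$collections, sc$genes)
  lab <- linkKey(a) %in% linkKey(sc$truth)
  expect_gt(rocAuc(-log10(a$p_greater + 1e-300), lab), 0.9)
  # with planting disabled the AUC collapses to chance; many planted
  # labels keep the Mann-Whitney sampling error well inside the band
  cfgN <- simulationConfig(seed = 78, targetRateInTerm = 0.05,
                           backgroundRate = 0.05, nPlantedLinks = 200L)
  spN <- generateGeneSpace(cfgN)
  cmN <- generateCompendium(cfgN, spN$genes, spN$collections)
  aN <- annotateTFs(cmN$compendium, spN$collections, spN$genes)
  labN <- linkKey(aN) %in% linkKey(cmN$truth)
  expect_equal(rocAuc(-log10(aN$p_greater + 1e-300), labN), 0.5,
               tolerance = 0.05)
  expect_error(rocAuc(1:3, c(TRUE, TRUE, TRUE)), "both")
})

test_that("terms with no universe overlap are dropped", {
  genes <- data.frame(gene_id = c("a", "b", "c", "d"),
                      is_coding = c(TRUE, TRUE, TRUE, FALSE),
                      S = c(TRUE, TRUE, FALSE, TRUE))
  attr(genes, "sourceTypes") <- c(S = "curated")
  coll <- list(S = annotationCollection("S", "curated",
    list(T1 = c("a", "b", "d"), T2 = "d")))  # T2 only non-coding
  cmp <- Compendium(data.frame(tf = "a", tg = c("a", "b")))
  a <- annotateTFs(cmp, coll, genes, minTermSize = 1L)
  expect_true(all(a$term == "T1"))
})
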