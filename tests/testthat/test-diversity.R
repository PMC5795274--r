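test_that("uniqueness follows the inverse accumulated squared phi", {
  expect_equal(unname(uniqueness(diag(3))), c(1, 1, 1))
  allOne <- matrix(1, 3, 3)
  expect_equal(unname(uniqueness(allOne)), rep(1 / 3, 3))
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- 0.5
  expect_equal(unname(uniqueness(m)), c(0.8, 0.8, 1.0))
  expect_error(uniqueness(matrix(c(2, 0, 0, 1), 2)), "unit diagonal")
  # undefined entries contribute nothing
  mNA <- diag(2); mNA[1, 2] <- mNA[2, 1] <- NA
  expect_equal(unname(uniqueness(mNA)), c(1, 1))
  expect_true(all(uniqueness(m) <= 1 & uniqueness(m) > 0))
})

test_that("diversity is the uniqueness-weighted effective number", {
  u <- c(A = 1, B = 1, C = 1)
  expect_equal(diversityIndex(c("A", "B", "C"), u), 3)
  # k perfectly redundant regulators collapse to one effective regulator
  sets <- list(A = letters[1:5], B = letters[1:5], C = letters[1:5])
  uRed <- uniqueness(phiMatrix(sets, letters))
  expect_equal(diversityIndex(c("A", "B", "C"), uRed), 1)
  expect_error(diversityIndex("Z", u), "unknown")
  expect_equal(diversityIndex(character(), u), 0)
})

test_that("phi matrix agrees with per-pair phi and the cor oracle", {
  universe <- sprintf("g%02d", 1:30)
  sets <- withr::with_seed(5, list(
    A = sample(universe, 10), B = sample(universe, 15),
    C = sample(universe, 8)))
  pm <- phiMatrix(sets, universe)
  expect_equal(pm, t(pm))
  expect_equal(unname(diag(pm)), rep(1, 3))
  M <- vapply(sets, function(s) as.numeric(universe %in% s),
              numeric(30))
  expect_equal(unname(pm), unname(stats::cor(M)), tolerance = 1e-12)
  expect_equal(pm["A", "B"],
               phiCoefficient(buildContingency(sets$A, sets$B, universe)))
})

test_that("pi is monotone and invariant to duplicating a regulator", {
  universe <- sprintf("g%02d", 1:40)
  sets <- withr::with_seed(9, lapply(stats::setNames(1:5,
    paste0("T", 1:5)), function(i) sample(universe, 12)))
  u <- uniqueness(phiMatrix(sets, universe))
  piBase <- diversityIndex(names(sets)[1:3], u)
  expect_gte(diversityIndex(names(sets)[1:4], u), piBase)
  # pairwise-independent regulators built from orthogonal bits of a
  # 16-element universe: off-diagonal phi is exactly 0
  u16 <- sprintf("u%02d", 1:16)
  bit <- function(b) u16[bitwAnd(0:15, b) > 0]
  ortho <- list(A = bit(1L), B = bit(2L), C = bit(4L))
  uO <- uniqueness(phiMatrix(ortho, u16))
  expect_equal(unname(uO), rep(1, 3))
  # replace C by two perfect copies: pi unchanged
  ortho2 <- c(ortho, list(Cb = ortho$C))
  uO2 <- uniqueness(phiMatrix(ortho2, u16))
  expect_equal(diversityIndex(c("A", "B", "C", "Cb"), uO2),
               diversityIndex(c("A", "B", "C"), uO), tolerance = 1e-9)
})

test_that("diversity profiles satisfy the effective-number bounds", {
  sc <- smallScenario(seed = 61)
  a <- annotateTFs(sc$compendium, sc$collections, sc$genes)
  prof <- diversityProfiles(sc$compendium, a, sc$collections, sc$genes)
  expect_equal(nrow(prof), length(tfIds(sc$compendium)))
  expect_true(all(prof$pi_TargetFun <= prof$n_TargetFun + 1e-9))
  expect_true(all(prof$pi_Reg <= prof$n_Reg + 1e-9))
  expect_true(all(prof$pi_KnownFun <= prof$n_KnownFun + 1e-9))
  expect_true(all((prof$n_TargetFun == 0) == (prof$pi_TargetFun == 0)))
  # per-source diversities sum to the total
  srcPi <- rowSums(prof[, grepl("^pi_TargetFun_", names(prof))])
  expect_equal(srcPi, prof$pi_TargetFun, ignore_attr = TRUE)
  rd <- regulatorDiversity(sc$compendium,
                           buildUniverse(sc$genes, "coding"))
  expect_true(all(rd$pi_Reg <= rd$n_Reg + 1e-9))
  expect_true(all(rd$pi_Reg > 0))
})

test_that("pleiotropy association recovers a generative dependence", {
  # function counts constructed to grow with regulator counts
  d <- withr::with_seed(13, {
    n <- 80
    reg <- stats::rpois(n, 8) + 1
    data.frame(reg = reg,
               fun = 0.5 * reg + stats::rnorm(n, sd = 1),
               ntg = stats::rpois(n, 50))
  })
  fit <- pleiotropyAssociation(d, "fun", "reg", covariates = "ntg")
  expect_gt(fit$estimate, 0)
  expect_lt(fit$p, 0.01)
  # a perfect fit is essentially certain
  d$exact <- d$reg
  expect_lt(suppressWarnings(pleiotropyAssociation(d, "exact", "reg"))$p,
            1e-12)
  # decoupled predictor: p approximately uniform across replicates
  ps <- withr::with_seed(17, vapply(1:1000, function(i) {
    dd <- data.frame(y = stats::rnorm(50), x = stats::rnorm(50))
    pleiotropyAssociation(dd, "y", "x")$p
  }, numeric(1)))
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.001)
  expect_error(pleiotropyAssociation(d[1:5, ], "fun", "reg"), "at least 10")
  d$dup <- d$reg
  expect_error(pleiotropyAssociation(d, "fun", "reg", covariates = "dup"),
               "collinear")
})

test_that("regulator diversity predicts planted function diversity", {
  # TFs with more planted terms accumulate more significant target functions
  cfg <- simulationConfig(seed = 71, nTFs = 30L, nPlantedLinks = 60L)
  sp <- generateGeneSpace(cfg)
  cmp <- generateCompendium(cfg, sp$genes, sp$collections)
  a <- annotateTFs(cmp$compendium, sp$collections, sp$genes)
  prof <- diversityProfiles(cmp$compendium, a, sp$collections, sp$genes)
  planted <- table(cmp$truth$tf)
  prof$planted <- as.integer(planted[prof$tf])
  prof$planted[is.na(prof$planted)] <- 0L
  fit <- pleiotropyAssociation(prof, "n_TargetFun", "planted",
                               covariates = "n_TG")
  expect_gt(fit$estimate, 0)
  expect_lt(fit$p, 0.01)
})

test_that("PageRank matches a power-iteration oracle", {
  # complete directed graph on 4 nodes: symmetry forces uniform scores
  full <- expand.grid(tf = paste0("T", 1:4), tg = paste0("T", 1:4),
                      stringsAsFactors = FALSE)
  full <- full[full$tf != full$tg, ]
  pr <- pageRankScores(Compendium(full))
  expect_equal(unname(pr), rep(0.25, 4))
  expect_equal(sum(pr), 1, tolerance = 1e-9)
  # single node
  one <- pageRankScores(Compendium(data.frame(tf = "T1", tg = "T1")))
  expect_equal(unname(one), 1)
  # 5-node chain vs dense power iteration
  chain <- Compendium(data.frame(tf = paste0("T", 1:4),
                                 tg = paste0("T", 2:5)))
  pr5 <- pageRankScores(chain, damping = 0.85)
  g <- tfNetwork(chain)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(A)
  out <- rowSums(A)
  P <- A / ifelse(out == 0, 1, out)
  P[out == 0, ] <- 1 / n                     # dangling nodes teleport
  v <- rep(1 / n, n)
  for (i in 1:500) v <- 0.85 * drop(v %*% P) + 0.15 / n
  expect_equal(unname(pr5[rownames(A)]), unname(v), tolerance = 1e-10)
  # node relabeling leaves the score multiset unchanged
  relab <- Compendium(data.frame(tf = paste0("X", 1:4),
                                 tg = paste0("X", 2:5)))
  expect_equal(sort(unname(pageRankScores(relab))), sort(unname(pr5)),
               tolerance = 1e-12)
  expect_error(pageRankScores(igraph::make_empty_graph(0)), "empty")
})
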