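#' @include AllClasses.R enrichment.R
NULL

#' Randomize a compendium into fake TFs
#'
#' For each real TF, constructs a fake TF with the same number of target
#' genes, sampled uniformly without replacement from the universe. Fake TFs
#' inherit the real TF's identity so real and fake association tests can be
#' paired per (TF, term).
#'
#' @param compendium a [Compendium-class].
#' @param universe character vector of gene ids to sample from (defaults to
#'   the enrichment universe in the higher-level drivers).
#' @param seed integer seed.
#' @return A [Compendium-class] of fake TFs (evidence label
#'   \code{"randomized"}).
#' @export
randomizeCompendium <- function(compendium, universe, seed) {
  sets <- tgSets(compendium)
  ks <- lengths(sets)
  if (any(ks > length(universe)))
    stop("a TF has more targets (", max(ks), ") than the universe (",
         length(universe), ")")
  fake <- withr::with_seed(as.integer(seed), {
    lapply(sets, function(s) sample(universe, length(s)))
  })
  edges <- data.frame(tf = rep(names(fake), lengths(fake)),
                      tg = unlist(fake, use.names = FALSE),
                      evidence = "randomized", stringsAsFactors = FALSE)
  Compendium(edges)
}

#' Pair real and fake association p-values
#'
#' Counts, over the matched (TF, term) grid, how many pairs fall in the
#' upper triangle (p_real < p_fake), the lower triangle (p_real > p_fake),
#' and on the diagonal (tied). Ties -- common with discrete test p-values --
#' contribute to neither triangle, preserving the antisymmetry the
#' true-association estimator assumes.
#'
#' @param pReal,pFake numeric vectors of matched p-values.
#' @return list with nUpper, nLower, nTied, nPairs.
#' @export
trianglePairing <- function(pReal, pFake) {
  stopifnot(length(pReal) == length(pFake))
  ok <- !is.na(pReal) & !is.na(pFake)
  pReal <- pReal[ok]; pFake <- pFake[ok]
  list(nUpper = sum(pReal < pFake), nLower = sum(pReal > pFake),
       nTied = sum(pReal == pFake), nPairs = length(pReal))
}

#' Estimate the number of true associations from a triangle pairing
#'
#' Assuming (1) true associations of real TFs all land in the upper triangle
#' and (2) false associations are distributed equally between the triangles,
#' the number of true associations is nUpper - nLower. A negative estimate
#' is reported as-is with a warning.
#'
#' @param pairing a [trianglePairing()] result.
#' @return the estimated count (can be negative).
#' @examples
#' estimateTrueAssociations(list(nUpper = 237566, nLower = 155801))  # 81765
#' @export
estimateTrueAssociations <- function(pairing) {
  est <- pairing$nUpper - pairing$nLower
  if (est < 0)
    warning("negative true-association estimate (", est,
            "): fake TFs outperform real TFs")
  est
}

#' Empirical FDR at a p-value cutoff
#'
#' The ratio of fake-TF associations passing the cutoff to real-TF
#' associations passing it (0 when no real association passes).
#'
#' @param pReal,pFake numeric p-value vectors (need not be matched).
#' @param cutoff p-value cutoff in (0, 1).
#' @return list with nReal, nFake, fdr.
#' @examples
#' # 999 fake vs 16158 real below cutoff -> FDR 6.18%
#' empiricalFdrAtCutoff(rep(0, 16158), rep(c(0, 1), c(999, 1)), 0.5)$fdr
#' @export
empiricalFdrAtCutoff <- function(pReal, pFake, cutoff) {
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie in (0, 1)")
  nReal <- sum(pReal <= cutoff, na.rm = TRUE)
  nFake <- sum(pFake <= cutoff, na.rm = TRUE)
  list(nReal = nReal, nFake = nFake,
       fdr = if (nReal == 0) 0 else nFake / nReal)
}

#' Randomized-compendium null-model analysis
#'
#' Runs the association analysis on the real compendium and on a randomized
#' (fake-TF) compendium with matched target counts, pairs the p-values per
#' (TF, source, term), and reports the triangle summary, the estimated
#' number of true associations, and the empirical FDR at each requested
#' cutoff.
#'
#' @param compendium a [Compendium-class].
#' @param collections named list of [AnnotationCollection-class].
#' @param genes gene table.
#' @param seed integer seed for the randomization.
#' @param pFlavor which p-value to pair: "gtest" (default) or "fisher"
#'   (one-tailed enrichment).
#' @param cutoffs numeric vector of p-value cutoffs.
#' @param universe sampling universe for the fake TFs; defaults to the
#'   coding universe so real and fake tests share one footing.
#' @param ... passed to [annotateTFs()].
#' @return list with \code{pairing}, \code{trueEstimate}, \code{fdrTable}
#'   (data.frame cutoff, nReal, nFake, fdr), \code{real} and \code{fake}
#'   association tables.
#' @export
nullModelAnalysis <- function(compendium, collections, genes, seed = 1L,
                              pFlavor = c("gtest", "fisher"),
                              cutoffs = c(0.001, 0.0001),
                              universe = buildUniverse(genes, "coding"),
                              ...) {
  pFlavor <- match.arg(pFlavor)
  real <- annotateTFs(compendium, collections, genes, ...)
  fakeCmp <- randomizeCompendium(compendium, universe, seed)
  fake <- annotateTFs(fakeCmp, collections, genes, ...)
  pcol <- if (pFlavor == "gtest") "p_gtest" else "p_greater"
  key <- function(d) paste(d$tf, d$source, d$term, sep = "\r")
  m <- match(key(real), key(fake))
  pReal <- real[[pcol]]
  pFake <- fake[[pcol]][m]
  pairing <- trianglePairing(pReal, pFake)
  fdrTable <- do.call(rbind, lapply(cutoffs, function(ct) {
    r <- empiricalFdrAtCutoff(pReal, pFake, ct)
    data.frame(cutoff = ct, nReal = r$nReal, nFake = r$nFake, fdr = r$fdr)
  }))
  list(pairing = pairing,
       trueEstimate = estimateTrueAssociations(pairing),
       fdrTable = fdrTable, real = real, fake = fake)
}
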