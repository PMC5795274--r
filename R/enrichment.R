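#' @include AllClasses.R utils.R
NULL

#' Build a gene universe
#'
#' The gene universe is the allowed set of genes restricting both a TF's
#' target genes and a term's member genes before association testing; the
#' choice of universe changes both the significance and the direction of
#' associations, so it must match how the annotations were obtained.
#' \code{"coding"} returns all coding genes (conservative background for
#' machine-derived annotations such as GWAS); \code{"literature_rich"}
#' returns coding genes carrying at least one curated-source annotation
#' (conservative background for manually curated catalogues) -- annotated
#' non-coding genes are purged.
#'
#' @param genes gene table from [generateGeneSpace()] or [readGeneTable()]:
#'   gene_id, is_coding, one logical membership column per source, with
#'   attribute \code{sourceTypes}.
#' @param kind "coding", "literature_rich" or "custom".
#' @param custom character vector of gene ids when \code{kind = "custom"}.
#' @return character vector of gene ids with attribute \code{kind}.
#' @export
buildUniverse <- function(genes, kind = c("coding", "literature_rich",
                                          "custom"), custom = NULL) {
  kind <- match.arg(kind)
  u <- switch(kind,
    coding = genes$gene_id[genes$is_coding],
    literature_rich = {
      types <- attr(genes, "sourceTypes")
      curated <- names(types)[types == "curated"]
      curated <- intersect(curated, names(genes))
      if (!length(curated)) stop("gene table has no curated-source columns")
      annotated <- Reduce(`|`, genes[curated])
      genes$gene_id[genes$is_coding & annotated]
    },
    custom = as.character(custom))
  if (!length(u)) stop("empty gene universe")
  structure(u, kind = kind)
}

#' Build a 2x2 contingency table over a universe
#'
#' Both input sets are intersected with the universe first; genes outside
#' the universe are never counted. Cells: n11 = TG and term member, n10 = TG
#' only, n01 = member only, n00 = neither; they sum to |universe|.
#'
#' @param tgSet,termSet character vectors of gene ids.
#' @param universe character vector of allowed gene ids.
#' @return named integer vector c(n11, n10, n01, n00).
#' @examples
#' buildContingency(c("a", "b"), c("b", "c"), c("a", "b", "c", "d"))
#' @export
buildContingency <- function(tgSet, termSet, universe) {
  tg <- unique(intersect(tgSet, universe))
  tm <- unique(intersect(termSet, universe))
  n11 <- length(intersect(tg, tm))
  n10 <- length(tg) - n11
  n01 <- length(tm) - n11
  c(n11 = n11, n10 = n10, n01 = n01,
    n00 = length(unique(universe)) - n11 - n10 - n01)
}

#' Fisher's exact test on a 2x2 table
#'
#' \code{alternative = "greater"} tests for enrichment (odds ratio > 1) via
#' the exact hypergeometric upper tail; \code{"two.sided"} is the standard
#' two-sided exact test.
#'
#' @param table 2x2 counts (named vector n11..n00 or matrix).
#' @param alternative "greater" or "two.sided".
#' @return the p-value.
#' @examples
#' fisherTest(c(n11 = 5, n10 = 0, n01 = 0, n00 = 5))  # 1/choose(10, 5)
#' @export
fisherTest <- function(table, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  tab <- as2x2(table)
  if (alternative == "greater") {
    # P(X >= n11), X ~ Hypergeom(|term|, N - |term|, |TG|)
    stats::phyper(tab["n11"] - 1, tab["n11"] + tab["n01"],
                  tab["n10"] + tab["n00"], tab["n11"] + tab["n10"],
                  lower.tail = FALSE)[[1]]
  } else {
    m <- matrix(tab, nrow = 2, byrow = TRUE)
    stats::fisher.test(m, alternative = "two.sided")$p.value
  }
}

#' Likelihood-ratio (G) test of independence for a 2x2 table
#'
#' G = 2 sum O ln(O / E) with expectations from the margins, compared to a
#' chi-square with one degree of freedom; a fast approximation to Fisher's
#' exact test for large counts.
#'
#' @param table 2x2 counts.
#' @return list with \code{G} and \code{p}.
#' @export
gTest <- function(table) {
  tab <- as2x2(table)
  m <- matrix(tab, nrow = 2, byrow = TRUE)
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0) || any(cs == 0)) stop("zero margin: G-test undefined")
  E <- outer(rs, cs) / sum(m)
  obs <- m[m > 0]
  G <- 2 * sum(obs * log(obs / E[m > 0]))
  list(G = G, p = stats::pchisq(G, df = 1, lower.tail = FALSE))
}

#' Pearson phi coefficient of a 2x2 table
#'
#' phi = (n11 n00 - n10 n01) / sqrt((n10+n11)(n00+n10)(n01+n11)(n00+n01)):
#' the Pearson correlation of the two binary indicators. Sample-size
#' independent; the sign gives the direction of association.
#'
#' @param table 2x2 counts; all four margins must be positive.
#' @return phi in [-1, 1].
#' @export
phiCoefficient <- function(table) {
  tab <- as.numeric(as2x2(table))
  names(tab) <- c("n11", "n10", "n01", "n00")
  n11 <- tab[["n11"]]; n10 <- tab[["n10"]]
  n01 <- tab[["n01"]]; n00 <- tab[["n00"]]
  denom <- (n10 + n11) * (n00 + n10) * (n01 + n11) * (n00 + n01)
  if (denom == 0) stop("zero margin: phi undefined")
  (n11 * n00 - n10 * n01) / sqrt(denom)
}

#' Odds ratio with optional Haldane-Anscombe correction
#'
#' Raw sample odds ratio n11 n00 / (n10 n01). The log2 odds ratio applies a
#' 0.5 pseudo-count to all cells only when some cell is zero, keeping it
#' finite; otherwise the uncorrected ratio is used.
#'
#' @param table 2x2 counts.
#' @return list with \code{or} (raw, possibly Inf/NaN) and \code{log2or}.
#' @export
oddsRatio <- function(table) {
  tab <- as2x2(table)
  storage.mode(tab) <- "double"
  or <- (tab[["n11"]] * tab[["n00"]]) / (tab[["n10"]] * tab[["n01"]])
  orH <- if (any(tab == 0)) {
    t2 <- tab + 0.5
    (t2[["n11"]] * t2[["n00"]]) / (t2[["n10"]] * t2[["n01"]])
  } else or
  list(or = or, log2or = log2(orH))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up procedure: q_(i) = min_{j >= i} p_(j) m / j, capped at 1. Thin
#' validated wrapper over \code{stats::p.adjust(method = "BH")}.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return q-values in the input order.
#' @export
bhFDR <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC of a score for a binary label: the
#' probability that a randomly chosen positive outranks a randomly chosen
#' negative, with ties counted half. Used to evaluate association p-values
#' as predictors of true TF-function links.
#'
#' @param score numeric predictive score (higher = more positive).
#' @param label logical (or 0/1) true labels.
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(score, label) {
  label <- as.logical(label)
  stopifnot(length(score) == length(label), !anyNA(label))
  n1 <- sum(label); n0 <- sum(!label)
  if (n1 == 0 || n0 == 0) stop("need both positive and negative labels")
  r <- rank(score)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Annotate TFs with their target functions
#'
#' For every TF x term pair (term having at least \code{minTermSize} members
#' in its universe), builds the 2x2 table of target-gene versus
#' term-membership status restricted to the source-appropriate universe and
#' reports the odds ratio, log2(OR), phi, one-tailed (enrichment) and
#' two-tailed Fisher p-values and the G-test. Benjamini-Hochberg q-values
#' are computed within each annotation source separately; the significant
#' set is q <= \code{fdr}, with the direction of association taken from the
#' sign of phi.
#'
#' @param compendium a [Compendium-class].
#' @param collections named list of [AnnotationCollection-class].
#' @param genes gene table (for universe construction).
#' @param universePolicy named character vector mapping source type to
#'   universe kind; default curated -> literature_rich, machine -> coding.
#' @param fdr FDR threshold on q (default 0.05).
#' @param qFrom which p-value drives the q-values: "two.sided" (default;
#'   both enrichment and depletion can be significant, direction read off
#'   phi) or "greater" (enrichment only).
#' @param minTermSize minimum universe members per term (default 3).
#' @return data.frame of association records: tf, term, source, n11..n00,
#'   odds_ratio, log2_odds_ratio, phi, p_greater, p_two_sided, g_stat,
#'   p_gtest, q, direction, significant.
#' @export
annotateTFs <- function(compendium, collections, genes,
                        universePolicy = c(curated = "literature_rich",
                                           machine = "coding"),
                        fdr = 0.05, qFrom = c("two.sided", "greater"),
                        minTermSize = 3L) {
  qFrom <- match.arg(qFrom)
  sets <- tgSets(compendium)
  out <- vector("list", length(collections))
  for (ci in seq_along(collections)) {
    cl <- collections[[ci]]
    type <- collectionType(cl)
    if (!type %in% names(universePolicy))
      stop("universe policy has no entry for source type '", type, "'")
    universe <- buildUniverse(genes, universePolicy[[type]])
    uSets <- lapply(geneSets(cl), intersect, y = universe)
    uSets <- uSets[lengths(uSets) >= minTermSize]
    if (!length(uSets) || !length(sets)) next
    N <- length(universe)
    termSize <- lengths(uSets)
    rows <- vector("list", length(sets))
    for (ti in seq_along(sets)) {
      tgU <- intersect(sets[[ti]], universe)
      nTg <- length(tgU)
      n11 <- vapply(uSets, function(s) length(intersect(tgU, s)), integer(1))
      n10 <- nTg - n11
      n01 <- termSize - n11
      n00 <- N - n11 - n10 - n01
      pGreater <- stats::phyper(n11 - 1, termSize, N - termSize, nTg,
                                lower.tail = FALSE)
      pTwo <- vapply(seq_along(n11), function(k)
        stats::fisher.test(matrix(c(n11[k], n10[k], n01[k], n00[k]),
                                  nrow = 2, byrow = TRUE))$p.value,
        numeric(1))
      pTwo <- pmin(pTwo, 1)  # exact-test summation can exceed 1 by eps
      g <- mapply(function(a, b, c, d) {
        if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
          return(c(NA_real_, NA_real_))
        res <- gTest(c(n11 = a, n10 = b, n01 = c, n00 = d))
        c(res$G, res$p)
      }, n11, n10, n01, n00)
      phi <- vapply(seq_along(n11), function(k) {
        a <- as.numeric(n11[k]); b <- as.numeric(n10[k])
        c <- as.numeric(n01[k]); d <- as.numeric(n00[k])
        denom <- (b + a) * (d + b) * (c + a) * (d + c)
        if (denom == 0) NA_real_ else (a * d - b * c) / sqrt(denom)
      }, numeric(1))
      ors <- lapply(seq_along(n11), function(k)
        oddsRatio(c(n11 = n11[k], n10 = n10[k], n01 = n01[k], n00 = n00[k])))
      rows[[ti]] <- data.frame(
        tf = names(sets)[ti], term = names(uSets),
        source = collectionName(cl),
        n11 = n11, n10 = n10, n01 = n01, n00 = n00,
        odds_ratio = vapply(ors, `[[`, numeric(1), "or"),
        log2_odds_ratio = vapply(ors, `[[`, numeric(1), "log2or"),
        phi = phi, p_greater = pGreater, p_two_sided = pTwo,
        g_stat = g[1, ], p_gtest = g[2, ],
        stringsAsFactors = FALSE, row.names = NULL)
    }
    out[[ci]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  if (is.null(res) || !nrow(res)) {
    res <- data.frame(tf = character(), term = character(),
                      source = character(), n11 = integer(), n10 = integer(),
                      n01 = integer(), n00 = integer(), odds_ratio = numeric(),
                      log2_odds_ratio = numeric(), phi = numeric(),
                      p_greater = numeric(), p_two_sided = numeric(),
                      g_stat = numeric(), p_gtest = numeric(), q = numeric(),
                      direction = character(), significant = logical(),
                      stringsAsFactors = FALSE)
    return(res)
  }
  pDriver <- if (qFrom == "two.sided") res$p_two_sided else res$p_greater
  res$q <- NA_real_
  for (s in unique(res$source)) {
    i <- res$source == s
    res$q[i] <- bhFDR(pDriver[i])
  }
  res$direction <- ifelse(!is.na(res$phi) & res$phi < 0, "negative",
                          "positive")
  res$significant <- res$q <= fdr
  rownames(res) <- NULL
  res
}
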