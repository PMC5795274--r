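#' @include AllClasses.R enrichment.R
NULL

#' Sharing statistics for one pair of sets
#'
#' Builds the 2x2 table of joint membership over the universe (or over a
#' term space, for function sharing) and returns phi (NA when a margin is
#' zero), the raw odds ratio, and the one-tailed Fisher enrichment p-value.
#' Symmetric in its two set arguments.
#'
#' @param setA,setB character vectors.
#' @param universe character vector of allowed elements.
#' @return list with counts (n11..n00), phi, or, p.
#' @export
pairSharing <- function(setA, setB, universe) {
  if (!length(universe)) stop("universe must be non-empty")
  tab <- buildContingency(setA, setB, universe)
  phi <- tryCatch(phiCoefficient(tab), error = function(e) NA_real_)
  list(counts = tab, phi = phi, or = oddsRatio(tab)$or,
       p = fisherTest(tab, "greater"))
}

#' All-pairs TF target-gene sharing
#'
#' Computes, for every unordered TF pair, the TG-sharing 2x2 over the
#' universe with phi, odds ratio, Fisher enrichment p and BH q across all
#' pairs. Flags: \code{significant_TG_sharing} at q <= \code{neighborFdr}
#' (the "TF neighbor" relation) and \code{low_TG_sharing} when the odds
#' ratio is < 1 (ties at OR = 1 count as high sharing).
#'
#' @param sets named list of TF target-gene sets (e.g. [tgSets()]).
#' @param universe character vector of allowed genes.
#' @param neighborFdr FDR for the neighbor call (default 0.01).
#' @return data.frame, one row per unordered pair.
#' @export
tfPairSharing <- function(sets, universe, neighborFdr = 0.01) {
  nm <- names(sets)
  if (length(nm) < 2L) stop("need at least two sets")
  M <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  N <- length(universe)
  C <- crossprod(M)                 # n11 for every pair
  k <- colSums(M)
  idx <- which(upper.tri(C), arr.ind = TRUE)
  n11 <- C[idx]
  n10 <- k[idx[, 1]] - n11
  n01 <- k[idx[, 2]] - n11
  n00 <- N - n11 - n10 - n01
  denom <- (n10 + n11) * (n00 + n10) * (n01 + n11) * (n00 + n01)
  phi <- ifelse(denom == 0, NA_real_,
                (n11 * n00 - n10 * n01) / sqrt(denom))
  or <- (n11 * n00) / (n10 * n01)
  p <- stats::phyper(n11 - 1, n11 + n01, n10 + n00, n11 + n10,
                     lower.tail = FALSE)
  q <- bhFDR(p)
  data.frame(a = nm[idx[, 1]], b = nm[idx[, 2]],
             n11 = n11, n10 = n10, n01 = n01, n00 = n00,
             phi_TG = phi, or_TG = or, p_TG = p, q_TG = q,
             significant_TG_sharing = q <= neighborFdr,
             low_TG_sharing = !is.na(or) & or < 1,
             stringsAsFactors = FALSE)
}

#' All-pairs sharing of term sets over a term space
#'
#' Fisher/phi overlap of per-entity term sets (target functions or known
#' functions) over the space of terms, with BH across pairs and a
#' significance flag at the given FDR.
#'
#' @param sets named list of term-id sets per entity.
#' @param termSpace character vector of all terms considered.
#' @param fdr significance threshold on q.
#' @param prefix column-name prefix (e.g. "targetFun", "knownFun").
#' @return data.frame keyed by (a, b).
#' @export
functionSharingPairs <- function(sets, termSpace, fdr = 0.05,
                                 prefix = "fun") {
  if (!length(termSpace)) {
    nm <- names(sets)
    idx <- utils::combn(seq_along(nm), 2L)
    out <- data.frame(a = nm[idx[1, ]], b = nm[idx[2, ]],
                      stringsAsFactors = FALSE)
    out[[paste0("n_shared_", prefix)]] <- 0L
    out[[paste0("phi_", prefix)]] <- NA_real_
    out[[paste0("or_", prefix)]] <- NA_real_
    out[[paste0("p_", prefix)]] <- NA_real_
    out[[paste0("q_", prefix)]] <- NA_real_
    out[[paste0("significant_", prefix, "_sharing")]] <- FALSE
    return(out)
  }
  res <- tfPairSharing(sets, termSpace, neighborFdr = fdr)
  out <- res[, c("a", "b")]
  out[[paste0("n_shared_", prefix)]] <- res$n11
  out[[paste0("phi_", prefix)]] <- res$phi_TG
  out[[paste0("or_", prefix)]] <- res$or_TG
  out[[paste0("p_", prefix)]] <- res$p_TG
  out[[paste0("q_", prefix)]] <- res$q_TG
  out[[paste0("significant_", prefix, "_sharing")]] <-
    res$significant_TG_sharing
  out
}

#' Per-TF significant target-function sets
#'
#' @param associations an [annotateTFs()] table.
#' @param direction keep "positive" associations only (default) or "any".
#' @return named list of term keys ("source/term") per TF, including TFs
#'   with no significant term (empty sets).
#' @export
targetFunctionSets <- function(associations, direction = c("positive",
                                                           "any")) {
  direction <- match.arg(direction)
  sig <- associations[associations$significant &
                      (direction == "any" |
                       associations$direction == "positive"), , drop = FALSE]
  keys <- paste(sig$source, sig$term, sep = "/")
  out <- split(keys, factor(sig$tf, levels = sort(unique(associations$tf))))
  lapply(out, unique)
}

#' Per-gene known-function sets
#'
#' The functional terms a gene is annotated with across the collections
#' (term keys "source/term").
#'
#' @param collections named list of [AnnotationCollection-class].
#' @param geneIds genes (e.g. the TF roster) to report.
#' @return named list of term-key sets.
#' @export
knownFunctionSets <- function(collections, geneIds) {
  perGene <- stats::setNames(vector("list", length(geneIds)), geneIds)
  for (cl in collections) {
    ss <- geneSets(cl)
    for (tn in names(ss)) {
      key <- paste(collectionName(cl), tn, sep = "/")
      hit <- intersect(ss[[tn]], geneIds)
      for (g in hit) perGene[[g]] <- c(perGene[[g]], key)
    }
  }
  lapply(perGene, function(v) unique(v %||% character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble the full TF-pair record table
#'
#' Joins target-gene sharing, target-function sharing and known-function
#' sharing for every unordered TF pair, producing the flags used by the
#' discordance analysis: significant/low TG sharing, significant
#' target-function sharing (FDR <= \code{targetFunFdr}) and significant
#' known-function sharing (FDR <= \code{knownFunFdr}).
#'
#' @param compendium a [Compendium-class].
#' @param associations an [annotateTFs()] table for that compendium.
#' @param collections named list of [AnnotationCollection-class].
#' @param genes gene table.
#' @param universe gene universe for TG sharing; defaults to the union of
#'   annotated genes policy, here the coding universe.
#' @param neighborFdr,targetFunFdr,knownFunFdr flag thresholds (defaults
#'   0.01, 0.05, 0.01).
#' @return data.frame of pair records.
#' @export
tfPairTable <- function(compendium, associations, collections, genes,
                        universe = buildUniverse(genes, "coding"),
                        neighborFdr = 0.01, targetFunFdr = 0.05,
                        knownFunFdr = 0.01) {
  sets <- tgSets(compendium)
  tg <- tfPairSharing(sets, universe, neighborFdr)
  tfs <- names(sets)
  termSpace <- unique(paste(associations$source, associations$term,
                            sep = "/"))
  tfun <- targetFunctionSets(associations)
  tfun <- tfun[tfs]
  names(tfun) <- tfs
  tfun <- lapply(tfun, function(v) v %||% character())
  tgt <- functionSharingPairs(tfun, termSpace, fdr = targetFunFdr,
                              prefix = "targetFun")
  kfun <- knownFunctionSets(collections, tfs)
  allKnown <- unique(unlist(kfun))
  kn <- functionSharingPairs(kfun, allKnown, fdr = knownFunFdr,
                             prefix = "knownFun")
  key <- function(d) paste(d$a, d$b, sep = "\r")
  out <- cbind(tg,
               tgt[match(key(tg), key(tgt)),
                   setdiff(names(tgt), c("a", "b")), drop = FALSE],
               kn[match(key(tg), key(kn)),
                  setdiff(names(kn), c("a", "b")), drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Discordance test from stratum counts
#'
#' Within one target-gene-sharing stratum, tests whether TF pairs with
#' significant target-function sharing are enriched for significant
#' known-function sharing, from the raw counts: \code{nSig} pairs with
#' significant target-function sharing of which \code{kSig} share known
#' functions, against \code{nOther} / \code{kOther} for the remaining pairs.
#'
#' @param nSig,kSig,nOther,kOther stratum counts.
#' @return list with or (sample odds ratio), p (one-tailed Fisher),
#'   pctSig, pctOther (percentages of known-function sharing).
#' @examples
#' discordanceTest(329, 117, 42373, 11704)  # OR 1.45, p ~ 0.001
#' @export
discordanceTest <- function(nSig, kSig, nOther, kOther) {
  stopifnot(kSig <= nSig, kOther <= nOther)
  tab <- c(n11 = kSig, n10 = nSig - kSig, n01 = kOther,
           n00 = nOther - kOther)
  list(or = oddsRatio(tab)$or, p = fisherTest(tab, "greater"),
       pctSig = 100 * kSig / nSig, pctOther = 100 * kOther / nOther)
}

#' Discordance analysis of target-function vs target-gene similarity
#'
#' Partitions TF pairs into four strata by (significant target-function
#' sharing: yes/no) x (target-gene sharing: low OR < 1 / high OR >= 1) and,
#' within each TG stratum, tests whether the pairs with significant
#' target-function sharing are enriched for significant known-function
#' sharing. Pairs in the low-TG / significant-target-function stratum are
#' the "unexpected" similarities: TFs that share functions without sharing
#' target genes.
#'
#' @param pairs a [tfPairTable()] data.frame.
#' @return list with \code{strata} (data.frame: stratum counts, percentage
#'   with known-function sharing) and \code{tests} (per TG stratum: or, p);
#'   a stratum with no pairs is reported with a notice and no test.
#' @export
discordanceAnalysis <- function(pairs) {
  need <- c("significant_targetFun_sharing", "low_TG_sharing",
            "significant_knownFun_sharing")
  if (!all(need %in% names(pairs)))
    stop("pair table lacks required flag columns")
  pairs <- pairs[stats::complete.cases(pairs[need]), , drop = FALSE]
  strata <- expand.grid(targetFunSharing = c("significant", "not"),
                        tgSharing = c("low", "high"),
                        stringsAsFactors = FALSE)
  strata$n <- NA_integer_; strata$nKnownShared <- NA_integer_
  for (i in seq_len(nrow(strata))) {
    sel <- (pairs$significant_targetFun_sharing ==
            (strata$targetFunSharing[i] == "significant")) &
           (pairs$low_TG_sharing == (strata$tgSharing[i] == "low"))
    strata$n[i] <- sum(sel)
    strata$nKnownShared[i] <- sum(pairs$significant_knownFun_sharing[sel])
  }
  strata$pctKnownShared <- ifelse(strata$n > 0,
                                  100 * strata$nKnownShared / strata$n, NA)
  tests <- list()
  for (lvl in c("low", "high")) {
    s <- strata[strata$tgSharing == lvl, ]
    sig <- s[s$targetFunSharing == "significant", ]
    oth <- s[s$targetFunSharing == "not", ]
    if (sig$n == 0 || oth$n == 0) {
      message("discordance: empty '", lvl, "' TG-sharing stratum; ",
              "test skipped")
      next
    }
    tests[[lvl]] <- discordanceTest(sig$n, sig$nKnownShared,
                                    oth$n, oth$nKnownShared)
  }
  list(strata = strata, tests = tests)
}

#' Function-function regulator sharing
#'
#' For every pair of functional terms having at least one significant
#' (positive) regulator, reports the shared and total regulator sets, a flag
#' for identical regulator sets, and the member-gene overlap (phi, odds
#' ratio) over the universe. The subset with identical regulators but
#' lower-than-expected gene overlap (OR < 1) is the set of function pairs
#' linked by regulation without shared genes.
#'
#' @param associations an [annotateTFs()] table.
#' @param collections named list of [AnnotationCollection-class].
#' @param universe gene universe for member-gene overlap.
#' @return data.frame, one row per term pair, with attribute
#'   \code{"linkedWithoutGenes"} holding the identical-regulator, OR < 1
#'   subset.
#' @export
functionRegulatorSharing <- function(associations, collections, universe) {
  sig <- associations[associations$significant &
                      associations$direction == "positive", , drop = FALSE]
  if (!nrow(sig))
    return(data.frame(termA = character(), termB = character(),
                      stringsAsFactors = FALSE))
  key <- paste(sig$source, sig$term, sep = "/")
  regs <- lapply(split(sig$tf, key), function(v) sort(unique(v)))
  members <- list()
  for (cl in collections)
    for (tn in names(geneSets(cl)))
      members[[paste(collectionName(cl), tn, sep = "/")]] <-
        geneSets(cl)[[tn]]
  terms <- names(regs)
  if (length(terms) < 2L)
    return(data.frame(termA = character(), termB = character(),
                      stringsAsFactors = FALSE))
  cmb <- utils::combn(terms, 2L)
  rows <- lapply(seq_len(ncol(cmb)), function(i) {
    a <- cmb[1, i]; b <- cmb[2, i]
    shared <- intersect(regs[[a]], regs[[b]])
    ident <- setequal(regs[[a]], regs[[b]])
    ps <- pairSharing(members[[a]], members[[b]], universe)
    data.frame(termA = a, termB = b,
               nRegA = length(regs[[a]]), nRegB = length(regs[[b]]),
               nSharedReg = length(shared), identicalRegulators = ident,
               geneOverlap = ps$counts[["n11"]], genePhi = ps$phi,
               geneOR = ps$or, geneP = ps$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "linkedWithoutGenes") <-
    out[out$identicalRegulators & !is.na(out$geneOR) & out$geneOR < 1, ,
        drop = FALSE]
  out
}

#' Odds ratio of two overlapping pair flags
#'
#' Given the total number of pairs, the counts flagged by each of two
#' criteria and the count flagged by both, forms the implied 2x2 table
#' (both, A only, B only, neither) and returns its odds ratio; a
#' Haldane-Anscombe 0.5 pseudo-count variant is also reported, which matters
#' only when some implied cell is zero.
#'
#' @param nTotalPairs,nFlagA,nFlagB,nBoth the four counts.
#' @return list with \code{or}, \code{orPseudo} and the implied
#'   \code{cells}.
#' @examples
#' overlapOddsRatio(73536, 11205, 12434, 5866)$or  # ~ 9.3
#' @export
overlapOddsRatio <- function(nTotalPairs, nFlagA, nFlagB, nBoth) {
  cells <- c(n11 = nBoth, n10 = nFlagA - nBoth, n01 = nFlagB - nBoth,
             n00 = nTotalPairs - nFlagA - nFlagB + nBoth)
  if (any(cells < 0)) stop("inconsistent counts: implied cell is negative")
  orr <- oddsRatio(cells)
  pc <- cells + 0.5
  list(or = orr$or,
       orPseudo = (pc[["n11"]] * pc[["n00"]]) / (pc[["n10"]] * pc[["n01"]]),
       cells = cells)
}
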