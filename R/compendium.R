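#' @include AllClasses.R
NULL

#' Merge TF-target edge lists from multiple evidence sources
#'
#' Unions edge lists sharing one gene-id space into a single
#' [Compendium-class]. Duplicate (tf, tg) pairs collapse to one edge whose
#' evidence is the union of the individual labels, reflecting that the
#' compendium counts unique regulatory relationships.
#'
#' @param edgeLists list of data.frames with columns tf, tg and optionally
#'   evidence.
#' @return A [Compendium-class].
#' @examples
#' a <- data.frame(tf = "T1", tg = "g1", evidence = "low_throughput")
#' b <- data.frame(tf = c("T1", "T2"), tg = c("g1", "g2"),
#'                 evidence = "encode")
#' mergeSources(list(a, b))
#' @export
mergeSources <- function(edgeLists) {
  stopifnot(is.list(edgeLists), length(edgeLists) >= 1L)
  for (i in seq_along(edgeLists)) {
    e <- edgeLists[[i]]
    if (!is.data.frame(e) || !all(c("tf", "tg") %in% names(e)))
      stop("edge list ", i, " lacks tf/tg columns")
    bad <- which(is.na(e$tf) | is.na(e$tg) |
                 !nzchar(as.character(e$tf)) | !nzchar(as.character(e$tg)))
    if (length(bad))
      stop("malformed edge in list ", i, " at line ", bad[1L],
           ": missing id")
    if (is.null(e$evidence)) e$evidence <- "other_high_throughput"
    edgeLists[[i]] <- e[, c("tf", "tg", "evidence")]
  }
  Compendium(do.call(rbind, edgeLists))
}

#' Evidence coverage of TFs
#'
#' Partitions the TF roster by evidence class: covered only by low-throughput
#' (literature) evidence, only by high-throughput (ChIP-seq: ENCODE or other)
#' evidence, or by both. The three counts always sum to the roster size.
#'
#' @param compendium a [Compendium-class].
#' @return list with counts \code{onlyLow}, \code{onlyHigh}, \code{both}.
#' @export
evidenceCoverage <- function(compendium) {
  e <- edgeTable(compendium)
  hasLow <- vapply(split(e$evidence, e$tf), function(v)
    any(grepl("low_throughput", v, fixed = TRUE)), logical(1))
  hasHigh <- vapply(split(e$evidence, e$tf), function(v)
    any(grepl("encode", v, fixed = TRUE) |
        grepl("other_high_throughput", v, fixed = TRUE)), logical(1))
  list(onlyLow = sum(hasLow & !hasHigh),
       onlyHigh = sum(hasHigh & !hasLow),
       both = sum(hasLow & hasHigh))
}

#' Degree statistics of a compendium
#'
#' Mean number of regulators per target gene (|edges| / |TG roster|), mean
#' number of targets per TF (|edges| / |TF roster|), and the fractions of
#' target genes with at least five regulators and with exactly one. The two
#' means satisfy meanRegulatorsPerGene x nTGs = meanTargetsPerTF x nTFs =
#' nEdges.
#'
#' @param compendium a non-empty [Compendium-class].
#' @return list with nEdges, nTFs, nTGs, meanRegulatorsPerGene,
#'   meanTargetsPerTF, fracTGsAtLeast5, fracTGsExactlyOne.
#' @export
degreeStatistics <- function(compendium) {
  e <- edgeTable(compendium)
  if (!nrow(e)) stop("empty compendium")
  regPerGene <- table(e$tg)
  list(nEdges = nrow(e),
       nTFs = length(unique(e$tf)),
       nTGs = length(regPerGene),
       meanRegulatorsPerGene = nrow(e) / length(regPerGene),
       meanTargetsPerTF = nrow(e) / length(unique(e$tf)),
       fracTGsAtLeast5 = mean(regPerGene >= 5),
       fracTGsExactlyOne = mean(regPerGene == 1))
}

#' Identify master regulators
#'
#' A master regulator is a TF with no incoming regulatory edge from any
#' other TF in the compendium; a self-loop does not disqualify it but is
#' flagged.
#'
#' @param compendium a [Compendium-class].
#' @return data.frame: tf, selfRegulated (only master regulators listed).
#' @export
masterRegulators <- function(compendium) {
  e <- edgeTable(compendium)
  tfs <- sort(unique(e$tf))
  tfEdges <- e[e$tg %in% tfs, , drop = FALSE]
  incomingOther <- tfEdges[tfEdges$tf != tfEdges$tg, , drop = FALSE]
  masters <- setdiff(tfs, unique(incomingOther$tg))
  selfLoop <- unique(tfEdges$tg[tfEdges$tf == tfEdges$tg])
  data.frame(tf = masters, selfRegulated = masters %in% selfLoop,
             stringsAsFactors = FALSE)
}
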