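#' @import methods
#' @importFrom S4Vectors metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' SimulationConfig: parameters of the synthetic study
#'
#' Holds every tunable of the synthetic-data generator: the gene space, the
#' annotation sources, the planted TF-function links, the per-gene target
#' sampling rates, and the shape of the TSS-anchored binding signal. All
#' downstream randomness flows from \code{seed}, expanded internally into
#' per-component substreams so that adding a generator does not perturb the
#' output of existing ones.
#'
#' @slot seed integer master seed.
#' @slot nGenes number of genes in the space.
#' @slot fracCoding fraction of genes flagged protein-coding.
#' @slot nTFs number of transcription factors (drawn from the coding genes).
#' @slot sources data.frame with columns \code{name}, \code{type}
#'   (\code{"curated"} or \code{"machine"}), \code{nTerms}, \code{minSize},
#'   \code{maxSize} describing each annotation source.
#' @slot nPlantedLinks number of true TF-term regulatory links planted.
#' @slot targetRateInTerm probability that a member gene of a planted term is
#'   a target gene of the linked TF.
#' @slot backgroundRate probability that any other gene is a target gene.
#' @slot windowBp,binBp TSS window and bin width in base pairs.
#' @slot peakHeight,peakSdBp,noiseSd Gaussian peak height and standard
#'   deviation (bp) for true targets, and the background noise sd.
#'
#' @seealso [simulationConfig()] for the user-facing constructor with the
#'   default study conditions.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  slots = c(
    seed = "integer",
    nGenes = "integer",
    fracCoding = "numeric",
    nTFs = "integer",
    sources = "data.frame",
    nPlantedLinks = "integer",
    targetRateInTerm = "numeric",
    backgroundRate = "numeric",
    windowBp = "integer",
    binBp = "integer",
    peakHeight = "numeric",
    peakSdBp = "numeric",
    noiseSd = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be positive")
  if (object@nTFs < 1L) msg <- c(msg, "nTFs must be positive")
  if (object@fracCoding < 0 || object@fracCoding > 1)
    msg <- c(msg, "fracCoding must lie in [0, 1]")
  if (object@backgroundRate < 0 || object@targetRateInTerm > 1 ||
      object@backgroundRate > object@targetRateInTerm)
    msg <- c(msg, "need 0 <= backgroundRate <= targetRateInTerm <= 1")
  if (object@windowBp %% object@binBp != 0L)
    msg <- c(msg, "windowBp must be divisible by binBp")
  if (object@windowBp < 1L || object@binBp < 1L)
    msg <- c(msg, "windowBp and binBp must be positive")
  if (object@nPlantedLinks < 0L) msg <- c(msg, "nPlantedLinks must be >= 0")
  src <- object@sources
  need <- c("name", "type", "nTerms", "minSize", "maxSize")
  if (!all(need %in% names(src))) {
    msg <- c(msg, paste("sources must have columns:", paste(need, collapse = ", ")))
  } else if (nrow(src) > 0) {
    if (anyDuplicated(src$name)) msg <- c(msg, "source names must be unique")
    if (!all(src$type %in% c("curated", "machine")))
      msg <- c(msg, "source type must be 'curated' or 'machine'")
    if (any(src$nTerms < 0)) msg <- c(msg, "nTerms must be >= 0")
    if (any(src$minSize > src$maxSize))
      msg <- c(msg, "term size range must have minSize <= maxSize")
    if (any(src$maxSize > object@nGenes))
      msg <- c(msg, "term sizes cannot exceed nGenes")
    if (any(src$minSize < 1)) msg <- c(msg, "term sizes must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' Build a simulation configuration
#'
#' The defaults define the study conditions under which the pipeline is
#' exercised: a gene space of 2,000 genes (85\% coding), 20 TFs, six
#' annotation sources emulating OMIM, GWAS, PharmGKB, Reactome, GO-BP and
#' GO-MF (GWAS being the one machine-derived source), 30 planted TF-term
#' links, a 60\% per-gene targeting rate inside planted terms against a 2\%
#' background, and a 6,000 bp / 100 bp-bin TSS window with a Gaussian binding
#' peak ten times the noise sd.
#'
#' @param seed integer master seed.
#' @param nGenes,fracCoding,nTFs gene-space parameters.
#' @param sources data.frame describing the annotation sources (see
#'   [SimulationConfig-class]); the default emulates the six sources above.
#' @param nPlantedLinks,targetRateInTerm,backgroundRate planted-structure
#'   parameters. \code{backgroundRate == targetRateInTerm} is allowed and
#'   yields a structure-free dataset in which the planted truth carries no
#'   signal (useful as a negative control).
#' @param windowBp,binBp,peakHeight,peakSdBp,noiseSd binding-signal shape.
#' @return A validated [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(seed = 1, nGenes = 500, nTFs = 5)
#' @export
simulationConfig <- function(seed = 1L,
                             nGenes = 2000L,
                             fracCoding = 0.85,
                             nTFs = 20L,
                             sources = defaultSources(),
                             nPlantedLinks = 30L,
                             targetRateInTerm = 0.6,
                             backgroundRate = 0.02,
                             windowBp = 6000L,
                             binBp = 100L,
                             peakHeight = 10,
                             peakSdBp = 300,
                             noiseSd = 1) {
  new("SimulationConfig",
      seed = as.integer(seed), nGenes = as.integer(nGenes),
      fracCoding = fracCoding, nTFs = as.integer(nTFs),
      sources = as.data.frame(sources, stringsAsFactors = FALSE),
      nPlantedLinks = as.integer(nPlantedLinks),
      targetRateInTerm = targetRateInTerm, backgroundRate = backgroundRate,
      windowBp = as.integer(windowBp), binBp = as.integer(binBp),
      peakHeight = peakHeight, peakSdBp = peakSdBp, noiseSd = noiseSd)
}

#' Default annotation-source layout
#'
#' Six sources mirroring the composition used for human TF annotation:
#' Mendelian diseases (OMIM), GWAS phenotypes (the one machine-derived
#' source), pharmacogenomic pathways (PharmGKB), signalling/metabolic
#' pathways (Reactome) and GO biological processes / molecular functions.
#'
#' @return data.frame with columns name, type, nTerms, minSize, maxSize.
#' @export
defaultSources <- function() {
  data.frame(
    name = c("OMIM", "GWAS", "PharmGKB", "Reactome", "GOBP", "GOMF"),
    type = c("curated", "machine", "curated", "curated", "curated", "curated"),
    nTerms = c(12L, 12L, 12L, 15L, 15L, 12L),
    minSize = 10L,
    maxSize = 60L,
    stringsAsFactors = FALSE
  )
}

#' AnnotationCollection: one source of term -> member-gene sets
#'
#' A named annotation source (e.g. an OMIM-like disease catalogue) holding a
#' list of functional terms, each a character vector of member gene ids.
#' The \code{type} distinguishes manually curated sources, tested against the
#' conservative literature-rich universe, from machine-derived sources
#' (GWAS-style), tested against the coding universe.
#'
#' @slot name source name.
#' @slot type \code{"curated"} or \code{"machine"}.
#' @slot sets named list of character vectors (term -> member genes).
#' @exportClass AnnotationCollection
setClass("AnnotationCollection",
  slots = c(name = "character", type = "character", sets = "list")
)

setValidity("AnnotationCollection", function(object) {
  msg <- character()
  if (length(object@name) != 1L) msg <- c(msg, "name must be a single string")
  if (!object@type %in% c("curated", "machine"))
    msg <- c(msg, "type must be 'curated' or 'machine'")
  if (length(object@sets)) {
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
      msg <- c(msg, "sets must have unique names")
    if (!all(vapply(object@sets, is.character, logical(1))))
      msg <- c(msg, "each set must be a character vector")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AnnotationCollection
#'
#' @param name source name.
#' @param type "curated" or "machine".
#' @param sets named list of character vectors of member gene ids.
#' @return An [AnnotationCollection-class] object.
#' @export
annotationCollection <- function(name, type = c("curated", "machine"),
                                 sets = list()) {
  type <- match.arg(type)
  new("AnnotationCollection", name = name, type = type, sets = sets)
}

#' Compendium: the TF -> target-gene regulatory network
#'
#' A deduplicated directed edge set from transcription factors to their
#' target genes. Each edge carries one or more evidence labels (multiple
#' labels are ';'-joined), reflecting a merge across low-throughput
#' literature evidence and high-throughput (ChIP-seq) sources. Self-loops
#' (a TF regulating itself) are permitted. The TF and TG rosters are always
#' the projections of the edge set.
#'
#' @slot edges data.frame with character columns \code{tf}, \code{tg},
#'   \code{evidence}.
#' @exportClass Compendium
setClass("Compendium", slots = c(edges = "data.frame"))

setValidity("Compendium", function(object) {
  e <- object@edges
  msg <- character()
  if (!all(c("tf", "tg", "evidence") %in% names(e)))
    msg <- c(msg, "edges must have columns tf, tg, evidence")
  else {
    if (nrow(e) && (anyNA(e$tf) || anyNA(e$tg) || any(!nzchar(e$tf)) ||
                    any(!nzchar(e$tg))))
      msg <- c(msg, "edges contain missing tf or tg ids")
    if (anyDuplicated(paste(e$tf, e$tg, sep = "\r")))
      msg <- c(msg, "duplicate (tf, tg) pairs; merge evidence instead")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Compendium from an edge table
#'
#' Duplicate (tf, tg) pairs are collapsed to one edge whose evidence is the
#' sorted, ';'-joined union of the individual labels, so an edge supported by
#' both a low-throughput experiment and ChIP-seq keeps both labels.
#'
#' @param edges data.frame with columns \code{tf}, \code{tg} and optionally
#'   \code{evidence} (default \code{"other_high_throughput"}).
#' @return A [Compendium-class] object.
#' @examples
#' Compendium(data.frame(tf = "T1", tg = c("g1", "g2")))
#' @export
Compendium <- function(edges) {
  if (!is.data.frame(edges) || !all(c("tf", "tg") %in% names(edges)))
    stop("edges must be a data.frame with columns 'tf' and 'tg'")
  if (is.null(edges$evidence))
    edges$evidence <- rep("other_high_throughput", nrow(edges))
  edges$tf <- as.character(edges$tf)
  edges$tg <- as.character(edges$tg)
  edges$evidence <- as.character(edges$evidence)
  bad <- which(is.na(edges$tf) | is.na(edges$tg) |
               !nzchar(edges$tf) | !nzchar(edges$tg))
  if (length(bad))
    stop("malformed edge with missing id at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  key <- paste(edges$tf, edges$tg, sep = "\r")
  if (anyDuplicated(key)) {
    ev <- vapply(split(edges$evidence, key), function(v)
      paste(sort(unique(unlist(strsplit(v, ";", fixed = TRUE)))),
            collapse = ";"), character(1))
    first <- !duplicated(key)
    edges <- edges[first, c("tf", "tg", "evidence")]
    edges$evidence <- unname(ev[paste(edges$tf, edges$tg, sep = "\r")])
  }
  rownames(edges) <- NULL
  new("Compendium", edges = edges[, c("tf", "tg", "evidence")])
}

#' BindingProfile: a TSS-anchored binding-signal matrix for one TF
#'
#' Extends \linkS4class{SummarizedExperiment}: rows are genes, columns are
#' fixed-width bins tiling a window centred on the transcription start site
#' (bin 1 covers [TSS - window/2, TSS - window/2 + bin)), and the single
#' assay \code{"signal"} holds non-negative binding intensities, as obtained
#' from ChIP-seq coverage pre-oriented 5'->3'. \code{tfId}, \code{windowBp}
#' and \code{binBp} live in the metadata.
#'
#' @exportClass BindingProfile
setClass("BindingProfile", contains = "SummarizedExperiment")

setValidity("BindingProfile", function(object) {
  msg <- character()
  md <- metadata(object)
  for (f in c("tfId", "windowBp", "binBp"))
    if (is.null(md[[f]])) msg <- c(msg, paste0("metadata field '", f, "' missing"))
  if (!length(msg)) {
    if (ncol(object) != md$windowBp %/% md$binBp)
      msg <- c(msg, "number of bins must equal windowBp / binBp")
    if (md$windowBp %% md$binBp != 0)
      msg <- c(msg, "windowBp must be divisible by binBp")
  }
  if (!"signal" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'signal' missing")
  else {
    s <- SummarizedExperiment::assay(object, "signal")
    if (any(s < 0)) msg <- c(msg, "signal intensities must be >= 0")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids (rownames) must be present and unique")
  if (length(msg)) msg else TRUE
})

#' Construct a BindingProfile
#'
#' @param signal numeric matrix of non-negative intensities, genes x bins,
#'   with gene ids as rownames.
#' @param tfId TF identifier.
#' @param windowBp,binBp window length and bin width in bp;
#'   \code{ncol(signal)} must equal \code{windowBp / binBp}.
#' @return A [BindingProfile-class] object.
#' @export
BindingProfile <- function(signal, tfId, windowBp = 6000L, binBp = 100L) {
  signal <- as.matrix(signal)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(signal = signal),
    metadata = list(tfId = tfId, windowBp = as.integer(windowBp),
                    binBp = as.integer(binBp)))
  new("BindingProfile", se)
}
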