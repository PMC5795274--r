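#' @include AllClasses.R
NULL

#' Accessors for tfanno core classes
#'
#' \code{tfIds} / \code{tgIds} return the TF and target-gene rosters of a
#' [Compendium-class] (the projections of its edge set); \code{edgeTable}
#' returns the edge data.frame; \code{tgSets} the named list of per-TF target
#' sets; \code{tfId}, \code{windowBp}, \code{binBp} and \code{signalMatrix}
#' unpack a [BindingProfile-class]; \code{collectionName},
#' \code{collectionType} and \code{geneSets} unpack an
#' [AnnotationCollection-class].
#'
#' @param x the object.
#' @return See the individual accessor descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("tfIds", function(x) standardGeneric("tfIds"))
#' @rdname accessors
#' @export
setGeneric("tgIds", function(x) standardGeneric("tgIds"))
#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
#' @rdname accessors
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))
#' @rdname accessors
#' @export
setGeneric("tgSets", function(x) standardGeneric("tgSets"))
#' @rdname accessors
#' @export
setGeneric("tfId", function(x) standardGeneric("tfId"))
#' @rdname accessors
#' @export
setGeneric("windowBp", function(x) standardGeneric("windowBp"))
#' @rdname accessors
#' @export
setGeneric("binBp", function(x) standardGeneric("binBp"))
#' @rdname accessors
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))
#' @rdname accessors
#' @export
setGeneric("collectionName", function(x) standardGeneric("collectionName"))
#' @rdname accessors
#' @export
setGeneric("collectionType", function(x) standardGeneric("collectionType"))
#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname accessors
#' @export
setMethod("tfIds", "Compendium", function(x) sort(unique(x@edges$tf)))

#' @rdname accessors
#' @export
setMethod("tgIds", "Compendium", function(x) sort(unique(x@edges$tg)))

#' @rdname accessors
#' @export
setMethod("edgeTable", "Compendium", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("edgeCount", "Compendium", function(x) nrow(x@edges))

#' @rdname accessors
#' @export
setMethod("tgSets", "Compendium", function(x)
  lapply(split(x@edges$tg, x@edges$tf), sort))

#' @rdname accessors
#' @export
setMethod("tfId", "BindingProfile", function(x) metadata(x)$tfId)

#' @rdname accessors
#' @export
setMethod("windowBp", "BindingProfile", function(x) metadata(x)$windowBp)

#' @rdname accessors
#' @export
setMethod("windowBp", "SimulationConfig", function(x) x@windowBp)

#' @rdname accessors
#' @export
setMethod("binBp", "BindingProfile", function(x) metadata(x)$binBp)

#' @rdname accessors
#' @export
setMethod("binBp", "SimulationConfig", function(x) x@binBp)

#' @rdname accessors
#' @export
setMethod("signalMatrix", "BindingProfile", function(x)
  SummarizedExperiment::assay(x, "signal"))

#' @rdname accessors
#' @export
setMethod("collectionName", "AnnotationCollection", function(x) x@name)

#' @rdname accessors
#' @export
setMethod("collectionType", "AnnotationCollection", function(x) x@type)

#' @rdname accessors
#' @export
setMethod("geneSets", "AnnotationCollection", function(x) x@sets)

#' @param x an AnnotationCollection
#' @describeIn accessors number of terms in the collection.
#' @export
setMethod("length", "AnnotationCollection", function(x) length(x@sets))

setMethod("show", "Compendium", function(object) {
  e <- object@edges
  cat("Compendium:", nrow(e), "TF->TG edges,",
      length(unique(e$tf)), "TFs,", length(unique(e$tg)), "target genes\n")
  ev <- sort(unique(unlist(strsplit(e$evidence, ";", fixed = TRUE))))
  if (length(ev)) cat("  evidence labels:", paste(ev, collapse = ", "), "\n")
})

setMethod("show", "AnnotationCollection", function(object) {
  sz <- lengths(object@sets)
  cat("AnnotationCollection '", object@name, "' (", object@type, "): ",
      length(object@sets), " terms", sep = "")
  if (length(sz)) cat(", sizes ", min(sz), "-", max(sz), sep = "")
  cat("\n")
})

setMethod("show", "BindingProfile", function(object) {
  cat("BindingProfile for TF ", tfId(object), ": ", nrow(object),
      " genes x ", ncol(object), " bins (window ", windowBp(object),
      " bp, bin ", binBp(object), " bp)\n", sep = "")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: seed", object@seed, "|", object@nGenes, "genes (",
      round(100 * object@fracCoding), "% coding ) |", object@nTFs, "TFs |",
      nrow(object@sources), "sources |", object@nPlantedLinks,
      "planted links\n")
  cat("  rates: in-term", object@targetRateInTerm, "background",
      object@backgroundRate, "| window", object@windowBp, "bp / bin",
      object@binBp, "bp\n")
})
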