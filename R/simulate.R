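#' @include AllClasses.R utils.R
NULL

#' Generate a synthetic gene space with annotation sources
#'
#' Creates \code{nGenes} genes with synthetic ids ("G000001", ...), flags a
#' \code{fracCoding} fraction as protein-coding, and draws each annotation
#' source's terms as random gene sets with sizes uniform in the configured
#' range. Curated sources annotate only coding genes (literature-derived
#' catalogues describe characterised proteins); machine sources draw from
#' the whole gene space. The returned gene table carries one logical
#' membership column per source, always consistent with the emitted sets.
#'
#' @param config a [SimulationConfig-class].
#' @return list with \code{genes} (data.frame: gene_id, is_coding, one
#'   logical column per source, with attribute \code{sourceTypes}) and
#'   \code{collections} (named list of [AnnotationCollection-class]).
#' @examples
#' sp <- generateGeneSpace(simulationConfig(seed = 7, nGenes = 200))
#' head(sp$genes)
#' @export
generateGeneSpace <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  n <- config@nGenes
  geneIds <- sprintf("G%06d", seq_len(n))
  isCoding <- withSubstream(config@seed, "gene_space", {
    stats::runif(n) < config@fracCoding
  })
  if (!any(isCoding)) isCoding[1L] <- TRUE  # degenerate fracCoding ~ 0
  coding <- geneIds[isCoding]

  src <- config@sources
  collections <- list()
  genes <- data.frame(gene_id = geneIds, is_coding = isCoding,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(src))) {
    nm <- src$name[i]
    pool <- if (src$type[i] == "curated") coding else geneIds
    if (src$maxSize[i] > length(pool))
      stop("invalid config: term size range for source '", nm,
           "' exceeds the available gene pool (", length(pool), ")")
    sets <- withSubstream(config@seed, paste0("source_", nm), {
      nt <- src$nTerms[i]
      if (nt == 0L) {
        list()
      } else {
        sizes <- sample(seq.int(src$minSize[i], src$maxSize[i]),
                        nt, replace = TRUE)
        out <- lapply(sizes, function(s) sort(sample(pool, s)))
        names(out) <- sprintf("%s_T%03d", nm, seq_len(nt))
        out
      }
    })
    collections[[nm]] <- annotationCollection(nm, src$type[i], sets)
    genes[[nm]] <- geneIds %in% unique(unlist(sets))
  }
  attr(genes, "sourceTypes") <- stats::setNames(src$type, src$name)
  list(genes = genes, collections = collections)
}

#' Plant true TF-term regulatory links
#'
#' Samples \code{nPlantedLinks} distinct (TF, source, term) triples uniformly
#' from the grid of TFs and available terms.
#'
#' @param config a [SimulationConfig-class].
#' @param tfs character vector of TF ids.
#' @param collections named list of [AnnotationCollection-class].
#' @return data.frame with columns tf, source, term.
#' @export
plantLinks <- function(config, tfs, collections) {
  terms <- do.call(rbind, lapply(collections, function(cl) {
    if (!length(geneSets(cl))) return(NULL)
    data.frame(source = collectionName(cl), term = names(geneSets(cl)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(terms) || config@nPlantedLinks == 0L)
    return(data.frame(tf = character(), source = character(),
                      term = character(), stringsAsFactors = FALSE))
  grid <- expand.grid(tfIdx = seq_along(tfs), termIdx = seq_len(nrow(terms)))
  k <- min(config@nPlantedLinks, nrow(grid))
  pick <- withSubstream(config@seed, "planted_links",
                        sample(nrow(grid), k))
  out <- data.frame(tf = tfs[grid$tfIdx[pick]],
                    source = terms$source[grid$termIdx[pick]],
                    term = terms$term[grid$termIdx[pick]],
                    stringsAsFactors = FALSE)
  out[order(out$tf, out$source, out$term), , drop = FALSE]
}

#' Generate a TF-target-gene compendium with planted structure
#'
#' Picks \code{nTFs} TFs among the coding genes and, for each TF, draws its
#' target genes per-gene independently: a gene belonging to any term planted
#' for that TF is a target with probability \code{targetRateInTerm}, any
#' other gene with probability \code{backgroundRate}. With
#' \code{targetRateInTerm = 1} and \code{backgroundRate = 0} a TF's target
#' set is exactly the union of its planted terms' members; with equal rates
#' the planted truth carries no signal.
#'
#' @param config a [SimulationConfig-class].
#' @param genes gene table from [generateGeneSpace()].
#' @param collections annotation collections from [generateGeneSpace()].
#' @param plantedLinks optional data.frame (tf, source, term); defaults to
#'   [plantLinks()] on TFs drawn from the coding genes. Links must reference
#'   existing TFs and terms.
#' @param tfs optional explicit TF roster (coding gene ids); defaults to a
#'   seeded draw of \code{nTFs} coding genes.
#' @param evidence evidence label given to the generated edges.
#' @return list with \code{compendium} ([Compendium-class]), \code{truth}
#'   (the planted-link table) and \code{tfs} (TF roster, including TFs that
#'   drew no targets).
#' @export
generateCompendium <- function(config, genes, collections,
                               plantedLinks = NULL, tfs = NULL,
                               evidence = "other_high_throughput") {
  stopifnot(is(config, "SimulationConfig"))
  coding <- genes$gene_id[genes$is_coding]
  if (is.null(tfs)) {
    tfs <- withSubstream(config@seed, "tf_roster",
                         sort(sample(coding,
                                     min(config@nTFs, length(coding)))))
  } else if (!all(tfs %in% genes$gene_id)) {
    stop("explicit TF roster contains unknown gene ids")
  }
  if (is.null(plantedLinks)) plantedLinks <- plantLinks(config, tfs, collections)
  if (nrow(plantedLinks)) {
    if (!all(plantedLinks$tf %in% tfs))
      stop("planted links reference unknown TFs")
    for (i in seq_len(nrow(plantedLinks))) {
      cl <- collections[[plantedLinks$source[i]]]
      if (is.null(cl) || !plantedLinks$term[i] %in% names(geneSets(cl)))
        stop("planted link references unknown term: ",
             plantedLinks$source[i], "/", plantedLinks$term[i])
    }
  }
  memberOf <- function(tf) {
    rows <- plantedLinks[plantedLinks$tf == tf, , drop = FALSE]
    unique(unlist(lapply(seq_len(nrow(rows)), function(i)
      geneSets(collections[[rows$source[i]]])[[rows$term[i]]])))
  }
  edges <- withSubstream(config@seed, "compendium", {
    out <- vector("list", length(tfs))
    for (j in seq_along(tfs)) {
      inTerm <- genes$gene_id %in% memberOf(tfs[j])
      p <- ifelse(inTerm, config@targetRateInTerm, config@backgroundRate)
      hit <- stats::runif(nrow(genes)) < p
      if (any(hit))
        out[[j]] <- data.frame(tf = tfs[j], tg = genes$gene_id[hit],
                               stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  if (is.null(edges))
    edges <- data.frame(tf = character(), tg = character(),
                        stringsAsFactors = FALSE)
  edges$evidence <- rep(evidence, nrow(edges))
  list(compendium = Compendium(edges), truth = plantedLinks, tfs = tfs)
}

#' Generate a TSS-anchored binding-signal matrix for one TF
#'
#' True target genes receive a Gaussian-shaped binding peak (height
#' \code{peakHeight}, sd \code{peakSdBp}) centred on the TSS-containing bin,
#' on top of Gaussian background noise (\code{noiseSd}); non-targets receive
#' noise only. Intensities are clipped at zero, emulating non-negative
#' ChIP-seq coverage.
#'
#' @param config a [SimulationConfig-class].
#' @param tf TF id.
#' @param geneIds character vector of genes (rows of the matrix).
#' @param trueTargets character vector of the TF's true target genes.
#' @param windowBp,binBp window geometry; default taken from \code{config}.
#' @return A [BindingProfile-class].
#' @export
generateBindingSignals <- function(config, tf, geneIds, trueTargets,
                                   windowBp = config@windowBp,
                                   binBp = config@binBp) {
  if (!length(geneIds)) stop("empty gene list")
  nBins <- windowBp %/% binBp
  if (windowBp %% binBp != 0L) stop("windowBp must be divisible by binBp")
  if (nBins < 4L) stop("window/bin geometry must yield at least 4 bins")
  binMid <- -windowBp / 2 + (seq_len(nBins) - 0.5) * binBp
  tssBin <- nBins %/% 2 + 1L            # bin containing the TSS
  peak <- config@peakHeight *
    exp(-(binMid - binMid[tssBin])^2 / (2 * max(config@peakSdBp, 1e-9)^2))
  if (config@peakHeight == 0) peak <- rep(0, nBins)
  isTarget <- geneIds %in% trueTargets
  signal <- withSubstream(config@seed, paste0("signal_", tf, "_", windowBp), {
    m <- matrix(stats::rnorm(length(geneIds) * nBins, sd = config@noiseSd),
                nrow = length(geneIds))
    if (any(isTarget))
      m[isTarget, ] <- m[isTarget, , drop = FALSE] +
        matrix(peak, nrow = sum(isTarget), ncol = nBins, byrow = TRUE)
    pmax(m, 0)
  })
  rownames(signal) <- geneIds
  colnames(signal) <- sprintf("bin%03d", seq_len(nBins))
  BindingProfile(signal, tfId = tf, windowBp = windowBp, binBp = binBp)
}
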