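#' @include AllClasses.R
NULL

#' Read a GMT gene-set file
#'
#' One set per line, tab-separated: set name, description, then member
#' genes (MSigDB dialect: UTF-8, no quoting). Duplicate members within a
#' line are deduplicated with a warning; line order is preserved.
#'
#' @param path file path.
#' @return named list of character vectors, with attribute
#'   \code{descriptions} (named character vector).
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  desc <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("GMT parse error at line ", i, ": fewer than 3 fields")
    nms[i] <- f[1]
    desc[i] <- f[2]
    members <- f[-(1:2)]
    if (anyDuplicated(members)) {
      warning("GMT line ", i, " ('", f[1], "'): duplicate members collapsed")
      members <- unique(members)
    }
    sets[[i]] <- members
  }
  names(sets) <- nms
  names(desc) <- nms
  structure(sets, descriptions = desc)
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors.
#' @param path output file path.
#' @param descriptions optional character vector of descriptions (recycled
#'   \code{"na"} when absent), preserved verbatim.
#' @return invisibly, the path.
#' @export
writeGMT <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions))
    descriptions <- attr(sets, "descriptions") %||% rep("na", length(sets))
  descriptions <- rep_len(descriptions, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Serialise / deserialise a compendium as GMT
#'
#' One line per TF: tf id, description (the ';'-joined evidence labels seen
#' on its edges), then its target genes. The GMT round trip preserves the
#' edge set exactly; per-edge evidence is coarsened to per-TF labels.
#'
#' @param compendium a [Compendium-class].
#' @param path file path.
#' @return [writeCompendiumGMT()] the path, invisibly;
#'   [readCompendiumGMT()] a [Compendium-class].
#' @export
writeCompendiumGMT <- function(compendium, path) {
  e <- edgeTable(compendium)
  sets <- tgSets(compendium)
  ev <- vapply(split(e$evidence, e$tf), function(v)
    paste(sort(unique(unlist(strsplit(v, ";", fixed = TRUE)))),
          collapse = ";"), character(1))
  writeGMT(sets, path, descriptions = unname(ev[names(sets)]))
}

#' @rdname writeCompendiumGMT
#' @export
readCompendiumGMT <- function(path) {
  sets <- readGMT(path)
  desc <- attr(sets, "descriptions")
  edges <- data.frame(tf = rep(names(sets), lengths(sets)),
                      tg = unlist(sets, use.names = FALSE),
                      evidence = rep(unname(desc), lengths(sets)),
                      stringsAsFactors = FALSE)
  Compendium(edges)
}

#' Write / read the gene table as TSV
#'
#' Tab-separated with a header; the source-type map (curated/machine per
#' annotation source) is stored in a \code{#% source_types:} comment line so
#' the round trip preserves the metadata needed for universe construction.
#'
#' @param genes gene table data.frame.
#' @param path file path.
#' @return the path ([writeGeneTable()]) or the gene table
#'   ([readGeneTable()]).
#' @export
writeGeneTable <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  types <- attr(genes, "sourceTypes")
  if (!is.null(types))
    writeLines(paste0("#% source_types: ",
                      paste(names(types), types, sep = "=", collapse = ",")),
               con)
  utils::write.table(genes, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeGeneTable
#' @export
readGeneTable <- function(path) {
  lines <- readLines(path, n = 5L)
  hdr <- grep("^#% source_types: ", lines, value = TRUE)
  genes <- utils::read.table(path, sep = "\t", header = TRUE,
                             comment.char = "#", stringsAsFactors = FALSE)
  if (length(hdr)) {
    kv <- strsplit(strsplit(sub("^#% source_types: ", "", hdr[1]),
                            ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
    attr(genes, "sourceTypes") <- stats::setNames(
      vapply(kv, `[`, character(1), 2L), vapply(kv, `[`, character(1), 1L))
  }
  genes
}

#' Write / read a binding-signal matrix as TSV
#'
#' Gene id plus one column per bin; the TF id and window geometry are kept
#' in \code{#%} metadata comment lines.
#'
#' @param bp a [BindingProfile-class] ([writeSignalMatrix()]).
#' @param path file path.
#' @return the path, or a [BindingProfile-class] ([readSignalMatrix()]).
#' @export
writeSignalMatrix <- function(bp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#% tf_id: ", tfId(bp)),
               paste0("#% window_bp: ", windowBp(bp)),
               paste0("#% bin_bp: ", binBp(bp))), con)
  m <- signalMatrix(bp)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSignalMatrix
#' @export
readSignalMatrix <- function(path) {
  lines <- readLines(path, n = 10L)
  meta <- function(key) {
    v <- grep(paste0("^#% ", key, ": "), lines, value = TRUE)
    if (!length(v)) stop("signal matrix metadata '", key, "' missing")
    sub(paste0("^#% ", key, ": "), "", v[1])
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  BindingProfile(m, tfId = meta("tf_id"),
                 windowBp = as.integer(meta("window_bp")),
                 binBp = as.integer(meta("bin_bp")))
}

#' Write a report table as TSV
#'
#' Tab-separated with a header, no quoting or row names; the shared output
#' convention for association tables, pair tables and diversity profiles.
#' Every table written this way is re-parseable with [readReportTSV()].
#'
#' @param x data.frame.
#' @param path file path.
#' @return invisibly, the path.
#' @export
writeReportTSV <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeReportTSV
#' @export
readReportTSV <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
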