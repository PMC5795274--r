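#' @include AllClasses.R enrichment.R
NULL

#' Pairwise phi matrix of a list of sets
#'
#' Symmetric matrix of phi coefficients between the membership indicators of
#' the sets over the universe, with unit diagonal. Entries undefined from a
#' zero margin (e.g. an empty set) are set to 0 off-diagonal, contributing
#' no redundancy.
#'
#' @param sets named list of character vectors.
#' @param universe character vector of allowed elements.
#' @return numeric matrix with dimnames = set names.
#' @export
phiMatrix <- function(sets, universe) {
  M <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) M <- matrix(M, nrow = 1,
                                          dimnames = list(NULL, names(sets)))
  N <- length(universe)
  C <- crossprod(M)
  k <- colSums(M)
  n11 <- C
  n10 <- matrix(k, nrow = length(k), ncol = length(k)) - C   # rows: set a
  n01 <- t(n10)
  n00 <- N - n11 - n10 - n01
  denom <- (n10 + n11) * (n00 + n10) * (n01 + n11) * (n00 + n01)
  phi <- ifelse(denom > 0, (n11 * n00 - n10 * n01) / sqrt(denom), 0)
  diag(phi) <- 1
  dimnames(phi) <- list(names(sets), names(sets))
  phi
}

#' Uniqueness weights from a phi matrix
#'
#' The uniqueness of entity t is u_t = 1 / sum_t' phi_tt'^2, the reciprocal
#' of its accumulated squared similarity to all entities including itself.
#' Since phi_tt = 1, u_t always lies in (0, 1]: 1 for an entity uncorrelated
#' with every other, 1/k for a member of a block of k perfectly correlated
#' entities. Undefined phi entries are treated as 0.
#'
#' @param phiMat symmetric numeric matrix with unit diagonal.
#' @return named numeric vector of uniqueness weights.
#' @examples
#' m <- diag(3); m[1, 2] <- m[2, 1] <- 0.5
#' uniqueness(m)  # 0.8 0.8 1.0
#' @export
uniqueness <- function(phiMat) {
  phiMat <- as.matrix(phiMat)
  if (nrow(phiMat) != ncol(phiMat))
    stop("phi matrix must be square")
  if (any(abs(diag(phiMat) - 1) > 1e-8))
    stop("phi matrix must have a unit diagonal")
  phiMat[is.na(phiMat)] <- 0
  1 / rowSums(phiMat^2)
}

#' Uniqueness-weighted diversity (effective number)
#'
#' The diversity of an entity is the sum of uniqueness weights over its
#' members: pi = sum_{t in members} u_t, the effective (non-redundant)
#' count. Adding a member never decreases pi, and replacing one member by k
#' perfect copies leaves pi unchanged.
#'
#' @param members character vector of member entities.
#' @param u named uniqueness vector from [uniqueness()].
#' @return the effective number (0 for no members).
#' @export
diversityIndex <- function(members, u) {
  members <- unique(members)
  if (!length(members)) return(0)
  if (!all(members %in% names(u)))
    stop("unknown entities: ",
         paste(utils::head(setdiff(members, names(u)), 3L), collapse = ", "))
  sum(u[members])
}

#' Per-TF diversity profiles
#'
#' Builds the Table-style diversity profile for every TF in the compendium:
#' raw and effective numbers of upstream regulators (TF uniqueness from the
#' TG-sharing phi matrix), of significant target functions per source and in
#' total (term uniqueness from the member-gene phi matrix within each
#' source), and of known functions, plus the number of TGs.
#'
#' @param compendium a [Compendium-class].
#' @param associations an [annotateTFs()] table.
#' @param collections named list of [AnnotationCollection-class].
#' @param genes gene table.
#' @param universe gene universe for the TF-TF phi matrix and the per-source
#'   term phi matrices (default coding).
#' @return data.frame, one row per TF: tf, n_TG, n_Reg, pi_Reg,
#'   n_TargetFun_<source>, pi_TargetFun_<source>, n_TargetFun, pi_TargetFun,
#'   n_KnownFun, pi_KnownFun.
#' @export
diversityProfiles <- function(compendium, associations, collections, genes,
                              universe = buildUniverse(genes, "coding")) {
  sets <- tgSets(compendium)
  tfs <- names(sets)
  uTF <- uniqueness(phiMatrix(sets, universe))
  edges <- edgeTable(compendium)
  regsOf <- split(edges$tf, edges$tg)

  # per-source term uniqueness from member-gene overlaps
  uTerm <- list()
  for (cl in collections) {
    ss <- geneSets(cl)
    if (!length(ss)) next
    keys <- paste(collectionName(cl), names(ss), sep = "/")
    names(ss) <- keys
    uTerm[[collectionName(cl)]] <- uniqueness(phiMatrix(ss, universe))
  }
  sig <- associations[associations$significant &
                      associations$direction == "positive", , drop = FALSE]
  known <- knownFunctionSets(collections, tfs)

  srcNames <- vapply(collections, collectionName, character(1))
  rows <- lapply(tfs, function(tf) {
    row <- list(tf = tf, n_TG = length(sets[[tf]]))
    regs <- unique(regsOf[[tf]])
    row$n_Reg <- length(regs)
    row$pi_Reg <- diversityIndex(intersect(regs, names(uTF)), uTF)
    totN <- 0L; totPi <- 0
    for (s in srcNames) {
      terms <- sig$term[sig$tf == tf & sig$source == s]
      keys <- paste(s, unique(terms), sep = "/")
      n <- length(unique(terms))
      pi <- if (n && !is.null(uTerm[[s]]))
        diversityIndex(keys, uTerm[[s]]) else 0
      row[[paste0("n_TargetFun_", s)]] <- n
      row[[paste0("pi_TargetFun_", s)]] <- pi
      totN <- totN + n; totPi <- totPi + pi
    }
    row$n_TargetFun <- totN
    row$pi_TargetFun <- totPi
    kf <- known[[tf]] %||% character()
    row$n_KnownFun <- length(kf)
    # known-function diversity: per-source term uniqueness, summed
    kpi <- 0
    for (s in srcNames) {
      ks <- kf[startsWith(kf, paste0(s, "/"))]
      if (length(ks) && !is.null(uTerm[[s]]))
        kpi <- kpi + diversityIndex(ks, uTerm[[s]])
    }
    row$pi_KnownFun <- kpi
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regulator diversity of every target gene
#'
#' For each gene in the compendium's TG roster: the number of TFs regulating
#' it and the effective (uniqueness-weighted) number.
#'
#' @param compendium a [Compendium-class].
#' @param universe gene universe for the TF-TF phi matrix.
#' @return data.frame: gene_id, n_Reg, pi_Reg.
#' @export
regulatorDiversity <- function(compendium, universe) {
  sets <- tgSets(compendium)
  uTF <- uniqueness(phiMatrix(sets, universe))
  edges <- edgeTable(compendium)
  regsOf <- lapply(split(edges$tf, edges$tg), unique)
  data.frame(gene_id = names(regsOf),
             n_Reg = lengths(regsOf),
             pi_Reg = vapply(regsOf, function(r)
               diversityIndex(intersect(r, names(uTF)), uTF), numeric(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Association between pleiotropy and a predictor with covariate control
#'
#' Ordinary least-squares fit of \code{response ~ predictor + covariates}
#' with the Wald t statistic and two-sided p-value for the predictor
#' coefficient (the linear-model control for confounders such as the number
#' of TGs per TF), plus the Spearman rank-correlation variant.
#'
#' @param data data.frame of per-entity measures (e.g.
#'   [diversityProfiles()]).
#' @param response,predictor column names.
#' @param covariates character vector of covariate column names.
#' @return list with estimate, t, p, spearmanRho, spearmanP, n, fit.
#' @export
pleiotropyAssociation <- function(data, response, predictor,
                                  covariates = character()) {
  cols <- c(response, predictor, covariates)
  if (!all(cols %in% names(data)))
    stop("missing columns: ",
         paste(setdiff(cols, names(data)), collapse = ", "))
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  if (nrow(d) < 10L) stop("need at least 10 complete observations")
  if (stats::var(d[[predictor]]) == 0)
    stop("predictor '", predictor, "' has zero variance")
  fml <- stats::reformulate(c(predictor, covariates), response)
  fit <- stats::lm(fml, data = d)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("collinear design: coefficient not estimable for ",
         paste(bad, collapse = ", "))
  }
  cf <- summary(fit)$coefficients
  sp <- suppressWarnings(
    stats::cor.test(d[[response]], d[[predictor]], method = "spearman"))
  list(estimate = cf[predictor, "Estimate"],
       t = cf[predictor, "t value"],
       p = cf[predictor, "Pr(>|t|)"],
       spearmanRho = unname(sp$estimate), spearmanP = sp$p.value,
       n = nrow(d), fit = fit)
}

#' TF-TF regulatory network
#'
#' Directed igraph of the compendium edges whose target is itself a TF,
#' with the full TF roster as vertices.
#'
#' @param compendium a [Compendium-class].
#' @return an igraph object.
#' @export
tfNetwork <- function(compendium) {
  e <- edgeTable(compendium)
  tfs <- sort(unique(e$tf))
  ee <- e[e$tg %in% tfs, c("tf", "tg"), drop = FALSE]
  igraph::graph_from_data_frame(ee, directed = TRUE,
                                vertices = data.frame(name = tfs))
}

#' PageRank scores of TFs
#'
#' Standard PageRank with uniform teleportation on the TF-TF regulatory
#' network; measures the hierarchical location of each TF. Scores sum to 1.
#'
#' @param x a [Compendium-class] or an igraph object.
#' @param damping damping factor (default 0.85).
#' @return named numeric vector of scores.
#' @export
pageRankScores <- function(x, damping = 0.85) {
  g <- if (is(x, "Compendium")) tfNetwork(x) else x
  if (igraph::vcount(g) == 0L) stop("empty graph")
  igraph::page_rank(g, damping = damping)$vector
}
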