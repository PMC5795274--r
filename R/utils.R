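#' Derive a per-component substream seed
#'
#' Expands one master seed into independent, stable substreams keyed by a
#' component label, so adding a new generator never perturbs the random
#' output of existing ones. The derived seed is kept within 32-bit integer
#' range.
#'
#' @param seed integer master seed.
#' @param component character label of the consuming component.
#' @return A single integer seed.
#' @export
substreamSeed <- function(seed, component) {
  stopifnot(length(component) == 1L, is.character(component))
  h <- 0
  for (ch in utf8ToInt(component)) h <- (h * 131 + ch) %% 2147483629
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h) %% 2147483399)
}

withSubstream <- function(seed, component, code) {
  withr::with_seed(substreamSeed(seed, component), code)
}

#' Validate a 2x2 contingency table argument
#'
#' Accepts a named or positional numeric vector (n11, n10, n01, n00) or a
#' 2x2 matrix (rows: first variable yes/no; columns: second variable
#' yes/no) and returns the canonical named count vector.
#'
#' @param table the table in either form.
#' @return named numeric vector c(n11, n10, n01, n00).
#' @keywords internal
as2x2 <- function(table) {
  if (is.matrix(table)) {
    stopifnot(identical(dim(table), c(2L, 2L)))
    table <- c(n11 = table[1, 1], n10 = table[1, 2],
               n01 = table[2, 1], n00 = table[2, 2])
  }
  if (length(table) != 4L) stop("a 2x2 table needs exactly four counts")
  if (anyNA(table) || any(table < 0)) stop("counts must be non-negative")
  nm <- c("n11", "n10", "n01", "n00")
  if (!is.null(names(table)) && all(nm %in% names(table))) table <- table[nm]
  names(table) <- nm
  table
}
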