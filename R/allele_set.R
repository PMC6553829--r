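#' Construct a set of alleles with intrinsic merits and recognition patterns
#'
#' An allele set is the basic input of all fitness models in this package.
#' Each allele \eqn{A_i} has an intrinsic merit \eqn{w_i \in [0,1]}, the
#' fitness of the homozygote carrying two copies of it.  For the divergent
#' allele advantage (DAA) model each allele additionally carries a binary
#' epitope-recognition pattern over \eqn{l_S} abstract epitope sets: entry
#' \code{TRUE} means the allele recognizes that epitope set.  When patterns
#' are present the merit is, by definition, the recognized fraction
#' \eqn{w_i = m(A_i)/l_S} where \eqn{m(A_i)} is the number of recognized
#' sites; merits supplied alongside patterns are checked against this and
#' recomputed from the patterns (with a warning) if they disagree, since the
#' pattern is the mechanistic object.
#'
#' @param merits numeric vector of intrinsic merits in \[0, 1\] (one per
#'   allele).  May be omitted when `patterns` is given.
#' @param patterns optional logical (or 0/1) matrix, alleles in rows, epitope
#'   sites in columns.
#' @param ids optional character vector of allele identifiers; defaults to
#'   `A1, A2, ...`.
#' @return An object of class `allele_set`: a list with elements `merits`,
#'   `patterns` (logical matrix or `NULL`), `ids`, `k` (allele count) and
#'   `ls` (number of epitope sites, `NA` without patterns).
#' @examples
#' allele_set(merits = c(0.8, 0.7, 0.1))
#' pats <- rbind(A = c(1,1,0,0), B = c(0,0,1,1)) > 0
#' allele_set(patterns = pats)
#' @export
allele_set <- function(merits = NULL, patterns = NULL, ids = NULL) {
  if (is.null(merits) && is.null(patterns))
    stop("supply `merits`, `patterns`, or both")
  if (!is.null(patterns)) {
    if (!is.matrix(patterns))
      patterns <- matrix(patterns, nrow = max(length(merits), 1L), byrow = TRUE)
    storage.mode(patterns) <- "logical"
    if (anyNA(patterns)) stop("patterns must not contain NA")
    k <- nrow(patterns)
    ls <- ncol(patterns)
    if (ls < 1L) stop("patterns must have at least one site")
    pattern_merits <- rowSums(patterns) / ls
    if (!is.null(merits)) {
      if (length(merits) != k)
        stop("length of `merits` (", length(merits),
             ") does not match number of pattern rows (", k, ")")
      if (any(abs(merits - pattern_merits) > 1e-12)) {
        warning("supplied merits disagree with recognized fractions; ",
                "merits recomputed from patterns")
      }
    }
    merits <- pattern_merits
  } else {
    merits <- as.numeric(merits)
    k <- length(merits)
    ls <- NA_integer_
  }
  if (k < 1L) stop("allele set must contain at least one allele")
  if (any(!is.finite(merits)) || any(merits < 0) || any(merits > 1))
    stop("intrinsic merits must be finite and lie in [0, 1]")
  if (is.null(ids)) {
    ids <- if (!is.null(patterns) && !is.null(rownames(patterns)))
      rownames(patterns) else paste0("A", seq_len(k))
  }
  if (length(ids) != k) stop("`ids` must have one entry per allele")
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("allele ids must be unique")
  if (!is.null(patterns)) rownames(patterns) <- ids
  structure(
    list(merits = unname(merits), patterns = patterns, ids = ids,
         k = k, ls = if (is.na(ls)) NA_integer_ else as.integer(ls)),
    class = "allele_set"
  )
}

#' @export
print.allele_set <- function(x, ...) {
  cat("Allele set with", x$k, "allele(s)")
  if (!is.na(x$ls)) cat(" over", x$ls, "epitope sites")
  cat("\n")
  show <- utils::head(seq_len(x$k), 10L)
  df <- data.frame(id = x$ids[show], merit = signif(x$merits[show], 6))
  if (!is.null(x$patterns))
    df$recognized <- as.integer(rowSums(x$patterns))[show]
  print(df, row.names = FALSE)
  if (x$k > 10L) cat("... and", x$k - 10L, "more\n")
  invisible(x)
}

#' Order an allele set by nonincreasing intrinsic merit
#'
#' The convention in the overdominance literature indexes alleles so that
#' \eqn{w_1 \ge w_2 \ge \dots \ge w_k}.  No function in this package sorts
#' silently; call this explicitly when that ordering is wanted.
#'
#' @param x an [allele_set].
#' @param decreasing sort nonincreasing (default) or nondecreasing.
#' @return the reordered `allele_set`.
#' @export
sort_alleles <- function(x, decreasing = TRUE) {
  stopifnot(inherits(x, "allele_set"))
  ord <- order(x$merits, decreasing = decreasing)
  allele_set(
    merits = if (is.null(x$patterns)) x$merits[ord] else NULL,
    patterns = if (is.null(x$patterns)) NULL else x$patterns[ord, , drop = FALSE],
    ids = x$ids[ord]
  )
}

#' Read and write recognition-pattern files
#'
#' Plain-text CSV with one row per allele: first column the allele ID, then
#' one 0/1 column per epitope site named `site_1 ... site_lS`.
#'
#' @param file path to a CSV file.
#' @return `read_patterns()` returns an [allele_set]; `write_patterns()`
#'   returns `file` invisibly.
#' @export
read_patterns <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("pattern file needs an ID column plus site columns")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!all(m %in% c(0, 1)))
    stop("pattern cells must be 0 or 1 in ", file)
  allele_set(patterns = m > 0, ids = ids)
}

#' @param alleles an [allele_set] with patterns.
#' @rdname read_patterns
#' @export
write_patterns <- function(alleles, file) {
  stopifnot(inherits(alleles, "allele_set"))
  if (is.null(alleles$patterns)) stop("allele set has no recognition patterns")
  df <- data.frame(allele = alleles$ids,
                   matrix(as.integer(alleles$patterns), nrow = alleles$k),
                   check.names = FALSE)
  names(df) <- c("allele", paste0("site_", seq_len(alleles$ls)))
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

as_allele_set <- function(x) {
  if (inherits(x, "allele_set")) x else allele_set(merits = x)
}
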