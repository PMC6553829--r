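#' Genotype fitness matrices
#'
#' A genotype fitness matrix \eqn{F = (f_{ij})} gives the viability of every
#' genotype \eqn{A_i A_j} at a single autosomal locus.  It is symmetric, has
#' the intrinsic merits on its diagonal (\eqn{f_{ii} = w_i}) and all entries
#' in \[0, 1\]: 0 is a non-viable genotype, 1 one fully protected against all
#' pathogens.  `fitness_matrix()` validates and classes a user-supplied
#' matrix; the model constructors below build the three overdominance models.
#'
#' @param values numeric square matrix of genotype fitnesses.
#' @param model tag recording how the matrix was built; one of
#'   `"custom"`, `"symmetric"`, `"ao"`, `"daa"`.
#' @param ids optional allele identifiers used as dimnames.
#' @return a matrix of class `fitness_matrix` with a `model` attribute.
#' @examples
#' fitness_ao(c(0.8, 0.7, 0.1))
#' @export
fitness_matrix <- function(values, model = c("custom", "symmetric", "ao", "daa"),
                           ids = NULL) {
  model <- match.arg(model)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("fitness matrix must be square")
  if (nrow(values) < 1L) stop("fitness matrix must be at least 1 x 1")
  if (any(!is.finite(values))) stop("fitness values must be finite")
  if (!isSymmetric(unname(values), tol = 1e-12))
    stop("fitness matrix must be symmetric (f_ji = f_ij)")
  if (any(values < -1e-12) || any(values > 1 + 1e-12))
    stop("genotype fitnesses must lie in [0, 1]")
  values[] <- pmin(pmax(values, 0), 1)
  if (is.null(ids)) {
    ids <- if (!is.null(rownames(values))) rownames(values)
           else paste0("A", seq_len(nrow(values)))
  }
  dimnames(values) <- list(ids, ids)
  structure(values, model = model, class = c("fitness_matrix", "matrix", "array"))
}

#' @export
print.fitness_matrix <- function(x, ...) {
  cat("Genotype fitness matrix (", attr(x, "model"), " model, k = ",
      nrow(x), ")\n", sep = "")
  k <- nrow(x)
  show <- seq_len(min(k, 8L))
  print(round(unclass(x)[show, show, drop = FALSE], 4))
  if (k > 8L) cat("... truncated to the first 8 alleles\n")
  invisible(x)
}

#' Intrinsic merits of a fitness matrix
#'
#' The diagonal \eqn{f_{ii} = w_i}: the fitness of each homozygote.
#'
#' @param f a [fitness_matrix].
#' @return numeric vector of intrinsic merits.
#' @export
merits <- function(f) {
  stopifnot(inherits(f, "fitness_matrix"))
  diag(unclass(f))
}

#' Symmetric overdominance fitness matrix
#'
#' Every heterozygote has fitness 1 (full protection), so any allele with
#' merit below 1 enjoys a heterozygote advantage.  This model maintains all
#' alleles regardless of their merits, which is one reason it is not a
#' plausible mechanism for observed MHC-type diversity; it is provided for
#' comparison and for the invariant tests.
#'
#' @param alleles an [allele_set] or a numeric vector of intrinsic merits.
#' @return a [fitness_matrix] with model tag `"symmetric"`.
#' @export
fitness_symmetric <- function(alleles) {
  a <- as_allele_set(alleles)
  if (any(a$merits >= 1))
    warning("some merits equal 1: those alleles are not overdominant")
  f <- matrix(1, a$k, a$k)
  diag(f) <- a$merits
  fitness_matrix(f, model = "symmetric", ids = a$ids)
}

#' Asymmetric overdominance (AO) fitness matrix
#'
#' Heterozygote fitness combines the protective contributions of the two
#' alleles and discounts an average overlap:
#' \deqn{f_{ij} = w_i + w_j - w_i w_j, \quad i \ne j.}
#' For \eqn{0 < w_i, w_j < 1} this satisfies
#' \eqn{\max(w_i, w_j) < f_{ij} < 1}, i.e. genuine overdominance with
#' heterozygote fitnesses strictly ordered by the underlying merits.
#'
#' @inheritParams fitness_symmetric
#' @return a [fitness_matrix] with model tag `"ao"`.
#' @examples
#' f <- fitness_ao(c(0.8, 0.7, 0.1))
#' f[1, 2]  # 0.94
#' @export
fitness_ao <- function(alleles) {
  a <- as_allele_set(alleles)
  w <- a$merits
  f <- outer(w, w, function(x, y) x + y - x * y)
  diag(f) <- w
  fitness_matrix(f, model = "ao", ids = a$ids)
}

#' Divergent allele advantage (DAA) fitness matrix
#'
#' MHC genes are codominantly expressed, so a heterozygote recognizes an
#' epitope set if either of its alleles does.  The fitness of genotype
#' \eqn{A_i A_j} is therefore the fraction of the \eqn{l_S} epitope sets in
#' the union of the two recognition patterns.  Unlike the AO model the
#' overlap is a property of the specific allele pair: two alleles of low
#' merit with complementary patterns can form a highly fit heterozygote.
#' Bounds: \eqn{\max(w_i, w_j) \le f_{ij} \le \min(1, w_i + w_j)}.
#'
#' @inheritParams fitness_symmetric
#' @param alleles an [allele_set] that carries recognition patterns.
#' @return a [fitness_matrix] with model tag `"daa"`.
#' @examples
#' pats <- rbind(A1 = c(0,1,1,1,1,1,1,1,1,0),
#'               A2 = c(1,1,1,1,1,1,1,0,0,0)) > 0
#' fitness_daa(allele_set(patterns = pats))[1, 2]  # 0.9
#' @export
fitness_daa <- function(alleles) {
  if (!inherits(alleles, "allele_set"))
    stop("the DAA model needs an `allele_set` with recognition patterns")
  if (is.null(alleles$patterns))
    stop("the DAA model needs recognition patterns; none present")
  r <- pattern_intersect_counts(alleles$patterns)
  m <- diag(r)
  u <- outer(m, m, `+`) - r          # |union| = m_i + m_j - |intersection|
  f <- u / alleles$ls
  fitness_matrix(f, model = "daa", ids = alleles$ids)
}

#' Pairwise epitope-recognition overlap fractions
#'
#' \eqn{g_{ij} = r_{ij} / l_S}, the fraction of epitope sets recognized by
#' both alleles of a pair; \eqn{g_{ii} = w_i}.
#'
#' @param alleles an [allele_set] with patterns.
#' @return symmetric k x k numeric matrix of overlap fractions.
#' @export
overlap_matrix <- function(alleles) {
  stopifnot(inherits(alleles, "allele_set"))
  if (is.null(alleles$patterns)) stop("allele set has no recognition patterns")
  r <- pattern_intersect_counts(alleles$patterns)
  g <- r / alleles$ls
  dimnames(g) <- list(alleles$ids, alleles$ids)
  g
}

#' Stability threshold of the AO model
#'
#' In the AO model all k alleles persist at equilibrium if and only if every
#' intrinsic merit exceeds the threshold
#' \deqn{t = \frac{k-1}{k}\,\hat w,}
#' where \eqn{\hat w} is the harmonic mean of the merits.  The harmonic mean
#' is undefined when any merit is zero, which is reported as an error.
#'
#' @inheritParams fitness_symmetric
#' @return object of class `ao_stability`: list with `threshold`,
#'   `harmonic_mean`, `stable` (all merits above the threshold), `k` and
#'   `merits`.
#' @examples
#' ao_threshold(c(0.8, 0.7, 0.1))  # t ~ 0.158, unstable
#' @export
ao_threshold <- function(alleles) {
  a <- as_allele_set(alleles)
  w <- a$merits
  if (any(w == 0))
    stop("harmonic mean undefined: at least one intrinsic merit is zero")
  k <- a$k
  hm <- k / sum(1 / w)
  t <- (k - 1) / k * hm
  structure(
    list(threshold = t, harmonic_mean = hm, stable = min(w) > t,
         k = k, merits = w),
    class = "ao_stability"
  )
}

#' @export
print.ao_stability <- function(x, ...) {
  cat("AO stability threshold: t =", signif(x$threshold, 6),
      "(harmonic mean", signif(x$harmonic_mean, 6), ", k =", x$k, ")\n")
  cat(if (x$stable) "All" else "Not all",
      "merits exceed t: the full k-allele polymorphism is",
      if (x$stable) "stable.\n" else "NOT stable.\n")
  invisible(x)
}

#' Read and write genotype fitness matrices
#'
#' CSV with a header and a leading column of allele IDs; row and column
#' labels must agree.
#'
#' @param file path to a CSV file.
#' @param model model tag to attach on read (default `"custom"`).
#' @return `read_fitness()` returns a [fitness_matrix]; `write_fitness()`
#'   returns `file` invisibly.
#' @export
read_fitness <- function(file, model = "custom") {
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("fitness file needs an ID column plus value columns")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m))
    stop("fitness matrix in ", file, " is not square (", nrow(m), " rows, ",
         ncol(m), " value columns)")
  if (!identical(ids, colnames(m)))
    stop("row and column allele IDs disagree in ", file)
  rownames(m) <- ids
  fitness_matrix(m, model = model)
}

#' @param f a [fitness_matrix].
#' @rdname read_fitness
#' @export
write_fitness <- function(f, file) {
  stopifnot(inherits(f, "fitness_matrix"))
  df <- data.frame(allele = rownames(f), unclass(f), check.names = FALSE)
  names(df) <- c("allele", colnames(f))
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
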