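#' Average overdominance at equilibrium
#'
#' Overdominance (heterozygote advantage) is the relative excess of mean
#' heterozygote fitness over mean homozygote fitness at equilibrium,
#' \deqn{\bar h = (\bar w_{het} - \bar w_{hom}) / \bar w_{hom},}
#' with the per-allele analogue
#' \eqn{h_i = (w_{het,i} - w_{hom,i}) / w_{hom,i}}.  With the default
#' `weighted = TRUE` the class means use Hardy--Weinberg genotype frequencies
#' at the equilibrium, renormalized within the heterozygote and homozygote
#' classes; `weighted = FALSE` uses plain (unweighted) means of the matrix
#' entries, for sensitivity analysis.
#'
#' @param f a [fitness_matrix].
#' @param eq a stable `allele_equilibrium` for `f`.
#' @param weighted use Hardy--Weinberg genotype-frequency weights (default).
#' @return list with `h_bar` (scalar, `NA` with a single survivor) and `h_i`
#'   (per-survivor vector, named by allele id).
#' @export
overdominance <- function(f, eq, weighted = TRUE) {
  f <- as_fitness(f)
  stopifnot(inherits(eq, "allele_equilibrium"))
  if (eq$status != "stable") stop("overdominance needs a stable equilibrium")
  s <- eq$surviving
  p <- eq$proportions[s]
  fs <- unclass(f)[s, s, drop = FALSE]
  w <- diag(fs)
  if (any(w == 0)) stop("homozygote fitness zero: overdominance undefined")
  n <- length(s)
  if (n == 1L)
    return(list(h_bar = NA_real_, h_i = stats::setNames(NA_real_, eq$ids[s])))
  if (weighted) {
    pp <- outer(p, p)
    het_mass <- 1 - sum(p^2)
    whet <- (sum(pp * fs) - sum(p^2 * w)) / het_mass
    whom <- sum(p^2 * w) / sum(p^2)
    whet_i <- (drop(fs %*% p) - w * p) / (1 - p)
  } else {
    whet <- mean(fs[upper.tri(fs)])
    whom <- mean(w)
    whet_i <- (rowSums(fs) - w) / (n - 1)
  }
  h_i <- (whet_i - w) / w
  list(h_bar = (whet - whom) / whom,
       h_i = stats::setNames(h_i, eq$ids[s]))
}

#' Average epitope-recognition overlap at equilibrium
#'
#' The pairwise overlap \eqn{g_{ij} = r_{ij}/l_S} is the fraction of epitope
#' sets recognized by both alleles.  The average overlap of allele \eqn{A_i}
#' with the rest of the gene pool weights its partners by their equilibrium
#' proportions,
#' \deqn{g_i = \sum_{j \ne i} p_j\, g_{ij} / (1 - p_i),}
#' (the self term is excluded; the \eqn{1/(1-p_i)} factor renormalizes the
#' partner weights), and the weighted mean overlap of the pool is
#' \eqn{\bar g = \sum_i p_i g_i}.
#'
#' @param alleles an [allele_set] with patterns (the full initial set).
#' @param eq a stable `allele_equilibrium` over the same alleles.
#' @return list with `g_i` (per-survivor, named), `g_bar`, and `g_matrix`
#'   (pairwise overlap fractions among survivors).
#' @export
overlap <- function(alleles, eq) {
  stopifnot(inherits(alleles, "allele_set"), inherits(eq, "allele_equilibrium"))
  if (is.null(alleles$patterns)) stop("allele set has no recognition patterns")
  if (eq$status != "stable") stop("overlap needs a stable equilibrium")
  if (alleles$k != eq$k) stop("allele set and equilibrium sizes disagree")
  s <- eq$surviving
  p <- eq$proportions[s]
  sub <- allele_set(patterns = alleles$patterns[s, , drop = FALSE],
                    ids = alleles$ids[s])
  g <- overlap_matrix(sub)
  overlap_summary(g, p, alleles$ids[s])
}

# g: pairwise overlap fractions among survivors; p their proportions.
overlap_summary <- function(g, p, ids) {
  n <- length(p)
  if (n == 1L) {
    g_i <- stats::setNames(NA_real_, ids)
    return(list(g_i = g_i, g_bar = NA_real_, g_matrix = g))
  }
  g_i <- (drop(g %*% p) - diag(g) * p) / (1 - p)
  g_i[p >= 1] <- NA_real_   # degenerate weight for a fixed allele
  g_i <- stats::setNames(g_i, ids)
  list(g_i = g_i, g_bar = sum(p * g_i), g_matrix = g)
}

#' Persisting-allele count and intrinsic-merit range
#'
#' `allele_count()` is the number of alleles with positive equilibrium
#' proportion; `merit_range()` is the difference between the largest and
#' smallest intrinsic merit among them (0 for a single survivor).  Merits are
#' taken from the allele set, i.e. the quantized values when patterns are
#' present, so ranges are exact multiples of \eqn{1/l_S}.
#'
#' @param alleles an [allele_set].
#' @param eq a stable `allele_equilibrium`.
#' @return scalar.
#' @export
merit_range <- function(alleles, eq) {
  alleles <- as_allele_set(alleles)
  stopifnot(inherits(eq, "allele_equilibrium"))
  if (eq$status != "stable") stop("merit_range needs a stable equilibrium")
  w <- alleles$merits[eq$surviving]
  max(w) - min(w)
}

#' @rdname merit_range
#' @export
allele_count <- function(eq) {
  stopifnot(inherits(eq, "allele_equilibrium"))
  length(eq$surviving)
}

#' All equilibrium summary metrics as one row
#'
#' Convenience wrapper collecting [allele_count()], [merit_range()],
#' [overdominance()], the population fitness and (optionally) the overlap
#' summaries into a one-row data frame, the per-repeat record of the
#' simulation experiments.  `r_equil_sites` is the merit range counted in
#' sites (an integer when patterns are present), which makes cross-model
#' range comparisons exact.
#'
#' @param alleles an [allele_set].
#' @param f the [fitness_matrix] the equilibrium was computed from.
#' @param eq a stable `allele_equilibrium`.
#' @param compute_overlap also compute the overlap summaries (requires
#'   patterns or a precomputed overlap matrix `g`).
#' @param weighted passed to [overdominance()].
#' @param g optional precomputed full k x k pairwise overlap-fraction matrix
#'   (as from [overlap_matrix()]); used instead of the patterns.
#' @param ls epitope-sequence length, needed for the site-count range when
#'   the allele set carries no patterns.
#' @return one-row data.frame.
#' @export
equilibrium_metrics <- function(alleles, f, eq, compute_overlap = FALSE,
                                weighted = TRUE, g = NULL, ls = NULL) {
  alleles <- as_allele_set(alleles)
  if (is.null(ls)) ls <- alleles$ls
  od <- overdominance(f, eq, weighted = weighted)
  rng <- merit_range(alleles, eq)
  out <- data.frame(
    n_equil = allele_count(eq),
    r_equil = rng,
    r_equil_sites = if (!is.na(ls)) as.integer(round(rng * ls))
                    else NA_integer_,
    h_bar = od$h_bar,
    w_bar = eq$population_fitness,
    min_merit = min(alleles$merits[eq$surviving]),
    max_merit = max(alleles$merits[eq$surviving])
  )
  if (compute_overlap) {
    ov <- if (!is.null(g)) {
      s <- eq$surviving
      overlap_summary(g[s, s, drop = FALSE], eq$proportions[s],
                      alleles$ids[s])
    } else overlap(alleles, eq)
    gi <- ov$g_i[!is.na(ov$g_i)]
    qs <- if (length(gi)) stats::quantile(gi, c(0.01, 0.02, 0.05, 0.10),
                                          names = FALSE, type = 7)
          else rep(NA_real_, 4)
    out$g_bar <- ov$g_bar
    out$g_min <- if (length(gi)) min(gi) else NA_real_
    out$g_p01 <- qs[1]; out$g_p02 <- qs[2]; out$g_p05 <- qs[3]; out$g_p10 <- qs[4]
  }
  out
}
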