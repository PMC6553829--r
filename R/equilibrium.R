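#' Marginal and population fitness
#'
#' For allele proportions `p` and genotype fitness matrix `F`, the marginal
#' fitness of allele \eqn{A_i} is the genotype-frequency-weighted mean
#' fitness of the genotypes carrying it, \eqn{w_i^{(m)}(p) = (Fp)_i}, and the
#' population fitness is the weighted mean of the marginals,
#' \eqn{\bar w(p) = p'Fp}.
#'
#' @param f a [fitness_matrix] (or plain symmetric matrix).
#' @param p numeric vector of allele proportions (nonnegative, summing to 1).
#' @return `marginal_fitness()`: numeric vector; `population_fitness()`:
#'   scalar.
#' @export
marginal_fitness <- function(f, p) {
  f <- as_fitness(f)
  check_simplex(p, nrow(f))
  drop(unclass(f) %*% p)
}

#' @rdname marginal_fitness
#' @export
population_fitness <- function(f, p) {
  f <- as_fitness(f)
  check_simplex(p, nrow(f))
  drop(crossprod(p, unclass(f) %*% p))
}

#' One generation of deterministic viability selection
#'
#' Discrete, non-overlapping generations with random mating (Hardy--Weinberg
#' genotype frequencies) in an effectively infinite population:
#' \deqn{p_i(t+1) = p_i(t)\, w_i^{(m)}(p(t)) / \bar w(p(t)).}
#' Along these trajectories the population fitness is nondecreasing for a
#' symmetric fitness matrix.
#'
#' @inheritParams marginal_fitness
#' @return the allele proportions of the next generation (sums to 1).
#' @export
step_dynamics <- function(f, p) {
  f <- as_fitness(f)
  check_simplex(p, nrow(f))
  wm <- drop(unclass(f) %*% p)
  wbar <- sum(p * wm)
  if (wbar <= 0) stop("degenerate population: population fitness is zero")
  out <- p * wm / wbar
  out / sum(out)
}

#' Equilibrium allele proportions by linear solve with elimination
#'
#' At a polymorphic equilibrium every persisting allele has marginal fitness
#' equal to the population fitness, so the equilibrium proportions solve the
#' linear system \eqn{F x = u} (u a vector of ones) after normalization.
#' Alleles with nonpositive solution entries cannot persist: they are removed
#' and the system is re-solved on the remaining principal submatrix until all
#' entries are strictly positive.  If the final principal submatrix
#' \eqn{\hat F} is singular the equilibrium is not guaranteed globally stable
#' and the result is flagged `status = "singular"` (callers typically discard
#' it and redraw the allele set); otherwise the normalized solution is the
#' unique equilibrium toward which population fitness increases from any
#' interior starting point.
#'
#' @param f a [fitness_matrix] (or plain symmetric numeric matrix).
#' @param eliminate `"all"` removes every allele with a nonpositive solution
#'   entry each round (default); `"one"` removes only the most negative one
#'   per round, for sensitivity checks.
#' @param rcond_tol reciprocal-condition-number threshold below which the
#'   final submatrix is declared singular (default `sqrt(.Machine$double.eps)`).
#' @return object of class `allele_equilibrium`: list with
#'   \describe{
#'     \item{proportions}{full-length vector of equilibrium proportions
#'       (zero for eliminated alleles);}
#'     \item{surviving}{integer indices of persisting alleles;}
#'     \item{population_fitness}{\eqn{\bar w(p^*)};}
#'     \item{marginal}{marginal fitnesses at the equilibrium;}
#'     \item{eliminations}{list of the allele indices removed in each round;}
#'     \item{status}{`"stable"`, `"singular"` or `"degenerate"`;}
#'     \item{method}{`"linear_solve"` here, `"time_step"` from
#'       [iterate_to_convergence()].}
#'   }
#' @examples
#' f <- fitness_matrix(rbind(c(0.8, 0.9, 0.9),
#'                           c(0.9, 0.7, 0.8),
#'                           c(0.9, 0.8, 0.1)))
#' solve_equilibrium(f)  # proportions 15/23, 7/23, 1/23
#' @export
solve_equilibrium <- function(f, eliminate = c("all", "one"),
                              rcond_tol = sqrt(.Machine$double.eps)) {
  eliminate <- match.arg(eliminate)
  f <- as_fitness(f)
  fm <- unclass(f)
  k <- nrow(fm)
  ids <- rownames(fm)

  active <- seq_len(k)
  eliminations <- list()
  x <- NULL
  singular <- FALSE
  while (length(active) > 0L) {
    fhat <- fm[active, active, drop = FALSE]
    x <- tryCatch(solve(fhat, rep(1, length(active))),
                  error = function(e) NULL)
    if (is.null(x)) { singular <- TRUE; break }
    neg <- which(x <= 0)
    if (length(neg) == 0L) break
    drop_idx <- if (eliminate == "all") neg else neg[which.min(x[neg])]
    eliminations <- c(eliminations, list(active[drop_idx]))
    active <- active[-drop_idx]
  }

  res <- list(proportions = stats::setNames(numeric(k), ids),
              surviving = integer(0),
              population_fitness = NA_real_,
              marginal = stats::setNames(rep(NA_real_, k), ids),
              eliminations = eliminations,
              status = "degenerate",
              method = "linear_solve",
              k = k, ids = ids)
  class(res) <- "allele_equilibrium"
  if (length(active) == 0L) return(res)
  if (!singular) {
    fhat <- fm[active, active, drop = FALSE]
    if (rcond(fhat) < rcond_tol) singular <- TRUE
  }
  if (singular) {
    res$status <- "singular"
    return(res)
  }
  p <- numeric(k)
  p[active] <- x / sum(x)
  res$proportions[] <- p
  res$surviving <- active
  res$marginal[] <- drop(fm %*% p)
  res$population_fitness <- sum(p * res$marginal)
  res$status <- "stable"
  res
}

#' Equilibrium by iterating the generation map
#'
#' Runs the discrete-generation dynamics from `p0` until the marginal
#' fitnesses of all non-vanishing alleles equal the population fitness within
#' `tol`.  This is the independent validation route for
#' [solve_equilibrium()]: for stable systems the two agree to high precision.
#' Alleles at a boundary equilibrium lose proportion only algebraically, so
#' an allele whose proportion has fallen below `vanish_tol` and is still
#' decreasing is classified as vanishing and excluded from the convergence
#' criterion; alleles below `prune` are removed outright.
#'
#' @inheritParams solve_equilibrium
#' @param p0 starting proportions; default uniform.
#' @param tol convergence tolerance on the marginal-fitness spread
#'   (default `1e-11`).
#' @param max_steps generation cap; exceeding it returns
#'   `status = "degenerate"`.
#' @param prune proportions below this are set to zero (default `1e-12`).
#' @param vanish_tol classification threshold for algebraically decaying
#'   alleles (default `1e-6`).
#' @return an `allele_equilibrium` (see [solve_equilibrium()]) with
#'   `method = "time_step"` and a `steps` element; proportions are
#'   renormalized over the surviving alleles.
#' @export
iterate_to_convergence <- function(f, p0 = NULL, tol = 1e-11,
                                   max_steps = 1e7, prune = 1e-12,
                                   vanish_tol = 1e-6) {
  f <- as_fitness(f)
  fm <- unclass(f)
  k <- nrow(fm)
  ids <- rownames(fm)
  if (is.null(p0)) p0 <- rep(1 / k, k)
  check_simplex(p0, k)
  stopifnot(tol > 0)
  out <- iterate_dynamics_cpp(fm, p0, tol, max_steps, prune, vanish_tol, 64L)

  surviving <- which(!out$vanishing & out$proportions > 0)
  p <- numeric(k)
  if (length(surviving) > 0L)
    p[surviving] <- out$proportions[surviving] / sum(out$proportions[surviving])
  eliminated <- setdiff(seq_len(k), surviving)
  res <- list(proportions = stats::setNames(p, ids),
              surviving = surviving,
              population_fitness = if (length(surviving)) sum(p * drop(fm %*% p)) else NA_real_,
              marginal = stats::setNames(drop(fm %*% p), ids),
              eliminations = if (length(eliminated)) list(eliminated) else list(),
              status = if (isTRUE(out$converged)) "stable" else "degenerate",
              method = "time_step",
              steps = out$steps,
              wbar_monotone = out$wbar_monotone,
              k = k, ids = ids)
  class(res) <- "allele_equilibrium"
  res
}

#' @export
print.allele_equilibrium <- function(x, digits = 4, ...) {
  cat("Allele equilibrium (", x$method, ", status: ", x$status, ")\n", sep = "")
  if (x$status == "stable") {
    cat(length(x$surviving), "of", x$k, "allele(s) persist; population fitness",
        signif(x$population_fitness, 6), "\n")
    p <- x$proportions[x$surviving]
    show <- utils::head(order(p, decreasing = TRUE), 10L)
    df <- data.frame(allele = names(p)[show],
                     proportion = round(p[show], digits))
    print(df, row.names = FALSE)
    if (length(p) > 10L) cat("... and", length(p) - 10L, "more\n")
  }
  invisible(x)
}

#' @export
summary.allele_equilibrium <- function(object, ...) {
  cat("Status:", object$status, " method:", object$method, "\n")
  cat("Alleles:", object$k, " surviving:", length(object$surviving), "\n")
  if (object$status == "stable") {
    cat("Population fitness:", format(object$population_fitness, digits = 12), "\n")
    spread <- max(abs(object$marginal[object$surviving] -
                        object$population_fitness))
    cat("Max |marginal - population| over survivors:",
        format(spread, digits = 3), "\n")
  }
  if (length(object$eliminations))
    cat("Elimination rounds:",
        paste(vapply(object$eliminations, length, 1L), collapse = ", "), "\n")
  invisible(object)
}

#' @export
coef.allele_equilibrium <- function(object, ...) object$proportions

#' Serialize an equilibrium result to JSON
#'
#' @param x an `allele_equilibrium`.
#' @param file optional path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `file`).
#' @export
equilibrium_json <- function(x, file = NULL) {
  stopifnot(inherits(x, "allele_equilibrium"))
  obj <- list(
    status = x$status,
    method = x$method,
    survivors = x$ids[x$surviving],
    proportions = unname(x$proportions[x$surviving]),
    population_fitness = x$population_fitness,
    eliminations = lapply(x$eliminations, function(i) x$ids[i])
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(js)
}

as_fitness <- function(f) {
  if (inherits(f, "fitness_matrix")) return(f)
  fitness_matrix(f)
}

check_simplex <- function(p, k, tol = 1e-9) {
  if (length(p) != k)
    stop("proportions have length ", length(p), " but the matrix has ", k,
         " alleles")
  if (any(!is.finite(p)) || any(p < -1e-12))
    stop("proportions must be finite and nonnegative")
  if (abs(sum(p) - 1) > tol)
    stop("proportions must sum to 1 (got ", format(sum(p)), ")")
  invisible(TRUE)
}
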