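#' The 80 simulation scenarios
#'
#' Each scenario is a quadruple: merit bounds `wmin`/`wmax`, initial allele
#' count `nini` (50, 100, 250, 500 or 1000) and the merit-resolution factor
#' `f` (2 or 10).  The eight merit ranges each appear with both values of `f`
#' and all five allele counts, giving 80 scenarios.  Scenario ids follow the
#' canonical table ordering: blocks of five allele counts, alternating
#' `f = 2` / `f = 10` within each merit range.
#'
#' @return data.frame with columns `scenario_id`, `wmin`, `wmax`, `nini`, `f`.
#' @export
scenario_table <- function() {
  ranges <- rbind(
    c(0.00, 0.10), c(0.45, 0.55), c(0.20, 0.60), c(0.30, 0.70),
    c(0.40, 0.80), c(0.10, 0.90), c(0.00, 1.00), c(0.90, 1.00)
  )
  nini <- c(50L, 100L, 250L, 500L, 1000L)
  out <- do.call(rbind, lapply(seq_len(nrow(ranges)), function(r) {
    do.call(rbind, lapply(c(2L, 10L), function(f) {
      data.frame(wmin = ranges[r, 1], wmax = ranges[r, 2], nini = nini, f = f)
    }))
  }))
  out <- cbind(scenario_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Specify a simulation scenario
#'
#' Either give a `scenario_id` from [scenario_table()] or the explicit
#' quadruple.  Two quantities are derived:
#' the edge margin \eqn{\epsilon = (w_{max}-w_{min})/(2 n_{ini})}, which
#' keeps "perfect" (w = 1) and "useless" (w = 0) alleles out of the draw,
#' and the epitope-sequence length \eqn{l_S} (see [sequence_length()]).
#'
#' @param scenario_id integer 1--80, or `NULL` to give the quadruple.
#' @param wmin,wmax intrinsic-merit bounds, `0 <= wmin < wmax <= 1`.
#' @param nini initial allele count.
#' @param f merit-resolution factor: the number of representable merits in
#'   the scenario range is at least `f` times `nini`.
#' @return object of class `scenario_spec`: list with the quadruple plus
#'   derived `eps`, `ls` and (possibly `NA`) `scenario_id`.
#' @examples
#' scenario_spec(62)  # wmin 0, wmax 1, nini 100, f 2
#' @export
scenario_spec <- function(scenario_id = NULL, wmin = NULL, wmax = NULL,
                          nini = NULL, f = NULL) {
  if (!is.null(scenario_id)) {
    tab <- scenario_table()
    if (!scenario_id %in% tab$scenario_id)
      stop("scenario_id must be an integer in 1..", nrow(tab))
    row <- tab[tab$scenario_id == scenario_id, ]
    wmin <- row$wmin; wmax <- row$wmax; nini <- row$nini; f <- row$f
  } else {
    if (is.null(wmin) || is.null(wmax) || is.null(nini) || is.null(f))
      stop("give either `scenario_id` or all of wmin, wmax, nini, f")
    scenario_id <- NA_integer_
  }
  if (!(wmin >= 0 && wmin < wmax && wmax <= 1))
    stop("need 0 <= wmin < wmax <= 1")
  if (nini < 1) stop("nini must be positive")
  if (f < 1) stop("f must be >= 1")
  spec <- list(scenario_id = as.integer(scenario_id),
               wmin = wmin, wmax = wmax,
               nini = as.integer(nini), f = as.integer(f),
               eps = (wmax - wmin) / (2 * nini))
  spec$ls <- ceiling(f * nini / (wmax - wmin))
  class(spec) <- "scenario_spec"
  spec
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Scenario", if (is.na(x$scenario_id)) "(custom)" else x$scenario_id,
      ": wmin =", x$wmin, " wmax =", x$wmax, " nini =", x$nini,
      " f =", x$f, "\n")
  cat("  derived: ls =", x$ls, " eps =", x$eps, "\n")
  invisible(x)
}

#' Epitope-sequence length for a scenario
#'
#' The sequence must be long enough that the scenario's merit range contains
#' at least `f` times `nini` representable intrinsic merits (multiples of
#' \eqn{1/l_S}), which reduces the chance of two alleles sharing a merit.
#' The minimal such length is \eqn{l_S = \lceil f\, n_{ini} / (w_{max} -
#' w_{min}) \rceil}, which guarantees
#' \eqn{(w_{max}-w_{min})\, l_S + 1 \ge f\, n_{ini}}.
#'
#' @param spec a [scenario_spec].
#' @return integer sequence length.
#' @export
sequence_length <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  spec$ls
}

#' Draw intrinsic merits for the Random experiment
#'
#' `nini` i.i.d. uniform draws on \eqn{[w_{min}+\epsilon, w_{max}-\epsilon]},
#' using the current RNG state (seed with [set.seed()] for reproducibility).
#'
#' @param spec a [scenario_spec].
#' @return numeric vector of length `nini`.
#' @export
draw_random_merits <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  stats::runif(spec$nini, min = spec$wmin + spec$eps, max = spec$wmax - spec$eps)
}

#' Evenly spaced intrinsic merits for the Fixed experiment
#'
#' `nini` evenly spaced values from \eqn{w_{min}+\epsilon} to
#' \eqn{w_{max}-\epsilon} inclusive; e.g. 0.005, 0.015, ..., 0.995 for the
#' full unit range with 100 alleles.
#'
#' @param spec a [scenario_spec].
#' @return numeric vector of length `nini`.
#' @export
fixed_merits <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$nini == 1L)
    return((spec$wmin + spec$wmax) / 2)
  seq(spec$wmin + spec$eps, spec$wmax - spec$eps, length.out = spec$nini)
}

#' Sample recognition patterns for given merits
#'
#' For each allele the number of recognized sites is the merit scaled to the
#' sequence length, \eqn{m(A_i) = l_S \cdot w_i}, rounded to an integer
#' (`rounding`, default round-half-to-even), and the recognized sites are a
#' uniform random subset of that size.  Both fitness models then operate on
#' the quantized merits \eqn{m(A_i)/l_S}, which differ from the drawn merits
#' by at most \eqn{1/(2 l_S)}, so the paired AO/DAA comparison uses exactly
#' the same merit vector.
#'
#' @param merits numeric vector of target merits in \[0, 1\].
#' @param ls epitope-sequence length.
#' @param rounding how to turn `ls * merit` into a site count.
#' @return an [allele_set] carrying the sampled patterns (and hence the
#'   quantized merits).
#' @export
sample_patterns <- function(merits, ls,
                            rounding = c("round", "floor", "ceiling")) {
  rounding <- match.arg(rounding)
  ls <- as.integer(ls)
  stopifnot(ls >= 1L, all(merits >= 0), all(merits <= 1))
  m <- switch(rounding,
              round = round(ls * merits),
              floor = floor(ls * merits),
              ceiling = ceiling(ls * merits))
  m <- as.integer(pmin(pmax(m, 0L), ls))
  k <- length(merits)
  pat <- matrix(FALSE, k, ls)
  for (i in seq_len(k))
    if (m[i] > 0L) pat[i, sample.int(ls, m[i])] <- TRUE
  if (any(m == 0L))
    warning("some alleles quantized to an empty pattern (merit 0)")
  allele_set(patterns = pat)
}
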