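#' Repeat counts per scenario
#'
#' The study design uses more repeats for the cheaper, smaller allele counts:
#' the main schedule is 10,000 repeats for 50 and 100 initial alleles, 2000
#' for 250, 500 for 500 and 100 for 1000; the reduced schedule used for the
#' overlap summaries is 500 / 200 / 50 / 20 / 5.  A global `scale` factor
#' shrinks either schedule proportionally for desk-scale runs;
#' `min_repeats` puts a floor under the scaled counts so that per-scenario
#' comparison fractions keep a bounded Monte Carlo error even for the
#' scenarios whose scaled schedule would round down to a handful of repeats.
#'
#' @param nini initial allele count (50, 100, 250, 500 or 1000).
#' @param schedule `"main"` or `"overlap"`.
#' @param scale multiplier applied to the schedule.
#' @param min_repeats lower bound on the returned count (default 1).
#' @return integer repeat count.
#' @export
repeat_schedule <- function(nini, schedule = c("main", "overlap"), scale = 1,
                            min_repeats = 1L) {
  schedule <- match.arg(schedule)
  counts <- switch(schedule,
    main    = c(`50` = 10000, `100` = 10000, `250` = 2000, `500` = 500, `1000` = 100),
    overlap = c(`50` = 500,   `100` = 200,   `250` = 50,   `500` = 20,  `1000` = 5))
  key <- as.character(nini)
  if (!key %in% names(counts))
    stop("no repeat schedule for nini = ", nini,
         " (expected one of 50, 100, 250, 500, 1000)")
  max(as.integer(min_repeats), 1L, as.integer(round(scale * counts[[key]])))
}

# Deterministic 31-bit seed from run coordinates. Plain integer-hash fold:
# exact in doubles (all intermediates < 2^53), independent of R's RNG.
derive_seed <- function(base_seed, scenario_id, repeat_index, experiment,
                        attempt = 0L) {
  parts <- c(base_seed, scenario_id, repeat_index,
             switch(experiment, random = 1, fixed = 2),
             attempt)
  h <- 0
  for (x in parts) h <- (h * 69069 + abs(x) + 1) %% 2147483647
  as.integer(h)
}

#' Run one paired AO/DAA repeat of a scenario
#'
#' Generates one allele set -- merits drawn uniformly (Random experiment) or
#' held at the fixed evenly spaced grid (Fixed experiment), plus fresh random
#' recognition patterns in both -- builds the AO and DAA fitness matrices
#' from the *same* quantized merits and patterns, solves both equilibria and
#' computes the summary metrics.  If either solve lands on a singular final
#' submatrix the draw is discarded and redone with a fresh seed: in the
#' Random experiment this redraws merits and patterns, in the Fixed
#' experiment the merits are fixed so effectively only the patterns are
#' redrawn.  The number of discarded draws is reported in the `redraws`
#' column.
#'
#' @param spec a [scenario_spec].
#' @param experiment `"random"` or `"fixed"`.
#' @param repeat_index 1-based repeat number (enters the seed).
#' @param base_seed integer base seed of the whole run.
#' @param compute_overlap include the overlap summaries.
#' @param max_redraws abort after this many consecutive singular draws.
#' @param rounding site-count rounding mode, see [sample_patterns()].
#' @param weighted overdominance weighting, see [overdominance()].
#' @return data.frame with two rows (model `"ao"` and `"daa"`) sharing the
#'   identical allele set.
#' @export
run_repeat <- function(spec, experiment = c("random", "fixed"), repeat_index,
                       base_seed, compute_overlap = FALSE, max_redraws = 100L,
                       rounding = "round", weighted = TRUE) {
  experiment <- match.arg(experiment)
  stopifnot(inherits(spec, "scenario_spec"))
  sid <- if (is.na(spec$scenario_id)) 0L else spec$scenario_id

  ls <- spec$ls
  attempt <- 0L
  repeat {
    seed <- derive_seed(base_seed, sid, repeat_index, experiment, attempt)
    set.seed(seed)
    target <- if (experiment == "random") draw_random_merits(spec)
              else fixed_merits(spec)
    m <- switch(rounding,
                round = round(ls * target),
                floor = floor(ls * target),
                ceiling = ceiling(ls * target))
    m <- as.integer(pmin(pmax(m, 0L), ls))
    # one draw of recognition patterns, shared by both models; the pairwise
    # intersection counts are all the DAA model and the overlap metrics need
    r <- sampled_intersect_counts(m, ls)
    alleles <- allele_set(merits = m / ls)   # quantized merits
    f_ao <- fitness_ao(alleles)
    f_daa <- fitness_matrix((outer(m, m, `+`) - r) / ls, model = "daa",
                            ids = alleles$ids)
    eq_ao <- solve_equilibrium(f_ao)
    eq_daa <- solve_equilibrium(f_daa)
    if (eq_ao$status == "stable" && eq_daa$status == "stable") break
    attempt <- attempt + 1L
    if (attempt > max_redraws)
      stop("scenario ", sid, " repeat ", repeat_index, " (", experiment,
           "): ", max_redraws, " consecutive singular draws")
  }

  g <- if (compute_overlap) r / ls
  one <- function(model, f, eq) {
    cbind(
      data.frame(scenario_id = sid, experiment = experiment,
                 repeat_index = as.integer(repeat_index), model = model,
                 seed = seed, status = eq$status, redraws = attempt),
      equilibrium_metrics(alleles, f, eq, compute_overlap = compute_overlap,
                          weighted = weighted, g = g, ls = ls)
    )
  }
  rbind(one("ao", f_ao, eq_ao), one("daa", f_daa, eq_daa))
}

#' Run the Random or Fixed experiment over many scenarios
#'
#' Executes [run_repeat()] for every requested scenario and repeat.  Repeats
#' are independent given their derived seeds, so results do not depend on
#' execution order.  With `outdir` set, per-scenario CSV shards are written
#' and existing shards are reused, which lets an interrupted sweep resume.
#'
#' @param experiment `"random"` or `"fixed"`.
#' @param scenarios `"all"` or a vector of scenario ids (1--80).
#' @param scale repeat-schedule multiplier (see [repeat_schedule()]).
#' @param min_repeats floor under the scaled per-scenario repeat counts.
#' @param base_seed integer base seed.
#' @param schedule `"main"` or `"overlap"` repeat schedule.
#' @param compute_overlap include overlap summaries (use with the
#'   `"overlap"` schedule for the study design).
#' @param outdir optional directory for per-scenario CSV shards.
#' @param progress print one line per scenario.
#' @param ... further arguments passed to [run_repeat()].
#' @return data.frame of per-repeat records (two rows per repeat).
#' @export
run_experiment <- function(experiment = c("random", "fixed"),
                           scenarios = "all", scale = 1, min_repeats = 1L,
                           base_seed = 1, schedule = "main",
                           compute_overlap = FALSE, outdir = NULL,
                           progress = FALSE, ...) {
  experiment <- match.arg(experiment)
  tab <- scenario_table()
  ids <- if (identical(scenarios, "all")) tab$scenario_id
         else as.integer(scenarios)
  if (!all(ids %in% tab$scenario_id)) stop("unknown scenario id(s)")
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)

  chunks <- vector("list", length(ids))
  for (idx in seq_along(ids)) {
    sid <- ids[idx]
    shard <- if (!is.null(outdir))
      file.path(outdir, sprintf("records_%s_%03d.csv", experiment, sid))
    if (!is.null(outdir) && file.exists(shard)) {
      chunks[[idx]] <- utils::read.csv(shard, stringsAsFactors = FALSE)
      next
    }
    spec <- scenario_spec(sid)
    n_rep <- repeat_schedule(spec$nini, schedule = schedule, scale = scale,
                             min_repeats = min_repeats)
    recs <- do.call(rbind, lapply(seq_len(n_rep), function(r)
      run_repeat(spec, experiment, r, base_seed,
                 compute_overlap = compute_overlap, ...)))
    if (!is.null(outdir)) utils::write.csv(recs, shard, row.names = FALSE)
    if (progress)
      message(sprintf("scenario %3d (%s): %d repeats done", sid, experiment,
                      n_rep))
    chunks[[idx]] <- recs
  }
  out <- do.call(rbind, chunks)
  rownames(out) <- NULL
  out
}

#' Per-scenario aggregation of paired AO/DAA records
#'
#' For each scenario (and experiment) computes, per model, the mean and
#' maximum persisting-allele count and merit range and the mean
#' overdominance, plus the paired-comparison fractions: the share of repeats
#' in which the DAA range exceeds, falls below, or exactly equals the AO
#' range (equality judged on the integer site-count ranges, so it is exact),
#' and the same three fractions for the allele counts.  Overlap summaries
#' are aggregated when present.
#'
#' @param records data.frame from [run_experiment()] / [run_repeat()].
#' @return data.frame with one row per scenario and experiment.
#' @export
aggregate_records <- function(records) {
  need <- c("scenario_id", "experiment", "repeat_index", "model",
            "n_equil", "r_equil", "r_equil_sites")
  if (!all(need %in% names(records)))
    stop("records are missing columns: ",
         paste(setdiff(need, names(records)), collapse = ", "))
  key <- interaction(records$scenario_id, records$experiment, drop = TRUE)
  out <- lapply(split(records, key), function(rec) {
    ao <- rec[rec$model == "ao", ]
    daa <- rec[rec$model == "daa", ]
    ao <- ao[order(ao$repeat_index), ]
    daa <- daa[order(daa$repeat_index), ]
    if (nrow(ao) != nrow(daa) ||
        !identical(ao$repeat_index, daa$repeat_index))
      stop("unpaired records for scenario ", rec$scenario_id[1],
           " (", rec$experiment[1], ")")
    row <- data.frame(
      scenario_id = rec$scenario_id[1],
      experiment = rec$experiment[1],
      n_repeats = nrow(ao),
      mean_n_ao = mean(ao$n_equil),   mean_n_daa = mean(daa$n_equil),
      max_n_ao = max(ao$n_equil),     max_n_daa = max(daa$n_equil),
      mean_r_ao = mean(ao$r_equil),   mean_r_daa = mean(daa$r_equil),
      max_r_ao = max(ao$r_equil),     max_r_daa = max(daa$r_equil),
      mean_h_ao = mean(ao$h_bar, na.rm = TRUE),
      mean_h_daa = mean(daa$h_bar, na.rm = TRUE),
      frac_range_daa_wider = mean(daa$r_equil_sites > ao$r_equil_sites),
      frac_range_ao_wider = mean(daa$r_equil_sites < ao$r_equil_sites),
      frac_range_equal = mean(daa$r_equil_sites == ao$r_equil_sites),
      frac_n_daa_more = mean(daa$n_equil > ao$n_equil),
      frac_n_ao_more = mean(daa$n_equil < ao$n_equil),
      frac_n_equal = mean(daa$n_equil == ao$n_equil)
    )
    if ("g_bar" %in% names(rec)) {
      row$mean_gbar_ao <- mean(ao$g_bar, na.rm = TRUE)
      row$mean_gbar_daa <- mean(daa$g_bar, na.rm = TRUE)
      row$mean_gmin_ao <- mean(ao$g_min, na.rm = TRUE)
      row$mean_gmin_daa <- mean(daa$g_min, na.rm = TRUE)
      for (q in c("p01", "p02", "p05", "p10")) {
        row[[paste0("mean_g", q, "_ao")]] <- mean(ao[[paste0("g_", q)]], na.rm = TRUE)
        row[[paste0("mean_g", q, "_daa")]] <- mean(daa[[paste0("g_", q)]], na.rm = TRUE)
      }
    }
    row
  })
  out <- do.call(rbind, out)
  out <- out[order(out$experiment, out$scenario_id), ]
  rownames(out) <- NULL
  out
}

#' Pooled cross-scenario comparison summary
#'
#' Pools the paired-comparison fractions over scenarios, per experiment.
#' Two pooling conventions are reported because the published comparison
#' table does not state which was used: `scenario_mean_*` is the unweighted
#' mean of the per-scenario fractions (the default reading, since repeat
#' counts differ by allele count), and `iteration_pooled_*` weights each
#' scenario by its repeat count.  All fractions are percentages.  The mean
#' absolute and relative differences in merit range (DAA minus AO) are also
#' reported.
#'
#' @param aggregates data.frame from [aggregate_records()].
#' @return nested list, one element per experiment present.
#' @export
pooled_summary <- function(aggregates) {
  out <- lapply(split(aggregates, aggregates$experiment), function(agg) {
    n <- agg$n_repeats
    pooled <- function(x) 100 * sum(x * n) / sum(n)
    list(
      n_scenarios = nrow(agg),
      n_repeats_total = sum(n),
      scenario_mean_range_daa_wider = 100 * mean(agg$frac_range_daa_wider),
      scenario_mean_range_ao_wider = 100 * mean(agg$frac_range_ao_wider),
      scenario_mean_range_equal = 100 * mean(agg$frac_range_equal),
      scenario_mean_n_daa_more = 100 * mean(agg$frac_n_daa_more),
      scenario_mean_n_ao_more = 100 * mean(agg$frac_n_ao_more),
      scenario_mean_n_equal = 100 * mean(agg$frac_n_equal),
      iteration_pooled_range_daa_wider = pooled(agg$frac_range_daa_wider),
      iteration_pooled_range_ao_wider = pooled(agg$frac_range_ao_wider),
      iteration_pooled_range_equal = pooled(agg$frac_range_equal),
      iteration_pooled_n_daa_more = pooled(agg$frac_n_daa_more),
      iteration_pooled_n_ao_more = pooled(agg$frac_n_ao_more),
      iteration_pooled_n_equal = pooled(agg$frac_n_equal),
      mean_range_diff_abs = mean(agg$mean_r_daa - agg$mean_r_ao),
      mean_range_diff_rel_pct =
        100 * mean((agg$mean_r_daa - agg$mean_r_ao) /
                     ifelse(agg$mean_r_ao > 0, agg$mean_r_ao, NA),
                   na.rm = TRUE),
      mean_n_diff_rel_pct =
        100 * mean((agg$mean_n_daa - agg$mean_n_ao) / agg$mean_n_ao)
    )
  })
  out
}
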