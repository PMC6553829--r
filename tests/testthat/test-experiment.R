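test_that("repeat schedules reproduce the study design and scale down", {
  expect_equal(repeat_schedule(100), 10000)
  expect_equal(repeat_schedule(50), 10000)
  expect_equal(repeat_schedule(250), 2000)
  expect_equal(repeat_schedule(1000, schedule = "overlap"), 5)
  expect_equal(repeat_schedule(50, schedule = "overlap"), 500)
  expect_equal(repeat_schedule(100, scale = 0.01), 100)
  expect_equal(repeat_schedule(1000, scale = 0.01), 1)
  expect_equal(repeat_schedule(1000, scale = 0.01, min_repeats = 20), 20)
  expect_error(repeat_schedule(75), "no repeat schedule")
})

test_that("a repeat is bitwise reproducible from its seeds", {
  spec <- scenario_spec(wmin = 0.2, wmax = 0.6, nini = 20, f = 2)
  a <- run_repeat(spec, "random", repeat_index = 3, base_seed = 7)
  b <- run_repeat(spec, "random", repeat_index = 3, base_seed = 7)
  expect_identical(a, b)
  c <- run_repeat(spec, "random", repeat_index = 4, base_seed = 7)
  expect_false(identical(a$seed[1], c$seed[1]))
})

test_that("paired AO and DAA rows share the allele draw", {
  spec <- scenario_spec(wmin = 0.3, wmax = 0.7, nini = 30, f = 10)
  rec <- run_repeat(spec, "random", repeat_index = 1, base_seed = 42)
  expect_equal(nrow(rec), 2)
  expect_setequal(rec$model, c("ao", "daa"))
  expect_equal(rec$seed[1], rec$seed[2])
  # both models see the same quantized merit grid, so the DAA extrema are
  # drawn from the same finite set as the AO ones
  expect_true(all(rec$min_merit * spec$ls == round(rec$min_merit * spec$ls)))
})

test_that("in the Fixed experiment the AO outcome is constant across repeats", {
  spec <- scenario_spec(62)
  recs <- do.call(rbind, lapply(1:5, function(r)
    run_repeat(spec, "fixed", repeat_index = r, base_seed = 11)))
  ao <- recs[recs$model == "ao", ]
  expect_equal(length(unique(ao$n_equil)), 1)
  expect_equal(length(unique(ao$r_equil)), 1)
  expect_equal(length(unique(ao$min_merit)), 1)
  expect_equal(ao$min_merit[1], 0.865)  # the AO persistence threshold here
  # the DAA outcome varies with the redrawn patterns
  daa <- recs[recs$model == "daa", ]
  expect_gt(length(unique(paste(daa$n_equil, daa$r_equil))), 1)
})

test_that("aggregation computes exact comparison fractions on a known fixture", {
  base <- data.frame(scenario_id = 1L, experiment = "random",
                     status = "stable", redraws = 0L, seed = 1L,
                     h_bar = 0.5, w_bar = 0.9, min_merit = 0.1,
                     max_merit = 0.6)
  mk <- function(repeat_index, model, n, sites) {
    cbind(base, data.frame(repeat_index = repeat_index, model = model,
                           n_equil = n, r_equil = sites / 100,
                           r_equil_sites = sites))
  }
  rec <- rbind(mk(1, "ao", 5, 40), mk(1, "daa", 4, 50),   # daa wider, ao more
               mk(2, "ao", 3, 30), mk(2, "daa", 3, 30),   # equal, equal
               mk(3, "ao", 2, 20), mk(3, "daa", 4, 10),   # ao wider, daa more
               mk(4, "ao", 2, 25), mk(4, "daa", 3, 60))   # daa wider, daa more
  agg <- aggregate_records(rec)
  expect_equal(agg$frac_range_daa_wider, 0.5)
  expect_equal(agg$frac_range_ao_wider, 0.25)
  expect_equal(agg$frac_range_equal, 0.25)
  expect_equal(agg$frac_n_daa_more, 0.5)
  expect_equal(agg$frac_n_ao_more, 0.25)
  expect_equal(agg$frac_n_equal, 0.25)
  expect_equal(agg$frac_range_daa_wider + agg$frac_range_ao_wider +
                 agg$frac_range_equal, 1)
  expect_equal(agg$max_n_daa, 4)
  expect_equal(agg$mean_r_ao, mean(c(40, 30, 20, 25)) / 100)

  ps <- pooled_summary(agg)$random
  expect_equal(ps$scenario_mean_range_daa_wider, 50)
  expect_equal(ps$iteration_pooled_range_daa_wider, 50)

  expect_error(aggregate_records(rec[-1, ]), "unpaired")
})

test_that("identical paired outcomes aggregate to the all-equal fractions", {
  spec <- scenario_spec(wmin = 0.4, wmax = 0.8, nini = 10, f = 2)
  rec <- run_repeat(spec, "fixed", 1, base_seed = 5)
  rec$r_equil_sites <- 10L; rec$n_equil <- 3L  # force a tie
  agg <- aggregate_records(rec)
  expect_equal(agg$frac_range_equal, 1)
  expect_equal(agg$frac_n_equal, 1)
})

test_that("experiment sweeps are order-invariant and resumable", {
  dir <- withr::local_tempdir()
  rec1 <- run_experiment("random", scenarios = c(11, 12), scale = 0.001,
                         min_repeats = 3, base_seed = 2, outdir = dir)
  # resumes from shards: identical result without recomputation
  rec2 <- run_experiment("random", scenarios = c(11, 12), scale = 0.001,
                         min_repeats = 3, base_seed = 2, outdir = dir)
  expect_equal(rec1$n_equil, rec2$n_equil)
  expect_equal(rec1$seed, rec2$seed)
  # scenario order does not change per-scenario results
  rec3 <- run_experiment("random", scenarios = c(12, 11), scale = 0.001,
                         min_repeats = 3, base_seed = 2)
  agg1 <- aggregate_records(rec1)
  agg3 <- aggregate_records(rec3)
  expect_equal(agg1, agg3)
})

test_that("low-merit scenarios show the expected strong overdominance", {
  # scenarios with merits in (0, 0.1) have mean equilibrium overdominance
  # near 90%
  rec <- run_experiment("random", scenarios = 1, scale = 0.003, base_seed = 3)
  expect_gt(mean(rec$h_bar), 0.8)
  expect_lt(mean(rec$h_bar), 1.0)
})

test_that("overlap-schedule runs produce overlap summaries", {
  rec <- run_experiment("fixed", scenarios = 11, scale = 0.01,
                        min_repeats = 3, base_seed = 4,
                        schedule = "overlap", compute_overlap = TRUE)
  expect_true(all(c("g_bar", "g_min", "g_p05") %in% names(rec)))
  expect_true(all(rec$g_bar >= 0 & rec$g_bar <= 1, na.rm = TRUE))
  agg <- aggregate_records(rec)
  expect_true(all(c("mean_gbar_ao", "mean_gbar_daa") %in% names(agg)))
})
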