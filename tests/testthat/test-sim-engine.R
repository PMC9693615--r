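test_that("cumulative metrics count benefit as defined", {
  log <- makeObservations(runif(10), efficacy = c(1, 1, 0, 1, 1, 1, 0, 1, 1, 1),
                          toxicity = 0)
  expect_equal(cumulativeEfficacy(log, 0), 0)
  expect_equal(cumulativeEfficacy(log, 10), 8)
  expect_equal(cumulativeEfficacy(log[c(1, 3), ], 2), 1)
  expect_true(all(diff(vapply(1:10, function(n) cumulativeEfficacy(log, n),
                              numeric(1))) >= 0))
  expect_error(cumulativeEfficacy(log, 11), "exceeds")
  # n * U(counts / n): with 9/10 efficacious, no toxicity
  log9 <- makeObservations(runif(10), efficacy = c(rep(1, 9), 0), toxicity = 0)
  expect_equal(cumulativeUtility(log9, 10, utilitySpec("maximum_efficacy")), 9)
  spec <- utilitySpec("utility_contour")
  expect_equal(cumulativeUtility(log9, 10, spec),
               10 * utility(0.9, 0, spec))
  # empirical fractions at the zero-utility anchor score zero
  anch <- makeObservations(runif(10), efficacy = rep(1, 10),
                           toxicity = c(rep(1, 6), rep(0, 4)))
  spec2 <- utilitySpec("utility_contour", anchor_tox = 0.6)
  expect_equal(cumulativeUtility(anch, 10, spec2), 0, tolerance = 1e-12)
})

test_that("a uniform trial with one cohort doses every grid point once", {
  sc <- makeScenario("gently_saturating", domain = coarseDomain(1))
  tr <- runTrial(sc, doaUniformNaive(coarseDomain(1)), n_participants = 6,
                 seed = 1)
  expect_equal(nrow(tr$trajectory), 1L)
  expect_equal(sort(tr$log$dose_1), seq(0, 1, by = 0.2))
})

test_that("a certain-efficacy scenario attains the cumulative upper bound", {
  sc <- makeScenario("gently_saturating", params = list(p_min = 1, p_max = 1))
  tr <- runTrial(sc, doaCobe(h = 1), n_participants = 30, seed = 2)
  expect_equal(tr$trajectory$cumulative_metric, tr$trajectory$n)
})

test_that("trials are bit-reproducible given the seed", {
  sc <- makeScenario("sharply_peaking")
  a <- runTrial(sc, doaCobe(h = 1), 30, seed = 42)
  b <- runTrial(sc, doaCobe(h = 1), 30, seed = 42)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$log, b$log)
  c <- runTrial(sc, doaCobe(h = 1), 30, seed = 43)
  expect_false(identical(a$log, c$log))
})

test_that("trajectories respect the scenario bounds and domain membership", {
  sc <- makeScenario("gently_peaking")
  opt <- scenarioOptimum(sc)
  tr <- runTrial(sc, doaCobe(h = 1), 60, seed = 3)
  expect_true(all(tr$trajectory$true_metric >= opt$min - 1e-12))
  expect_true(all(tr$trajectory$true_metric <= opt$value + 1e-12))
  expect_true(all(tr$trajectory$cumulative_metric <=
                    tr$trajectory$n * opt$value + 1e-9))
  expect_true(all(tr$trajectory$predicted_dose_1 %in%
                    sc$domain$doses[, 1]))
  # a final short cohort is truncated, not dropped
  tr2 <- runTrial(sc, doaCobe(h = 1), 20, cohort_size = 6, seed = 3)
  expect_equal(tr2$trajectory$n, c(6L, 12L, 18L, 20L))
})

test_that("incompatible strategy and scenario pairings are refused", {
  sc <- makeScenario("synergistic_saturating")
  expect_error(runTrial(sc, doaCobe(h = 1), 30, seed = 1), "dimensionality")
  expect_error(runTrial(makeScenario("gently_saturating"),
                        doaCobe(h = 1, utility = utilitySpec("utility_contour")),
                        30, seed = 1),
               "utility")
})

test_that("studies enumerate pairings with stable derived substreams", {
  sc <- list(peak = makeScenario("sharply_peaking", domain = coarseDomain(1)))
  doas <- list(adaptive = function() doaAdaptiveNaive(coarseDomain(1)),
               uniform = function() doaUniformNaive(coarseDomain(1)))
  study <- runStudy(sc, doas, n_participants = 12, n_reps = 3, seed = 9)
  # 1 scenario x 2 strategies x 3 reps x 2 cohorts
  expect_equal(nrow(study), 12L)
  expect_equal(length(attr(study, "failures")), 0L)
  study2 <- runStudy(sc, doas, n_participants = 12, n_reps = 3, seed = 9)
  attr(study2, "failures") <- attr(study, "failures")
  expect_identical(study, study2)
  # adding a strategy leaves existing replicate streams untouched
  study3 <- runStudy(sc, c(doas, list(cobe = function()
    doaCobe(coarseDomain(1)))), n_participants = 12, n_reps = 3, seed = 9)
  expect_identical(study[study$doa == "adaptive", ],
                   study3[study3$doa == "adaptive", ])
})

test_that("failed pairings are logged without aborting the study", {
  sc <- list(peak2d = makeScenario("synergistic_peaking",
                                   domain = coarseDomain(2)))
  doas <- list(bad1d = function() doaAdaptiveNaive(coarseDomain(1)),
               ok = function() doaAdaptiveNaive(coarseDomain(2)))
  study <- runStudy(sc, doas, n_participants = 9, n_reps = 2, seed = 5)
  expect_named(attr(study, "failures"), "peak2d/bad1d")
  expect_true(all(study$doa == "ok"))
})

test_that("aggregation reports means, intervals and reference lines", {
  # identical trajectories collapse to a zero-width interval
  base <- data.frame(scenario = "s", doa = "d", replicate = rep(1:3, each = 2),
                     cohort = rep(1:2, 3), n = rep(c(6, 12), 3),
                     true_metric = rep(c(0.4, 0.6), 3),
                     cumulative_metric = rep(c(2, 7), 3))
  agg <- aggregateTrials(base)
  expect_equal(agg$ci_lo_true, agg$ci_hi_true)
  expect_equal(agg$mean_true, c(0.4, 0.6))
  # t interval contains the mean and matches a bootstrap within 10% width
  set.seed(151)
  vals <- rnorm(100, 0.5, 0.1)
  noisy <- data.frame(scenario = "s", doa = "d", replicate = 1:100,
                      cohort = 1, n = 6, true_metric = vals,
                      cumulative_metric = vals * 6)
  t_agg <- aggregateTrials(noisy, method = "t")
  b_agg <- aggregateTrials(noisy, method = "bootstrap", boot_reps = 4000)
  expect_true(t_agg$ci_lo_true < t_agg$mean_true &
                t_agg$mean_true < t_agg$ci_hi_true)
  w_t <- t_agg$ci_hi_true - t_agg$ci_lo_true
  w_b <- b_agg$ci_hi_true - b_agg$ci_lo_true
  expect_lt(abs(w_t - w_b) / w_t, 0.1)
  # reference lines: a 90%-max scenario bounds cumulative efficacy by 0.9 n
  sc <- makeScenario("sharply_peaking")
  ref <- referenceLines(sc, 300)
  expect_equal(ref$ref_max, 0.9)
  expect_equal(ref$ref_max_cumulative, 270)
  agg2 <- aggregateTrials(transform(noisy, scenario = "peak"),
                          scenarios = list(peak = sc))
  expect_equal(agg2$ref_max, 0.9)
  expect_true(all(agg2$mean_true <= agg2$ref_max))
})
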