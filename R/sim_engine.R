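#' Per-participant benefit metrics
#'
#' `cumulativeEfficacy()` counts the efficacious responders among the first
#' `n` participants of an observation log. `cumulativeUtility()` is `n` times
#' the utility of the empirical efficacy and toxicity fractions among the
#' first `n` participants (0 when `n = 0`). With the maximum-efficacy utility
#' the two coincide.
#'
#' @param log Observation data frame in participant order.
#' @param n Number of leading participants to evaluate (default: all).
#' @param spec A [utilitySpec()].
#' @return A count, or a real cumulative utility.
#' @export
cumulativeEfficacy <- function(log, n = nrow(log)) {
  if (n > nrow(log)) stop("n exceeds the observation log", call. = FALSE)
  if (n == 0L) return(0)
  sum(log$efficacy[seq_len(n)])
}

#' @rdname cumulativeEfficacy
#' @export
cumulativeUtility <- function(log, n = nrow(log), spec) {
  stopifnot(inherits(spec, "utility_spec"))
  if (n > nrow(log)) stop("n exceeds the observation log", call. = FALSE)
  if (n == 0L) return(0)
  eff_frac <- mean(log$efficacy[seq_len(n)])
  tox_frac <- if (spec$kind == "utility_contour") {
    mean(log$toxicity[seq_len(n)])
  } else NA
  n * utility(eff_frac, tox_frac, spec)
}

cumulative_metric <- function(log, n, spec) {
  if (spec$kind == "utility_contour") cumulativeUtility(log, n, spec)
  else cumulativeEfficacy(log, n)
}

#' Run one simulated adaptive dose-finding trial
#'
#' The full adaptive loop: the strategy proposes a sampling cohort, outcomes
#' are drawn from the scenario's true dose-response probabilities, the
#' strategy absorbs the data, and an interim optimal dose is nominated and
#' scored against the ground truth -- repeated until all `n_participants`
#' have been used (a final short cohort when `n_participants` is not a
#' multiple of the cohort size). Fully deterministic given `seed`.
#'
#' @param scenario A [makeScenario()] scenario.
#' @param doa A freshly constructed strategy (see [doas]) matching the
#'   scenario's dimensionality and utility.
#' @param n_participants Total trial participants.
#' @param cohort_size Sampling-cohort size; defaults to [cohortSize()].
#' @param seed Integer RNG seed for the replicate.
#' @return An object of class `trial_trajectory`: a list with `trajectory`
#'   (per-cohort data frame: `cohort`, `n`, predicted dose components,
#'   `true_metric`, `cumulative_metric`) and the full observation `log`.
#' @export
runTrial <- function(scenario, doa, n_participants = 300L,
                     cohort_size = cohortSize(doa), seed = 1L) {
  stopifnot(inherits(scenario, "scenario"), inherits(doa, "doa"))
  if (scenario$domain$h != doa$domain$h) {
    stop("strategy and scenario dimensionality differ", call. = FALSE)
  }
  if (scenario$utility$kind != doa$utility$kind) {
    stop("strategy and scenario utility kinds differ", call. = FALSE)
  }
  stopifnot(n_participants >= cohort_size, cohort_size >= 1L)
  set.seed(as.integer(seed))
  n_cohorts <- ceiling(n_participants / cohort_size)
  log <- NULL
  rows <- vector("list", n_cohorts)
  for (k in seq_len(n_cohorts)) {
    this_c <- min(cohort_size, n_participants - (k - 1L) * cohort_size)
    doses <- proposeCohort(doa, this_c)
    obs <- do.call(rbind, lapply(seq_len(this_c), function(j) {
      sampleOutcome(scenario, doses[j, ])
    }))
    doa <- absorb(doa, obs)
    log <- if (is.null(log)) obs else rbind(log, obs)
    fd <- finalDose(doa)
    n_so_far <- nrow(log)
    row <- data.frame(cohort = k, n = n_so_far)
    pd <- as.list(fd$dose)
    names(pd) <- paste0("predicted_dose_", seq_along(pd))
    row <- cbind(row, as.data.frame(pd))
    row$true_metric <- trueMetricAt(scenario, fd$dose)
    row$cumulative_metric <- cumulative_metric(log, n_so_far,
                                               scenario$utility)
    rows[[k]] <- row
  }
  structure(list(trajectory = do.call(rbind, rows), log = log,
                 scenario_tag = scenario$shape_tag, doa_name = doa$name),
            class = "trial_trajectory")
}

#' @export
print.trial_trajectory <- function(x, ...) {
  cat(sprintf("<trial_trajectory> %s on %s: %d cohorts, %d participants\n",
              x$doa_name, x$scenario_tag, nrow(x$trajectory), nrow(x$log)))
  invisible(x)
}

# 31-bit string-fold hash so each (seed, scenario, doa, replicate) gets a
# stable RNG substream that does not move when strategies are added
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "|")
  h <- as.numeric(seed) %% 2147483647
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

#' Run a replicated simulation study
#'
#' Simulates every scenario/strategy pairing `n_reps` times. Each replicate's
#' seed is derived deterministically from `seed` and the pairing's names, so
#' the study is bit-reproducible and individual pairings can be re-run in
#' isolation. A pairing whose trials error is recorded and skipped rather
#' than aborting the study.
#'
#' @param scenarios Named list of scenarios.
#' @param doas Named list of strategy constructors -- zero-argument functions
#'   returning a fresh `doa` (each replicate needs an unused model state) --
#'   or plain `doa` objects, which are reused as the pristine initial state.
#' @param n_participants Total participants per trial.
#' @param n_reps Replicates per pairing.
#' @param seed Master integer seed.
#' @return A tidy data frame with columns `scenario`, `doa`, `replicate`,
#'   `cohort`, `n`, `predicted_dose_*`, `true_metric`, `cumulative_metric`.
#'   Failed pairings are attached as the `"failures"` attribute.
#' @export
runStudy <- function(scenarios, doas, n_participants = 300L, n_reps = 100L,
                     seed = 1L) {
  stopifnot(length(names(scenarios)) == length(scenarios),
            length(names(doas)) == length(doas), n_reps >= 1L)
  out <- list()
  failures <- list()
  for (sc_name in names(scenarios)) {
    for (doa_name in names(doas)) {
      maker <- doas[[doa_name]]
      res <- tryCatch({
        reps <- lapply(seq_len(n_reps), function(r) {
          doa <- if (is.function(maker)) maker() else maker
          tr <- runTrial(scenarios[[sc_name]], doa, n_participants,
                         seed = derive_seed(seed, sc_name, doa_name, r))
          cbind(data.frame(scenario = sc_name, doa = doa_name,
                           replicate = r), tr$trajectory)
        })
        do.call(rbind, reps)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[paste(sc_name, doa_name, sep = "/")]] <-
          conditionMessage(res)
      } else {
        out[[paste(sc_name, doa_name, sep = "/")]] <- res
      }
    }
  }
  study <- do.call(rbind, out)
  rownames(study) <- NULL
  attr(study, "failures") <- failures
  study
}

#' Aggregate replicated trajectories
#'
#' Per scenario, strategy and cohort: the across-replicate mean of each
#' metric with a 95% (by default) confidence interval for the true mean,
#' either Student-t based or percentile bootstrap. When the corresponding
#' scenario objects are supplied, theoretical reference lines are attached:
#' the domain-wide maximum and minimum of the true metric, and `n` times each
#' for the cumulative metric (no strategy can exceed the upper line, which
#' corresponds to dosing every participant at the true optimum).
#'
#' @param study Tidy results from [runStudy()].
#' @param scenarios Named list of the scenarios used (optional, for reference
#'   lines).
#' @param level Confidence level.
#' @param method `"t"` or `"bootstrap"`.
#' @param boot_reps Bootstrap resamples when `method = "bootstrap"`.
#' @return A data frame with per-cohort `mean_true`, `ci_lo_true`,
#'   `ci_hi_true`, `mean_cumulative`, `ci_lo_cumulative`,
#'   `ci_hi_cumulative`, and reference columns `ref_max`, `ref_min`,
#'   `ref_max_cumulative`, `ref_min_cumulative`.
#' @export
aggregateTrials <- function(study, scenarios = NULL, level = 0.95,
                            method = c("t", "bootstrap"), boot_reps = 2000L) {
  method <- match.arg(method)
  stopifnot(level > 0, level < 1)
  ci <- function(x) {
    m <- mean(x)
    if (length(x) < 2L || stats::sd(x) == 0) return(c(m, m, m))
    if (method == "t") {
      half <- stats::qt(1 - (1 - level) / 2, length(x) - 1L) *
        stats::sd(x) / sqrt(length(x))
      c(m, m - half, m + half)
    } else {
      boots <- vapply(seq_len(boot_reps), function(i) {
        mean(x[sample.int(length(x), replace = TRUE)])
      }, numeric(1L))
      c(m, stats::quantile(boots, (1 - level) / 2, names = FALSE),
        stats::quantile(boots, 1 - (1 - level) / 2, names = FALSE))
    }
  }
  groups <- split(study, list(study$scenario, study$doa, study$cohort),
                  drop = TRUE)
  rows <- lapply(groups, function(g) {
    ct <- ci(g$true_metric)
    cc <- ci(g$cumulative_metric)
    out <- data.frame(scenario = g$scenario[[1L]], doa = g$doa[[1L]],
                      cohort = g$cohort[[1L]], n = g$n[[1L]],
                      n_reps = nrow(g),
                      mean_true = ct[[1L]], ci_lo_true = ct[[2L]],
                      ci_hi_true = ct[[3L]],
                      mean_cumulative = cc[[1L]], ci_lo_cumulative = cc[[2L]],
                      ci_hi_cumulative = cc[[3L]])
    if (!is.null(scenarios) && out$scenario %in% names(scenarios)) {
      ref <- referenceLines(scenarios[[out$scenario]], out$n)
      out <- cbind(out, as.data.frame(ref))
    }
    out
  })
  agg <- do.call(rbind, rows)
  agg <- agg[order(agg$scenario, agg$doa, agg$cohort), ]
  rownames(agg) <- NULL
  agg
}

#' Theoretical reference lines for a scenario
#'
#' The bounds against which strategies are compared: the maximum and minimum
#' true metric over the dosing domain, and their cumulative counterparts
#' after `n` participants (`n` times each extreme -- e.g. a scenario whose
#' best dose has 90% true efficacy bounds cumulative efficacy by 270 after
#' 300 participants).
#'
#' @param scenario A scenario.
#' @param n Number of participants for the cumulative bounds.
#' @return List with `ref_max`, `ref_min`, `ref_max_cumulative`,
#'   `ref_min_cumulative`.
#' @export
referenceLines <- function(scenario, n) {
  opt <- scenarioOptimum(scenario)
  list(ref_max = opt$value, ref_min = opt$min,
       ref_max_cumulative = n * opt$value, ref_min_cumulative = n * opt$min)
}

#' Participant budget of the uniform strategy
#'
#' The uniform strategy spends one cohort per sweep of its domain, so with
#' `n_participants` available it completes `floor(n_participants /
#' domain_size)` cohorts and uses that many participants per dose (297 of 300
#' on a 9-dose grid, for example).
#'
#' @param n_participants Available participants.
#' @param domain_size Number of doses in the coarse domain.
#' @return List with `n_cohorts` and `n_used`.
#' @export
uniformSchedule <- function(n_participants, domain_size) {
  stopifnot(n_participants >= domain_size, domain_size >= 1L)
  n_cohorts <- as.integer(n_participants %/% domain_size)
  list(n_cohorts = n_cohorts, n_used = as.integer(n_cohorts * domain_size))
}
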