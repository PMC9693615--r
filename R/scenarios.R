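#' Synthetic dose-response scenario catalogue
#'
#' A scenario is the ground truth of a simulated trial: a dosing domain, a
#' utility specification, a true dose-efficacy surface and (for contour
#' utilities) a true dose-toxicity surface. The catalogue recreates the
#' qualitative families studied in the simulation work with documented closed
#' forms -- saturating (Hill), peaking (Gaussian bump), decreasing, undulating
#' (trend plus sinusoid), flattened peaks, and multi-administration
#' compositions of saturating marginals with interaction terms. Curves are
#' evaluated lazily per dose, so dense model-strategy grids and coarse naive
#' grids share one ground truth.
#'
#' Available `shape_tag` values:
#' single administration efficacy `gently_saturating`, `sharply_saturating`,
#' `gently_peaking`, `sharply_peaking`, `decreasing`, `undulating`,
#' `flattened_peaking`; prime/boost efficacy `synergistic_peaking`,
#' `antagonistic_saturating`, `synergistic_saturating`,
#' `saturating_with_high_dose_decline`, `one_dose_dominant`;
#' prime/boost/second-boost efficacy `independent_peaking`,
#' `two_of_three_maximal`; toxicity (`tox_tag`) `gradually_increasing`,
#' `sharply_increasing` (single administration) and
#' `increasing_in_either_dose` (prime/boost).
#'
#' @param shape_tag Efficacy curve family (see above).
#' @param domain A [doseDomain()]; defaults to the fine grid for the tag's
#'   dimensionality.
#' @param utility A [utilitySpec()]. A toxicity curve is attached iff the
#'   utility is the contour.
#' @param tox_tag Toxicity curve family, required iff `utility` is the
#'   contour.
#' @param params,tox_params Named lists overriding the documented default
#'   curve parameters.
#' @return An object of class `scenario` with elements `domain`, `utility`,
#'   `true_eff` and `true_tox` (dose-matrix -> probability functions),
#'   `shape_tag`, `tox_tag`.
#' @examples
#' sc <- makeScenario("sharply_peaking")
#' scenarioOptimum(sc)$value # 0.9 at dose 0.5
#' @export
makeScenario <- function(shape_tag, domain = NULL,
                         utility = utilitySpec("maximum_efficacy"),
                         tox_tag = NULL, params = list(),
                         tox_params = list()) {
  eff <- scenario_curve(shape_tag, params)
  if (is.null(domain)) domain <- fineDomain(eff$h)
  stopifnot(inherits(domain, "dose_domain"), inherits(utility, "utility_spec"))
  if (domain$h != eff$h) {
    stop(sprintf("'%s' is a %d-administration shape but the domain has %d",
                 shape_tag, eff$h, domain$h), call. = FALSE)
  }
  true_tox <- NULL
  if (utility$kind == "utility_contour") {
    if (is.null(tox_tag)) {
      stop("a contour utility requires a toxicity curve (tox_tag)",
           call. = FALSE)
    }
    tox <- scenario_curve(tox_tag, tox_params, toxicity = TRUE)
    if (tox$h != domain$h) {
      stop("toxicity curve dimensionality does not match the domain",
           call. = FALSE)
    }
    true_tox <- tox$fn
  } else if (!is.null(tox_tag)) {
    stop("a toxicity curve is only used with the contour utility",
         call. = FALSE)
  }
  sc <- structure(list(domain = domain, utility = utility,
                       true_eff = eff$fn, true_tox = true_tox,
                       shape_tag = shape_tag, tox_tag = tox_tag),
                  class = "scenario")
  check_curve_range(sc)
  sc
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s%s | %s | %d doses (%dD)\n", x$shape_tag,
              if (is.null(x$tox_tag)) "" else paste0(" + ", x$tox_tag),
              x$utility$kind, nDoses(x$domain), x$domain$h))
  invisible(x)
}

# normalised Hill saturation: 0 at dose 0, 1 at dose 1, monotone increasing
hill01 <- function(d, h, d50) {
  (d^h * (1 + d50^h)) / (d^h + d50^h)
}

# closed-form curve families; each entry returns list(h, fn)
scenario_curve <- function(tag, params = list(), toxicity = FALSE) {
  p <- function(name, default) {
    if (!is.null(params[[name]])) params[[name]] else default
  }
  make <- function(h, fn) list(h = h, fn = fn)
  out <- switch(
    tag,
    gently_saturating = {
      lo <- p("p_min", 0.1); hi <- p("p_max", 0.85)
      s <- p("steepness", 2); d50 <- p("d50", 0.35)
      make(1L, function(d) lo + (hi - lo) * hill01(d[, 1L], s, d50))
    },
    sharply_saturating = {
      lo <- p("p_min", 0.05); hi <- p("p_max", 0.9)
      s <- p("steepness", 8); d50 <- p("d50", 0.3)
      make(1L, function(d) lo + (hi - lo) * hill01(d[, 1L], s, d50))
    },
    gently_peaking = {
      lo <- p("p_min", 0.1); hi <- p("p_max", 0.8)
      ctr <- p("peak", 0.55); w <- p("width", 0.35)
      make(1L, function(d) lo + (hi - lo) * exp(-((d[, 1L] - ctr) / w)^2))
    },
    sharply_peaking = {
      lo <- p("p_min", 0.1); hi <- p("p_max", 0.9)
      ctr <- p("peak", 0.5); w <- p("width", 0.12)
      make(1L, function(d) lo + (hi - lo) * exp(-((d[, 1L] - ctr) / w)^2))
    },
    decreasing = {
      lo <- p("p_min", 0.1); hi <- p("p_max", 0.85)
      s <- p("steepness", 3); d50 <- p("d50", 0.4)
      make(1L, function(d) lo + (hi - lo) * (1 - hill01(d[, 1L], s, d50)))
    },
    undulating = {
      base <- p("base", 0.45); trend <- p("trend", 0.15)
      amp <- p("amplitude", 0.22); cycles <- p("cycles", 1.5)
      make(1L, function(d) {
        base + trend * d[, 1L] + amp * sin(2 * pi * cycles * d[, 1L])
      })
    },
    flattened_peaking = {
      lo <- p("p_min", 0.5); hi <- p("p_max", 0.62)
      ctr <- p("peak", 0.5); w <- p("width", 0.35)
      make(1L, function(d) lo + (hi - lo) * exp(-((d[, 1L] - ctr) / w)^6))
    },
    synergistic_peaking = {
      lo <- p("p_min", 0.1); hi <- p("p_max", 0.9)
      ctr <- p("peak", c(0.6, 0.6)); w <- p("width", 0.35)
      make(2L, function(d) {
        lo + (hi - lo) *
          exp(-((d[, 1L] - ctr[1L])^2 + (d[, 2L] - ctr[2L])^2) / w^2)
      })
    },
    antagonistic_saturating = {
      lo <- p("p_min", 0.05); hi <- p("p_max", 0.9)
      make(2L, function(d) {
        s1 <- hill01(d[, 1L], 2.5, 0.35); s2 <- hill01(d[, 2L], 2.5, 0.35)
        lo + (hi - lo) * (0.6 * s1 + 0.6 * s2 - 0.35 * s1 * s2) / 0.85
      })
    },
    synergistic_saturating = {
      lo <- p("p_min", 0.05); hi <- p("p_max", 0.9)
      make(2L, function(d) {
        s1 <- hill01(d[, 1L], 2.5, 0.35); s2 <- hill01(d[, 2L], 2.5, 0.35)
        lo + (hi - lo) * (0.35 * s1 + 0.35 * s2 + 0.3 * s1 * s2)
      })
    },
    saturating_with_high_dose_decline = {
      lo <- p("p_min", 0.05); hi <- p("p_max", 0.9)
      make(2L, function(d) {
        s1 <- hill01(d[, 1L], 2.5, 0.35); s2 <- hill01(d[, 2L], 2.5, 0.35)
        g <- 0.35 * s1 + 0.35 * s2 + 0.3 * s1 * s2
        decline <- 1 - 0.45 *
          exp(-((d[, 1L] - 1)^2 + (d[, 2L] - 1)^2) / 0.35^2)
        lo + (hi - lo) * g * decline
      })
    },
    one_dose_dominant = {
      lo <- p("p_min", 0.05); hi <- p("p_max", 0.9)
      make(2L, function(d) {
        s1 <- hill01(d[, 1L], 2.5, 0.35); s2 <- hill01(d[, 2L], 2.5, 0.35)
        lo + (hi - lo) * (0.75 * s1 + 0.15 * s2 + 0.1 * s1 * s2)
      })
    },
    independent_peaking = {
      lo <- p("p_min", 0.1); hi <- p("p_max", 0.9)
      ctr <- p("peak", c(0.4, 0.6, 0.5)); w <- p("width", 0.4)
      make(3L, function(d) {
        lo + (hi - lo) * exp(-((d[, 1L] - ctr[1L])^2 +
                                 (d[, 2L] - ctr[2L])^2 +
                                 (d[, 3L] - ctr[3L])^2) / w^2)
      })
    },
    two_of_three_maximal = {
      lo <- p("p_min", 0.1); hi <- p("p_max", 0.9)
      make(3L, function(d) {
        t1 <- d[, 1L]^2; t2 <- d[, 2L]^2; t3 <- d[, 3L]^2
        lo + (hi - lo) * (t1 * t2 + t1 * t3 + t2 * t3 - 3 * t1 * t2 * t3)
      })
    },
    gradually_increasing = {
      lo <- p("p_min", 0.02); hi <- p("p_max", 0.5)
      make(1L, function(d) lo + (hi - lo) * d[, 1L]^1.5)
    },
    sharply_increasing = {
      lo <- p("p_min", 0.02); hi <- p("p_max", 0.7)
      s <- p("steepness", 8); d50 <- p("d50", 0.75)
      make(1L, function(d) lo + (hi - lo) * hill01(d[, 1L], s, d50))
    },
    increasing_in_either_dose = {
      lo <- p("p_min", 0.02); hi <- p("p_max", 0.6)
      make(2L, function(d) {
        lo + (hi - lo) * (1 - (1 - d[, 1L]^2.5) * (1 - d[, 2L]^2.5))
      })
    },
    stop(sprintf("unknown scenario shape '%s'", tag), call. = FALSE)
  )
  out
}

#' @rdname makeScenario
#' @export
scenarioShapes <- function() {
  list(efficacy_1d = c("gently_saturating", "sharply_saturating",
                       "gently_peaking", "sharply_peaking", "decreasing",
                       "undulating", "flattened_peaking"),
       efficacy_2d = c("synergistic_peaking", "antagonistic_saturating",
                       "synergistic_saturating",
                       "saturating_with_high_dose_decline",
                       "one_dose_dominant"),
       efficacy_3d = c("independent_peaking", "two_of_three_maximal"),
       toxicity_1d = c("gradually_increasing", "sharply_increasing"),
       toxicity_2d = "increasing_in_either_dose")
}

check_curve_range <- function(sc) {
  dense <- sc$domain$doses
  for (fn in Filter(Negate(is.null), list(sc$true_eff, sc$true_tox))) {
    vals <- fn(dense)
    if (anyNA(vals) || any(vals < 0) || any(vals > 1)) {
      stop("scenario parameters produce probabilities outside [0, 1]",
           call. = FALSE)
    }
  }
  invisible(sc)
}

#' True efficacy, toxicity and utility over the domain
#'
#' @param scenario A [makeScenario()] scenario.
#' @return A data frame of dose components, `true_eff`, `true_tox` (`NA` when
#'   undefined) and `true_utility`.
#' @export
scenarioTable <- function(scenario) {
  stopifnot(inherits(scenario, "scenario"))
  d <- scenario$domain$doses
  out <- as.data.frame(d)
  out$true_eff <- scenario$true_eff(d)
  out$true_tox <- if (is.null(scenario$true_tox)) NA_real_ else
    scenario$true_tox(d)
  out$true_utility <- trueMetricAt(scenario, d)
  out
}

#' Ground-truth metric at given doses
#'
#' Evaluates the scenario's true evaluation metric -- the true efficacy under
#' the maximum-efficacy utility, or the contour utility of the true efficacy
#' and toxicity probabilities -- at one or more doses.
#'
#' @param scenario A scenario.
#' @param doses Dose vector or matrix of dose rows.
#' @return Numeric vector of true metric values.
#' @export
trueMetricAt <- function(scenario, doses) {
  stopifnot(inherits(scenario, "scenario"))
  if (is.numeric(doses) && is.null(dim(doses))) {
    doses <- matrix(doses, ncol = scenario$domain$h)
  }
  doses <- as.matrix(doses)
  p_eff <- scenario$true_eff(doses)
  if (scenario$utility$kind == "maximum_efficacy") {
    utility(p_eff, NA, scenario$utility)
  } else {
    utility(p_eff, scenario$true_tox(doses), scenario$utility)
  }
}

#' Scenario optimum and reference bounds
#'
#' Exhaustive scan of the true metric over the domain: the best achievable
#' dose and value, plus the minimum (the lower reference line in the
#' simulation summaries).
#'
#' @param scenario A scenario.
#' @return List with `index`, `dose`, `value` (maximum) and `min`.
#' @export
scenarioOptimum <- function(scenario) {
  stopifnot(inherits(scenario, "scenario"))
  vals <- trueMetricAt(scenario, scenario$domain$doses)
  i <- which.max(vals)
  list(index = i, dose = scenario$domain$doses[i, ], value = vals[[i]],
       min = min(vals))
}

#' Simulate one participant's outcomes at a dose
#'
#' Binary efficacy (and, when the scenario defines toxicity, binary toxicity)
#' drawn independently from the scenario's true probabilities at the given
#' dose.
#'
#' @param scenario A scenario.
#' @param dose A single dose (vector of the domain's dimensionality).
#' @return A one-row observation data frame ([makeObservations()]).
#' @export
sampleOutcome <- function(scenario, dose) {
  stopifnot(inherits(scenario, "scenario"))
  d <- matrix(as.numeric(dose), ncol = scenario$domain$h)
  eff <- stats::rbinom(1L, 1L, scenario$true_eff(d))
  tox <- if (is.null(scenario$true_tox)) NA_real_ else
    stats::rbinom(1L, 1L, scenario$true_tox(d))
  makeObservations(d, efficacy = eff, toxicity = tox)
}

#' Expert prior derived from a scenario's ground truth
#'
#' Builds the expert-opinion priors used in the prior-elicitation experiments:
#' a "correct" expert predicts the true response probability at every domain
#' dose, an "incorrect" expert predicts one minus it; `confidence` 3
#' represents a strong prior and 20 a very strong one.
#'
#' @param scenario A scenario.
#' @param domain Domain to elicit over (default: the scenario's own).
#' @param correct Logical; `FALSE` flips the prediction to `1 - truth`.
#' @param confidence Data-equivalent prior weight (per dose).
#' @return Named list of [expertPrior()] objects suitable for
#'   [betaState()]/[doaCobe()] (`efficacy`, plus `toxicity` when defined).
#' @export
scenarioExpertPrior <- function(scenario, domain = scenario$domain,
                                correct = TRUE, confidence = 3) {
  stopifnot(inherits(scenario, "scenario"), inherits(domain, "dose_domain"))
  flip <- function(p) if (correct) p else 1 - p
  priors <- list(efficacy = expertPrior(flip(scenario$true_eff(domain$doses)),
                                        confidence))
  if (!is.null(scenario$true_tox)) {
    priors$toxicity <- expertPrior(flip(scenario$true_tox(domain$doses)),
                                   confidence)
  }
  priors
}
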