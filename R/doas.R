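#' Dose-optimisation strategies
#'
#' A dose-optimisation approach (DOA) combines a dose-response model, a
#' trial-dose selection rule, a final-dose selection rule and a dosing-domain
#' discretisation. Four strategies are provided, sharing the generics
#' [proposeCohort()], [absorb()] and [finalDose()]:
#'
#' * `doaCobe()`: the CCBP model over a dense grid, Thompson sampling for
#'   trial doses, and maximised utility of posterior medians for the final
#'   dose. Optionally seeded with [expertPrior()]s.
#' * `doaParametric()`: latent quadratic efficacy / latent linear toxicity
#'   models calibrated by pseudo-data-stabilised maximum likelihood over a
#'   dense grid, softmax trial-dose allocation, and maximum predicted utility
#'   for the final dose.
#' * `doaAdaptiveNaive()`: independent per-dose beta distributions on a coarse
#'   grid (no similarity kernel), Thompson sampling, median-based final dose.
#' * `doaUniformNaive()`: the coarse grid with participants divided evenly
#'   across it (cohort size must equal the number of doses) and median-based
#'   final dose; entirely non-adaptive.
#'
#' Efficacy is always modelled; toxicity is modelled iff `utility` is the
#' contour. Every proposal is a member of the strategy's trial domain and
#' every nomination a member of its prediction domain (equal here); exact
#' utility ties are broken uniformly at random.
#'
#' @param domain A [doseDomain()]; defaults to the fine grid (CoBe,
#'   Parametric) or coarse grid (naive strategies) for `h` administrations.
#' @param utility A [utilitySpec()].
#' @param h Number of administrations used for the default domain.
#' @param kernel A [kernelSpec()] or named list with `efficacy` and `toxicity`
#'   kernels; defaults to the per-dimensionality standard lengths for both
#'   channels.
#' @param priors Optional named list of [expertPrior()]s (see [betaState()]).
#' @param temperature Softmax temperature for the parametric strategy.
#' @param pseudo_weight Likelihood weight of each pseudo-observation.
#' @return A `doa` object.
#' @name doas
NULL

doa_responses <- function(utility) {
  if (utility$kind == "utility_contour") c("efficacy", "toxicity")
  else "efficacy"
}

#' @rdname doas
#' @export
doaCobe <- function(domain = NULL, utility = utilitySpec("maximum_efficacy"),
                    h = 1L, kernel = NULL, priors = NULL) {
  if (is.null(domain)) domain <- fineDomain(h)
  stopifnot(inherits(domain, "dose_domain"), inherits(utility, "utility_spec"))
  if (is.null(kernel)) kernel <- defaultKernelSpec(domain$h)
  if (inherits(kernel, "kernel_spec")) {
    kernel <- list(efficacy = kernel, toxicity = kernel)
  }
  state <- betaState(domain, doa_responses(utility), priors = priors)
  structure(list(name = "cobe", domain = domain, utility = utility,
                 kernel = kernel, state = state),
            class = c("doa_cobe", "doa"))
}

#' @rdname doas
#' @export
doaParametric <- function(domain = NULL,
                          utility = utilitySpec("maximum_efficacy"),
                          h = 1L, temperature = 0.07, pseudo_weight = 0.5) {
  if (is.null(domain)) domain <- fineDomain(h)
  stopifnot(inherits(domain, "dose_domain"), inherits(utility, "utility_spec"))
  if (utility$kind == "utility_contour" && domain$h > 2L) {
    stop("the parametric strategy has no toxicity model for 3 administrations",
         call. = FALSE)
  }
  obj <- structure(list(name = "parametric", domain = domain,
                        utility = utility, temperature = temperature,
                        pseudo = pseudoData(domain$h, pseudo_weight),
                        log = NULL, fits = NULL),
                   class = c("doa_parametric", "doa"))
  refit_parametric(obj)
}

#' @rdname doas
#' @export
doaAdaptiveNaive <- function(domain = NULL,
                             utility = utilitySpec("maximum_efficacy"),
                             h = 1L) {
  if (is.null(domain)) domain <- coarseDomain(h)
  stopifnot(inherits(domain, "dose_domain"), inherits(utility, "utility_spec"))
  state <- betaState(domain, doa_responses(utility))
  structure(list(name = "adaptive_naive", domain = domain, utility = utility,
                 state = state),
            class = c("doa_adaptive_naive", "doa"))
}

#' @rdname doas
#' @export
doaUniformNaive <- function(domain = NULL,
                            utility = utilitySpec("maximum_efficacy"),
                            h = 1L) {
  if (is.null(domain)) domain <- coarseDomain(h)
  stopifnot(inherits(domain, "dose_domain"), inherits(utility, "utility_spec"))
  state <- betaState(domain, doa_responses(utility))
  structure(list(name = "uniform_naive", domain = domain, utility = utility,
                 state = state),
            class = c("doa_uniform_naive", "doa"))
}

#' @export
print.doa <- function(x, ...) {
  cat(sprintf("<doa:%s> %d doses (%dD), %s utility\n", x$name,
              nDoses(x$domain), x$domain$h, x$utility$kind))
  invisible(x)
}

#' Default sampling-cohort size of a strategy
#'
#' Adaptive strategies use cohorts of 6 participants; the uniform strategy's
#' cohort equals its domain size so each cohort covers every dose once.
#'
#' @param doa A `doa` object.
#' @return Integer cohort size.
#' @export
cohortSize <- function(doa) {
  stopifnot(inherits(doa, "doa"))
  if (doa$name == "uniform_naive") nDoses(doa$domain) else 6L
}

#' Propose the next sampling cohort
#'
#' Returns the doses the strategy assigns to the next `n` participants:
#' independent Thompson draws (CoBe, adaptive naive), softmax draws over
#' predicted utilities (parametric), or one sweep of the whole domain
#' (uniform naive, which requires `n` equal to the domain size and ignores
#' all data).
#'
#' @param doa A `doa` object.
#' @param n Number of participants in the cohort.
#' @return Matrix with `n` dose rows, each a member of the trial domain.
#' @export
proposeCohort <- function(doa, n = cohortSize(doa)) {
  UseMethod("proposeCohort")
}

#' Absorb a cohort's observations into a strategy
#'
#' @param doa A `doa` object.
#' @param obs Observation data frame ([makeObservations()]).
#' @return The updated strategy.
#' @export
absorb <- function(doa, obs) {
  UseMethod("absorb")
}

#' Nominate the currently optimal dose
#'
#' Deterministic given the model state up to uniform random tie-breaking:
#' CoBe and the naive strategies maximise the utility of the per-dose
#' posterior medians; the parametric strategy maximises the utility of its
#' calibrated model's predictions.
#'
#' @param doa A `doa` object.
#' @return List with `index` and `dose`.
#' @export
finalDose <- function(doa) {
  UseMethod("finalDose")
}

thompson_propose <- function(doa, n) {
  stopifnot(n >= 1L)
  contour <- doa$utility$kind == "utility_contour"
  idx <- vapply(seq_len(n), function(i) {
    p_eff <- sampleProbs(doa$state, "efficacy")
    p_tox <- if (contour) sampleProbs(doa$state, "toxicity") else NA
    argmax_random(utility(p_eff, p_tox, doa$utility))
  }, integer(1L))
  doa$domain$doses[idx, , drop = FALSE]
}

median_final <- function(doa) {
  contour <- doa$utility$kind == "utility_contour"
  p_eff <- stateMedian(doa$state, "efficacy")
  p_tox <- if (contour) stateMedian(doa$state, "toxicity") else NA
  i <- argmax_random(utility(p_eff, p_tox, doa$utility))
  list(index = i, dose = doa$domain$doses[i, ])
}

#' @export
proposeCohort.doa_cobe <- function(doa, n = cohortSize(doa)) {
  thompson_propose(doa, n)
}

#' @export
absorb.doa_cobe <- function(doa, obs) {
  doa$state <- updateState(doa$state, obs, doa$kernel)
  doa
}

#' @export
finalDose.doa_cobe <- function(doa) median_final(doa)

#' @export
proposeCohort.doa_adaptive_naive <- function(doa, n = cohortSize(doa)) {
  thompson_propose(doa, n)
}

#' @export
absorb.doa_adaptive_naive <- function(doa, obs) {
  doa$state <- updateStateUncorrelated(doa$state, obs)
  doa
}

#' @export
finalDose.doa_adaptive_naive <- function(doa) median_final(doa)

#' @export
proposeCohort.doa_uniform_naive <- function(doa, n = cohortSize(doa)) {
  if (n != nDoses(doa$domain)) {
    stop("the uniform strategy requires a cohort size equal to its domain size",
         call. = FALSE)
  }
  doa$domain$doses
}

#' @export
absorb.doa_uniform_naive <- function(doa, obs) {
  doa$state <- updateStateUncorrelated(doa$state, obs)
  doa
}

#' @export
finalDose.doa_uniform_naive <- function(doa) median_final(doa)

refit_parametric <- function(doa) {
  h <- doa$domain$h
  log <- doa$log
  fit_channel <- function(model, col) {
    if (is.null(log)) {
      d <- matrix(numeric(), 0L, h)
      y <- numeric()
    } else {
      rows <- !is.na(log[[col]])
      d <- obs_dose_matrix(log[rows, , drop = FALSE], h)
      y <- log[[col]][rows]
    }
    fitParametric(model, d, y, h, doa$pseudo)
  }
  fits <- list(efficacy = fit_channel("efficacy", "efficacy"))
  if (doa$utility$kind == "utility_contour") {
    fits$toxicity <- fit_channel("toxicity", "toxicity")
  }
  doa$fits <- fits
  doa
}

parametric_utilities <- function(doa) {
  p_eff <- latentQuadratic(doa$domain$doses, doa$fits$efficacy$params)
  p_tox <- if (doa$utility$kind == "utility_contour") {
    latentLinear(doa$domain$doses, doa$fits$toxicity$params)
  } else NA
  utility(p_eff, p_tox, doa$utility)
}

#' @export
proposeCohort.doa_parametric <- function(doa, n = cohortSize(doa)) {
  stopifnot(n >= 1L)
  w <- softmaxWeights(parametric_utilities(doa), doa$temperature)
  idx <- sample.int(length(w), n, replace = TRUE, prob = w)
  doa$domain$doses[idx, , drop = FALSE]
}

#' @export
absorb.doa_parametric <- function(doa, obs) {
  validate_observations(obs)
  doa$log <- if (is.null(doa$log)) obs else rbind(doa$log, obs)
  refit_parametric(doa)
}

#' @export
finalDose.doa_parametric <- function(doa) {
  i <- argmax_random(parametric_utilities(doa))
  list(index = i, dose = doa$domain$doses[i, ])
}
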