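#' Expert-elicited beta prior
#'
#' Expert knowledge enters the CCBP through the initial beta parameters. For a
#' predicted response probability `p` held with confidence `c` (interpretable
#' as the number of individuals' worth of data the expert opinion is worth),
#' the prior is `Beta(p * c + 1, (1 - p) * c + 1)`, whose mode is exactly `p`
#' whenever `c > 0`. Zero confidence reduces to the uninformative `Beta(1, 1)`.
#'
#' @param p_expert Per-dose predicted response probabilities in `[0, 1]`.
#' @param c_expert Per-dose confidences, non-negative; recycled if scalar.
#' @return An object of class `expert_prior` with `alpha0` and `beta0` vectors.
#' @examples
#' expertPrior(0.2, 3) # Beta(1.6, 3.4), mode 0.2
#' @export
expertPrior <- function(p_expert, c_expert) {
  p_expert <- as.numeric(p_expert)
  c_expert <- rep_len(as.numeric(c_expert), length(p_expert))
  if (anyNA(p_expert) || any(p_expert < 0) || any(p_expert > 1)) {
    stop("expert probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (anyNA(c_expert) || any(c_expert < 0)) {
    stop("expert confidences must be non-negative", call. = FALSE)
  }
  structure(list(p_expert = p_expert, c_expert = c_expert,
                 alpha0 = p_expert * c_expert + 1,
                 beta0 = (1 - p_expert) * c_expert + 1),
            class = "expert_prior")
}

#' Continuous Correlated Beta Process state
#'
#' Holds one beta distribution per dose and response channel. With no prior
#' information every distribution starts at the uninformative `Beta(1, 1)`;
#' an [expertPrior()] supplied for a channel replaces its initial parameters.
#' Efficacy and toxicity are tracked as independent channels that absorb the
#' same participant records.
#'
#' @param domain A [doseDomain()].
#' @param responses Character vector, subset of `c("efficacy", "toxicity")`.
#' @param priors Optional named list of [expertPrior()] objects, one entry per
#'   response channel (e.g. `list(efficacy = expertPrior(p, 3))`). Prior
#'   vectors must match the domain size.
#' @return An object of class `beta_state` with matrices `alpha` and `beta`
#'   (doses by responses), their initial values `alpha0`/`beta0`, and the
#'   observation count `n_obs`.
#' @examples
#' st <- betaState(doseDomain(c(0, 0.5, 1)), "efficacy")
#' stateMedian(st, "efficacy") # all 0.5 under the flat prior
#' @export
betaState <- function(domain, responses = c("efficacy", "toxicity"),
                      priors = NULL) {
  stopifnot(inherits(domain, "dose_domain"))
  responses <- match.arg(responses, c("efficacy", "toxicity"),
                         several.ok = TRUE)
  n <- nDoses(domain)
  alpha <- matrix(1, n, length(responses),
                  dimnames = list(NULL, responses))
  beta <- alpha
  for (r in names(priors)) {
    if (!r %in% responses) {
      stop(sprintf("prior supplied for unknown response channel '%s'", r),
           call. = FALSE)
    }
    pr <- priors[[r]]
    stopifnot(inherits(pr, "expert_prior"))
    if (length(pr$alpha0) != n) {
      stop("expert prior length must match the domain size", call. = FALSE)
    }
    alpha[, r] <- pr$alpha0
    beta[, r] <- pr$beta0
  }
  structure(list(domain = domain, alpha = alpha, beta = beta,
                 alpha0 = alpha, beta0 = beta, n_obs = 0L),
            class = "beta_state")
}

#' @export
print.beta_state <- function(x, ...) {
  cat(sprintf("<beta_state> %d doses x {%s}, %d observation(s) absorbed\n",
              nrow(x$alpha), paste(colnames(x$alpha), collapse = ", "),
              x$n_obs))
  invisible(x)
}

#' Participant observation records
#'
#' Observations are plain data frames with one row per participant: dose
#' component columns `dose_1[, dose_2, dose_3]` and binary `efficacy` and
#' `toxicity` columns (`NA` when that response was not assessed). Each row
#' must record at least one response.
#'
#' @param doses Numeric vector (1 administration) or matrix of dose rows.
#' @param efficacy,toxicity Binary (0/1) vectors or `NA`.
#' @return A data frame of observations.
#' @examples
#' makeObservations(c(0.2, 0.8), efficacy = c(1, 0))
#' @export
makeObservations <- function(doses, efficacy = NA, toxicity = NA) {
  if (is.numeric(doses) && is.null(dim(doses))) {
    doses <- matrix(doses, ncol = 1L)
  }
  doses <- as.matrix(doses)
  n <- nrow(doses)
  obs <- as.data.frame(doses)
  names(obs) <- paste0("dose_", seq_len(ncol(doses)))
  obs$efficacy <- rep_len(as.numeric(efficacy), n)
  obs$toxicity <- rep_len(as.numeric(toxicity), n)
  validate_observations(obs)
  obs
}

validate_observations <- function(obs) {
  stopifnot(is.data.frame(obs))
  for (col in c("efficacy", "toxicity")) {
    v <- obs[[col]]
    if (!all(is.na(v) | v %in% c(0, 1))) {
      stop(sprintf("%s outcomes must be 0, 1 or NA", col), call. = FALSE)
    }
  }
  if (any(is.na(obs$efficacy) & is.na(obs$toxicity))) {
    stop("every observation must record at least one response", call. = FALSE)
  }
  invisible(obs)
}

obs_dose_matrix <- function(obs, h) {
  cols <- paste0("dose_", seq_len(h))
  if (!all(cols %in% names(obs))) {
    stop("observation dose columns do not match the domain dimensionality",
         call. = FALSE)
  }
  as.matrix(obs[, cols, drop = FALSE])
}

#' Correlated CCBP update
#'
#' Absorbs participant records into a [betaState()]. For each observation at
#' dose `d_j`, every dose `d_i` gains kernel mass `K(d_i, d_j)` on its alpha
#' parameter (response observed) or beta parameter (response not observed) of
#' the relevant channel. The update is pure addition, so absorbing a batch is
#' order-independent, the tested dose itself always gains exactly 1, and the
#' total added mass per channel equals the summed kernel similarities.
#' Observation doses need not belong to the discretised domain.
#'
#' @param state A [betaState()].
#' @param obs Observations, as built by [makeObservations()].
#' @param spec A [kernelSpec()] matching the domain (one may use different
#'   kernels for the efficacy and toxicity channels by passing a named list
#'   `list(efficacy = ..., toxicity = ...)`).
#' @return The updated `beta_state`.
#' @examples
#' dom <- doseDomain(c(0, 0.1665109))
#' st <- betaState(dom, "efficacy")
#' st <- updateState(st, makeObservations(0, efficacy = 1), kernelSpec(0.2))
#' st$alpha[, "efficacy"] # 2 at the tested dose, 1.5 at the 50%-similar dose
#' @export
updateState <- function(state, obs, spec) {
  stopifnot(inherits(state, "beta_state"))
  validate_observations(obs)
  if (inherits(spec, "kernel_spec")) {
    spec <- list(efficacy = spec, toxicity = spec)
  }
  doses <- obs_dose_matrix(obs, state$domain$h)
  for (j in seq_len(nrow(obs))) {
    for (r in colnames(state$alpha)) {
      y <- obs[[r]][j]
      if (is.na(y)) next
      k <- kernelRow(doses[j, ], state$domain, spec[[r]])
      if (y == 1) {
        state$alpha[, r] <- state$alpha[, r] + k
      } else {
        state$beta[, r] <- state$beta[, r] + k
      }
    }
    state$n_obs <- state$n_obs + 1L
  }
  state
}

#' Uncorrelated beta-Bernoulli update
#'
#' The naive strategies' update rule: an observation informs only the exact
#' dose at which it was taken (equivalently, a kernel that is 1 on the tested
#' dose and 0 elsewhere). Observation doses must be members of the domain.
#'
#' @inheritParams updateState
#' @return The updated `beta_state`.
#' @export
updateStateUncorrelated <- function(state, obs) {
  stopifnot(inherits(state, "beta_state"))
  validate_observations(obs)
  doses <- obs_dose_matrix(obs, state$domain$h)
  for (j in seq_len(nrow(obs))) {
    i <- dose_index(state$domain, doses[j, ])
    if (is.na(i)) {
      stop("uncorrelated updates require observation doses in the domain",
           call. = FALSE)
    }
    for (r in colnames(state$alpha)) {
      y <- obs[[r]][j]
      if (is.na(y)) next
      if (y == 1) {
        state$alpha[i, r] <- state$alpha[i, r] + 1
      } else {
        state$beta[i, r] <- state$beta[i, r] + 1
      }
    }
    state$n_obs <- state$n_obs + 1L
  }
  state
}

check_response <- function(state, response) {
  if (!response %in% colnames(state$alpha)) {
    stop(sprintf("state does not track the '%s' channel", response),
         call. = FALSE)
  }
  response
}

#' Posterior summaries of a CCBP state
#'
#' `stateMedian()` returns the exact per-dose posterior medians (the
#' 0.5-quantile of each beta distribution, used for deterministic final dose
#' selection); `sampleProbs()` draws one probability per dose (the Thompson
#' sampling primitive); `credibleInterval()` gives an equal-tailed interval
#' for one dose.
#'
#' @param state A [betaState()].
#' @param response `"efficacy"` or `"toxicity"`.
#' @param i Dose index.
#' @param level Coverage level in `(0, 1)`.
#' @return `stateMedian()` and `sampleProbs()`: a numeric vector over doses;
#'   `credibleInterval()`: `c(lo, hi)`.
#' @export
stateMedian <- function(state, response = "efficacy") {
  stopifnot(inherits(state, "beta_state"))
  check_response(state, response)
  stats::qbeta(0.5, state$alpha[, response], state$beta[, response])
}

#' @rdname stateMedian
#' @export
sampleProbs <- function(state, response = "efficacy") {
  stopifnot(inherits(state, "beta_state"))
  check_response(state, response)
  stats::rbeta(nrow(state$alpha), state$alpha[, response],
               state$beta[, response])
}

#' @rdname stateMedian
#' @export
credibleInterval <- function(state, i, response = "efficacy", level = 0.95) {
  stopifnot(inherits(state, "beta_state"))
  check_response(state, response)
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    stop("level must lie strictly between 0 and 1", call. = FALSE)
  }
  a <- state$alpha[i, response]
  b <- state$beta[i, response]
  tail <- (1 - level) / 2
  c(lo = stats::qbeta(tail, a, b), hi = stats::qbeta(1 - tail, a, b))
}

#' Tabular snapshot of a CCBP state
#'
#' Serialises a [betaState()] to a long data frame (dose components, response,
#' alpha, beta) and back; `writeStateCsv()`/`readStateCsv()` do the same via
#' CSV on disk. Observation logs use [writeObservationsCsv()].
#'
#' @param state A [betaState()].
#' @return A data frame with one row per dose/response pair.
#' @export
stateTable <- function(state) {
  stopifnot(inherits(state, "beta_state"))
  responses <- colnames(state$alpha)
  do.call(rbind, lapply(responses, function(r) {
    out <- as.data.frame(state$domain$doses)
    out$response <- r
    out$alpha <- state$alpha[, r]
    out$beta <- state$beta[, r]
    out
  }))
}

#' @param path File path.
#' @rdname stateTable
#' @export
writeStateCsv <- function(state, path) {
  utils::write.csv(stateTable(state), path, row.names = FALSE)
  invisible(path)
}

#' @rdname stateTable
#' @export
readStateCsv <- function(path) {
  tab <- utils::read.csv(path)
  dose_cols <- grep("^dose_", names(tab), value = TRUE)
  responses <- unique(tab$response)
  first <- tab[tab$response == responses[[1L]], ]
  domain <- doseDomain(as.matrix(first[, dose_cols, drop = FALSE]))
  state <- betaState(domain, responses)
  for (r in responses) {
    slice <- tab[tab$response == r, ]
    state$alpha[, r] <- slice$alpha
    state$beta[, r] <- slice$beta
  }
  state
}

#' Observation log CSV round-trip
#'
#' Observation streams are written with header
#' `dose_1[,dose_2,dose_3],efficacy,toxicity`, using empty cells for responses
#' that were not assessed.
#'
#' @param obs An observation data frame ([makeObservations()]).
#' @param path File path.
#' @export
writeObservationsCsv <- function(obs, path) {
  validate_observations(obs)
  utils::write.csv(obs, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeObservationsCsv
#' @export
readObservationsCsv <- function(path) {
  obs <- utils::read.csv(path)
  for (col in c("efficacy", "toxicity")) {
    if (!col %in% names(obs)) obs[[col]] <- NA_real_
    obs[[col]] <- as.numeric(obs[[col]])
  }
  validate_observations(obs)
  obs
}
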