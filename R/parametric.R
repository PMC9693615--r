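#' Latent quadratic and latent linear dose-response models
#'
#' The parametric comparator strategy models dose-efficacy with a logistic
#' sigmoid of a per-axis quadratic latent score and dose-toxicity with a
#' sigmoid of a linear latent score:
#'
#' * efficacy: `p(d) = sigmoid(a + sum_o (b_o d_o - c_o d_o^2))`, parameter
#'   vector `c(a, b_1, ..., b_H, c_1, ..., c_H)`;
#' * toxicity: `p(d) = sigmoid(a + sum_o b_o d_o)`, parameters
#'   `c(a, b_1, ..., b_H)` (single or prime/boost administration only).
#'
#' The quadratic term allows non-monotone (peaking) efficacy; the linear
#' toxicity model is monotone in each component whenever its slopes are
#' positive.
#'
#' @param doses Dose vector or matrix of dose rows.
#' @param params Numeric parameter vector as above.
#' @return Probabilities strictly inside `(0, 1)`, one per dose row.
#' @examples
#' latentQuadratic(0.5, c(0, 4, 4)) # sigmoid(1)
#' latentLinear(0.5, c(-2, 4))      # sigmoid(0) = 0.5
#' @export
latentQuadratic <- function(doses, params) {
  if (length(params) %% 2L != 1L || length(params) < 3L) {
    stop("latent quadratic needs parameters c(a, b_1..b_H, c_1..c_H)",
         call. = FALSE)
  }
  h <- (length(params) - 1L) %/% 2L
  d <- as_dose_matrix(doses, h)
  a <- params[[1L]]
  b <- params[1L + seq_len(h)]
  cc <- params[1L + h + seq_len(h)]
  stats::plogis(a + as.vector(d %*% b) - as.vector(d^2 %*% cc))
}

#' @rdname latentQuadratic
#' @export
latentLinear <- function(doses, params) {
  h <- length(params) - 1L
  if (h < 1L || h > 2L) {
    stop("the latent linear toxicity model covers 1 or 2 administrations only",
         call. = FALSE)
  }
  d <- as_dose_matrix(doses, h)
  stats::plogis(params[[1L]] + as.vector(d %*% params[1L + seq_len(h)]))
}

# bare numeric vectors are read as stacked doses of dimensionality h
as_dose_matrix <- function(doses, h) {
  if (is.numeric(doses) && is.null(dim(doses))) {
    doses <- matrix(doses, ncol = h, byrow = TRUE)
  }
  doses <- as.matrix(doses)
  if (ncol(doses) != h) {
    stop(sprintf("dose matrix has %d components per dose but %d were expected",
                 ncol(doses), h), call. = FALSE)
  }
  doses
}

#' Stabilising pseudo-data for parametric calibration
#'
#' Maximum likelihood for a logistic latent model diverges under separation
#' (e.g. all participants responding). A small set of pseudo-observations --
#' one success and one failure, each at likelihood weight `weight`, placed at
#' the extremes and centre of the dose space (the endpoints and midpoint in
#' one dimension; the corners plus the centre for prime/boost grids) -- keeps
#' the optimum finite with minimal bias.
#'
#' @param h Number of administrations.
#' @param weight Likelihood weight of each pseudo-observation.
#' @return A list with `doses` (matrix), `outcomes` and `weights` vectors.
#' @export
pseudoData <- function(h = 1L, weight = 0.5) {
  stopifnot(h %in% 1:3, weight >= 0)
  corners <- as.matrix(expand.grid(rep(list(c(0, 1)), h),
                                   KEEP.OUT.ATTRS = FALSE))
  pts <- rbind(corners, matrix(0.5, 1L, h))
  doses <- pts[rep(seq_len(nrow(pts)), each = 2L), , drop = FALSE]
  outcomes <- rep(c(1, 0), nrow(pts))
  list(doses = unname(doses), outcomes = outcomes,
       weights = rep(weight, length(outcomes)))
}

#' Maximum-likelihood calibration of the latent models
#'
#' Fits [latentQuadratic()] (`model = "efficacy"`) or [latentLinear()]
#' (`model = "toxicity"`) to binary outcomes by minimising the weighted
#' Bernoulli negative log-likelihood of the real observations plus
#' [pseudoData()]. Optimisation is multi-start BFGS from three fixed starting
#' points with a fixed tolerance, so the fit is deterministic given the data.
#'
#' @param model `"efficacy"` or `"toxicity"`.
#' @param doses Matrix of observed dose rows (possibly zero rows).
#' @param outcomes Binary outcome vector matching `doses`.
#' @param h Number of administrations.
#' @param pseudo Pseudo-data list from [pseudoData()].
#' @return List with `params`, the minimised `nll` and a `converged` flag.
#'   Non-convergence is reported with a warning and the best parameters found.
#' @export
fitParametric <- function(model = c("efficacy", "toxicity"), doses, outcomes,
                          h = 1L, pseudo = pseudoData(h)) {
  model <- match.arg(model)
  if (model == "toxicity" && h > 2L) {
    stop("the latent linear toxicity model covers 1 or 2 administrations only",
         call. = FALSE)
  }
  doses <- if (is.null(doses) || length(doses) == 0L) {
    matrix(numeric(), 0L, h)
  } else {
    as_dose_matrix(doses, h)
  }
  all_d <- rbind(doses, pseudo$doses)
  all_y <- c(outcomes, pseudo$outcomes)
  all_w <- c(rep(1, nrow(doses)), pseudo$weights)
  predict_fn <- if (model == "efficacy") latentQuadratic else latentLinear
  n_par <- if (model == "efficacy") 1L + 2L * h else 1L + h

  nll <- function(theta) {
    p <- pmin(pmax(predict_fn(all_d, theta), 1e-12), 1 - 1e-12)
    -sum(all_w * (all_y * log(p) + (1 - all_y) * log(1 - p)))
  }
  starts <- list(rep(0, n_par),
                 c(-1, rep(4, n_par - 1L)),
                 c(1, rep(-2, n_par - 1L)))
  best <- NULL
  any_conv <- FALSE
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, nll, method = "BFGS",
                   control = list(maxit = 500L, reltol = 1e-8)),
      error = function(e) NULL)
    if (is.null(fit)) next
    any_conv <- any_conv || fit$convergence == 0L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop("parametric calibration failed from every starting point",
         call. = FALSE)
  }
  if (!any_conv) {
    warning("parametric calibration did not converge; returning best-so-far parameters",
            call. = FALSE)
  }
  list(params = best$par, nll = best$value, converged = any_conv)
}

#' Softmax dose-allocation weights
#'
#' Trial-dose selection for the parametric strategy: a dose is drawn with
#' probability proportional to `exp(U_i / temperature)` over its predicted
#' utilities. Low temperatures concentrate on the predicted optimum (greedy
#' in the limit), high temperatures approach uniform exploration. The default
#' temperature of 0.07 on the unit utility scale concentrates sampling near
#' the predicted optimum while retaining exploration.
#'
#' @param utilities Numeric predicted utilities over the domain.
#' @param temperature Positive softmax temperature.
#' @return Selection probabilities summing to 1.
#' @export
softmaxWeights <- function(utilities, temperature = 0.07) {
  if (!is.numeric(temperature) || temperature <= 0) {
    stop("softmax temperature must be positive", call. = FALSE)
  }
  z <- utilities / temperature
  w <- exp(z - max(z))
  w / sum(w)
}
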