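#' Dose-similarity kernel specification
#'
#' The CCBP propagates information between doses through a similarity kernel.
#' A kernel specification holds one positive length hyperparameter per
#' administration axis; smaller lengths restrict the influence of an
#' observation to nearby doses. The defaults (0.2 for single administration,
#' 0.25 per axis for prime/boost, 0.4 per axis for prime/boost/second-boost)
#' are the values used in the simulation study; they need not be equal across
#' axes.
#'
#' @param lengths Numeric vector of positive length hyperparameters, one per
#'   administration axis.
#' @return An object of class `kernel_spec`.
#' @examples
#' kernelSpec(0.2)
#' defaultKernelSpec(2)
#' @export
kernelSpec <- function(lengths) {
  lengths <- as.numeric(lengths)
  if (length(lengths) < 1L || length(lengths) > 3L) {
    stop("a kernel needs 1 to 3 length hyperparameters", call. = FALSE)
  }
  if (anyNA(lengths) || any(lengths <= 0)) {
    stop("kernel length hyperparameters must be positive", call. = FALSE)
  }
  structure(list(lengths = lengths), class = "kernel_spec")
}

#' @param h Number of administrations.
#' @rdname kernelSpec
#' @export
defaultKernelSpec <- function(h = 1L) {
  stopifnot(h %in% 1:3)
  kernelSpec(rep(c(0.2, 0.25, 0.4)[h], h))
}

#' Squared-exponential dose similarity
#'
#' Similarity between doses `d_i` and `d_j` is
#' `exp(-sum_o (d_io - d_jo)^2 / l_o^2)`: 1 for identical doses, strictly
#' positive, symmetric, and decaying with per-component distance. The
#' multi-administration kernel factorises into the product of per-axis
#' one-dimensional kernels. Values are never truncated to zero; complete
#' dissimilarity is only a limit.
#'
#' @param d_i,d_j Numeric dose vectors of equal length (1--3 components).
#' @param spec A [kernelSpec()] with matching dimensionality.
#' @return Similarity in `(0, 1]`.
#' @examples
#' sqExpKernel(0.5, 0.7, kernelSpec(0.2)) # exp(-1)
#' @export
sqExpKernel <- function(d_i, d_j, spec) {
  d_i <- as.numeric(d_i)
  d_j <- as.numeric(d_j)
  stopifnot(inherits(spec, "kernel_spec"))
  if (length(d_i) != length(d_j) || length(d_i) != length(spec$lengths)) {
    stop("doses and kernel lengths must share dimensionality", call. = FALSE)
  }
  exp(-sum((d_i - d_j)^2 / spec$lengths^2))
}

#' Kernel similarities between one dose and a whole domain
#'
#' Vectorised evaluation of [sqExpKernel()] between `d_j` and every dose in
#' `domain`. `d_j` need not be a member of the domain: the kernel is defined
#' continuously, so observations taken off-grid still inform every on-grid
#' dose.
#'
#' @param d_j Numeric dose vector with the domain's dimensionality.
#' @param domain A [doseDomain()].
#' @param spec A [kernelSpec()].
#' @return Numeric vector of similarities, one per domain dose.
#' @export
kernelRow <- function(d_j, domain, spec) {
  stopifnot(inherits(domain, "dose_domain"), inherits(spec, "kernel_spec"))
  d_j <- as.numeric(d_j)
  if (length(d_j) != domain$h || length(spec$lengths) != domain$h) {
    stop("dose, domain and kernel lengths must share dimensionality",
         call. = FALSE)
  }
  diffs <- sweep(domain$doses, 2L, d_j, "-")
  exp(-as.vector(diffs^2 %*% (1 / spec$lengths^2)))
}
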