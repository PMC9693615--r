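#' Construct a discretised dosing domain
#'
#' A dosing domain is the finite, ordered set of candidate doses a trial may
#' test or nominate. Each dose is a vector of 1--3 components (the scaled
#' amounts given at the prime, boost and second-boost administrations), every
#' component scaled to `[0, 1]`. A zero component is the smallest dose a
#' developer would consider, not necessarily "no vaccine".
#'
#' @param doses Numeric vector (single-administration) or matrix with one row
#'   per dose and one column per administration (1--3 columns). All values must
#'   lie in `[0, 1]` and rows must be distinct.
#' @return An object of class `dose_domain` with elements `doses` (matrix) and
#'   `h` (number of administrations).
#' @examples
#' doseDomain(seq(0, 1, by = 0.2))
#' doseDomain(as.matrix(expand.grid(c(0, 0.5, 1), c(0, 0.5, 1))))
#' @export
doseDomain <- function(doses) {
  if (is.numeric(doses) && is.null(dim(doses))) {
    doses <- matrix(doses, ncol = 1L)
  }
  doses <- as.matrix(doses)
  storage.mode(doses) <- "double"
  if (nrow(doses) < 1L) {
    stop("a dosing domain needs at least one dose", call. = FALSE)
  }
  if (!(ncol(doses) %in% 1:3)) {
    stop("doses must have 1, 2 or 3 components per administration", call. = FALSE)
  }
  if (anyNA(doses) || any(doses < 0) || any(doses > 1)) {
    stop("all dose components must lie in [0, 1]", call. = FALSE)
  }
  if (anyDuplicated(doses)) {
    stop("dosing domain contains duplicate doses", call. = FALSE)
  }
  dimnames(doses) <- list(NULL, paste0("dose_", seq_len(ncol(doses))))
  structure(list(doses = doses, h = ncol(doses)), class = "dose_domain")
}

#' Regular grid dosing domains
#'
#' `doseGrid()` builds a regular lattice over `[0,1]^h`. `fineDomain()` and
#' `coarseDomain()` return the discretisations used throughout the simulation
#' study: model-based strategies search a dense grid (101 doses for single
#' administration, a 21-by-21 grid of 441 doses for prime/boost, an
#' 11-by-11-by-11 grid of 1331 doses for prime/boost/second-boost) while the
#' naive strategies use a small one (6, 9 or 27 doses).
#'
#' @param h Number of administrations (1, 2 or 3).
#' @param points_per_axis Number of equally spaced points on each axis.
#' @return A [doseDomain()].
#' @examples
#' nDoses(fineDomain(1))   # 101
#' nDoses(coarseDomain(3)) # 27
#' @export
doseGrid <- function(h = 1L, points_per_axis) {
  stopifnot(h %in% 1:3, points_per_axis >= 2L)
  axis <- seq(0, 1, length.out = points_per_axis)
  grid <- as.matrix(expand.grid(rep(list(axis), h), KEEP.OUT.ATTRS = FALSE))
  doseDomain(grid)
}

#' @rdname doseGrid
#' @export
fineDomain <- function(h = 1L) {
  doseGrid(h, c(101L, 21L, 11L)[h])
}

#' @rdname doseGrid
#' @export
coarseDomain <- function(h = 1L) {
  doseGrid(h, c(6L, 3L, 3L)[h])
}

#' @param domain A `dose_domain`.
#' @rdname doseDomain
#' @export
nDoses <- function(domain) {
  stopifnot(inherits(domain, "dose_domain"))
  nrow(domain$doses)
}

#' @param i Dose index.
#' @rdname doseDomain
#' @export
doseAt <- function(domain, i) {
  stopifnot(inherits(domain, "dose_domain"))
  domain$doses[i, , drop = TRUE]
}

# index of an exact member of the domain, or NA
dose_index <- function(domain, dose) {
  hits <- which(colSums(abs(t(domain$doses) - as.numeric(dose))) == 0)
  if (length(hits)) hits[[1L]] else NA_integer_
}

#' @export
print.dose_domain <- function(x, ...) {
  cat(sprintf("<dose_domain> %d doses, %d administration(s)\n",
              nrow(x$doses), x$h))
  invisible(x)
}
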