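#' Dose utility specification
#'
#' Optimal dose is defined as the maximiser of a utility of the efficacy and
#' toxicity probabilities. Two utilities are supported:
#'
#' * `"maximum_efficacy"`: `U = p_eff`, ignoring toxicity.
#' * `"utility_contour"`: the efficacy-toxicity trade-off
#'   `U = 1 - ((1 - p_eff) / (1 - anchor_eff))^rho - (p_tox / anchor_tox)^rho)^(1/rho)`
#'   whose zero-utility level set passes exactly through the clinician-chosen
#'   anchor points `(anchor_eff, 0)` and `(1, anchor_tox)`, with curvature
#'   controlled by `rho`.
#'
#' The shipped contour defaults (`anchor_eff = 0.5`, `anchor_tox = 0.65`,
#' `rho = 2`) are illustrative trade-off values in the style of
#' efficacy-toxicity contour designs; clinicians should set them per trial.
#' Contour values are not clamped: a dose worse than the zero-utility contour
#' legitimately scores below zero.
#'
#' @param kind `"maximum_efficacy"` or `"utility_contour"`.
#' @param anchor_eff,anchor_tox Contour anchors, strictly inside `(0, 1)`.
#' @param rho Positive contour curvature.
#' @return An object of class `utility_spec`.
#' @export
utilitySpec <- function(kind = c("maximum_efficacy", "utility_contour"),
                        anchor_eff = 0.5, anchor_tox = 0.65, rho = 2) {
  kind <- match.arg(kind)
  if (kind == "utility_contour") {
    if (!is.numeric(anchor_eff) || anchor_eff <= 0 || anchor_eff >= 1 ||
        !is.numeric(anchor_tox) || anchor_tox <= 0 || anchor_tox >= 1) {
      stop("contour anchors must lie strictly inside (0, 1)", call. = FALSE)
    }
    if (!is.numeric(rho) || rho <= 0) {
      stop("rho must be positive", call. = FALSE)
    }
  }
  structure(list(kind = kind, anchor_eff = anchor_eff,
                 anchor_tox = anchor_tox, rho = rho),
            class = "utility_spec")
}

#' Evaluate a dose utility
#'
#' Vectorised over doses: `p_eff` and `p_tox` may be equal-length vectors.
#' The maximum-efficacy utility ignores `p_tox` entirely (it may be `NA`).
#'
#' @param p_eff,p_tox Probabilities in `[0, 1]`.
#' @param spec A [utilitySpec()].
#' @return Numeric utilities (increasing in `p_eff`; for the contour,
#'   decreasing in `p_tox`).
#' @examples
#' utility(0.37, NA, utilitySpec("maximum_efficacy"))
#' utility(1, 0, utilitySpec("utility_contour")) # 1
#' @export
utility <- function(p_eff, p_tox = NA, spec) {
  stopifnot(inherits(spec, "utility_spec"))
  p_eff <- as.numeric(p_eff)
  if (anyNA(p_eff) || any(p_eff < 0) || any(p_eff > 1)) {
    stop("efficacy probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (spec$kind == "maximum_efficacy") {
    return(p_eff)
  }
  p_tox <- as.numeric(p_tox)
  if (length(p_tox) != length(p_eff)) {
    if (length(p_tox) == 1L) p_tox <- rep_len(p_tox, length(p_eff))
    else stop("p_eff and p_tox must have equal length", call. = FALSE)
  }
  if (anyNA(p_tox) || any(p_tox < 0) || any(p_tox > 1)) {
    stop("the utility contour requires toxicity probabilities in [0, 1]",
         call. = FALSE)
  }
  1 - (((1 - p_eff) / (1 - spec$anchor_eff))^spec$rho +
         (p_tox / spec$anchor_tox)^spec$rho)^(1 / spec$rho)
}

# internal: argmax with uniform random resolution of exact ties
argmax_random <- function(x, tol = 0) {
  m <- max(x)
  idx <- which(x >= m - tol)
  if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)]
}
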