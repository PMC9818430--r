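#' Transform CA-125 to the modelling scale
#'
#' The longitudinal sub-model works on the natural logarithm of the square
#' root of CA-125, i.e. `log(sqrt(x)) = log(x) / 2`. This transform
#' stabilises the residual variance of marker trajectories, whose raw scale
#' spans several orders of magnitude (tens to tens of thousands of IU/mL),
#' and makes the within-chemotherapy decline approximately linear in time.
#'
#' @param x Numeric vector of CA-125 concentrations in IU/mL; must be
#'   strictly positive.
#' @return Numeric vector on the transformed scale.
#' @seealso [inv_transform_ca125()] for the inverse.
#' @examples
#' transform_ca125(926)
#' inv_transform_ca125(transform_ca125(926))
#' @export
transform_ca125 <- function(x) {
  if (!is.numeric(x)) {
    rlang::abort("`x` must be numeric.", class = "ca125jm_error_type")
  }
  if (any(!is.finite(x)) || any(x <= 0)) {
    rlang::abort(
      "CA-125 values must be finite and strictly positive (IU/mL).",
      class = "ca125jm_error_domain"
    )
  }
  log(x) / 2
}

#' @rdname transform_ca125
#' @param y Numeric vector on the transformed (log-square-root) scale.
#' @export
inv_transform_ca125 <- function(y) {
  exp(2 * y)
}
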