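#' Canonical regime parameter points
#'
#' The (G_CaL, G_Ks) multiplier pairs used as the package's worked examples
#' of the four dynamical regimes, chosen from the package's own single-cell
#' phase diagram (see the methods vignette):
#' \describe{
#'   \item{baseline}{(1, 1): normal AP; plain propagation / single stable
#'     spiral in tissue.}
#'   \item{sf_a}{(4, 0.6): multiple EADs per AP; tissue breakup into many
#'     small Ca-mediated spirals (spiral fibrillation type a).}
#'   \item{sf_b}{(6, 1): normal single-stimulus AP near the EAD boundary;
#'     S1--S2 spirals break up into Na-mediated chaotic waves (type b).}
#'   \item{osc}{(8, 0.4): non-repolarizing oscillatory AP, single-cell
#'     oscillation near 6 Hz; phase-wave patterns in tissue.}
#' }
#'
#' @param regime One of `"baseline"`, `"sf_a"`, `"sf_b"`, `"osc"`.
#' @param ... Passed on to [make_params()].
#' @return A `tp06_params` object.
#' @export
regime_params <- function(regime = c("baseline", "sf_a", "sf_b", "osc"), ...) {
  regime <- match.arg(regime)
  m <- switch(regime,
              baseline = c(1, 1),
              sf_a = c(4, 0.6),
              sf_b = c(6, 1),
              osc = c(8, 0.4))
  make_params(mult_CaL = m[1], mult_Ks = m[2], ...)
}
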