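#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted complex
#'
#' One row per estimated kinetic parameter.
#'
#' @param x A `chemios_fit` from [fit_etc_complex()].
#' @param ... Unused.
#' @return A tibble with `param` and `estimate`.
#' @method tidy chemios_fit
#' @export
tidy.chemios_fit <- function(x, ...) x$estimates

#' One-row summary of a fitted complex
#'
#' @param x A `chemios_fit` from [fit_etc_complex()].
#' @param ... Unused.
#' @return A one-row tibble with the combined residual, curve count,
#'   degeneracy flag and complex name.
#' @method glance chemios_fit
#' @export
glance.chemios_fit <- function(x, ...) {
  tibble::tibble(complex = x$complex,
                 combined_residual = x$combined_residual,
                 n_curves = length(x$per_curve_residuals),
                 degenerate = x$degenerate,
                 Km_A_fitted = x$Km_A_fitted)
}

#' @rdname tidy.chemios_fit
#' @method tidy model_comparison
#' @export
tidy.model_comparison <- function(x, ...) {
  tibble::tibble(model = x$model, residual = x$residual)
}
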