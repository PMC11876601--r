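#' Accessors for fitted dose-response curves
#'
#' Extract fitted parameters and derived statistics from a
#' \linkS4class{CurveFit} object.
#'
#' @param object A \linkS4class{CurveFit}.
#' @return A numeric scalar (`ec50` in molar, `pec50` unitless, `fitR2` in
#'   \[0,1\], `fitAuc` in percent) or a logical (`isConverged`).
#' @seealso [fit4PL()]
#' @examples
#' fit <- fit4PL(10^seq(-10, -5, length.out = 8),
#'               fourPL(10^seq(-10, -5, length.out = 8), 100, 0, 1, 1e-7))
#' ec50(fit)
#' pec50(fit)
#' @aliases ec50 pec50 fitR2 fitAuc isConverged
#' @name CurveFit-accessors
NULL

#' @rdname CurveFit-accessors
#' @export
setGeneric("ec50", function(object) standardGeneric("ec50"))

#' @rdname CurveFit-accessors
#' @export
setGeneric("pec50", function(object) standardGeneric("pec50"))

#' @rdname CurveFit-accessors
#' @export
setGeneric("fitR2", function(object) standardGeneric("fitR2"))

#' @rdname CurveFit-accessors
#' @export
setGeneric("fitAuc", function(object) standardGeneric("fitAuc"))

#' @rdname CurveFit-accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))
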