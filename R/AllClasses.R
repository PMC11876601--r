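#' @include AllGenerics.R
NULL

#' Fitted four-parameter log-logistic dose-response curve
#'
#' Container for the result of [fit4PL()]. The model is
#' \deqn{R(d) = bottom + \frac{top - bottom}{1 + 10^{\,slope\,(\log_{10} d -
#'   \log_{10} EC_{50})}}}
#' so `top` is the zero-dose asymptote, `bottom` the saturating plateau and a
#' positive `slope` describes a response that decreases with dose (the viability
#' convention). Degenerate inputs (all-identical responses, optimizer failure)
#' yield a flat fallback with `top == bottom` and undefined `ec50`.
#'
#' @slot top,bottom Asymptotes, in response units (percent of vehicle for
#'   viability, intensity ratio or log2 ratio for proteomic series).
#' @slot slope Unitless Hill-type slope (> 0); `NA` for flat fits.
#' @slot ec50 Half-maximal effective concentration in molar; `NA` for flat fits.
#' @slot r2 Squared Pearson correlation between fitted and observed responses;
#'   0 by convention when either side has zero variance.
#' @slot auc Normalized area under the clipped curve over `doseRange`, in
#'   percent (`NA` when the response scale is not percent-of-vehicle).
#' @slot converged Logical; `FALSE` when the flat fallback was used because
#'   optimization failed.
#' @slot flat Logical; `TRUE` for a flat (constant) fit.
#' @slot doseRange Numeric length-2, tested dose range in molar.
#' @slot n Integer, number of observations fitted.
#' @slot sse Residual sum of squares of the winning start.
#'
#' @seealso [fit4PL()], [curveAuc()], [classifyEfficacy()]
#' @examples
#' d <- 1e-9 * 3^(0:10)
#' fit <- fit4PL(d, fourPL(d, 100, 0, 1, 1e-7))
#' fit
#' coef(fit)
#' @aliases CurveFit
#' @export
setClass("CurveFit",
  slots = c(
    top = "numeric", bottom = "numeric", slope = "numeric", ec50 = "numeric",
    r2 = "numeric", auc = "numeric", converged = "logical", flat = "logical",
    doseRange = "numeric", n = "integer", sse = "numeric"
  ),
  prototype = list(
    top = NA_real_, bottom = NA_real_, slope = NA_real_, ec50 = NA_real_,
    r2 = NA_real_, auc = NA_real_, converged = FALSE, flat = FALSE,
    doseRange = c(NA_real_, NA_real_), n = 0L, sse = NA_real_
  )
)

setValidity("CurveFit", function(object) {
  msg <- character()
  if (length(object@ec50) != 1L)
    msg <- c(msg, "'ec50' must be a single value")
  if (!is.na(object@ec50) && object@ec50 <= 0)
    msg <- c(msg, "'ec50' must be positive")
  if (!is.na(object@r2) && (object@r2 < 0 || object@r2 > 1))
    msg <- c(msg, "'r2' must lie in [0, 1]")
  if (length(object@doseRange) != 2L)
    msg <- c(msg, "'doseRange' must have length 2")
  if (length(msg)) msg else TRUE
})

#' @rdname CurveFit-accessors
#' @export
setMethod("ec50", "CurveFit", function(object) object@ec50)

#' @rdname CurveFit-accessors
#' @export
setMethod("pec50", "CurveFit", function(object) {
  if (is.na(object@ec50)) NA_real_ else -log10(object@ec50)
})

#' @rdname CurveFit-accessors
#' @export
setMethod("fitR2", "CurveFit", function(object) object@r2)

#' @rdname CurveFit-accessors
#' @export
setMethod("fitAuc", "CurveFit", function(object) object@auc)

#' @rdname CurveFit-accessors
#' @export
setMethod("isConverged", "CurveFit", function(object) object@converged)

#' @describeIn CurveFit-accessors Named vector of the four fitted parameters.
#' @exportMethod coef
setMethod("coef", "CurveFit", function(object) {
  c(top = object@top, bottom = object@bottom,
    slope = object@slope, ec50 = object@ec50)
})

#' @describeIn CurveFit-accessors One-row data.frame of all fit statistics.
#' @param x A `CurveFit`.
#' @param row.names,optional,... Passed on conventions of [as.data.frame()];
#'   ignored.
#' @exportMethod as.data.frame
setMethod("as.data.frame", "CurveFit",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(
      top = x@top, bottom = x@bottom, slope = x@slope, ec50 = x@ec50,
      pec50 = pec50(x), r2 = x@r2, auc = x@auc,
      converged = x@converged, flat = x@flat,
      dose_min = x@doseRange[1], dose_max = x@doseRange[2], n = x@n
    )
  })

setMethod("show", "CurveFit", function(object) {
  cat("CurveFit (4PL, log10-dose logistic)\n")
  if (object@flat) {
    cat(sprintf("  flat fit: response = %.4g (n = %d)\n",
                object@top, object@n))
  } else {
    cat(sprintf("  top = %.4g  bottom = %.4g  slope = %.3g\n",
                object@top, object@bottom, object@slope))
    cat(sprintf("  EC50 = %.4g M (pEC50 = %.3g)\n",
                object@ec50, pec50(object)))
  }
  cat(sprintf("  R2 = %.3f  AUC = %s  converged = %s\n",
              object@r2,
              if (is.na(object@auc)) "NA" else sprintf("%.1f%%", object@auc),
              object@converged))
  invisible(object)
})

#' Phosphosite-level reporter-intensity experiment
#'
#' A thin extension of
#' \link[SummarizedExperiment]{SummarizedExperiment} holding summed
#' reporter-ion intensities for localized phosphosites. Rows are site records
#' (keyed by protein and site set so that singly and multiply phosphorylated
#' forms are distinct analytes); columns are (batch, channel) combinations.
#'
#' `colData` must contain `batch` (character), `channel` (integer 1..11),
#' `role` (`"dose"`, `"gem"` or `"vehicle"`) and `dose_nM` (`NA` for
#' non-titration channels). `rowData` must contain `protein`, `site`,
#' `sequence_window` and `localization_prob`.
#'
#' Objects are normally created by [aggregateSites()].
#'
#' @seealso [aggregateSites()], [normalizeChannels()], [callRegulation()]
#' @aliases PhosphoExperiment
#' @export
setClass("PhosphoExperiment", contains = "SummarizedExperiment")

#' @param intensity Numeric matrix of summed reporter intensities, sites in
#'   rows, (batch, channel) combinations in columns.
#' @param rowData,colData `DataFrame`s as described above.
#' @return `PhosphoExperiment()` returns a validated object.
#' @rdname PhosphoExperiment-class
#' @export
PhosphoExperiment <- function(intensity, rowData, colData) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensity),
    rowData = rowData, colData = colData)
  methods::new("PhosphoExperiment", se)
}

setValidity("PhosphoExperiment", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  need <- c("batch", "channel", "role", "dose_nM")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks column(s): ",
                         paste(miss, collapse = ", ")))
  if ("role" %in% colnames(cd) &&
      !all(cd$role %in% c("dose", "gem", "vehicle")))
    msg <- c(msg, "role must be one of 'dose', 'gem', 'vehicle'")
  rd <- SummarizedExperiment::rowData(object)
  needr <- c("protein", "site", "sequence_window", "localization_prob")
  missr <- setdiff(needr, colnames(rd))
  if (length(missr))
    msg <- c(msg, paste0("rowData lacks column(s): ",
                         paste(missr, collapse = ", ")))
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PhosphoExperiment", function(object) {
  callNextMethod()
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("batches(%d): %s\n", length(unique(cd$batch)),
              paste(unique(cd$batch), collapse = " ")))
  invisible(object)
})
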