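#' @include AllClasses.R
NULL

#' Evaluate the four-parameter log-logistic model
#'
#' \code{fourPL(d) = bottom + (top - bottom) / (1 + 10^(slope * (log10(d) -
#' log10(ec50))))}. A positive slope gives a response that decreases with
#' dose, the usual convention for viability and competition-binding curves.
#'
#' @param dose Numeric vector of strictly positive doses (molar).
#' @param top,bottom Asymptotes in response units.
#' @param slope Unitless slope (> 0 for decreasing curves).
#' @param ec50 Half-maximal effective concentration (molar, > 0).
#' @return Numeric vector of model responses.
#' @examples
#' fourPL(1e-7, top = 100, bottom = 0, slope = 1, ec50 = 1e-7)  # midpoint: 50
#' @export
fourPL <- function(dose, top, bottom, slope, ec50) {
  stopifnot(all(dose > 0), ec50 > 0)
  bottom + (top - bottom) / (1 + 10^(slope * (log10(dose) - log10(ec50))))
}

## Residuals for nls.lm; parameters on the optimizer scale:
## (top, bottom, slope, logEc50) or (top, bottom, logEc50) with fixed slope.
.fourPLResiduals <- function(par, dose, resp, fixedSlope = NULL) {
  logd <- log10(dose)
  if (is.null(fixedSlope)) {
    top <- par[1]; bottom <- par[2]; slope <- par[3]; logEc50 <- par[4]
  } else {
    top <- par[1]; bottom <- par[2]; slope <- fixedSlope; logEc50 <- par[3]
  }
  resp - (bottom + (top - bottom) / (1 + 10^(slope * (logd - logEc50))))
}

.flatFit <- function(doses, responses, converged) {
  m <- mean(responses)
  new("CurveFit",
      top = m, bottom = m, slope = NA_real_, ec50 = NA_real_,
      r2 = 0, auc = NA_real_, converged = converged, flat = TRUE,
      doseRange = range(doses), n = length(responses),
      sse = sum((responses - m)^2))
}

#' Fit a four-parameter log-logistic dose-response curve
#'
#' Multi-start bounded least squares on the model of [fourPL()]. Candidate
#' starts place the EC50 at every tested dose and try slopes 0.5, 1 and 2
#' (a single slope when `fixedSlope` is given); starts are ranked by their
#' initial residual sum of squares and the best `maxStarts` are refined with
#' Levenberg-Marquardt (\code{minpack.lm}). The refined fit with the smallest
#' final SSE wins; exact ties go to the smaller EC50. EC50 is constrained to
#' `ec50Bounds` (default: tested range widened 100-fold on both sides) and the
#' slope to \[0.01, 15\].
#'
#' Goodness of fit `r2` is the squared Pearson correlation between fitted and
#' observed responses (0 by convention when either is constant). When
#' `percentScale = TRUE` the normalized AUC over the tested dose range is
#' stored in the object (see [curveAuc()]).
#'
#' All-identical responses give a converged flat fit with undefined EC50;
#' optimizer failure on all starts gives a non-converged flat fallback with
#' `top == bottom ==` mean response.
#'
#' @param doses Strictly positive molar doses, at least 4 distinct values.
#' @param responses Finite numeric responses, same length as `doses`.
#' @param fixedSlope Optional fixed slope (e.g. `1` for sparse organoid-style
#'   designs); `NULL` (default) fits the slope freely.
#' @param ec50Bounds Length-2 molar bounds for the EC50.
#' @param percentScale Responses are percent-of-vehicle; compute the AUC.
#' @param maxStarts Number of ranked candidate starts refined (default 6).
#' @return A \linkS4class{CurveFit}.
#' @examples
#' d <- 10000e-9 / 3^(10:0)                 # 170 pM .. 10 uM, 1:3 steps
#' fit <- fit4PL(d, fourPL(d, 100, 0, 1, 1e-7))
#' c(ec50(fit), pec50(fit), fitR2(fit))
#' @export
fit4PL <- function(doses, responses, fixedSlope = NULL,
                   ec50Bounds = c(min(doses) / 100, max(doses) * 100),
                   percentScale = TRUE, maxStarts = 6L) {
  stopifnot(is.numeric(doses), is.numeric(responses),
            length(doses) == length(responses))
  keep <- is.finite(doses) & is.finite(responses) & doses > 0
  doses <- doses[keep]; responses <- responses[keep]
  if (length(unique(doses)) < 4L)
    stop("fit4PL() needs at least 4 distinct positive doses")
  ord <- order(doses)
  doses <- doses[ord]; responses <- responses[ord]

  if (diff(range(responses)) == 0) {
    fit <- .flatFit(doses, responses, converged = TRUE)
    if (percentScale) fit@auc <- curveAuc(fit, min(doses), max(doses))
    return(fit)
  }

  logd <- log10(doses)
  nLow <- max(2L, ceiling(length(doses) / 4))
  top0 <- mean(responses[seq_len(nLow)])
  bot0 <- mean(responses[seq(length(responses) - nLow + 1, length(responses))])
  slopes <- if (is.null(fixedSlope)) c(0.5, 1, 2) else 1
  starts <- expand.grid(logEc50 = logd, slope = slopes,
                        KEEP.OUT.ATTRS = FALSE)

  sse0 <- vapply(seq_len(nrow(starts)), function(i) {
    par <- if (is.null(fixedSlope)) {
      c(top0, bot0, starts$slope[i], starts$logEc50[i])
    } else c(top0, bot0, starts$logEc50[i])
    sum(.fourPLResiduals(par, doses, responses, fixedSlope)^2)
  }, numeric(1))
  ## deterministic ranking; stable tie-break by grid order
  starts <- starts[order(sse0, seq_along(sse0)), , drop = FALSE]
  starts <- utils::head(starts, maxStarts)

  lb <- if (is.null(fixedSlope)) c(-Inf, -Inf, 0.01, log10(ec50Bounds[1])) else
        c(-Inf, -Inf, log10(ec50Bounds[1]))
  ub <- if (is.null(fixedSlope)) c(Inf, Inf, 15, log10(ec50Bounds[2])) else
        c(Inf, Inf, log10(ec50Bounds[2]))

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    par0 <- if (is.null(fixedSlope)) {
      c(top0, bot0, starts$slope[i], starts$logEc50[i])
    } else c(top0, bot0, starts$logEc50[i])
    par0 <- pmin(pmax(par0, lb), ub)
    res <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par0, lower = lb, upper = ub,
                           fn = .fourPLResiduals, dose = doses,
                           resp = responses, fixedSlope = fixedSlope,
                           control = minpack.lm::nls.lm.control(maxiter = 100))),
      error = function(e) NULL)
    if (is.null(res) || !res$info %in% 1:4) next
    sse <- sum(res$fvec^2)
    ecCand <- 10^res$par[length(res$par)]
    if (is.null(best) || sse < best$sse - 1e-12 ||
        (abs(sse - best$sse) <= 1e-12 && ecCand < best$ec50)) {
      best <- list(par = res$par, sse = sse, ec50 = ecCand)
    }
  }

  if (is.null(best)) {
    fit <- .flatFit(doses, responses, converged = FALSE)
    if (percentScale) fit@auc <- curveAuc(fit, min(doses), max(doses))
    return(fit)
  }

  p <- best$par
  if (is.null(fixedSlope)) {
    top <- p[1]; bottom <- p[2]; slope <- p[3]; ecFit <- 10^p[4]
  } else {
    top <- p[1]; bottom <- p[2]; slope <- fixedSlope; ecFit <- 10^p[3]
  }
  fitted <- fourPL(doses, top, bottom, slope, ecFit)
  r2 <- if (stats::sd(fitted) == 0 || stats::sd(responses) == 0) 0 else
    suppressWarnings(stats::cor(fitted, responses))^2
  if (is.na(r2)) r2 <- 0

  fit <- new("CurveFit",
             top = top, bottom = bottom, slope = slope, ec50 = ecFit,
             r2 = r2, auc = NA_real_, converged = TRUE, flat = FALSE,
             doseRange = range(doses), n = length(responses), sse = best$sse)
  if (percentScale) fit@auc <- curveAuc(fit, min(doses), max(doses))
  fit
}

#' Normalized area under a dose-response curve
#'
#' \deqn{AUC = \frac{1}{\log_{10} d_{max} - \log_{10} d_{min}}
#'   \int \mathrm{clip}(R(x), 0, 100)\, dx, \qquad x = \log_{10} d,}
#' evaluated by a fixed `n`-point composite trapezoid rule. The result lies in
#' \[0, 100\] for percent-of-vehicle responses: a flat 100% curve scores 100
#' (no effect), a flat 0% curve scores 0 (complete kill).
#'
#' @param fit A \linkS4class{CurveFit}.
#' @param dmin,dmax Integration range in molar, `dmin < dmax`.
#' @param n Number of grid points (default 1000).
#' @return AUC in percent.
#' @examples
#' d <- 10^seq(-10, -6, length.out = 11)
#' curveAuc(fit4PL(d, fourPL(d, 100, 0, 1, 1e-8)), 1e-10, 1e-6)
#' @export
curveAuc <- function(fit, dmin, dmax, n = 1000L) {
  stopifnot(is(fit, "CurveFit"))
  if (!(dmin > 0 && dmax > 0 && dmin < dmax))
    stop("curveAuc() requires 0 < dmin < dmax")
  x <- seq(log10(dmin), log10(dmax), length.out = n)
  y <- if (fit@flat) rep(fit@top, n) else
    fourPL(10^x, fit@top, fit@bottom, fit@slope, fit@ec50)
  y <- pmin(pmax(y, 0), 100)
  h <- x[2] - x[1]
  area <- h * (sum(y) - (y[1] + y[n]) / 2)
  area / (x[n] - x[1])
}

#' Single-agent efficacy classification
#'
#' A curve is called efficacious when `auc < aucMax` and `pec50 > pec50Min`
#' and `r2 > r2Min` (all strict, thresholds as commonly applied to anchored
#' viability screens: 80%, 6, 0.8). Reason codes name every failed criterion.
#'
#' @param fit A \linkS4class{CurveFit}, or `NULL` if the scalar triple is
#'   given.
#' @param auc,pec50,r2 Scalars overriding the values in `fit` (all three must
#'   be given when `fit` is `NULL`).
#' @param aucMax,pec50Min,r2Min Thresholds.
#' @return A list with `efficacious` (logical) and `reasons`
#'   (character vector, empty when efficacious).
#' @examples
#' classifyEfficacy(auc = 40, pec50 = 7.5, r2 = 0.95)$efficacious
#' classifyEfficacy(auc = 85, pec50 = 7.5, r2 = 0.95)$reasons
#' @export
classifyEfficacy <- function(fit = NULL, auc = NULL, pec50 = NULL, r2 = NULL,
                             aucMax = 80, pec50Min = 6, r2Min = 0.8) {
  if (!is.null(fit)) {
    stopifnot(is(fit, "CurveFit"))
    if (is.null(auc)) auc <- fitAuc(fit)
    if (is.null(pec50)) pec50 <- pec50(fit)
    if (is.null(r2)) r2 <- fitR2(fit)
  }
  reasons <- character()
  if (!isTRUE(auc < aucMax)) reasons <- c(reasons, "auc")
  if (!isTRUE(pec50 > pec50Min)) reasons <- c(reasons, "pec50")
  if (!isTRUE(r2 > r2Min)) reasons <- c(reasons, "r2")
  list(efficacious = length(reasons) == 0L, reasons = reasons)
}
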