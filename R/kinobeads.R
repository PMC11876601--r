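#' @include synergy.R
NULL

#' Residual binding from competition-pulldown intensities
#'
#' Residual binding at each drug dose is the intensity ratio to the vehicle
#' pulldown. Ratios can exceed 1 through noise and are deliberately not
#' clipped.
#'
#' @param intensities Numeric vector of per-dose pulldown intensities.
#' @param vehicleIntensity Vehicle (DMSO) pulldown intensity, must be > 0.
#' @return Numeric vector of ratios.
#' @examples
#' residualBinding(c(8e6, 4e6, 1e6), 8e6)
#' @export
residualBinding <- function(intensities, vehicleIntensity) {
  stopifnot(is.numeric(intensities), length(vehicleIntensity) == 1L)
  if (!is.finite(vehicleIntensity) || vehicleIntensity <= 0)
    stop("residualBinding(): vehicle intensity must be positive")
  intensities / vehicleIntensity
}

#' Target verdict for a competition-binding curve
#'
#' A protein is called a potential target when the residual-binding curve has
#' `r2 > 0.7`, a plateau fold change `bottom/top < 0.5` (the protein is at
#' least half competed at saturation), `slope > 0.2`, `pec50 > 6`, and the
#' protein was quantified with at least 4 unique peptides in the vehicle
#' pulldown. Reason codes name every failed criterion.
#'
#' An optional curation heuristic additionally requires a negative Spearman
#' correlation between dose and spectral (MS/MS) counts, mimicking manual
#' inspection of dose-dependent count reduction; it is off by default.
#'
#' @param fit \linkS4class{CurveFit} on the residual-binding series.
#' @param uniquePeptides Unique-peptide count in the vehicle pulldown.
#' @param msmsCounts Optional numeric vector of per-dose MS/MS counts (same
#'   order as the dose series) for the curation heuristic.
#' @param doses Doses matching `msmsCounts` (required with `msmsCounts`).
#' @param curation Apply the MS/MS-count heuristic (default `FALSE`).
#' @param r2Min,foldChangeMax,slopeMin,pec50Min,minPeptides Thresholds
#'   (defaults 0.7, 0.5, 0.2, 6, 4).
#' @return List with `target` (logical) and `reasons` (character).
#' @examples
#' d <- 1e-9 * c(1, 3, 10, 30, 100, 300, 1000, 3000, 30000)
#' fit <- fit4PL(d, 1 / (1 + d / 5e-9), percentScale = FALSE)
#' callTarget(fit, uniquePeptides = 12)$target
#' @export
callTarget <- function(fit, uniquePeptides, msmsCounts = NULL, doses = NULL,
                       curation = FALSE, r2Min = 0.7, foldChangeMax = 0.5,
                       slopeMin = 0.2, pec50Min = 6, minPeptides = 4) {
  stopifnot(is(fit, "CurveFit"))
  reasons <- character()
  fc <- if (fit@flat || fit@top == 0) NA_real_ else fit@bottom / fit@top
  if (!isTRUE(fitR2(fit) > r2Min)) reasons <- c(reasons, "r2")
  if (!isTRUE(fc < foldChangeMax)) reasons <- c(reasons, "fold_change")
  if (!isTRUE(fit@slope > slopeMin)) reasons <- c(reasons, "slope")
  if (!isTRUE(pec50(fit) > pec50Min)) reasons <- c(reasons, "pec50")
  if (!isTRUE(uniquePeptides >= minPeptides)) reasons <- c(reasons, "peptides")
  if (curation) {
    if (is.null(msmsCounts) || is.null(doses))
      stop("curation heuristic needs 'msmsCounts' and 'doses'")
    rho <- suppressWarnings(
      stats::cor(doses, msmsCounts, method = "spearman"))
    if (!isTRUE(rho < 0)) reasons <- c(reasons, "msms_trend")
  }
  list(target = length(reasons) == 0L, reasons = reasons,
       fold_change = fc)
}

#' Depletion-corrected apparent dissociation constant
#'
#' Competition EC50s overestimate the dissociation constant when the beads
#' deplete the protein from the lysate. The correction factor is the mean
#' protein-intensity ratio of two sequential pulldowns of the same lysate
#' (re-pulldown / first pulldown, averaged over experiments), and
#' `kd_app = ec50 * cf`.
#'
#' @param ec50 Competition EC50 (molar).
#' @param cfValues Numeric vector of per-experiment depletion ratios, each in
#'   (0, 1\]; `NA`s dropped. An all-missing vector yields `kd_app = NA` with
#'   `cf_missing = TRUE`.
#' @return List with `kd_app`, `pkd_app`, `cf` and `cf_missing`.
#' @examples
#' kdApp(10e-9, c(0.4, 0.6))$kd_app  # 5 nM
#' @export
kdApp <- function(ec50, cfValues) {
  cfValues <- cfValues[is.finite(cfValues)]
  if (length(cfValues) == 0L)
    return(list(kd_app = NA_real_, pkd_app = NA_real_, cf = NA_real_,
                cf_missing = TRUE))
  stopifnot(all(cfValues > 0))
  cf <- mean(cfValues)
  kd <- ec50 * cf
  list(kd_app = kd, pkd_app = -log10(kd), cf = cf, cf_missing = FALSE)
}

#' Full competition-pulldown target analysis
#'
#' Computes residual-binding curves for every protein, fits them with the
#' shared 4PL machinery, applies the target criteria and derives
#' depletion-corrected apparent dissociation constants. Proteins missing from
#' the re-pulldown receive the panel-median correction factor with
#' `cf_missing = TRUE`; proteins with a non-positive vehicle intensity are
#' excluded and listed in the `excluded` element.
#'
#' Before fitting, the series is anchored with the vehicle point: residual
#' binding 1 at a pseudo-dose well below the lowest tested
#' dose. The vehicle ratio is 1 by construction, and the anchor pins the
#' upper asymptote, which is otherwise poorly determined for the most potent
#' binders. Set `vehicleAnchor = FALSE` to fit the dosed points only.
#'
#' @param pulldown Data frame with columns `protein`, `n_unique_peptides`,
#'   `vehicle_intensity` and one `intensity_<k>` column per dose
#'   (see [simulateKinobeads()]).
#' @param repulldown Sequential-pulldown data: either long format with
#'   columns `protein`, `first_intensity`, `re_intensity` (one row per
#'   experiment, depletion ratio = re/first, averaged per protein) or a
#'   single-experiment table with `protein` and `vehicle_intensity` (ratio
#'   taken against the first pulldown's vehicle intensity).
#' @param doses Molar dose vector matching the intensity columns.
#' @param vehicleAnchor Include the vehicle ratio as a zero-dose anchor
#'   point (default `TRUE`).
#' @param ... Threshold overrides passed to [callTarget()].
#' @return List with `targets` (one row per protein: fit parameters, `cf`,
#'   `kd_app`, `pkd_app`, verdict and reason codes) and `excluded`
#'   (character vector of skipped proteins).
#' @examples
#' truth <- bindingTruth(nProteins = 6, nBinders = 3, seed = 1)
#' sim <- simulateKinobeads(truth, seed = 1, noiseSd = 0.02)
#' res <- analyzeKinobeads(sim$pulldown, sim$repulldown, sim$doses)
#' res$targets[, c("protein", "kd_app", "target")]
#' @export
analyzeKinobeads <- function(pulldown, repulldown, doses,
                             vehicleAnchor = TRUE, ...) {
  stopifnot(all(c("protein", "n_unique_peptides", "vehicle_intensity") %in%
                colnames(pulldown)))
  intCols <- grep("^intensity_", colnames(pulldown), value = TRUE)
  stopifnot(length(intCols) == length(doses), all(doses > 0),
            !is.unsorted(doses))

  if (all(c("first_intensity", "re_intensity") %in% colnames(repulldown))) {
    cfRows <- repulldown$re_intensity / repulldown$first_intensity
    cfAgg <- tapply(cfRows, repulldown$protein, mean, na.rm = TRUE)
    cfAll <- as.numeric(cfAgg[pulldown$protein])
  } else {
    cfAll <- repulldown$vehicle_intensity[
      match(pulldown$protein, repulldown$protein)] /
      pulldown$vehicle_intensity
  }
  cfMedian <- stats::median(cfAll, na.rm = TRUE)
  anchorDose <- min(doses) / 30   # pseudo-dose well below the tested range

  excluded <- character()
  rows <- list()
  for (i in seq_len(nrow(pulldown))) {
    v <- pulldown$vehicle_intensity[i]
    if (!is.finite(v) || v <= 0) {
      excluded <- c(excluded, pulldown$protein[i])
      next
    }
    ratios <- residualBinding(as.numeric(pulldown[i, intCols]), v)
    fit <- if (vehicleAnchor) {
      fit4PL(c(anchorDose, doses), c(1, ratios), percentScale = FALSE)
    } else {
      fit4PL(doses, ratios, percentScale = FALSE)
    }
    cfMissing <- !is.finite(cfAll[i])
    cf <- if (cfMissing) cfMedian else cfAll[i]
    kd <- if (fit@flat) {
      list(kd_app = NA_real_, pkd_app = NA_real_, cf = cf,
           cf_missing = cfMissing)
    } else {
      k <- kdApp(ec50(fit), cf)
      k$cf_missing <- cfMissing
      k
    }
    verdict <- callTarget(fit, pulldown$n_unique_peptides[i], ...)
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(protein = pulldown$protein[i],
                 n_unique_peptides = pulldown$n_unique_peptides[i]),
      as.data.frame(fit),
      data.frame(fold_change = verdict$fold_change, cf = kd$cf,
                 cf_missing = kd$cf_missing, kd_app = kd$kd_app,
                 pkd_app = kd$pkd_app, target = verdict$target,
                 reasons = paste(verdict$reasons, collapse = ";")))
  }
  list(targets = do.call(rbind, rows), excluded = excluded)
}
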