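#' @include plateQC.R
NULL

#' Bliss-independence hypothetical combination response
#'
#' Under Bliss independence the expected fractional viability of a
#' combination is the product of the single-agent fractional viabilities,
#' \eqn{E_{A+B} = E_A \cdot E_B}. The anchor response is a single fixed-dose
#' fractional viability; negative library responses (assay noise) are clipped
#' to 0 before multiplication and counted in the `"n_clipped"` attribute.
#'
#' @param libFrac Numeric vector, library-drug single-agent fractional
#'   viabilities per dose (1 = vehicle level).
#' @param anchorFrac Scalar fractional viability of the anchor drug at its
#'   fixed dose.
#' @return Numeric vector of hypothetical fractional viabilities with
#'   attribute `n_clipped`.
#' @examples
#' blissHypothetical(c(1, 0.5, 0.1), 0.5)
#' @export
blissHypothetical <- function(libFrac, anchorFrac) {
  stopifnot(is.numeric(libFrac), length(anchorFrac) == 1L,
            is.finite(anchorFrac))
  nClip <- sum(libFrac < 0, na.rm = TRUE)
  if (nClip > 0) {
    warning(nClip, " negative library response(s) clipped to 0")
    libFrac <- pmax(libFrac, 0)
  }
  out <- libFrac * max(anchorFrac, 0)
  attr(out, "n_clipped") <- nClip
  out
}

#' AUC shift between hypothetical and experimental combination curves
#'
#' `aucDelta = AUC(hypothetical) - AUC(experimental)` over the common tested
#' dose range; positive values mean the measured combination killed more than
#' Bliss additivity predicts.
#'
#' @param expFit,hypFit \linkS4class{CurveFit} objects fitted over the same
#'   dose range.
#' @param tol Relative tolerance for the dose-range equality check.
#' @return AUC difference in percentage points.
#' @export
aucDelta <- function(expFit, hypFit, tol = 1e-6) {
  stopifnot(is(expFit, "CurveFit"), is(hypFit, "CurveFit"))
  if (any(abs(log10(expFit@doseRange) - log10(hypFit@doseRange)) > tol))
    stop("aucDelta(): experimental and hypothetical dose ranges differ")
  rng <- expFit@doseRange
  curveAuc(hypFit, rng[1], rng[2]) - curveAuc(expFit, rng[1], rng[2])
}

#' Synergy verdict for a drug over two anchor doses
#'
#' A combination is synergistic when the summed AUC shift over the two anchor
#' doses exceeds `sumMin` (10 percentage points) and at least one of the two
#' combination curves is itself effective (`auc < aucMax` and
#' `pec50 > pec50Min`). Combinations where either experimental curve has
#' `r2 <= r2Min` are excluded from the synergy analysis
#' (`verdict = "not_evaluable"`).
#'
#' @param aucDeltas Numeric length 2, AUC shifts at the low and high anchor
#'   dose.
#' @param comboAuc,comboPec50,comboR2 Numeric length 2, statistics of the two
#'   experimental combination curves.
#' @param sumMin,aucMax,pec50Min,r2Min Thresholds (defaults 10, 80, 6, 0.8).
#' @return List with `sum_auc_delta`, flags (`sum_gt_10`,
#'   `any_combo_efficacious`, `r2_ok_both`) and `verdict` in
#'   `"synergistic"`, `"not_synergistic"`, `"not_evaluable"`.
#' @examples
#' classifySynergy(c(12, 13), comboAuc = c(40, 38),
#'                 comboPec50 = c(7, 7.2), comboR2 = c(0.95, 0.97))$verdict
#' @export
classifySynergy <- function(aucDeltas, comboAuc, comboPec50, comboR2,
                            sumMin = 10, aucMax = 80, pec50Min = 6,
                            r2Min = 0.8) {
  stopifnot(length(aucDeltas) == 2L, length(comboAuc) == 2L,
            length(comboPec50) == 2L, length(comboR2) == 2L)
  sumDelta <- sum(aucDeltas)
  r2Ok <- all(is.finite(comboR2) & comboR2 > r2Min)
  anyEff <- any(comboAuc < aucMax & comboPec50 > pec50Min, na.rm = TRUE)
  sumOk <- isTRUE(sumDelta > sumMin)
  verdict <- if (!r2Ok) "not_evaluable" else
    if (sumOk && anyEff) "synergistic" else "not_synergistic"
  list(sum_auc_delta = sumDelta,
       sum_gt_10 = sumOk, any_combo_efficacious = anyEff, r2_ok_both = r2Ok,
       verdict = verdict)
}

#' Replicate EC50-shift test between monotherapy and combination
#'
#' For each condition, compares replicate EC50s of the anchor drug alone with
#' those of the anchor plus a fixed partner dose: reports the log2 fold
#' change of geometric-mean EC50s (negative = combination more potent) and a
#' two-sided equal-variance t-test on log10 EC50, Benjamini-Hochberg adjusted
#' across all conditions tested together (the experiment family).
#'
#' Conditions with fewer than 2 replicates in either arm get a fold change
#' only (`tested = FALSE`). Identical replicate sets give p = 1.
#'
#' @param mono,combo Named lists of replicate EC50 vectors (molar); names are
#'   condition labels and must match.
#' @return Data frame with one row per condition: replicate counts, `log2fc`,
#'   `p`, `p_adj`, `tested`.
#' @examples
#' ec50ShiftTest(mono = list(a = c(45e-9, 44e-9, 46e-9)),
#'               combo = list(a = c(6e-9, 6.2e-9, 5.9e-9)))
#' @export
ec50ShiftTest <- function(mono, combo) {
  stopifnot(is.list(mono), is.list(combo),
            identical(sort(names(mono)), sort(names(combo))))
  conditions <- names(mono)
  rows <- lapply(conditions, function(cn) {
    m <- mono[[cn]]; cb <- combo[[cn]]
    stopifnot(all(m > 0), all(cb > 0))
    fc <- log2(exp(mean(log(cb))) / exp(mean(log(m))))
    tested <- length(m) >= 2L && length(cb) >= 2L
    p <- NA_real_
    if (tested) {
      lm10 <- log10(m); lc10 <- log10(cb)
      if (stats::sd(lm10) == 0 && stats::sd(lc10) == 0) {
        p <- if (mean(lm10) == mean(lc10)) 1 else 0
      } else {
        p <- stats::t.test(lc10, lm10, var.equal = TRUE)$p.value
      }
    }
    data.frame(condition = cn, n_mono = length(m), n_combo = length(cb),
               log2fc = fc, p = p, tested = tested)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  out$p_adj[out$tested] <- stats::p.adjust(out$p[out$tested], method = "BH")
  out
}

#' Anchor-dose selection from the anchor drug's own potency
#'
#' Cell lines relatively insensitive to the anchor drug (EC50 at or above
#' `threshold`) get the higher anchor-dose pair; sensitive lines get the
#' lower pair.
#'
#' @param anchorEc50 Anchor-drug single-agent EC50 (molar).
#' @param threshold Sensitivity cutoff (molar; default 10 nM).
#' @param lowPair,highPair Length-2 molar dose pairs.
#' @return Named numeric length 2 (`low`, `high`).
#' @export
selectAnchorDoses <- function(anchorEc50, threshold = 10e-9,
                              lowPair = c(1e-9, 3e-9),
                              highPair = c(10e-9, 30e-9)) {
  pair <- if (isTRUE(anchorEc50 >= threshold)) highPair else lowPair
  c(low = pair[1], high = pair[2])
}

## Mean measured percent response per dose for one (cell line, drug) series.
.meanByDose <- function(dose, response) {
  agg <- tapply(response, dose, mean)
  data.frame(dose = as.numeric(names(agg)), response = as.numeric(agg))
}

#' Full anchored combination-screen analysis
#'
#' Runs the complete screen pipeline on a long-format plate table:
#' vehicle normalization, per-plate Z-prime QC, single-agent and combination
#' 4PL fits, Bliss hypothetical curves (built from measured single-agent
#' responses, refitted with the same 4PL machinery), AUC shifts at both
#' anchor doses and the final synergy verdict per (cell line, library drug).
#'
#' The anchor response entering the Bliss product is the measured single-agent
#' viability of the anchor drug at the anchor dose (mean over replicate
#' wells); the fitted anchor curve value is used only when no such wells
#' exist.
#'
#' @param plate Long-format table with columns `plate`, `well`, `role`,
#'   `cell_line`, `drug`, `dose_nM`, `anchor_drug`, `anchor_dose_nM`,
#'   `signal` (see [simulateScreen()]).
#' @param anchorDrug Name of the anchor drug (default `"GEM"`).
#' @param thresholds Named list overriding the classification thresholds
#'   `sumMin`, `aucMax`, `pec50Min`, `r2Min`.
#' @param zPrimeMode Denominator mode for [zPrime()].
#' @return List with `curves` (per cell line/drug/condition fit table), `qc`
#'   (per-plate Z-prime table), `synergy` (one row per cell line x library
#'   drug) and `summary` (efficacy and synergy counts).
#' @examples
#' truth <- screenTruth(nCellLines = 1, nDrugs = 2, synergyFraction = 0.5,
#'                      seed = 1)
#' sim <- simulateScreen(truth, seed = 1, noiseSd = 0.02)
#' res <- analyzeScreen(sim$plate)
#' res$synergy[, c("cell_line", "drug", "sum_auc_delta", "verdict")]
#' @export
analyzeScreen <- function(plate, anchorDrug = "GEM", thresholds = list(),
                          zPrimeMode = c("printed", "standard")) {
  zPrimeMode <- match.arg(zPrimeMode)
  th <- utils::modifyList(
    list(sumMin = 10, aucMax = 80, pec50Min = 6, r2Min = 0.8), thresholds)
  need <- c("plate", "role", "cell_line", "drug", "dose_nM",
            "anchor_dose_nM", "signal")
  stopifnot(all(need %in% colnames(plate)))

  norm <- normalizeToVehicle(plate)
  qc <- plateQC(plate, mode = zPrimeMode)
  smp <- norm[norm$role == "sample", , drop = FALSE]
  smp$dose <- smp$dose_nM * 1e-9

  mono <- smp[smp$anchor_dose_nM == 0, , drop = FALSE]
  combo <- smp[smp$anchor_dose_nM > 0, , drop = FALSE]

  curveRows <- list()
  fits <- list()   # keyed "cell|drug|anchor_nM"
  monoMeans <- list()
  for (key in unique(paste(mono$cell_line, mono$drug, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- mono[mono$cell_line == parts[1] & mono$drug == parts[2], ]
    mm <- .meanByDose(sub$dose, sub$response)
    monoMeans[[key]] <- mm
    fit <- fit4PL(mm$dose, mm$response)
    fits[[paste0(key, "\r0")]] <- fit
    curveRows[[length(curveRows) + 1L]] <- cbind(
      data.frame(cell_line = parts[1], drug = parts[2], anchor_dose_nM = 0),
      as.data.frame(fit))
  }
  comboGroups <- unique(combo[, c("cell_line", "drug", "anchor_dose_nM")])
  for (g in seq_len(nrow(comboGroups))) {
    cl <- comboGroups$cell_line[g]; dg <- comboGroups$drug[g]
    a <- comboGroups$anchor_dose_nM[g]
    sub <- combo[combo$cell_line == cl & combo$drug == dg &
                 combo$anchor_dose_nM == a, ]
    mm <- .meanByDose(sub$dose, sub$response)
    fit <- fit4PL(mm$dose, mm$response)
    fits[[paste(cl, dg, a, sep = "\r")]] <- fit
    curveRows[[length(curveRows) + 1L]] <- cbind(
      data.frame(cell_line = cl, drug = dg, anchor_dose_nM = a),
      as.data.frame(fit))
  }
  curves <- do.call(rbind, curveRows)

  ## measured anchor single-agent response (fraction) per cell line and dose
  anchorFrac <- function(cl, anchorNM) {
    key <- paste(cl, anchorDrug, sep = "\r")
    mm <- monoMeans[[key]]
    if (!is.null(mm)) {
      hit <- which(abs(mm$dose - anchorNM * 1e-9) < 1e-15)
      if (length(hit)) return(mean(mm$response[hit]) / 100)
    }
    fit <- fits[[paste0(key, "\r0")]]
    if (is.null(fit))
      stop("no single-agent data for anchor drug in cell line ", cl)
    if (fit@flat) fit@top / 100 else
      fourPL(anchorNM * 1e-9, fit@top, fit@bottom, fit@slope, fit@ec50) / 100
  }

  synRows <- list()
  libDrugs <- unique(combo[, c("cell_line", "drug")])
  for (i in seq_len(nrow(libDrugs))) {
    cl <- libDrugs$cell_line[i]; dg <- libDrugs$drug[i]
    anchors <- sort(unique(combo$anchor_dose_nM[combo$cell_line == cl &
                                                combo$drug == dg]))
    if (length(anchors) != 2L) next
    mm <- monoMeans[[paste(cl, dg, sep = "\r")]]
    if (is.null(mm)) next
    perAnchor <- lapply(anchors, function(a) {
      expFit <- fits[[paste(cl, dg, a, sep = "\r")]]
      af <- anchorFrac(cl, a)
      hyp <- blissHypothetical(mm$response / 100, af)
      hypFit <- suppressWarnings(fit4PL(mm$dose, 100 * as.numeric(hyp)))
      list(expFit = expFit, hypFit = hypFit,
           delta = aucDelta(expFit, hypFit))
    })
    cs <- classifySynergy(
      vapply(perAnchor, `[[`, numeric(1), "delta"),
      comboAuc = vapply(perAnchor, function(x) fitAuc(x$expFit), numeric(1)),
      comboPec50 = vapply(perAnchor, function(x) pec50(x$expFit), numeric(1)),
      comboR2 = vapply(perAnchor, function(x) fitR2(x$expFit), numeric(1)),
      sumMin = th$sumMin, aucMax = th$aucMax, pec50Min = th$pec50Min,
      r2Min = th$r2Min)
    synRows[[length(synRows) + 1L]] <- data.frame(
      cell_line = cl, drug = dg,
      anchor_low_nM = anchors[1], anchor_high_nM = anchors[2],
      auc_delta_low = perAnchor[[1]]$delta,
      auc_delta_high = perAnchor[[2]]$delta,
      sum_auc_delta = cs$sum_auc_delta,
      combo_auc_low = fitAuc(perAnchor[[1]]$expFit),
      combo_auc_high = fitAuc(perAnchor[[2]]$expFit),
      combo_pec50_low = pec50(perAnchor[[1]]$expFit),
      combo_pec50_high = pec50(perAnchor[[2]]$expFit),
      combo_r2_low = fitR2(perAnchor[[1]]$expFit),
      combo_r2_high = fitR2(perAnchor[[2]]$expFit),
      sum_gt_10 = cs$sum_gt_10,
      any_combo_efficacious = cs$any_combo_efficacious,
      r2_ok_both = cs$r2_ok_both,
      verdict = cs$verdict)
  }
  synergy <- if (length(synRows)) do.call(rbind, synRows) else
    data.frame()

  monoCurves <- curves[curves$anchor_dose_nM == 0 & curves$drug != anchorDrug, ]
  nEff <- if (nrow(monoCurves)) sum(vapply(seq_len(nrow(monoCurves)),
    function(i) classifyEfficacy(auc = monoCurves$auc[i],
                                 pec50 = monoCurves$pec50[i],
                                 r2 = monoCurves$r2[i],
                                 aucMax = th$aucMax, pec50Min = th$pec50Min,
                                 r2Min = th$r2Min)$efficacious,
    logical(1))) else 0L
  summary <- data.frame(
    n_pairs = nrow(synergy),
    n_single_agent_efficacious = nEff,
    n_synergistic = sum(synergy$verdict == "synergistic"),
    n_not_evaluable = sum(synergy$verdict == "not_evaluable"),
    median_z_prime = stats::median(qc$z_prime))

  list(curves = curves, qc = qc, synergy = synergy, summary = summary)
}
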