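#' @include phospho.R
NULL

AMINO_ACIDS <- strsplit("ACDEFGHIKLMNPRVWY", "")[[1]]  # no S/T/Q by design

#' Standard 11-dose library titration grid
#'
#' Eleven 1:3 dilution steps from 10 uM down to ~170 pM, the usual anchored
#' viability-screen design.
#'
#' @return Molar doses, ascending.
#' @export
screenDoses <- function() 10000e-9 / 3^(10:0)

#' Ground truth for a synthetic anchored combination screen
#'
#' Draws one 4PL viability curve per (cell line, drug) plus the anchor drug's
#' own curve per cell line, and assigns each (cell line, library drug) an
#' interaction mode: `bliss_additive` (the null), `synergistic`
#' (library potency improved `phi`-fold in the combination) or `antagonistic`
#' (`phi` < 1). Anchor doses follow the sensitivity rule of
#' [selectAnchorDoses()] applied to the anchor drug's true EC50.
#'
#' Defaults emulate a realistic screen: library EC50s log-uniform between
#' 10 nM and 2 uM, tops near 100% with bottoms 0-20%, slopes 0.7-2, anchor
#' EC50s log-uniform 2-80 nM, and a moderate anchor effect (its curve spans
#' the tested range).
#'
#' @param nCellLines,nDrugs Panel dimensions.
#' @param synergyFraction,antagonismFraction Fractions of (cell line, drug)
#'   pairs assigned the non-additive modes (defaults 0.1 and 0).
#' @param phi Potency-shift factor for synergistic pairs (> 1; default 10).
#' @param anchorDrug Anchor drug name (default `"GEM"`).
#' @param seed Integer seed; the truth is fully reproducible.
#' @return List of class `screenTruth`: `curves` (per cell line/drug 4PL
#'   parameters, percent units / molar EC50), `interactions` (per cell line,
#'   library drug and anchor dose: mode and phi), `anchorDoses` (per cell
#'   line), `anchorDrug`, `plateScale`, `doses`.
#' @export
screenTruth <- function(nCellLines = 4, nDrugs = 10, synergyFraction = 0.1,
                        antagonismFraction = 0, phi = 10,
                        anchorDrug = "GEM", seed = 1) {
  set.seed(seed)
  cellLines <- sprintf("CL%02d", seq_len(nCellLines))
  drugs <- sprintf("drug%03d", seq_len(nDrugs))

  draw <- function(cl, dg, ec50Range) {
    data.frame(cell_line = cl, drug = dg,
               top = stats::runif(1, 95, 105),
               bottom = stats::runif(1, 0, 20),
               slope = stats::runif(1, 0.7, 2),
               ec50 = 10^stats::runif(1, log10(ec50Range[1]),
                                      log10(ec50Range[2])))
  }
  curves <- do.call(rbind, c(
    lapply(cellLines, function(cl) draw(cl, anchorDrug, c(2e-9, 80e-9))),
    unlist(lapply(cellLines, function(cl)
      lapply(drugs, function(dg) draw(cl, dg, c(10e-9, 2e-6)))),
      recursive = FALSE)))
  stopifnot(all(curves$ec50 > 0),
            all(curves$bottom >= 0 & curves$bottom <= curves$top &
                curves$top <= 120))

  pairs <- expand.grid(cell_line = cellLines, drug = drugs,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  nPairs <- nrow(pairs)
  mode <- rep("bliss_additive", nPairs)
  nSyn <- round(synergyFraction * nPairs)
  nAnt <- round(antagonismFraction * nPairs)
  pick <- sample.int(nPairs, nSyn + nAnt)
  mode[pick[seq_len(nSyn)]] <- "synergistic"
  if (nAnt) mode[pick[nSyn + seq_len(nAnt)]] <- "antagonistic"
  pairs$mode <- mode
  pairs$phi <- ifelse(mode == "synergistic", phi,
                      ifelse(mode == "antagonistic", 1 / phi, 1))
  stopifnot(all(pairs$phi > 0))

  anchorDoses <- t(vapply(cellLines, function(cl) {
    ec <- curves$ec50[curves$cell_line == cl & curves$drug == anchorDrug]
    selectAnchorDoses(ec)
  }, numeric(2)))

  structure(list(curves = curves, interactions = pairs,
                 anchorDoses = anchorDoses, anchorDrug = anchorDrug,
                 plateScale = 2e6, doses = screenDoses()),
            class = "screenTruth")
}

.truthViability <- function(truth, cl, dg) {
  row <- truth$curves[truth$curves$cell_line == cl &
                      truth$curves$drug == dg, ]
  if (nrow(row) != 1L)
    stop("screen truth has no curve for (", cl, ", ", dg, ")")
  function(d) fourPL(d, row$top, row$bottom, row$slope, row$ec50) / 100
}

#' Simulate a long-format plate viability table from known truth
#'
#' One plate per (cell line, library drug) carrying the 11-dose single-agent
#' titration, both anchored combinations, duplicate anchor-alone wells at the
#' two anchor doses, 8 vehicle (negative) and 16 kill (positive) control
#' wells; plus one anchor-titration plate per cell line. Raw signals are the
#' true viability fraction times the plate scale under multiplicative
#' log-normal noise; kill controls have true signal 0. Combination wells
#' follow the Bliss product `E_lib(d) * E_anchor` for additive pairs, with
#' the library dose divided by `phi` for potency-shift synergy/antagonism.
#'
#' @param truth A [screenTruth()] object.
#' @param seed Integer seed.
#' @param noiseSd Log-normal sigma of the multiplicative noise (default
#'   0.05, i.e. ~5% CV).
#' @param negSd Extra multiplicative noise on control wells (defaults to
#'   `noiseSd`).
#' @return List with `plate` (the long-format table) and `truth`.
#' @export
simulateScreen <- function(truth, seed = 1, noiseSd = 0.05,
                           negSd = noiseSd) {
  stopifnot(inherits(truth, "screenTruth"))
  set.seed(seed)
  scale <- truth$plateScale
  doses <- truth$doses
  noise <- function(n, sd) if (sd == 0) rep(1, n) else
    exp(stats::rnorm(n, 0, sd))

  rows <- list()
  wellCounter <- new.env(parent = emptyenv())
  addWells <- function(plateId, role, cl, dg, doseNM, anchorDg, anchorNM,
                       frac, sd) {
    n <- length(frac)
    k <- mget(plateId, wellCounter, ifnotfound = 0L)[[1]]
    assign(plateId, k + n, wellCounter)
    rows[[length(rows) + 1L]] <<- data.frame(
      plate = plateId,
      well = sprintf("W%03d", k + seq_len(n)),
      role = role, cell_line = cl, drug = dg, dose_nM = doseNM,
      anchor_drug = anchorDg, anchor_dose_nM = anchorNM,
      signal = frac * scale * noise(n, sd))
  }
  addControls <- function(plateId, cl) {
    addWells(plateId, "neg", cl, "", 0, "", 0, rep(1, 8), negSd)
    addWells(plateId, "pos", cl, "", 0, "", 0, rep(0, 16), negSd)
  }

  cellLines <- unique(truth$interactions$cell_line)
  for (cl in cellLines) {
    eAnchor <- .truthViability(truth, cl, truth$anchorDrug)
    plateId <- paste0(cl, "_", truth$anchorDrug)
    addWells(plateId, "sample", cl, truth$anchorDrug, doses * 1e9,
             "", 0, eAnchor(doses), noiseSd)
    addControls(plateId, cl)
  }
  for (i in seq_len(nrow(truth$interactions))) {
    cl <- truth$interactions$cell_line[i]
    dg <- truth$interactions$drug[i]
    phi <- truth$interactions$phi[i]
    eLib <- .truthViability(truth, cl, dg)
    eAnchor <- .truthViability(truth, cl, truth$anchorDrug)
    anchors <- truth$anchorDoses[cl, ]
    plateId <- paste0(cl, "_", dg)
    addWells(plateId, "sample", cl, dg, doses * 1e9, "", 0,
             eLib(doses), noiseSd)
    for (a in anchors) {
      ## potency shift: EC50 divided by phi, i.e. the curve evaluated at phi*d
      combo <- eLib(doses * phi) * eAnchor(a)
      addWells(plateId, "sample", cl, dg, doses * 1e9,
               truth$anchorDrug, a * 1e9, combo, noiseSd)
      addWells(plateId, "sample", cl, truth$anchorDrug,
               rep(a * 1e9, 2), "", 0, rep(eAnchor(a), 2), noiseSd)
    }
    addControls(plateId, cl)
  }
  plate <- do.call(rbind, rows)
  rownames(plate) <- NULL
  list(plate = plate, truth = truth)
}

#' Ground truth for a synthetic competition-pulldown panel
#'
#' Binders get a true dissociation constant log-uniform between `kdRange`
#' (default 1-100 nM) and non-binders do not respond to the drug at all
#' (`kd = NA`). Every protein carries a depletion correction factor in
#' (0, 1\], a unique-peptide count (binders at least 4) and a vehicle
#' intensity scale.
#'
#' @param nProteins,nBinders Panel composition.
#' @param kdRange Molar range for true dissociation constants.
#' @param cfRange Range of depletion correction factors.
#' @param seed Integer seed.
#' @return Data frame of class `bindingTruth`: `protein`, `is_binder`, `kd`,
#'   `cf`, `n_unique_peptides`, `intensity`.
#' @export
bindingTruth <- function(nProteins = 50, nBinders = 20,
                         kdRange = c(1e-9, 100e-9), cfRange = c(0.3, 1),
                         seed = 1) {
  stopifnot(nBinders <= nProteins)
  set.seed(seed)
  isBinder <- seq_len(nProteins) <= nBinders
  truth <- data.frame(
    protein = sprintf("PROT%03d", seq_len(nProteins)),
    is_binder = isBinder,
    kd = ifelse(isBinder,
                10^stats::runif(nProteins, log10(kdRange[1]),
                                log10(kdRange[2])), NA),
    cf = stats::runif(nProteins, cfRange[1], cfRange[2]),
    n_unique_peptides = ifelse(isBinder,
                               4L + stats::rpois(nProteins, 8),
                               1L + stats::rpois(nProteins, 6)),
    intensity = 10^stats::runif(nProteins, 6, 9))
  stopifnot(all(truth$cf > 0 & truth$cf <= 1),
            all(is.na(truth$kd) | truth$kd > 0))
  class(truth) <- c("bindingTruth", class(truth))
  truth
}

#' Simulate a competition pulldown and its paired re-pulldowns
#'
#' The vehicle pulldown intensity is the protein's reference scale; dosed
#' intensities follow the competition isotherm with midpoint at the
#' depletion-inflated apparent EC50 `kd / cf` (so that multiplying the
#' fitted EC50 by the correction factor recovers the true dissociation
#' constant) under multiplicative log-normal noise. The paired sequential
#' pulldown of the depleted lysate reads `intensity * cf * noise`; it is
#' simulated for `nExperiments` independent experiments, mirroring designs
#' where the depletion factor is averaged over several profiling runs.
#' Per-dose MS/MS counts are emitted for the optional curation heuristic.
#'
#' @param truth A [bindingTruth()] data frame.
#' @param doses Strictly positive, sorted molar doses (default the 9-dose
#'   1 nM - 30 uM competition grid).
#' @param seed Integer seed.
#' @param noiseSd Log-normal sigma (default 0.05).
#' @param nExperiments Number of sequential-pulldown experiment pairs for
#'   the correction factor (default 4).
#' @return List with `pulldown`, `repulldown` (long format: `protein`,
#'   `experiment`, `first_intensity`, `re_intensity`), `doses`, `truth`.
#' @export
simulateKinobeads <- function(truth,
                              doses = c(1, 3, 10, 30, 100, 300, 1000, 3000,
                                        30000) * 1e-9,
                              seed = 1, noiseSd = 0.05, nExperiments = 4L) {
  stopifnot(inherits(truth, "bindingTruth"))
  if (any(doses <= 0) || is.unsorted(doses))
    stop("doses must be strictly positive and sorted ascending")
  set.seed(seed)
  n <- nrow(truth); k <- length(doses)
  noise <- function(m) if (noiseSd == 0) rep(1, m) else
    exp(stats::rnorm(m, 0, noiseSd))

  pulldown <- data.frame(protein = truth$protein,
                         n_unique_peptides = truth$n_unique_peptides,
                         vehicle_intensity = truth$intensity)
  ratioTrue <- matrix(1, n, k)
  for (i in which(truth$is_binder)) {
    ec50 <- truth$kd[i] / truth$cf[i]
    ratioTrue[i, ] <- 1 / (1 + doses / ec50)
  }
  for (j in seq_len(k)) {
    pulldown[[paste0("intensity_", j)]] <-
      truth$intensity * ratioTrue[, j] * noise(n)
    pulldown[[paste0("msms_", j)]] <- stats::rpois(n, 5 + 25 * ratioTrue[, j])
  }
  repulldown <- do.call(rbind, lapply(seq_len(nExperiments), function(e)
    data.frame(protein = truth$protein, experiment = e,
               first_intensity = truth$intensity,
               re_intensity = truth$intensity * truth$cf * noise(n))))
  list(pulldown = pulldown, repulldown = repulldown, doses = doses,
       truth = truth)
}

#' Ground truth for a synthetic dose-resolved phosphoproteome
#'
#' Builds `nSites` phosphosite records across three categories:
#' `reverted` (chemo-induced, suppressed dose-dependently by every drug),
#' `restored` (chemo-suppressed, re-established by every drug) and `null`
#' (unaffected). Reverted sites carry the pSQ/pTQ motif with probability
#' `psqFractionReverted` (restored sites never do, null sites at the
#' background rate), matching the biology the pipeline is meant to resolve.
#' Per-drug potencies are drawn around drug-specific means so that potency
#' summaries separate more and less potent compounds.
#'
#' @param nSites,nReverted,nRestored Category sizes (rest is null).
#' @param drugs Drug (batch) names; default four.
#' @param drugPec50 Named mean true pEC50 per drug.
#' @param gemFcRange Absolute log2 fold-change range of the chemo effect.
#' @param drugFcRange Absolute curve log2 fold-change range of the drug
#'   effect.
#' @param psqFractionReverted,psqBackground pSQ/pTQ motif rates.
#' @param seed Integer seed.
#' @return Data frame of class `phosphoTruth`; one row per site with the
#'   window, motif flag, chemo effect, reversal category and per-drug
#'   `fc_<drug>` / `pec50_<drug>` columns.
#' @export
phosphoTruth <- function(nSites = 1000, nReverted = 40, nRestored = 60,
                         drugs = c("drugA", "drugB", "drugC", "drugD"),
                         drugPec50 = c(drugA = 8, drugB = 7.7,
                                       drugC = 6.9, drugD = 6.7),
                         gemFcRange = c(1.5, 4.5), drugFcRange = c(1, 3),
                         psqFractionReverted = 0.8, psqBackground = 0.1,
                         seed = 1) {
  stopifnot(nReverted + nRestored <= nSites,
            all(drugs %in% names(drugPec50)))
  set.seed(seed)
  category <- rep("null", nSites)
  category[seq_len(nReverted)] <- "reverted"
  category[nReverted + seq_len(nRestored)] <- "restored"

  isPsq <- stats::runif(nSites) < ifelse(
    category == "reverted", psqFractionReverted,
    ifelse(category == "restored", 0, psqBackground))
  residue <- ifelse(isPsq, sample(c("S", "T"), nSites, replace = TRUE),
                    sample(c("S", "T", "Y"), nSites, replace = TRUE,
                           prob = c(0.75, 0.2, 0.05)))
  plus1 <- ifelse(isPsq, "Q",
                  sample(AMINO_ACIDS, nSites, replace = TRUE))
  flank <- function(k) vapply(seq_len(nSites), function(i)
    paste(sample(AMINO_ACIDS, k, replace = TRUE), collapse = ""),
    character(1))
  window <- paste0(flank(7), residue, plus1, flank(6))
  position <- sample(30:900, nSites, replace = TRUE)

  gemFc <- numeric(nSites)
  gemFc[category == "reverted"] <-
    stats::runif(nReverted, gemFcRange[1], gemFcRange[2])
  gemFc[category == "restored"] <-
    -stats::runif(nRestored, gemFcRange[1], gemFcRange[2])

  truth <- data.frame(
    site = sprintf("P%04d_%s%d", seq_len(nSites), residue, position),
    protein = sprintf("P%04d", seq_len(nSites)),
    residue = residue, position = position,
    sequence_window = window, psq_ptq = isPsq,
    category = category, gem_log2fc = gemFc,
    base_log2 = stats::rnorm(nSites, 20, 1))

  for (dg in drugs) {
    fc <- numeric(nSites)
    affected <- category != "null"
    mag <- stats::runif(nSites, drugFcRange[1], drugFcRange[2])
    fc[affected] <- -sign(gemFc[affected]) * mag[affected]
    truth[[paste0("fc_", dg)]] <- fc
    truth[[paste0("pec50_", dg)]] <- ifelse(
      affected, drugPec50[[dg]] + stats::runif(nSites, -0.3, 0.3), NA)
  }
  stopifnot(all(truth$category != "reverted" | truth$gem_log2fc != 0))
  attr(truth, "drugs") <- drugs
  class(truth) <- c("phosphoTruth", class(truth))
  truth
}

#' Simulate evidence-style phosphopeptide tables from known truth
#'
#' One TMT batch per drug with the 11-channel design of [decryptmDesign()]:
#' channels 1-9 titrate the drug on the chemo background, channel 10 is
#' chemo-only, channel 11 vehicle. Linear-scale intensities are
#' `2^(base + gem_fc + drug_response(dose))` times a per-batch scale factor
#' (2^U(-1, 1)) and multiplicative log-normal noise, where the drug response
#' in log2 units follows a slope-1 binding curve from 0 to the site's true
#' fold change. Each site contributes 1-2 confidently localized peptides;
#' ambiguous extra rows (localization below 0.75) are emitted at the
#' configured overall fraction, and channel values go missing at random at
#' `missingRate`.
#'
#' @param truth A [phosphoTruth()] data frame.
#' @param design Channel map, see [decryptmDesign()].
#' @param seed Integer seed.
#' @param noiseSd Log-normal sigma on linear intensities (default 0.05).
#' @param missingRate Per-channel missing-at-random probability (default 0).
#' @param subLocFraction Target fraction of evidence rows with localization
#'   probability below 0.75 (default 0.1).
#' @param batchEffects Apply per-batch scale factors (default `TRUE`).
#' @return List with `evidence` (all batches stacked) and `truth`.
#' @export
simulatePhospho <- function(truth, design = decryptmDesign(), seed = 1,
                            noiseSd = 0.05, missingRate = 0,
                            subLocFraction = 0.1, batchEffects = TRUE) {
  stopifnot(inherits(truth, "phosphoTruth"))
  if (!all(c("dose", "gem", "vehicle") %in% design$role))
    stop("channel design must assign the roles 'dose', 'gem' and 'vehicle'")
  drugs <- attr(truth, "drugs")
  set.seed(seed)
  nSites <- nrow(truth)
  doses <- design$dose_nM[design$role == "dose"] * 1e-9
  pAmb <- if (subLocFraction <= 0) 0 else
    subLocFraction / (1 - subLocFraction)

  batchTables <- list()
  for (dg in drugs) {
    fc <- truth[[paste0("fc_", dg)]]
    ec50 <- 10^(-truth[[paste0("pec50_", dg)]])
    scaleB <- if (batchEffects) 2^stats::runif(1, -1, 1) else 1
    ## true log2 level per channel
    lvl <- matrix(truth$base_log2, nSites, 11)
    lvl[, design$role != "vehicle"] <-
      lvl[, design$role != "vehicle"] + truth$gem_log2fc
    for (j in which(design$role == "dose")) {
      d <- design$dose_nM[j] * 1e-9
      resp <- ifelse(is.na(ec50), 0, fc / (1 + ec50 / d))
      lvl[, j] <- lvl[, j] + resp
    }
    nPep <- 1L + (stats::runif(nSites) < 0.4)
    siteIdx <- rep(seq_len(nSites), nPep)
    pepIdx <- sequence(nPep)
    s1 <- stats::runif(nSites, 0.3, 0.7)   # split for 2-peptide sites
    share <- ifelse(nPep[siteIdx] == 1L, 1,
                    ifelse(pepIdx == 1L, s1[siteIdx], 1 - s1[siteIdx]))
    nRows <- length(siteIdx)
    inten <- 2^lvl[siteIdx, , drop = FALSE] * share * scaleB
    if (noiseSd > 0)
      inten <- inten * exp(matrix(stats::rnorm(nRows * 11, 0, noiseSd),
                                  nRows, 11))
    if (missingRate > 0)
      inten[matrix(stats::runif(nRows * 11) < missingRate, nRows, 11)] <- NA
    tab <- data.frame(
      modified_sequence = sprintf("%s_pep%d", truth$site[siteIdx], pepIdx),
      protein = truth$protein[siteIdx],
      site_positions = paste0(truth$residue[siteIdx],
                              truth$position[siteIdx]),
      localization_prob = stats::runif(nRows, 0.85, 1),
      sequence_window = truth$sequence_window[siteIdx],
      batch = dg)
    tab[paste0("reporter_intensity_", 1:11)] <- as.data.frame(inten)
    if (pAmb > 0) {
      ambSel <- which(stats::runif(nRows) < pAmb)
      if (length(ambSel)) {
        amb <- tab[ambSel, , drop = FALSE]
        amb$modified_sequence <- paste0(amb$modified_sequence, "_amb")
        amb$localization_prob <- stats::runif(length(ambSel), 0.3, 0.75)
        tab <- rbind(tab, amb)
      }
    }
    batchTables[[dg]] <- tab
  }
  evidence <- do.call(rbind, batchTables)
  rownames(evidence) <- NULL
  list(evidence = evidence, truth = truth)
}

#' Write simulated tables and their ground truth to disk
#'
#' Writes every data-frame element of a simulation result as a
#' tab-separated file and the truth object as JSON, so a dataset can be
#' shared or re-analyzed file-based.
#'
#' @param sim Result list of one of the `simulate*()` functions.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the written paths.
#' @export
writeSimTables <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(sim)) {
    el <- sim[[nm]]
    if (nm == "truth") {
      p <- file.path(dir, paste0(prefix, "_truth.json"))
      jsonlite::write_json(el, p, auto_unbox = TRUE, digits = NA,
                           force = TRUE)
    } else if (is.data.frame(el)) {
      p <- file.path(dir, paste0(prefix, "_", nm, ".tsv"))
      utils::write.table(el, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    } else next
    paths <- c(paths, p)
  }
  invisible(paths)
}
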