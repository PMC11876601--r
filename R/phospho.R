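#' @include kinobeads.R
NULL

#' Standard 11-channel dose-resolved design
#'
#' Channel map for one dose-resolved (decryptM-style) TMT batch: channels
#' 1-9 carry increasing drug doses on top of the chemo background, channel 10
#' is the chemo-only reference and channel 11 the untreated vehicle.
#'
#' @param dosesNM Nine drug doses in nM for channels 1-9.
#' @return Data frame with columns `channel`, `role`, `dose_nM`.
#' @examples
#' decryptmDesign()
#' @export
decryptmDesign <- function(dosesNM = c(1, 3, 10, 30, 100, 300,
                                       1000, 3000, 10000)) {
  stopifnot(length(dosesNM) == 9L, all(dosesNM > 0), !is.unsorted(dosesNM))
  data.frame(channel = 1:11,
             role = c(rep("dose", 9), "gem", "vehicle"),
             dose_nM = c(dosesNM, NA, NA))
}

## canonical site key: protein + sorted site-position set
.siteKey <- function(protein, positions) {
  toks <- strsplit(positions, ";", fixed = TRUE)
  sorted <- vapply(toks, function(x) {
    num <- as.integer(sub("^[A-Z]", "", x))
    paste(x[order(num)], collapse = ";")
  }, character(1))
  paste0(protein, "_", sorted)
}

#' Aggregate peptide evidence to localized phosphosite records
#'
#' Applies the localization-probability filter, checks that each sequence
#' window is consistent with its stated site, and sums the corrected
#' reporter-ion intensities of all peptides carrying the same phosphosite
#' set. Singly and multiply phosphorylated forms of the same position are
#' distinct analytes (records are keyed by the full site set).
#'
#' @param evidence Data frame of peptide evidence with columns
#'   `modified_sequence`, `protein`, `site_positions` (e.g. `"S468"` or
#'   `"S12;T15"`, `;`-separated for multi-site peptides), `localization_prob`,
#'   `sequence_window` (15-mer per site, `;`-separated), `batch` and
#'   `reporter_intensity_1` .. `reporter_intensity_11` (0 or `NA` = missing).
#' @param design Channel map as from [decryptmDesign()], applied per batch.
#' @param locThreshold Minimum localization probability (rows at or below it
#'   are removed before summation; default 0.75).
#' @return A \linkS4class{PhosphoExperiment}; `metadata()` carries
#'   `n_filtered_localization` and `n_dropped_window`.
#' @examples
#' ev <- data.frame(modified_sequence = "AAAS(ph)QK", protein = "P1",
#'                  site_positions = "S4", localization_prob = 0.99,
#'                  sequence_window = "AAAAAAASQAAAAAA", batch = "drugA")
#' ev[paste0("reporter_intensity_", 1:11)] <- as.list(rep(100, 11))
#' aggregateSites(ev)
#' @export
aggregateSites <- function(evidence, design = decryptmDesign(),
                           locThreshold = 0.75) {
  need <- c("modified_sequence", "protein", "site_positions",
            "localization_prob", "sequence_window", "batch",
            paste0("reporter_intensity_", 1:11))
  miss <- setdiff(need, colnames(evidence))
  if (length(miss))
    stop("evidence lacks column(s): ", paste(miss, collapse = ", "))

  nLoc <- sum(!(evidence$localization_prob > locThreshold))
  evidence <- evidence[evidence$localization_prob > locThreshold, ,
                       drop = FALSE]

  ## window/site consistency: per-site 15-mer centered on the stated residue
  ok <- vapply(seq_len(nrow(evidence)), function(i) {
    sites <- strsplit(evidence$site_positions[i], ";", fixed = TRUE)[[1]]
    wins <- strsplit(evidence$sequence_window[i], ";", fixed = TRUE)[[1]]
    if (length(wins) != length(sites)) return(FALSE)
    all(nchar(wins) == 15L &
        substr(wins, 8, 8) == substr(sites, 1, 1))
  }, logical(1))
  nWin <- sum(!ok)
  evidence <- evidence[ok, , drop = FALSE]
  if (nrow(evidence) == 0L)
    stop("no evidence rows left after localization and window filtering")

  evidence$key <- .siteKey(evidence$protein, evidence$site_positions)
  batches <- unique(evidence$batch)
  keys <- unique(evidence$key)
  intCols <- paste0("reporter_intensity_", 1:11)

  mat <- matrix(NA_real_, nrow = length(keys),
                ncol = length(batches) * 11,
                dimnames = list(keys, paste(rep(batches, each = 11),
                                            1:11, sep = ".")))
  for (b in batches) {
    sub <- evidence[evidence$batch == b, , drop = FALSE]
    for (ci in 1:11) {
      v <- sub[[intCols[ci]]]
      v[!is.finite(v) | v <= 0] <- NA
      s <- tapply(v, sub$key, function(x)
        if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE))
      mat[names(s), paste(b, ci, sep = ".")] <- as.numeric(s)
    }
  }

  first <- evidence[!duplicated(evidence$key), , drop = FALSE]
  first <- first[match(keys, first$key), ]
  locMax <- tapply(evidence$localization_prob, evidence$key, max)[keys]
  rowDat <- S4Vectors::DataFrame(
    protein = first$protein,
    site = first$site_positions,
    sequence_window = first$sequence_window,
    localization_prob = as.numeric(locMax),
    row.names = keys)

  colDat <- S4Vectors::DataFrame(
    batch = rep(batches, each = 11),
    channel = rep(design$channel, length(batches)),
    role = rep(design$role, length(batches)),
    dose_nM = rep(design$dose_nM, length(batches)),
    row.names = colnames(mat))

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = mat), rowData = rowDat, colData = colDat)
  pe <- methods::new("PhosphoExperiment", se)
  S4Vectors::metadata(pe)$n_filtered_localization <- nLoc
  S4Vectors::metadata(pe)$n_dropped_window <- nWin
  pe
}

#' Channel and reference normalization of reporter intensities
#'
#' Removes per-channel scale (labeling and loading differences) and per-batch
#' row scale. Alternates two proportional scalings to a fixed point:
#' each batch's channels are scaled so their median intensity is 1, and each
#' row (site) is scaled within each batch so the mean of its anchor channels
#' (default: the chemo-only and vehicle reference channels 10 and 11) is 1.
#' Running the function on already-normalized data is a no-op (idempotent to
#' well below 1e-9).
#'
#' @param pe A \linkS4class{PhosphoExperiment}.
#' @param anchorChannels Channels whose per-row mean anchors the row within
#'   each batch (default `c(10, 11)`); use a single designated reference
#'   channel for common-reference designs.
#' @param tol Convergence tolerance on the largest log scale change.
#' @param maxIter Iteration cap.
#' @return The normalized `PhosphoExperiment`.
#' @export
normalizeChannels <- function(pe, anchorChannels = c(10, 11), tol = 1e-12,
                              maxIter = 100L) {
  stopifnot(is(pe, "PhosphoExperiment"))
  mat <- SummarizedExperiment::assay(pe, "intensity")
  cd <- SummarizedExperiment::colData(pe)
  for (j in seq_len(ncol(mat))) {
    v <- mat[, j]
    if (all(!is.finite(v) | v <= 0))
      stop("normalizeChannels(): channel ", colnames(mat)[j],
           " has no positive intensities")
  }
  batches <- unique(cd$batch)
  for (iter in seq_len(maxIter)) {
    maxChange <- 0
    for (b in batches) {
      cols <- which(cd$batch == b)
      ## channel median scaling
      for (j in cols) {
        med <- stats::median(mat[, j], na.rm = TRUE)
        if (is.finite(med) && med > 0) {
          mat[, j] <- mat[, j] / med
          maxChange <- max(maxChange, abs(log(med)))
        }
      }
      ## row anchoring on the reference channels
      anchorCols <- cols[cd$channel[cols] %in% anchorChannels]
      if (length(anchorCols)) {
        a <- rowMeans(mat[, anchorCols, drop = FALSE], na.rm = TRUE)
        scale <- ifelse(is.finite(a) & a > 0, a, 1)
        mat[, cols] <- mat[, cols, drop = FALSE] / scale
        maxChange <- max(maxChange, max(abs(log(scale))))
      }
    }
    if (maxChange < tol) break
  }
  SummarizedExperiment::assay(pe, "intensity") <- mat
  S4Vectors::metadata(pe)$normalized <- TRUE
  pe
}

#' Dose-response regulation call for every site in one batch
#'
#' Forms per-dose log2 ratios to the chemo-only reference channel, fits the
#' shared 4PL model on log2 ratio versus log10 dose, and classifies each site
#' with a 2D rule: an F-test of the 4PL against a flat (constant) model at
#' `alpha`, combined with a minimum absolute curve log2 fold change. The
#' curve fold change is the fitted saturating plateau minus the zero-dose
#' baseline, so down-regulated sites have negative values; the direction is
#' its sign. A site is `regulated` when it is significant and additionally
#' `pec50 > pec50Min`.
#'
#' @param pe A normalized \linkS4class{PhosphoExperiment}.
#' @param batch Batch (drug) identifier to analyze.
#' @param alpha F-test significance limit (default 0.05).
#' @param fcMin Minimum absolute curve log2 fold change (default 0.45).
#' @param pec50Min Minimum pEC50 for the regulated call (default 5).
#' @param minFinite Minimum number of finite dose points (default 6; fewer
#'   gives `direction = "none"` with `flag = "insufficient"`).
#' @return Data frame with one row per site: `site`, `drug`, `direction`
#'   (`"up"`, `"down"`, `"none"`), `curve_log2fc`, `pec50`, `p_f`,
#'   `significant`, `regulated`, `flag`.
#' @export
callRegulation <- function(pe, batch, alpha = 0.05, fcMin = 0.45,
                           pec50Min = 5, minFinite = 6L) {
  stopifnot(is(pe, "PhosphoExperiment"))
  cd <- SummarizedExperiment::colData(pe)
  cols <- which(cd$batch == batch)
  if (!length(cols)) stop("unknown batch: ", batch)
  doseCols <- cols[cd$role[cols] == "dose"]
  gemCol <- cols[cd$role[cols] == "gem"]
  stopifnot(length(doseCols) == 9L, length(gemCol) == 1L)
  doseCols <- doseCols[order(cd$dose_nM[doseCols])]
  doses <- cd$dose_nM[doseCols] * 1e-9
  mat <- SummarizedExperiment::assay(pe, "intensity")

  rows <- lapply(seq_len(nrow(mat)), function(i) {
    ref <- mat[i, gemCol]
    y <- log2(mat[i, doseCols] / ref)
    fin <- is.finite(y)
    base <- data.frame(site = rownames(mat)[i], drug = batch,
                       direction = "none", curve_log2fc = NA_real_,
                       pec50 = NA_real_, p_f = NA_real_,
                       significant = FALSE, regulated = FALSE, flag = "")
    if (!is.finite(ref) || sum(fin) < minFinite) {
      base$flag <- "insufficient"
      return(base)
    }
    d <- doses[fin]; yy <- as.numeric(y[fin]); n <- sum(fin)
    fit <- fit4PL(d, yy, percentScale = FALSE)
    sse0 <- sum((yy - mean(yy))^2)
    if (fit@flat || sse0 == 0) return(base)
    sse1 <- fit@sse
    fstat <- ((sse0 - sse1) / 3) / (sse1 / max(n - 4, 1))
    pF <- if (sse1 == 0) 0 else
      stats::pf(fstat, 3, max(n - 4, 1), lower.tail = FALSE)
    fc <- fit@bottom - fit@top   # plateau minus zero-dose baseline
    sig <- isTRUE(pF < alpha) && isTRUE(abs(fc) >= fcMin)
    reg <- sig && isTRUE(pec50(fit) > pec50Min)
    base$curve_log2fc <- fc
    base$pec50 <- pec50(fit)
    base$p_f <- pF
    base$significant <- sig
    base$regulated <- reg
    base$direction <- if (reg) (if (fc < 0) "down" else "up") else "none"
    base
  })
  do.call(rbind, rows)
}

## vectorized equal-variance two-sided t-test over matrix rows
.rowTTest <- function(x, y) {
  nx <- rowSums(is.finite(x)); ny <- rowSums(is.finite(y))
  mx <- rowMeans(x, na.rm = TRUE); my <- rowMeans(y, na.rm = TRUE)
  vx <- apply(x, 1, stats::var, na.rm = TRUE)
  vy <- apply(y, 1, stats::var, na.rm = TRUE)
  df <- nx + ny - 2
  sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / df
  se <- sqrt(sp2 * (1 / nx + 1 / ny))
  t <- (mx - my) / se
  p <- 2 * stats::pt(-abs(t), df)
  p[is.finite(sp2) & sp2 == 0 & mx == my] <- 1
  list(estimate = mx - my, p = p, nx = nx, ny = ny)
}

#' Chemo-versus-vehicle differential phosphorylation test
#'
#' Two-sided equal-variance t-test on log2 intensities of the chemo-only
#' reference channel against the vehicle channel across batches (replicates),
#' Benjamini-Hochberg adjusted over all sites tested. A site is called only
#' with at least `minValid` finite values per group, adjusted p below
#' `adjPMax` and absolute log2 fold change above `fcMin`.
#'
#' @param pe A normalized \linkS4class{PhosphoExperiment}.
#' @param adjPMax Maximum BH-adjusted p (default 0.01).
#' @param fcMin Minimum absolute log2 fold change, exclusive (default 1).
#' @param minValid Minimum finite values per group (default 3).
#' @return Data frame with one row per site: `site`, `log2fc`, `p`, `p_adj`,
#'   `n_gem`, `n_vehicle`, `tested`, `verdict` (`"up"`, `"down"`, `"none"`).
#' @export
gemVsVehicle <- function(pe, adjPMax = 0.01, fcMin = 1, minValid = 3L) {
  stopifnot(is(pe, "PhosphoExperiment"))
  cd <- SummarizedExperiment::colData(pe)
  mat <- SummarizedExperiment::assay(pe, "intensity")
  gem <- log2(mat[, cd$role == "gem", drop = FALSE])
  veh <- log2(mat[, cd$role == "vehicle", drop = FALSE])
  gem[!is.finite(gem)] <- NA; veh[!is.finite(veh)] <- NA
  tt <- .rowTTest(gem, veh)
  tested <- tt$nx >= minValid & tt$ny >= minValid & is.finite(tt$p)
  pAdj <- rep(NA_real_, nrow(mat))
  pAdj[tested] <- stats::p.adjust(tt$p[tested], method = "BH")
  verdict <- rep("none", nrow(mat))
  hit <- tested & pAdj < adjPMax & abs(tt$estimate) > fcMin
  verdict[hit & tt$estimate > 0] <- "up"
  verdict[hit & tt$estimate < 0] <- "down"
  data.frame(site = rownames(mat), log2fc = tt$estimate,
             p = tt$p, p_adj = pAdj, n_gem = tt$nx, n_vehicle = tt$ny,
             tested = tested, verdict = verdict, row.names = NULL)
}

#' Annotate the phosphosite substrate motif
#'
#' Classifies each 15-residue sequence window (position 8 = phosphosite) as
#' `"pSQ/pTQ"` when the central residue is S or T and the +1 residue is Q —
#' the substrate motif of the apical DNA-damage-response kinases — and
#' `"other"` otherwise. Terminal sites whose +1 position is padding (`_`)
#' are `"other"`. Multi-site windows (`;`-separated) are classified on their
#' first window. Windows of the wrong length yield `NA` and are counted in
#' the `n_malformed` attribute.
#'
#' @param window Character vector of sequence windows.
#' @return Character vector (`"pSQ/pTQ"` / `"other"` / `NA`) with attribute
#'   `n_malformed`.
#' @examples
#' annotateMotif(c("AAAAAAASQAAAAAA", "AAAAAAAYQAAAAAA"))
#' @export
annotateMotif <- function(window) {
  first <- vapply(strsplit(window, ";", fixed = TRUE),
                  function(x) x[1], character(1))
  bad <- is.na(first) | nchar(first) != 15L
  center <- substr(first, 8, 8)
  plus1 <- substr(first, 9, 9)
  out <- ifelse(center %in% c("S", "T") & plus1 == "Q", "pSQ/pTQ", "other")
  out[bad] <- NA_character_
  attr(out, "n_malformed") <- sum(bad)
  out
}

#' Consensus and reversal classification across drugs
#'
#' Joins per-drug regulation calls with the chemo-effect test per site. A
#' site reaches consensus when at least `minDrugs` of the drug experiments
#' agree on the same non-none direction. Reversal categories: `"reverted"`
#' (chemo-induced and consensus down) and `"restored"` (chemo-suppressed and
#' consensus up); everything else is `"none"`. Sites present in fewer than
#' `minDrugs` drug experiments are not evaluable for consensus.
#'
#' @param regCalls Data frame stacking [callRegulation()] results over drugs.
#' @param gemEffects Data frame from [gemVsVehicle()].
#' @param motifs Optional named character vector (site -> motif class) used
#'   for the summary counts.
#' @param minDrugs Consensus quorum (default 3).
#' @return List with `records` (one row per site: `site`, `motif`,
#'   `gem_verdict`, `n_drugs`, `consensus_direction`, `consensus`,
#'   `reversal`, `evaluable`) and `summary` (category counts, split by motif
#'   class when `motifs` is given).
#' @export
consensusAndReversal <- function(regCalls, gemEffects, motifs = NULL,
                                 minDrugs = 3L) {
  stopifnot(all(c("site", "drug", "direction") %in% colnames(regCalls)),
            all(c("site", "verdict") %in% colnames(gemEffects)))
  sites <- unique(c(regCalls$site, gemEffects$site))
  gemV <- gemEffects$verdict[match(sites, gemEffects$site)]
  gemV[is.na(gemV)] <- "none"

  nDrugs <- as.integer(table(regCalls$site)[sites])
  nDrugs[is.na(nDrugs)] <- 0L
  consDir <- vapply(sites, function(s) {
    d <- regCalls$direction[regCalls$site == s]
    for (dir in c("up", "down"))
      if (sum(d == dir) >= minDrugs) return(dir)
    "none"
  }, character(1))
  evaluable <- nDrugs >= minDrugs
  consDir[!evaluable] <- "none"
  consensus <- consDir != "none"

  reversal <- rep("none", length(sites))
  reversal[gemV == "up" & consDir == "down"] <- "reverted"
  reversal[gemV == "down" & consDir == "up"] <- "restored"

  motif <- if (is.null(motifs)) rep(NA_character_, length(sites)) else
    unname(motifs[sites])
  records <- data.frame(site = sites, motif = motif, gem_verdict = gemV,
                        n_drugs = nDrugs, consensus_direction = consDir,
                        consensus = consensus, reversal = reversal,
                        evaluable = evaluable, row.names = NULL)
  tab <- table(factor(records$reversal,
                      levels = c("reverted", "restored", "none")),
               useNA = "no")
  summary <- data.frame(category = names(tab), n = as.integer(tab))
  if (!is.null(motifs)) {
    sq <- records$motif == "pSQ/pTQ" & !is.na(records$motif)
    summary$n_psq_ptq <- as.integer(table(factor(
      records$reversal[sq], levels = c("reverted", "restored", "none"))))
  }
  list(records = records, summary = summary)
}

#' Per-drug potency summary over regulated motif sites
#'
#' Median EC50/pEC50 per drug across the regulated pSQ/pTQ sites (or another
#' motif class), the standard readout for comparing cellular pathway
#' engagement potencies between drugs. Drugs without any regulated site in
#' the class are omitted with a message.
#'
#' @param regCalls Stacked [callRegulation()] results with a `motif` column
#'   (join [annotateMotif()] output on site).
#' @param motifClass Class to summarize (default `"pSQ/pTQ"`).
#' @return Data frame: `drug`, `n_sites`, `median_ec50`, `median_pec50`,
#'   plus a `pec50` list-column export of the per-site values for plotting.
#' @export
potencySummary <- function(regCalls, motifClass = "pSQ/pTQ") {
  stopifnot(all(c("drug", "regulated", "pec50", "motif") %in%
                colnames(regCalls)))
  sel <- regCalls[regCalls$regulated & regCalls$motif %in% motifClass, ,
                  drop = FALSE]
  drugs <- unique(regCalls$drug)
  rows <- list()
  for (dg in drugs) {
    p <- sel$pec50[sel$drug == dg]
    p <- p[is.finite(p)]
    if (!length(p)) {
      message("potencySummary(): no regulated ", motifClass,
              " site for drug ", dg, "; omitted")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      drug = dg, n_sites = length(p),
      median_pec50 = stats::median(p),
      median_ec50 = 10^(-stats::median(p)))
  }
  out <- do.call(rbind, rows)
  if (!is.null(out))
    out$pec50 <- I(lapply(out$drug, function(dg) {
      p <- sel$pec50[sel$drug == dg]; p[is.finite(p)]
    }))
  out
}

#' Conversely regulated proteins in a two-drug time course
#'
#' A protein is conversely regulated when, at the 24 h time point, its
#' absolute log2 fold change versus the time-matched vehicle exceeds `fcMin`
#' for at least one drug and the two drugs affect it in opposite directions
#' (a fold change of exactly 0 is not opposite to anything). Proteins
#' missing a 24 h value for either drug are not evaluable.
#'
#' @param ratios Data frame with columns `protein`, `drug`, `time_h`,
#'   `log2fc`; exactly two drugs expected.
#' @param fcMin Absolute log2 fold-change threshold, exclusive (default 2).
#' @param timeH Evaluation time point in hours (default 24).
#' @return Data frame: `protein`, per-drug fold changes, `evaluable`,
#'   `converse`.
#' @export
timecourseConverse <- function(ratios, fcMin = 2, timeH = 24) {
  stopifnot(all(c("protein", "drug", "time_h", "log2fc") %in%
                colnames(ratios)))
  drugs <- sort(unique(ratios$drug))
  if (length(drugs) != 2L)
    stop("timecourseConverse() expects exactly 2 drugs, got ",
         length(drugs))
  at24 <- ratios[ratios$time_h == timeH, , drop = FALSE]
  prots <- unique(ratios$protein)
  fc1 <- at24$log2fc[match(paste(prots, drugs[1]),
                           paste(at24$protein, at24$drug))]
  fc2 <- at24$log2fc[match(paste(prots, drugs[2]),
                           paste(at24$protein, at24$drug))]
  evaluable <- is.finite(fc1) & is.finite(fc2)
  converse <- evaluable &
    (abs(fc1) > fcMin | abs(fc2) > fcMin) &
    sign(fc1) * sign(fc2) == -1
  out <- data.frame(protein = prots, fc1 = fc1, fc2 = fc2,
                    evaluable = evaluable, converse = converse)
  names(out)[2:3] <- paste0("log2fc_", drugs)
  out
}
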