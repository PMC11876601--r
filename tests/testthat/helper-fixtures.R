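# Shared fixture builders; everything is generated in code, no files.

# screen truth with hand-set curves: anchor either flat (no effect) or a
# proper titration curve, one library drug with known parameters
handScreenTruth <- function(libEc50 = 1e-7, libSlope = 1, libTop = 100,
                            libBottom = 0, mode = "bliss_additive",
                            phi = 1, anchorFlat = FALSE,
                            anchorEc50 = 2e-8) {
  curves <- rbind(
    data.frame(cell_line = "CL01", drug = "GEM",
               top = 100, bottom = if (anchorFlat) 100 else 0,
               slope = 1, ec50 = anchorEc50),
    data.frame(cell_line = "CL01", drug = "LIB",
               top = libTop, bottom = libBottom, slope = libSlope,
               ec50 = libEc50))
  interactions <- data.frame(cell_line = "CL01", drug = "LIB",
                             mode = mode, phi = phi)
  anchorDoses <- matrix(c(10e-9, 30e-9), 1, 2,
                        dimnames = list("CL01", c("low", "high")))
  structure(list(curves = curves, interactions = interactions,
                 anchorDoses = anchorDoses, anchorDrug = "GEM",
                 plateScale = 2e6, doses = screenDoses()),
            class = "screenTruth")
}

# minimal evidence table: one row per entry in `rows`, a list of lists with
# fields protein, site, loc, window, batch, intensities (length 11)
handEvidence <- function(rows) {
  out <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    df <- data.frame(
      modified_sequence = r$seq %||% sprintf("PEP%02d", i),
      protein = r$protein %||% "P1",
      site_positions = r$site %||% "S8",
      localization_prob = r$loc %||% 0.99,
      sequence_window = r$window %||% "AAAAAAASQAAAAAA",
      batch = r$batch %||% "drugA")
    df[paste0("reporter_intensity_", 1:11)] <-
      as.list(r$intensities %||% rep(100, 11))
    df
  }))
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# PhosphoExperiment built directly from a per-batch list of 11-column
# intensity matrices (sites x channels), bypassing evidence aggregation
handPhosphoExperiment <- function(batchMats, windows = NULL) {
  batches <- names(batchMats)
  nSites <- nrow(batchMats[[1]])
  design <- decryptmDesign()
  mat <- do.call(cbind, batchMats)
  colnames(mat) <- paste(rep(batches, each = 11), 1:11, sep = ".")
  siteIds <- rownames(batchMats[[1]])
  if (is.null(siteIds)) siteIds <- sprintf("P%03d_S10", seq_len(nSites))
  rownames(mat) <- siteIds
  if (is.null(windows)) windows <- rep("AAAAAAASQAAAAAA", nSites)
  rd <- S4Vectors::DataFrame(protein = sub("_.*", "", siteIds),
                             site = sub(".*_", "", siteIds),
                             sequence_window = windows,
                             localization_prob = rep(1, nSites),
                             row.names = siteIds)
  cd <- S4Vectors::DataFrame(batch = rep(batches, each = 11),
                             channel = rep(design$channel, length(batches)),
                             role = rep(design$role, length(batches)),
                             dose_nM = rep(design$dose_nM, length(batches)),
                             row.names = colnames(mat))
  PhosphoExperiment(mat, rd, cd)
}
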