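test_that("evidence aggregation sums intensities per site set", {
  ev <- handEvidence(list(
    list(seq = "pepA", intensities = c(10, rep(1, 10))),
    list(seq = "pepB", intensities = c(30, rep(1, 10)))))
  pe <- aggregateSites(ev)
  expect_equal(nrow(pe), 1)
  expect_equal(unname(SummarizedExperiment::assay(pe)[1, 1]), 40)
})

test_that("localization filter is strict at 0.75", {
  ev <- handEvidence(list(
    list(seq = "keep", loc = 0.76, intensities = rep(10, 11)),
    list(seq = "drop", loc = 0.74, intensities = rep(90, 11)),
    list(seq = "dropToo", loc = 0.75, intensities = rep(90, 11))))
  pe <- aggregateSites(ev)
  expect_equal(unname(SummarizedExperiment::assay(pe)[1, 1]), 10)
  expect_equal(S4Vectors::metadata(pe)$n_filtered_localization, 2)
})

test_that("three peptides over two sites give two records", {
  ev <- handEvidence(list(
    list(seq = "p1", site = "S8"),
    list(seq = "p2", site = "S8"),
    list(seq = "p3", site = "T20", window = "AAAAAAATQAAAAAA")))
  expect_equal(nrow(aggregateSites(ev)), 2)
})

test_that("multiply phosphorylated peptides are distinct analytes", {
  ev <- handEvidence(list(
    list(seq = "single", site = "S8"),
    list(seq = "double", site = "S8;T20",
         window = "AAAAAAASQAAAAAA;AAAAAAATQAAAAAA"),
    # same site set in a different row order collapses to the same key
    list(seq = "double2", site = "T20;S8",
         window = "AAAAAAATQAAAAAA;AAAAAAASQAAAAAA")))
  pe <- aggregateSites(ev)
  expect_equal(nrow(pe), 2)
  expect_setequal(rownames(pe), c("P1_S8", "P1_S8;T20"))
})

test_that("windows inconsistent with the stated site are dropped", {
  ev <- handEvidence(list(
    list(seq = "ok", site = "S8"),
    list(seq = "badResidue", site = "T9", window = "AAAAAAASQAAAAAA"),
    list(seq = "badLength", site = "S8", window = "AAASQAA")))
  pe <- aggregateSites(ev)
  expect_equal(nrow(pe), 1)
  expect_equal(S4Vectors::metadata(pe)$n_dropped_window, 2)
  expect_error(aggregateSites(ev[, -3]), "site_positions")
})

test_that("channel normalization removes a global channel factor exactly", {
  set.seed(2)
  batch <- list(b1 = matrix(2^rnorm(1100, 20, 1), 100, 11))
  pe <- handPhosphoExperiment(batch)
  scaled <- pe
  a <- SummarizedExperiment::assay(scaled)
  a[, 3] <- a[, 3] * 2                         # one channel scaled x2
  SummarizedExperiment::assay(scaled) <- a
  n1 <- normalizeChannels(pe)
  n2 <- normalizeChannels(scaled)
  expect_equal(SummarizedExperiment::assay(n1),
               SummarizedExperiment::assay(n2), tolerance = 1e-12)
})

test_that("normalization is idempotent", {
  truth <- phosphoTruth(nSites = 60, nReverted = 5, nRestored = 5, seed = 3)
  sim <- simulatePhospho(truth, seed = 3, noiseSd = 0.1)
  pe <- normalizeChannels(aggregateSites(sim$evidence))
  pe2 <- normalizeChannels(pe)
  expect_lt(max(abs(SummarizedExperiment::assay(pe) -
                    SummarizedExperiment::assay(pe2)), na.rm = TRUE), 1e-9)
})

test_that("normalization shrinks between-batch variation of null sites", {
  truth <- phosphoTruth(nSites = 150, nReverted = 0, nRestored = 0, seed = 4)
  sim <- simulatePhospho(truth, seed = 4, noiseSd = 0.05, batchEffects = TRUE)
  pe <- normalizeChannels(aggregateSites(sim$evidence))
  mat <- log2(SummarizedExperiment::assay(pe))
  cd <- SummarizedExperiment::colData(pe)
  gemCols <- which(cd$role == "gem")
  # between-batch SD of the reference channel vs within-batch channel SD
  between <- apply(mat[, gemCols], 1, sd)
  within <- apply(mat[, cd$batch == cd$batch[1]], 1, sd)
  expect_lt(median(between), 1.2 * median(within))
})

test_that("an all-missing channel is rejected by name", {
  pe <- handPhosphoExperiment(list(b1 = matrix(100, 5, 11)))
  a <- SummarizedExperiment::assay(pe); a[, 2] <- NA
  SummarizedExperiment::assay(pe) <- a
  expect_error(normalizeChannels(pe), "b1.2")
})

test_that("regulation calls recover noiseless curves and apply the 2D rule", {
  d <- decryptmDesign()$dose_nM[1:9] * 1e-9
  base <- 2^20
  down <- 2^(log2(base) + (-2) / (1 + 1e-8 / d))      # pEC50 8, log2FC -2
  flat <- rep(base, 9)
  weakDeep <- 2^(log2(base) + (-3) / (1 + 10^(-4.5) / d))  # pEC50 4.5
  mats <- list(b1 = rbind(c(down, base, base),
                          c(flat, base, base),
                          c(weakDeep, base, base)))
  rownames(mats$b1) <- c("P001_S10", "P002_S10", "P003_S10")
  pe <- handPhosphoExperiment(mats)
  calls <- callRegulation(pe, "b1")
  expect_equal(calls$direction, c("down", "none", "none"))
  expect_equal(calls$curve_log2fc[1], -2, tolerance = 0.05)
  expect_equal(calls$pec50[1], 8, tolerance = 0.05)
  # the weak-potency curve is significant but filtered by the pEC50 rule
  expect_true(calls$significant[3])
  expect_false(calls$regulated[3])
})

test_that("sites with too few finite points are flagged", {
  d <- rep(2^20, 9); d[1:5] <- NA
  mats <- list(b1 = matrix(c(d, 2^20, 2^20), 1))
  pe <- handPhosphoExperiment(mats)
  calls <- callRegulation(pe, "b1")
  expect_equal(calls$flag, "insufficient")
  expect_equal(calls$direction, "none")
  expect_error(callRegulation(pe, "nope"), "unknown batch")
})

test_that("chemo-vs-vehicle test applies thresholds and valid-value rule", {
  set.seed(10)
  nB <- 4
  batches <- list()
  shifts <- c(4.2, 0.5, 0, 3)
  for (s in seq_along(shifts)) {
    for (b in seq_len(nB)) {
      key <- paste0("b", b)
      m <- matrix(c(rep(2^20, 9), 2^(20 + shifts[s]), 2^20), 1)
      batches[[key]] <- rbind(batches[[key]], m)
    }
  }
  for (b in seq_len(nB)) rownames(batches[[paste0("b", b)]]) <-
    sprintf("P%03d_S10", seq_along(shifts))
  pe <- handPhosphoExperiment(batches)
  g <- gemVsVehicle(pe)
  expect_equal(g$verdict, c("up", "none", "none", "up"))
  expect_equal(g$log2fc[1], 4.2, tolerance = 1e-9)
  expect_equal(g$p[3], 1)          # identical groups
  # knock out two batches for site 2: below the valid-value minimum
  a <- SummarizedExperiment::assay(pe)
  a[2, c("b1.10", "b2.10")] <- NA
  SummarizedExperiment::assay(pe) <- a
  g2 <- gemVsVehicle(pe)
  expect_false(g2$tested[2])
})

test_that("the 4.2 log2FC chemo effect is detected reliably at SD 0.3", {
  set.seed(77)
  nSites <- 400; nTrue <- 60
  base <- rnorm(nSites, 20, 1)
  fc <- c(rep(4.2, nTrue), rep(0, nSites - nTrue))
  batches <- lapply(1:4, function(b) {
    m <- matrix(2^20, nSites, 11)
    m[, 10] <- 2^(base + fc + rnorm(nSites, 0, 0.3))
    m[, 11] <- 2^(base + rnorm(nSites, 0, 0.3))
    rownames(m) <- sprintf("P%04d_S10", seq_len(nSites))
    m
  })
  names(batches) <- paste0("b", 1:4)
  g <- gemVsVehicle(handPhosphoExperiment(batches))
  expect_gte(mean(g$verdict[1:nTrue] == "up"), 0.95)
  expect_lte(mean(g$verdict[-(1:nTrue)] != "none"), 0.05)
})

test_that("motif annotation matches a regex oracle on all center/+1 pairs", {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  grid <- expand.grid(center = aa, plus1 = aa, stringsAsFactors = FALSE)
  windows <- paste0(strrep("A", 7), grid$center, grid$plus1, strrep("A", 6))
  got <- annotateMotif(windows)
  oracle <- ifelse(grepl("^.{7}[ST]Q", windows), "pSQ/pTQ", "other")
  expect_equal(as.character(got), oracle)
  expect_equal(attr(got, "n_malformed"), 0)
})

test_that("motif annotation handles padding, multi-windows and bad input", {
  expect_equal(as.character(annotateMotif("AAAAAAAS_AAAAAA")), "other")
  expect_equal(as.character(annotateMotif("AAAAAAAYQAAAAAA")), "other")
  expect_equal(as.character(
    annotateMotif("AAAAAAATQAAAAAA;AAAAAAAYAAAAAAA")), "pSQ/pTQ")
  bad <- annotateMotif(c("SHORT", "AAAAAAASQAAAAAA"))
  expect_true(is.na(bad[1]))
  expect_equal(attr(bad, "n_malformed"), 1)
})

test_that("consensus and reversal follow the quorum rule", {
  reg <- data.frame(
    site = rep(c("s1", "s2", "s3", "s4"), each = 4),
    drug = rep(paste0("d", 1:4), 4),
    direction = c("down", "down", "down", "none",    # s1: consensus down
                  "down", "down", "up", "down",      # s2: 3 of 4 down
                  "up", "up", "none", "none",        # s3: no quorum
                  "up", "up", "up", "none"))         # s4: consensus up
  reg <- reg[!(reg$site == "s4" & reg$drug == "d4"), ]  # s4 in 3 experiments
  gem <- data.frame(site = c("s1", "s2", "s3", "s4"),
                    verdict = c("up", "none", "up", "down"))
  out <- consensusAndReversal(reg, gem)
  rec <- out$records[match(c("s1", "s2", "s3", "s4"), out$records$site), ]
  expect_equal(rec$consensus_direction, c("down", "down", "none", "up"))
  expect_equal(rec$reversal, c("reverted", "none", "none", "restored"))
  expect_true(all(rec$evaluable[c(1, 2, 4)]))
  # a site seen in too few experiments is not evaluable
  reg2 <- reg[!(reg$site == "s4" & reg$drug == "d3"), ]
  out2 <- consensusAndReversal(reg2, gem)
  expect_false(out2$records$evaluable[out2$records$site == "s4"])
  expect_equal(out2$records$reversal[out2$records$site == "s4"], "none")
})

test_that("category recovery on a small simulated panel is exact-ish", {
  truth <- phosphoTruth(nSites = 120, nReverted = 10, nRestored = 12,
                        seed = 15)
  sim <- simulatePhospho(truth, seed = 16, noiseSd = 0.05)
  pe <- normalizeChannels(aggregateSites(sim$evidence))
  cd <- SummarizedExperiment::colData(pe)
  calls <- do.call(rbind, lapply(unique(cd$batch), function(b)
    callRegulation(pe, b)))
  gem <- gemVsVehicle(pe)
  out <- consensusAndReversal(calls, gem)
  nRev <- sum(out$records$reversal == "reverted")
  nRes <- sum(out$records$reversal == "restored")
  expect_equal(nRev, 10, tolerance = 0.2)
  expect_equal(nRes, 12, tolerance = 0.2)
  # structural invariants
  revSites <- out$records$site[out$records$reversal != "none"]
  expect_true(all(revSites %in% gem$site[gem$verdict != "none"]))
  consSites <- out$records$site[out$records$consensus]
  regSites <- unique(calls$site[calls$regulated])
  expect_true(all(consSites %in% regSites))
})

test_that("potency summary reports per-drug medians over motif sites", {
  calls <- data.frame(
    drug = c("d1", "d1", "d1", "d2", "d2"),
    site = paste0("s", 1:5),
    regulated = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    pec50 = c(8, 7, 6, 8.5, 9),
    motif = c("pSQ/pTQ", "pSQ/pTQ", "pSQ/pTQ", "pSQ/pTQ", "pSQ/pTQ"))
  out <- potencySummary(calls)
  expect_equal(out$median_pec50[out$drug == "d1"], 7)
  expect_equal(out$median_ec50[out$drug == "d1"], 1e-7)
  expect_equal(out$n_sites[out$drug == "d2"], 1)
  expect_equal(out$median_pec50[out$drug == "d2"], 8.5)
  calls$motif[4] <- "other"
  expect_message(out2 <- potencySummary(calls), "omitted")
  expect_equal(out2$drug, "d1")
})

test_that("per-drug potency ranking is recovered from simulation", {
  truth <- phosphoTruth(nSites = 80, nReverted = 20, nRestored = 0,
                        drugPec50 = c(drugA = 8, drugB = 8, drugC = 6.8,
                                      drugD = 6.8), seed = 19)
  sim <- simulatePhospho(truth, seed = 20, noiseSd = 0.05)
  pe <- normalizeChannels(aggregateSites(sim$evidence))
  cd <- SummarizedExperiment::colData(pe)
  calls <- do.call(rbind, lapply(unique(cd$batch), function(b)
    callRegulation(pe, b)))
  motifs <- annotateMotif(SummarizedExperiment::rowData(pe)$sequence_window)
  names(motifs) <- rownames(pe)
  calls$motif <- motifs[calls$site]
  out <- potencySummary(calls)
  # medians within 2-fold of the drug-specific truth
  for (dg in out$drug) {
    trueMed <- c(drugA = 8, drugB = 8, drugC = 6.8, drugD = 6.8)[[dg]]
    expect_lt(abs(out$median_pec50[out$drug == dg] - trueMed), log10(2))
  }
})

test_that("converse time-course regulation follows the 24 h rule", {
  ratios <- data.frame(
    protein = rep(c("A", "B", "C", "D"), each = 2),
    drug = rep(c("GEM", "ATRi"), 4),
    time_h = 24,
    log2fc = c(2.5, -0.3,    # converse
               2.5, 0.1,     # same sign
               1.5, -1.5,    # neither exceeds 2
               0, -2.5))     # zero is not opposite
  out <- timecourseConverse(ratios)
  expect_equal(out$converse, c(TRUE, FALSE, FALSE, FALSE))
  # missing 24 h value -> not evaluable
  ratios2 <- ratios[-2, ]
  out2 <- timecourseConverse(ratios2)
  expect_false(out2$evaluable[out2$protein == "A"])
  expect_error(timecourseConverse(ratios[ratios$drug == "GEM", ]),
               "exactly 2 drugs")
})
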