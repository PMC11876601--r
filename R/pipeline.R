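#' @include simulate.R
NULL

.defaultConfig <- function() {
  list(
    seed = 1L,
    outDir = "synergyMoA_out",
    inputs = list(),
    thresholds = list(
      screen = list(aucMax = 80, pec50Min = 6, r2Min = 0.8, sumMin = 10),
      kinobeads = list(r2Min = 0.7, foldChangeMax = 0.5, slopeMin = 0.2,
                       pec50Min = 6, minPeptides = 4),
      phospho = list(alpha = 0.05, fcMin = 0.45, pec50Min = 5),
      gem = list(adjPMax = 0.01, fcMin = 1, minValid = 3)
    ),
    zPrimeMode = "printed",
    anchorDrug = "GEM"
  )
}

.readConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs needs the 'yaml' package")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  cfg <- utils::modifyList(.defaultConfig(), config)
  stopifnot(length(cfg$seed) == 1L, cfg$seed == as.integer(cfg$seed))
  badThr <- unlist(cfg$thresholds) <= 0
  if (any(badThr))
    stop("non-positive threshold(s): ",
         paste(names(unlist(cfg$thresholds))[badThr], collapse = ", "))
  cfg
}

.writeTable <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.readInput <- function(cfg, name) {
  path <- cfg$inputs[[name]]
  if (is.null(path) || !file.exists(path))
    stop("required input '", name, "' missing or not found: ",
         if (is.null(path)) "<unset>" else path)
  utils::read.delim(path, check.names = FALSE)
}

#' Run one pipeline stage end to end
#'
#' Deterministic orchestration over the package's analysis modules. Each
#' stage reads its tab-separated inputs (paths under `config$inputs`), runs
#' the corresponding analysis with the configured thresholds and seed, and
#' writes its result tables plus a JSON run manifest (package version, seed,
#' thresholds and row counts) to `config$outDir`. Identical configuration
#' and inputs produce byte-identical outputs; partially written outputs are
#' removed when a stage fails.
#'
#' Stages: `"simulate"` (generate all three synthetic input kinds with known
#' truth), `"screen"` (input `plate`), `"kinobeads"` (inputs `pulldown`,
#' `repulldown`; `config$kinobeadsDosesNM` gives the dose grid), `"decryptm"`
#' (input `evidence`) and `"timecourse"` (input `ratios`).
#'
#' @param config Named list, or path to a JSON/YAML file, overriding the
#'   defaults: `seed`, `outDir`, `inputs` (named paths), `thresholds`
#'   (blocks `screen`, `kinobeads`, `phospho`, `gem`), `zPrimeMode`,
#'   `anchorDrug`.
#' @param stage One of `"simulate"`, `"screen"`, `"kinobeads"`,
#'   `"decryptm"`, `"timecourse"`.
#' @return Invisibly, a list with the stage results and the manifest.
#' @examples
#' out <- file.path(tempdir(), "simdemo")
#' runPipeline(list(seed = 7, outDir = out), stage = "simulate")
#' list.files(out)
#' @export
runPipeline <- function(config = list(),
                        stage = c("screen", "kinobeads", "decryptm",
                                  "timecourse", "simulate")) {
  stage <- match.arg(stage)
  cfg <- .readConfig(config)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(df, name) {
    written <<- c(written, .writeTable(df, file.path(cfg$outDir,
                                                     paste0(name, ".tsv"))))
  }

  result <- tryCatch({
    if (stage == "simulate") {
      truthS <- screenTruth(seed = cfg$seed)
      simS <- simulateScreen(truthS, seed = cfg$seed)
      truthK <- bindingTruth(seed = cfg$seed)
      simK <- simulateKinobeads(truthK, seed = cfg$seed)
      truthP <- phosphoTruth(nSites = 200, nReverted = 10, nRestored = 15,
                             seed = cfg$seed)
      simP <- simulatePhospho(truthP, seed = cfg$seed)
      written <- c(written,
                   writeSimTables(simS, cfg$outDir, "screen"),
                   writeSimTables(simK, cfg$outDir, "kinobeads"),
                   writeSimTables(simP, cfg$outDir, "phospho"))
      list(screen = simS, kinobeads = simK, phospho = simP)
    } else if (stage == "screen") {
      plate <- .readInput(cfg, "plate")
      th <- cfg$thresholds$screen
      res <- analyzeScreen(plate, anchorDrug = cfg$anchorDrug,
                           thresholds = th, zPrimeMode = cfg$zPrimeMode)
      emit(res$curves, "curves"); emit(res$qc, "plate_qc")
      emit(res$synergy, "synergy"); emit(res$summary, "summary")
      res
    } else if (stage == "kinobeads") {
      pd <- .readInput(cfg, "pulldown")
      rp <- .readInput(cfg, "repulldown")
      doses <- cfg$kinobeadsDosesNM
      if (is.null(doses))
        doses <- c(1, 3, 10, 30, 100, 300, 1000, 3000, 30000)
      th <- cfg$thresholds$kinobeads
      res <- analyzeKinobeads(pd, rp, doses * 1e-9,
                              r2Min = th$r2Min,
                              foldChangeMax = th$foldChangeMax,
                              slopeMin = th$slopeMin, pec50Min = th$pec50Min,
                              minPeptides = th$minPeptides)
      emit(res$targets, "targets")
      res
    } else if (stage == "decryptm") {
      ev <- .readInput(cfg, "evidence")
      pe <- normalizeChannels(aggregateSites(ev))
      thP <- cfg$thresholds$phospho; thG <- cfg$thresholds$gem
      cd <- SummarizedExperiment::colData(pe)
      calls <- do.call(rbind, lapply(unique(cd$batch), function(b)
        callRegulation(pe, b, alpha = thP$alpha, fcMin = thP$fcMin,
                       pec50Min = thP$pec50Min)))
      gem <- gemVsVehicle(pe, adjPMax = thG$adjPMax, fcMin = thG$fcMin,
                          minValid = thG$minValid)
      motifs <- annotateMotif(
        SummarizedExperiment::rowData(pe)$sequence_window)
      names(motifs) <- rownames(pe)
      cr <- consensusAndReversal(calls, gem, motifs = motifs)
      calls$motif <- motifs[calls$site]
      pot <- potencySummary(calls)
      emit(calls, "site_calls")
      emit(gem, "gem_effect")
      emit(cr$records, "consensus_reversal")
      emit(cr$summary, "reversal_summary")
      if (!is.null(pot))
        emit(pot[, c("drug", "n_sites", "median_pec50", "median_ec50")],
             "potency_summary")
      list(calls = calls, gem = gem, consensus = cr, potency = pot)
    } else {  # timecourse
      ratios <- .readInput(cfg, "ratios")
      res <- timecourseConverse(ratios)
      emit(res, "timecourse_converse")
      res
    }
  }, error = function(e) {
    unlink(written)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  counts <- vapply(written, function(p)
    length(readLines(p)) - 1L, integer(1))
  manifest <- list(
    package = "synergyMoA",
    version = as.character(utils::packageVersion("synergyMoA")),
    stage = stage, seed = cfg$seed, thresholds = cfg$thresholds,
    tables = as.list(counts))
  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(result = result, manifest = manifest))
}
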