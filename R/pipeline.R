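# Configuration, delimited-table I/O and the end-to-end pipeline tying
# spectra, blanks and metadata into a results table. Units are embedded in
# column names (litres, seconds, Bq); dates are ISO-8601; workers appear
# only as anonymized codes.

#' Assay configuration
#'
#' All method choices in one place: ROI windows, the MDC formula variant,
#' the K-constant mode and aggregation, the decay-correction toggle, the
#' recovery counting mode and the non-counting uncertainty components.
#' Every result row records [configDigest()] of the configuration that
#' produced it.
#'
#' @param lines Named alpha-line energies `c(tracer=, analyte=)`, keV.
#' @param roiLowOffset,roiHighOffset ROI extent below/above each line, keV.
#' @param mdcFormula `"currie_sqrt"` (default) or `"as_printed"`; see
#'   [mdc()].
#' @param kMode `"net"` (default) or `"as_printed"`; see [kSingle()].
#' @param kAggregate `"mean"` (default) or `"median"`.
#' @param uKRelDefault Relative uncertainty of K for single-blank series.
#' @param decayCorrect,delayDays Decay correction toggle (default off) and
#'   collection-to-count delay in days.
#' @param recoveryNetCounts Use net tracer counts in [tracerRecovery()].
#' @param relTracerActivity,relTracerMass Non-counting relative uncertainty
#'   components; see [uncertaintyBudget()].
#' @return A list of class `po210Config`.
#' @examples
#' cfg <- assayConfig()
#' configDigest(cfg)
#' @export
assayConfig <- function(lines = poAlphaLines(), roiLowOffset = 60,
                        roiHighOffset = 40,
                        mdcFormula = c("currie_sqrt", "as_printed"),
                        kMode = c("net", "as_printed"),
                        kAggregate = c("mean", "median"),
                        uKRelDefault = 0.3, decayCorrect = FALSE,
                        delayDays = 0, recoveryNetCounts = FALSE,
                        relTracerActivity = 0.0050 / 2 / 0.4891,
                        relTracerMass = 0.001) {
  cfg <- list(lines = lines, roiLowOffset = roiLowOffset,
              roiHighOffset = roiHighOffset,
              mdcFormula = match.arg(mdcFormula),
              kMode = match.arg(kMode),
              kAggregate = match.arg(kAggregate),
              uKRelDefault = uKRelDefault, decayCorrect = decayCorrect,
              delayDays = delayDays,
              recoveryNetCounts = recoveryNetCounts,
              relTracerActivity = relTracerActivity,
              relTracerMass = relTracerMass)
  class(cfg) <- "po210Config"
  cfg
}

#' @describeIn assayConfig Stable MD5 digest of a configuration (first 12
#'   hex digits), recorded in every result row.
#' @param config A `po210Config` list.
#' @export
configDigest <- function(config) {
  x <- unclass(config)
  x <- x[order(names(x))]
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(x, precision = 15), tf)
  substr(unname(tools::md5sum(tf)), 1, 12)
}

#' @describeIn assayConfig Read a configuration from a YAML file; fields
#'   not present keep their defaults.
#' @param path Path to a YAML file.
#' @export
readAssayConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$lines)) vals$lines <- unlist(vals$lines)
  do.call(assayConfig, vals)
}

.requireColumns <- function(df, need, what) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}

#' Read per-sample metadata
#'
#' Tab-delimited table with one row per analytical sample. Required
#' columns: `sample_id`, `v_aliquot_l`, `v_24h_l`, `tracer_mass_g`,
#' `live_time_s`. Optional: `worker_code`, `collection_date`,
#' `tracer_specific_activity_bq_g` (default 0.4891, the certified solution
#' value), `detector_id`, `bkg_rate_210po_s`, `bkg_rate_tracer_s`,
#' `efficiency`, `spectrum_file` (default `<sample_id>.spe`). The tracer
#' activity is `tracer_mass_g * tracer_specific_activity_bq_g` and must be
#' positive; the aliquot may not exceed the 24-hour volume.
#'
#' @param path Path to the table.
#' @return A `data.frame` with a computed `tracer_activity_bq` column.
#' @export
readSampleMetadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("metadata table is empty: ", path, call. = FALSE)
  .requireColumns(df, c("sample_id", "v_aliquot_l", "v_24h_l",
                        "tracer_mass_g", "live_time_s"), "metadata table")
  if (is.null(df$tracer_specific_activity_bq_g))
    df$tracer_specific_activity_bq_g <- 0.4891
  if (is.null(df$worker_code)) df$worker_code <- NA_character_
  if (is.null(df$collection_date)) df$collection_date <- NA_character_
  if (is.null(df$detector_id)) df$detector_id <- NA_character_
  if (is.null(df$bkg_rate_210po_s)) df$bkg_rate_210po_s <- 0
  if (is.null(df$bkg_rate_tracer_s)) df$bkg_rate_tracer_s <- 0
  if (is.null(df$efficiency)) df$efficiency <- NA_real_
  if (is.null(df$spectrum_file))
    df$spectrum_file <- paste0(df$sample_id, ".spe")
  df$tracer_activity_bq <- df$tracer_mass_g * df$tracer_specific_activity_bq_g
  bad <- which(!is.finite(df$tracer_activity_bq) | df$tracer_activity_bq <= 0)
  if (length(bad))
    stop("non-positive tracer activity for sample(s): ",
         paste(df$sample_id[bad], collapse = ", "), call. = FALSE)
  bad <- which(df$v_aliquot_l > df$v_24h_l)
  if (length(bad))
    stop("aliquot exceeds 24-h volume for sample(s): ",
         paste(df$sample_id[bad], collapse = ", "), call. = FALSE)
  df
}

#' Read a blank-series table
#'
#' Tab-delimited with columns `blank_id`, `n_210po`, `n_tracer`,
#' `tracer_activity_bq`, `live_time_s` and optional `bkg_rate_210po_s`,
#' `bkg_rate_tracer_s`.
#'
#' @param path Path to the table.
#' @return A list of [BlankMeasurement-class] objects.
#' @export
readBlankTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("blank table is empty: ", path, call. = FALSE)
  .requireColumns(df, c("blank_id", "n_210po", "n_tracer",
                        "tracer_activity_bq", "live_time_s"), "blank table")
  if (is.null(df$bkg_rate_210po_s)) df$bkg_rate_210po_s <- 0
  if (is.null(df$bkg_rate_tracer_s)) df$bkg_rate_tracer_s <- 0
  lapply(seq_len(nrow(df)), function(i)
    blankMeasurement(counts210Po = df$n_210po[i],
                     countsTracer = df$n_tracer[i],
                     tracerActivity = df$tracer_activity_bq[i],
                     liveTime = df$live_time_s[i],
                     bkgRate210Po = df$bkg_rate_210po_s[i],
                     bkgRateTracer = df$bkg_rate_tracer_s[i],
                     blankId = df$blank_id[i]))
}

.sniffDialect <- function(path) {
  first <- readLines(path, n = 5L, warn = FALSE)
  first <- first[nzchar(trimws(first))]
  if (length(first) && startsWith(trimws(first[1]), "$")) "spe"
  else "two_column"
}

#' Run the full analysis pipeline
#'
#' For every metadata row: read the sample's spectrum, integrate the tracer
#' and analyte ROIs, assemble a [MeasurementRecord-class], and evaluate it
#' against the K constant derived from the blank series. Emits one result
#' row per sample with C_lab, uncertainties, MDC, recovery, the below-MDC
#' flag, the K used and the configuration digest. Missing spectra,
#' inconsistent detector ids and unparseable rows raise errors naming the
#' sample. Reruns on identical inputs produce byte-identical output files.
#'
#' @param spectraDir Directory holding the spectrum files named in the
#'   metadata.
#' @param metadataFile Path to the sample metadata table
#'   ([readSampleMetadata()]).
#' @param blanksFile Path to the blank-series table ([readBlankTable()]).
#' @param config An [assayConfig()] list.
#' @param outFile Optional path for the tab-delimited results table.
#' @param logFile Optional path for a JSON log of every equation input.
#' @return The results `data.frame` (invisibly when `outFile` is given),
#'   with the [KConstant-class] attached as attribute `"K"`.
#' @export
runPipeline <- function(spectraDir, metadataFile, blanksFile,
                        config = assayConfig(), outFile = NULL,
                        logFile = NULL) {
  meta <- readSampleMetadata(metadataFile)
  blanks <- readBlankTable(blanksFile)
  K <- kAggregate(blanks, mode = config$kMode,
                  aggregate = config$kAggregate,
                  uKRelDefault = config$uKRelDefault)
  rois <- defaultROIs(lines = config$lines,
                      lowOffset = config$roiLowOffset,
                      highOffset = config$roiHighOffset)
  digest <- configDigest(config)
  rows <- vector("list", nrow(meta))
  log <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    id <- meta$sample_id[i]
    spPath <- file.path(spectraDir, meta$spectrum_file[i])
    if (!file.exists(spPath))
      stop(sprintf("sample '%s': spectrum file not found (%s)", id, spPath),
           call. = FALSE)
    sp <- tryCatch(readSpectrum(spPath, dialect = .sniffDialect(spPath)),
                   error = function(e)
                     stop(sprintf("sample '%s': %s", id, conditionMessage(e)),
                          call. = FALSE))
    if (!is.na(meta$detector_id[i]) && nzchar(detectorId(sp)) &&
        detectorId(sp) != meta$detector_id[i])
      stop(sprintf("sample '%s': spectrum detector '%s' does not match metadata detector '%s'",
                   id, detectorId(sp), meta$detector_id[i]), call. = FALSE)
    an <- integrateROI(sp, rois$analyte)
    tr <- integrateROI(sp, rois$tracer)
    rec <- measurementRecord(
      counts210Po = an@grossCounts, countsTracer = tr@grossCounts,
      liveTime = liveTime(sp),
      tracerActivity = meta$tracer_activity_bq[i],
      aliquotVolume = meta$v_aliquot_l[i],
      bkgRate210Po = meta$bkg_rate_210po_s[i],
      bkgRateTracer = meta$bkg_rate_tracer_s[i],
      efficiency = meta$efficiency[i], sampleId = id)
    res <- analyzeSample(rec, K, config)
    rows[[i]] <- data.frame(
      sample_id = id, worker_code = meta$worker_code[i],
      collection_date = meta$collection_date[i],
      c_lab_bq_l = res@concentration, u_rel = res@uRel,
      u_exp_bq_l = res@expanded, mdc_bq_l = res@mdc,
      recovery = res@recovery, below_mdc = res@belowMdc,
      k_bq = res@kValue, config_digest = digest,
      stringsAsFactors = FALSE)
    log[[i]] <- list(sample_id = id,
                     n_210po = an@grossCounts, n_tracer = tr@grossCounts,
                     live_time_s = liveTime(sp),
                     tracer_activity_bq = meta$tracer_activity_bq[i],
                     bkg_rate_210po_s = meta$bkg_rate_210po_s[i],
                     bkg_rate_tracer_s = meta$bkg_rate_tracer_s[i],
                     v_aliquot_l = meta$v_aliquot_l[i],
                     k_bq = K@K, u_k_rel = K@uKRel,
                     config_digest = digest)
  }
  results <- do.call(rbind, rows)
  attr(results, "K") <- K
  if (!is.null(logFile))
    jsonlite::write_json(log, logFile, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(outFile)) {
    writeResults(results, outFile)
    return(invisible(results))
  }
  results
}

#' Write / read the results table
#'
#' Tab-delimited text with full (`%.17g`) numeric precision so that the
#' write/read round trip reconstructs every value exactly.
#'
#' @param results Results `data.frame` from [runPipeline()].
#' @param path File path.
#' @return `writeResults()` returns `path` invisibly; `readResults()` the
#'   `data.frame`.
#' @export
writeResults <- function(results, path) {
  out <- results
  for (nm in names(out))
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]]))
      out[[nm]] <- ifelse(is.na(out[[nm]]), "NA",
                          sprintf("%.17g", out[[nm]]))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeResults
#' @export
readResults <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname writeResults
#' @param df A results `data.frame` as returned by [readResults()].
#' @return `resultsToActivity()` returns a list of
#'   [ActivityResult-class] objects rebuilt from the table.
#' @export
resultsToActivity <- function(df) {
  lapply(seq_len(nrow(df)), function(i)
    new("ActivityResult", sampleId = df$sample_id[i],
        concentration = df$c_lab_bq_l[i], uRel = df$u_rel[i],
        expanded = df$u_exp_bq_l[i], mdc = df$mdc_bq_l[i],
        recovery = df$recovery[i], belowMdc = df$below_mdc[i],
        kValue = df$k_bq[i], configDigest = df$config_digest[i]))
}

#' Write a simulated campaign as pipeline input files
#'
#' Fixture-generation mode: writes each simulated spectrum as an SPE file
#' plus the metadata and blank tables that [runPipeline()] consumes. The
#' campaign must have been simulated with `spectra = TRUE`.
#'
#' @param campaign Result of [simulateCampaign()] with spectra.
#' @param dir Output directory (created if needed).
#' @return Named list of the paths written (`spectraDir`, `metadataFile`,
#'   `blanksFile`).
#' @export
writeCampaign <- function(campaign, dir) {
  if (is.null(campaign$spectra))
    stop("campaign was simulated without spectra; rerun with spectra = TRUE",
         call. = FALSE)
  cfg <- campaign$config
  spectraDir <- file.path(dir, "spectra")
  dir.create(spectraDir, recursive = TRUE, showWarnings = FALSE)
  ids <- campaign$truth$sampleId
  for (i in seq_along(ids))
    writeSpectrum(campaign$spectra[[i]],
                  file.path(spectraDir, paste0(ids[i], ".spe")))
  meta <- data.frame(
    sample_id = ids, worker_code = "W001",
    collection_date = "2024-01-01",
    v_aliquot_l = cfg@aliquotVolume, v_24h_l = 3 * cfg@aliquotVolume,
    tracer_mass_g = cfg@tracerActivity / 0.4891,
    tracer_specific_activity_bq_g = 0.4891,
    detector_id = "SIM", live_time_s = cfg@liveTime,
    bkg_rate_210po_s = cfg@bkgRate210Po,
    bkg_rate_tracer_s = cfg@bkgRateTracer,
    efficiency = cfg@efficiency,
    spectrum_file = paste0(ids, ".spe"), stringsAsFactors = FALSE)
  metadataFile <- file.path(dir, "metadata.tsv")
  utils::write.table(meta, metadataFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  blanksFile <- file.path(dir, "blanks.tsv")
  bl <- do.call(rbind, lapply(campaign$blanks, function(b)
    data.frame(blank_id = b@blankId, n_210po = b@counts210Po,
               n_tracer = b@countsTracer,
               tracer_activity_bq = b@tracerActivity,
               live_time_s = b@liveTime,
               bkg_rate_210po_s = b@bkgRate210Po,
               bkg_rate_tracer_s = b@bkgRateTracer,
               stringsAsFactors = FALSE)))
  utils::write.table(bl, blanksFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(spectraDir = spectraDir, metadataFile = metadataFile,
       blanksFile = blanksFile)
}
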