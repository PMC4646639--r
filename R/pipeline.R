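# End-to-end pipeline: cohort manifest handling, per-sample processing
# (counting -> QC -> normalization -> ratios -> exon summaries -> calls),
# summary reports and plot-ready ratio tables.

#' Read and validate a cohort manifest
#'
#' Tab-separated, one row per sample: \code{sample_id}, \code{kind} (blood,
#' tumour, ascites, ntc or control), \code{paired_with} (sample_id of the
#' matched blood sample, or empty), \code{detection} and \code{confirmation}
#' (paths to per-library FASTQ(.gz) or counts TSV; confirmation may be
#' empty). Every referenced file must exist and every \code{paired_with}
#' must name a manifest row; a missing no-template control only warns.
#'
#' @param path manifest TSV path.
#' @param requireNtc warn when no NTC row is present (default TRUE).
#' @return Validated manifest data.frame.
#' @export
readManifest <- function(path, requireNtc = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "kind", "paired_with", "detection", "confirmation")
  miss <- setdiff(req, names(m))
  if (length(miss))
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  kinds <- c("blood", "tumour", "ascites", "ntc", "control")
  bad <- !m$kind %in% kinds
  if (any(bad))
    stop("invalid kind in manifest row(s) ",
         paste(which(bad), collapse = ", "), ": ",
         paste(unique(m$kind[bad]), collapse = ", "))
  for (i in seq_len(nrow(m))) {
    for (col in c("detection", "confirmation")) {
      f <- m[[col]][i]
      if (!is.na(f) && nzchar(f) && !file.exists(f))
        stop("manifest row ", i, " (", m$sample_id[i], "): ", col,
             " file not found: ", f)
    }
    pw <- m$paired_with[i]
    if (!is.na(pw) && nzchar(pw) && !pw %in% m$sample_id)
      stop("manifest row ", i, ": paired_with sample '", pw,
           "' not in manifest")
  }
  if (requireNtc && !any(m$kind == "ntc"))
    warning("no NTC row in manifest; contamination check will be skipped")
  m
}

isFastqPath <- function(path) {
  grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE)
}

# load one reaction library from disk (FASTQ or precomputed counts)
loadLibrary <- function(path, design, mix, sampleId,
                        isControl = FALSE, isNTC = FALSE, ...) {
  if (isFastqPath(path))
    countProbes(path, design, mix, sampleId = sampleId,
                isControl = isControl, isNTC = isNTC, ...)
  else
    readCountsTable(path, sampleId = sampleId, mix = mix,
                    isControl = isControl, isNTC = isNTC)
}

#' Process one sample against prebuilt baselines
#'
#' Runs QC, depth normalization, baseline ratios, exon aggregation and
#' classification for a sample's detection (and optional confirmation)
#' library.
#'
#' @param det,conf [LibraryCounts-class] for the two reaction libraries
#'   (\code{conf} may be NULL; exon pooling then uses detection only).
#' @param baselines named list of [Baseline-class] objects
#'   (\code{$detection}, \code{$confirmation}).
#' @param design the [ProbeDesign-class].
#' @param sampleKind "blood" or "tumour" (classification rules differ for
#'   gains).
#' @param cfg a [classificationConfig()].
#' @param ntc optional NTC [LibraryCounts-class] for the contamination check.
#' @param medianRequirement,coverageFloor QC thresholds (see [qcLibrary()]).
#' @return A list of class \code{SampleReport}: sample metadata, per-library
#'   QC, the per-exon table (with category column) and merged region calls.
#' @export
processSample <- function(det, conf = NULL, baselines, design,
                          sampleKind = "blood",
                          cfg = classificationConfig(), ntc = NULL,
                          medianRequirement = 1000L, coverageFloor = 500L) {
  qcDet <- qcLibrary(det, ntc, medianRequirement, coverageFloor)
  qcConf <- if (!is.null(conf))
    qcLibrary(conf, ntc, medianRequirement, coverageFloor) else NULL
  rDet <- computeRatios(depthNormalize(det, design),
                        baselines$detection, design)
  rConf <- if (!is.null(conf))
    computeRatios(depthNormalize(conf, design),
                  baselines$confirmation, design) else NULL
  exons <- summarizeExons(rDet, rConf, design)
  exons$category <- classifyExon(exons$mean_ratio, cfg, sampleKind,
                                 sdRatio = exons$sd_ratio)
  calls <- mergeContiguous(exons, design)
  libs <- Filter(Negate(is.null), list(detection = det, confirmation = conf))
  structure(list(
    sample_id = sampleId(det), sample_kind = sampleKind,
    qc = Filter(Negate(is.null), list(detection = qcDet,
                                      confirmation = qcConf)),
    reads = lapply(libs, function(l)
      list(total = l@totalReads, on_target = l@onTargetReads,
           ambiguous = l@ambiguousReads)),
    ntc_mean_coverage = qcDet$ntc_mean_coverage,
    exons = exons, calls = calls,
    excluded = rbind(rDet@excluded,
                     if (!is.null(rConf)) rConf@excluded)
  ), class = "SampleReport")
}

#' Run the full pipeline over a cohort manifest
#'
#' Loads every library (counting FASTQ or reading count tables), builds the
#' detection and confirmation baselines from the manifest's control samples
#' (unless prebuilt baselines are supplied), then processes every
#' case/control sample: QC, normalization, ratios, exon summaries, calls and
#' — where \code{paired_with} names a blood sample — germline/somatic origin
#' assignment. Failures are isolated per sample: one bad sample is reported
#' as an error entry, the rest of the cohort completes.
#'
#' @param manifest manifest data.frame (see [readManifest()]) or a path.
#' @param design a [ProbeDesign-class].
#' @param baselines optional prebuilt named list (\code{$detection},
#'   \code{$confirmation}); default builds them from control rows.
#' @param cfg a [classificationConfig()].
#' @param minControls,cvCap baseline construction settings (see
#'   [buildBaseline()]).
#' @param medianRequirement,coverageFloor QC thresholds.
#' @param matchMode key-matching mode for FASTQ inputs.
#' @return A list with \code{reports} (named list of \code{SampleReport} or
#'   error entries), \code{baselines}, \code{calls} (combined calls
#'   data.frame across samples) and \code{log} (character vector of stage
#'   messages).
#' @export
runPipeline <- function(manifest, design, baselines = NULL,
                        cfg = classificationConfig(),
                        minControls = 3L, cvCap = 0.30,
                        medianRequirement = 1000L, coverageFloor = 500L,
                        matchMode = "exact") {
  if (is.character(manifest)) manifest <- readManifest(manifest)
  log <- character()
  note <- function(...) log <<- c(log, paste0(...))
  loadRow <- function(row) {
    libs <- list()
    for (mix in c("detection", "confirmation")) {
      f <- row[[mix]]
      if (!is.na(f) && nzchar(f))
        libs[[mix]] <- loadLibrary(f, design, mix, row$sample_id,
                                   isControl = row$kind == "control",
                                   isNTC = row$kind == "ntc",
                                   matchMode = matchMode)
    }
    libs
  }
  ntcRow <- manifest[manifest$kind == "ntc", , drop = FALSE]
  ntc <- if (nrow(ntcRow)) loadRow(ntcRow[1, ])$detection else NULL
  if (is.null(ntc)) note("no NTC library; contamination check skipped")
  ctrlRows <- manifest[manifest$kind == "control", , drop = FALSE]
  ctrlLibs <- lapply(seq_len(nrow(ctrlRows)),
                     function(i) loadRow(ctrlRows[i, ]))
  if (is.null(baselines)) {
    baselines <- list()
    for (mix in c("detection", "confirmation")) {
      dns <- lapply(Filter(function(l) !is.null(l[[mix]]), ctrlLibs),
                    function(l) depthNormalize(l[[mix]], design))
      baselines[[mix]] <- buildBaseline(dns, design, minControls, cvCap)
      note("built ", mix, " baseline from ", length(dns), " controls")
    }
  } else if (baselines$detection@designChecksum != designChecksum(design)) {
    stop("supplied baseline was built against a different design ",
         "(checksum mismatch)")
  }
  sampleRows <- manifest[manifest$kind != "ntc", , drop = FALSE]
  reports <- list()
  for (i in seq_len(nrow(sampleRows))) {
    row <- sampleRows[i, ]
    kind <- if (row$kind %in% c("tumour", "ascites")) "tumour" else "blood"
    reports[[row$sample_id]] <- tryCatch({
      libs <- loadRow(row)
      processSample(libs$detection, libs$confirmation, baselines, design,
                    sampleKind = kind, cfg = cfg, ntc = ntc,
                    medianRequirement = medianRequirement,
                    coverageFloor = coverageFloor)
    }, error = function(e) {
      note("sample ", row$sample_id, " failed: ", conditionMessage(e))
      structure(list(sample_id = row$sample_id, error = conditionMessage(e)),
                class = "SampleReport")
    })
  }
  # origin assignment for tumour samples with a paired blood sample
  for (i in seq_len(nrow(sampleRows))) {
    row <- sampleRows[i, ]
    rep <- reports[[row$sample_id]]
    if (!is.null(rep$error) || is.null(rep$exons)) next
    if (rep$sample_kind != "tumour") next
    pw <- row$paired_with
    blood <- if (!is.na(pw) && nzchar(pw)) reports[[pw]] else NULL
    bloodExons <- if (!is.null(blood) && is.null(blood$error))
      blood$exons else NULL
    reports[[row$sample_id]]$exons <-
      assignOrigin(rep$exons, bloodExons)
  }
  callRows <- lapply(reports, function(r)
    if (is.null(r$error) && nrow(r$calls))
      cbind(sample_id = r$sample_id, r$calls) else NULL)
  calls <- do.call(rbind, Filter(Negate(is.null), callRows))
  list(reports = reports, baselines = baselines, calls = calls, log = log)
}

#' Write a per-sample summary report (text + JSON)
#'
#' Serialises the fields of a \code{SampleReport}: per-library mean probe
#' coverage, total aligned on-target reads, NTC mean coverage, the per-exon
#' mean ratio and SD table (sorted by gene then panel exon order), calls and
#' QC verdicts. Writes \code{<path>.txt} and \code{<path>.json}.
#'
#' @param report a \code{SampleReport} from [processSample()].
#' @param path output path prefix.
#' @return Invisibly, the two paths written.
#' @export
writeSummaryReport <- function(report, path) {
  txt <- paste0(path, ".txt"); js <- paste0(path, ".json")
  con <- file(txt, "w"); on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("Sample summary report")
  w("sample_id\t", report$sample_id)
  w("sample_kind\t", report$sample_kind)
  for (mix in names(report$qc)) {
    q <- report$qc[[mix]]
    w(mix, "_mean_probe_coverage\t", format(q$mean_probe_coverage))
    w(mix, "_median_probe_coverage\t", format(q$median_probe_coverage))
    w(mix, "_qc_pass\t", q$pass)
    w(mix, "_on_target_reads\t", report$reads[[mix]]$on_target)
    w(mix, "_total_reads\t", report$reads[[mix]]$total)
  }
  w("ntc_mean_coverage\t",
    if (is.na(report$ntc_mean_coverage)) "NA"
    else format(report$ntc_mean_coverage))
  w("")
  w("gene\texon_label\tmean_ratio\tsd_ratio\tn_probes\tcategory")
  ex <- report$exons
  for (i in seq_len(nrow(ex)))
    w(ex$gene[i], "\t", ex$exon_label[i], "\t",
      formatC(ex$mean_ratio[i], digits = 4, format = "f"), "\t",
      formatC(ex$sd_ratio[i], digits = 4, format = "f"), "\t",
      ex$n_probes[i], "\t", ex$category[i])
  w("")
  if (nrow(report$calls)) {
    w("calls:")
    for (i in seq_len(nrow(report$calls)))
      w("  ", report$calls$gene[i], " ", report$calls$exons[i], " ",
        report$calls$category[i], " ratio=",
        formatC(report$calls$mean_ratio[i], digits = 3, format = "f"),
        " copies=",
        formatC(report$calls$copies[i], digits = 2, format = "f"))
  } else w("calls: none")
  jsonlite::write_json(
    list(sample_id = report$sample_id,
         sample_kind = report$sample_kind,
         reads = report$reads,
         qc = lapply(report$qc, function(q)
           q[c("mean_probe_coverage", "median_probe_coverage",
               "n_probes_below_floor", "ntc_mean_coverage", "pass")]),
         exons = report$exons, calls = report$calls),
    js, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(txt, js))
}

#' Plot-ready exon ratio series with normal-band annotations
#'
#' One row per design exon in panel order: mean ratio, SD and the normal
#' band's lower (0.7) and upper (1.3) limits, ready for a per-exon dosage
#' plot.
#'
#' @param report a \code{SampleReport} from [processSample()].
#' @param cfg a [classificationConfig()] supplying the band limits.
#' @return data.frame with columns exon_index, gene, exon_label, mean_ratio,
#'   sd_ratio, band_lower, band_upper.
#' @export
exportRatioPlotData <- function(report, cfg = classificationConfig()) {
  ex <- report$exons
  data.frame(exon_index = seq_len(nrow(ex)), gene = ex$gene,
             exon_label = ex$exon_label, mean_ratio = ex$mean_ratio,
             sd_ratio = ex$sd_ratio,
             band_lower = cfg$normalBand[1], band_upper = cfg$normalBand[2],
             stringsAsFactors = FALSE)
}
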