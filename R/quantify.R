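# Quantification: within-library depth normalization, control-baseline
# copy-number ratios, exon-level aggregation.
#
# Per library i, probe k: x'_ik = x_ik / X_i with X_i the arithmetic mean of
# raw counts over probes of non-amplification genes; the copy-number ratio is
# x''_ik = x'_ik / mean over accumulated control samples of x'_ik, so 1.0
# corresponds to two copies. Exon summaries pool detection and confirmation
# probes (and within-library replicate probes) per exon.

#' Depth-normalise one library against its non-amplification probes
#'
#' Divides every probe's raw count by the library normalizer X, the
#' arithmetic mean of raw counts over probes whose gene is not under
#' amplification surveillance. Excluding amplification-gene probes from X
#' keeps a genuine high-level amplification from deflating every other
#' probe's value. All probes — including amplification-gene probes — are
#' divided by the same X.
#'
#' @param lib a [LibraryCounts-class].
#' @param design the matching [ProbeDesign-class].
#' @return A [DepthNormalized-class]; the mean of its values over
#'   non-amplification probes is 1 by construction.
#' @export
depthNormalize <- function(lib, design) {
  p <- probesForMix(design, mixName(lib))
  extra <- setdiff(names(probeCounts(lib)), p$probe_id)
  if (length(extra))
    stop("counts contain probe ids not in the ", mixName(lib), " mix: ",
         paste(extra, collapse = ", "))
  x <- setNames(numeric(nrow(p)), p$probe_id)
  x[names(probeCounts(lib))] <- probeCounts(lib)
  nonAmp <- !(p$gene %in% design@amplificationGenes)
  X <- mean(x[p$probe_id[nonAmp]])
  if (!is.finite(X) || X <= 0)
    stop("library ", sampleId(lib), " is unusable: normalizer X is 0")
  new("DepthNormalized", sampleId = sampleId(lib), mix = mixName(lib),
      values = x / X, normalizer = X)
}

#' Build the control baseline for one mix
#'
#' Accumulates per-probe means of depth-normalised values across copy-neutral
#' control samples — the denominator of the copy-number ratio. The per-probe
#' coefficient of variation across controls is recorded; probes with CV above
#' \code{cvCap} (noisy in the very samples that define "normal") or with a
#' zero mean are marked unusable.
#'
#' @param controls list of [DepthNormalized-class] objects, one mix.
#' @param design the matching [ProbeDesign-class].
#' @param minControls minimum number of controls (default 3).
#' @param cvCap maximum tolerated CV across controls (default 0.30).
#' @return A [Baseline-class] carrying the design checksum.
#' @export
buildBaseline <- function(controls, design, minControls = 3L, cvCap = 0.30) {
  if (length(controls) < minControls)
    stop("need at least ", minControls, " control samples, got ",
         length(controls))
  mixes <- unique(vapply(controls, mixName, character(1)))
  if (length(mixes) != 1L)
    stop("controls mix reaction mixes: ", paste(mixes, collapse = ", "))
  ids <- names(normValues(controls[[1]]))
  mat <- matrix(unlist(lapply(controls, function(dn) {
    v <- normValues(dn)
    if (!identical(names(v), ids))
      stop("controls cover different probe sets")
    v
  })), nrow = length(ids), dimnames = list(ids, NULL))
  m <- rowMeans(mat)
  s <- apply(mat, 1L, sd)
  cv <- ifelse(m > 0, s / m, Inf)
  new("Baseline", mix = mixes, perProbeMean = m, perProbeCV = cv,
      nControls = length(controls),
      usable = m > 0 & cv <= cvCap,
      designChecksum = designChecksum(design))
}

#' Copy-number ratios for one sample library
#'
#' Divides each depth-normalised probe value by that probe's mean across the
#' accumulated controls. Probes with an unusable baseline are excluded with a
#' reason rather than silently dropped.
#'
#' @param sample a [DepthNormalized-class].
#' @param baseline a [Baseline-class] built from the same design and mix.
#' @param design the matching [ProbeDesign-class]; checksum must agree with
#'   the baseline's.
#' @return A [RatioMatrix-class].
#' @export
computeRatios <- function(sample, baseline, design) {
  if (baseline@designChecksum != designChecksum(design))
    stop("baseline was built against a different probe design ",
         "(checksum mismatch)")
  if (baseline@mix != mixName(sample))
    stop("baseline mix (", baseline@mix, ") does not match sample mix (",
         mixName(sample), ")")
  v <- normValues(sample)
  common <- intersect(names(v), names(baselineMeans(baseline)))
  noBase <- setdiff(names(v), common)
  usable <- common[baseline@usable[common]]
  unusable <- setdiff(common, usable)
  excluded <- data.frame(
    probe_id = c(noBase, unusable),
    reason = c(rep("no_baseline", length(noBase)),
               rep("unusable_baseline", length(unusable))),
    stringsAsFactors = FALSE)
  if (nrow(excluded))
    warning(nrow(excluded), " probe(s) excluded from ratios for ",
            sampleId(sample), " [", mixName(sample), "]")
  ratios <- v[usable] / baselineMeans(baseline)[usable]
  new("RatioMatrix", sampleId = sampleId(sample), mix = mixName(sample),
      ratios = ratios, excluded = excluded)
}

#' Pool probe ratios into exon-level summaries
#'
#' Per exon label, pools every usable probe ratio from the detection library,
#' the confirmation library (when present) and within-library replicate
#' probes, and reports their mean and sample standard deviation (n - 1
#' denominator; 0 when a single probe). Every design exon appears exactly
#' once; exons with no usable probe are emitted with \code{missing = TRUE},
#' never dropped.
#'
#' @param det a [RatioMatrix-class] from the detection library.
#' @param conf optional [RatioMatrix-class] from the confirmation library of
#'   the same sample.
#' @param design the matching [ProbeDesign-class].
#' @return data.frame with columns sample_id, gene, exon_label, mean_ratio,
#'   sd_ratio, n_probes, missing — in design (panel) exon order.
#' @export
summarizeExons <- function(det, conf = NULL, design) {
  mats <- list(det)
  if (!is.null(conf)) {
    if (sampleId(conf) != sampleId(det))
      stop("detection and confirmation ratios are from different samples")
    mats <- c(mats, list(conf))
  }
  p <- probes(design)
  exonOf <- setNames(p$exon_label, p$probe_id)
  pooled <- list()
  for (rm in mats) {
    r <- cnvRatios(rm)
    for (i in seq_along(r)) {
      ex <- exonOf[[names(r)[i]]]
      pooled[[ex]] <- c(pooled[[ex]], r[[i]])
    }
  }
  et <- exonTable(design)
  n <- vapply(et$exon_label, function(ex) length(pooled[[ex]]), integer(1))
  mean_ratio <- vapply(et$exon_label, function(ex)
    if (length(pooled[[ex]])) mean(pooled[[ex]]) else NA_real_, numeric(1))
  sd_ratio <- vapply(et$exon_label, function(ex) {
    v <- pooled[[ex]]
    if (length(v) >= 2L) sd(v) else if (length(v) == 1L) 0 else NA_real_
  }, numeric(1))
  data.frame(sample_id = sampleId(det), gene = et$gene,
             exon_label = et$exon_label, mean_ratio = mean_ratio,
             sd_ratio = sd_ratio, n_probes = n, missing = n == 0L,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Persist / reload a control baseline
#'
#' TSV with columns probe_id, mean, cv, usable plus comment lines recording
#' the mix, the number of controls and the design checksum; reloading against
#' a different design refuses with a checksum error.
#'
#' @param baseline a [Baseline-class].
#' @param path file path.
#' @return \code{writeBaseline} returns the path invisibly;
#'   \code{readBaseline} the reloaded [Baseline-class].
#' @export
writeBaseline <- function(baseline, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# mix=", baseline@mix),
               paste0("# n_controls=", baseline@nControls),
               paste0("# design_checksum=", baseline@designChecksum)), con)
  df <- data.frame(probe_id = names(baselineMeans(baseline)),
                   mean = unname(baselineMeans(baseline)),
                   cv = unname(baseline@perProbeCV),
                   usable = unname(baseline@usable))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBaseline
#' @param design the [ProbeDesign-class] the baseline must match.
#' @export
readBaseline <- function(path, design) {
  if (!file.exists(path)) stop("baseline file not found: ", path)
  hdr <- readLines(path, n = 3L)
  meta <- sub("^# [a-z_]+=", "", hdr)
  names(meta) <- sub("^# ([a-z_]+)=.*$", "\\1", hdr)
  if (meta[["design_checksum"]] != designChecksum(design))
    stop("baseline file was built against a different probe design ",
         "(checksum mismatch)")
  df <- read.delim(path, skip = 3L, stringsAsFactors = FALSE)
  new("Baseline", mix = meta[["mix"]],
      perProbeMean = setNames(df$mean, df$probe_id),
      perProbeCV = setNames(df$cv, df$probe_id),
      nControls = as.integer(meta[["n_controls"]]),
      usable = setNames(df$usable, df$probe_id),
      designChecksum = meta[["design_checksum"]])
}
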