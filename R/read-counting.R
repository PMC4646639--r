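# Read counting: assign FASTQ reads to probes by exact (or one-mismatch)
# search for the 20-base ligation-junction keys, with adapter trimming and
# library-level QC.

#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   PDict vwhichPDict reverseComplement vmatchPattern BStringSet
NULL

#' Construct a LibraryCounts object from known per-probe counts
#'
#' Convenience constructor for count tables that did not come from FASTQ
#' (precomputed counts, simulations, tests). Bookkeeping defaults assume all
#' reads were uniquely on target.
#'
#' @param sampleId sample identifier.
#' @param mix "detection" or "confirmation".
#' @param counts named numeric/integer vector, probe_id -> read count.
#' @param totalReads,onTargetReads,ambiguousReads read bookkeeping; defaults
#'   treat every counted read as the only reads seen.
#' @param isControl,isNTC sample flags.
#' @return A [LibraryCounts-class] object.
#' @export
libraryCounts <- function(sampleId, mix, counts,
                          totalReads = sum(counts) + ambiguousReads,
                          onTargetReads = sum(counts) + ambiguousReads,
                          ambiguousReads = 0L,
                          isControl = FALSE, isNTC = FALSE) {
  new("LibraryCounts", sampleId = as.character(sampleId), mix = mix,
      counts = setNames(as.integer(round(counts)), names(counts)),
      totalReads = as.integer(totalReads),
      onTargetReads = as.integer(onTargetReads),
      ambiguousReads = as.integer(ambiguousReads),
      isControl = isControl, isNTC = isNTC)
}

readFastqSeqs <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  if (file.size(path) == 0L) return(DNAStringSet())
  out <- tryCatch(readDNAStringSet(path, format = "fastq"),
                  error = function(e)
                    stop("unreadable FASTQ record in ", path, ": ",
                         conditionMessage(e)))
  out
}

#' Trim the downstream sequencing adapter off reads
#'
#' Removes everything from the leftmost occurrence of the adapter's first
#' \code{minOverlap} bases onward; reads without such an occurrence are
#' returned unchanged. With ~60 bp ligated probe inserts and 150-cycle reads,
#' essentially every read runs into the downstream adapter.
#'
#' @param reads character vector or [Biostrings::DNAStringSet] of read
#'   sequences.
#' @param adapter downstream adapter sequence (default the read-1 downstream
#'   adapter of [nexteraAdapters()]).
#' @param minOverlap minimum adapter prefix length that must match
#'   (default 10).
#' @return Object of the same class as \code{reads}, adapter-trimmed.
#' @export
#' @examples
#' extractInsert(paste0("ACGTACGTACGT", nexteraAdapters()[["downstream"]]))
extractInsert <- function(reads, adapter = nexteraAdapters()[["downstream"]],
                          minOverlap = 10L) {
  chr <- is.character(reads)
  dss <- if (chr) DNAStringSet(reads) else reads
  if (!length(dss)) return(reads)
  probe <- substr(adapter, 1L, minOverlap)
  hits <- vmatchPattern(probe, dss)
  starts <- vapply(Biostrings::startIndex(hits), function(s)
    if (is.null(s) || !length(s)) NA_integer_ else min(s), integer(1))
  ends <- ifelse(is.na(starts), Biostrings::width(dss), starts - 1L)
  out <- Biostrings::subseq(dss, start = 1L, end = ends)
  if (chr) as.character(out) else out
}

# per-read sets of matched key indices (forward + reverse complement),
# optionally tolerating one mismatch via two complementary trusted bands
matchKeySets <- function(reads, keys, matchMode = c("exact", "one_mismatch")) {
  matchMode <- match.arg(matchMode)
  keySet <- DNAStringSet(keys)
  dicts <- list(list(pd = PDict(keySet), mm = 0L),
                list(pd = PDict(reverseComplement(keySet)), mm = 0L))
  if (matchMode == "one_mismatch") {
    w <- unique(nchar(keys)); half <- w %/% 2L
    for (ks in list(keySet, reverseComplement(keySet))) {
      dicts <- c(dicts,
                 list(list(pd = PDict(ks, tb.start = 1L, tb.end = half), mm = 1L),
                      list(pd = PDict(ks, tb.start = half + 1L, tb.end = w), mm = 1L)))
    }
  }
  sets <- vector("list", length(reads))
  for (d in dicts) {
    hits <- vwhichPDict(d$pd, reads, max.mismatch = d$mm)
    sets <- mapply(function(a, b) if (length(b)) unique(c(a, b)) else a,
                   sets, hits, SIMPLIFY = FALSE)
  }
  sets
}

#' Count probe-identifying keys in FASTQ reads for one reaction library
#'
#' For every read (read 1 of the pair; the ~60 bp insert is fully contained
#' in either mate), the downstream adapter is trimmed and the read is scanned
#' for the middle keys of the requested mix, forward and reverse complement.
#' A read matching exactly one probe key increments that probe's count; reads
#' matching two or more distinct keys are chimera-like and are discarded as
#' ambiguous (counted, not assigned); reads matching none are off target.
#'
#' @param fastq character vector of FASTQ(.gz) paths, concatenated.
#' @param design a [ProbeDesign-class].
#' @param mix "detection" or "confirmation".
#' @param matchMode "exact" (default, mirroring fixed-key genotyping) or
#'   "one_mismatch".
#' @param sampleId sample identifier recorded on the result.
#' @param adapters adapter set as from [nexteraAdapters()].
#' @param minOverlap minimum adapter overlap for trimming.
#' @param isControl,isNTC sample flags.
#' @return A [LibraryCounts-class] with one count per design probe of the mix.
#' @export
countProbes <- function(fastq, design, mix,
                        matchMode = c("exact", "one_mismatch"),
                        sampleId = "sample", adapters = nexteraAdapters(),
                        minOverlap = 10L, isControl = FALSE, isNTC = FALSE) {
  matchMode <- match.arg(matchMode)
  p <- probesForMix(design, mix)
  keys <- setNames(p$middle_key, p$probe_id)
  if (anyDuplicated(keys))
    stop("middle-key collision within the ", mix, " mix")
  counts <- setNames(integer(length(keys)), names(keys))
  total <- 0L; ambiguous <- 0L
  for (path in fastq) {
    reads <- readFastqSeqs(path)
    total <- total + length(reads)
    if (!length(reads)) next
    reads <- extractInsert(reads, adapters[["downstream"]], minOverlap)
    sets <- matchKeySets(reads, keys, matchMode)
    nHit <- lengths(sets)
    ambiguous <- ambiguous + sum(nHit >= 2L)
    uniq <- unlist(sets[nHit == 1L], use.names = FALSE)
    if (length(uniq)) {
      tab <- tabulate(uniq, nbins = length(keys))
      counts <- counts + tab
    }
  }
  libraryCounts(sampleId, mix, counts,
                totalReads = total,
                onTargetReads = sum(counts) + ambiguous,
                ambiguousReads = ambiguous,
                isControl = isControl, isNTC = isNTC)
}

#' Library-level quality control
#'
#' A library passes QC when its median per-probe raw coverage meets the
#' run-design requirement (default 1000-fold) and, when a no-template control
#' is supplied, the NTC's mean probe coverage stays below a small fraction of
#' the library's own mean (contamination guard, default 1 percent). Probes
#' below the raw-coverage floor (default 500-fold, the minimum for optimal
#' ratio precision) are counted and flagged; in control samples these flags
#' feed into baseline usability.
#'
#' @param lib a [LibraryCounts-class].
#' @param ntc optional [LibraryCounts-class] for the no-template control.
#' @param medianRequirement required median probe coverage (default 1000).
#' @param coverageFloor per-probe raw-coverage floor (default 500).
#' @param ntcFraction maximum NTC mean coverage as a fraction of the sample
#'   mean (default 0.01).
#' @return A list of class \code{QCMetrics}: \code{median_probe_coverage},
#'   \code{mean_probe_coverage}, \code{n_probes_below_floor},
#'   \code{below_floor} (named logical), \code{coverage_floor},
#'   \code{median_coverage_requirement}, \code{ntc_mean_coverage} (NA when no
#'   NTC), \code{ntc_ok} and \code{pass}.
#' @export
qcLibrary <- function(lib, ntc = NULL, medianRequirement = 1000L,
                      coverageFloor = 500L, ntcFraction = 0.01) {
  x <- probeCounts(lib)
  med <- median(as.numeric(x))
  below <- x < coverageFloor
  ntcMean <- NA_real_
  ntcOk <- TRUE
  if (!is.null(ntc)) {
    ntcMean <- mean(as.numeric(probeCounts(ntc)))
    ntcOk <- ntcMean < ntcFraction * mean(as.numeric(x))
  }
  structure(list(
    sample_id = sampleId(lib), mix = mixName(lib),
    median_probe_coverage = med,
    mean_probe_coverage = mean(as.numeric(x)),
    n_probes_below_floor = sum(below),
    below_floor = below,
    coverage_floor = coverageFloor,
    median_coverage_requirement = medianRequirement,
    ntc_mean_coverage = ntcMean,
    ntc_ok = ntcOk,
    pass = (med >= medianRequirement) && ntcOk
  ), class = "QCMetrics")
}

#' @export
print.QCMetrics <- function(x, ...) {
  cat("QC [", x$sample_id, "/", x$mix, "]: ",
      if (x$pass) "PASS" else "FAIL", "\n", sep = "")
  cat("  median probe coverage:", format(x$median_probe_coverage),
      "(required", paste0(x$median_coverage_requirement, ")"), "\n")
  cat("  probes below ", x$coverage_floor, "x floor: ",
      x$n_probes_below_floor, "\n", sep = "")
  if (!is.na(x$ntc_mean_coverage))
    cat("  NTC mean coverage:", format(x$ntc_mean_coverage),
        if (x$ntc_ok) "(ok)" else "(contamination?)", "\n")
  invisible(x)
}

#' Write / read a per-probe count table
#'
#' Two-column TSV (probe_id, count) with a header, the on-disk form of a
#' library's raw counts.
#'
#' @param lib a [LibraryCounts-class].
#' @param path file path.
#' @return \code{writeCountsTable} returns the path invisibly;
#'   \code{readCountsTable} returns a [LibraryCounts-class].
#' @export
writeCountsTable <- function(lib, path) {
  df <- data.frame(probe_id = names(probeCounts(lib)),
                   count = as.integer(probeCounts(lib)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCountsTable
#' @param sampleId,mix,isControl,isNTC metadata for the reloaded library.
#' @export
readCountsTable <- function(path, sampleId = "sample", mix = "detection",
                            isControl = FALSE, isNTC = FALSE) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "count") %in% names(df)))
    stop("counts file must have columns probe_id and count: ", path)
  libraryCounts(sampleId, mix, setNames(df$count, df$probe_id),
                isControl = isControl, isNTC = isNTC)
}
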