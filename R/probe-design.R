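# Probe-design handling: load/write/validate panels, derive the 20-base
# ligation-junction keys used by the counting stage, emit suspects files.

#' Default sequencing-adapter overhangs on the probe oligos
#'
#' MLPA probe oligos carry transposase-adapter overhangs so that indexed
#' sequencing adapters can be added during the amplification PCR. The left
#' probe oligo is stored as (read-1 adapter + hybridising arm) and the right
#' oligo as (hybridising arm + reverse-complemented read-2 adapter); read 1
#' therefore runs left arm, ligation junction, right arm and then into the
#' downstream adapter.
#'
#' @return Named character vector with elements \code{left} (adapter prefix on
#'   the left oligo), \code{right} (adapter suffix on the right oligo) and
#'   \code{downstream} (the adapter sequence as seen at the 3' end of read 1;
#'   equal to \code{right}).
#' @export
#' @examples
#' nexteraAdapters()["downstream"]
nexteraAdapters <- function() {
  c(left = "TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG",
    right = "CTGTCTCTTATACACATCTCCGAGCCCACGAGAC",
    downstream = "CTGTCTCTTATACACATCTCCGAGCCCACGAGAC")
}

stripLeftAdapter <- function(seqs, adapter) {
  has <- startsWith(seqs, adapter)
  seqs[has] <- substring(seqs[has], nchar(adapter) + 1L)
  seqs
}

stripRightAdapter <- function(seqs, adapter) {
  has <- endsWith(seqs, adapter)
  seqs[has] <- substring(seqs[has], 1L, nchar(seqs[has]) - nchar(adapter))
  seqs
}

#' Derive the middle key spanning a probe pair's ligation junction
#'
#' The key is the k-base window centred on the ligation junction: the last
#' k/2 bases of the (adapter-stripped) left hybridising arm followed by the
#' first k/2 bases of the right arm. Because it spans the junction, the key
#' occurs only in correctly ligated (and amplified) probe pairs, making it a
#' specific identifier for read counting.
#'
#' @param leftArm,rightArm character vectors of adapter-free hybridising arm
#'   sequences (recycled to common length).
#' @param k even integer, key length (default 20).
#' @return Character vector of k-base keys.
#' @export
#' @examples
#' deriveMiddleKey("AAAAACGTACGTAC", "GTCAGTCAGTAAAA", k = 20)
deriveMiddleKey <- function(leftArm, rightArm, k = 20L) {
  k <- as.integer(k)
  if (k < 2L || k %% 2L != 0L)
    stop("key length k must be a positive even integer")
  n <- max(length(leftArm), length(rightArm))
  leftArm <- rep_len(leftArm, n); rightArm <- rep_len(rightArm, n)
  half <- k %/% 2L
  short <- nchar(leftArm) < half | nchar(rightArm) < half
  if (any(short))
    stop("hybridising arms too short for a ", k, "-base key at position(s): ",
         paste(which(short), collapse = ", "))
  paste0(substring(leftArm, nchar(leftArm) - half + 1L, nchar(leftArm)),
         substring(rightArm, 1L, half))
}

# adapter-free hybridising arms for a probe table (empty string if no seqs)
probeArms <- function(p, adapters = nexteraAdapters()) {
  left <- if ("left_seq" %in% names(p)) p$left_seq else rep("", nrow(p))
  right <- if ("right_seq" %in% names(p)) p$right_seq else rep("", nrow(p))
  left[is.na(left)] <- ""; right[is.na(right)] <- ""
  list(left = stripLeftAdapter(left, adapters[["left"]]),
       right = stripRightAdapter(right, adapters[["right"]]))
}

#' Construct a validated ProbeDesign from a probe table
#'
#' Derives middle keys from the oligo sequences where absent, derives the
#' amplification- and reference-gene sets from the probe roles, and runs all
#' design invariants (unique probe ids, 20-base DNA keys unique within each
#' mix, one role group per gene, key consistency with the arms).
#'
#' @param probeTable data.frame with columns probe_id, gene, exon_label, mix,
#'   role and either middle_key or left_seq/right_seq (with adapter
#'   overhangs); optional chrom, start, end (1-based inclusive, annotation
#'   only).
#' @param adapters adapter set as from [nexteraAdapters()].
#' @return A [ProbeDesign-class] object.
#' @export
probeDesign <- function(probeTable, adapters = nexteraAdapters()) {
  p <- as.data.frame(probeTable, stringsAsFactors = FALSE)
  req <- c("probe_id", "gene", "exon_label", "mix", "role")
  miss <- setdiff(req, names(p))
  if (length(miss))
    stop("probe table is missing required column(s): ",
         paste(miss, collapse = ", "))
  arms <- probeArms(p, adapters)
  haveArms <- nchar(arms$left) > 0L & nchar(arms$right) > 0L
  if (!"middle_key" %in% names(p)) p$middle_key <- NA_character_
  needKey <- is.na(p$middle_key) | !nzchar(p$middle_key)
  if (any(needKey & !haveArms))
    stop("probes without middle_key and without oligo sequences: ",
         paste(p$probe_id[needKey & !haveArms], collapse = ", "))
  if (any(needKey))
    p$middle_key[needKey] <- deriveMiddleKey(arms$left[needKey],
                                             arms$right[needKey])
  # when both key and arms are given they must agree
  chk <- !needKey & haveArms
  if (any(chk)) {
    expected <- deriveMiddleKey(arms$left[chk], arms$right[chk])
    bad <- p$probe_id[chk][expected != p$middle_key[chk]]
    if (length(bad))
      stop("middle_key inconsistent with oligo arms for probe(s): ",
           paste(bad, collapse = ", "))
  }
  ampGenes <- sort(unique(p$gene[p$role == "target_amplification"]))
  refGenes <- sort(unique(p$gene[p$role == "reference"]))
  new("ProbeDesign", probes = p,
      amplificationGenes = ampGenes, referenceGenes = refGenes)
}

#' Read a probe design from a tab-separated file
#'
#' @param path path to a TSV with header probe_id, gene, exon_label, mix,
#'   role, left_seq, right_seq and optional middle_key, chrom, start, end.
#' @param adapters adapter set as from [nexteraAdapters()].
#' @return A validated [ProbeDesign-class].
#' @seealso [writeDesign()], [probeDesign()]
#' @export
loadDesign <- function(path, adapters = nexteraAdapters()) {
  if (!file.exists(path)) stop("design file not found: ", path)
  p <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  for (col in c("start", "end"))
    if (col %in% names(p)) p[[col]] <- suppressWarnings(as.integer(p[[col]]))
  probeDesign(p, adapters)
}

#' Write a probe design to a tab-separated file
#'
#' @param design a [ProbeDesign-class].
#' @param path output path.
#' @return Invisibly, the path written.
#' @export
writeDesign <- function(design, path) {
  stopifnot(is(design, "ProbeDesign"))
  write.table(probes(design), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# probe rows participating in one reaction mix ('both' joins each mix)
probesForMix <- function(design, mix) {
  mix <- match.arg(mix, c("detection", "confirmation"))
  p <- probes(design)
  p[p$mix %in% c(mix, "both"), , drop = FALSE]
}

#' Write the suspects key file for one reaction mix
#'
#' The counting stage assigns reads to probes by searching for each probe's
#' 20-base middle key; the "suspects" file is the headerless two-column
#' (probe_id, key) table it consumes, one file per mix, rows ordered by
#' probe_id.
#'
#' @param design a [ProbeDesign-class].
#' @param mix "detection" or "confirmation".
#' @param path output path.
#' @return Invisibly, the path written.
#' @export
writeSuspects <- function(design, mix, path) {
  p <- probesForMix(design, mix)
  p <- p[order(p$probe_id), c("probe_id", "middle_key"), drop = FALSE]
  write.table(p, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Per-gene probe counts for a design
#'
#' @param design a [ProbeDesign-class].
#' @return data.frame with columns gene and n_probes, one row per gene plus a
#'   final "Total" row whose count equals the number of probes.
#' @export
designSummary <- function(design) {
  p <- probes(design)
  if (!nrow(p))
    return(data.frame(gene = "Total", n_probes = 0L,
                      stringsAsFactors = FALSE))
  tab <- table(factor(p$gene, levels = unique(p$gene)))
  out <- data.frame(gene = names(tab), n_probes = as.integer(tab),
                    stringsAsFactors = FALSE)
  rbind(out, data.frame(gene = "Total", n_probes = nrow(p)))
}

# cheap stable polynomial checksum over the id|key rows, used to refuse
# baselines built against a different design
designChecksum <- function(design) {
  p <- probes(design)
  txt <- paste(p$probe_id, p$middle_key, sep = "|", collapse = ";")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# exon labels of a design in panel order (first appearance), with genes
exonTable <- function(design) {
  p <- probes(design)
  keep <- !duplicated(p$exon_label)
  data.frame(gene = p$gene[keep], exon_label = p$exon_label[keep],
             stringsAsFactors = FALSE)
}

# adapter-free ligated amplicon insert per probe (left arm + right arm)
ampliconInserts <- function(design, adapters = nexteraAdapters()) {
  p <- probes(design)
  arms <- probeArms(p, adapters)
  if (any(!nzchar(arms$left) | !nzchar(arms$right)))
    stop("design lacks oligo sequences; cannot build amplicon inserts")
  setNames(paste0(arms$left, arms$right), p$probe_id)
}
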