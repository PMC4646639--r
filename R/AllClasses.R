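#' @import methods
#' @importFrom stats median rnorm rlnorm rpois runif sd setNames
#' @importFrom utils read.delim write.table
NULL

PROBE_MIXES <- c("detection", "confirmation", "both")
PROBE_ROLES <- c("target_deletion", "target_amplification", "reference",
                 "pten_flank", "pten_pseudogene")
DNA_ALPHABET_RE <- "^[ACGT]+$"

#' ProbeDesign: the assay definition
#'
#' Holds one validated MLPA probe panel: one row per ligation probe pair with
#' its gene, exon label, reaction-mix membership, role, optional oligo
#' sequences (with sequencing-adapter overhangs) and the 20-base middle key
#' spanning the ligation junction that identifies the probe in reads.
#' Genes flagged for amplification surveillance are excluded from the
#' within-library depth-normalization mean; reference genes carry copy-neutral
#' normalization probes.
#'
#' @slot probes data.frame with columns probe_id, gene, exon_label, mix, role,
#'   left_seq, right_seq, middle_key and optional chrom/start/end (1-based,
#'   inclusive, annotation only).
#' @slot amplificationGenes character, genes whose probes are excluded from
#'   the depth-normalization mean.
#' @slot referenceGenes character, copy-neutral reference genes.
#'
#' @aliases ProbeDesign-class
#' @exportClass ProbeDesign
setClass("ProbeDesign",
  representation(probes = "data.frame",
                 amplificationGenes = "character",
                 referenceGenes = "character"))

setValidity("ProbeDesign", function(object) {
  p <- object@probes
  msgs <- character()
  req <- c("probe_id", "gene", "exon_label", "mix", "role", "middle_key")
  miss <- setdiff(req, names(p))
  if (length(miss))
    return(paste0("missing probe column(s): ", paste(miss, collapse = ", ")))
  dup <- unique(p$probe_id[duplicated(p$probe_id)])
  if (length(dup))
    msgs <- c(msgs, paste0("duplicate probe_id(s): ", paste(dup, collapse = ", ")))
  if (!all(p$mix %in% PROBE_MIXES))
    msgs <- c(msgs, paste0("invalid mix value(s): ",
                           paste(unique(setdiff(p$mix, PROBE_MIXES)), collapse = ", ")))
  if (!all(p$role %in% PROBE_ROLES))
    msgs <- c(msgs, paste0("invalid role value(s): ",
                           paste(unique(setdiff(p$role, PROBE_ROLES)), collapse = ", ")))
  if (nrow(p)) {
    if (!all(nchar(p$middle_key) == 20L))
      msgs <- c(msgs, "middle_key must be exactly 20 bases")
    if (!all(grepl(DNA_ALPHABET_RE, p$middle_key)))
      msgs <- c(msgs, "middle_key must be over the alphabet {A,C,G,T}")
    for (m in c("detection", "confirmation")) {
      keys <- p$middle_key[p$mix %in% c(m, "both")]
      if (anyDuplicated(keys))
        msgs <- c(msgs, paste0("middle keys not unique within ", m, " mix"))
    }
    # a gene may appear in exactly one role group
    byGene <- split(roleGroup(p$role), p$gene)
    bad <- names(byGene)[vapply(byGene, function(g) length(unique(g)) > 1L, logical(1))]
    if (length(bad))
      msgs <- c(msgs, paste0("gene(s) with probes in more than one role group: ",
                             paste(bad, collapse = ", ")))
  }
  if (length(intersect(object@amplificationGenes, object@referenceGenes)))
    msgs <- c(msgs, "amplificationGenes and referenceGenes must be disjoint")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

# pten_flank / pten_pseudogene probes are deletion-confirmation probes;
# they normalise like ordinary deletion targets
roleGroup <- function(role) {
  ifelse(role == "target_amplification", "amplification",
         ifelse(role == "reference", "reference", "target"))
}

#' LibraryCounts: raw per-probe read counts for one reaction library
#'
#' The per-probe read tally produced by the counting stage for a single
#' sample/mix reaction, together with the read bookkeeping needed for QC:
#' total reads, on-target reads (reads containing at least one probe key)
#' and ambiguous reads (matching two or more distinct keys; discarded).
#'
#' @slot sampleId character scalar.
#' @slot mix "detection" or "confirmation".
#' @slot counts named integer vector, probe_id -> raw read count.
#' @slot totalReads integer, all reads seen.
#' @slot onTargetReads integer, reads matching >= 1 key (includes ambiguous).
#' @slot ambiguousReads integer, reads matching >= 2 distinct keys.
#' @slot isControl logical, copy-neutral control sample.
#' @slot isNTC logical, no-template control.
#'
#' @aliases LibraryCounts-class
#' @exportClass LibraryCounts
setClass("LibraryCounts",
  representation(sampleId = "character", mix = "character",
                 counts = "integer", totalReads = "integer",
                 onTargetReads = "integer", ambiguousReads = "integer",
                 isControl = "logical", isNTC = "logical"))

setValidity("LibraryCounts", function(object) {
  msgs <- character()
  if (!object@mix %in% c("detection", "confirmation"))
    msgs <- c(msgs, "mix must be 'detection' or 'confirmation'")
  if (is.null(names(object@counts)) && length(object@counts))
    msgs <- c(msgs, "counts must be named by probe_id")
  if (any(object@counts < 0L)) msgs <- c(msgs, "counts must be non-negative")
  if (sum(object@counts) + object@ambiguousReads != object@onTargetReads)
    msgs <- c(msgs, "on-target reads must equal sum(counts) + ambiguous reads")
  if (object@onTargetReads > object@totalReads)
    msgs <- c(msgs, "on-target reads cannot exceed total reads")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' DepthNormalized: within-library depth-normalised probe values
#'
#' Raw counts divided by the library normalizer X, the arithmetic mean of raw
#' counts over probes of non-amplification genes. Values are dimensionless;
#' their mean over non-amplification probes is 1 by construction.
#'
#' @slot sampleId character scalar.
#' @slot mix character scalar.
#' @slot values named numeric, probe_id -> depth-normalised value.
#' @slot normalizer numeric scalar X (mean raw coverage, non-amplification probes).
#'
#' @aliases DepthNormalized-class
#' @exportClass DepthNormalized
setClass("DepthNormalized",
  representation(sampleId = "character", mix = "character",
                 values = "numeric", normalizer = "numeric"))

#' Baseline: accumulated control-sample means per probe
#'
#' Per-probe mean (and coefficient of variation) of depth-normalised values
#' across accumulated copy-neutral control samples; the denominator of the
#' copy-number ratio. Probes whose CV across controls exceeds a cap, or whose
#' raw coverage fell below the floor in the controls, are marked unusable.
#'
#' @slot mix character scalar.
#' @slot perProbeMean named numeric.
#' @slot perProbeCV named numeric (sd/mean across controls).
#' @slot nControls integer, number of control samples accumulated.
#' @slot usable named logical.
#' @slot designChecksum character, guards against mixing designs.
#'
#' @aliases Baseline-class
#' @exportClass Baseline
setClass("Baseline",
  representation(mix = "character", perProbeMean = "numeric",
                 perProbeCV = "numeric", nControls = "integer",
                 usable = "logical", designChecksum = "character"))

#' RatioMatrix: per-probe copy-number ratios for one library
#'
#' Depth-normalised values divided by the control baseline, per probe;
#' 1.0 corresponds to two copies. Probes without a usable baseline are
#' excluded with a recorded reason.
#'
#' @slot sampleId character scalar.
#' @slot mix character scalar.
#' @slot ratios named numeric, probe_id -> observed/expected copy ratio.
#' @slot excluded data.frame with columns probe_id, reason.
#'
#' @aliases RatioMatrix-class
#' @exportClass RatioMatrix
setClass("RatioMatrix",
  representation(sampleId = "character", mix = "character",
                 ratios = "numeric", excluded = "data.frame"))

setMethod("show", "ProbeDesign", function(object) {
  p <- object@probes
  cat("ProbeDesign with", nrow(p), "probes over",
      length(unique(p$gene)), "genes\n")
  cat("  amplification genes:",
      paste(object@amplificationGenes, collapse = ", "), "\n")
  cat("  reference genes:    ",
      paste(object@referenceGenes, collapse = ", "), "\n")
  cat("  mixes: detection", sum(p$mix %in% c("detection", "both")),
      "| confirmation", sum(p$mix %in% c("confirmation", "both")), "\n")
})

setMethod("show", "LibraryCounts", function(object) {
  cat("LibraryCounts:", object@sampleId, "[", object@mix, "]\n")
  cat("  probes:", length(object@counts),
      "| total reads:", object@totalReads,
      "| on-target:", object@onTargetReads,
      "| ambiguous:", object@ambiguousReads, "\n")
  if (object@isControl) cat("  (control sample)\n")
  if (object@isNTC) cat("  (no-template control)\n")
})

setMethod("show", "Baseline", function(object) {
  cat("Baseline [", object@mix, "] from", object@nControls, "control samples\n")
  cat("  probes:", length(object@perProbeMean),
      "| usable:", sum(object@usable), "\n")
})

setMethod("show", "DepthNormalized", function(object) {
  cat("DepthNormalized:", object@sampleId, "[", object@mix, "]",
      "normalizer X =", format(object@normalizer, digits = 6), "\n")
})

setMethod("show", "RatioMatrix", function(object) {
  cat("RatioMatrix:", object@sampleId, "[", object@mix, "]",
      length(object@ratios), "probe ratios,",
      nrow(object@excluded), "excluded\n")
})
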