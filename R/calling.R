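# CNV calling: ratio-band classification, germline/somatic origin from
# blood-tumour pairs, ratio-to-copies conversion, analytic mixture/purity
# dosage model, contiguous-exon merging.

CNV_CATEGORIES <- c("normal", "het_deletion", "hom_deletion", "duplication",
                    "amplification", "equivocal_gain", "missing")

#' Ratio-band classification thresholds
#'
#' Dimensionless copy-ratio thresholds: ratios in the closed normal band are
#' within normal variation; ratios at or below \code{homDelMax} are
#' homozygous deletions; between \code{homDelMax} and the normal band,
#' heterozygous deletions. Gains above the normal band are duplications in
#' blood; in tumour samples, only gains above \code{amplificationMin} are
#' called (amplification) — gains in (1.3, 1.5] are reported as equivocal to
#' avoid false positives from genomic instability. Band boundaries fall into
#' the normal category (conservative calling).
#'
#' @param normalBand closed interval of normal variation (default
#'   \code{c(0.7, 1.3)}).
#' @param amplificationMin tumour amplification threshold, exclusive
#'   (default 1.5).
#' @param homDelMax homozygous-deletion threshold, inclusive (default 0.3).
#' @param requireSdSupport if TRUE, additionally require
#'   \code{|mean - 1| > 2 * sd} before any non-normal call (off by default;
#'   calling is on the mean ratio alone).
#' @return A list of class \code{ClassificationConfig}.
#' @export
classificationConfig <- function(normalBand = c(0.7, 1.3),
                                 amplificationMin = 1.5,
                                 homDelMax = 0.3,
                                 requireSdSupport = FALSE) {
  stopifnot(length(normalBand) == 2L,
            homDelMax < normalBand[1], normalBand[1] < normalBand[2],
            normalBand[2] <= amplificationMin)
  structure(list(normalBand = normalBand,
                 amplificationMin = amplificationMin,
                 homDelMax = homDelMax,
                 requireSdSupport = requireSdSupport),
            class = "ClassificationConfig")
}

#' Classify exon mean ratios into CNV categories
#'
#' @param meanRatio numeric vector of exon mean ratios (NA allowed:
#'   classified "missing").
#' @param cfg a [classificationConfig()].
#' @param sampleKind "blood" (constitutional: any gain above the normal band
#'   is a duplication) or "tumour" (gains are called amplification only above
#'   the amplification threshold; gains between the normal band and that
#'   threshold are "equivocal_gain" and not called).
#' @param sdRatio optional exon SDs, used only when
#'   \code{cfg$requireSdSupport} is TRUE.
#' @return Character vector of categories; every non-negative ratio maps to
#'   exactly one category.
#' @export
#' @examples
#' cfg <- classificationConfig()
#' classifyExon(c(0.2, 0.5, 1.0, 1.45, 1.8), cfg, "tumour")
classifyExon <- function(meanRatio, cfg = classificationConfig(),
                         sampleKind = c("blood", "tumour"), sdRatio = NULL) {
  sampleKind <- match.arg(sampleKind)
  lo <- cfg$normalBand[1]; hi <- cfg$normalBand[2]
  out <- ifelse(is.na(meanRatio), "missing",
         ifelse(meanRatio <= cfg$homDelMax, "hom_deletion",
         ifelse(meanRatio < lo, "het_deletion",
         ifelse(meanRatio <= hi, "normal",
         if (sampleKind == "blood") "duplication" else
           NA_character_))))
  if (sampleKind == "tumour") {
    gain <- !is.na(meanRatio) & meanRatio > hi
    out[gain] <- ifelse(meanRatio[gain] > cfg$amplificationMin,
                        "amplification", "equivocal_gain")
  }
  if (isTRUE(cfg$requireSdSupport) && !is.null(sdRatio)) {
    weak <- !is.na(meanRatio) & out != "normal" & out != "missing" &
      abs(meanRatio - 1) <= 2 * sdRatio
    out[weak] <- "normal"
  }
  out
}

#' Convert a mean copy ratio to average copies
#'
#' Autosomal diploid reference: copies = referencePloidy x ratio, so a ratio
#' of 1.5 corresponds to 3 average copies and 0.5 to 1 copy.
#'
#' @param meanRatio numeric vector of non-negative ratios.
#' @param referencePloidy reference copy number (default 2).
#' @return Numeric vector of average copy numbers.
#' @export
ratioToCopies <- function(meanRatio, referencePloidy = 2) {
  stopifnot(all(meanRatio >= 0, na.rm = TRUE))
  referencePloidy * meanRatio
}

#' Annotate amplification level from average copies
#'
#' Conventional reporting bands on the assay's own copy estimates: low for
#' more than 3 and at most 6 copies, medium for more than 6 and at most 12,
#' high above 12; NA below the amplification range.
#'
#' @param copies numeric vector of average copy numbers.
#' @return Character vector: "low", "medium", "high" or NA.
#' @export
amplificationLevel <- function(copies) {
  ifelse(is.na(copies) | copies <= 3, NA_character_,
         ifelse(copies <= 6, "low", ifelse(copies <= 12, "medium", "high")))
}

#' Expected copy ratio of a cell mixture
#'
#' Analytic dosage model for mixed specimens (tumour/normal admixture, DNA
#' dilution series): components contribute copies in proportion to their cell
#' fraction, and the expected assay ratio is the mean copy number over the
#' diploid reference, sum(fraction x copies) / 2.
#'
#' @param fractions numeric vector of component proportions, summing to 1
#'   (tolerance 1e-9).
#' @param copies numeric vector of per-component copy numbers at the locus.
#' @return Expected dimensionless ratio.
#' @export
#' @examples
#' expectedMixtureRatio(c(0.5, 0.5), c(1, 2))   # 0.75
#' expectedMixtureRatio(c(2, 1) / 3, c(1, 2))   # 0.6667
expectedMixtureRatio <- function(fractions, copies) {
  stopifnot(length(fractions) == length(copies), all(copies >= 0))
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("component fractions must sum to 1 (got ", sum(fractions), ")")
  sum(fractions * copies) / 2
}

#' Smallest somatic copy loss detectable at a given tumour purity
#'
#' A somatic loss of D copies in a tumour of purity p yields an expected
#' ratio of 1 - p * D / 2 against a diploid background; the loss is
#' detectable when that ratio falls below the lower bound of the normal
#' band. Returns the smallest integer D in {1, 2} that is detectable, or NA
#' when even a homozygous loss stays inside the normal band.
#'
#' @param purity tumour cell fraction in (0, 1].
#' @param cfg a [classificationConfig()] supplying the normal band.
#' @return Integer copy loss (1 or 2), or NA_integer_ (undetectable).
#' @export
#' @examples
#' somaticDetectionLimit(1.0)  # 1 (heterozygous loss visible)
#' somaticDetectionLimit(0.5)  # 2 (only homozygous loss visible)
somaticDetectionLimit <- function(purity, cfg = classificationConfig()) {
  stopifnot(purity > 0, purity <= 1)
  for (delta in 1:2) {
    r <- expectedMixtureRatio(c(purity, 1 - purity), c(2 - delta, 2))
    if (r < cfg$normalBand[1]) return(delta)
  }
  NA_integer_
}

#' Merge contiguous same-category exons into region-level calls
#'
#' Maximal runs of identical non-normal category within a gene (in panel exon
#' order) are merged into a single call, mirroring how multi-exon events are
#' reported as one finding; the merged mean ratio is the mean of the member
#' exon ratios and copies = 2 x mean ratio.
#'
#' @param exonCalls data.frame with columns gene, exon_label, category,
#'   mean_ratio (and optionally sd_ratio), in design exon order as produced
#'   by [summarizeExons()] + [classifyExon()].
#' @param design the matching [ProbeDesign-class] (fixes exon order).
#' @return data.frame with columns gene, exons (label range), exon_labels
#'   (semicolon-joined), n_exons, category, mean_ratio, copies.
#' @export
mergeContiguous <- function(exonCalls, design) {
  et <- exonTable(design)
  ord <- match(exonCalls$exon_label, et$exon_label)
  if (anyNA(ord))
    stop("exon labels not in design: ",
         paste(exonCalls$exon_label[is.na(ord)], collapse = ", "))
  exonCalls <- exonCalls[order(ord), , drop = FALSE]
  key <- paste(exonCalls$gene, exonCalls$category)
  runs <- rle(key)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- lapply(seq_along(starts), function(i) {
    block <- exonCalls[starts[i]:ends[i], , drop = FALSE]
    if (block$category[1] %in% c("normal", "missing")) return(NULL)
    labs <- block$exon_label
    mr <- mean(block$mean_ratio)
    data.frame(gene = block$gene[1],
               exons = if (length(labs) == 1L) labs else
                 paste0(labs[1], "-", labs[length(labs)]),
               exon_labels = paste(labs, collapse = ";"),
               n_exons = length(labs),
               category = block$category[1],
               mean_ratio = mr,
               copies = ratioToCopies(mr),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene = character(), exons = character(),
                      exon_labels = character(), n_exons = integer(),
                      category = character(), mean_ratio = numeric(),
                      copies = numeric(), stringsAsFactors = FALSE)
  out
}

#' Assign germline/somatic origin from a blood-tumour pair
#'
#' Per exon: an event seen in both blood and tumour is germline; a loss or
#' gain seen only in the tumour is somatic; a tumour homozygous deletion over
#' a blood heterozygous deletion is a germline deletion with loss of
#' heterozygosity. A tumour homozygous deletion is reported as
#' germline-with-LOH even without a blood sample (the zero-copy state implies
#' a constitutional first hit); all other events without a paired blood
#' sample are undetermined.
#'
#' @param tumourCalls data.frame of per-exon tumour classifications (columns
#'   gene, exon_label, category).
#' @param bloodCalls optional matching data.frame for the paired blood
#'   sample; must cover the same exons.
#' @return \code{tumourCalls} with an added \code{origin} column (one of
#'   "germline", "somatic", "germline_with_LOH", "undetermined", or NA for
#'   normal/missing exons).
#' @export
assignOrigin <- function(tumourCalls, bloodCalls = NULL) {
  lossCats <- c("het_deletion", "hom_deletion")
  gainCats <- c("duplication", "amplification", "equivocal_gain")
  origin <- rep(NA_character_, nrow(tumourCalls))
  evented <- tumourCalls$category %in% c(lossCats, gainCats)
  if (is.null(bloodCalls)) {
    origin[evented] <- "undetermined"
    origin[tumourCalls$category == "hom_deletion"] <- "germline_with_LOH"
  } else {
    if (!setequal(bloodCalls$exon_label, tumourCalls$exon_label))
      stop("blood and tumour calls cover different exon sets ",
           "(mismatched designs?)")
    bcat <- bloodCalls$category[match(tumourCalls$exon_label,
                                      bloodCalls$exon_label)]
    for (i in which(evented)) {
      tc <- tumourCalls$category[i]; bc <- bcat[i]
      origin[i] <-
        if (tc == "hom_deletion" && bc == "het_deletion") "germline_with_LOH"
        else if (tc %in% lossCats && bc %in% lossCats) "germline"
        else if (tc %in% gainCats && bc %in% gainCats) "germline"
        else "somatic"
    }
  }
  tumourCalls$origin <- origin
  tumourCalls
}
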