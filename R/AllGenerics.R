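#' Accessors for mlpaseq classes
#'
#' Small accessor generics: \code{probes} returns the probe table of a
#' \code{ProbeDesign}; \code{probeIds} and \code{middleKeys} its identifier
#' and key columns; \code{sampleId} and \code{mixName} the sample/mix labels
#' of a per-library object; \code{probeCounts}, \code{normValues} and
#' \code{cnvRatios} the per-probe vectors of a \code{LibraryCounts},
#' \code{DepthNormalized} and \code{RatioMatrix}; \code{baselineMeans} the
#' per-probe control means of a \code{Baseline}.
#'
#' @param x an mlpaseq object.
#' @return A data.frame, character vector or named numeric/integer vector,
#'   depending on the accessor.
#' @name accessors
#' @examples
#' d <- simulateDesign(nGenes = 2, exonsPerGene = 3, probesPerExon = 1,
#'                     nReference = 2, seed = 1)
#' head(probes(d))
#' middleKeys(d)[1:2]
NULL

#' @rdname accessors
#' @export
setGeneric("probes", function(x) standardGeneric("probes"))
#' @rdname accessors
#' @export
setGeneric("probeIds", function(x) standardGeneric("probeIds"))
#' @rdname accessors
#' @export
setGeneric("middleKeys", function(x) standardGeneric("middleKeys"))
#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("mixName", function(x) standardGeneric("mixName"))
#' @rdname accessors
#' @export
setGeneric("probeCounts", function(x) standardGeneric("probeCounts"))
#' @rdname accessors
#' @export
setGeneric("normValues", function(x) standardGeneric("normValues"))
#' @rdname accessors
#' @export
setGeneric("cnvRatios", function(x) standardGeneric("cnvRatios"))
#' @rdname accessors
#' @export
setGeneric("baselineMeans", function(x) standardGeneric("baselineMeans"))

#' @rdname accessors
setMethod("probes", "ProbeDesign", function(x) x@probes)
#' @rdname accessors
setMethod("probeIds", "ProbeDesign", function(x) x@probes$probe_id)
#' @rdname accessors
setMethod("middleKeys", "ProbeDesign",
          function(x) setNames(x@probes$middle_key, x@probes$probe_id))
#' @rdname accessors
setMethod("sampleId", "LibraryCounts", function(x) x@sampleId)
#' @rdname accessors
setMethod("sampleId", "DepthNormalized", function(x) x@sampleId)
#' @rdname accessors
setMethod("sampleId", "RatioMatrix", function(x) x@sampleId)
#' @rdname accessors
setMethod("mixName", "LibraryCounts", function(x) x@mix)
#' @rdname accessors
setMethod("mixName", "DepthNormalized", function(x) x@mix)
#' @rdname accessors
setMethod("mixName", "RatioMatrix", function(x) x@mix)
#' @rdname accessors
setMethod("probeCounts", "LibraryCounts", function(x) x@counts)
#' @rdname accessors
setMethod("normValues", "DepthNormalized", function(x) x@values)
#' @rdname accessors
setMethod("cnvRatios", "RatioMatrix", function(x) x@ratios)
#' @rdname accessors
setMethod("baselineMeans", "Baseline", function(x) x@perProbeMean)
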