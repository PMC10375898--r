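#' @name accessors
#' @title Accessors for chemclipseq classes
#' @description Read-only accessors for the coverage, profile, null-model
#'   and rescue classes; use these rather than reaching into slots.
#' @param x,object an object of the documented class.
#' @return The slot value (see individual accessor).
NULL

#' @rdname accessors
#' @export
setGeneric("contigName", function(x) standardGeneric("contigName"))

#' @rdname accessors
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))

#' @rdname accessors
#' @export
setGeneric("trackOffset", function(x) standardGeneric("trackOffset"))

#' @rdname accessors
#' @export
setGeneric("ratioValues", function(x) standardGeneric("ratioValues"))

#' @rdname accessors
#' @export
setGeneric("neglog10p", function(x) standardGeneric("neglog10p"))

#' @rdname accessors
#' @export
setGeneric("profileMask", function(x) standardGeneric("profileMask"))

#' @rdname accessors
#' @export
setGeneric("nullMu", function(x) standardGeneric("nullMu"))

#' @rdname accessors
#' @export
setGeneric("nullSigma", function(x) standardGeneric("nullSigma"))

#' @rdname accessors
#' @export
setGeneric("fitN", function(x) standardGeneric("fitN"))

#' @rdname accessors
#' @export
setGeneric("rescueSummary", function(x) standardGeneric("rescueSummary"))

#' @rdname accessors
#' @export
setMethod("contigName", "CoverageTrack", function(x) x@contig)

#' @rdname accessors
#' @export
setMethod("trackValues", "CoverageTrack", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("trackOffset", "CoverageTrack", function(x) x@offset)

#' @rdname accessors
#' @export
setMethod("length", "CoverageTrack", function(x) length(x@values))

#' @rdname accessors
#' @export
setMethod("contigName", "EnrichmentProfile", function(x) x@contig)

#' @rdname accessors
#' @export
setMethod("trackOffset", "EnrichmentProfile", function(x) x@offset)

#' @rdname accessors
#' @export
setMethod("ratioValues", "EnrichmentProfile", function(x) x@ratio)

#' @rdname accessors
#' @export
setMethod("neglog10p", "EnrichmentProfile", function(x) x@neglog10p)

#' @rdname accessors
#' @export
setMethod("profileMask", "EnrichmentProfile", function(x) x@mask)

#' @rdname accessors
#' @export
setMethod("length", "EnrichmentProfile", function(x) length(x@ratio))

#' @rdname accessors
#' @export
setMethod("nullMu", "NullModel", function(x) x@mu)

#' @rdname accessors
#' @export
setMethod("nullSigma", "NullModel", function(x) x@sigma)

#' @rdname accessors
#' @export
setMethod("fitN", "NullModel", function(x) x@fitN)

#' @rdname accessors
#' @export
setMethod("rescueSummary", "RescueTable", function(x) x@summary)

#' @rdname accessors
#' @description `rescueFlags` returns the per-feature classification
#'   `DataFrame` of a [RescueTable-class].
#' @export
setGeneric("rescueFlags", function(x) standardGeneric("rescueFlags"))

#' @rdname accessors
#' @export
setMethod("rescueFlags", "RescueTable", function(x) x@table)

setMethod("show", "CoverageTrack", function(object) {
    v <- object@values
    cat(sprintf("CoverageTrack on '%s': %d nt (offset %d), total %.6g, mean %.3g\n",
                object@contig, length(v), object@offset, sum(v),
                if (length(v)) mean(v) else NA_real_))
})

setMethod("show", "EnrichmentProfile", function(object) {
    hasP <- !all(is.na(object@neglog10p))
    cat(sprintf(
        "EnrichmentProfile on '%s': %d nt, %d masked out%s\n",
        object@contig, length(object@ratio), sum(!object@mask),
        if (hasP) sprintf(", max -log10 p = %.2f",
                          max(object@neglog10p, na.rm = TRUE))
        else " (p-values not yet computed)"))
})

setMethod("show", "NullModel", function(object) {
    cat(sprintf(
        "Log-normal null model (%s fit): mu = %.4f, sigma = %.4f (n = %d)\n",
        object@method, object@mu, object@sigma, object@fitN))
})

setMethod("show", "FilterConfig", function(object) {
    cat("Region filter configuration:\n")
    cat(sprintf("  -log10 p cutoff       > %g\n", object@pCutoff))
    cat(sprintf("  min AUC (%s-mode)  >= %g\n", object@aucMode,
                object@minAuc))
    cat(sprintf("  length range            %d-%d nt\n", object@lengthMin,
                object@lengthMax))
    cat(sprintf("  min output reads     >= %g\n", object@minReads))
    cat(sprintf("  min log2 FC, all reps >= %g\n", object@minLog2fc))
    cat(sprintf("  max merged gap          %d nt\n", object@maxGap))
})

setMethod("show", "RescueTable", function(object) {
    s <- object@summary
    cat(sprintf("RescueTable: %d features at alpha = %g\n",
                s$n_features, object@alpha))
    cat(sprintf("  dysregulated: %d\n", s$n_dysregulated))
    cat(sprintf("  rescued:      %d (naive fraction %.3f)\n",
                s$n_rescued, s$fraction_rescued))
    cat(sprintf("  rescue fraction estimate (high-confidence subset): %.3f\n",
                s$rescue_fraction_estimate))
})
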