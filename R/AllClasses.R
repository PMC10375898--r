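#' CoverageTrack: dense per-nucleotide read coverage on one contig
#'
#' Holds the per-nucleotide read counts of one library (input or output,
#' i.e. before or after pull-down) on a single named contig, as a dense
#' vector starting at `offset` nucleotides from the contig origin. Raw
#' coverage is integer-valued; derived tracks (ratios, -log10 p) reuse the
#' container in float mode.
#'
#' @slot contig single contig name.
#' @slot offset 0-based start coordinate of the first element of `values`.
#' @slot values non-negative per-nucleotide values.
#'
#' @seealso [readBedGraph()], [writeBedGraph()], [computeRatio()]
#' @export
setClass("CoverageTrack",
    representation(contig = "character", offset = "integer",
                   values = "numeric"),
    prototype(contig = NA_character_, offset = 0L, values = numeric()))

setValidity("CoverageTrack", function(object) {
    msg <- NULL
    if (length(object@contig) != 1L || is.na(object@contig) ||
        !nzchar(object@contig))
        msg <- c(msg, "'contig' must be a single non-empty string")
    if (length(object@offset) != 1L || is.na(object@offset) ||
        object@offset < 0L)
        msg <- c(msg, "'offset' must be a single non-negative integer")
    if (anyNA(object@values) || any(object@values < 0) ||
        any(!is.finite(object@values)))
        msg <- c(msg, "'values' must be finite and non-negative")
    if (is.null(msg)) TRUE else msg
})

#' Construct a CoverageTrack
#'
#' @param contig contig name.
#' @param values numeric vector of per-nucleotide values.
#' @param offset 0-based coordinate of `values[1]` on the contig.
#' @return A [CoverageTrack-class] object.
#' @examples
#' CoverageTrack("chrT", c(3, 3, 3, 0, 1))
#' @export
CoverageTrack <- function(contig, values, offset = 0L) {
    new("CoverageTrack", contig = as.character(contig),
        values = as.numeric(values), offset = as.integer(offset))
}

#' EnrichmentProfile: per-nucleotide enrichment ratio and significance
#'
#' Per-nucleotide output/input enrichment ratio on one contig, the validity
#' mask (input coverage at or above the minimum), and -- once a null model
#' has been applied -- the -log10 p-value of each nucleotide under the
#' log-normal null.
#'
#' @slot contig single contig name.
#' @slot offset 0-based start coordinate of the dense arrays.
#' @slot ratio per-nucleotide enrichment ratio (NA where masked).
#' @slot neglog10p per-nucleotide -log10 p (NA where masked or not yet
#'   computed).
#' @slot mask logical; TRUE where the nucleotide enters the analysis.
#'
#' @seealso [computeRatio()], [pvalueTrack()]
#' @export
setClass("EnrichmentProfile",
    representation(contig = "character", offset = "integer",
                   ratio = "numeric", neglog10p = "numeric",
                   mask = "logical"))

setValidity("EnrichmentProfile", function(object) {
    msg <- NULL
    n <- length(object@ratio)
    if (length(object@neglog10p) != n || length(object@mask) != n)
        msg <- c(msg, "'ratio', 'neglog10p' and 'mask' must have equal length")
    if (any(object@ratio < 0, na.rm = TRUE))
        msg <- c(msg, "'ratio' must be non-negative")
    if (any(object@neglog10p < 0, na.rm = TRUE))
        msg <- c(msg, "'neglog10p' must be non-negative where defined")
    if (anyNA(object@mask))
        msg <- c(msg, "'mask' must not contain NA")
    if (is.null(msg)) TRUE else msg
})

#' NullModel: fitted log-normal null of the enrichment ratio
#'
#' Parameters of the background distribution of the per-nucleotide
#' enrichment ratio: under the null, ln(ratio) ~ Normal(mu, sigma^2).
#' Upper-tail probabilities of this distribution are the per-nucleotide
#' enrichment p-values.
#'
#' @slot mu mean of ln(ratio) under the null.
#' @slot sigma standard deviation of ln(ratio) under the null.
#' @slot fitN number of nucleotides used in the fit.
#' @slot method estimator used ("robust", "moments" or "tail").
#'
#' @seealso [fitNull()], [pvalueTrack()]
#' @export
setClass("NullModel",
    representation(mu = "numeric", sigma = "numeric", fitN = "integer",
                   method = "character"))

setValidity("NullModel", function(object) {
    msg <- NULL
    if (length(object@sigma) != 1L || is.na(object@sigma) ||
        object@sigma <= 0)
        msg <- c(msg, "'sigma' must be a single positive value")
    if (length(object@mu) != 1L || is.na(object@mu))
        msg <- c(msg, "'mu' must be a single finite value")
    if (length(object@fitN) != 1L || is.na(object@fitN) || object@fitN <= 0L)
        msg <- c(msg, "'fitN' must be a single positive integer")
    if (is.null(msg)) TRUE else msg
})

#' FilterConfig: region-calling thresholds and filter cascade settings
#'
#' Thresholds of the significance cutoff and the four-stage region filter
#' cascade: (i) minimum area under the -log10 p curve, (ii) region length
#' range matching the pulled-down fragment sizes, (iii) minimum read count,
#' and (iv) replicate-consistent minimum log2 fold enrichment. Defaults are
#' the published thresholds (cutoff 10; AUC 200; 400-1000 nt; 10 reads;
#' log2 FC 0.8 in every replicate).
#'
#' @slot pCutoff -log10 p threshold a nucleotide must exceed.
#' @slot minAuc minimum area score of a region.
#' @slot lengthMin,lengthMax allowed region length range (nt).
#' @slot minReads minimum pooled output-side read count in the region.
#' @slot minLog2fc minimum per-replicate log2 fold enrichment.
#' @slot maxGap regions separated by at most this many sub-threshold or
#'   masked nucleotides are merged (0 = strict adjacency).
#' @slot aucMode "above" sums max(0, neglog10p - pCutoff) over the region;
#'   "raw" sums neglog10p itself.
#' @slot pseudocount pseudocount used in per-replicate fold changes.
#'
#' @seealso [callRegions()], [applyFilters()]
#' @export
setClass("FilterConfig",
    representation(pCutoff = "numeric", minAuc = "numeric",
                   lengthMin = "integer", lengthMax = "integer",
                   minReads = "numeric", minLog2fc = "numeric",
                   maxGap = "integer", aucMode = "character",
                   pseudocount = "numeric"))

setValidity("FilterConfig", function(object) {
    msg <- NULL
    num1 <- function(x) length(x) == 1L && !is.na(x)
    if (!num1(object@pCutoff) || object@pCutoff < 0)
        msg <- c(msg, "'pCutoff' must be a single value >= 0")
    if (!num1(object@minAuc) || object@minAuc < 0)
        msg <- c(msg, "'minAuc' must be a single value >= 0")
    if (!num1(object@lengthMin) || !num1(object@lengthMax) ||
        object@lengthMin < 0L || object@lengthMin > object@lengthMax)
        msg <- c(msg, "'lengthMin' must be in [0, lengthMax]")
    if (!num1(object@minReads) || object@minReads < 0)
        msg <- c(msg, "'minReads' must be a single value >= 0")
    if (!num1(object@minLog2fc))
        msg <- c(msg, "'minLog2fc' must be a single value")
    if (!num1(object@maxGap) || object@maxGap < 0L)
        msg <- c(msg, "'maxGap' must be a single integer >= 0")
    if (!object@aucMode %in% c("above", "raw"))
        msg <- c(msg, "'aucMode' must be \"above\" or \"raw\"")
    if (!num1(object@pseudocount) || object@pseudocount < 0)
        msg <- c(msg, "'pseudocount' must be a single value >= 0")
    if (is.null(msg)) TRUE else msg
})

#' Construct a FilterConfig
#'
#' @param pCutoff,minAuc,lengthMin,lengthMax,minReads,minLog2fc,maxGap,aucMode,pseudocount
#'   see [FilterConfig-class]; the defaults are the published thresholds.
#' @return A [FilterConfig-class] object.
#' @examples
#' FilterConfig()                  # published thresholds
#' FilterConfig(maxGap = 5L)       # bridge isolated sub-threshold dips
#' @export
FilterConfig <- function(pCutoff = 10, minAuc = 200, lengthMin = 400L,
                         lengthMax = 1000L, minReads = 10, minLog2fc = 0.8,
                         maxGap = 0L, aucMode = c("above", "raw"),
                         pseudocount = 1) {
    new("FilterConfig", pCutoff = as.numeric(pCutoff),
        minAuc = as.numeric(minAuc), lengthMin = as.integer(lengthMin),
        lengthMax = as.integer(lengthMax), minReads = as.numeric(minReads),
        minLog2fc = as.numeric(minLog2fc), maxGap = as.integer(maxGap),
        aucMode = match.arg(aucMode), pseudocount = as.numeric(pseudocount))
}

#' SpikeSpec: a ground-truth enriched interval for the simulator
#'
#' An interval of a simulated transcript whose true enrichment ratio is
#' multiplied by `fold`, emulating a genuinely bound region. Coordinates are
#' 1-based closed (Bioconductor convention).
#'
#' @slot transcriptId host transcript.
#' @slot start,end interval bounds (1-based, closed).
#' @slot fold true enrichment multiplier (> 0; enriched spikes use > 1).
#' @export
setClass("SpikeSpec",
    representation(transcriptId = "character", start = "integer",
                   end = "integer", fold = "numeric"))

setValidity("SpikeSpec", function(object) {
    msg <- NULL
    if (length(object@transcriptId) != 1L || is.na(object@transcriptId))
        msg <- c(msg, "'transcriptId' must be a single string")
    if (object@end < object@start || object@start < 1L)
        msg <- c(msg, "need 1 <= start <= end")
    if (length(object@fold) != 1L || is.na(object@fold) || object@fold <= 0)
        msg <- c(msg, "'fold' must be a single positive value")
    if (is.null(msg)) TRUE else msg
})

#' @rdname SpikeSpec-class
#' @param transcriptId,start,end,fold see slots.
#' @return A [SpikeSpec-class] object.
#' @examples
#' SpikeSpec("tx001", 501, 1100, fold = 8)
#' @export
SpikeSpec <- function(transcriptId, start, end, fold) {
    new("SpikeSpec", transcriptId = as.character(transcriptId),
        start = as.integer(start), end = as.integer(end),
        fold = as.numeric(fold))
}

#' RepeatSpec: a repeat locus with alignment dropout
#'
#' Marks an interval emulating a GC-rich pure-repeat segment whose reads
#' cannot be aligned to a reference lacking the expansion: coverage on
#' *both* library sides is thinned by `dropoutFraction` inside the interval.
#' Because the dropout is symmetric it cancels in the enrichment ratio.
#'
#' @slot transcriptId host transcript.
#' @slot start,end interval bounds (1-based, closed).
#' @slot dropoutFraction fraction of coverage lost in both libraries (0-1).
#' @export
setClass("RepeatSpec",
    representation(transcriptId = "character", start = "integer",
                   end = "integer", dropoutFraction = "numeric"))

setValidity("RepeatSpec", function(object) {
    msg <- NULL
    if (object@end < object@start || object@start < 1L)
        msg <- c(msg, "need 1 <= start <= end")
    f <- object@dropoutFraction
    if (length(f) != 1L || is.na(f) || f < 0 || f > 1)
        msg <- c(msg, "'dropoutFraction' must be in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' @rdname RepeatSpec-class
#' @param transcriptId,start,end,dropoutFraction see slots.
#' @return A [RepeatSpec-class] object.
#' @examples
#' RepeatSpec("tx001", 2001, 2200, dropoutFraction = 0.9)
#' @export
RepeatSpec <- function(transcriptId, start, end, dropoutFraction) {
    new("RepeatSpec", transcriptId = as.character(transcriptId),
        start = as.integer(start), end = as.integer(end),
        dropoutFraction = as.numeric(dropoutFraction))
}

#' SimulationConfig: study conditions for the synthetic Chem-CLIP-Seq data
#'
#' Defines a toy transcriptome and the generative model for its coverage
#' tracks: input-side coverage is Poisson(`depthInput`) per nucleotide;
#' the true per-nucleotide enrichment ratio is
#' exp(Normal(`backgroundMu`, `backgroundSigma`^2)) outside spiked
#' intervals and `fold` times that inside them; output-side coverage is
#' Poisson(depth x true ratio). A repeat locus thins both sides by its
#' dropout fraction. Draws are independent per replicate and per
#' nucleotide, and deterministic for a given `seed`.
#'
#' @slot nTranscripts number of transcripts (one contig each).
#' @slot lengthRange transcript length range in nt, drawn uniformly.
#' @slot nReplicates replicates per condition (experimental design: 3).
#' @slot depthInput mean input-library reads per nucleotide.
#' @slot backgroundMu mean of ln(ratio) under the null.
#' @slot backgroundSigma sd of ln(ratio) under the null.
#' @slot spikes list of [SpikeSpec-class] ground-truth enriched intervals.
#' @slot repeatLocus a [RepeatSpec-class] or NULL.
#' @slot seed RNG seed.
#' @seealso [generateAnnotation()], [simulateCoverage()]
#' @export
setClass("SimulationConfig",
    representation(nTranscripts = "integer", lengthRange = "integer",
                   nReplicates = "integer", depthInput = "numeric",
                   backgroundMu = "numeric", backgroundSigma = "numeric",
                   spikes = "list", repeatLocus = "ANY", seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- NULL
    if (object@nTranscripts < 1L)
        msg <- c(msg, "'nTranscripts' must be >= 1")
    if (length(object@lengthRange) != 2L ||
        any(object@lengthRange < 1L) ||
        object@lengthRange[1L] > object@lengthRange[2L])
        msg <- c(msg, "'lengthRange' must be c(min, max) with 1 <= min <= max")
    if (object@nReplicates < 1L)
        msg <- c(msg, "'nReplicates' must be >= 1")
    if (object@depthInput <= 0)
        msg <- c(msg, "'depthInput' must be > 0")
    if (object@backgroundSigma <= 0)
        msg <- c(msg, "'backgroundSigma' must be > 0")
    if (!all(vapply(object@spikes, is, logical(1L), class2 = "SpikeSpec")))
        msg <- c(msg, "'spikes' must be a list of SpikeSpec objects")
    if (!is.null(object@repeatLocus) && !is(object@repeatLocus, "RepeatSpec"))
        msg <- c(msg, "'repeatLocus' must be NULL or a RepeatSpec")
    if (is.null(msg)) TRUE else msg
})

#' Construct a SimulationConfig
#'
#' Defaults are the package's reference study conditions: 100 transcripts
#' of 2-8 kb, 3 replicates, 30x input depth, and background ln-ratio noise
#' with sd 0.15 (see the methods vignette for the rationale).
#'
#' @param nTranscripts,lengthRange,nReplicates,depthInput,backgroundMu,backgroundSigma,spikes,repeatLocus,seed
#'   see [SimulationConfig-class].
#' @return A [SimulationConfig-class] object.
#' @examples
#' cfg <- SimulationConfig(nTranscripts = 5, seed = 7)
#' @export
SimulationConfig <- function(nTranscripts = 100L,
                             lengthRange = c(2000L, 8000L),
                             nReplicates = 3L, depthInput = 30,
                             backgroundMu = 0, backgroundSigma = 0.15,
                             spikes = list(), repeatLocus = NULL,
                             seed = 1L) {
    if (length(lengthRange) != 2L || any(is.na(lengthRange)) ||
        lengthRange[1L] > lengthRange[2L])
        stop("invalid 'lengthRange': need c(min, max) with min <= max",
             call. = FALSE)
    new("SimulationConfig", nTranscripts = .assertCount(nTranscripts,
            "nTranscripts"),
        lengthRange = as.integer(lengthRange),
        nReplicates = .assertCount(nReplicates, "nReplicates"),
        depthInput = as.numeric(depthInput),
        backgroundMu = as.numeric(backgroundMu),
        backgroundSigma = as.numeric(backgroundSigma),
        spikes = spikes, repeatLocus = repeatLocus,
        seed = .assertCount(seed, "seed", min = 0L))
}

#' RescueSimConfig: study conditions for the rescue simulation
#'
#' Generates feature-by-replicate matrices for three groups -- healthy
#' vehicle (WT), disease vehicle, disease treated -- with `nDysregulated`
#' features offset by +/- `effectSize` in the disease group, of which a
#' `trueRescueFraction` is returned to the WT mean under treatment.
#' Gaussian noise with sd `noiseSd` is added on the analysis scale
#' (log2 expression, or Psi clipped to \[0, 1\]).
#'
#' @slot nGenes number of features.
#' @slot nDysregulated number of truly dysregulated features.
#' @slot trueRescueFraction fraction of dysregulated features rescued.
#' @slot effectSize dysregulation offset on the analysis scale.
#' @slot noiseSd replicate noise sd on the analysis scale.
#' @slot nReplicates replicates per group.
#' @slot seed RNG seed.
#' @seealso [simulateRescueMatrices()], [classifyRescued()]
#' @export
setClass("RescueSimConfig",
    representation(nGenes = "integer", nDysregulated = "integer",
                   trueRescueFraction = "numeric", effectSize = "numeric",
                   noiseSd = "numeric", nReplicates = "integer",
                   seed = "integer"))

setValidity("RescueSimConfig", function(object) {
    msg <- NULL
    if (object@nDysregulated > object@nGenes || object@nDysregulated < 0L)
        msg <- c(msg, "'nDysregulated' must be in [0, nGenes]")
    f <- object@trueRescueFraction
    if (length(f) != 1L || is.na(f) || f < 0 || f > 1)
        msg <- c(msg, "'trueRescueFraction' must be in [0, 1]")
    if (object@noiseSd <= 0)
        msg <- c(msg, "'noiseSd' must be > 0")
    if (object@nReplicates < 2L)
        msg <- c(msg, "'nReplicates' must be >= 2")
    if (is.null(msg)) TRUE else msg
})

#' Construct a RescueSimConfig
#'
#' @param nGenes,nDysregulated,trueRescueFraction,effectSize,noiseSd,nReplicates,seed
#'   see [RescueSimConfig-class].
#' @return A [RescueSimConfig-class] object.
#' @examples
#' RescueSimConfig(nGenes = 5000, nDysregulated = 200,
#'                 trueRescueFraction = 0.8, seed = 3)
#' @export
RescueSimConfig <- function(nGenes, nDysregulated, trueRescueFraction,
                            effectSize = 2, noiseSd = 0.3,
                            nReplicates = 3L, seed = 1L) {
    new("RescueSimConfig", nGenes = .assertCount(nGenes, "nGenes"),
        nDysregulated = .assertCount(nDysregulated, "nDysregulated",
                                     min = 0L),
        trueRescueFraction = .assertFraction(trueRescueFraction,
                                             "trueRescueFraction"),
        effectSize = as.numeric(effectSize), noiseSd = as.numeric(noiseSd),
        nReplicates = .assertCount(nReplicates, "nReplicates", min = 2L),
        seed = .assertCount(seed, "seed", min = 0L))
}

#' RescueTable: per-feature dysregulation and rescue classification
#'
#' Per-feature classification of disease-vs-healthy dysregulation and
#' treatment rescue, plus summary counts. A feature is *dysregulated* when
#' disease-vehicle differs from WT at `alpha` (Welch test); *shifted toward
#' WT* when the treated group mean is closer to the WT mean than the
#' vehicle mean is; and *rescued* when it is dysregulated, shifted, and no
#' longer significantly different from WT after treatment.
#'
#' @slot table per-feature `DataFrame` (means, p-values, flags).
#' @slot summary list of counts and fractions, including the naive rescue
#'   fraction and a bias-reduced `rescue_fraction_estimate` (see the
#'   methods vignette).
#' @slot alpha significance level used throughout.
#' @seealso [classifyRescued()], [rescueAnalysis()]
#' @export
setClass("RescueTable",
    representation(table = "DataFrame", summary = "list", alpha = "numeric"))

setValidity("RescueTable", function(object) {
    msg <- NULL
    tb <- object@table
    need <- c("dysregulated", "shifted_toward_wt", "rescued",
              "p_vehicle", "p_treated")
    if (!all(need %in% colnames(tb)))
        msg <- c(msg, paste("'table' must contain columns:",
                            paste(need, collapse = ", ")))
    else {
        if (any(tb$rescued & !tb$dysregulated))
            msg <- c(msg, "'rescued' implies 'dysregulated'")
        if (any(tb$rescued & !tb$shifted_toward_wt))
            msg <- c(msg, "'rescued' implies 'shifted_toward_wt'")
        pv <- c(tb$p_vehicle, tb$p_treated)
        if (any(pv <= 0 | pv > 1, na.rm = TRUE))
            msg <- c(msg, "p-values must lie in (0, 1]")
    }
    if (length(object@alpha) != 1L || object@alpha <= 0 || object@alpha >= 1)
        msg <- c(msg, "'alpha' must be in (0, 1)")
    if (is.null(msg)) TRUE else msg
})
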