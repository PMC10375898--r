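# Compile significant nucleotides into candidate regions and apply the
# four-stage filter cascade.

# Runs of TRUE in `above`, bridging FALSE runs of length <= maxGap that lie
# strictly between TRUE runs. Returns matrix [start, end] (1-based closed).
.sigRuns <- function(above, maxGap) {
    r <- rle(above)
    if (maxGap > 0L && length(r$lengths) > 2L) {
        inner <- seq_along(r$values)[-c(1L, length(r$values))]
        bridge <- inner[!r$values[inner] & r$lengths[inner] <= maxGap]
        if (length(bridge)) {
            r$values[bridge] <- TRUE
            r <- rle(inverse.rle(r))
        }
    }
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    cbind(start = starts[keep], end = ends[keep])
}

#' Compile significant nucleotides into candidate regions
#'
#' Maximal runs of nucleotides with -log10 p strictly above
#' `pCutoff(config)` are compiled into regions; runs separated by at most
#' `maxGap` sub-threshold or masked nucleotides are merged. Each region is
#' annotated with its area score (`aucMode = "above"`: sum of
#' max(0, neglog10p - pCutoff); `"raw"`: sum of neglog10p), its maximum
#' -log10 p, and -- when pooled tracks are supplied -- its summed raw
#' input/output reads.
#'
#' @param profiles an [EnrichmentProfile-class] or named list of them,
#'   with p-values populated (see [pvalueTrack()]).
#' @param config a [FilterConfig-class].
#' @param inputPooled,outputPooled optional pooled coverage sets used for
#'   the region read sums.
#' @return `GRanges` of candidate regions (1-based closed coordinates on
#'   the profile contigs) with metadata columns `auc`, `max_neglog10p`,
#'   `reads_input`, `reads_output` and `name`.
#' @examples
#' p <- new("EnrichmentProfile", contig = "chrT", offset = 0L,
#'          ratio = rep(1, 4), neglog10p = c(0, 12, 12, 0),
#'          mask = rep(TRUE, 4))
#' callRegions(p, FilterConfig())   # one region, width 2, auc 4
#' @export
callRegions <- function(profiles, config = FilterConfig(),
                        inputPooled = NULL, outputPooled = NULL) {
    stopifnot(is(config, "FilterConfig"))
    methods::validObject(config)
    if (is(profiles, "EnrichmentProfile"))
        profiles <- stats::setNames(list(profiles), contigName(profiles))
    res <- list()
    for (p in profiles) {
        ctg <- contigName(p)
        x <- neglog10p(p)
        above <- !is.na(x) & x > config@pCutoff
        if (!any(above))
            next
        runs <- .sigRuns(above, config@maxGap)
        x0 <- ifelse(is.na(x), 0, x)
        contrib <- if (config@aucMode == "above")
            pmax(0, x0 - config@pCutoff) else x0
        cum <- c(0, cumsum(contrib))
        auc <- cum[runs[, "end"] + 1L] - cum[runs[, "start"]]
        mx <- vapply(seq_len(nrow(runs)), function(k)
            max(x[runs[k, "start"]:runs[k, "end"]], na.rm = TRUE),
            numeric(1L))
        sumTrack <- function(set) {
            if (is.null(set) || is.null(set[[ctg]]))
                return(rep(NA_real_, nrow(runs)))
            cv <- c(0, cumsum(trackValues(set[[ctg]])))
            cv[runs[, "end"] + 1L] - cv[runs[, "start"]]
        }
        off <- trackOffset(p)
        res[[ctg]] <- GenomicRanges::GRanges(
            seqnames = ctg,
            ranges = IRanges::IRanges(start = runs[, "start"] + off,
                                      end = runs[, "end"] + off),
            auc = auc, max_neglog10p = mx,
            reads_input = sumTrack(inputPooled),
            reads_output = sumTrack(outputPooled))
    }
    if (length(res) == 0L) {
        gr <- GenomicRanges::GRanges()
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            auc = numeric(), max_neglog10p = numeric(),
            reads_input = numeric(), reads_output = numeric(),
            name = character())
        return(gr)
    }
    gr <- unlist(GenomicRanges::GRangesList(res), use.names = FALSE)
    gr$name <- sprintf("region%04d", seq_along(gr))
    gr
}

# Region sums of one replicate's coverage set on one contig.
.regionSum <- function(set, ctg, start, end) {
    tr <- set[[ctg]]
    if (is.null(tr))
        stop(sprintf("replicate tracks lack contig '%s'", ctg),
             call. = FALSE)
    i <- (start - trackOffset(tr)):(end - trackOffset(tr))
    sum(trackValues(tr)[i])
}

#' Apply the four-stage region filter cascade
#'
#' A candidate region passes when (i) its area score is at least
#' `minAuc`, (ii) its length lies in `[lengthMin, lengthMax]`, (iii) its
#' pooled output-side read count is at least `minReads`, and (iv) its
#' depth-normalized log2 fold enrichment is at least `minLog2fc` in
#' *every* replicate. Per-replicate fold enrichment of a region is
#' log2( ((sum O + pc)/N_O) / ((sum I + pc)/N_I) ) with that replicate's
#' library totals.
#'
#' @param regions `GRanges` from [callRegions()] (with `reads_output`
#'   populated).
#' @param inputReps,outputReps lists of per-replicate coverage sets (equal
#'   length).
#' @param config a [FilterConfig-class].
#' @return list with `passing` (`GRanges` of surviving regions) and
#'   `verdicts` (`GRanges` of all regions with per-filter logical columns
#'   `pass_auc`, `pass_length`, `pass_reads`, `pass_replicates`, `pass`
#'   and a `log2fc` matrix column, one column per replicate).
#' @examples
#' # see the package tests for a fully worked cascade fixture
#' @export
applyFilters <- function(regions, inputReps, outputReps,
                         config = FilterConfig()) {
    stopifnot(is(regions, "GRanges"), is(config, "FilterConfig"))
    if (!is.list(inputReps) || !is.list(outputReps) ||
        length(inputReps) != length(outputReps) ||
        length(inputReps) == 0L)
        stop("'inputReps' and 'outputReps' must be non-empty lists of equal length",
             call. = FALSE)
    nrep <- length(inputReps)
    nI <- vapply(inputReps, .librarySize, numeric(1L))
    nO <- vapply(outputReps, .librarySize, numeric(1L))
    if (any(nI <= 0) || any(nO <= 0))
        stop("zero total library reads in a replicate", call. = FALSE)
    n <- length(regions)
    l2fc <- matrix(NA_real_, nrow = n, ncol = nrep,
                   dimnames = list(NULL, sprintf("rep%d", seq_len(nrep))))
    pc <- config@pseudocount
    if (n) {
        ctgs <- as.character(GenomicRanges::seqnames(regions))
        st <- GenomicRanges::start(regions)
        en <- GenomicRanges::end(regions)
        for (k in seq_len(n)) {
            for (r in seq_len(nrep)) {
                si <- .regionSum(inputReps[[r]], ctgs[k], st[k], en[k])
                so <- .regionSum(outputReps[[r]], ctgs[k], st[k], en[k])
                l2fc[k, r] <- log2(((so + pc) / nO[r]) /
                                   ((si + pc) / nI[r]))
            }
        }
    }
    wid <- GenomicRanges::width(regions)
    verdicts <- regions
    verdicts$log2fc <- l2fc
    verdicts$pass_auc <- regions$auc >= config@minAuc
    verdicts$pass_length <- wid >= config@lengthMin & wid <= config@lengthMax
    verdicts$pass_reads <- !is.na(regions$reads_output) &
        regions$reads_output >= config@minReads
    verdicts$pass_replicates <- if (n)
        apply(l2fc >= config@minLog2fc, 1L, all) else logical()
    verdicts$pass <- verdicts$pass_auc & verdicts$pass_length &
        verdicts$pass_reads & verdicts$pass_replicates
    list(passing = verdicts[verdicts$pass], verdicts = verdicts)
}
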