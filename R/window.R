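# Fixed-width window quantification around a locus of interest (e.g. the
# repeat region of a disease allele), with per-replicate output.

#' Quantify enrichment in a fixed window around a locus
#'
#' Places a window of `width` nt centered on the locus midpoint (shifted,
#' not shrunk, when the contig boundary would truncate it) and computes,
#' per replicate, the depth-normalized fold enrichment
#' ((sum O + pc)/N_O) / ((sum I + pc)/N_I) over the window, where N are the
#' replicate's total library counts. Because a repeat locus loses coverage
#' on *both* library sides (unalignable pure-repeat reads), symmetric
#' dropout cancels in this ratio; asymmetric dropout does not and is the
#' caller's risk.
#'
#' @param inputReps,outputReps lists of per-replicate coverage sets.
#' @param locus the locus of interest: a length-1 `GRanges`, or a list
#'   with `contig`, `start`, `end` (1-based closed).
#' @param width window width in nt (default 500).
#' @param pseudocount added to both window sums (default 1).
#' @param depthNormalize scale each side by its library total (default
#'   TRUE).
#' @param locusId label for the output row.
#' @return data.frame with one row: locus id, window coordinates
#'   (1-based closed), one `fold_rep<i>` column per replicate, `mean_fold`
#'   and `sd_fold`.
#' @examples
#' inp <- list(list(chrT = CoverageTrack("chrT", rep(12, 2000))))
#' out <- list(list(chrT = CoverageTrack("chrT",
#'     c(rep(4, 750), rep(36, 500), rep(4, 750)))))
#' windowEnrichment(inp, out, list(contig = "chrT", start = 902,
#'                                 end = 1100))$mean_fold   # ~3
#' @export
windowEnrichment <- function(inputReps, outputReps, locus, width = 500L,
                             pseudocount = 1, depthNormalize = TRUE,
                             locusId = "locus") {
    if (is(locus, "GRanges")) {
        stopifnot(length(locus) == 1L)
        locus <- list(contig = as.character(GenomicRanges::seqnames(locus)),
                      start = GenomicRanges::start(locus),
                      end = GenomicRanges::end(locus))
    }
    if (!all(c("contig", "start", "end") %in% names(locus)))
        stop("'locus' needs contig, start and end", call. = FALSE)
    if (length(inputReps) != length(outputReps) || length(inputReps) == 0L)
        stop("need equal, non-empty replicate lists", call. = FALSE)
    nrep <- length(inputReps)
    ctg <- locus$contig
    tr1 <- inputReps[[1L]][[ctg]]
    if (is.null(tr1))
        stop(sprintf("locus contig '%s' not present in the tracks", ctg),
             call. = FALSE)
    L <- length(trackValues(tr1))
    off <- trackOffset(tr1)
    width <- as.integer(width)
    if (L < width)
        stop(sprintf("contig '%s' (%d nt) is shorter than the window (%d nt)",
                     ctg, L, width), call. = FALSE)
    mid <- floor((locus$start + locus$end) / 2)
    wStart <- mid - width %/% 2L
    wStart <- max(off + 1L, min(wStart, off + L - width + 1L))
    wEnd <- wStart + width - 1L

    folds <- vapply(seq_len(nrep), function(r) {
        si <- .regionSum(inputReps[[r]], ctg, wStart, wEnd)
        so <- .regionSum(outputReps[[r]], ctg, wStart, wEnd)
        if (depthNormalize) {
            nI <- .librarySize(inputReps[[r]])
            nO <- .librarySize(outputReps[[r]])
            if (nI <= 0 || nO <= 0)
                stop("zero total library reads in a replicate",
                     call. = FALSE)
            ((so + pseudocount) / nO) / ((si + pseudocount) / nI)
        } else {
            (so + pseudocount) / (si + pseudocount)
        }
    }, numeric(1L))

    df <- data.frame(locus_id = locusId, contig = ctg, window_start = wStart,
                     window_end = wEnd, width = width,
                     stringsAsFactors = FALSE)
    for (r in seq_len(nrep))
        df[[sprintf("fold_rep%d", r)]] <- folds[r]
    df$mean_fold <- mean(folds)
    df$sd_fold <- if (nrep > 1L) stats::sd(folds) else NA_real_
    df
}

#' Welch test on per-replicate window folds between two conditions
#'
#' A deliberately simple significance test of a window's fold enrichment
#' between two conditions (e.g. disease vs healthy), run on the
#' per-replicate fold values. This is a simplification of a full two-way
#' ANOVA across conditions and probes.
#'
#' @param foldsA,foldsB numeric vectors of per-replicate folds.
#' @return `htest` from [stats::t.test()].
#' @export
compareWindowFolds <- function(foldsA, foldsB) {
    stats::t.test(foldsA, foldsB)
}
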