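# Per-nucleotide enrichment ratios, the log-normal null model and
# -log10 p-value tracks.

#' Pool replicate coverage sets
#'
#' Per-nucleotide sum across replicates, per library side. The p-value
#' analysis runs on pooled tracks; per-replicate fold change is a separate
#' downstream filter.
#'
#' @param replicates list of coverage sets (named lists of
#'   [CoverageTrack-class] over the same contigs/spans).
#' @return a single pooled coverage set.
#' @examples
#' t1 <- list(chrT = CoverageTrack("chrT", c(1, 2)))
#' t2 <- list(chrT = CoverageTrack("chrT", c(3, 4)))
#' trackValues(poolReplicates(list(t1, t2))$chrT)   # 4 6
#' @export
poolReplicates <- function(replicates) {
    if (!is.list(replicates) || length(replicates) == 0L)
        stop("'replicates' must be a non-empty list of coverage sets",
             call. = FALSE)
    pooled <- .checkTrackSet(replicates[[1L]], "replicates[[1]]")
    if (length(replicates) == 1L)
        return(pooled)
    for (k in seq_along(replicates)[-1L]) {
        sets <- .checkMatchedSets(pooled, replicates[[k]], "pooled",
                                  sprintf("replicates[[%d]]", k))
        pooled <- sets[[1L]]
        other <- sets[[2L]]
        for (ctg in names(pooled))
            pooled[[ctg]]@values <- pooled[[ctg]]@values +
                other[[ctg]]@values
    }
    pooled
}

#' Compute per-nucleotide enrichment ratios
#'
#' The enrichment ratio at each nucleotide is the output (post-pull-down)
#' coverage divided by the input (pre-pull-down) coverage. With
#' `depthNormalize = TRUE` (default) both sides are first scaled by their
#' total library counts:
#' r_i = ((O_i + pc) / N_O) / ((I_i + pc) / N_I).
#' Nucleotides with input coverage below `minInput` are masked and excluded
#' from the null fit and p-value tracks.
#'
#' @param input,output coverage sets (named lists of
#'   [CoverageTrack-class]) over identical contigs and spans.
#' @param pseudocount added to both sides (default 1); prevents division
#'   blow-ups at low coverage.
#' @param depthNormalize scale each side by its total library count.
#' @param minInput minimum raw input coverage for a nucleotide to enter
#'   the analysis.
#' @return named list of [EnrichmentProfile-class], one per contig, with
#'   ratios populated and p-values unset.
#' @examples
#' inp <- list(chrT = CoverageTrack("chrT", c(10, 10)))
#' out <- list(chrT = CoverageTrack("chrT", c(10, 40)))
#' ratioValues(computeRatio(inp, out, pseudocount = 0,
#'                          depthNormalize = FALSE)$chrT)   # 1 4
#' @export
computeRatio <- function(input, output, pseudocount = 1,
                         depthNormalize = TRUE, minInput = 1) {
    if (pseudocount < 0)
        stop("'pseudocount' must be >= 0", call. = FALSE)
    sets <- .checkMatchedSets(input, output)
    input <- sets[[1L]]; output <- sets[[2L]]
    scale <- 1
    if (depthNormalize) {
        nI <- .librarySize(input)
        nO <- .librarySize(output)
        if (nI <= 0 || nO <= 0)
            stop("zero total library reads; cannot depth-normalize",
                 call. = FALSE)
        scale <- nI / nO
    }
    lapply(input, function(tin) {
        ctg <- contigName(tin)
        iv <- trackValues(tin)
        ov <- trackValues(output[[ctg]])
        mask <- iv >= minInput
        r <- scale * (ov + pseudocount) / (iv + pseudocount)
        r[!mask] <- NA_real_
        new("EnrichmentProfile", contig = ctg, offset = trackOffset(tin),
            ratio = r, neglog10p = rep(NA_real_, length(r)), mask = mask)
    })
}

# ln ratios over unmasked, non-excluded nucleotides of a profile set
.collectLogRatios <- function(profiles, exclude = NULL) {
    if (is(profiles, "EnrichmentProfile"))
        profiles <- stats::setNames(list(profiles), contigName(profiles))
    unlist(lapply(profiles, function(p) {
        keep <- profileMask(p)
        if (!is.null(exclude) && length(exclude)) {
            sel <- exclude[as.character(
                GenomicRanges::seqnames(exclude)) == contigName(p)]
            if (length(sel)) {
                drop <- unlist(lapply(seq_along(sel), function(k)
                    GenomicRanges::start(sel)[k]:GenomicRanges::end(sel)[k]))
                drop <- drop - trackOffset(p)
                drop <- drop[drop >= 1L & drop <= length(keep)]
                keep[drop] <- FALSE
            }
        }
        r <- ratioValues(p)[keep]
        log(r[r > 0])
    }), use.names = FALSE)
}

#' Fit the log-normal null model
#'
#' Estimates the mean and sd of ln(ratio) under the null from unmasked
#' (and optionally non-excluded) nucleotides. Three estimators:
#'
#' * `"robust"` (default): median and MAD (x 1.4826). Insensitive to a
#'   minority of genuinely enriched nucleotides contaminating the fit.
#' * `"moments"`: plain mean and sd.
#' * `"tail"`: variance-weighted fit of a normal to the empirical
#'   upper-tail quantiles at p = 0.9, 0.99 and 0.999. At finite
#'   sequencing depth the count noise makes the realized ln-ratio
#'   distribution slightly non-normal, and bulk estimators then
#'   miscalibrate extreme-tail p-values; the tail fit anchors the null
#'   where significance decisions are made. Use on data without
#'   substantial enrichment (or after excluding called regions).
#'
#' @param profiles an [EnrichmentProfile-class] or named list of them.
#' @param exclude optional `GRanges` of candidate regions excluded from
#'   the fit (iterate: fit, call regions, refit excluding them).
#' @param method estimator; see above.
#' @param minFitN minimum number of usable nucleotides.
#' @return a [NullModel-class].
#' @examples
#' set.seed(1)
#' p <- new("EnrichmentProfile", contig = "chrT", offset = 0L,
#'          ratio = exp(rnorm(5000, 0.2, 0.5)),
#'          neglog10p = rep(NA_real_, 5000), mask = rep(TRUE, 5000))
#' fitNull(p)
#' @export
fitNull <- function(profiles, exclude = NULL,
                    method = c("robust", "moments", "tail"),
                    minFitN = 100L) {
    method <- match.arg(method)
    x <- .collectLogRatios(profiles, exclude)
    x <- x[is.finite(x)]
    if (length(x) < minFitN)
        stop(sprintf("only %d usable nucleotides for the null fit (need >= %d)",
                     length(x), minFitN), call. = FALSE)
    est <- switch(method,
        robust = c(stats::median(x), stats::mad(x)),
        moments = c(mean(x), stats::sd(x)),
        tail = {
            # weighted fit of a normal to the empirical upper-tail
            # quantiles at p = 0.9, 0.99, 0.999 (the span where
            # significance decisions are made); weights are the inverse
            # sampling variances of the matching exceedance frequencies
            tt <- 1:3
            ps <- 1 - 10^-tt
            z <- stats::qnorm(ps)
            qe <- stats::quantile(x, ps, names = FALSE, type = 8)
            w <- stats::dnorm(z)^2 / (10^-tt * ps)
            X <- cbind(1, z)
            co <- solve(t(X) %*% (w * X), t(X) %*% (w * qe))
            c(co[1L], co[2L])
        })
    if (!is.finite(est[2L]) || est[2L] <= 0)
        stop("degenerate null fit: zero dispersion in ln(ratio)",
             call. = FALSE)
    new("NullModel", mu = est[1L], sigma = est[2L],
        fitN = length(x), method = method)
}

#' Compute -log10 p-value tracks under the null
#'
#' The p-value of nucleotide i is the upper-tail probability of
#' Normal(mu, sigma^2) at ln(r_i). The survival function is evaluated in
#' log space, so p-values far below 1e-300 remain finite and accurate;
#' -log10 p is clipped at `cap`. Masked nucleotides stay NA.
#'
#' @param profiles an [EnrichmentProfile-class] or named list of them
#'   (from [computeRatio()]).
#' @param null a fitted [NullModel-class].
#' @param cap upper clip for -log10 p (default 350).
#' @return the profiles with `neglog10p` populated (single profile in,
#'   single profile out).
#' @examples
#' p <- new("EnrichmentProfile", contig = "chrT", offset = 0L,
#'          ratio = exp(c(0, 3 * 0.5)), neglog10p = rep(NA_real_, 2),
#'          mask = rep(TRUE, 2))
#' null <- new("NullModel", mu = 0, sigma = 0.5, fitN = 100L,
#'             method = "moments")
#' neglog10p(pvalueTrack(p, null))   # 0.301 (median), 2.87 (3 sigma)
#' @export
pvalueTrack <- function(profiles, null, cap = 350) {
    stopifnot(is(null, "NullModel"))
    single <- is(profiles, "EnrichmentProfile")
    if (single)
        profiles <- stats::setNames(list(profiles), contigName(profiles))
    out <- lapply(profiles, function(p) {
        r <- ratioValues(p)
        nl <- rep(NA_real_, length(r))
        ok <- profileMask(p) & !is.na(r)
        lnr <- suppressWarnings(log(r[ok]))
        logsf <- stats::pnorm(lnr, mean = nullMu(null), sd = nullSigma(null),
                              lower.tail = FALSE, log.p = TRUE)
        nl[ok] <- pmin(-logsf / log(10), cap)
        nl[ok][r[ok] == 0] <- 0
        p@neglog10p <- nl
        p
    })
    if (single) out[[1L]] else out
}
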