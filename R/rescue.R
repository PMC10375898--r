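# Classification of disease-dysregulated features (genes or splicing
# events) and of their rescue by treatment.

# Row-wise Welch tests of two feature-by-replicate matrices.
# Constant-variance rows get p = 1 with a single warning.
.rowWelch <- function(a, b) {
    n <- nrow(a)
    p <- numeric(n)
    degenerate <- FALSE
    for (i in seq_len(n)) {
        p[i] <- tryCatch(stats::t.test(a[i, ], b[i, ])$p.value,
                         error = function(e) {
                             degenerate <<- TRUE
                             1
                         })
        if (is.na(p[i])) {      # zero variance in both groups
            degenerate <- TRUE
            p[i] <- 1
        }
    }
    if (degenerate)
        warning("constant features encountered; their p-values were set to 1",
                call. = FALSE)
    p
}

.prepMatrices <- function(mats, mode) {
    ids <- rownames(mats[[1L]])
    if (is.null(ids))
        stop("matrices must carry feature rownames", call. = FALSE)
    for (m in mats) {
        if (!identical(rownames(m), ids))
            stop("feature indices of the matrices do not match",
                 call. = FALSE)
        if (ncol(m) < 2L)
            stop("need at least 2 replicates per group", call. = FALSE)
    }
    switch(mode,
        expression = lapply(mats, function(m) {
            if (any(m < 0))
                stop("negative values in an expression (TPM) matrix",
                     call. = FALSE)
            log2(m + 1)
        }),
        psi = lapply(mats, function(m) {
            if (any(m < -1e-8) || any(m > 1 + 1e-8))
                warning("Psi values outside [0, 1] were clipped",
                        call. = FALSE)
            pmin(pmax(m, 0), 1)
        }))
}

#' Classify features dysregulated in disease vs healthy samples
#'
#' Per-feature two-sample Welch test between the healthy (WT) and disease
#' matrices; a feature is dysregulated when p < `alpha`. Expression
#' matrices (TPM) are tested on log2(TPM + 1); splicing matrices (Psi) are
#' tested untransformed, clipped to \[0, 1\]. No multiple-testing
#' correction is applied to the call itself (the classification mirrors a
#' raw p < 0.05 rule); see [classifyRescued()] for how the summary deals
#' with the resulting false discoveries.
#'
#' @param matrixWT,matrixDisease feature-by-replicate matrices with
#'   matching rownames.
#' @param alpha significance level (default 0.05).
#' @param mode `"expression"` (log2(TPM+1)) or `"psi"`.
#' @return `DataFrame` with per-feature group means (on the tested
#'   scale), `p_value` and `dysregulated`.
#' @export
classifyDysregulated <- function(matrixWT, matrixDisease, alpha = 0.05,
                                 mode = c("expression", "psi")) {
    mode <- match.arg(mode)
    mm <- .prepMatrices(list(matrixWT, matrixDisease), mode)
    p <- .rowWelch(mm[[1L]], mm[[2L]])
    S4Vectors::DataFrame(
        feature_id = rownames(matrixWT),
        mean_wt = rowMeans(mm[[1L]]),
        mean_disease = rowMeans(mm[[2L]]),
        sd_wt = apply(mm[[1L]], 1L, stats::sd),
        sd_disease = apply(mm[[2L]], 1L, stats::sd),
        p_value = p,
        dysregulated = p < alpha)
}

#' Classify treatment rescue of dysregulated features
#'
#' Builds the full [RescueTable-class]: a feature is *shifted toward WT*
#' when the treated group mean is strictly closer to the WT mean than the
#' vehicle mean is, and *rescued* when it is dysregulated (vehicle vs WT,
#' p < alpha), shifted toward WT, and no longer significantly different
#' from WT after treatment (treated vs WT, p > alpha).
#'
#' The summary reports the naive rescue fraction
#' n_rescued / n_dysregulated and, separately, `rescue_fraction_estimate`:
#' the rescue fraction computed over the high-confidence dysregulated
#' subset (p_vehicle < alpha/10) divided by (1 - alpha). False discoveries
#' of the raw p < alpha rule have a null treated arm, look "rescued", and
#' bias the naive fraction; the high-confidence subset removes most of
#' them, and the (1 - alpha) factor undoes the attenuation from truly
#' rescued features that re-test significant by chance. See the methods
#' vignette.
#'
#' @param matrixWT,matrixVehicle,matrixTreated feature-by-replicate
#'   matrices with matching rownames (WT vehicle, disease vehicle,
#'   disease treated).
#' @param alpha significance level (default 0.05).
#' @param mode `"expression"` or `"psi"`.
#' @param highconfFactor the high-confidence subset uses
#'   p < alpha * highconfFactor (default 0.1).
#' @return a [RescueTable-class].
#' @seealso [rescueAnalysis()], [simulateRescueMatrices()]
#' @export
classifyRescued <- function(matrixWT, matrixVehicle, matrixTreated,
                            alpha = 0.05, mode = c("expression", "psi"),
                            highconfFactor = 0.1) {
    mode <- match.arg(mode)
    if (alpha <= 0 || alpha >= 1)
        stop("'alpha' must be in (0, 1)", call. = FALSE)
    mm <- .prepMatrices(list(matrixWT, matrixVehicle, matrixTreated), mode)
    pVeh <- .rowWelch(mm[[1L]], mm[[2L]])
    pTrt <- .rowWelch(mm[[1L]], mm[[3L]])
    mWT <- rowMeans(mm[[1L]])
    mVeh <- rowMeans(mm[[2L]])
    mTrt <- rowMeans(mm[[3L]])
    dys <- pVeh < alpha
    shifted <- abs(mTrt - mWT) < abs(mVeh - mWT)
    noLonger <- pTrt > alpha
    rescued <- dys & shifted & noLonger
    highconf <- pVeh < alpha * highconfFactor
    tb <- S4Vectors::DataFrame(
        feature_id = rownames(matrixWT),
        mean_wt = mWT, mean_vehicle = mVeh, mean_treated = mTrt,
        p_vehicle = pVeh, p_treated = pTrt,
        dysregulated = dys, shifted_toward_wt = shifted,
        no_longer_significant = noLonger, rescued = rescued,
        high_confidence = highconf)
    nDys <- sum(dys)
    nHigh <- sum(highconf)
    est <- if (nHigh > 0)
        min(1, sum(rescued & highconf) / nHigh / (1 - alpha)) else NA_real_
    summary <- list(
        n_features = nrow(tb),
        n_dysregulated = nDys,
        n_rescued = sum(rescued),
        n_shifted = sum(dys & shifted),
        fraction_shifted = if (nDys) sum(dys & shifted) / nDys else NA_real_,
        fraction_rescued = if (nDys) sum(rescued) / nDys else NA_real_,
        n_highconf = nHigh,
        rescue_fraction_estimate = est,
        alpha = alpha,
        highconf_alpha = alpha * highconfFactor,
        mode = mode)
    new("RescueTable", table = tb, summary = summary, alpha = alpha)
}

#' One-call rescue analysis
#'
#' Convenience wrapper: [classifyDysregulated()] (WT vs vehicle) followed
#' by [classifyRescued()].
#'
#' @inheritParams classifyRescued
#' @return a [RescueTable-class].
#' @export
rescueAnalysis <- function(matrixWT, matrixVehicle, matrixTreated,
                           alpha = 0.05, mode = c("expression", "psi")) {
    classifyRescued(matrixWT, matrixVehicle, matrixTreated, alpha = alpha,
                    mode = match.arg(mode))
}
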