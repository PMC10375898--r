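# Ground-truth generator for the rescue classification.

#' Simulate expression or splicing matrices with known rescue ground truth
#'
#' Generates the three feature-by-replicate matrices of a rescue study --
#' WT vehicle, disease vehicle, disease treated. `nDysregulated` features
#' are offset by +/- `effectSize` in the disease group (random sign); a
#' `trueRescueFraction` of them is returned to the WT mean under
#' treatment, the rest keep their disease offset. Replicate noise is
#' Gaussian with sd `noiseSd` on the analysis scale.
#'
#' * `type = "expression"`: baselines are drawn as log2 expression
#'   ~ Normal(5, 1.5^2) and matrices are returned as TPM
#'   (2^x - 1, so the classifier's log2(TPM + 1) transform recovers the
#'   simulated scale); `effectSize` is in log2 units.
#' * `type = "psi"`: baselines ~ Uniform(0.15, 0.85), values clipped to
#'   \[0, 1\]; `effectSize` is on the Psi scale (e.g. 0.3).
#'
#' @param config a [RescueSimConfig-class].
#' @param type `"expression"` or `"psi"`.
#' @return list with matrices `wt`, `vehicle`, `treated` and a `truth`
#'   list giving the dysregulated and rescued feature ids.
#' @examples
#' sim <- simulateRescueMatrices(RescueSimConfig(100, 10, 0.5, seed = 2))
#' str(sim$truth)
#' @export
simulateRescueMatrices <- function(config, type = c("expression", "psi")) {
    stopifnot(is(config, "RescueSimConfig"))
    methods::validObject(config)
    type <- match.arg(type)
    nG <- config@nGenes
    nD <- config@nDysregulated
    nR <- config@nReplicates
    ids <- sprintf("feat%05d", seq_len(nG))

    withSeed(config@seed, {
        base <- if (type == "expression") stats::rnorm(nG, 5, 1.5)
                else stats::runif(nG, 0.15, 0.85)
        dysIdx <- if (nD > 0L) sort(sample.int(nG, nD)) else integer()
        nResc <- round(config@trueRescueFraction * nD)
        rescIdx <- if (nResc > 0L) sort(sample(dysIdx, nResc)) else integer()
        sgn <- sample(c(-1, 1), nD, replace = TRUE)
        # Psi offsets are pushed away from the nearer boundary so the
        # dysregulated mean stays inside [0, 1].
        if (type == "psi" && nD > 0L)
            sgn <- ifelse(base[dysIdx] + sgn * config@effectSize > 1 |
                          base[dysIdx] + sgn * config@effectSize < 0,
                          -sgn, sgn)
        mWT <- base
        mVeh <- base
        mVeh[dysIdx] <- base[dysIdx] + sgn * config@effectSize
        mTrt <- mVeh
        mTrt[rescIdx] <- base[rescIdx]

        draw <- function(mu) {
            m <- matrix(stats::rnorm(nG * nR, mean = mu, sd = config@noiseSd),
                        nrow = nG, ncol = nR,
                        dimnames = list(ids, sprintf("rep%d", seq_len(nR))))
            if (type == "expression") pmax(2^m - 1, 0) else pmin(pmax(m, 0), 1)
        }
        # with a zero effect size nothing is truly dysregulated
        truly <- config@effectSize != 0
        list(wt = draw(mWT), vehicle = draw(mVeh), treated = draw(mTrt),
             truth = list(dysregulated = if (truly) ids[dysIdx] else
                              character(),
                          rescued = if (truly) ids[rescIdx] else character(),
                          effect_sign = sgn))
    })
}
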