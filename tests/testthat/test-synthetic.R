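# Synthetic-data generator: determinism, annotation properties, the
# generative coverage model and the rescue-matrix simulator.

test_that("annotation generation respects the configured length range", {
    cfg <- SimulationConfig(nTranscripts = 1, lengthRange = c(1000L, 1000L),
                            seed = 7)
    ann <- generateAnnotation(cfg)
    expect_length(ann, 1L)
    expect_equal(GenomicRanges::width(ann), 1000L)

    cfg <- SimulationConfig(nTranscripts = 50,
                            lengthRange = c(2000L, 8000L), seed = 3)
    w <- GenomicRanges::width(generateAnnotation(cfg))
    expect_true(all(w >= 2000L & w <= 8000L))
    expect_identical(anyDuplicated(generateAnnotation(cfg)$transcript_id),
                     0L)
})

test_that("identical config and seed give identical annotations and coverage", {
    cfg <- SimulationConfig(nTranscripts = 10, lengthRange = c(500L, 900L),
                            seed = 11)
    a1 <- generateAnnotation(cfg)
    a2 <- generateAnnotation(cfg)
    expect_identical(a1, a2)
    cfg@spikes <- list(SpikeSpec(a1$transcript_id[1], 101, 300, 4))
    c1 <- simulateCoverage(a1, cfg)
    c2 <- simulateCoverage(a1, cfg)
    expect_identical(c1, c2)
    # and a different seed changes the draws
    cfg2 <- cfg
    cfg2@seed <- 12L
    expect_false(identical(simulateCoverage(a1, cfg2), c1))
})

test_that("invalid configurations are rejected", {
    expect_error(SimulationConfig(lengthRange = c(100L, 50L)),
                 "lengthRange")
    expect_error(SimulationConfig(nReplicates = 0L), "nReplicates")
    expect_error(validObject(new("SpikeSpec", transcriptId = "t",
                                 start = 10L, end = 5L, fold = 2)),
                 "start")
    cfg <- SimulationConfig(nTranscripts = 1,
                            lengthRange = c(1000L, 1000L), seed = 1)
    ann <- generateAnnotation(cfg)
    cfg@spikes <- list(SpikeSpec(ann$transcript_id[1], 900, 1200, 4))
    expect_error(simulateCoverage(ann, cfg), "outside transcript")
})

test_that("spiked intervals carry the configured fold in the realized ratio", {
    # mean realized ratio inside a fold-8 spike ~ 8x the outside mean,
    # averaged over repeated simulations
    folds <- vapply(100 + seq_len(20), function(seed) {
        cfg <- SimulationConfig(nTranscripts = 1,
                                lengthRange = c(2000L, 2000L),
                                nReplicates = 1L, depthInput = 50,
                                backgroundSigma = 0.2, seed = seed,
                                spikes = list(SpikeSpec("tx0001", 501,
                                                        1100, 8)))
        ann <- generateAnnotation(cfg)
        cov <- simulateCoverage(ann, cfg)
        iv <- trackValues(cov$input[[1]]$tx0001)
        ov <- trackValues(cov$output[[1]]$tx0001)
        r <- (ov + 1) / (iv + 1)
        mean(r[501:1100]) / mean(r[-(501:1100)])
    }, numeric(1))
    expect_gt(mean(folds), 8 * 0.85)
    expect_lt(mean(folds), 8 * 1.15)
})

test_that("larger spike folds give larger realized ratios", {
    meanRatio <- vapply(c(2, 4, 8), function(f) {
        cfg <- SimulationConfig(nTranscripts = 1,
                                lengthRange = c(1500L, 1500L),
                                nReplicates = 1L, seed = 99,
                                spikes = list(SpikeSpec("tx0001", 201,
                                                        800, f)))
        ann <- generateAnnotation(cfg)
        cov <- simulateCoverage(ann, cfg)
        iv <- trackValues(cov$input[[1]]$tx0001)[201:800]
        ov <- trackValues(cov$output[[1]]$tx0001)[201:800]
        mean((ov + 1) / (iv + 1))
    }, numeric(1))
    expect_true(all(diff(meanRatio) > 0))
})

test_that("total repeat-locus dropout zeroes both library sides", {
    cfg <- SimulationConfig(nTranscripts = 1,
                            lengthRange = c(1000L, 1000L), seed = 5,
                            repeatLocus = RepeatSpec("tx0001", 301, 500,
                                                     1.0))
    ann <- generateAnnotation(cfg)
    cov <- simulateCoverage(ann, cfg)
    for (r in seq_along(cov$input)) {
        expect_true(all(trackValues(cov$input[[r]]$tx0001)[301:500] == 0))
        expect_true(all(trackValues(cov$output[[r]]$tx0001)[301:500] == 0))
    }
    # outside the locus coverage is untouched
    expect_gt(mean(trackValues(cov$input[[1]]$tx0001)[-(301:500)]), 20)
})

test_that("latent null ratio field matches the configured log-normal", {
    cfg <- SimulationConfig(nTranscripts = 2,
                            lengthRange = c(50000L, 50000L),
                            nReplicates = 1L, backgroundMu = 0.1,
                            backgroundSigma = 0.3, seed = 21)
    ann <- generateAnnotation(cfg)
    cov <- simulateCoverage(ann, cfg, returnTruth = TRUE)
    lnrho <- log(unlist(attr(cov, "truth")[[1]], use.names = FALSE))
    n <- length(lnrho)
    expect_equal(mean(lnrho), 0.1, tolerance = 4 * 0.3 / sqrt(n) / 0.1)
    expect_equal(sd(lnrho), 0.3, tolerance = 0.01)
    # at high depth the realized count-level ln ratio approaches the
    # latent distribution
    cfg2 <- SimulationConfig(nTranscripts = 1,
                             lengthRange = c(50000L, 50000L),
                             nReplicates = 1L, depthInput = 3000,
                             backgroundMu = 0, backgroundSigma = 0.3,
                             seed = 22)
    ann2 <- generateAnnotation(cfg2)
    cov2 <- simulateCoverage(ann2, cfg2)
    lnr <- log((trackValues(cov2$output[[1]][[1]]) + 1) /
               (trackValues(cov2$input[[1]][[1]]) + 1))
    expect_equal(sd(lnr), 0.3, tolerance = 0.02)
})

test_that("rescue matrices encode the configured ground truth", {
    cfg <- RescueSimConfig(nGenes = 300, nDysregulated = 40,
                           trueRescueFraction = 0.5, effectSize = 2,
                           noiseSd = 0.1, seed = 9)
    sim <- simulateRescueMatrices(cfg)
    expect_identical(sim, simulateRescueMatrices(cfg))
    expect_length(sim$truth$dysregulated, 40L)
    expect_length(sim$truth$rescued, 20L)
    dys <- rownames(sim$wt) %in% sim$truth$dysregulated
    resc <- rownames(sim$wt) %in% sim$truth$rescued
    dWT <- rowMeans(log2(sim$vehicle + 1)) - rowMeans(log2(sim$wt + 1))
    expect_true(all(abs(dWT[dys]) > 1))
    expect_true(all(abs(dWT[!dys]) < 1))
    dTr <- rowMeans(log2(sim$treated + 1)) - rowMeans(log2(sim$wt + 1))
    expect_true(all(abs(dTr[resc]) < 1))
    expect_true(all(abs(dTr[dys & !resc]) > 1))
})

test_that("zero effect size means nothing is truly dysregulated", {
    sim <- simulateRescueMatrices(RescueSimConfig(200, 50, 0.5,
                                                  effectSize = 0,
                                                  seed = 2))
    expect_length(sim$truth$dysregulated, 0L)
    expect_length(sim$truth$rescued, 0L)
    d <- rowMeans(log2(sim$vehicle + 1)) - rowMeans(log2(sim$wt + 1))
    expect_lt(max(abs(d)), 1)
})

test_that("psi matrices stay inside [0, 1]", {
    sim <- simulateRescueMatrices(RescueSimConfig(500, 50, 0.5,
                                                  effectSize = 0.4,
                                                  noiseSd = 0.15,
                                                  seed = 3),
                                  type = "psi")
    for (m in sim[c("wt", "vehicle", "treated")]) {
        expect_true(all(m >= 0 & m <= 1))
    }
    # dysregulated features are genuinely moved (clipping at the [0, 1]
    # boundary attenuates the realized offset for extreme baselines)
    dys <- rownames(sim$wt) %in% sim$truth$dysregulated
    d <- abs(rowMeans(sim$vehicle) - rowMeans(sim$wt))
    expect_gt(min(d[dys]), 0.1)
    expect_gt(mean(d[dys]), 0.25)
})
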