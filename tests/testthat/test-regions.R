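# Region compilation above the significance cutoff and the four-stage
# filter cascade.

test_that("adjacent significant nucleotides compile into one region", {
    p <- profileFromNeglog(c(0, 12, 12, 0))
    gr <- callRegions(p, FilterConfig())
    expect_length(gr, 1L)
    expect_equal(GenomicRanges::start(gr), 2L)
    expect_equal(GenomicRanges::end(gr), 3L)
    expect_equal(GenomicRanges::width(gr), 2L)
    expect_equal(gr$auc, 4)
    expect_equal(gr$max_neglog10p, 12)
})

test_that("an all-zero track yields an empty region set", {
    gr <- callRegions(profileFromNeglog(rep(0, 100)), FilterConfig())
    expect_length(gr, 0L)
    expect_true(all(c("auc", "reads_output") %in%
                    colnames(S4Vectors::mcols(gr))))
})

test_that("the cutoff is strict and masked nucleotides break regions", {
    # exactly at the cutoff does not pass ("> 10", not ">=")
    gr <- callRegions(profileFromNeglog(c(10, 10, 10)), FilterConfig())
    expect_length(gr, 0L)
    # a masked nucleotide splits a run at maxGap 0 but is bridged at 1
    p <- profileFromNeglog(c(12, 12, NA, 12, 12))
    expect_length(callRegions(p, FilterConfig(maxGap = 0L)), 2L)
    m <- callRegions(p, FilterConfig(maxGap = 1L))
    expect_length(m, 1L)
    expect_equal(GenomicRanges::width(m), 5L)
    # the bridged gap contributes nothing to the area score
    expect_equal(m$auc, 8)
})

test_that("region calling matches the brute-force scanner on random tracks", {
    set.seed(13)
    for (k in 1:50) {
        n <- sample(300:3000, 1)
        x <- pmax(0, rnorm(n, 8, 3))
        x[sample(n, n * 0.02)] <- NA
        for (gap in c(0L, 2L)) {
            cfg <- FilterConfig(maxGap = gap)
            gr <- callRegions(profileFromNeglog(x), cfg)
            oracle <- bruteRegions(x, 10, gap)
            expect_equal(GenomicRanges::start(gr),
                         unname(oracle[, "start"]))
            expect_equal(GenomicRanges::end(gr), unname(oracle[, "end"]))
            if (nrow(oracle)) {
                aucs <- vapply(seq_len(nrow(oracle)), function(i)
                    bruteAuc(x, oracle[i, 1], oracle[i, 2], 10),
                    numeric(1))
                expect_equal(gr$auc, aucs)
            }
        }
    }
})

test_that("raw-sum area mode sums the whole curve over the region", {
    x <- c(0, 12, 15, NA, 11, 0)
    gr <- callRegions(profileFromNeglog(x), FilterConfig(maxGap = 1L,
                                                         aucMode = "raw"))
    expect_length(gr, 1L)
    expect_equal(gr$auc, 12 + 15 + 0 + 11)
})

test_that("region read sums integrate the pooled tracks", {
    x <- c(0, 12, 12, 12, 0)
    iv <- ts(c(1, 2, 3, 4, 5))
    ov <- ts(c(10, 20, 30, 40, 50))
    gr <- callRegions(profileFromNeglog(x), FilterConfig(),
                      inputPooled = iv, outputPooled = ov)
    expect_equal(gr$reads_input, 2 + 3 + 4)
    expect_equal(gr$reads_output, 20 + 30 + 40)
})

test_that("the filter cascade passes exactly the designed regions", {
    fx <- cascadeFixture()
    inP <- poolReplicates(fx$inputReps)
    outP <- poolReplicates(fx$outputReps)
    regions <- callRegions(fx$profiles, FilterConfig(), inP, outP)
    expect_length(regions, 10L)
    res <- applyFilters(regions, fx$inputReps, fx$outputReps,
                        FilterConfig())
    passing <- as.character(GenomicRanges::seqnames(res$passing))
    expect_setequal(passing, c("r1", "r7", "r8", "r9"))

    # independent per-region recomputation of all four filter quantities
    v <- res$verdicts
    nrep <- 3L
    nI <- vapply(fx$inputReps, function(s)
        sum(vapply(s, function(t) sum(trackValues(t)), numeric(1))),
        numeric(1))
    nO <- vapply(fx$outputReps, function(s)
        sum(vapply(s, function(t) sum(trackValues(t)), numeric(1))),
        numeric(1))
    for (k in seq_along(v)) {
        ctg <- as.character(GenomicRanges::seqnames(v))[k]
        s <- GenomicRanges::start(v)[k]
        e <- GenomicRanges::end(v)[k]
        x <- neglog10p(fx$profiles[[ctg]])
        expect_equal(v$auc[k], bruteAuc(x, s, e, 10))
        len <- e - s + 1L
        so <- sum(trackValues(outP[[ctg]])[s:e])
        expect_equal(v$reads_output[k], so)
        fc <- vapply(seq_len(nrep), function(r) {
            si <- sum(trackValues(fx$inputReps[[r]][[ctg]])[s:e])
            sor <- sum(trackValues(fx$outputReps[[r]][[ctg]])[s:e])
            log2(((sor + 1) / nO[r]) / ((si + 1) / nI[r]))
        }, numeric(1))
        expect_equal(unname(v$log2fc[k, ]), fc)
        expect_equal(v$pass[k],
                     v$auc[k] >= 200 && len >= 400 && len <= 1000 &&
                     so >= 10 && all(fc >= 0.8))
    }
    # the designed failure modes trip the intended filters
    vd <- stats::setNames(seq_along(v),
                          as.character(GenomicRanges::seqnames(v)))
    expect_false(v$pass_auc[vd["r2"]])
    expect_false(v$pass_length[vd["r3"]])
    expect_false(v$pass_length[vd["r4"]])
    expect_false(v$pass_reads[vd["r5"]])
    expect_false(v$pass_replicates[vd["r6"]])
    expect_true(all(!v$pass_auc[vd["r10"]], !v$pass_length[vd["r10"]],
                    !v$pass_reads[vd["r10"]],
                    !v$pass_replicates[vd["r10"]]))
})

test_that("relaxing any single threshold never removes a passing region", {
    fx <- cascadeFixture()
    inP <- poolReplicates(fx$inputReps)
    outP <- poolReplicates(fx$outputReps)
    regions <- callRegions(fx$profiles, FilterConfig(), inP, outP)
    base <- applyFilters(regions, fx$inputReps, fx$outputReps,
                         FilterConfig())
    basePass <- as.character(GenomicRanges::seqnames(base$passing))
    relaxed <- list(FilterConfig(minAuc = 50),
                    FilterConfig(lengthMin = 100L),
                    FilterConfig(lengthMax = 2000L),
                    FilterConfig(minReads = 0),
                    FilterConfig(minLog2fc = 0.2))
    for (cfg in relaxed) {
        res <- applyFilters(regions, fx$inputReps, fx$outputReps, cfg)
        expect_true(all(basePass %in%
                        as.character(GenomicRanges::seqnames(res$passing))))
    }
})

test_that("replicate count mismatches are rejected", {
    fx <- cascadeFixture()
    regions <- callRegions(fx$profiles, FilterConfig(),
                           poolReplicates(fx$inputReps),
                           poolReplicates(fx$outputReps))
    expect_error(applyFilters(regions, fx$inputReps[1:2], fx$outputReps,
                              FilterConfig()), "equal length")
})
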