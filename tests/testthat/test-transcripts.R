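# Region-to-transcript assignment, transcript-level aggregation and
# cross-condition hit comparison.

test_that("regions are assigned to every overlapping transcript", {
    ann <- annotationGR(c("c1", "c1"), c(1, 801), c(1000, 1500),
                        transcript_id = c("tx1", "tx2"))
    reg <- GenomicRanges::GRanges("c1", IRanges::IRanges(101, 600),
                                  name = "regA")
    res <- assignRegions(reg, ann)
    expect_equal(res$assignments$transcript_id, "tx1")
    expect_false(any(res$assignments$ambiguous))
    expect_length(res$intergenic, 0L)

    # a region spanning both transcripts is assigned to both, ambiguous
    reg2 <- GenomicRanges::GRanges("c1", IRanges::IRanges(700, 900),
                                   name = "regB")
    res2 <- assignRegions(reg2, ann)
    expect_setequal(res2$assignments$transcript_id, c("tx1", "tx2"))
    expect_true(all(res2$assignments$ambiguous))

    # no overlap: reported intergenic
    reg3 <- GenomicRanges::GRanges("c1", IRanges::IRanges(1600, 1700))
    res3 <- assignRegions(reg3, ann)
    expect_equal(nrow(res3$assignments), 0L)
    expect_length(res3$intergenic, 1L)
})

test_that("assignment matches the all-pairs overlap oracle", {
    set.seed(23)
    for (k in 1:10) {
        nr <- sample(5:20, 1)
        nt <- sample(3:10, 1)
        ctgs <- paste0("c", sample(1:3, nt, replace = TRUE))
        tstart <- sample(1:2000, nt)
        tdf <- data.frame(contig = ctgs, start = tstart,
                          end = tstart + sample(200:1500, nt))
        ann <- annotationGR(tdf$contig, tdf$start, tdf$end,
                            transcript_id = paste0("tx", seq_len(nt)))
        rstart <- sample(1:3000, nr)
        rdf <- data.frame(contig = paste0("c", sample(1:3, nr,
                                                      replace = TRUE)),
                          start = rstart, end = rstart + sample(50:800, nr))
        reg <- GenomicRanges::GRanges(rdf$contig,
                                      IRanges::IRanges(rdf$start, rdf$end))
        got <- assignRegions(reg, ann)$assignments
        oracle <- bruteOverlaps(rdf, tdf)
        if (is.null(oracle)) {
            expect_equal(nrow(got), 0L)
        } else {
            gotPairs <- paste(got$region_index, got$transcript_id)
            oraclePairs <- paste(oracle[, 1],
                                 paste0("tx", oracle[, 2]))
            expect_setequal(gotPairs, oraclePairs)
        }
    }
})

# shared fixture for aggregation: transcript c1:[1,100] with two regions
# holding output reads {30, 50} and input reads {20, 20}; ballast makes
# the two library sizes equal
aggFixture <- function() {
    ann <- annotationGR("c1", 1, 100, transcript_id = "tx1")
    iv <- numeric(100); ov <- numeric(100)
    iv[11:20] <- 2;  ov[11:20] <- 3    # region 1: in 20, out 30
    iv[31:40] <- 2;  ov[31:40] <- 5    # region 2: in 20, out 50
    iv[51:90] <- 2                     # ballast input  (+80 -> 120)
    ov[61:70] <- 4                     # ballast output (+40 -> 120)
    reg <- callRegions(
        profileFromNeglog(
            replace(numeric(100), c(11:20, 31:40), 12), contig = "c1"),
        FilterConfig(), ts(iv, "c1"), ts(ov, "c1"))
    list(ann = ann, input = ts(iv, "c1"), output = ts(ov, "c1"),
         regions = reg)
}

test_that("multi-region transcripts sum reads before normalization", {
    fx <- aggFixture()
    expect_length(fx$regions, 2L)
    asn <- assignRegions(fx$regions, fx$ann)
    # pseudocount 0: the hand-computable case, log2(80/40) = 1
    hits <- aggregateTranscripts(asn, fx$regions, fx$input, fx$output,
                                 pseudocount = 0)
    expect_equal(nrow(hits), 1L)
    expect_equal(hits$n_regions, 2L)
    expect_equal(hits$reads_input, 40)
    expect_equal(hits$reads_output, 80)
    expect_equal(hits$reads_input_norm, 40 / 120 * 1e6)
    expect_equal(hits$log2_enrichment, 1)
    expect_true(hits$passing)
    # default pseudocount 1 on the raw sums: log2(81/41)
    hits1 <- aggregateTranscripts(asn, fx$regions, fx$input, fx$output,
                                  pseudocount = 1)
    expect_equal(hits1$log2_enrichment, log2(81 / 41))
})

test_that("per-region reads are conserved in the transcript aggregate", {
    fx <- aggFixture()
    asn <- assignRegions(fx$regions, fx$ann)
    hits <- aggregateTranscripts(asn, fx$regions, fx$input, fx$output)
    expect_equal(hits$reads_output, sum(fx$regions$reads_output))
    expect_equal(hits$reads_input, sum(fx$regions$reads_input))
})

test_that("scaling every track by a constant leaves enrichment unchanged", {
    fx <- aggFixture()
    asn <- assignRegions(fx$regions, fx$ann)
    base <- aggregateTranscripts(asn, fx$regions, fx$input, fx$output,
                                 pseudocount = 0)
    scale <- function(s, f) {
        s[[1]]@values <- s[[1]]@values * f
        s
    }
    regScaled <- fx$regions
    regScaled$reads_input <- regScaled$reads_input * 7
    regScaled$reads_output <- regScaled$reads_output * 7
    scaled <- aggregateTranscripts(asn, regScaled, scale(fx$input, 7),
                                   scale(fx$output, 7), pseudocount = 0)
    expect_equal(scaled$log2_enrichment, base$log2_enrichment)
})

test_that("a balanced transcript is not called a hit", {
    ann <- annotationGR("c1", 1, 60, transcript_id = "tx1")
    iv <- replace(numeric(60), 11:20, 4)
    reg <- callRegions(profileFromNeglog(replace(numeric(60), 11:20, 12),
                                         contig = "c1"),
                       FilterConfig(), ts(iv, "c1"), ts(iv, "c1"))
    hits <- aggregateTranscripts(assignRegions(reg, ann), reg,
                                 ts(iv, "c1"), ts(iv, "c1"),
                                 pseudocount = 0)
    expect_equal(hits$log2_enrichment, 0)
    expect_false(hits$passing)
})

test_that("condition comparison splits exclusive and shared hits", {
    mk <- function(ids, l2) S4Vectors::DataFrame(
        transcript_id = ids, gene_id = sub("tx", "gene", ids),
        n_regions = 1L, ambiguous = FALSE, reads_input = 1,
        reads_output = 1, reads_input_norm = 1, reads_output_norm = 1,
        log2_enrichment = l2, passing = l2 >= 0.8)
    a <- mk(c("tx1", "tx2"), c(1.2, 0.91))
    b <- mk(c("tx2", "tx3"), c(0.29, 1.5))
    cmp <- compareConditions(a, b, labels = c("dm1", "wt"))
    expect_setequal(cmp$onlyA$transcript_id, c("tx1", "tx2"))
    expect_equal(cmp$onlyB$transcript_id, "tx3")
    expect_equal(nrow(cmp$shared), 0L)
    # both conditions' values sit side by side
    i <- match("tx2", cmp$all$transcript_id)
    expect_equal(cmp$all$log2_dm1[i], 0.91)
    expect_equal(cmp$all$log2_wt[i], 0.29)
    # identical hit lists give empty exclusive sets
    cmp2 <- compareConditions(a, a)
    expect_equal(nrow(cmp2$onlyA), 0L)
    expect_equal(nrow(cmp2$onlyB), 0L)
    expect_setequal(cmp2$shared$transcript_id, c("tx1", "tx2"))
})
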