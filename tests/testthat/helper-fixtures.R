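# Small in-code fixture builders shared across test files.

# One-contig coverage set from a plain numeric vector.
ts <- function(values, contig = "chrT") {
    stats::setNames(list(CoverageTrack(contig, values)), contig)
}

# EnrichmentProfile built directly from a -log10 p vector (ratio slot is
# irrelevant for region calling and set to 1).
profileFromNeglog <- function(neglog, contig = "chrT", mask = NULL) {
    if (is.null(mask))
        mask <- !is.na(neglog)
    new("EnrichmentProfile", contig = contig, offset = 0L,
        ratio = rep(1, length(neglog)),
        neglog10p = as.numeric(neglog), mask = mask)
}

# A minimal GRanges transcript annotation from parallel vectors.
annotationGR <- function(contig, start, end, transcript_id = contig,
                         gene_id = sub("^tx", "gene", transcript_id)) {
    GenomicRanges::GRanges(
        seqnames = contig,
        ranges = IRanges::IRanges(start = start, end = end),
        strand = "+",
        transcript_id = transcript_id, gene_id = gene_id)
}

# Crafted cascade fixture: 10 regions on 10 contigs plus a ballast contig
# that equalizes per-replicate library sizes between input and output.
# Region k sits at [501, 500 + len_k] on contig "r<k>"; profile values and
# coverage are constant inside the region, zero outside. Returns profiles,
# replicate track lists, and the per-region design table.
cascadeFixture <- function() {
    design <- data.frame(
        id = paste0("r", 1:10),
        len = c(500L, 500L, 350L, 1200L, 500L, 500L, 400L, 1000L, 400L,
                200L),
        neglog = c(12, 10.2, 12, 12, 12, 12, 12, 12, 10.5, 10.1),
        inputVal = c(5, 5, 5, 5, 5, 5, 5, 5, 5, 5),
        # per-replicate output value (rep1, rep2, rep3)
        out1 = c(10, 10, 10, 10, 0, 10, 10, 10, 10, 0),
        out2 = c(10, 10, 10, 10, 0, 10, 10, 10, 10, 0),
        out3 = c(10, 10, 10, 10, 0, 7, 10, 10, 10, 0),
        stringsAsFactors = FALSE)
    contigLen <- 2000L
    nrep <- 3L
    profiles <- list()
    inputReps <- rep(list(list()), nrep)
    outputReps <- rep(list(list()), nrep)
    for (k in seq_len(nrow(design))) {
        ctg <- design$id[k]
        idx <- 501:(500 + design$len[k])
        nl <- numeric(contigLen)
        nl[idx] <- design$neglog[k]
        profiles[[ctg]] <- profileFromNeglog(nl, contig = ctg)
        for (r in seq_len(nrep)) {
            iv <- numeric(contigLen)
            iv[idx] <- design$inputVal[k]
            ov <- numeric(contigLen)
            ov[idx] <- design[[paste0("out", r)]][k]
            inputReps[[r]][[ctg]] <- CoverageTrack(ctg, iv)
            outputReps[[r]][[ctg]] <- CoverageTrack(ctg, ov)
        }
    }
    # ballast contig equalizes library sizes so depth normalization is a
    # no-op and per-replicate fold changes are hand-computable
    for (r in seq_len(nrep)) {
        inTot <- sum(vapply(inputReps[[r]], function(t) sum(trackValues(t)),
                            numeric(1)))
        outTot <- sum(vapply(outputReps[[r]],
                             function(t) sum(trackValues(t)), numeric(1)))
        tot <- max(inTot, outTot)
        bl <- 1000L
        inputReps[[r]]$ballast <- CoverageTrack("ballast",
            rep((tot - inTot) / bl, bl))
        outputReps[[r]]$ballast <- CoverageTrack("ballast",
            rep((tot - outTot) / bl, bl))
        profiles$ballast <- profileFromNeglog(numeric(bl),
                                              contig = "ballast")
    }
    list(design = design, profiles = profiles, inputReps = inputReps,
         outputReps = outputReps, contigLen = contigLen)
}
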