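# Synthetic Chem-CLIP-Seq data with known ground truth. Each transcript is
# placed on its own contig (named by transcript_id), which keeps interval
# logic trivial while remaining valid GTF.

#' Generate a toy transcript annotation
#'
#' Draws `nTranscripts` transcript lengths uniformly from
#' `lengthRange(config)` and places each transcript on its own contig named
#' after the transcript. Deterministic for a given seed.
#'
#' @param config a [SimulationConfig-class].
#' @return `GRanges` annotation with `transcript_id` and `gene_id`
#'   metadata and seqlengths set to the transcript lengths.
#' @examples
#' generateAnnotation(SimulationConfig(nTranscripts = 3, seed = 7))
#' @export
generateAnnotation <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    methods::validObject(config)
    n <- config@nTranscripts
    rng <- config@lengthRange
    lens <- withSeed(config@seed,
        if (rng[1L] == rng[2L]) rep.int(rng[1L], n)
        else sample(seq.int(rng[1L], rng[2L]), n, replace = TRUE))
    ids <- sprintf("tx%04d", seq_len(n))
    gr <- GenomicRanges::GRanges(
        seqnames = ids,
        ranges = IRanges::IRanges(start = 1L, width = lens),
        strand = "+",
        transcript_id = ids,
        gene_id = sprintf("gene%04d", seq_len(n)),
        seqlengths = stats::setNames(as.integer(lens), ids))
    gr
}

# spike/repeat interval bounds, checked against the host transcript
.hostWidth <- function(annotation, txid, what) {
    i <- match(txid, annotation$transcript_id)
    if (is.na(i))
        stop(sprintf("%s refers to unknown transcript '%s'", what, txid),
             call. = FALSE)
    GenomicRanges::width(annotation)[i]
}

#' Place random ground-truth spikes on an annotation
#'
#' Chooses `n` distinct transcripts and places one enriched interval on
#' each, with lengths drawn uniformly from `lengthRange` and positions
#' uniform within the transcript. Deterministic for a given seed.
#'
#' @param annotation `GRanges` from [generateAnnotation()].
#' @param n number of spikes.
#' @param fold true enrichment multiplier of every spike.
#' @param lengthRange spike length range in nt.
#' @param seed RNG seed.
#' @return list of [SpikeSpec-class].
#' @export
randomSpikes <- function(annotation, n, fold = 6, lengthRange = c(500L, 800L),
                         seed = 1L) {
    wid <- GenomicRanges::width(annotation)
    eligible <- which(wid >= max(lengthRange))
    if (length(eligible) < n)
        stop("not enough transcripts long enough to host spikes",
             call. = FALSE)
    withSeed(seed, {
        hosts <- sample(eligible, n)
        lens <- sample(seq.int(lengthRange[1L], lengthRange[2L]), n,
                       replace = TRUE)
        lapply(seq_len(n), function(k) {
            L <- wid[hosts[k]]
            s <- sample.int(L - lens[k] + 1L, 1L)
            SpikeSpec(annotation$transcript_id[hosts[k]], s,
                      s + lens[k] - 1L, fold)
        })
    })
}

#' Simulate replicate coverage tracks for one condition
#'
#' Generative model: at every nucleotide, input coverage is
#' Poisson(`depthInput`); the true enrichment ratio is
#' exp(Normal(`backgroundMu`, `backgroundSigma`^2)), multiplied by the
#' spike `fold` inside spiked intervals; output coverage is
#' Poisson(depth x true ratio). Inside the repeat locus the Poisson means
#' of *both* sides are multiplied by (1 - dropoutFraction), emulating
#' unalignable pure-repeat reads. All draws are independent per replicate
#' and nucleotide, and deterministic for a given seed.
#'
#' @param annotation `GRanges` from [generateAnnotation()].
#' @param config a [SimulationConfig-class]; every spike must lie within
#'   its host transcript.
#' @param returnTruth if TRUE, attach the latent true-ratio field (one
#'   numeric vector per contig per replicate) as attribute `"truth"`.
#' @return list with elements `input` and `output`, each a list of
#'   `nReplicates` coverage sets (named lists of [CoverageTrack-class]).
#' @examples
#' cfg <- SimulationConfig(nTranscripts = 2, lengthRange = c(500L, 500L),
#'                         seed = 3)
#' cov <- simulateCoverage(generateAnnotation(cfg), cfg)
#' length(cov$input)   # 3 replicates
#' @export
simulateCoverage <- function(annotation, config, returnTruth = FALSE) {
    stopifnot(is(annotation, "GRanges"), is(config, "SimulationConfig"))
    methods::validObject(config)
    wid <- stats::setNames(GenomicRanges::width(annotation),
                           annotation$transcript_id)
    for (sp in config@spikes)
        if (sp@end > .hostWidth(annotation, sp@transcriptId, "spike"))
            stop(sprintf("spike [%d, %d] outside transcript '%s' (length %d)",
                         sp@start, sp@end, sp@transcriptId,
                         .hostWidth(annotation, sp@transcriptId, "spike")),
                 call. = FALSE)
    rp <- config@repeatLocus
    if (!is.null(rp) &&
        rp@end > .hostWidth(annotation, rp@transcriptId, "repeat locus"))
        stop("repeat locus outside its host transcript", call. = FALSE)

    nrep <- config@nReplicates
    contigs <- as.character(GenomicRanges::seqnames(annotation))
    spikesByTx <- split(config@spikes,
                        vapply(config@spikes, function(s) s@transcriptId,
                               character(1L)))
    input <- rep(list(list()), nrep)
    output <- rep(list(list()), nrep)
    truth <- if (returnTruth) rep(list(list()), nrep) else NULL

    withSeed(config@seed, {
        for (ctg in contigs) {
            L <- wid[[ctg]]
            foldVec <- rep.int(1, L)
            for (sp in spikesByTx[[ctg]])
                foldVec[sp@start:sp@end] <- foldVec[sp@start:sp@end] * sp@fold
            keepVec <- rep.int(1, L)
            if (!is.null(rp) && rp@transcriptId == ctg)
                keepVec[rp@start:rp@end] <- 1 - rp@dropoutFraction
            for (r in seq_len(nrep)) {
                rho <- exp(stats::rnorm(L, config@backgroundMu,
                                        config@backgroundSigma)) * foldVec
                lamI <- config@depthInput * keepVec
                lamO <- config@depthInput * rho * keepVec
                input[[r]][[ctg]] <- CoverageTrack(ctg,
                    stats::rpois(L, lamI))
                output[[r]][[ctg]] <- CoverageTrack(ctg,
                    stats::rpois(L, lamO))
                if (returnTruth)
                    truth[[r]][[ctg]] <- rho
            }
        }
    })
    out <- list(input = input, output = output)
    if (returnTruth)
        attr(out, "truth") <- truth
    out
}

#' Ground-truth spike intervals as GRanges
#'
#' @param config a [SimulationConfig-class] (or a list of
#'   [SpikeSpec-class]).
#' @return `GRanges` with `name` (host transcript) and `fold` columns.
#' @export
spikeRanges <- function(config) {
    spikes <- if (is(config, "SimulationConfig")) config@spikes else config
    if (length(spikes) == 0L)
        return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(
        seqnames = vapply(spikes, function(s) s@transcriptId, character(1L)),
        ranges = IRanges::IRanges(
            start = vapply(spikes, function(s) s@start, integer(1L)),
            end = vapply(spikes, function(s) s@end, integer(1L))),
        name = vapply(spikes, function(s) s@transcriptId, character(1L)),
        fold = vapply(spikes, function(s) s@fold, numeric(1L)))
}

# Serializable view of a SimulationConfig, for the YAML sidecar.
.configAsList <- function(config) {
    list(nTranscripts = config@nTranscripts,
         lengthRange = as.integer(config@lengthRange),
         nReplicates = config@nReplicates,
         depthInput = config@depthInput,
         backgroundMu = config@backgroundMu,
         backgroundSigma = config@backgroundSigma,
         spikes = lapply(config@spikes, function(s)
             list(transcriptId = s@transcriptId, start = s@start,
                  end = s@end, fold = s@fold)),
         repeatLocus = if (is.null(config@repeatLocus)) NULL else
             list(transcriptId = config@repeatLocus@transcriptId,
                  start = config@repeatLocus@start,
                  end = config@repeatLocus@end,
                  dropoutFraction = config@repeatLocus@dropoutFraction),
         seed = config@seed)
}

#' Write a simulated condition to disk
#'
#' Writes the annotation (GTF), per-replicate input/output BedGraphs, the
#' ground-truth spike BED and a YAML copy of the configuration into `dir`.
#'
#' @param dir output directory (created if needed).
#' @param annotation `GRanges` annotation.
#' @param coverage result of [simulateCoverage()].
#' @param config the [SimulationConfig-class] used.
#' @param condition label used in file names.
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(dir, annotation, coverage, config,
                            condition = "cond") {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeGtf(annotation, file.path(dir, "annotation.gtf"))
    for (r in seq_along(coverage$input)) {
        writeBedGraph(coverage$input[[r]],
                      file.path(dir, sprintf("%s_input_rep%d.bedgraph",
                                             condition, r)))
        writeBedGraph(coverage$output[[r]],
                      file.path(dir, sprintf("%s_output_rep%d.bedgraph",
                                             condition, r)))
    }
    writeBed(spikeRanges(config), file.path(dir, "truth_spikes.bed"))
    yaml::write_yaml(.configAsList(config), file.path(dir, "config.yaml"))
    invisible(dir)
}
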