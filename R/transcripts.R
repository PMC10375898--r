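# Map passing regions to transcripts, aggregate multi-region transcripts
# into per-million-normalized enrichment, and compare hit lists across
# conditions.

#' Assign regions to overlapping transcripts
#'
#' A region is assigned to every transcript whose span it overlaps by at
#' least one nucleotide; regions overlapping more than one transcript are
#' flagged ambiguous (and count toward each, so no signal is silently
#' dropped). Regions overlapping no transcript are reported as intergenic.
#'
#' @param regions `GRanges` of regions.
#' @param annotation `GRanges` transcript annotation (from [readGtf()] or
#'   [generateAnnotation()]).
#' @return list with `assignments` (a `DataFrame` with columns
#'   `region_id`, `transcript_id`, `gene_id`, `ambiguous`) and
#'   `intergenic` (`GRanges` of unassigned regions).
#' @export
assignRegions <- function(regions, annotation) {
    stopifnot(is(regions, "GRanges"), is(annotation, "GRanges"))
    hits <- GenomicRanges::findOverlaps(regions, annotation,
                                        minoverlap = 1L,
                                        ignore.strand = TRUE)
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    nPer <- tabulate(q, nbins = length(regions))
    assignments <- S4Vectors::DataFrame(
        region_id = if (!is.null(regions$name)) regions$name[q] else
            as.character(q),
        region_index = q,
        transcript_id = annotation$transcript_id[s],
        gene_id = annotation$gene_id[s],
        ambiguous = nPer[q] > 1L)
    list(assignments = assignments,
         intergenic = regions[nPer == 0L])
}

#' Aggregate assigned regions into transcript-level enrichment
#'
#' For every transcript with at least one assigned region, raw reads are
#' summed over its regions per library side (each region counted once per
#' transcript), divided by the total library reads and scaled to reads
#' per million; the transcript's enrichment is
#' log2((output_norm + pc') / (input_norm + pc')) where pc' is the
#' pseudocount normalized the same way. A transcript is a hit when its
#' log2 enrichment reaches `hitThreshold`.
#'
#' @param assignment result of [assignRegions()] (or its `assignments`
#'   element).
#' @param regions the `GRanges` the assignment was computed from, with
#'   `reads_input`/`reads_output` populated.
#' @param inputPooled,outputPooled pooled coverage sets (for library
#'   totals).
#' @param hitThreshold log2 enrichment required to call a hit
#'   (default 0.8).
#' @param pseudocount added to raw summed reads on both sides
#'   (default 1).
#' @return `DataFrame` with one row per transcript: `transcript_id`,
#'   `gene_id`, `n_regions`, `ambiguous`, raw and per-million read sums,
#'   `log2_enrichment` and `passing`, sorted by decreasing enrichment.
#' @export
aggregateTranscripts <- function(assignment, regions, inputPooled,
                                 outputPooled, hitThreshold = 0.8,
                                 pseudocount = 1) {
    if (is.list(assignment) && !is.null(assignment$assignments))
        assignment <- assignment$assignments
    nI <- .librarySize(.checkTrackSet(inputPooled, "inputPooled"))
    nO <- .librarySize(.checkTrackSet(outputPooled, "outputPooled"))
    if (nI <= 0 || nO <= 0)
        stop("zero total library reads", call. = FALSE)
    if (nrow(assignment) == 0L)
        return(S4Vectors::DataFrame(
            transcript_id = character(), gene_id = character(),
            n_regions = integer(), ambiguous = logical(),
            reads_input = numeric(), reads_output = numeric(),
            reads_input_norm = numeric(), reads_output_norm = numeric(),
            log2_enrichment = numeric(), passing = logical()))
    idx <- assignment$region_index
    ri <- regions$reads_input[idx]
    ro <- regions$reads_output[idx]
    if (anyNA(ri) || anyNA(ro))
        stop("regions lack read sums; call callRegions() with pooled tracks",
             call. = FALSE)
    tx <- assignment$transcript_id
    sumBy <- function(v) as.numeric(tapply(v, tx, sum))
    ids <- sort(unique(tx))
    si <- sumBy(ri)[match(ids, sort(unique(tx)))]
    so <- sumBy(ro)[match(ids, sort(unique(tx)))]
    nReg <- as.integer(table(tx)[ids])
    amb <- as.logical(tapply(assignment$ambiguous, tx, any)[ids])
    gene <- assignment$gene_id[match(ids, tx)]
    inNorm <- si / nI * 1e6
    outNorm <- so / nO * 1e6
    pcI <- pseudocount / nI * 1e6
    pcO <- pseudocount / nO * 1e6
    l2 <- log2((outNorm + pcO) / (inNorm + pcI))
    res <- S4Vectors::DataFrame(
        transcript_id = ids, gene_id = gene, n_regions = nReg,
        ambiguous = amb, reads_input = si, reads_output = so,
        reads_input_norm = inNorm, reads_output_norm = outNorm,
        log2_enrichment = l2, passing = l2 >= hitThreshold)
    res[order(-res$log2_enrichment, res$transcript_id), ]
}

#' Compare transcript hit lists between two conditions
#'
#' Splits the union of two hit tables into condition-exclusive and shared
#' hits, with both conditions' log2 enrichment side by side (NA where a
#' transcript received no region in a condition).
#'
#' @param hitsA,hitsB `DataFrame`s from [aggregateTranscripts()].
#' @param labels length-2 character used in column names.
#' @return list of `DataFrame`s `onlyA`, `onlyB`, `shared` (passing hits
#'   only) and `all` (every transcript seen in either condition).
#' @export
compareConditions <- function(hitsA, hitsB, labels = c("A", "B")) {
    ids <- sort(union(hitsA$transcript_id, hitsB$transcript_id))
    ia <- match(ids, hitsA$transcript_id)
    ib <- match(ids, hitsB$transcript_id)
    gene <- ifelse(is.na(ia), hitsB$gene_id[ib], hitsA$gene_id[ia])
    passA <- !is.na(ia) & hitsA$passing[ia]
    passB <- !is.na(ib) & hitsB$passing[ib]
    all <- S4Vectors::DataFrame(
        transcript_id = ids, gene_id = gene,
        log2_A = hitsA$log2_enrichment[ia],
        log2_B = hitsB$log2_enrichment[ib],
        passing_A = passA, passing_B = passB)
    colnames(all) <- c("transcript_id", "gene_id",
                       paste0("log2_", labels[1L]),
                       paste0("log2_", labels[2L]),
                       paste0("passing_", labels[1L]),
                       paste0("passing_", labels[2L]))
    list(onlyA = all[passA & !passB, ],
         onlyB = all[passB & !passA, ],
         shared = all[passA & passB, ],
         all = all)
}
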