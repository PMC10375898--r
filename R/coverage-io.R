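# Readers and writers for the standard formats the pipeline touches:
# BedGraph coverage, GTF transcript annotations, BED region output and TSV
# result tables. Readers reject malformed input rather than repairing it.

#' Read a BedGraph file into dense coverage tracks
#'
#' Parses a 4-column BedGraph (contig, start, end, value; 0-based
#' half-open) into one dense [CoverageTrack-class] per contig, expanding
#' each record to per-nucleotide values and filling gaps with 0. Records
#' for a contig may appear in any order but must not overlap. `track`
#' header lines and `#` comments are ignored.
#'
#' @param path file to read.
#' @param integer if TRUE (default), values must be non-negative integers
#'   (raw read coverage); set FALSE for derived float tracks (ratios,
#'   -log10 p).
#' @return Named list of [CoverageTrack-class] objects, keyed by contig,
#'   each starting at offset 0 and extending to the largest end coordinate
#'   seen for that contig.
#' @examples
#' f <- tempfile(fileext = ".bedgraph")
#' writeLines(c("chrT\t0\t2\t1", "chrT\t4\t6\t2"), f)
#' trackValues(readBedGraph(f)$chrT)   # 1 1 0 0 2 2
#' @seealso [writeBedGraph()]
#' @export
readBedGraph <- function(path, integer = TRUE) {
    if (!file.exists(path))
        stop("no such file: ", path, call. = FALSE)
    lines <- readLines(path)
    keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
    lineno <- which(keep)
    lines <- lines[keep]
    if (length(lines) == 0L)
        return(structure(list(), names = character()))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != 4L))
        stop(sprintf("malformed BedGraph line %d in '%s': expected 4 fields, got %d",
                     lineno[which(nf != 4L)[1L]], path, nf[nf != 4L][1L]),
             call. = FALSE)
    m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
    contig <- m[, 1L]
    start <- suppressWarnings(as.numeric(m[, 2L]))
    end <- suppressWarnings(as.numeric(m[, 3L]))
    value <- suppressWarnings(as.numeric(m[, 4L]))
    bad <- which(is.na(start) | is.na(end) | is.na(value) |
                 start < 0 | end <= start)
    if (length(bad))
        stop(sprintf("malformed BedGraph line %d in '%s': bad coordinates or value",
                     lineno[bad[1L]], path), call. = FALSE)
    neg <- which(value < 0)
    if (length(neg))
        stop(sprintf("negative value on BedGraph line %d in '%s'",
                     lineno[neg[1L]], path), call. = FALSE)
    if (integer) {
        nonint <- which(value != floor(value))
        if (length(nonint))
            stop(sprintf("non-integer coverage on BedGraph line %d in '%s' (use integer = FALSE for derived tracks)",
                         lineno[nonint[1L]], path), call. = FALSE)
    }
    out <- list()
    for (ctg in unique(contig)) {
        i <- which(contig == ctg)
        L <- max(end[i])
        vals <- numeric(L)
        seen <- logical(L)
        for (j in i) {
            idx <- (start[j] + 1L):end[j]
            if (any(seen[idx]))
                stop(sprintf("overlapping BedGraph records at line %d in '%s' (contig '%s')",
                             lineno[j], path, ctg), call. = FALSE)
            seen[idx] <- TRUE
            vals[idx] <- value[j]
        }
        out[[ctg]] <- CoverageTrack(ctg, vals, offset = 0L)
    }
    out
}

#' Write coverage tracks as BedGraph
#'
#' Writes a set of [CoverageTrack-class] objects as 4-column BedGraph,
#' merging equal-valued adjacent nucleotides into single records and
#' omitting zero runs (read back as gaps, i.e. zeros). Round-tripping
#' through [readBedGraph()] therefore reproduces the dense values exactly.
#'
#' @param tracks a [CoverageTrack-class] or a (named) list of them.
#' @param path output file.
#' @param digits significant digits for float tracks.
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(tracks, path, digits = 10L) {
    if (is(tracks, "CoverageTrack"))
        tracks <- stats::setNames(list(tracks), contigName(tracks))
    tracks <- .checkTrackSet(tracks)
    con <- file(path, open = "wt")
    on.exit(close(con))
    for (ctg in names(tracks)) {
        tr <- tracks[[ctg]]
        v <- trackValues(tr)
        if (length(v) == 0L)
            next
        r <- rle(v)
        ends <- cumsum(r$lengths) + trackOffset(tr)
        starts <- ends - r$lengths
        nz <- r$values != 0
        if (!any(nz))
            next
        writeLines(sprintf("%s\t%d\t%d\t%s", ctg,
                           as.integer(starts[nz]), as.integer(ends[nz]),
                           formatC(r$values[nz], digits = digits,
                                   format = "g")), con)
    }
    invisible(path)
}

#' Read a transcript annotation from GTF
#'
#' Imports `transcript` features from a GTF file (1-based closed
#' coordinates, converted by rtracklayer) into a `GRanges` with
#' `transcript_id` and `gene_id` metadata columns.
#'
#' @param path GTF file.
#' @return `GRanges` of transcripts.
#' @seealso [writeGtf()]
#' @export
readGtf <- function(path) {
    if (!file.exists(path))
        stop("no such file: ", path, call. = FALSE)
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[!is.na(gr$type) & gr$type == "transcript"]
    if (length(gr) == 0L)
        stop("no 'transcript' features in '", path, "'", call. = FALSE)
    if (is.null(gr$transcript_id) || anyNA(gr$transcript_id))
        stop("GTF transcripts in '", path,
             "' lack mandatory 'transcript_id' attributes", call. = FALSE)
    if (is.null(gr$gene_id) || anyNA(gr$gene_id))
        stop("GTF transcripts in '", path,
             "' lack mandatory 'gene_id' attributes", call. = FALSE)
    if (anyDuplicated(gr$transcript_id))
        stop("duplicate transcript_id in '", path, "'", call. = FALSE)
    S4Vectors::mcols(gr) <- S4Vectors::mcols(gr)[, c("transcript_id",
                                                     "gene_id")]
    gr
}

#' Write a transcript annotation as GTF
#'
#' @param annotation `GRanges` with `transcript_id` and `gene_id` columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGtf <- function(annotation, path) {
    if (!is(annotation, "GRanges"))
        stop("'annotation' must be a GRanges", call. = FALSE)
    if (is.null(annotation$transcript_id) || is.null(annotation$gene_id))
        stop("'annotation' needs 'transcript_id' and 'gene_id' columns",
             call. = FALSE)
    gr <- annotation
    gr$type <- "transcript"
    gr$source <- "chemclipseq"
    rtracklayer::export(gr, path, format = "gtf")
    invisible(path)
}

#' Write regions as BED
#'
#' Exports a `GRanges` of regions as BED (0-based half-open on disk, the
#' conversion handled by rtracklayer). An empty `GRanges` yields a valid
#' empty file.
#'
#' @param regions `GRanges`; a `name` metadata column is used for the BED
#'   name field when present.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeBed <- function(regions, path) {
    if (!is(regions, "GRanges"))
        stop("'regions' must be a GRanges", call. = FALSE)
    gr <- regions
    keep <- intersect(c("name", "score"), colnames(S4Vectors::mcols(gr)))
    S4Vectors::mcols(gr) <- S4Vectors::mcols(gr)[, keep, drop = FALSE]
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}

#' Write a result table as TSV with provenance header
#'
#' Writes a data.frame (or `DataFrame`) as tab-separated text, optionally
#' preceded by `# key=value` provenance comment lines. Numeric formatting
#' is plain `write.table` formatting, so identical inputs give
#' byte-identical files.
#'
#' @param table data.frame or DataFrame.
#' @param path output file.
#' @param header named character/list echoed as `# key=value` lines.
#' @return `path`, invisibly.
#' @seealso [readResultsTsv()]
#' @export
writeResultsTsv <- function(table, path, header = NULL) {
    df <- as.data.frame(table)
    con <- file(path, open = "wt")
    on.exit(close(con))
    if (length(header))
        writeLines(sprintf("# %s=%s", names(header),
                           vapply(header, function(x)
                               paste(format(x), collapse = ","),
                               character(1L))), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Read a TSV written by [writeResultsTsv()]
#'
#' @param path file to read.
#' @return data.frame (comment lines skipped).
#' @export
readResultsTsv <- function(path) {
    utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                      stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read/write feature-by-replicate matrices
#'
#' TSV matrices with features in rows (first column `feature_id`) and
#' replicates in columns, as used by the rescue-classification module.
#'
#' @param path file to read or write.
#' @return `readMatrixTsv`: numeric matrix with feature rownames.
#' @export
readMatrixTsv <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            comment.char = "#", stringsAsFactors = FALSE,
                            check.names = FALSE)
    if (ncol(df) < 2L)
        stop("matrix TSV '", path,
             "' needs a feature_id column plus >= 1 replicate column",
             call. = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m))
        stop("non-numeric replicate values in '", path, "'", call. = FALSE)
    rownames(m) <- as.character(df[[1L]])
    m
}

#' @rdname readMatrixTsv
#' @param m numeric matrix with feature rownames.
#' @export
writeMatrixTsv <- function(m, path) {
    df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}
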