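# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic generators in the package go through this so
# that identical config + seed gives bit-identical output.
withSeed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("'seed' must be a single integer", call. = FALSE)
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has)
        old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has)
            assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

.assertCount <- function(x, name, min = 1L) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
        x != as.integer(x))
        stop(sprintf("'%s' must be a single integer >= %d", name, min),
             call. = FALSE)
    invisible(as.integer(x))
}

.assertFraction <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
        stop(sprintf("'%s' must be a single value in [0, 1]", name),
             call. = FALSE)
    invisible(as.numeric(x))
}

# A coverage "set" is a named list of CoverageTrack objects keyed by contig.
.checkTrackSet <- function(x, name = "tracks") {
    if (!is.list(x) || length(x) == 0L)
        stop(sprintf("'%s' must be a non-empty list of CoverageTrack objects",
                     name), call. = FALSE)
    ok <- vapply(x, is, logical(1L), class2 = "CoverageTrack")
    if (!all(ok))
        stop(sprintf("'%s' must contain only CoverageTrack objects", name),
             call. = FALSE)
    contigs <- vapply(x, contigName, character(1L))
    if (is.null(names(x)))
        names(x) <- contigs
    if (!identical(unname(names(x)), unname(contigs)))
        stop(sprintf("names of '%s' must equal the contained contig names",
                     name), call. = FALSE)
    if (anyDuplicated(contigs))
        stop(sprintf("duplicate contigs in '%s'", name), call. = FALSE)
    invisible(x)
}

# Elementwise compatibility of two sets (same contigs, same spans).
.checkMatchedSets <- function(a, b, nameA = "input", nameB = "output") {
    a <- .checkTrackSet(a, nameA)
    b <- .checkTrackSet(b, nameB)
    if (!setequal(names(a), names(b)))
        stop(sprintf("'%s' and '%s' cover different contigs", nameA, nameB),
             call. = FALSE)
    b <- b[names(a)]
    for (ctg in names(a)) {
        if (trackOffset(a[[ctg]]) != trackOffset(b[[ctg]]) ||
            length(trackValues(a[[ctg]])) != length(trackValues(b[[ctg]])))
            stop(sprintf("span mismatch on contig '%s' between %s and %s",
                         ctg, nameA, nameB), call. = FALSE)
    }
    list(a, b)
}

# Total mapped reads of a coverage set (library size for depth normalization).
.librarySize <- function(tracks) {
    sum(vapply(tracks, function(t) sum(trackValues(t)), numeric(1L)))
}
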