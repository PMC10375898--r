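# Independent reference implementations used as oracles. These are kept
# deliberately naive (position scans, all-pairs loops, textbook formulas)
# and share no code with the package internals they check.

# Brute-force position scanner: walks the track one nucleotide at a time,
# opening a region at the first significant position and closing it when
# the run of non-significant positions exceeds maxGap. Returns a matrix of
# 1-based closed [start, end] rows.
bruteRegions <- function(x, cutoff, maxGap) {
    n <- length(x)
    cap <- n %/% 2L + 1L
    starts <- integer(cap)
    ends <- integer(cap)
    k <- 0L
    regStart <- NA_integer_
    lastSig <- NA_integer_
    for (i in seq_len(n)) {
        sig <- !is.na(x[i]) && x[i] > cutoff
        if (sig) {
            if (is.na(regStart)) {
                regStart <- i
            } else if (i - lastSig - 1L > maxGap) {
                k <- k + 1L
                starts[k] <- regStart
                ends[k] <- lastSig
                regStart <- i
            }
            lastSig <- i
        }
    }
    if (!is.na(regStart)) {
        k <- k + 1L
        starts[k] <- regStart
        ends[k] <- lastSig
    }
    cbind(start = starts[seq_len(k)], end = ends[seq_len(k)])
}

# Region area score recomputed by direct summation.
bruteAuc <- function(x, start, end, cutoff, mode = "above") {
    v <- x[start:end]
    v[is.na(v)] <- 0
    if (mode == "above") sum(pmax(0, v - cutoff)) else sum(v)
}

# All-pairs overlap of regions and transcripts (both data.frames with
# contig/start/end columns, 1-based closed).
bruteOverlaps <- function(regions, transcripts) {
    hits <- NULL
    for (i in seq_len(nrow(regions))) {
        for (j in seq_len(nrow(transcripts))) {
            if (regions$contig[i] == transcripts$contig[j] &&
                regions$start[i] <= transcripts$end[j] &&
                regions$end[i] >= transcripts$start[j])
                hits <- rbind(hits, c(i, j))
        }
    }
    hits
}

# Textbook Welch t-test p-value (two-sided).
welchP <- function(a, b) {
    n1 <- length(a); n2 <- length(b)
    v1 <- var(a); v2 <- var(b)
    se2 <- v1 / n1 + v2 / n2
    if (se2 == 0) return(1)
    tstat <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    2 * pt(abs(tstat), df, lower.tail = FALSE)
}

# Jaccard index of two 1-based closed intervals on the same contig.
jaccard <- function(s1, e1, s2, e2) {
    inter <- max(0L, min(e1, e2) - max(s1, s2) + 1L)
    union <- (e1 - s1 + 1L) + (e2 - s2 + 1L) - inter
    inter / union
}
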