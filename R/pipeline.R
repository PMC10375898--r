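# End-to-end orchestration with reproducible, versioned outputs. Each
# run* function writes its results plus a run log (parameters, seed,
# input checksums) into an output directory; identical inputs and seeds
# give byte-identical files.

.writeRunLog <- function(dir, step, params, inputs = character()) {
    log <- list(step = step,
                package_version = as.character(
                    utils::packageVersion("chemclipseq")),
                parameters = params,
                input_checksums = if (length(inputs))
                    as.list(tools::md5sum(inputs)) else list())
    yaml::write_yaml(log, file.path(dir, sprintf("%s_log.yaml", step)))
}

#' Simulate a condition and write its fixture directory
#'
#' Generates an annotation and replicate coverage tracks from `config`
#' and writes GTF, BedGraphs, ground-truth BED and config YAML into
#' `outDir`.
#'
#' @param config a [SimulationConfig-class].
#' @param outDir output directory.
#' @param condition label used in file names.
#' @param nSpikes,spikeFold,spikeLengthRange when `nSpikes > 0` and the
#'   config carries no spikes, this many random spikes are placed first
#'   (seeded from `config`).
#' @return invisible list with the annotation, coverage and final config.
#' @export
runSimulate <- function(config, outDir, condition = "cond", nSpikes = 0L,
                        spikeFold = 6, spikeLengthRange = c(500L, 800L)) {
    annotation <- generateAnnotation(config)
    if (nSpikes > 0L && length(config@spikes) == 0L) {
        config@spikes <- randomSpikes(annotation, nSpikes, fold = spikeFold,
                                      lengthRange = spikeLengthRange,
                                      seed = config@seed + 1L)
    }
    coverage <- simulateCoverage(annotation, config)
    writeSimulation(outDir, annotation, coverage, config,
                    condition = condition)
    .writeRunLog(outDir, "simulate", .configAsList(config))
    invisible(list(annotation = annotation, coverage = coverage,
                   config = config))
}

# read per-replicate bedgraphs named <condition>_<side>_rep<i>.bedgraph
.readReplicates <- function(dir, condition, side, nReplicates) {
    lapply(seq_len(nReplicates), function(r) {
        f <- file.path(dir, sprintf("%s_%s_rep%d.bedgraph", condition,
                                    side, r))
        if (!file.exists(f))
            stop("missing coverage track: ", f, call. = FALSE)
        readBedGraph(f)
    })
}

#' Run the enrichment calling pipeline on one condition
#'
#' Reads per-replicate input/output BedGraphs and the annotation, pools
#' replicates, computes ratios, fits the log-normal null, derives
#' -log10 p tracks, calls candidate regions, applies the filter cascade
#' and aggregates passing regions into transcript hits. Writes
#' `regions_passing.bed`, `regions_verdicts.tsv`, `hits.tsv`,
#' `null_model.yaml` and `call_log.yaml` into `outDir`.
#'
#' @param dir directory holding `<condition>_<side>_rep<i>.bedgraph` and
#'   `annotation.gtf` (as written by [runSimulate()]).
#' @param outDir output directory.
#' @param condition file-name label of the condition to analyse.
#' @param nReplicates number of replicates to read.
#' @param config a [FilterConfig-class].
#' @param nullMethod estimator for [fitNull()].
#' @param refit when TRUE, the null is refitted after excluding the
#'   first-pass candidate regions.
#' @param pseudocount,minInput passed to [computeRatio()].
#' @param hitThreshold transcript-level log2 enrichment hit threshold.
#' @return invisible list with regions, verdicts, hits and the null
#'   model.
#' @export
runCall <- function(dir, outDir, condition = "cond", nReplicates = 3L,
                    config = FilterConfig(), nullMethod = "robust",
                    refit = FALSE, pseudocount = 1, minInput = 1,
                    hitThreshold = 0.8) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    annotation <- readGtf(file.path(dir, "annotation.gtf"))
    inputReps <- .readReplicates(dir, condition, "input", nReplicates)
    outputReps <- .readReplicates(dir, condition, "output", nReplicates)
    inPooled <- poolReplicates(inputReps)
    outPooled <- poolReplicates(outputReps)
    profiles <- computeRatio(inPooled, outPooled, pseudocount = pseudocount,
                             minInput = minInput)
    null <- fitNull(profiles, method = nullMethod)
    if (refit) {
        prof1 <- pvalueTrack(profiles, null)
        first <- callRegions(prof1, config, inPooled, outPooled)
        if (length(first))
            null <- fitNull(profiles, exclude = first, method = nullMethod)
    }
    profiles <- pvalueTrack(profiles, null)
    regions <- callRegions(profiles, config, inPooled, outPooled)
    filtered <- applyFilters(regions, inputReps, outputReps, config)
    assignment <- assignRegions(filtered$passing, annotation)
    hits <- aggregateTranscripts(assignment, filtered$passing, inPooled,
                                 outPooled, hitThreshold = hitThreshold,
                                 pseudocount = pseudocount)

    params <- list(condition = condition, nReplicates = nReplicates,
                   pCutoff = config@pCutoff, minAuc = config@minAuc,
                   lengthMin = config@lengthMin,
                   lengthMax = config@lengthMax,
                   minReads = config@minReads,
                   minLog2fc = config@minLog2fc, maxGap = config@maxGap,
                   aucMode = config@aucMode, pseudocount = pseudocount,
                   minInput = minInput, nullMethod = nullMethod,
                   refit = refit, hitThreshold = hitThreshold)
    hdr <- lapply(params, identity)
    writeBed(filtered$passing, file.path(outDir, "regions_passing.bed"))
    vdf <- as.data.frame(filtered$verdicts)
    if (nrow(vdf)) {
        l2 <- filtered$verdicts$log2fc
        vdf <- vdf[, setdiff(colnames(vdf), "log2fc")]
        for (r in seq_len(ncol(l2)))
            vdf[[sprintf("log2fc_rep%d", r)]] <- l2[, r]
    }
    writeResultsTsv(vdf, file.path(outDir, "regions_verdicts.tsv"),
                    header = hdr)
    writeResultsTsv(as.data.frame(hits), file.path(outDir, "hits.tsv"),
                    header = hdr)
    yaml::write_yaml(list(mu = nullMu(null), sigma = nullSigma(null),
                          fit_n = fitN(null), method = null@method),
                     file.path(outDir, "null_model.yaml"))
    .writeRunLog(outDir, "call", params,
                 inputs = c(file.path(dir, "annotation.gtf"),
                            list.files(dir, pattern = "\\.bedgraph$",
                                       full.names = TRUE)))
    invisible(list(regions = regions, verdicts = filtered$verdicts,
                   passing = filtered$passing, hits = hits, null = null))
}

#' Run the fixed-window locus quantification
#'
#' @param dir directory with the per-replicate BedGraphs.
#' @param outDir output directory.
#' @param locus list with `contig`, `start`, `end` (1-based closed).
#' @param condition,nReplicates which tracks to read.
#' @param width,pseudocount,depthNormalize passed to
#'   [windowEnrichment()].
#' @param locusId label for the output row.
#' @return invisible data.frame (also written to `window.tsv`).
#' @export
runWindow <- function(dir, outDir, locus, condition = "cond",
                      nReplicates = 3L, width = 500L, pseudocount = 1,
                      depthNormalize = TRUE, locusId = "locus") {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    inputReps <- .readReplicates(dir, condition, "input", nReplicates)
    outputReps <- .readReplicates(dir, condition, "output", nReplicates)
    res <- windowEnrichment(inputReps, outputReps, locus, width = width,
                            pseudocount = pseudocount,
                            depthNormalize = depthNormalize,
                            locusId = locusId)
    params <- list(condition = condition, locus = locus, width = width,
                   pseudocount = pseudocount,
                   depthNormalize = depthNormalize)
    writeResultsTsv(res, file.path(outDir, "window.tsv"),
                    header = list(condition = condition, width = width))
    .writeRunLog(outDir, "window", params)
    invisible(res)
}

#' Run the rescue classification from matrix TSVs
#'
#' @param wtPath,vehiclePath,treatedPath TSV matrices (see
#'   [readMatrixTsv()]).
#' @param outDir output directory; writes `rescue_table.tsv` and
#'   `rescue_summary.json`.
#' @param alpha significance level.
#' @param mode `"expression"` or `"psi"`.
#' @return invisible [RescueTable-class].
#' @export
runRescue <- function(wtPath, vehiclePath, treatedPath, outDir,
                      alpha = 0.05, mode = c("expression", "psi")) {
    mode <- match.arg(mode)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    rt <- classifyRescued(readMatrixTsv(wtPath), readMatrixTsv(vehiclePath),
                          readMatrixTsv(treatedPath), alpha = alpha,
                          mode = mode)
    writeResultsTsv(as.data.frame(rescueFlags(rt)),
                    file.path(outDir, "rescue_table.tsv"),
                    header = list(alpha = alpha, mode = mode))
    jsonlite::write_json(rescueSummary(rt),
                         file.path(outDir, "rescue_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    .writeRunLog(outDir, "rescue",
                 list(alpha = alpha, mode = mode),
                 inputs = c(wtPath, vehiclePath, treatedPath))
    invisible(rt)
}

#' Summarize a pipeline run directory
#'
#' Reads the outputs of [runCall()] in `runDir` and produces a single
#' summary: counts per filter stage, the hit table and the parameters
#' used. The summary is written to `report.txt` and returned.
#'
#' @param runDir directory written by [runCall()].
#' @return invisible list with `counts`, `hits` and `parameters`.
#' @export
runReport <- function(runDir) {
    vf <- file.path(runDir, "regions_verdicts.tsv")
    hf <- file.path(runDir, "hits.tsv")
    lf <- file.path(runDir, "call_log.yaml")
    if (!file.exists(vf) || !file.exists(hf))
        stop("'", runDir, "' does not look like a runCall() output directory",
             call. = FALSE)
    verdicts <- readResultsTsv(vf)
    hits <- readResultsTsv(hf)
    params <- if (file.exists(lf)) yaml::read_yaml(lf)$parameters else list()
    counts <- c(candidate_regions = nrow(verdicts),
                pass_auc = sum(verdicts$pass_auc),
                pass_length = sum(verdicts$pass_length),
                pass_reads = sum(verdicts$pass_reads),
                pass_replicates = sum(verdicts$pass_replicates),
                passing_regions = sum(verdicts$pass),
                transcripts_with_regions = nrow(hits),
                passing_transcripts = sum(hits$passing))
    lines <- c("chemclipseq run report",
               sprintf("  %-26s %d", names(counts), counts),
               "parameters:",
               sprintf("  %s = %s", names(params),
                       vapply(params, function(x)
                           paste(format(x), collapse = ","),
                           character(1L))))
    writeLines(lines, file.path(runDir, "report.txt"))
    invisible(list(counts = counts, hits = hits, parameters = params))
}
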