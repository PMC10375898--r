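# chemclipseq

Enrichment analysis for **Chem-CLIP-Seq**: sequencing experiments in
which a small molecule is cross-linked to the RNAs it binds in cells,
the tagged RNA is pulled down, and pulled-down ("output") libraries are
compared with matched pre-pull-down ("input") libraries to map binding
transcriptome-wide. The package is aimed at analysts of such pull-down
experiments — in particular studies of repeat-expansion targets, where
the bound locus itself is largely unalignable — and at method developers
who need a fully synthetic, ground-truth-bearing test bed for this class
of analysis.

## What it computes

For each nucleotide *i* the enrichment ratio is

    r_i = ((O_i + c)/N_O) / ((I_i + c)/N_I)

(output over input coverage, depth-normalized, pseudocount *c*). Under
the null, ln *r* ~ N(μ, σ²); per-nucleotide p-values are upper-tail
probabilities of this log-normal null, computed via the log-space
survival function so that −log₁₀ *p* stays accurate to the clip at 350.
Adjacent nucleotides with −log₁₀ *p* > 10 are compiled into regions,
which must then survive a four-stage filter cascade:

1. area score ≥ 200 (area of the −log₁₀ *p* curve above the cutoff),
2. length 400–1000 nt (the pulled-down fragment-size range),
3. pooled output reads ≥ 10,
4. log₂ fold enrichment ≥ 0.8 in *every* replicate.

Passing regions are aggregated per transcript (reads summed over a
transcript's regions, per-million normalized, hit at log₂ ≥ 0.8), hit
lists are compared across conditions, a fixed 500-nt window around a
repeat locus is quantified per replicate (symmetric alignment dropout
cancels in the ratio), and expression/splicing matrices are classified
for treatment *rescue*: features dysregulated in disease (Welch test,
p < 0.05), shifted toward healthy levels under treatment, and no longer
significantly different from healthy.

A first-class synthetic-data module generates every input — annotation,
replicate coverage tracks, repeat-locus dropout, expression and Ψ
matrices — with known ground truth (see the methods vignette,
`vignettes/chemclipseq-methods.Rmd`).

## Worked example

```r
library(chemclipseq)

cfg <- SimulationConfig(nTranscripts = 30, seed = 42)   # 30 tx, 2-8 kb, 3 reps
ann <- generateAnnotation(cfg)
cfg@spikes <- randomSpikes(ann, 3, fold = 6, seed = 43) # ground truth
cov <- simulateCoverage(ann, cfg)

inputPooled  <- poolReplicates(cov$input)
outputPooled <- poolReplicates(cov$output)
profiles <- computeRatio(inputPooled, outputPooled)
(null <- fitNull(profiles))
#> Log-normal null model (robust fit): mu = -0.0637, sigma = 0.1730 (n = 150425)

profiles <- pvalueTrack(profiles, null)
regions  <- callRegions(profiles, FilterConfig(), inputPooled, outputPooled)
filtered <- applyFilters(regions, cov$input, cov$output, FilterConfig())
hits <- aggregateTranscripts(assignRegions(filtered$passing, ann),
                             filtered$passing, inputPooled, outputPooled)
as.data.frame(hits)[, c("transcript_id", "n_regions", "log2_enrichment", "passing")]
#>   transcript_id n_regions log2_enrichment passing
#> 1        tx0008         1        2.504284    TRUE
#> 2        tx0012         1        2.491312    TRUE
#> 3        tx0004         1        2.485411    TRUE
```

The three passing transcripts are exactly the three spiked ones
(tx0004, tx0008, tx0012); their log₂ ≈ 2.5 reflects the simulated
fold-6 enrichment after depth normalization. The fitted null mean is
slightly negative because the spiked reads inflate the output library
total — the region-level statistics are computed against this fitted
background, not the nominal one.

Rescue classification on simulated matrices (3000 genes, 150 truly
dysregulated, 80% truly rescued):

```r
sim <- simulateRescueMatrices(RescueSimConfig(nGenes = 3000,
        nDysregulated = 150, trueRescueFraction = 0.8, seed = 44))
rescueAnalysis(sim$wt, sim$vehicle, sim$treated)
#> RescueTable: 3000 features at alpha = 0.05
#>   dysregulated: 244
#>   rescued:      181 (naive fraction 0.742)
#>   rescue fraction estimate (high-confidence subset): 0.855
```

The naive fraction (0.742) is diluted by false discoveries of the raw
p < 0.05 rule; the high-confidence estimator (0.855) is the package's
estimate of the true rescue fraction (here 0.8). The methods vignette
explains both numbers.

End-to-end runs with on-disk provenance (BedGraph/GTF in, BED/TSV/YAML
out) go through `runSimulate()`, `runCall()`, `runWindow()`,
`runRescue()` and `runReport()`; a thin command-line wrapper is in
`inst/scripts/chemclipseq-cli.R`.

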