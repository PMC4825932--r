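## Fixture builders and independent per-bp oracles used across tests.
## Oracles are deliberately written in plain base R (loops over bp),
## independent of the package's Rle/GRanges machinery.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
    library(S4Vectors)
})

## write a BED3 file of 1-based closed intervals given as a data.frame
## with columns start, end (converted to 0-based half-open on disk)
writeBed3 <- function(df, path = tempfile(fileext = ".bed"),
                      chrom = "chr1") {
    writeLines(sprintf("%s\t%d\t%d", chrom, df$start - 1L, df$end), path)
    path
}

## per-bp boolean coverage oracle: logical vector of length len, TRUE where
## any [start, end] (1-based closed) interval covers the bp
bpCoverOracle <- function(starts, ends, len) {
    covered <- logical(len)
    for (i in seq_along(starts))
        covered[seq(starts[i], ends[i])] <- TRUE
    covered
}

## per-bp 0/1 mark matrix oracle for a MarkTrackSet on one chromosome
markMatrixOracle <- function(ts, chrom) {
    len <- genomeLengths(ts)[[chrom]]
    vapply(markNames(ts), function(m) {
        gr <- peaks(ts)[[m]]
        gr <- gr[as.character(seqnames(gr)) == chrom]
        as.numeric(bpCoverOracle(start(gr), end(gr), len))
    }, numeric(len))
}

## random toy MarkTrackSet on a single chromosome: nIv random intervals
## per mark
randomTrackSet <- function(len = 10000L, nIv = 12L, seed = 1L,
                           tissue = "toy") {
    withr::with_seed(seed, {
        files <- lapply(epigeneticMarks(), function(m) {
            s <- sort(sample.int(len - 50L, nIv))
            w <- sample(10:80, nIv, replace = TRUE)
            writeBed3(data.frame(start = s, end = pmin(len, s + w)))
        })
        names(files) <- epigeneticMarks()
        buildMarkTrackSet(files, c(chr1 = len), tissue)
    })
}

## random ScoreTrack: nRun runs of random scores on one chromosome
randomScoreTrack <- function(len = 10000L, nRun = 50L, seed = 1L) {
    withr::with_seed(seed, {
        cuts <- sort(sample.int(len - 1L, nRun - 1L))
        lens <- diff(c(0L, cuts, len))
        ScoreTrack(list(chr1 = Rle(round(runif(nRun), 6), lens)))
    })
}

## a single-bin uniform density on [0, 1]
flatDensity <- function() {
    new("HistogramDensity", breaks = c(0, 1), heights = 1)
}

## a PValueModel with flat nulls and chosen signal parameters, for
## hand-computable posterior checks
flatNullModel <- function(alphaTissue = 0.5, wCond = 0.3,
                          alphaGeneral = 0.5, wGeneral = 0.3) {
    trace <- new("EmTrace", logLik = numeric(0), nIter = 0L, converged = NA)
    new("PValueModel",
        fTissueNull = flatDensity(), fGeneralNull = flatDensity(),
        alphaTissue = alphaTissue, wCond = wCond,
        alphaGeneral = alphaGeneral, wGeneral = wGeneral,
        traceTissue = trace, traceGeneral = trace,
        threshold = 0.1, windowBp = 10000)
}
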