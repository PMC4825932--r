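## Synthetic data with the statistical structure the models assume: binary
## mark tracks generated from the two-component Bernoulli model around
## planted functional regions, and GWAS p-values drawn from the
## case-I/II/III beta-uniform mixture conditioned on planted functionality.
## A single seed keys all stages; per-stage sub-seeds are derived from it.

#' Simulation configuration
#'
#' Bundles the generating parameters for synthetic mark tracks and GWAS
#' tables. Defaults describe a desk-scale study: a 1 Mb single-chromosome
#' genome with 10\% planted functional bp in regions of mean length 1 kb,
#' mark peak rates 0.7 (functional) vs 0.1 (background), and 10,000 GWAS
#' SNPs whose disease-functional fraction within tissue-functional regions
#' is 0.3 with Beta(0.3, 1) signal p-values.
#'
#' @param genome named integer vector of chromosome lengths.
#' @param nTissues number of tissues to simulate.
#' @param p1,p0 per-mark Bernoulli peak rates for functional/background bp.
#' @param regionLengthMean mean planted functional region length (bp,
#'   geometric).
#' @param functionalFraction target fraction of functional bp per tissue.
#' @param nSnps number of GWAS SNPs.
#' @param alpha true Beta shape of disease-functional p-values, in (0, 1).
#' @param wCond true P(disease-functional | tissue-functional).
#' @param seed master RNG seed.
#' @param marks mark names.
#' @return A list of class \code{SimConfig}.
#' @export
simConfig <- function(genome = c(chr1 = 1000000L), nTissues = 1L,
                      p1 = rep(0.7, 8), p0 = rep(0.1, 8),
                      regionLengthMean = 1000, functionalFraction = 0.1,
                      nSnps = 10000L, alpha = 0.3, wCond = 0.3, seed = 1L,
                      marks = epigeneticMarks()) {
    stopifnot(functionalFraction >= 0, functionalFraction < 1,
              alpha > 0, alpha < 1, wCond >= 0, wCond <= 1,
              all(genome > 0), regionLengthMean >= 1)
    cfg <- list(genome = genome, nTissues = as.integer(nTissues),
                p1 = p1, p0 = p0, regionLengthMean = regionLengthMean,
                functionalFraction = functionalFraction,
                nSnps = as.integer(nSnps), alpha = alpha, wCond = wCond,
                seed = as.integer(seed), marks = marks)
    class(cfg) <- "SimConfig"
    cfg
}

#' True mixture parameters implied by a SimConfig
#'
#' @param cfg a \code{SimConfig}.
#' @return A \code{MixtureParams} with \code{pi = functionalFraction}.
#' @export
trueParams <- function(cfg) {
    MixtureParams(pi = max(cfg$functionalFraction, 1e-6), p1 = cfg$p1,
                  p0 = cfg$p0, marks = cfg$marks)
}

## sub-seed for a named stage, kept well below 2^31
.stageSeed <- function(seed, stage) {
    offs <- c(tracks = 11L, gwas = 23L, sample = 37L, workspace = 53L)
    (as.integer(seed) %% 20000000L) * 100L + offs[[stage]]
}

#' Simulate a training sample directly from the mixture
#'
#' Draws pattern counts from the exact 256-pattern multinomial implied by
#' the mixture, i.e. n i.i.d. bp observations.
#'
#' @param params a \code{MixtureParams}.
#' @param n number of bp observations.
#' @param seed RNG seed.
#' @return A \code{TrainingSample}.
#' @export
simulateTrainingSample <- function(params, n, seed = 1L) {
    patterns <- .patternMatrix()
    prob <- params@pi * exp(.componentLogLik(patterns, params@p1)) +
        (1 - params@pi) * exp(.componentLogLik(patterns, params@p0))
    counts <- withr::with_seed(seed,
        as.numeric(stats::rmultinom(1L, n, prob)))
    trainingSampleFromCounts(counts, markNames(params))
}

## plant functional segments on one chromosome: geometric lengths (mean
## regionLengthMean), total functional bp capped at the target by
## truncating the final segment, gaps placed by integer stars-and-bars
.plantSegments <- function(len, targetBp, meanLen) {
    if (targetBp == 0)
        return(IRanges())
    if (targetBp > len)
        stop("functional fraction unattainable on a ", len, " bp chromosome")
    lens <- integer(0)
    while (sum(lens) < targetBp)
        lens <- c(lens, stats::rgeom(max(16L, ceiling(targetBp / meanLen)),
                                     1 / meanLen) + 1L)
    cut <- which(cumsum(as.numeric(lens)) >= targetBp)[1L]
    lens <- lens[seq_len(cut)]
    lens[cut] <- lens[cut] - (sum(lens) - targetBp)
    lens <- lens[lens > 0L]
    nSeg <- length(lens)
    free <- len - sum(lens)
    cuts <- sort(sample.int(free + 1L, nSeg, replace = TRUE) - 1L)
    starts <- cuts + c(0, cumsum(as.numeric(lens[-nSeg]))) + 1
    IRanges(start = starts, width = lens)
}

## chop an IRanges into consecutive blocks of at most blockLen bp
.tileRanges <- function(ir, blockLen) {
    if (length(ir) == 0L)
        return(IRanges())
    tiles <- IRanges::tile(ir, width = blockLen)
    unlist(tiles, use.names = FALSE)
}

#' Simulate per-tissue mark tracks with planted functional regions
#'
#' Functional regions are planted as non-overlapping segments with
#' geometric lengths until the target functional fraction is reached
#' (truncating the final segment so the realized fraction matches the
#' target exactly). Mark presence is drawn block-wise -- one Bernoulli draw
#' per segment (rate p1) or per background block (rate p0) per mark -- so
#' peak files contain realistic contiguous intervals while per-bp marginals
#' equal the model's.
#'
#' @param cfg a \code{SimConfig}.
#' @return list with \code{tracks} (named list of \code{MarkTrackSet}, one
#'   per tissue), \code{truth} (named list of logical \code{RleList}s of
#'   per-bp functionality), and \code{functionalRegions} (named list of
#'   \code{GRanges}).
#' @export
simulateTracks <- function(cfg) {
    withr::with_seed(.stageSeed(cfg$seed, "tracks"), {
        si <- Seqinfo(names(cfg$genome), unname(cfg$genome))
        tissues <- paste0("tissue", seq_len(cfg$nTissues))
        out <- lapply(tissues, function(tissue) {
            segByChrom <- lapply(names(cfg$genome), function(chrom) {
                len <- cfg$genome[[chrom]]
                .plantSegments(len, round(cfg$functionalFraction * len),
                               cfg$regionLengthMean)
            })
            names(segByChrom) <- names(cfg$genome)
            func <- GRanges(rep(names(segByChrom), vapply(segByChrom, length, integer(1))),
                            unlist(IRanges::IRangesList(segByChrom),
                                   use.names = FALSE),
                            seqinfo = si)
            bgByChrom <- lapply(names(cfg$genome), function(chrom)
                .tileRanges(IRanges::gaps(segByChrom[[chrom]],
                                          start = 1L,
                                          end = cfg$genome[[chrom]]),
                            cfg$regionLengthMean))
            names(bgByChrom) <- names(cfg$genome)
            bg <- GRanges(rep(names(bgByChrom), vapply(bgByChrom, length, integer(1))),
                          unlist(IRanges::IRangesList(bgByChrom),
                                 use.names = FALSE),
                          seqinfo = si)
            peaksByMark <- lapply(seq_len(.N_MARKS), function(i) {
                keepF <- func[stats::runif(length(func)) < cfg$p1[i]]
                keepB <- bg[stats::runif(length(bg)) < cfg$p0[i]]
                sort(reduce(c(keepF, keepB)))
            })
            names(peaksByMark) <- cfg$marks
            ts <- new("MarkTrackSet", tissueLabel = tissue,
                      marks = cfg$marks,
                      peaks = GRangesList(peaksByMark, compress = FALSE),
                      seqinfo = si)
            truth <- coverage(func, width = cfg$genome) > 0L
            list(ts = ts, truth = truth, func = sort(func))
        })
        names(out) <- tissues
        list(tracks = lapply(out, `[[`, "ts"),
             truth = lapply(out, `[[`, "truth"),
             functionalRegions = lapply(out, `[[`, "func"))
    })
}

#' Simulate a GWAS table conditioned on planted functionality
#'
#' SNP positions are uniform over the genome. A SNP on functional bp is
#' disease-functional (case I) with probability \code{wCond} and draws its
#' p-value from Beta(alpha, 1); all other SNPs (case II on functional bp,
#' case III elsewhere) draw Uniform(0, 1) p-values.
#'
#' @param cfg a \code{SimConfig}.
#' @param truth logical \code{RleList} of per-bp functionality for the
#'   disease-relevant tissue (one element of \code{simulateTracks()$truth}).
#' @return data.frame with columns SNP, CHR, BP, P and CASE (1, 2 or 3).
#' @export
simulateGwas <- function(cfg, truth) {
    withr::with_seed(.stageSeed(cfg$seed, "gwas"), {
        lens <- vapply(truth, length, numeric(1))
        nByChrom <- round(cfg$nSnps * lens / sum(lens))
        nByChrom[1L] <- cfg$nSnps - sum(nByChrom[-1L])
        rows <- lapply(names(truth), function(chrom) {
            n <- nByChrom[[chrom]]
            if (n == 0L) return(NULL)
            pos <- sort(sample.int(as.integer(lens[[chrom]]), n))
            func <- as.logical(truth[[chrom]][pos])
            caseI <- func & stats::runif(n) < cfg$wCond
            p <- stats::runif(n)
            p[caseI] <- stats::rbeta(sum(caseI), cfg$alpha, 1)
            data.frame(CHR = chrom, BP = pos, P = pmax(p, .P_FLOOR),
                       CASE = ifelse(caseI, 1L, ifelse(func, 2L, 3L)),
                       stringsAsFactors = FALSE)
        })
        tab <- do.call(rbind, rows)
        tab$SNP <- paste0("rs", seq_len(nrow(tab)))
        tab[, c("SNP", "CHR", "BP", "P", "CASE")]
    })
}

#' Write a complete demo workspace to disk
#'
#' Simulates tracks and GWAS data and writes every file the pipeline
#' consumes: per-mark peak BED files per tissue, a genome sizes file, the
#' GWAS table, a risk-loci BED (windows around the strongest planted
#' associations), training seed positions, truth tables, and a checksum
#' manifest. Regeneration with the same seed reproduces identical files.
#'
#' @param cfg a \code{SimConfig}.
#' @param outDir output directory (created if needed).
#' @param nLoci number of risk loci to derive from the top associations.
#' @param locusHalfWidth half-width of each locus in bp.
#' @return Invisibly, a data.frame manifest (file, md5).
#' @export
makeDemoWorkspace <- function(cfg, outDir, nLoci = 5L,
                              locusHalfWidth = 25000L) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    sim <- simulateTracks(cfg)
    gwas <- simulateGwas(cfg, sim$truth[[1L]])
    files <- character(0)

    writeTab <- function(df, name) {
        path <- file.path(outDir, name)
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        files <<- c(files, path)
        path
    }
    for (tissue in names(sim$tracks)) {
        ts <- sim$tracks[[tissue]]
        for (m in markNames(ts)) {
            path <- file.path(outDir, paste0(tissue, "_", m, ".bed"))
            writeBed(peaks(ts)[[m]], path)
            files <- c(files, path)
        }
        path <- file.path(outDir, paste0(tissue, "_functional_truth.bed"))
        writeBed(sim$functionalRegions[[tissue]], path)
        files <- c(files, path)
    }
    genomePath <- file.path(outDir, "genome.txt")
    writeLines(sprintf("%s\t%d", names(cfg$genome), cfg$genome), genomePath)
    files <- c(files, genomePath)

    writeTab(gwas[, c("SNP", "CHR", "BP", "P")], "gwas.tsv")
    writeTab(gwas, "gwas_truth.tsv")

    ## training seeds: positions of the strongest associations (analog of
    ## genome-wide significant catalog SNPs)
    nSeeds <- max(200L, round(0.2 * nrow(gwas)))
    seeds <- gwas[order(gwas$P)[seq_len(min(nSeeds, nrow(gwas)))],
                  c("CHR", "BP")]
    writeTab(seeds, "train_seeds.tsv")

    ## risk loci: windows around the best distinct associations
    best <- gwas[order(gwas$P), ]
    chosen <- best[seq_len(min(nLoci * 10L, nrow(best))), ]
    gl <- cfg$genome
    lociGr <- reduce(GRanges(chosen$CHR,
        IRanges(pmax(1, chosen$BP - locusHalfWidth),
                pmin(gl[chosen$CHR], chosen$BP + locusHalfWidth))))
    lociGr <- head(lociGr, nLoci)
    lociPath <- file.path(outDir, "loci.bed")
    writeLines(sprintf("%s\t%.0f\t%.0f\tlocus%d",
                       as.character(seqnames(lociGr)), start(lociGr) - 1,
                       end(lociGr), seq_along(lociGr)), lociPath)
    files <- c(files, lociPath)

    manifest <- data.frame(file = basename(files),
                           md5 = unname(tools::md5sum(files)),
                           stringsAsFactors = FALSE)
    writeTab(manifest, "manifest.tsv")
    invisible(manifest)
}
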