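#' @import methods
#' @importFrom S4Vectors Rle runValue runLength isSorted metadata metadata<-
#' @importFrom IRanges IRanges RleList Views viewMeans slice reduce extractList
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end width
#'   coverage findOverlaps countOverlaps
#' @importFrom GenomeInfoDb Seqinfo seqlengths seqlevels seqinfo seqinfo<- seqlevels<-
#' @importFrom withr with_seed
#' @importFrom stats rbeta runif rgeom pbinom setNames
#' @importFrom utils read.table write.table
NULL

#' Canonical epigenetic mark names
#'
#' The eight chromatin features used for tissue-specific functional
#' annotation: seven histone modifications plus DNase I hypersensitivity,
#' each summarized as presence/absence of a called peak.
#'
#' @return Character vector of length 8.
#' @export
#' @examples
#' epigeneticMarks()
epigeneticMarks <- function() {
    c("H3K4me1", "H3K4me3", "H3K36me3", "H3K27me3",
      "H3K9me3", "H3K27ac", "H3K9ac", "DNase")
}

.N_MARKS <- 8L
.N_PATTERNS <- 256L

## ---------------------------------------------------------------------------
## MarkTrackSet
## ---------------------------------------------------------------------------

#' MarkTrackSet: binarized 8-mark peak coverage for one tissue
#'
#' Holds, for a single tissue group, the union-of-samples peak coverage for
#' each of eight epigenetic marks, as reduced \code{GRanges} sharing one
#' \code{Seqinfo}. Coordinates follow the Bioconductor convention (1-based,
#' closed); conversion to/from the 0-based half-open file formats happens at
#' the parse/serialize boundary only.
#'
#' @slot tissueLabel single character, the tissue group name.
#' @slot marks character(8), ordered mark names; all observation vectors and
#'   parameter vectors inherit this order.
#' @slot peaks \code{GRangesList} of length 8, one reduced sorted element per
#'   mark, clipped to the genome bounds.
#' @slot seqinfo \code{Seqinfo} giving the genome (chromosome lengths).
#' @export
setClass("MarkTrackSet",
    representation(tissueLabel = "character",
                   marks = "character",
                   peaks = "GRangesList",
                   seqinfo = "Seqinfo"))

setValidity("MarkTrackSet", function(object) {
    msg <- character()
    if (length(object@marks) != .N_MARKS)
        msg <- c(msg, sprintf("exactly %d marks required, got %d",
                              .N_MARKS, length(object@marks)))
    if (anyDuplicated(object@marks))
        msg <- c(msg, "mark names must be unique")
    if (length(object@peaks) != length(object@marks) ||
        !identical(names(object@peaks), object@marks))
        msg <- c(msg, "peaks must be a GRangesList named by marks, in order")
    if (any(is.na(seqlengths(object@seqinfo))))
        msg <- c(msg, "all chromosome lengths must be known")
    for (m in names(object@peaks)) {
        gr <- object@peaks[[m]]
        if (length(gr) && (any(start(gr) < 1L) ||
            any(end(gr) > seqlengths(object@seqinfo)[as.character(seqnames(gr))])))
            msg <- c(msg, sprintf("peaks for mark '%s' exceed genome bounds", m))
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn MarkTrackSet-class tissue label accessor
#' @param x,object a \code{MarkTrackSet}
#' @export
setGeneric("tissueLabel", function(x) standardGeneric("tissueLabel"))
#' @export
setMethod("tissueLabel", "MarkTrackSet", function(x) x@tissueLabel)

#' @describeIn MarkTrackSet-class ordered mark names
#' @export
setGeneric("markNames", function(x) standardGeneric("markNames"))
#' @export
setMethod("markNames", "MarkTrackSet", function(x) x@marks)

#' @describeIn MarkTrackSet-class per-mark peak coverage (\code{GRangesList})
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))
#' @export
setMethod("peaks", "MarkTrackSet", function(x) x@peaks)

#' @describeIn MarkTrackSet-class named integer vector of chromosome lengths
#' @export
setGeneric("genomeLengths", function(x) standardGeneric("genomeLengths"))
#' @export
setMethod("genomeLengths", "MarkTrackSet",
          function(x) seqlengths(x@seqinfo))

setMethod("show", "MarkTrackSet", function(object) {
    cat("MarkTrackSet for tissue '", object@tissueLabel, "'\n", sep = "")
    cat("  genome: ", length(seqlevels(object@seqinfo)), " chromosome(s), ",
        format(sum(as.numeric(seqlengths(object@seqinfo))), big.mark = ","),
        " bp\n", sep = "")
    np <- vapply(object@peaks, length, integer(1))
    cov <- vapply(object@peaks, function(g) sum(as.numeric(width(g))),
                  numeric(1))
    for (i in seq_along(object@marks))
        cat(sprintf("  %-9s %6d peak(s), %s bp\n", object@marks[i], np[i],
                    format(cov[i], big.mark = ",")))
})

## ---------------------------------------------------------------------------
## ScoreTrack
## ---------------------------------------------------------------------------

#' ScoreTrack: a per-nucleotide score in [0,1] over a genome
#'
#' Run-length-encoded genome-wide score (a tissue functionality posterior
#' track, an externally supplied general-functionality track, or any other
#' per-bp probability). Internally an \code{RleList} with one numeric
#' \code{Rle} per chromosome spanning its full length; positions without
#' annotation carry score 0.
#'
#' @slot scores numeric \code{RleList}, one element per chromosome.
#' @export
setClass("ScoreTrack", representation(scores = "RleList"))

setValidity("ScoreTrack", function(object) {
    msg <- character()
    if (is.null(names(object@scores)) || anyDuplicated(names(object@scores)))
        msg <- c(msg, "scores must be uniquely named by chromosome")
    rng <- suppressWarnings(range(unlist(lapply(object@scores,
        function(r) range(runValue(r))), use.names = FALSE)))
    if (length(object@scores) && (rng[1] < 0 || rng[2] > 1))
        msg <- c(msg, "scores must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' ScoreTrack constructor
#'
#' @param scores a numeric \code{RleList} (or named list of numeric
#'   vectors/Rles) with one element per chromosome covering its full length.
#' @return A \code{ScoreTrack}.
#' @export
ScoreTrack <- function(scores) {
    if (is.list(scores))
        scores <- RleList(lapply(scores, Rle), compress = FALSE)
    new("ScoreTrack", scores = scores)
}

#' @describeIn ScoreTrack-class the underlying numeric \code{RleList}
#' @param x,object a \code{ScoreTrack}
#' @export
setGeneric("scoreRle", function(x) standardGeneric("scoreRle"))
#' @export
setMethod("scoreRle", "ScoreTrack", function(x) x@scores)

#' @export
setMethod("genomeLengths", "ScoreTrack", function(x) {
    n <- vapply(x@scores, length, numeric(1))
    storage.mode(n) <- "integer"
    n
})

setMethod("show", "ScoreTrack", function(object) {
    tot <- sum(vapply(object@scores, length, numeric(1)))
    nrun <- sum(vapply(object@scores, function(r) length(runValue(r)),
                       numeric(1)))
    cat("ScoreTrack over ", length(object@scores), " chromosome(s), ",
        format(tot, big.mark = ","), " bp, ", nrun, " run(s)\n", sep = "")
    cat("  mean score: ",
        format(sum(vapply(object@scores, function(r)
            sum(as.numeric(runValue(r)) * runLength(r)), numeric(1))) / tot,
            digits = 4), "\n", sep = "")
})

## ---------------------------------------------------------------------------
## MixtureParams
## ---------------------------------------------------------------------------

#' MixtureParams: parameters of the two-component Bernoulli mixture
#'
#' The 17 free parameters of the functional-annotation model: the prior
#' probability of functionality \eqn{\pi = P(Z=1)} and, for each of the 8
#' marks, the Bernoulli peak rates in the functional
#' (\eqn{p_{i1} = P(A_i=1 \mid Z=1)}) and non-functional
#' (\eqn{p_{i0} = P(A_i=1 \mid Z=0)}) components.
#'
#' @slot pi numeric(1), prior probability of functionality.
#' @slot p1 numeric(8), functional-component peak rates, in mark order.
#' @slot p0 numeric(8), non-functional-component peak rates.
#' @slot marks character(8), the mark order the rates refer to.
#' @export
setClass("MixtureParams",
    representation(pi = "numeric", p1 = "numeric", p0 = "numeric",
                   marks = "character"))

setValidity("MixtureParams", function(object) {
    msg <- character()
    if (length(object@pi) != 1L || object@pi <= 0 || object@pi >= 1)
        msg <- c(msg, "pi must be a single value in (0, 1)")
    if (length(object@p1) != .N_MARKS || length(object@p0) != .N_MARKS)
        msg <- c(msg, sprintf("p1 and p0 must each have %d rates", .N_MARKS))
    if (any(c(object@p1, object@p0) <= 0) || any(c(object@p1, object@p0) >= 1))
        msg <- c(msg, "all rates must lie strictly in (0, 1)")
    if (length(object@marks) != .N_MARKS)
        msg <- c(msg, "marks must have length 8")
    if (length(msg)) msg else TRUE
})

#' MixtureParams constructor
#'
#' @param pi prior probability of functionality, in (0, 1).
#' @param p1 numeric(8) functional-component Bernoulli rates.
#' @param p0 numeric(8) non-functional-component Bernoulli rates.
#' @param marks character(8) mark names (default \code{epigeneticMarks()}).
#' @return A \code{MixtureParams}.
#' @export
#' @examples
#' MixtureParams(0.1, rep(0.7, 8), rep(0.1, 8))
MixtureParams <- function(pi, p1, p0, marks = epigeneticMarks()) {
    new("MixtureParams", pi = unname(pi), p1 = unname(p1), p0 = unname(p0),
        marks = marks)
}

#' @describeIn MixtureParams-class prior probability of functionality
#' @param x,object a \code{MixtureParams}
#' @export
setGeneric("mixturePi", function(x) standardGeneric("mixturePi"))
#' @export
setMethod("mixturePi", "MixtureParams", function(x) x@pi)

#' @describeIn MixtureParams-class functional-component rates, named by mark
#' @export
setGeneric("functionalRates", function(x) standardGeneric("functionalRates"))
#' @export
setMethod("functionalRates", "MixtureParams",
          function(x) stats::setNames(x@p1, x@marks))

#' @describeIn MixtureParams-class non-functional-component rates
#' @export
setGeneric("backgroundRates", function(x) standardGeneric("backgroundRates"))
#' @export
setMethod("backgroundRates", "MixtureParams",
          function(x) stats::setNames(x@p0, x@marks))

#' @export
setMethod("markNames", "MixtureParams", function(x) x@marks)

setMethod("show", "MixtureParams", function(object) {
    cat("MixtureParams (17 free parameters)\n")
    cat("  pi =", format(object@pi, digits = 4), "\n")
    tab <- rbind(p1 = object@p1, p0 = object@p0)
    colnames(tab) <- object@marks
    print(round(tab, 4))
})

## ---------------------------------------------------------------------------
## TrainingSample
## ---------------------------------------------------------------------------

#' TrainingSample: mark-pattern observations with multiplicities
#'
#' A genome sample for mixture fitting, stored compactly as counts over the
#' 256 possible 8-mark binary patterns (each sampled bp contributes one
#' observation; overlapping sampling windows are merged first so no bp is
#' double counted).
#'
#' @slot marks character(8) mark order.
#' @slot patternCounts numeric(256); entry \code{k+1} is the number of bp
#'   whose pattern has integer code \code{k} (bit \code{i-1} set iff mark
#'   \code{i} present).
#' @slot sourceIntervals \code{GRanges} of the merged sampled intervals
#'   (may be empty for purely simulated samples).
#' @slot totalBp numeric(1), total observations; equals
#'   \code{sum(patternCounts)}.
#' @export
setClass("TrainingSample",
    representation(marks = "character", patternCounts = "numeric",
                   sourceIntervals = "GRanges", totalBp = "numeric"))

setValidity("TrainingSample", function(object) {
    msg <- character()
    if (length(object@patternCounts) != .N_PATTERNS)
        msg <- c(msg, "patternCounts must have length 256")
    if (any(object@patternCounts < 0))
        msg <- c(msg, "patternCounts must be nonnegative")
    if (!isTRUE(all.equal(sum(object@patternCounts), object@totalBp)))
        msg <- c(msg, "totalBp must equal sum(patternCounts)")
    if (length(msg)) msg else TRUE
})

#' @describeIn TrainingSample-class counts over the 256 patterns
#' @param x,object a \code{TrainingSample}
#' @export
setGeneric("patternCounts", function(x) standardGeneric("patternCounts"))
#' @export
setMethod("patternCounts", "TrainingSample", function(x) x@patternCounts)

#' @describeIn TrainingSample-class total observed bp
#' @export
setGeneric("totalBp", function(x) standardGeneric("totalBp"))
#' @export
setMethod("totalBp", "TrainingSample", function(x) x@totalBp)

#' @export
setMethod("markNames", "TrainingSample", function(x) x@marks)

setMethod("show", "TrainingSample", function(object) {
    cat("TrainingSample: ", format(object@totalBp, big.mark = ","),
        " bp, ", sum(object@patternCounts > 0),
        " distinct mark pattern(s)\n", sep = "")
})

#' Build a TrainingSample directly from pattern counts
#'
#' @param counts numeric(256) pattern counts (code order).
#' @param marks character(8) mark names.
#' @return A \code{TrainingSample} with empty source intervals.
#' @export
trainingSampleFromCounts <- function(counts, marks = epigeneticMarks()) {
    new("TrainingSample", marks = marks, patternCounts = as.numeric(counts),
        sourceIntervals = GRanges(), totalBp = sum(as.numeric(counts)))
}

## ---------------------------------------------------------------------------
## EmTrace
## ---------------------------------------------------------------------------

#' EmTrace: convergence diagnostics for an EM fit
#'
#' @slot logLik numeric, log-likelihood after each iteration.
#' @slot nIter integer, iterations performed.
#' @slot converged logical, whether the relative log-likelihood change fell
#'   below tolerance before the iteration cap.
#' @export
setClass("EmTrace",
    representation(logLik = "numeric", nIter = "integer",
                   converged = "logical"))

setMethod("show", "EmTrace", function(object) {
    cat("EmTrace: ", object@nIter, " iteration(s), ",
        if (object@converged) "converged" else "NOT converged",
        ", final logLik = ", format(object@logLik[length(object@logLik)],
                                    digits = 8), "\n", sep = "")
})

#' @describeIn EmTrace-class per-iteration log-likelihood
#' @param x,object an \code{EmTrace}
#' @export
setGeneric("emLogLik", function(x) standardGeneric("emLogLik"))
#' @export
setMethod("emLogLik", "EmTrace", function(x) x@logLik)

#' @describeIn EmTrace-class convergence flag
#' @export
setGeneric("emConverged", function(x) standardGeneric("emConverged"))
#' @export
setMethod("emConverged", "EmTrace", function(x) x@converged)

## ---------------------------------------------------------------------------
## HistogramDensity
## ---------------------------------------------------------------------------

#' HistogramDensity: an equal-width histogram density on [0, 1]
#'
#' Used as nonparametric estimate of null p-value densities. Heights include
#' a +0.5 pseudocount per bin and are renormalized so the density integrates
#' to 1.
#'
#' @slot breaks numeric(nBins + 1), increasing, from 0 to 1.
#' @slot heights numeric(nBins), nonnegative density heights.
#' @export
setClass("HistogramDensity",
    representation(breaks = "numeric", heights = "numeric"))

setValidity("HistogramDensity", function(object) {
    msg <- character()
    nb <- length(object@heights)
    if (length(object@breaks) != nb + 1L)
        msg <- c(msg, "breaks must have length(heights) + 1 entries")
    if (is.unsorted(object@breaks, strictly = TRUE))
        msg <- c(msg, "breaks must be strictly increasing")
    if (any(object@heights < 0))
        msg <- c(msg, "heights must be nonnegative")
    mass <- sum(object@heights * diff(object@breaks))
    if (abs(mass - 1) > 1e-9)
        msg <- c(msg, sprintf("density must integrate to 1 (got %.12g)", mass))
    if (length(msg)) msg else TRUE
})

setMethod("show", "HistogramDensity", function(object) {
    cat("HistogramDensity: ", length(object@heights),
        " equal-width bin(s) on [0, 1]\n", sep = "")
})

#' @describeIn HistogramDensity-class number of bins
#' @param x,object a \code{HistogramDensity}
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))
#' @export
setMethod("nBins", "HistogramDensity", function(x) length(x@heights))

## ---------------------------------------------------------------------------
## PValueModel
## ---------------------------------------------------------------------------

#' PValueModel: fitted densities and weights for SNP prioritization
#'
#' Everything needed to turn a GWAS p-value plus per-SNP functionality
#' priors into posterior scores: histogram null densities estimated from the
#' low-prior SNP partitions, Beta(alpha, 1) signal densities for
#' disease-functional SNPs, and the global conditional weights estimated by
#' EM on the high-prior partitions.
#'
#' @slot fTissueNull \code{HistogramDensity} for \eqn{f(p \mid Z_T = 0)}.
#' @slot fGeneralNull \code{HistogramDensity} for \eqn{f(p \mid Z = 0)},
#'   which also stands in for \eqn{f(p \mid Z_D=0, Z_T=1)}.
#' @slot alphaTissue Beta shape for the tissue-model signal density.
#' @slot wCond \eqn{P(Z_D=1 \mid Z_T=1)}, global conditional weight.
#' @slot alphaGeneral Beta shape for the general-functionality signal model.
#' @slot wGeneral signal weight of the general-functionality model.
#' @slot traceTissue,traceGeneral \code{EmTrace} of the two signal-mixture
#'   fits.
#' @slot threshold prior threshold used to partition SNPs.
#' @slot windowBp window width (bp) used for the per-SNP mean-score priors.
#' @export
setClass("PValueModel",
    representation(fTissueNull = "HistogramDensity",
                   fGeneralNull = "HistogramDensity",
                   alphaTissue = "numeric", wCond = "numeric",
                   alphaGeneral = "numeric", wGeneral = "numeric",
                   traceTissue = "EmTrace", traceGeneral = "EmTrace",
                   threshold = "numeric", windowBp = "numeric"))

setValidity("PValueModel", function(object) {
    msg <- character()
    for (nm in c("alphaTissue", "alphaGeneral")) {
        a <- slot(object, nm)
        if (length(a) != 1L || a <= 0 || a >= 1)
            msg <- c(msg, sprintf("%s must be in (0, 1)", nm))
    }
    for (nm in c("wCond", "wGeneral")) {
        w <- slot(object, nm)
        if (length(w) != 1L || w < 0 || w > 1)
            msg <- c(msg, sprintf("%s must be in [0, 1]", nm))
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "PValueModel", function(object) {
    cat("PValueModel\n")
    cat("  tissue model:  alpha =", format(object@alphaTissue, digits = 4),
        " P(Z_D=1|Z_T=1) =", format(object@wCond, digits = 4), "\n")
    cat("  general model: alpha =", format(object@alphaGeneral, digits = 4),
        " w =", format(object@wGeneral, digits = 4), "\n")
    cat("  null densities:", nBins(object@fTissueNull), "bins (tissue),",
        nBins(object@fGeneralNull), "bins (general)\n")
    cat("  prior threshold", object@threshold, "| prior window",
        object@windowBp, "bp\n")
})
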