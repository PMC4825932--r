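## Reading peak calls and genome files, building binarized mark tracksets,
## extracting observation vectors and training samples, and writing score /
## binary-annotation tracks. File formats are BED-family (0-based half-open);
## in-memory objects are GRanges/Rle (1-based closed).

#' Read peak intervals from a BED or narrowPeak file
#'
#' Reads the first three columns (chrom, start, end; 0-based half-open),
#' validates them line by line, and returns the merged interval set.
#' Columns beyond the third (e.g. the 7 extra narrowPeak columns) are
#' ignored. Lines starting with \code{#}, \code{track} or \code{browser}
#' are skipped.
#'
#' @param path path to a tab-separated BED3+/narrowPeak file.
#' @param format one of \code{"auto"}, \code{"bed"}, \code{"narrowPeak"};
#'   informational only, since both formats share the first three columns.
#' @return A sorted, reduced \code{GRanges} (overlapping or book-ended
#'   input intervals are merged).
#' @export
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t200", "chr1\t150\t300"), f)
#' readPeakIntervals(f)  # single interval chr1:101-300
readPeakIntervals <- function(path, format = c("auto", "bed", "narrowPeak")) {
    format <- match.arg(format)
    if (!file.exists(path))
        stop("peak file not found: ", path)
    lines <- readLines(path)
    keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
    if (!any(keep))
        return(GRanges())
    idx <- which(keep)
    fields <- strsplit(lines[idx], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop("line ", idx[which(nf < 3L)[1L]], " of '", basename(path),
             "': fewer than 3 tab-separated columns")
    chrom <- vapply(fields, `[[`, character(1), 1L)
    s <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
    e <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
    bad <- is.na(s) | is.na(e) | s != floor(s) | e != floor(e)
    if (any(bad))
        stop("line ", idx[which(bad)[1L]], " of '", basename(path),
             "': non-integer coordinates")
    bad <- s < 0 | s >= e
    if (any(bad))
        stop("line ", idx[which(bad)[1L]], " of '", basename(path),
             "': requires 0 <= start < end")
    gr <- GRanges(chrom, IRanges(start = s + 1, end = e))
    sort(reduce(gr))
}

#' Read a two-column genome sizes file
#'
#' @param path path to a tab-separated \code{chrom\\tlength} file.
#' @return Named integer vector of chromosome lengths.
#' @export
readGenomeFile <- function(path) {
    if (!file.exists(path))
        stop("genome file not found: ", path)
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             col.names = c("chrom", "length"),
                             colClasses = c("character", "numeric"))
    if (any(tab$length <= 0 | tab$length != floor(tab$length)))
        stop("genome lengths must be positive integers")
    stats::setNames(as.integer(tab$length), tab$chrom)
}

#' Build a MarkTrackSet from per-mark peak files
#'
#' For each mark, the peak coverage is the interval union across all sample
#' files for that mark, clipped to the genome bounds. All eight marks must
#' be supplied.
#'
#' @param sampleFiles named list (one element per mark, in the desired mark
#'   order) of character vectors of peak file paths.
#' @param genome named integer vector of chromosome lengths, or a path to a
#'   genome sizes file.
#' @param tissueLabel tissue group name.
#' @return A \code{MarkTrackSet}.
#' @export
buildMarkTrackSet <- function(sampleFiles, genome, tissueLabel = "tissue") {
    if (is.character(genome) && length(genome) == 1L && file.exists(genome))
        genome <- readGenomeFile(genome)
    marks <- names(sampleFiles)
    if (is.null(marks) || length(sampleFiles) != .N_MARKS)
        stop("sampleFiles must be a named list with one entry per mark (8)")
    empty <- vapply(sampleFiles, length, integer(1)) == 0L
    if (any(empty))
        stop("no peak files for mark(s): ", paste(marks[empty],
             collapse = ", "))
    si <- Seqinfo(seqnames = names(genome), seqlengths = unname(genome))
    grl <- lapply(sampleFiles, function(files) {
        grs <- lapply(files, readPeakIntervals)
        gr <- reduce(do.call(c, grs))
        gr <- gr[as.character(seqnames(gr)) %in% names(genome)]
        GenomeInfoDb::seqlevels(gr) <- names(genome)
        seqinfo(gr) <- si
        sort(IRanges::trim(gr))
    })
    new("MarkTrackSet", tissueLabel = tissueLabel, marks = marks,
        peaks = GRangesList(grl, compress = FALSE), seqinfo = si)
}

#' Mark observation vector at one genomic position
#'
#' @param ts a \code{MarkTrackSet}.
#' @param chrom chromosome name.
#' @param pos 1-based position.
#' @return Named integer(8); entry \code{i} is 1 iff the position is covered
#'   by a peak for mark \code{i}.
#' @export
markVectorAt <- function(ts, chrom, pos) {
    sl <- genomeLengths(ts)
    if (!chrom %in% names(sl))
        stop("unknown chromosome: ", chrom)
    if (pos < 1L || pos > sl[[chrom]])
        stop("position ", pos, " outside ", chrom, " (length ", sl[[chrom]], ")")
    q <- GRanges(chrom, IRanges(pos, pos))
    v <- vapply(peaks(ts), function(gr) as.integer(countOverlaps(q, gr) > 0L),
                integer(1))
    stats::setNames(v, markNames(ts))
}

#' Build a training sample from seed positions
#'
#' Each seed is expanded to a fixed-width window (default 1 kb: the seed bp
#' plus \code{flankBp} on each side minus one, mirroring the convention that
#' significant GWAS positions tag nearby functional elements of uncertain
#' extent). Overlapping windows are merged so every bp contributes exactly
#' one observation, then converted into mark-pattern counts.
#'
#' @param seeds data.frame with columns \code{CHR} and \code{BP} (1-based),
#'   or a \code{GRanges} of width-1 positions.
#' @param ts a \code{MarkTrackSet}.
#' @param flankBp flank on each side of the seed; window width is
#'   \code{2 * flankBp} (500 gives the default 1000 bp windows).
#' @return A \code{TrainingSample}. Seeds on unknown chromosomes or outside
#'   the genome are skipped with a warning giving their count.
#' @export
buildTrainingSample <- function(seeds, ts, flankBp = 500L) {
    sl <- genomeLengths(ts)
    if (is(seeds, "GRanges"))
        seeds <- data.frame(CHR = as.character(seqnames(seeds)),
                            BP = start(seeds))
    ok <- seeds$CHR %in% names(sl)
    ok[ok] <- seeds$BP[ok] >= 1L & seeds$BP[ok] <= sl[seeds$CHR[ok]]
    if (any(!ok))
        warning(sum(!ok), " seed(s) outside the genome were skipped")
    seeds <- seeds[ok, , drop = FALSE]
    if (nrow(seeds) == 0L)
        stop("no usable seeds")
    ## 0-based window [pos0 - flank, pos0 + flank) maps to 1-based
    ## [BP - flank, BP + flank - 1], width 2 * flank
    gr <- GRanges(seeds$CHR,
                  IRanges(start = pmax(1L, seeds$BP - flankBp),
                          end = pmin(sl[seeds$CHR], seeds$BP + flankBp - 1L)),
                  seqinfo = Seqinfo(names(sl), unname(sl)))
    merged <- reduce(sort(gr))
    pr <- .patternRle(ts)
    counts <- numeric(.N_PATTERNS)
    for (chrom in unique(as.character(seqnames(merged)))) {
        ir <- IRanges::ranges(merged[seqnames(merged) == chrom])
        counts <- counts + .rleTabulate(.rleRestrict(pr[[chrom]], ir))
    }
    new("TrainingSample", marks = markNames(ts), patternCounts = counts,
        sourceIntervals = merged, totalBp = sum(as.numeric(width(merged))))
}

#' Write a ScoreTrack as bedGraph
#'
#' One line per maximal constant-score run (adjacent equal-score runs are
#' already merged in the run-length encoding), 0-based half-open
#' coordinates, scores printed with full precision so a read-back
#' reproduces the track to better than 1e-9.
#'
#' @param track a \code{ScoreTrack}.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeScoreTrack <- function(track, path) {
    con <- file(path, open = "wt")
    on.exit(close(con))
    rl <- scoreRle(track)
    for (chrom in names(rl)) {
        r <- rl[[chrom]]
        ends <- cumsum(as.numeric(runLength(r)))
        starts <- c(0, ends[-length(ends)])
        writeLines(sprintf("%s\t%.0f\t%.0f\t%.17g", chrom, starts, ends,
                           runValue(r)), con)
    }
    invisible(path)
}

#' Read a bedGraph score track
#'
#' @param path bedGraph path (chrom, start, end, score; 0-based half-open).
#' @param genome optional named integer vector of chromosome lengths (or
#'   genome file path); when omitted, each chromosome's length is taken as
#'   the largest end coordinate seen. Uncovered positions score 0.
#' @return A \code{ScoreTrack}.
#' @export
readScoreTrack <- function(path, genome = NULL) {
    if (is.character(genome) && length(genome) == 1L && file.exists(genome))
        genome <- readGenomeFile(genome)
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             col.names = c("chrom", "start", "end", "score"),
                             colClasses = c("character", "numeric", "numeric",
                                            "numeric"))
    if (is.null(genome))
        genome <- vapply(split(tab$end, tab$chrom), max, numeric(1))
    rl <- lapply(names(genome), function(chrom) {
        len <- genome[[chrom]]
        sub <- tab[tab$chrom == chrom, , drop = FALSE]
        if (nrow(sub) == 0L)
            return(Rle(0, len))
        sub <- sub[order(sub$start), , drop = FALSE]
        n <- nrow(sub)
        if (any(sub$end > len))
            stop("bedGraph interval exceeds length of ", chrom)
        if (n > 1L && any(sub$start[-1L] < sub$end[-n]))
            stop("overlapping bedGraph intervals on ", chrom)
        ## interleave zero-filled gaps with scored runs, then trailing gap
        gapBefore <- sub$start - c(0, sub$end[-n])
        vals <- c(rbind(0, sub$score), 0)
        lens <- c(rbind(gapBefore, sub$end - sub$start), len - sub$end[n])
        Rle(vals[lens > 0], lens[lens > 0])
    })
    names(rl) <- names(genome)
    ScoreTrack(RleList(rl, compress = FALSE))
}

#' Threshold a ScoreTrack into a binary annotation
#'
#' @param track a \code{ScoreTrack}.
#' @param cutoff score cutoff in [0, 1]; bp with score >= cutoff are
#'   annotated (0.5 is the conventional cutoff for calling a bp functional).
#' @return A reduced \code{GRanges} of annotated intervals.
#' @export
exportBinaryAnnotation <- function(track, cutoff = 0.5) {
    stopifnot(cutoff >= 0, cutoff <= 1)
    rl <- scoreRle(track)
    grs <- lapply(names(rl), function(chrom) {
        ir <- as(slice(rl[[chrom]], lower = cutoff, includeLower = TRUE,
                       rangesOnly = TRUE), "IRanges")
        GRanges(rep(chrom, length(ir)), ir)
    })
    reduce(do.call(c, grs))
}

#' Write intervals as BED3
#'
#' @param gr a \code{GRanges}.
#' @param path output path (0-based half-open BED).
#' @return Invisibly, the path.
#' @export
writeBed <- function(gr, path) {
    writeLines(sprintf("%s\t%.0f\t%.0f", as.character(seqnames(gr)),
                       start(gr) - 1, end(gr)), path)
    invisible(path)
}
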