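## Internal helpers for the 8-mark binary pattern encoding.
##
## A pattern is the 8-vector A of mark indicators at one bp. Its integer
## code is sum(A_i * 2^(i-1)) in mark order, i.e. mark 1 is the least
## significant bit; codes run 0..255.

## 256 x 8 matrix of all patterns, row k+1 = pattern with code k
.patternMatrix <- function() {
    k <- 0:(.N_PATTERNS - 1L)
    m <- vapply(seq_len(.N_MARKS),
                function(i) as.numeric(bitwAnd(k, bitwShiftL(1L, i - 1L)) > 0L),
                numeric(.N_PATTERNS))
    dimnames(m) <- NULL
    m
}

## integer codes (0..255) for a matrix of 0/1 observations (n x 8)
.patternCodes <- function(a) {
    a <- matrix(as.integer(a), ncol = .N_MARKS)
    code <- integer(nrow(a))
    for (i in seq_len(.N_MARKS))
        code <- code + a[, i] * bitwShiftL(1L, i - 1L)
    code
}

## integer RleList of pattern codes over the whole genome of a MarkTrackSet
.patternRle <- function(ts) {
    sl <- genomeLengths(ts)
    covs <- lapply(seq_len(.N_MARKS), function(i)
        coverage(peaks(ts)[[i]], width = sl))
    out <- lapply(names(sl), function(chrom) {
        r <- covs[[1L]][[chrom]]
        ## peak coverage is 0/1 (peaks are reduced), so this sum is the code
        if (.N_MARKS > 1L)
            for (i in 2:.N_MARKS)
                r <- r + covs[[i]][[chrom]] * bitwShiftL(1L, i - 1L)
        r
    })
    names(out) <- names(sl)
    RleList(out, compress = FALSE)
}

## tabulate an integer Rle (values 0..255) into counts of length 256,
## weighting by run lengths -- no per-bp expansion
.rleTabulate <- function(r, n = .N_PATTERNS) {
    v <- as.integer(runValue(r))
    l <- as.numeric(runLength(r))
    counts <- numeric(n)
    agg <- rowsum(l, v)
    counts[as.integer(rownames(agg)) + 1L] <- agg[, 1L]
    counts
}

## concatenated Rle of r restricted to an IRanges (sorted, disjoint)
.rleRestrict <- function(r, ir) {
    if (length(ir) == 0L) return(Rle(integer(0)))
    unlist(extractList(r, ir), use.names = FALSE)
}
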