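## Locus-level analytics: local maximum GSP and relevant-tissue assignment
## (with tie handling), genome-wide best rank per locus, exact one-sided
## binomial comparison of rank improvements, and fold-enrichment curves
## for top-ranked SNPs.

#' Read risk loci from a BED3+label file
#'
#' @param path BED file (chrom, start, end, optional label; 0-based
#'   half-open).
#' @return data.frame with columns CHR, START, END (1-based closed) and
#'   LABEL.
#' @export
readLoci <- function(path) {
    gr <- readPeakIntervals(path)  # validates coordinates; merges nothing new
    lines <- readLines(path)
    keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    chrom <- vapply(fields, `[[`, character(1), 1L)
    s <- as.numeric(vapply(fields, `[[`, character(1), 2L))
    e <- as.numeric(vapply(fields, `[[`, character(1), 3L))
    lab <- vapply(seq_along(fields), function(i)
        if (length(fields[[i]]) >= 4L) fields[[i]][[4L]]
        else paste0(chrom[i], ":", s[i], "-", e[i]), character(1))
    data.frame(CHR = chrom, START = s + 1, END = e, LABEL = lab,
               stringsAsFactors = FALSE)
}

#' Local maximum GSP and relevant tissue for one risk locus
#'
#' For each tissue, the local maximum GSP is the largest GSP among SNPs in
#' the locus; the tissue attaining the overall largest value is the
#' predicted relevant tissue. When the top two per-tissue maxima differ by
#' less than \code{tieTol} the assignment is flagged as a tie and all
#' tissues within \code{tieTol} of the maximum are listed.
#'
#' @param gspByTissue named list (one element per tissue) of data.frames
#'   with columns CHR, BP, GSP.
#' @param locus a single-row data.frame with CHR, START, END (1-based
#'   closed) and optionally LABEL.
#' @param tieTol tie tolerance on the posterior scale (default 1e-4,
#'   matching typical reporting precision).
#' @return list with \code{perTissueMax} (named numeric),
#'   \code{relevantTissue} (character, all tied tissues when tied),
#'   \code{tie} (logical) and \code{tieTolerance}.
#' @export
localMaxGsp <- function(gspByTissue, locus, tieTol = 1e-4) {
    label <- if ("LABEL" %in% names(locus)) locus$LABEL else
        paste0(locus$CHR, ":", locus$START, "-", locus$END)
    perTissueMax <- vapply(gspByTissue, function(df) {
        inside <- df$CHR == locus$CHR & df$BP >= locus$START &
            df$BP <= locus$END
        if (!any(inside)) NA_real_ else max(df$GSP[inside])
    }, numeric(1))
    if (all(is.na(perTissueMax)))
        stop("no SNPs inside locus '", label, "'")
    top <- max(perTissueMax, na.rm = TRUE)
    tied <- names(perTissueMax)[!is.na(perTissueMax) &
                                perTissueMax > top - tieTol]
    list(perTissueMax = perTissueMax,
         relevantTissue = tied,
         tie = length(tied) > 1L,
         tieTolerance = tieTol)
}

#' Relevant-tissue table for a set of risk loci
#'
#' @param gspByTissue named list of per-tissue scored SNP data.frames
#'   (columns CHR, BP, GSP).
#' @param loci data.frame of loci (see \code{readLoci}).
#' @param tieTol tie tolerance.
#' @return data.frame with one row per locus: LABEL, per-tissue local
#'   maximum GSP columns, RELEVANT_TISSUE (\code{"NA (tie)"} when tied)
#'   and TIE.
#' @export
locusTissueTable <- function(gspByTissue, loci, tieTol = 1e-4) {
    rows <- lapply(seq_len(nrow(loci)), function(i) {
        rep <- localMaxGsp(gspByTissue, loci[i, , drop = FALSE], tieTol)
        out <- data.frame(LABEL = loci$LABEL[i], stringsAsFactors = FALSE)
        for (tissue in names(rep$perTissueMax))
            out[[tissue]] <- rep$perTissueMax[[tissue]]
        out$RELEVANT_TISSUE <- if (rep$tie) "NA (tie)" else rep$relevantTissue
        out$TIE <- rep$tie
        out
    })
    do.call(rbind, rows)
}

#' Best genome-wide rank attained inside each locus
#'
#' SNPs are ranked genome-wide (rank 1 = best; ties share the minimum,
#' i.e. competition ranking) and each locus is assigned the numerically
#' smallest rank among its SNPs.
#'
#' @param snps data.frame with columns CHR, BP and the score column.
#' @param scoreCol name of the column to rank on.
#' @param loci data.frame of loci (CHR, START, END, LABEL).
#' @param direction \code{"higher_better"} (posterior scores) or
#'   \code{"lower_better"} (p-values).
#' @return Named numeric vector, one best rank per locus label; loci
#'   containing no SNPs are dropped with a warning naming them.
#' @export
bestRankAtLoci <- function(snps, scoreCol, loci,
                           direction = c("higher_better", "lower_better")) {
    direction <- match.arg(direction)
    s <- snps[[scoreCol]]
    if (is.null(s))
        stop("no column '", scoreCol, "' in snps")
    rk <- if (direction == "higher_better")
        rank(-s, ties.method = "min") else rank(s, ties.method = "min")
    out <- numeric(0)
    empty <- character(0)
    for (i in seq_len(nrow(loci))) {
        inside <- snps$CHR == loci$CHR[i] & snps$BP >= loci$START[i] &
            snps$BP <= loci$END[i]
        if (!any(inside)) {
            empty <- c(empty, loci$LABEL[i])
        } else {
            out[loci$LABEL[i]] <- min(rk[inside])
        }
    }
    if (length(empty))
        warning("locus/loci without SNPs excluded: ",
                paste(empty, collapse = ", "))
    out
}

#' Exact one-sided binomial test for an improvement count
#'
#' Tests whether \code{nImproved} successes out of \code{nTotal}
#' informative comparisons exceed chance (probability 1/2):
#' \eqn{P(X \ge n_{improved})} for \eqn{X \sim Bin(n_{total}, 1/2)}.
#'
#' @param nImproved number of comparisons favoring the second method.
#' @param nTotal number of strictly differing comparisons.
#' @return list with \code{nImproved}, \code{nTotal}, \code{pValue}.
#' @export
#' @examples
#' binomialImprovementTest(67, 105)$pValue  # ~0.003
binomialImprovementTest <- function(nImproved, nTotal) {
    stopifnot(nTotal >= 1, nImproved >= 0, nImproved <= nTotal)
    list(nImproved = as.integer(nImproved), nTotal = as.integer(nTotal),
         pValue = stats::pbinom(nImproved - 1, nTotal, 0.5,
                                lower.tail = FALSE))
}

#' Compare per-locus ranks of two methods
#'
#' Counts loci where method B attains a strictly better (numerically
#' smaller) best rank than method A; loci with tied ranks are dropped; the
#' exact one-sided binomial tail gives the p-value.
#'
#' @param ranksA,ranksB named numeric vectors over the same locus labels
#'   (see \code{bestRankAtLoci}).
#' @return list with \code{nImproved}, \code{nTotal}, \code{pValue}.
#' @export
rankImprovementTest <- function(ranksA, ranksB) {
    if (!setequal(names(ranksA), names(ranksB)))
        stop("the two rank maps must cover the same loci")
    ranksB <- ranksB[names(ranksA)]
    diffNonzero <- ranksA != ranksB
    nTotal <- sum(diffNonzero)
    if (nTotal == 0L)
        stop("all per-locus ranks tie between the two methods")
    binomialImprovementTest(sum(ranksB < ranksA), nTotal)
}

#' Fold enrichment of a target set among top-ranked SNPs
#'
#' \code{fold(N)} is the target rate among the N top-ranked SNPs divided by
#' the genome-wide target rate.
#'
#' @param rankedSnps character vector of SNP ids, best first.
#' @param targetSet character vector of target SNP ids (e.g. eQTLs).
#' @param topNs integer vector of top-list sizes.
#' @return data.frame with columns N and fold.
#' @export
enrichmentCurve <- function(rankedSnps, targetSet, topNs) {
    total <- length(rankedSnps)
    if (any(topNs > total))
        stop("top-N exceeds the number of ranked SNPs")
    isTarget <- rankedSnps %in% targetSet
    baseRate <- sum(isTarget) / total
    if (baseRate == 0)
        stop("target set and ranked SNPs do not intersect")
    hits <- cumsum(isTarget)
    data.frame(N = as.integer(topNs),
               fold = (hits[topNs] / topNs) / baseRate)
}
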