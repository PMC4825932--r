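## SNP prioritization from GWAS summary statistics: per-SNP window-mean
## functionality priors, histogram null densities chosen by cross
## validation, a beta-uniform signal mixture fitted by closed-form EM, and
## the posterior scores -- GSP (joint disease- and tissue-functionality)
## and NSFP (disease functionality from a general score track).

.P_FLOOR <- 1e-300
.ALPHA_CLIP <- 1e-4

## clip p-values into (1e-300, 1] so log p is finite
.clipP <- function(p) pmin(pmax(p, .P_FLOOR), 1)

#' Read GWAS summary statistics
#'
#' Whitespace/tab-delimited table with a header; required columns
#' \code{CHR}, \code{BP}, \code{P} (case-insensitive), optional \code{SNP}.
#' Missing SNP ids are synthesized as \code{chrom:pos}.
#'
#' @param path file path.
#' @return data.frame with columns SNP, CHR, BP, P.
#' @export
readGwas <- function(path) {
    tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
    names(tab) <- toupper(names(tab))
    need <- c("CHR", "BP", "P")
    miss <- setdiff(need, names(tab))
    if (length(miss))
        stop("GWAS table lacks required column(s): ",
             paste(miss, collapse = ", "))
    if (!"SNP" %in% names(tab))
        tab$SNP <- paste0(tab$CHR, ":", tab$BP)
    if (any(tab$P <= 0 | tab$P > 1))
        stop("p-values must lie in (0, 1]")
    tab[, c("SNP", "CHR", "BP", "P",
            setdiff(names(tab), c("SNP", "CHR", "BP", "P")))]
}

#' Assign window-mean functionality priors to SNPs
#'
#' The per-SNP prior of tissue functionality, P(Z_T = 1), is the mean
#' tissue score over the surrounding window (default 10 kb); the general
#' functionality prior is computed the same way from the general score
#' track. Windows are clipped at chromosome bounds; unannotated bp score 0.
#'
#' @param snps data.frame with columns CHR, BP (1-based), P.
#' @param tissueTrack \code{ScoreTrack} of tissue functionality scores.
#' @param generalTrack \code{ScoreTrack} of general functionality scores
#'   (an externally produced track); when \code{NULL} the tissue track is
#'   substituted with a warning, making NSFP a same-track baseline.
#' @param windowBp even window width in bp (default 10000).
#' @return \code{snps} with columns \code{PRIOR_T} and \code{PRIOR_G}
#'   appended; SNPs on chromosomes absent from the track genome are dropped
#'   with a warning.
#' @export
assignPriors <- function(snps, tissueTrack, generalTrack = NULL,
                         windowBp = 10000L) {
    stopifnot(windowBp %% 2 == 0, windowBp > 0)
    if (is.null(generalTrack)) {
        warning("no general-functionality track supplied; ",
                "using the tissue track (NSFP becomes a same-track baseline)")
        generalTrack <- tissueTrack
    }
    gl <- genomeLengths(tissueTrack)
    if (!identical(gl, genomeLengths(generalTrack)))
        stop("tissue and general tracks must share the same genome")
    ok <- snps$CHR %in% names(gl)
    if (any(!ok)) {
        warning(sum(!ok), " SNP(s) on chromosomes absent from the score ",
                "track were skipped")
        snps <- snps[ok, , drop = FALSE]
    }
    half <- windowBp %/% 2L
    windowMean <- function(track) {
        out <- numeric(nrow(snps))
        for (chrom in unique(snps$CHR)) {
            i <- which(snps$CHR == chrom)
            s <- pmax(1L, snps$BP[i] - half)
            e <- pmin(gl[[chrom]], snps$BP[i] + half - 1L)
            out[i] <- viewMeans(Views(scoreRle(track)[[chrom]],
                                      start = s, end = e))
        }
        out
    }
    snps$PRIOR_T <- windowMean(tissueTrack)
    snps$PRIOR_G <- windowMean(generalTrack)
    snps
}

#' Partition SNPs by a functionality prior
#'
#' @param snps data.frame with priors assigned (see \code{assignPriors}).
#' @param which which prior to threshold: \code{"tissue"} (PRIOR_T) or
#'   \code{"general"} (PRIOR_G).
#' @param threshold prior threshold (default 0.1; the window-mean priors
#'   are bimodal, so the split is insensitive to this choice).
#' @return list with data.frames \code{low} (prior < threshold) and
#'   \code{high} (prior >= threshold).
#' @export
partitionSnps <- function(snps, which = c("tissue", "general"),
                          threshold = 0.1) {
    which <- match.arg(which)
    col <- if (which == "tissue") "PRIOR_T" else "PRIOR_G"
    if (!col %in% names(snps))
        stop("priors not assigned; run assignPriors() first")
    high <- snps[[col]] >= threshold
    if (all(high) || !any(high))
        stop("prior partition at threshold ", threshold, " left the '",
             if (all(high)) "low" else "high",
             "' subset empty; threshold and data are mismatched")
    list(low = snps[!high, , drop = FALSE],
         high = snps[high, , drop = FALSE])
}

## equal-width bin index on [0, 1] for clipped p-values
.binIndex <- function(p, nb) pmin(pmax(ceiling(.clipP(p) * nb), 1L), nb)

#' Fit a histogram density on [0, 1] with cross-validated bin count
#'
#' Equal-width histogram with +0.5 pseudocount per bin. The number of bins
#' is chosen by K-fold cross validation maximizing the mean held-out
#' log-likelihood; ties go to the fewest bins.
#'
#' @param pvalues numeric vector in (0, 1], at least 50 values.
#' @param candidateBins integer vector of candidate bin counts.
#' @param folds number of CV folds.
#' @param seed RNG seed for the fold shuffle.
#' @return A \code{HistogramDensity}; the selected bin count is
#'   \code{nBins()} of the result.
#' @export
fitHistogramDensity <- function(pvalues, candidateBins = c(5L, seq(10L, 200L,
                                by = 10L)), folds = 10L, seed = 1L) {
    p <- .clipP(pvalues)
    n <- length(p)
    if (n < 50L)
        stop("need at least 50 p-values to fit a histogram density, got ", n)
    candidateBins <- sort(unique(as.integer(candidateBins)))
    fold <- withr::with_seed(seed, sample(rep_len(seq_len(folds), n)))
    cvll <- vapply(candidateBins, function(nb) {
        idx <- .binIndex(p, nb)
        full <- tabulate(idx, nb)
        ll <- vapply(seq_len(folds), function(f) {
            test <- fold == f
            cnt <- full - tabulate(idx[test], nb) + 0.5
            h <- cnt / sum(cnt) * nb   # density heights, bin width 1/nb
            sum(log(h[idx[test]]))
        }, numeric(1))
        mean(ll)
    }, numeric(1))
    nb <- candidateBins[which.max(cvll)]   # first max = fewest bins on ties
    cnt <- tabulate(.binIndex(p, nb), nb) + 0.5
    new("HistogramDensity", breaks = seq(0, 1, length.out = nb + 1L),
        heights = cnt / sum(cnt) * nb)
}

#' Evaluate a histogram density
#'
#' @param h a \code{HistogramDensity}.
#' @param p p-values in (0, 1] (clipped below at 1e-300).
#' @return Density heights at \code{p}.
#' @export
evalDensity <- function(h, p) {
    h@heights[.binIndex(p, nBins(h))]
}

## Beta(alpha, 1) density alpha * p^(alpha - 1), on clipped p
.betaDensity <- function(p, alpha) {
    p <- .clipP(p)
    alpha * p^(alpha - 1)
}

#' Fit the beta-uniform signal mixture by EM
#'
#' Models the p-values of SNPs in functional regions as the mixture
#' \eqn{f(p) = w\,\alpha p^{\alpha-1} + (1-w)\,f_0(p)} with a fixed,
#' previously estimated null density \eqn{f_0}. Both M-step updates are
#' closed form: \eqn{w = \bar r} and
#' \eqn{\alpha = -\sum r_j / \sum r_j \log p_j}.
#'
#' @param pvalues p-values of the high-prior SNP partition (>= 50).
#' @param fNull a \code{HistogramDensity} for the null component.
#' @param wInit,alphaInit starting values.
#' @param tol relative log-likelihood change declaring convergence.
#' @param maxIter iteration cap; on hitting it the fit is returned with
#'   \code{converged = FALSE}.
#' @return list with \code{alpha}, \code{w} (the conditional probability of
#'   disease functionality given tissue functionality) and \code{trace}
#'   (\code{EmTrace}).
#' @export
fitSignalMixture <- function(pvalues, fNull, wInit = 0.5, alphaInit = 0.5,
                             tol = 1e-8, maxIter = 1000L) {
    p <- .clipP(pvalues)
    if (length(p) < 50L)
        stop("need at least 50 p-values to fit the signal mixture")
    logp <- log(p)
    f0 <- evalDensity(fNull, p)
    w <- wInit; alpha <- alphaInit
    ll <- -Inf
    logLik <- numeric(0)
    converged <- FALSE
    for (it in seq_len(maxIter)) {
        sig <- .betaDensity(p, alpha)
        num <- w * sig
        den <- num + (1 - w) * f0
        llNew <- sum(log(den))
        logLik <- c(logLik, llNew)
        r <- num / den
        w <- mean(r)
        alpha <- -sum(r) / sum(r * logp)
        alpha <- min(max(alpha, .ALPHA_CLIP), 1 - .ALPHA_CLIP)
        if (is.finite(ll) && abs(llNew - ll) < tol * abs(llNew)) {
            converged <- TRUE
            break
        }
        ll <- llNew
    }
    list(alpha = alpha, w = w,
         trace = new("EmTrace", logLik = logLik, nIter = length(logLik),
                     converged = converged))
}

#' Fit the full p-value model for SNP prioritization
#'
#' Composes the estimation pipeline: histogram null densities from the
#' low-prior partitions (tissue and general), then beta-uniform signal
#' mixtures on the high-prior partitions, using the general null
#' \eqn{f(p \mid Z=0)} as the null component in both mixtures.
#'
#' @param snps data.frame with priors assigned.
#' @param threshold prior threshold for the partitions.
#' @param windowBp window width recorded in the model (bp).
#' @param candidateBins,folds,seed passed to \code{fitHistogramDensity}.
#' @return A \code{PValueModel}.
#' @export
fitPValueModel <- function(snps, threshold = 0.1, windowBp = 10000L,
                           candidateBins = c(5L, seq(10L, 200L, by = 10L)),
                           folds = 10L, seed = 1L) {
    partT <- partitionSnps(snps, "tissue", threshold)
    partG <- partitionSnps(snps, "general", threshold)
    fTissueNull <- fitHistogramDensity(partT$low$P, candidateBins, folds, seed)
    fGeneralNull <- fitHistogramDensity(partG$low$P, candidateBins, folds,
                                        seed)
    fitT <- fitSignalMixture(partT$high$P, fGeneralNull)
    fitG <- fitSignalMixture(partG$high$P, fGeneralNull)
    new("PValueModel",
        fTissueNull = fTissueNull, fGeneralNull = fGeneralNull,
        alphaTissue = fitT$alpha, wCond = fitT$w,
        alphaGeneral = fitG$alpha, wGeneral = fitG$w,
        traceTissue = fitT$trace, traceGeneral = fitG$trace,
        threshold = threshold, windowBp = as.numeric(windowBp))
}

#' Posterior probabilities of the three SNP cases
#'
#' Case I: disease- and tissue-functional; case II: tissue-functional only;
#' case III: not tissue-functional. Given the p-value and the per-SNP
#' tissue prior t, the unnormalized case masses are
#' \eqn{f_{sig}(p)\, w\, t}, \eqn{f(p|Z=0)\,(1-w)\, t} and
#' \eqn{f(p|Z_T=0)\,(1-t)}; the three posteriors sum to 1.
#'
#' @param p p-value(s).
#' @param priorT per-SNP tissue-functionality prior(s).
#' @param model a \code{PValueModel}.
#' @return n x 3 matrix with columns case1, case2, case3.
#' @export
casePosteriors <- function(p, priorT, model) {
    t <- priorT
    c1 <- .betaDensity(p, model@alphaTissue) * model@wCond * t
    c2 <- evalDensity(model@fGeneralNull, p) * (1 - model@wCond) * t
    c3 <- evalDensity(model@fTissueNull, p) * (1 - t)
    tot <- c1 + c2 + c3
    cbind(case1 = c1 / tot, case2 = c2 / tot, case3 = c3 / tot)
}

#' GSP score: posterior of joint disease- and tissue-functionality
#'
#' @inheritParams casePosteriors
#' @return \eqn{P(Z_D=1, Z_T=1 \mid p)} in [0, 1]; exactly 0 when the
#'   tissue prior is 0.
#' @export
gspScore <- function(p, priorT, model) {
    unname(casePosteriors(p, priorT, model)[, "case1"])
}

#' NSFP score: posterior of disease functionality from a general score
#'
#' Two-case model on the general-functionality track:
#' \eqn{P(Z_D=1 \mid p) = f_{sig}(p)\,g / [f_{sig}(p)\,g + f_0(p)\,(1-g)]}
#' with per-SNP prior \eqn{g = \mathrm{PRIOR\_G} \times w_{general}}.
#'
#' @param p p-value(s).
#' @param priorG per-SNP general-functionality prior(s).
#' @param model a \code{PValueModel}.
#' @return Posterior(s) in [0, 1].
#' @export
nsfpScore <- function(p, priorG, model) {
    g <- priorG * model@wGeneral
    sig <- .betaDensity(p, model@alphaGeneral)
    f0 <- evalDensity(model@fGeneralNull, p)
    num <- sig * g
    den <- num + f0 * (1 - g)
    out <- num / den
    out[g == 0] <- 0
    out
}

#' End-to-end SNP prioritization
#'
#' Assigns window-mean priors, partitions SNPs, fits the p-value model, and
#' appends GSP and NSFP scores. Deterministic given \code{seed}.
#'
#' @param snps GWAS data.frame (columns CHR, BP, P; see \code{readGwas}).
#' @param tissueTrack tissue \code{ScoreTrack}.
#' @param generalTrack general-functionality \code{ScoreTrack} or NULL.
#' @param windowBp prior window width.
#' @param threshold prior partition threshold.
#' @param candidateBins,folds,seed histogram CV settings.
#' @return The annotated data.frame with columns PRIOR_T, PRIOR_G, GSP,
#'   NSFP appended; the fitted \code{PValueModel} is attached as
#'   \code{attr(, "model")}.
#' @export
prioritize <- function(snps, tissueTrack, generalTrack = NULL,
                       windowBp = 10000L, threshold = 0.1,
                       candidateBins = c(5L, seq(10L, 200L, by = 10L)),
                       folds = 10L, seed = 1L) {
    snps <- assignPriors(snps, tissueTrack, generalTrack, windowBp)
    model <- fitPValueModel(snps, threshold, windowBp, candidateBins, folds,
                            seed)
    snps$GSP <- gspScore(snps$P, snps$PRIOR_T, model)
    snps$NSFP <- nsfpScore(snps$P, snps$PRIOR_G, model)
    attr(snps, "model") <- model
    snps
}

#' Serialize a PValueModel as key-value text
#'
#' @param model a \code{PValueModel}.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writePValueModel <- function(model, path) {
    num <- function(x) paste(sprintf("%.17g", x), collapse = ",")
    writeLines(c(
        paste0("alpha_tissue\t", num(model@alphaTissue)),
        paste0("w_cond\t", num(model@wCond)),
        paste0("alpha_general\t", num(model@alphaGeneral)),
        paste0("w_general\t", num(model@wGeneral)),
        paste0("threshold\t", num(model@threshold)),
        paste0("window_bp\t", num(model@windowBp)),
        paste0("tissue_null_heights\t", num(model@fTissueNull@heights)),
        paste0("general_null_heights\t", num(model@fGeneralNull@heights))),
        path)
    invisible(path)
}

#' Read a PValueModel written by \code{writePValueModel}
#'
#' @param path model file path.
#' @return A \code{PValueModel} (EM traces are not serialized and come back
#'   empty).
#' @export
readPValueModel <- function(path) {
    kv <- strsplit(readLines(path), "\t", fixed = TRUE)
    vals <- stats::setNames(lapply(kv, function(x)
        as.numeric(strsplit(x[[2L]], ",")[[1L]])),
        vapply(kv, `[[`, character(1), 1L))
    mkHist <- function(h)
        new("HistogramDensity",
            breaks = seq(0, 1, length.out = length(h) + 1L), heights = h)
    emptyTrace <- new("EmTrace", logLik = numeric(0), nIter = 0L,
                      converged = NA)
    new("PValueModel",
        fTissueNull = mkHist(vals[["tissue_null_heights"]]),
        fGeneralNull = mkHist(vals[["general_null_heights"]]),
        alphaTissue = vals[["alpha_tissue"]], wCond = vals[["w_cond"]],
        alphaGeneral = vals[["alpha_general"]],
        wGeneral = vals[["w_general"]],
        traceTissue = emptyTrace, traceGeneral = emptyTrace,
        threshold = vals[["threshold"]], windowBp = vals[["window_bp"]])
}
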