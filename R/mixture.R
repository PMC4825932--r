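## Two-component Bernoulli mixture over the 8 binary marks: likelihood,
## EM fitting, per-position posterior (the GS score), genome-wide scoring
## and genome-level summaries. All genome-scale computation runs over the
## <= 256 distinct mark patterns with bp multiplicities, never per bp.

.RATE_CLIP <- 1e-6

## per-pattern log component densities; accumulation is an explicit loop
## over marks so pattern-table and per-observation evaluation follow the
## identical floating-point path
.componentLogLik <- function(a, p) {
    a <- matrix(as.numeric(a), ncol = .N_MARKS)
    lp <- log(p); lq <- log1p(-p)
    ll <- numeric(nrow(a))
    for (i in seq_len(.N_MARKS))
        ll <- ll + a[, i] * lp[i] + (1 - a[, i]) * lq[i]
    ll
}

## E-step over patterns: responsibilities r = P(Z=1|A) and per-pattern
## log mixture density
.eStep <- function(params, a) {
    l1 <- log(params@pi) + .componentLogLik(a, params@p1)
    l0 <- log1p(-params@pi) + .componentLogLik(a, params@p0)
    m <- pmax(l1, l0)
    logMix <- m + log(exp(l1 - m) + exp(l0 - m))
    list(r = exp(l1 - logMix), logMix = logMix)
}

## M-step from pattern counts and responsibilities
.mStep <- function(counts, r, patterns, marks) {
    w1 <- counts * r
    w0 <- counts * (1 - r)
    n1 <- sum(w1); n0 <- sum(w0); n <- n1 + n0
    clip <- function(p) pmin(pmax(p, .RATE_CLIP), 1 - .RATE_CLIP)
    ## a component with no responsibility mass keeps uninformative rates
    p1 <- if (n1 > 0) clip(as.numeric(crossprod(patterns, w1)) / n1)
        else rep(0.5, .N_MARKS)
    p0 <- if (n0 > 0) clip(as.numeric(crossprod(patterns, w0)) / n0)
        else rep(0.5, .N_MARKS)
    MixtureParams(pi = clip(n1 / n), p1 = p1, p0 = p0, marks = marks)
}

#' Log-likelihood of a training sample under the mixture
#'
#' @param params a \code{MixtureParams}.
#' @param data a \code{TrainingSample}.
#' @return The observed-data log-likelihood
#'   \eqn{\sum_{bp} \log[\pi \prod_i p_{i1}^{A_i}(1-p_{i1})^{1-A_i} +
#'   (1-\pi) \prod_i p_{i0}^{A_i}(1-p_{i0})^{1-A_i}]},
#'   computed over the distinct patterns with multiplicities.
#' @export
logLikelihood <- function(params, data) {
    counts <- patternCounts(data)
    if (sum(counts) == 0)
        stop("empty training sample")
    es <- .eStep(params, .patternMatrix())
    sum(counts * es$logMix)
}

#' Fit the Bernoulli mixture by expectation-maximization
#'
#' Estimates the 17 parameters (prior pi and per-mark rates for both
#' components) by EM over the pattern counts. By default several random
#' restarts are run and the fit with the best final log-likelihood kept;
#' after fitting, components are labeled so that the functional component
#' is the annotation-rich one (\code{mean(p1) >= mean(p0)}).
#'
#' @param data a \code{TrainingSample} with at least 2 distinct patterns.
#' @param init optional \code{MixtureParams} to start from; when given,
#'   random restarts are skipped.
#' @param tol relative log-likelihood change declaring convergence.
#' @param maxIter iteration cap per restart.
#' @param nRestarts number of random initializations.
#' @param seed RNG seed for the random initializations.
#' @return A list with elements \code{params} (\code{MixtureParams}) and
#'   \code{trace} (\code{EmTrace}).
#' @export
emFit <- function(data, init = NULL, tol = 1e-8, maxIter = 1000L,
                  nRestarts = 5L, seed = 1L) {
    counts <- patternCounts(data)
    if (sum(counts > 0) < 2L)
        stop("training sample has a single distinct mark pattern; ",
             "the data are uninformative for a two-component mixture")
    patterns <- .patternMatrix()
    marks <- markNames(data)

    runOne <- function(start) {
        params <- start
        ll <- -Inf
        logLik <- numeric(0)
        converged <- FALSE
        for (it in seq_len(maxIter)) {
            es <- .eStep(params, patterns)
            llNew <- sum(counts * es$logMix)
            logLik <- c(logLik, llNew)
            params <- .mStep(counts, es$r, patterns, marks)
            if (is.finite(ll) && abs(llNew - ll) < tol * abs(llNew)) {
                converged <- TRUE
                break
            }
            ll <- llNew
        }
        list(params = params, logLik = logLik, converged = converged)
    }

    if (!is.null(init)) {
        starts <- list(init)
    } else {
        starts <- withr::with_seed(seed, lapply(seq_len(nRestarts),
            function(k) MixtureParams(pi = 0.5,
                                      p1 = stats::runif(.N_MARKS, 0.5, 0.9),
                                      p0 = stats::runif(.N_MARKS, 0.05, 0.3),
                                      marks = marks)))
    }
    fits <- lapply(starts, runOne)
    best <- fits[[which.max(vapply(fits,
        function(f) f$logLik[length(f$logLik)], numeric(1)))]]
    params <- best$params
    if (mean(params@p1) < mean(params@p0))
        params <- MixtureParams(pi = 1 - params@pi, p1 = params@p0,
                                p0 = params@p1, marks = marks)
    list(params = params,
         trace = new("EmTrace", logLik = best$logLik,
                     nIter = length(best$logLik),
                     converged = best$converged))
}

#' Posterior probability of functionality given a mark pattern (GS score)
#'
#' \eqn{P(Z=1 \mid A) = \pi f(A|Z=1) / [\pi f(A|Z=1) + (1-\pi) f(A|Z=0)]}.
#'
#' @param params a \code{MixtureParams}.
#' @param a a 0/1 vector of length 8, or an n x 8 matrix of patterns.
#' @return Posterior probability(ies) in [0, 1].
#' @export
#' @examples
#' p <- MixtureParams(0.1, rep(0.8, 8), rep(0.05, 8))
#' gsPosterior(p, rep(1, 8))
gsPosterior <- function(params, a) {
    .eStep(params, a)$r
}

#' Score a genome: per-bp GS score track
#'
#' Overlays the 8 binary mark tracks into an integer pattern code per bp
#' (run-length encoded) and maps codes through a 256-entry posterior
#' lookup, which is exactly equivalent to evaluating the posterior at
#' every bp.
#'
#' @param params a \code{MixtureParams}.
#' @param ts a \code{MarkTrackSet} (mark order must match \code{params}).
#' @return A \code{ScoreTrack}.
#' @export
scoreGenome <- function(params, ts) {
    if (!identical(markNames(params), markNames(ts)))
        stop("mark order of params and trackset differ")
    lookup <- gsPosterior(params, .patternMatrix())
    pr <- .patternRle(ts)
    out <- lapply(pr, function(r) {
        Rle(lookup[as.integer(runValue(r)) + 1L], runLength(r))
    })
    ScoreTrack(RleList(out, compress = FALSE))
}

#' Fraction of the genome called functional
#'
#' @param track a \code{ScoreTrack}.
#' @param cutoff score cutoff (bp with score >= cutoff count as functional).
#' @return (functional bp) / (total genome bp).
#' @export
functionalFraction <- function(track, cutoff = 0.5) {
    rl <- scoreRle(track)
    func <- sum(vapply(rl, function(r)
        sum(as.numeric(runLength(r))[runValue(r) >= cutoff]), numeric(1)))
    func / sum(vapply(rl, length, numeric(1)))
}

#' Distribution of per-bp functional tissue counts
#'
#' For a set of tissue tracks over the same genome, counts for each k the
#' number of bp functional (score >= cutoff) in exactly k tissues.
#'
#' @param tracks named list of \code{ScoreTrack}s sharing one genome.
#' @param cutoff score cutoff.
#' @return Named numeric vector of bp counts for k = 0..length(tracks).
#' @export
tissueCountProfile <- function(tracks, cutoff = 0.5) {
    gl <- lapply(tracks, genomeLengths)
    if (!all(vapply(gl[-1], identical, logical(1), gl[[1]])))
        stop("tracks must share the same genome")
    nT <- length(tracks)
    chroms <- names(gl[[1]])
    counts <- numeric(nT + 1L)
    for (chrom in chroms) {
        k <- Rle(0L, gl[[1]][[chrom]])
        for (tr in tracks)
            k <- k + (scoreRle(tr)[[chrom]] >= cutoff)
        counts <- counts + .rleTabulate(k, nT + 1L)
    }
    stats::setNames(counts, 0:nT)
}

#' Log odds ratio of functional overlap between two tracks
#'
#' Builds the 2x2 bp-count table of functional (score >= cutoff) vs not for
#' the two tracks and returns the log odds ratio with the Haldane-Anscombe
#' +0.5 correction applied to every cell.
#'
#' @param trackA,trackB \code{ScoreTrack}s over the same genome.
#' @param cutoff score cutoff.
#' @return \code{log[(n11 + .5)(n00 + .5) / ((n10 + .5)(n01 + .5))]}.
#' @export
overlapLogOdds <- function(trackA, trackB, cutoff = 0.5) {
    glA <- genomeLengths(trackA)
    if (!identical(glA, genomeLengths(trackB)))
        stop("tracks must share the same genome")
    n11 <- n10 <- n01 <- 0
    for (chrom in names(glA)) {
        a <- scoreRle(trackA)[[chrom]] >= cutoff
        b <- scoreRle(trackB)[[chrom]] >= cutoff
        n11 <- n11 + sum(a & b)
        n10 <- n10 + sum(a & !b)
        n01 <- n01 + sum(!a & b)
    }
    n00 <- sum(as.numeric(glA)) - n11 - n10 - n01
    log(((n11 + 0.5) * (n00 + 0.5)) / ((n10 + 0.5) * (n01 + 0.5)))
}

#' Write fitted mixture parameters as a key-value text file
#'
#' Full-precision serialization: reading the file back reproduces the
#' parameters bit-exactly.
#'
#' @param params a \code{MixtureParams}.
#' @param path output path.
#' @param trace optional \code{EmTrace} whose final log-likelihood and
#'   iteration count are recorded alongside.
#' @return Invisibly, the path.
#' @export
writeMixtureParams <- function(params, path, trace = NULL) {
    num <- function(x) sprintf("%.17g", x)
    lines <- c(paste0("marks\t", paste(markNames(params), collapse = ",")),
               paste0("pi\t", num(params@pi)),
               paste0("p1\t", paste(num(params@p1), collapse = ",")),
               paste0("p0\t", paste(num(params@p0), collapse = ",")))
    if (!is.null(trace))
        lines <- c(lines,
                   paste0("loglik\t", num(emLogLik(trace)[trace@nIter])),
                   paste0("n_iter\t", trace@nIter))
    writeLines(lines, path)
    invisible(path)
}

#' Read mixture parameters written by \code{writeMixtureParams}
#'
#' @param path parameter file path.
#' @return A \code{MixtureParams}.
#' @export
readMixtureParams <- function(path) {
    lines <- readLines(path)
    kv <- strsplit(lines, "\t", fixed = TRUE)
    vals <- stats::setNames(vapply(kv, `[[`, character(1), 2L),
                            vapply(kv, `[[`, character(1), 1L))
    MixtureParams(pi = as.numeric(vals[["pi"]]),
                  p1 = as.numeric(strsplit(vals[["p1"]], ",")[[1L]]),
                  p0 = as.numeric(strsplit(vals[["p0"]], ",")[[1L]]),
                  marks = strsplit(vals[["marks"]], ",")[[1L]])
}
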