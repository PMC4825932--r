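test_that("logLikelihood matches direct arithmetic and a per-site oracle", {
    params <- MixtureParams(0.1, rep(0.8, 8), rep(0.05, 8))
    ## a single all-zero observation
    counts <- numeric(256); counts[1L] <- 1
    s <- trainingSampleFromCounts(counts)
    expect_equal(logLikelihood(params, s),
                 log(0.1 * 0.2^8 + 0.9 * 0.95^8))

    ## random data: pattern-table evaluation equals a naive per-site sum
    withr::with_seed(21, {
        a <- matrix(rbinom(50 * 8, 1, 0.4), ncol = 8)
    })
    codes <- as.integer(a %*% 2^(0:7))
    s2 <- trainingSampleFromCounts(tabulate(codes + 1L, 256))
    perSite <- sum(vapply(seq_len(nrow(a)), function(j) {
        l1 <- prod(ifelse(a[j, ] == 1, 0.8, 0.2))
        l0 <- prod(ifelse(a[j, ] == 1, 0.05, 0.95))
        log(0.1 * l1 + 0.9 * l0)
    }, numeric(1)))
    expect_equal(logLikelihood(params, s2), perSite)

    expect_error(logLikelihood(params, trainingSampleFromCounts(numeric(256))),
                 "empty")
})

test_that("identical components collapse the likelihood and the posterior", {
    p <- rep(0.3, 8)
    params <- MixtureParams(0.5, p, p)
    counts <- numeric(256); counts[c(1L, 256L)] <- c(3, 2)
    s <- trainingSampleFromCounts(counts)
    ## single Bernoulli product model
    expect_equal(logLikelihood(params, s),
                 3 * 8 * log(0.7) + 2 * 8 * log(0.3))
    ## posterior equals the prior for every pattern
    pats <- rbind(rep(0, 8), rep(1, 8), c(1, rep(0, 7)))
    expect_equal(gsPosterior(params, pats), rep(0.5, 3))
})

test_that("one M-step with unit responsibilities returns empirical means", {
    withr::with_seed(31, {
        a <- matrix(rbinom(200 * 8, 1, runif(8)[rep(1:8, each = 200)]),
                    ncol = 8)
    })
    codes <- as.integer(a %*% 2^(0:7))
    counts <- as.numeric(tabulate(codes + 1L, 256))
    fitted <- TissueMix:::.mStep(counts, rep(1, 256),
                                 TissueMix:::.patternMatrix(),
                                 epigeneticMarks())
    expect_equal(unname(functionalRates(fitted)), colMeans(a),
                 tolerance = 1e-12)
})

test_that("EM recovers planted parameters and has 17 free parameters", {
    truth <- MixtureParams(0.1, rep(0.7, 8), rep(0.1, 8))
    data <- simulateTrainingSample(truth, 200000L, seed = 42L)
    fit <- emFit(data)
    expect_lt(abs(mixturePi(fit$params) - 0.1), 0.01)
    expect_lt(max(abs(functionalRates(fit$params) - 0.7)), 0.02)
    expect_lt(max(abs(backgroundRates(fit$params) - 0.1)), 0.02)
    ## 1 + 8 + 8 free parameters
    expect_length(c(mixturePi(fit$params), functionalRates(fit$params),
                    backgroundRates(fit$params)), 17L)
    ## component labeling: functional component is annotation-rich
    expect_gte(mean(functionalRates(fit$params)),
               mean(backgroundRates(fit$params)))
})

test_that("EM log-likelihood is non-decreasing and beats its start", {
    withr::with_seed(55, {
        for (k in 1:5) {
            truth <- MixtureParams(runif(1, 0.05, 0.4),
                                   runif(8, 0.5, 0.9), runif(8, 0.02, 0.3))
            data <- simulateTrainingSample(truth, 5000L, seed = 100L + k)
            fit <- emFit(data, nRestarts = 2L, seed = k)
            ll <- emLogLik(fit$trace)
            expect_true(all(diff(ll) >= -1e-9 * abs(ll[-length(ll)])))
        }
    })
    ## degenerate data: a single pattern is uninformative
    counts <- numeric(256); counts[5L] <- 100
    expect_error(emFit(trainingSampleFromCounts(counts)), "uninformative")
})

test_that("EM estimates sharpen as the sample grows", {
    truth <- MixtureParams(0.1, rep(0.7, 8), rep(0.1, 8))
    err <- vapply(c(20000L, 200000L), function(n) {
        fit <- emFit(simulateTrainingSample(truth, n, seed = 77L))
        max(abs(functionalRates(fit$params) - 0.7))
    }, numeric(1))
    expect_lt(err[2L], err[1L])
})

test_that("gsPosterior follows the closed form and is monotone", {
    params <- MixtureParams(0.1, rep(0.8, 8), rep(0.05, 8))
    expect_equal(gsPosterior(params, rep(1, 8)),
                 0.1 * 0.8^8 / (0.1 * 0.8^8 + 0.9 * 0.05^8))
    ## degenerate prior: pi at the clip floor keeps the posterior near 0
    tiny <- MixtureParams(1e-6, rep(0.8, 8), rep(0.05, 8))
    expect_lt(gsPosterior(tiny, rep(0, 8)), 1e-5)
    ## raising p_{i1} with A_i = 1 never lowers the posterior
    a <- c(1, 0, 1, 0, 1, 0, 1, 0)
    p1 <- rep(0.6, 8)
    post <- vapply(seq(0.6, 0.9, by = 0.05), function(v) {
        p1 [1L] <- v
        gsPosterior(MixtureParams(0.2, p1, rep(0.1, 8)), a)
    }, numeric(1))
    expect_true(all(diff(post) >= 0))
    ## always a probability
    pats <- TissueMix:::.patternMatrix()
    post <- gsPosterior(params, pats)
    expect_true(all(post >= 0 & post <= 1))
})

test_that("scoreGenome equals the per-bp posterior oracle exactly", {
    ts <- randomTrackSet(len = 10000L, seed = 91)
    params <- MixtureParams(0.15, rep(0.75, 8), rep(0.08, 8))
    track <- scoreGenome(params, ts)
    mm <- markMatrixOracle(ts, "chr1")
    oracle <- gsPosterior(params, mm)
    expect_identical(as.numeric(scoreRle(track)$chr1), oracle)
    ## pigeonhole: no more than 256 distinct run values
    expect_lte(length(unique(runValue(scoreRle(track)$chr1))), 256L)
})

test_that("a peakless genome scores constant at the all-zero posterior", {
    f <- writeBed3(data.frame(start = 1L, end = 5L), chrom = "chrZ")
    files <- stats::setNames(rep(list(f), 8), epigeneticMarks())
    ts <- buildMarkTrackSet(files, c(chr1 = 2000L, chrZ = 10L), "t")
    params <- MixtureParams(0.1, rep(0.7, 8), rep(0.1, 8))
    track <- scoreGenome(params, ts)
    r <- scoreRle(track)$chr1
    expect_length(runValue(r), 1L)
    expect_equal(runValue(r), gsPosterior(params, rep(0, 8)))
})

test_that("functionalFraction counts thresholded bp", {
    ones <- ScoreTrack(list(chr1 = Rle(1, 100L)))
    expect_equal(functionalFraction(ones, 0.5), 1)
    expect_equal(functionalFraction(ones, 1), 1)
    mixed <- ScoreTrack(list(chr1 = Rle(c(0.9, 0.2, 0.6), c(10, 70, 20))))
    expect_equal(functionalFraction(mixed, 0.5), 0.3)
    expect_equal(functionalFraction(mixed, 0), 1)
})

test_that("tissueCountProfile matches a per-bp counting oracle", {
    t1 <- randomScoreTrack(len = 4000L, nRun = 30L, seed = 13)
    ## identical tracks concentrate mass at k = 0 and k = n
    prof <- tissueCountProfile(list(a = t1, b = t1, c = t1), 0.5)
    expect_equal(sum(prof), 4000)
    expect_equal(unname(prof[c("1", "2")]), c(0, 0))
    ## disjoint functional regions: only k in {0, 1}
    d1 <- ScoreTrack(list(chr1 = Rle(c(1, 0), c(50, 50))))
    d2 <- ScoreTrack(list(chr1 = Rle(c(0, 1), c(50, 50))))
    profD <- tissueCountProfile(list(d1, d2), 0.5)
    expect_equal(unname(profD), c(0, 100, 0))
    ## random tracks vs per-bp oracle
    t2 <- randomScoreTrack(len = 4000L, nRun = 25L, seed = 14)
    profR <- tissueCountProfile(list(t1, t2), 0.5)
    k <- (as.numeric(scoreRle(t1)$chr1) >= 0.5) +
        (as.numeric(scoreRle(t2)$chr1) >= 0.5)
    expect_equal(unname(profR), as.numeric(tabulate(k + 1L, 3L)))
    ## mismatched genomes error
    short <- ScoreTrack(list(chr1 = Rle(0, 10L)))
    expect_error(tissueCountProfile(list(t1, short), 0.5), "genome")
})

test_that("overlapLogOdds applies the Haldane-Anscombe correction", {
    ## toy 2x2 table: n11=100, n10=50, n01=25, n00=825
    a <- ScoreTrack(list(chr1 = Rle(c(1, 1, 0, 0), c(100, 50, 25, 825))))
    b <- ScoreTrack(list(chr1 = Rle(c(1, 0, 1, 0), c(100, 50, 25, 825))))
    expect_equal(overlapLogOdds(a, b, 0.5),
                 log((100.5 * 825.5) / (50.5 * 25.5)))
    ## self-overlap: large but finite
    lo <- overlapLogOdds(a, a, 0.5)
    expect_true(is.finite(lo) && lo > 5)
    ## independent-by-construction tracks: log OR near 0
    withr::with_seed(17, {
        x <- ScoreTrack(list(chr1 = Rle(as.numeric(runif(50000) < 0.3))))
        y <- ScoreTrack(list(chr1 = Rle(as.numeric(runif(50000) < 0.3))))
    })
    expect_lt(abs(overlapLogOdds(x, y, 0.5)), 0.1)
})

test_that("mixture parameters serialize bit-exactly", {
    withr::with_seed(19, {
        params <- MixtureParams(runif(1), runif(8), runif(8))
    })
    path <- tempfile()
    writeMixtureParams(params, path)
    back <- readMixtureParams(path)
    expect_identical(mixturePi(back), mixturePi(params))
    expect_identical(functionalRates(back), functionalRates(params))
    expect_identical(backgroundRates(back), backgroundRates(params))
})
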