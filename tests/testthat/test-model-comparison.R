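.fakeReport <- function(strategy, transform, r2cv, r2p_pos1, r2p_range,
                        rmsep_range = 0.3) {
    pp <- data.frame(position = 1:4, n = 10,
                     r2p = c(r2p_pos1, r2p_pos1 + r2p_range / 2,
                             r2p_pos1 + r2p_range, r2p_pos1 + r2p_range / 3),
                     rmsep = 1, low_n = FALSE)
    methods::new("AccuracyReport", strategy = strategy,
                 transform = transform, r2cv = r2cv, rmsecv = 1,
                 r2p = r2p_pos1, rmsep = 1, perPosition = pp,
                 r2pRange = r2p_range, rmsepRange = rmsep_range,
                 details = list(cvSeed = 1L, splitSeed = 1L))
}

test_that("transform shortlisting keeps the raw baseline and all ties", {
    r2 <- c(R = 0.80, R1 = 0.83, SNV = 0.75, logR = 0.80)
    out <- shortlistTransforms(r2)
    expect_identical(out[1], "R1")
    expect_true(all(c("R", "logR") %in% out))  # >= is inclusive
    expect_false("SNV" %in% out)

    worse <- c(R = 0.80, SNV = 0.7, MSC = 0.6)
    expect_identical(shortlistTransforms(worse), "R")
    expect_error(shortlistTransforms(c(R1 = 0.9)), "baseline")
})

test_that("water-effect deltas are percentage changes of each metric", {
    same <- .fakeReport("CA", "log_invR", 0.8, 0.7, 0.1)
    d0 <- compareWaterEffect(same, same)
    expect_true(all(d0$pct_change == 0))

    # the documented improvement pair: R2 0.7300 -> 0.8094 is +10.88%,
    # RMSE 3.6133 -> 2.9085 is -19.51%
    d <- compareWaterEffect(c(r2cv = 0.7300, rmsecv = 3.6133),
                            c(r2cv = 0.8094, rmsecv = 2.9085))
    expect_equal(round(d$pct_change[d$metric == "r2cv"], 2), 10.88)
    expect_equal(round(d$pct_change[d$metric == "rmsecv"], 2), -19.51)

    other <- .fakeReport("CAW", "log_invR", 0.81, 0.71, 0.1)
    other@details$cvSeed <- 99L
    expect_error(compareWaterEffect(same, other), "seeds")
})

test_that("strategy ranking follows the position-1 bottleneck then uniformity", {
    reps <- list(
        .fakeReport("CAW", "log_invR", 0.80, r2p_pos1 = 0.78,
                    r2p_range = 0.05),
        .fakeReport("AB", "R1", 0.83, r2p_pos1 = 0.70, r2p_range = 0.10),
        .fakeReport("PCA", "R1", 0.87, r2p_pos1 = 0.65, r2p_range = 0.20))
    tr <- selectOptimal(reps)
    expect_identical(tr$strategy, c("CAW", "AB", "PCA"))
    expect_identical(tr$rank, 1:3)

    # tie on position-1 accuracy breaks by the smaller range
    tie <- list(
        .fakeReport("AB", "R1", 0.83, r2p_pos1 = 0.75, r2p_range = 0.12),
        .fakeReport("CAW", "log_invR", 0.80, r2p_pos1 = 0.75 + 1e-8,
                    r2p_range = 0.04))
    tt <- selectOptimal(tie)
    expect_identical(tt$strategy[1], "CAW")

    # per strategy, the best transform by CV accuracy is retained
    multi <- list(
        .fakeReport("CA", "R1", 0.73, 0.70, 0.1),
        .fakeReport("CA", "log_invR", 0.69, 0.72, 0.1))
    tm <- selectOptimal(multi)
    expect_identical(nrow(tm), 1L)
    expect_identical(tm$transform, "R1")

    # deterministic in its inputs
    expect_identical(selectOptimal(reps), selectOptimal(reps))

    noPos1 <- .fakeReport("AB", "R1", 0.8, 0.7, 0.1)
    noPos1@perPosition <- noPos1@perPosition[-1, ]
    expect_error(selectOptimal(list(noPos1)), "position-1")
})

test_that("the published ten-band equation evaluates as printed", {
    m <- publishedCAWModel()
    expect_identical(m@bands,
                     c(547, 548, 549, 550, 551, 552, 1464, 1465, 1933,
                       1944))
    expect_equal(evaluatePublishedModel(m, rep(0, 10)), 2.1754)
    # all-ones input: intercept plus the coefficient sum
    coefSum <- sum(c(57.7898, 18.9012, -151.3200, -103.7400, 39.6828,
                     142.0900, 489.6450, -494.9750, -36.6924, 37.3505))
    expect_equal(evaluatePublishedModel(m, rep(1, 10)), 2.1754 + coefSum,
                 tolerance = 1e-10)
    set.seed(51)
    x <- matrix(rnorm(30), 3, 10)
    expect_equal(evaluatePublishedModel(m, x),
                 as.numeric(2.1754 + x %*% m@coefficients),
                 tolerance = 1e-12)
    expect_error(evaluatePublishedModel(m, rep(0, 9)), "ten band")
})

test_that("the published model consumes spectra through its input transform", {
    set.seed(52)
    wl <- wavelengthGrid()
    refl <- matrix(runif(2 * length(wl), 0.05, 0.6), nrow = 2)
    md <- data.frame(seedling_id = c("a", "b"), treatment = "T1",
                     pair_position = 1L, leaf_side = 1L, chlorophyll = 8)
    s <- SpectraSet(refl, wl, md)
    m <- publishedCAWModel()  # applies log(1/R) first
    got <- evaluatePublishedModel(m, s)
    X <- -log10(refl[, match(m@bands, wl)])
    expect_equal(got, as.numeric(2.1754 + X %*% m@coefficients),
                 tolerance = 1e-10)
    mraw <- publishedCAWModel(inputTransform = "R")
    gotRaw <- evaluatePublishedModel(mraw, s)
    expect_equal(gotRaw,
                 as.numeric(2.1754 + refl[, match(m@bands, wl)] %*%
                            m@coefficients), tolerance = 1e-10)
})

test_that("runStrategy wires selection, CV and hold-out together", {
    s <- makeFixture("tiny")$spectra
    rep <- runStrategy(s, "CAW", transform = "log(1/R)")
    sel <- rep@details$info$selection
    expect_length(selectedBands(sel), 10)
    expect_identical(sum(bandProvenance(sel) != "main"), 4L)
    expect_true(all(rep@perPosition$position %in% 1:4))
    expect_true(1 %in% rep@perPosition$position)
    expect_gte(rep@r2pRange, 0)
    # hold-out seedlings never appear in the training folds
    expect_identical(sum(rep@details$test), nLeaves(s) -
                     length(rep@details$folds))
    # index strategies insist on raw reflectance
    expect_error(runStrategy(s, "VI", transform = "logR"),
                 "raw reflectance")
})

test_that("an affine transform pair gives numerically identical accuracy", {
    s <- makeFixture("tiny")$spectra
    r1 <- runStrategy(s, "CA", transform = "logR")
    r2 <- runStrategy(s, "CA", transform = "log(1/R)")
    expect_equal(r1@r2cv, r2@r2cv, tolerance = 1e-8)
    expect_equal(r1@rmsecv, r2@rmsecv, tolerance = 1e-8)
    expect_equal(r1@r2p, r2@r2p, tolerance = 1e-8)
})

test_that("a single-index linear model on noise-free spectra is near perfect", {
    cfg <- generatorConfig(nSeedlingsPerTreatment = 10L, seed = 7L,
        noiseAdditiveSd = 0, noiseMultiplicativeSd = 0,
        positionJitterSd = rep(0, 4), opticalMismatchSd = rep(0, 4))
    d <- generateDataset(cfg, grid = wavelengthGrid(350, 2500, 5))
    rep <- runStrategy(d$spectra, "VIL", indices = "GNDVI")
    expect_gte(rep@r2p, 0.99)
})
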