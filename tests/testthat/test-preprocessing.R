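test_that("the registry holds 21 transforms with the six-member shortlist", {
    tl <- listTransforms()
    expect_identical(nrow(tl), 21L)
    expect_identical(anyDuplicated(tl$name), 0L)
    expect_true(tl$shortlisted[tl$name == "R1"])     # first derivative
    expect_false(tl$shortlisted[tl$name == "SNV"])
    expect_identical(sort(tl$name[tl$shortlisted]),
                     sort(c("R1", "sqrtR", "logR", "log_invR",
                            "log_sqrtR", "R")))
    expect_identical(normalizeTransformName("log(1/R)"), "log_invR")
    expect_identical(normalizeTransformName("R'"), "R1")
    expect_error(normalizeTransformName("wavelet"), "unknown transform")
})

test_that("derivatives match the difference-quotient oracle and annihilate constants", {
    wl <- seq(400, 445, by = 5)
    set.seed(3)
    m <- matrix(runif(3 * 10, 0.1, 0.9), nrow = 3)
    md <- data.frame(seedling_id = letters[1:3], treatment = "T1",
                     pair_position = 1L, leaf_side = 1L, chlorophyll = 5)
    s <- SpectraSet(m, wl, md)
    d1 <- spectraMatrix(firstDerivative(s))
    for (i in 1:3)
        expect_equal(unname(d1[i, ]), oracleDeriv1(m[i, ], 5),
                     tolerance = 1e-12)

    const <- SpectraSet(matrix(0.3, 2, 10), wl, md[1:2, ])
    expect_true(all(spectraMatrix(firstDerivative(const)) == 0))
    expect_true(all(spectraMatrix(secondDerivative(const)) == 0))

    ramp <- SpectraSet(rbind(0.001 + 2e-4 * wl, 0.002 + 1e-4 * wl), wl,
                       md[1:2, ])
    dr <- spectraMatrix(firstDerivative(ramp))
    expect_equal(unname(dr[1, 2:9]), rep(2e-4, 8), tolerance = 1e-12)
    expect_equal(unname(dr[2, 2:9]), rep(1e-4, 8), tolerance = 1e-12)
    # second derivative annihilates affine spectra
    expect_equal(max(abs(spectraMatrix(secondDerivative(ramp)))), 0,
                 tolerance = 1e-12)
})

test_that("SNV standardizes rows and is affine-invariant", {
    s <- randomSpectraSet(4, seed = 9)
    z <- spectraMatrix(snv(s))
    expect_true(all(abs(rowMeans(z)) < 1e-10))
    expect_equal(unname(apply(z, 1, sd)), rep(1, 4), tolerance = 1e-10)
    # snv(a*x + b) == snv(x) for a > 0
    m <- spectraMatrix(s)
    s2 <- SpectraSet(0.5 * m + 0.1, wavelengths(s), leafInfo(s))
    expect_equal(spectraMatrix(snv(s2)), z, tolerance = 1e-10)
    # already-standardized input is a fixed point (up to tag)
    zset <- SpectraSet(z, wavelengths(s), leafInfo(s), transformTag = "SNV")
    expect_equal(spectraMatrix(applyTransform("SNV", zset)), z,
                 tolerance = 1e-10)
    bad <- SpectraSet(matrix(0.4, 2, nBands(s)), wavelengths(s),
                      leafInfo(s)[1:2, ])
    expect_error(snv(bad), "zero-variance")
})

test_that("MSC inverts the per-leaf affine scatter model", {
    wl <- seq(500, 595, by = 5)
    md <- function(n) data.frame(seedling_id = paste0("s", 1:n),
                                 treatment = "T1", pair_position = 1L,
                                 leaf_side = 1L, chlorophyll = 5)
    ref <- seq(0.1, 0.3, length.out = length(wl))
    s <- SpectraSet(rbind(ref, 2 * ref + 0.1), wl, md(2))
    out <- spectraMatrix(msc(s, reference = ref))
    expect_equal(unname(out[1, ]), unname(ref), tolerance = 1e-10)
    expect_equal(unname(out[2, ]), unname(ref), tolerance = 1e-10)

    set.seed(21)
    m <- matrix(runif(5 * 20, 0.1, 0.8), nrow = 5)
    s5 <- SpectraSet(m, seq(500, 595, by = 5), md(5))
    corr <- spectraMatrix(msc(s5))
    mu <- colMeans(m)
    for (i in 1:5) {
        ab <- oracleOLS(mu, m[i, ])  # x ~ a + b * ref
        expect_equal(unname(corr[i, ]), unname((m[i, ] - ab[1]) / ab[2]),
                     tolerance = 1e-10)
    }
})

test_that("MSC context corrects held-out leaves against the training mean", {
    s <- randomSpectraSet(6, seed = 4)
    train <- s[, 1:4]
    test <- s[, 5:6]
    ctx <- fitTransformContext("MSC", train)
    expect_equal(ctx$msc_reference,
                 colMeans(spectraMatrix(train)), tolerance = 1e-12)
    out <- spectraMatrix(applyTransform("MSC", test, context = ctx))
    mu <- colMeans(spectraMatrix(train))
    m <- spectraMatrix(test)
    for (i in 1:2) {
        ab <- oracleOLS(mu, m[i, ])
        expect_equal(unname(out[i, ]), unname((m[i, ] - ab[1]) / ab[2]),
                     tolerance = 1e-10)
    }
    # FD-MSC reference is the mean of the derivative, not of reflectance
    ctx2 <- fitTransformContext("FD-MSC", train)
    expect_equal(ctx2$msc_reference,
                 colMeans(spectraMatrix(firstDerivative(train))),
                 tolerance = 1e-12)
})

test_that("chains compose as named and log-family identities hold", {
    s <- randomSpectraSet(3, seed = 8)
    expect_equal(spectraMatrix(applyTransform("R", s)), spectraMatrix(s))
    # log(1/R) closed form at a single value
    wl <- seq(400, 445, by = 5)
    md <- data.frame(seedling_id = "a", treatment = "T1",
                     pair_position = 1L, leaf_side = 1L, chlorophyll = 5)
    one <- SpectraSet(matrix(0.1, 1, 10), wl, md)
    expect_equal(unname(spectraMatrix(applyTransform("log(1/R)", one))[1, 1]),
                 1.0, tolerance = 1e-12)
    # (sqrt(R))' equals d1 after elementwise sqrt (difference-quotient oracle)
    quad <- SpectraSet(matrix((1e-6 * wl^2 + 0.05), 1, 10, byrow = TRUE),
                       wl, md)
    got <- spectraMatrix(applyTransform("(sqrt(R))'", quad))
    expect_equal(unname(got[1, ]),
                 oracleDeriv1(sqrt(1e-6 * wl^2 + 0.05), 5),
                 tolerance = 1e-12)
    # affine log-family identities
    m <- spectraMatrix(s)
    lg <- spectraMatrix(applyTransform("logR", s))
    expect_equal(spectraMatrix(applyTransform("log(1/R)", s)), -lg,
                 tolerance = 1e-12)
    expect_equal(spectraMatrix(applyTransform("log(sqrt(R))", s)), 0.5 * lg,
                 tolerance = 1e-12)
})

test_that("domain violations fail loudly with row and wavelength", {
    wl <- seq(400, 445, by = 5)
    md <- data.frame(seedling_id = "a", treatment = "T1",
                     pair_position = 1L, leaf_side = 1L, chlorophyll = 5)
    one <- SpectraSet(matrix(c(rep(0.5, 9), 1), 1, 10), wl, md)
    # R = 1 makes logR = 0, so 1/logR is undefined
    expect_error(applyTransform("1/logR", one), "reciprocal of zero")
    expect_error(applyTransform("R1", one[1:2, ]), "at least 3 bands")
})
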