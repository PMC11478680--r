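test_that("PLS1 reduces to least squares in the classical limits", {
    set.seed(41)
    # one predictor, one latent variable: simple regression
    x <- matrix(rnorm(40), ncol = 1)
    y <- 3 + 2 * x[, 1] + rnorm(40, 0, 0.1)
    m <- fitPLS1(x, y, 1)
    ols <- oracleOLS(x, y)
    expect_equal(m@intercept, ols[1], tolerance = 1e-8)
    expect_equal(m@coefficients, ols[2], tolerance = 1e-8)

    # full-rank tall X with nlv = p: predictions equal OLS
    X <- matrix(rnorm(60 * 4), 60, 4)
    y2 <- X %*% c(1, -2, 0.5, 3) + rnorm(60, 0, 0.2)
    mf <- fitPLS1(X, y2, 4)
    beta <- oracleOLS(X, y2)
    expect_equal(predict(mf, X),
                 as.numeric(cbind(1, X) %*% beta), tolerance = 1e-8)
})

test_that("PLS1 predictions are invariant to global predictor scaling", {
    set.seed(42)
    X <- matrix(rnorm(50 * 6), 50, 6)
    y <- X %*% rnorm(6) + rnorm(50, 0, 0.3)
    m1 <- fitPLS1(X, y, 3)
    m2 <- fitPLS1(0.5 * X, y, 3)
    expect_equal(predict(m2, 0.5 * X), predict(m1, X), tolerance = 1e-10)
    expect_equal(m2@coefficients, m1@coefficients / 0.5, tolerance = 1e-8)
})

test_that("prediction is the Eq.-style linear form", {
    set.seed(43)
    X <- matrix(rnorm(30 * 5), 30, 5)
    y <- rnorm(30)
    m <- fitPLS1(X, y, 2)
    # training mean row predicts the response mean (centering identity)
    expect_equal(predict(m, matrix(colMeans(X), 1)), mean(y),
                 tolerance = 1e-10)
    # dot-product oracle on random inputs
    Xn <- matrix(rnorm(10 * 5), 10, 5)
    expect_equal(predict(m, Xn),
                 as.numeric(m@intercept + Xn %*% m@coefficients),
                 tolerance = 1e-12)
    expect_error(predict(m, Xn[, 1:3]), "predictor count")
})

test_that("PLS1 agrees with an independent implementation", {
    skip_if_not_installed("mixOmics")
    set.seed(44)
    X <- matrix(rnorm(40 * 8), 40, 8,
                dimnames = list(NULL, paste0("b", 1:8)))
    y <- X %*% rnorm(8) + rnorm(40, 0, 0.5)
    m <- fitPLS1(X, y, 3)
    ref <- mixOmics::pls(X, y, ncomp = 3, scale = FALSE, mode = "regression")
    pref <- predict(ref, X)$predict[, 1, 3]
    expect_equal(unname(predict(m, X)), unname(pref), tolerance = 1e-6)
})

test_that("latent-variable choice recovers low rank and resists noise", {
    set.seed(45)
    n <- 120
    T2 <- matrix(rnorm(n * 2), n, 2)
    X <- T2 %*% matrix(rnorm(2 * 15), 2, 15) +
        matrix(rnorm(n * 15, 0, 0.01), n, 15)
    y <- T2 %*% c(2, -1) + rnorm(n, 0, 0.05)
    expect_lte(chooseNLV(X, y, seed = 1), 3L)

    ynoise <- rnorm(n)
    expect_identical(chooseNLV(X, ynoise, seed = 1), 1L)
    expect_identical(chooseNLV(X, y, seed = 7), chooseNLV(X, y, seed = 7))
})

test_that("grouped folds keep seedlings whole and are seed-deterministic", {
    groups <- rep(paste0("s", 1:10), each = 3)
    f1 <- makeFolds(groups, k = 5, seed = 3)
    f2 <- makeFolds(groups, k = 5, seed = 3)
    expect_identical(f1, f2)
    expect_identical(sort(unique(f1)), 1:5)
    for (g in unique(groups))
        expect_length(unique(f1[groups == g]), 1L)
    expect_error(makeFolds(groups, k = 11, seed = 1), "exceeds")
})

test_that("cross-validation pools out-of-fold predictions leak-free", {
    set.seed(46)
    X <- matrix(rnorm(60 * 3), 60, 3)
    y <- X %*% c(1, 2, -1)  # exact linear, noise-free
    cv <- kfoldCV(plsRecipe(nlv = 3), X, as.numeric(y), seed = 2)
    expect_gte(cv$r2cv, 0.999)
    expect_identical(sort(unique(cv$folds)), 1:5)

    # a null model's CV RMSE is close to sd(y)
    meanRecipe <- list(fit = function(X, y, groups = NULL) mean(y),
                       predict = function(m, X) rep(m, nrow(X)))
    yr <- rnorm(200, 10, 2)
    Xr <- matrix(rnorm(200), ncol = 1)
    cv0 <- kfoldCV(meanRecipe, Xr, yr, seed = 3)
    expect_equal(cv0$rmsecv, sd(yr), tolerance = 0.05 * sd(yr))

    # instrumented recipe: every fit sees only training rows
    seen <- list()
    spy <- list(
        fit = function(X, y, groups = NULL) {
            seen[[length(seen) + 1]] <<- rownames(X)
            mean(y)
        },
        predict = function(m, X) rep(m, nrow(X)))
    Xs <- matrix(rnorm(30), ncol = 1)
    rownames(Xs) <- paste0("r", 1:30)
    cvs <- kfoldCV(spy, Xs, rnorm(30), seed = 5)
    for (f in 1:5) {
        testRows <- paste0("r", which(cvs$folds == f))
        expect_length(intersect(seen[[f]], testRows), 0)
        expect_setequal(c(seen[[f]], testRows), paste0("r", 1:30))
    }
})

test_that("a permuted response carries no cross-validated signal", {
    fx <- makeFixture("tiny")
    s <- fx$spectra
    X <- spectraMatrix(s)[, bandIndex(s, seq(530, 575, by = 5))]
    y <- chlorophyll(s)
    set.seed(47)
    yperm <- sample(y)
    cv <- kfoldCV(plsRecipe(nlv = 3), X, yperm, seed = 4,
                  groups = leafInfo(s)$seedling_id)
    expect_lte(cv$r2cv, 0.1)
})

test_that("index-model least squares is exact and rank-checked", {
    set.seed(48)
    g <- runif(50, 0.2, 0.7)
    y <- 1 + 2 * g
    m <- fitLinear(matrix(g, ncol = 1), y)
    expect_equal(m@intercept, 1, tolerance = 1e-10)
    expect_equal(m@coefficients, 2, tolerance = 1e-10)

    X <- matrix(rnorm(100), 50, 2)
    y2 <- rnorm(50)
    m2 <- fitLinear(X, y2)
    expect_equal(c(m2@intercept, m2@coefficients), oracleOLS(X, y2),
                 tolerance = 1e-10)
    expect_error(fitLinear(cbind(X, X[, 1]), y2), "rank")
})
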