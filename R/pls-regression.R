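## PLS1 (NIPALS) regression, ordinary least squares for index models, and
## seedling-grouped k-fold cross-validation with R2/RMSE.

#' Coefficient of determination of predictions
#' @param obs Observed values.
#' @param pred Predicted values.
#' @return 1 - SS_res / SS_tot.
#' @export
rSquared <- function(obs, pred) {
    1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}

#' Root mean square error of predictions
#' @inheritParams rSquared
#' @return sqrt(mean squared error), same units as `obs`.
#' @export
rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))

## NIPALS PLS1 core. For a univariate response each component has a
## closed form: w = X'y (normalized), t = Xw, p = X't/t't, q = y't/t't,
## then X and y are deflated. Returns per-component weights/loadings so
## coefficients for any smaller component count can be extracted without
## refitting.
.pls1Engine <- function(X, y, maxLv) {
    X <- as.matrix(X)
    n <- nrow(X); p <- ncol(X)
    xm <- colMeans(X); ym <- mean(y)
    Xc <- sweep(X, 2, xm)
    yc <- y - ym
    maxLv <- min(maxLv, n - 1L, p)
    W <- matrix(0, p, maxLv); P <- matrix(0, p, maxLv)
    q <- numeric(maxLv)
    a <- 0L
    for (i in seq_len(maxLv)) {
        w <- drop(crossprod(Xc, yc))
        nw <- sqrt(sum(w^2))
        if (nw < 1e-12) break
        w <- w / nw
        tt <- drop(Xc %*% w)
        t2 <- sum(tt^2)
        if (t2 < 1e-12) break
        pp <- drop(crossprod(Xc, tt)) / t2
        qq <- sum(yc * tt) / t2
        Xc <- Xc - tcrossprod(tt, pp)
        yc <- yc - qq * tt
        a <- i
        W[, i] <- w; P[, i] <- pp; q[i] <- qq
    }
    list(W = W[, seq_len(a), drop = FALSE],
         P = P[, seq_len(a), drop = FALSE],
         q = q[seq_len(a)], xMeans = xm, yMean = ym, rank = a)
}

.pls1Coef <- function(eng, nlv) {
    A <- seq_len(nlv)
    R <- eng$W[, A, drop = FALSE] %*%
        solve(crossprod(eng$P[, A, drop = FALSE], eng$W[, A, drop = FALSE]),
              eng$q[A])
    b <- drop(R)
    list(coefficients = b, intercept = eng$yMean - sum(eng$xMeans * b))
}

#' Fit a PLS1 regression
#'
#' NIPALS partial least squares with a single response on centered data.
#' The returned coefficients and intercept express the fitted model on the
#' original predictor scale, so predictions via the linear form
#' a0 + X a reproduce the latent-space predictions exactly.
#'
#' @param X Predictor matrix (leaves x predictors), no missing values.
#' @param y Response vector (chlorophyll, mg/g).
#' @param nlv Number of latent variables; silently capped at
#'   min(n - 1, p) and reduced with a warning if the achieved rank is
#'   lower.
#' @return A [PLSModel-class].
#' @export
fitPLS1 <- function(X, y, nlv) {
    X <- as.matrix(X)
    if (anyNA(X) || anyNA(y)) stop("missing values in predictors or response")
    if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
    if (nlv < 1) stop("nlv must be >= 1")
    eng <- .pls1Engine(X, y, nlv)
    if (eng$rank < min(nlv, nrow(X) - 1L, ncol(X)))
        warning("latent-variable count reduced to rank ", eng$rank)
    cf <- .pls1Coef(eng, eng$rank)
    methods::new("PLSModel", coefficients = cf$coefficients,
                 intercept = cf$intercept, xMeans = eng$xMeans,
                 yMean = eng$yMean, nlv = as.integer(eng$rank),
                 method = "pls1")
}

#' Ordinary least squares fit for index models
#'
#' @param X Predictor matrix with full column rank (one to a few index
#'   columns).
#' @param y Response vector.
#' @return A [PLSModel-class] (degenerate: `nlv` equals the predictor
#'   count, `method` is `"ols"`).
#' @export
fitLinear <- function(X, y) {
    X <- as.matrix(X)
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
    if (fit$rank < ncol(X) + 1L)
        stop("rank-deficient predictor matrix in fitLinear")
    cf <- fit$coefficients
    methods::new("PLSModel", coefficients = unname(cf[-1]),
                 intercept = unname(cf[1]), xMeans = colMeans(X),
                 yMean = mean(y), nlv = as.integer(ncol(X)),
                 method = "ols")
}

#' @describeIn fitPLS1 Predict chlorophyll (mg/g) for new predictors:
#'   a0 + X a.
#' @param object A [PLSModel-class].
#' @param newdata Predictor matrix with matching column count.
#' @export
setMethod("predict", "PLSModel", function(object, newdata) {
    X <- as.matrix(newdata)
    if (ncol(X) != length(object@coefficients))
        stop("predictor count does not match the fitted model")
    drop(object@intercept + X %*% object@coefficients)
})

setMethod("show", "PLSModel", function(object) {
    cat(sprintf("PLSModel (%s): %d predictor(s), %d latent variable(s)\n",
                object@method, length(object@coefficients), object@nlv))
    cat(sprintf("  intercept %.4f; response mean %.4f\n",
                object@intercept, object@yMean))
})

#' Grouped fold assignment
#'
#' Assigns whole groups (seedlings) to folds so twin leaves of one
#' seedling never straddle a train/test boundary. Deterministic given the
#' seed.
#'
#' @param groups Group id per sample (seedling ids); `NULL` makes each
#'   sample its own group.
#' @param n Number of samples (used when `groups` is `NULL`).
#' @param k Number of folds.
#' @param seed Integer seed for the group shuffle.
#' @return Integer fold id (1..k) per sample.
#' @export
makeFolds <- function(groups = NULL, n = length(groups), k = 5L, seed = 1L) {
    if (is.null(groups)) groups <- seq_len(n)
    ug <- unique(groups)
    if (k < 2) stop("k must be >= 2")
    if (k > length(ug))
        stop("k exceeds the number of groups (seedlings)")
    shuffled <- .withSeed(seed, sample(ug))
    foldOfGroup <- stats::setNames(rep(seq_len(k), length.out = length(ug)),
                                   as.character(shuffled))
    unname(foldOfGroup[as.character(groups)])
}

#' Choose the PLS latent-variable count by inner cross-validation
#'
#' Minimizes cross-validated RMSE over 1..`maxLv` latent variables, then
#' applies the one-standard-error parsimony rule: the smallest count whose
#' RMSE is within one standard error (across folds) of the minimum.
#'
#' @param X Predictor matrix.
#' @param y Response vector.
#' @param kFolds Folds for the inner CV (default 5).
#' @param maxLv Largest count tried; default min(20, p, n - 1).
#' @param seed Seed for fold construction.
#' @param groups Optional group ids (seedlings) kept whole within folds.
#' @return The chosen latent-variable count (integer >= 1).
#' @export
chooseNLV <- function(X, y, kFolds = 5L, maxLv = min(20L, ncol(X)),
                      seed = 1L, groups = NULL) {
    X <- as.matrix(X)
    n <- nrow(X)
    maxLv <- min(maxLv, ncol(X), n - 2L)
    if (maxLv < 1L) return(1L)
    folds <- makeFolds(groups = groups, n = n, k = kFolds, seed = seed)
    sqerr <- matrix(NA_real_, n, maxLv)
    for (f in sort(unique(folds))) {
        tr <- folds != f
        eng <- .pls1Engine(X[tr, , drop = FALSE], y[tr], maxLv)
        for (a in seq_len(eng$rank)) {
            cf <- .pls1Coef(eng, a)
            pred <- drop(cf$intercept +
                X[!tr, , drop = FALSE] %*% cf$coefficients)
            sqerr[!tr, a] <- (y[!tr] - pred)^2
        }
        if (eng$rank < maxLv && eng$rank >= 1)
            for (a in seq(eng$rank + 1L, maxLv))
                sqerr[!tr, a] <- sqerr[!tr, eng$rank]
    }
    pooled <- sqrt(colMeans(sqerr))
    best <- which.min(pooled)
    perFold <- vapply(sort(unique(folds)), function(f)
        sqrt(mean(sqerr[folds == f, best])), numeric(1))
    se <- stats::sd(perFold) / sqrt(length(perFold))
    if (!is.finite(se)) se <- 0
    as.integer(which(pooled <= pooled[best] + se)[1])
}

#' A PLS recipe for kfoldCV
#'
#' @param nlv Fixed latent-variable count, or `NULL` to choose per fold by
#'   inner cross-validation ([chooseNLV()]).
#' @param maxLv Upper bound passed to [chooseNLV()].
#' @param seed Seed for the inner CV folds.
#' @return A recipe list with `fit(X, y, groups)` and `predict(model, X)`.
#' @export
plsRecipe <- function(nlv = NULL, maxLv = 20L, seed = 1L) {
    list(
        fit = function(X, y, groups = NULL) {
            a <- if (is.null(nlv))
                chooseNLV(X, y, maxLv = maxLv, seed = seed, groups = groups)
            else nlv
            fitPLS1(X, y, a)
        },
        predict = function(model, X) predict(model, X))
}

#' k-fold cross-validation of a model recipe
#'
#' Fits the recipe on each training fold (all fitted statistics --
#' including latent-variable selection -- see only training rows) and
#' pools out-of-fold predictions; R2 is 1 - SS_res/SS_tot on the pooled
#' predictions. Groups (seedlings) are assigned wholly to one fold.
#'
#' @param recipe A list with `fit(X, y, groups)` and `predict(model, X)`,
#'   e.g. [plsRecipe()].
#' @param X Predictor matrix.
#' @param y Response vector.
#' @param k Number of folds (default 5).
#' @param seed Seed for fold construction.
#' @param groups Optional group ids; k must not exceed the group count.
#' @return A list: `r2cv`, `rmsecv`, `folds` (per-sample fold id),
#'   `perFold` (data.frame of per-fold n/R2/RMSE) and `predictions`
#'   (pooled out-of-fold).
#' @export
kfoldCV <- function(recipe, X, y, k = 5L, seed = 1L, groups = NULL) {
    X <- as.matrix(X)
    n <- nrow(X)
    folds <- makeFolds(groups = groups, n = n, k = k, seed = seed)
    pred <- rep(NA_real_, n)
    for (f in sort(unique(folds))) {
        tr <- folds != f
        fit <- recipe$fit(X[tr, , drop = FALSE], y[tr],
                          groups = if (!is.null(groups)) groups[tr])
        pred[!tr] <- recipe$predict(fit, X[!tr, , drop = FALSE])
    }
    perFold <- do.call(rbind, lapply(sort(unique(folds)), function(f) {
        i <- folds == f
        data.frame(fold = f, n = sum(i), r2 = rSquared(y[i], pred[i]),
                   rmse = rmse(y[i], pred[i]))
    }))
    list(r2cv = rSquared(y, pred), rmsecv = rmse(y, pred), folds = folds,
         perFold = perFold, predictions = pred)
}
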