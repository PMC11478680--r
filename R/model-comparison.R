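## The comparative experiment: run a strategy x transform matrix with
## leak-free cross-validation and a seedling-level hold-out split,
## shortlist transforms against the raw-reflectance baseline, stratify
## prediction accuracy by leaf position, and rank strategies by the
## position-1 bottleneck criterion.

.strategies <- c("AB", "PCA", "CA", "CAW", "VI", "VIL")

## Build train/test predictor matrices for one strategy, fitting every
## statistic (transform context, correlation screening, PCA rotation) on
## the training leaves only.
.buildPredictors <- function(strategy, train, test, transform, indices,
                             kTop, kMain, kPerWindow, windows, tviForm) {
    info <- list()
    if (strategy %in% c("AB", "PCA", "CA", "CAW")) {
        ctx <- fitTransformContext(transform, train)
        trT <- applyTransform(transform, train, context = ctx)
        teT <- applyTransform(transform, test, context = ctx)
        if (strategy == "AB") {
            Xtr <- spectraMatrix(trT); Xte <- spectraMatrix(teT)
        } else if (strategy == "PCA") {
            red <- pcaReduce(trT)
            Xtr <- red@scores
            Xte <- projectPCA(red, teT)
            info$k <- red@k
            info$cumVariance <- red@cumVariance
        } else {
            prof <- correlationProfile(trT)
            sel <- if (strategy == "CA") selectTopK(prof, kTop)
                   else selectWithWater(prof, kMain = kMain,
                                        windows = windows,
                                        kPerWindow = kPerWindow)
            cols <- bandIndex(trT, selectedBands(sel))
            Xtr <- spectraMatrix(trT)[, cols, drop = FALSE]
            Xte <- spectraMatrix(teT)[, cols, drop = FALSE]
            info$selection <- sel
        }
    } else {
        nm <- if (is.null(indices)) indexNames("vi") else indices
        Xtr <- computeIndexTable(train, nm, tviForm = tviForm)
        Xte <- computeIndexTable(test, nm, tviForm = tviForm)
        info$indices <- nm
    }
    list(Xtr = Xtr, Xte = Xte, info = info)
}

.positionMetrics <- function(obs, pred, position, lowN = 5L) {
    out <- do.call(rbind, lapply(sort(unique(position)), function(p) {
        i <- position == p
        data.frame(position = p, n = sum(i),
                   r2p = rSquared(obs[i], pred[i]),
                   rmsep = rmse(obs[i], pred[i]),
                   low_n = sum(i) < lowN)
    }))
    rownames(out) <- NULL
    out
}

#' Hold-out split of seedlings, stratified by treatment
#'
#' @param s A [SpectraSet-class].
#' @param fraction Test fraction of seedlings per treatment (default 0.2).
#' @param seed Seed for the seedling shuffle.
#' @return Logical vector, `TRUE` for test leaves.
#' @export
holdoutSplit <- function(s, fraction = 0.2, seed = 1L) {
    info <- leafInfo(s)
    test <- rep(FALSE, nrow(info))
    .withSeed(seed, {
        for (tr in unique(info$treatment)) {
            sdl <- unique(info$seedling_id[info$treatment == tr])
            nTest <- max(1L, round(fraction * length(sdl)))
            pick <- sample(sdl, nTest)
            test[info$seedling_id %in% pick] <- TRUE
        }
    })
    test
}

#' Run one modeling strategy end to end
#'
#' Builds predictors per the strategy, evaluates seedling-grouped 5-fold
#' cross-validation accuracy on the training seedlings (every fitted
#' statistic re-estimated per fold on training leaves only), fits the
#' final model on all training leaves, and reports hold-out prediction
#' accuracy overall and per leaf pair position.
#'
#' Strategies: `"AB"` -- PLS on all transformed bands; `"PCA"` --
#' Kaiser-rule PCA scores; `"CA"` -- top-`kTop` correlation-selected
#' bands; `"CAW"` -- `kMain` main-round plus `kPerWindow`-per-window
#' water-window bands; `"VI"` -- PLS on a vegetation-index table (raw
#' reflectance); `"VIL"` -- ordinary least squares on one or a few
#' indices.
#'
#' @param s A raw [SpectraSet-class].
#' @param strategy One of `"AB"`, `"PCA"`, `"CA"`, `"CAW"`, `"VI"`,
#'   `"VIL"`.
#' @param transform Transform name for the band strategies (ignored by
#'   index strategies, which always use raw reflectance).
#' @param indices Index names for `"VI"`/`"VIL"` (default: the ten
#'   vegetation indices).
#' @param k Cross-validation folds (default 5).
#' @param cvSeed,splitSeed Seeds for fold construction and the hold-out
#'   split.
#' @param holdout Test fraction of seedlings per treatment.
#' @param kTop,kMain,kPerWindow,windows Band-selection parameters.
#' @param maxLv Largest latent-variable count tried.
#' @param tviForm TVI parenthesization, see [computeIndex()].
#' @return An [AccuracyReport-class].
#' @export
runStrategy <- function(s, strategy = .strategies, transform = "R",
                        indices = NULL, k = 5L, cvSeed = 1L,
                        splitSeed = 1L, holdout = 0.2, kTop = 10L,
                        kMain = 6L, kPerWindow = 2L,
                        windows = list(c(1390, 1490), c(1870, 1970)),
                        maxLv = 20L, tviForm = "literal") {
    strategy <- match.arg(strategy)
    transform <- normalizeTransformName(transform)
    if (strategy %in% c("VI", "VIL") && transform != "R")
        stop("index strategies compute indices on raw reflectance; ",
             "transform must be 'R'")
    info <- leafInfo(s)
    test <- holdoutSplit(s, fraction = holdout, seed = splitSeed)
    trainSet <- s[, !test]
    testSet <- s[, test]
    if (!1L %in% leafInfo(testSet)$pair_position)
        stop("hold-out test set lacks position-1 leaves; ",
             "use a treatment-stratified split")
    yTr <- chlorophyll(trainSet)
    yTe <- chlorophyll(testSet)
    gTr <- leafInfo(trainSet)$seedling_id

    useOLS <- strategy == "VIL"
    fitFun <- function(X, y, groups) {
        if (useOLS) return(fitLinear(X, y))
        a <- chooseNLV(X, y, maxLv = maxLv, seed = cvSeed + 101L,
                       groups = groups)
        fitPLS1(X, y, a)
    }

    ## cross-validation on training seedlings, leak-free per fold
    folds <- makeFolds(groups = gTr, k = k, seed = cvSeed)
    cvPred <- rep(NA_real_, length(yTr))
    for (f in sort(unique(folds))) {
        tr <- folds != f
        bp <- .buildPredictors(strategy, trainSet[, tr], trainSet[, !tr],
                               transform, indices, kTop, kMain, kPerWindow,
                               windows, tviForm)
        fit <- fitFun(bp$Xtr, yTr[tr], gTr[tr])
        cvPred[!tr] <- predict(fit, bp$Xte)
    }

    ## final model on all training leaves, evaluated on held-out seedlings
    bp <- .buildPredictors(strategy, trainSet, testSet, transform, indices,
                           kTop, kMain, kPerWindow, windows, tviForm)
    finalFit <- fitFun(bp$Xtr, yTr, gTr)
    tePred <- predict(finalFit, bp$Xte)
    perPos <- .positionMetrics(yTe, tePred, leafInfo(testSet)$pair_position)

    methods::new("AccuracyReport",
        strategy = strategy, transform = transform,
        r2cv = rSquared(yTr, cvPred), rmsecv = rmse(yTr, cvPred),
        r2p = rSquared(yTe, tePred), rmsep = rmse(yTe, tePred),
        perPosition = perPos,
        r2pRange = max(perPos$r2p) - min(perPos$r2p),
        rmsepRange = max(perPos$rmsep) - min(perPos$rmsep),
        details = list(k = k, cvSeed = cvSeed, splitSeed = splitSeed,
                       holdout = holdout, folds = folds, test = test,
                       nlv = finalFit@nlv, info = bp$info,
                       cvPredictions = cvPred, testPredictions = tePred))
}

setMethod("show", "AccuracyReport", function(object) {
    cat(sprintf("AccuracyReport: %s (%s)\n", object@strategy,
                object@transform))
    cat(sprintf("  CV:       R2 = %.4f, RMSE = %.4f mg/g\n",
                object@r2cv, object@rmsecv))
    cat(sprintf("  hold-out: R2 = %.4f, RMSE = %.4f mg/g\n",
                object@r2p, object@rmsep))
    cat("  per position:\n")
    print(object@perPosition, row.names = FALSE)
})

#' Shortlist transforms against the raw-reflectance baseline
#'
#' Keeps every transform whose cross-validation R2 is at least that of raw
#' reflectance `"R"`, ordered by descending R2 (`"R"` always qualifies).
#'
#' @param r2cv Named numeric vector of cross-validation R2 per transform
#'   (canonical names); must include `"R"`.
#' @return Character vector of shortlisted transform names.
#' @export
shortlistTransforms <- function(r2cv) {
    if (!"R" %in% names(r2cv))
        stop("shortlisting needs the raw-reflectance baseline 'R'")
    keep <- r2cv[r2cv >= r2cv[["R"]]]
    names(keep)[order(-keep)]
}

#' Percentage change in accuracy after adding water-window bands
#'
#' 100 * (new - old) / old for each accuracy metric, comparing a
#' correlation-only model with its water-window-augmented counterpart.
#'
#' @param before,after Either [AccuracyReport-class] objects (required to
#'   share fold and split seeds) or named numeric vectors with elements
#'   among `r2cv`, `rmsecv`, `r2p`, `rmsep`.
#' @return data.frame with `metric`, `before`, `after`, `pct_change`.
#' @export
compareWaterEffect <- function(before, after) {
    asVec <- function(x) {
        if (methods::is(x, "AccuracyReport"))
            c(r2cv = x@r2cv, rmsecv = x@rmsecv, r2p = x@r2p,
              rmsep = x@rmsep)
        else unlist(x)
    }
    if (methods::is(before, "AccuracyReport") &&
        methods::is(after, "AccuracyReport")) {
        if (!identical(before@details$cvSeed, after@details$cvSeed) ||
            !identical(before@details$splitSeed, after@details$splitSeed))
            stop("reports use different fold/split seeds; not comparable")
    }
    b <- asVec(before); a <- asVec(after)
    common <- intersect(names(b), names(a))
    data.frame(metric = common, before = unname(b[common]),
               after = unname(a[common]),
               pct_change = unname(100 * (a[common] - b[common]) / b[common]))
}

#' Rank strategies by the leaf-position bottleneck criterion
#'
#' Within each strategy the best transform is the one with the highest
#' cross-validation R2. Across strategies, ranking is primarily by
#' hold-out R2 at pair position 1 -- the position present in every
#' treatment and hence the hardest, bottleneck subgroup -- and
#' secondarily (ties within `tol`) by the smallest max-min range of
#' per-position R2 (uniformity). Deterministic in its inputs.
#'
#' @param reports List of [AccuracyReport-class] objects; every report
#'   must carry position-1 hold-out metrics.
#' @param tol Tie tolerance on position-1 R2 (default 1e-6).
#' @return data.frame trace, one row per strategy, ranked; columns include
#'   the position-1 R2, the uniformity ranges and the per-strategy best
#'   transform.
#' @export
selectOptimal <- function(reports, tol = 1e-6) {
    rows <- lapply(reports, function(rep) {
        pp <- rep@perPosition
        if (!1 %in% pp$position)
            stop("report for strategy ", rep@strategy,
                 " lacks position-1 hold-out metrics")
        data.frame(strategy = rep@strategy, transform = rep@transform,
                   r2cv = rep@r2cv, rmsecv = rep@rmsecv, r2p = rep@r2p,
                   rmsep = rep@rmsep,
                   r2p_pos1 = pp$r2p[pp$position == 1],
                   r2p_range = rep@r2pRange, rmsep_range = rep@rmsepRange)
    })
    trace <- do.call(rbind, rows)
    ## per strategy keep its best transform by cross-validation R2
    trace <- do.call(rbind, lapply(split(trace, trace$strategy),
        function(d) d[which.max(d$r2cv), , drop = FALSE]))
    ## bottleneck criterion with uniformity tie-break: quantize position-1
    ## R2 at tol so near-ties fall through to the range
    key1 <- -round(trace$r2p_pos1 / tol) * tol
    trace <- trace[order(key1, trace$r2p_range), , drop = FALSE]
    trace$rank <- seq_len(nrow(trace))
    rownames(trace) <- NULL
    trace
}

#' The published ten-band water-window regression equation
#'
#' Fixed coefficients of the reported best correlation-plus-water-band
#' chlorophyll model: intercept 2.1754 and ten weights on the bands 547,
#' 548, 549, 550, 551, 552, 1464, 1465, 1933 and 1944 nm.
#'
#' @param inputTransform Preprocessing applied to reflectance before the
#'   dot product: `"log_invR"` (the transform reported best for this
#'   model; default) or `"R"` (the literal raw-reflectance reading of the
#'   printed equation). The source text supports both readings, so both
#'   are available.
#' @return A [PublishedModel-class].
#' @export
publishedCAWModel <- function(inputTransform = c("log_invR", "R")) {
    inputTransform <- match.arg(inputTransform)
    methods::new("PublishedModel",
        bands = c(547, 548, 549, 550, 551, 552, 1464, 1465, 1933, 1944),
        coefficients = c(57.7898, 18.9012, -151.3200, -103.7400, 39.6828,
                         142.0900, 489.6450, -494.9750, -36.6924, 37.3505),
        intercept = 2.1754, inputTransform = inputTransform)
}

setMethod("show", "PublishedModel", function(object) {
    cat("PublishedModel: 10-band regression, input transform",
        object@inputTransform, "\n")
    cat("  intercept:", object@intercept, "\n")
    print(stats::setNames(object@coefficients,
                          paste0("R", object@bands)))
})

#' Evaluate the published model on band inputs
#'
#' @param m A [PublishedModel-class].
#' @param x Either a [SpectraSet-class] (raw; the model's input transform
#'   is applied, then the ten bands are extracted) or a numeric matrix /
#'   vector of already-transformed band values in the model's band order.
#' @return Predicted chlorophyll content (mg/g), one value per leaf/row.
#' @examples
#' evaluatePublishedModel(publishedCAWModel(), rep(0, 10))  # the intercept
#' @export
evaluatePublishedModel <- function(m, x) {
    stopifnot(methods::is(m, "PublishedModel"))
    if (methods::is(x, "SpectraSet")) {
        s <- if (m@inputTransform == "R") x else
            applyTransform(m@inputTransform, x)
        X <- bandValue(s, m@bands)
    } else {
        X <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
        if (ncol(X) != 10L)
            stop("expected ten band inputs in the model's band order")
    }
    unname(drop(m@intercept + X %*% m@coefficients))
}
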