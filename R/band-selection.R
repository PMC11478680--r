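## Predictor-construction strategies: per-band Pearson screening (with and
## without dedicated water-absorption windows) and Kaiser-rule PCA
## reduction.

#' Per-band Pearson correlation with chlorophyll
#'
#' @param s A (possibly transformed) [SpectraSet-class].
#' @param y Chlorophyll vector; defaults to `chlorophyll(s)`.
#' @return A data.frame with `wavelength` and `r` (Pearson correlation per
#'   band). Zero-variance bands get r = 0 with a warning.
#' @export
correlationProfile <- function(s, y = chlorophyll(s)) {
    m <- spectraMatrix(s)
    if (length(y) != nrow(m))
        stop("length(y) must equal the number of leaves")
    if (nrow(m) < 3) stop("need at least 3 leaves for correlation screening")
    sds <- apply(m, 2, stats::sd)
    r <- rep(0, ncol(m))
    ok <- sds > 0
    if (!all(ok))
        warning(sum(!ok), " zero-variance band(s); correlation set to 0")
    if (stats::sd(y) == 0) stop("chlorophyll vector has zero variance")
    r[ok] <- as.numeric(stats::cor(m[, ok, drop = FALSE], y))
    data.frame(wavelength = wavelengths(s), r = r)
}

.topByAbsR <- function(profile, k, within = NULL) {
    p <- profile
    if (!is.null(within))
        p <- p[p$wavelength >= within[1] & p$wavelength <= within[2], ,
               drop = FALSE]
    # ties in |r| break by ascending wavelength (order() is stable)
    p <- p[order(-abs(p$r), p$wavelength), , drop = FALSE]
    p[seq_len(min(k, nrow(p))), , drop = FALSE]
}

#' Select the k most chlorophyll-correlated bands
#'
#' Bands ranked by |r|, ties broken by ascending wavelength; k defaults to
#' the ten-band selection used for correlation-analysis PLS.
#'
#' @param profile Output of [correlationProfile()].
#' @param k Number of bands (default 10).
#' @return A [BandSelection-class] with all bands tagged `"main"`.
#' @export
selectTopK <- function(profile, k = 10L) {
    if (k <= 0) stop("k must be positive")
    if (k > nrow(profile)) stop("k exceeds the number of bands")
    top <- .topByAbsR(profile, k)
    methods::new("BandSelection", bands = top$wavelength, r = top$r,
                 provenance = rep("main", nrow(top)))
}

#' Two-round band selection with water-absorption windows
#'
#' Round one takes the `kMain` bands with the largest |r| over the whole
#' grid; round two adds the `kPerWindow` most correlated bands inside each
#' water-absorption window (1390-1490 and 1870-1970 nm by default). A
#' window band already chosen in the main round counts for the window and
#' the next-best window band is taken, so the selection size is always
#' `kMain + length(windows) * kPerWindow`.
#'
#' @param profile Output of [correlationProfile()].
#' @param kMain Main-round band count (default 6).
#' @param windows List of `c(lo, hi)` windows in nm.
#' @param kPerWindow Bands per window (default 2).
#' @return A [BandSelection-class]; provenance tags distinguish main-round
#'   from window bands.
#' @export
selectWithWater <- function(profile, kMain = 6L,
                            windows = list(c(1390, 1490), c(1870, 1970)),
                            kPerWindow = 2L) {
    wl <- profile$wavelength
    for (w in windows) {
        inw <- sum(wl >= w[1] & wl <= w[2])
        if (inw < kPerWindow)
            stop(sprintf("window %g-%g nm holds %d band(s); need >= %d",
                         w[1], w[2], inw, kPerWindow))
    }
    main <- .topByAbsR(profile, kMain)
    bands <- main$wavelength
    r <- main$r
    prov <- rep("main", nrow(main))
    for (w in windows) {
        tag <- sprintf("window_%g_%g", w[1], w[2])
        cand <- .topByAbsR(profile, nrow(profile), within = w)
        # a window band already taken in the main round keeps its "main"
        # tag; the window backfills with its next-best bands so the total
        # selection size stays fixed at kMain + windows * kPerWindow
        cand <- cand[!(cand$wavelength %in% bands), , drop = FALSE]
        if (nrow(cand) < kPerWindow)
            stop(sprintf("window %g-%g nm has too few unselected bands",
                         w[1], w[2]))
        cand <- cand[seq_len(kPerWindow), , drop = FALSE]
        bands <- c(bands, cand$wavelength)
        r <- c(r, cand$r)
        prov <- c(prov, rep(tag, kPerWindow))
    }
    methods::new("BandSelection", bands = bands, r = r, provenance = prov)
}

#' @describeIn BandSelection Selected wavelengths (nm), main-round bands
#'   first, each round ordered by descending |r|.
#' @param x A `BandSelection`.
#' @export
setMethod("selectedBands", "BandSelection", function(x) x@bands)

#' @describeIn BandSelection Provenance tag per band.
#' @export
setMethod("bandProvenance", "BandSelection", function(x) x@provenance)

setMethod("show", "BandSelection", function(object) {
    cat("BandSelection with", length(object@bands), "bands\n")
    df <- data.frame(wavelength = object@bands,
                     r = round(object@r, 4),
                     provenance = object@provenance)
    print(df, row.names = FALSE)
})

#' Kaiser-rule PCA reduction of a spectra matrix
#'
#' Principal components of the standardized (correlation-scale) band
#' matrix, retaining every component with eigenvalue > 1. The training
#' centering, scaling and rotation are stored so held-out spectra are
#' projected with [projectPCA()], never refit. Zero-variance bands are
#' left centered but unscaled (they contribute nothing).
#'
#' @param s A (possibly transformed) [SpectraSet-class] or numeric matrix
#'   (leaves x bands) with n >= 2.
#' @return A [PCAReduction-class].
#' @export
pcaReduce <- function(s) {
    m <- if (methods::is(s, "SpectraSet")) spectraMatrix(s) else as.matrix(s)
    if (nrow(m) < 2) stop("PCA needs at least 2 leaves")
    ctr <- colMeans(m)
    scl <- apply(m, 2, stats::sd)
    scl[scl == 0] <- 1
    z <- sweep(sweep(m, 2, ctr), 2, scl, "/")
    pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
    ev <- pc$sdev^2
    k <- sum(ev > 1)
    if (k == 0) k <- 1L  # degenerate near-spherical data: keep one score
    totvar <- sum(ev)
    methods::new("PCAReduction",
        scores = pc$x[, seq_len(k), drop = FALSE],
        loadings = pc$rotation[, seq_len(k), drop = FALSE],
        eigenvalues = ev,
        cumVariance = sum(ev[seq_len(k)]) / totvar,
        k = as.integer(k), center = ctr, scale = scl)
}

#' Project new spectra onto a fitted PCA reduction
#'
#' @param red A [PCAReduction-class] fitted on training leaves.
#' @param s A [SpectraSet-class] or matrix with the same bands.
#' @return Scores matrix (leaves x retained components).
#' @export
projectPCA <- function(red, s) {
    m <- if (methods::is(s, "SpectraSet")) spectraMatrix(s) else as.matrix(s)
    if (ncol(m) != length(red@center))
        stop("band count does not match the fitted reduction")
    z <- sweep(sweep(m, 2, red@center), 2, red@scale, "/")
    z %*% red@loadings
}

setMethod("show", "PCAReduction", function(object) {
    cat("PCAReduction:", object@k, "component(s) with eigenvalue > 1;",
        sprintf("cumulative variance %.2f%%\n", 100 * object@cumVariance))
})
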