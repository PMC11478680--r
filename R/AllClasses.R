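#' SpectraSet: leaf reflectance spectra with per-leaf metadata
#'
#' An S4 container for leaf-level hyperspectral measurements, extending
#' \linkS4class{SummarizedExperiment}. The single assay \code{"spectra"}
#' stores one column per leaf and one row per wavelength (features in rows,
#' samples in columns, the Bioconductor convention). \code{rowData} carries
#' the wavelength grid in nm; \code{colData} carries the leaf metadata:
#' \code{seedling_id}, \code{treatment} (\code{T1}-\code{T4}),
#' \code{pair_position} (1 = first pair of top leaves), \code{leaf_side}
#' (1-2 within a pair) and measured \code{chlorophyll} (mg/g).
#'
#' The applied preprocessing is recorded in \code{transformTag()}; raw
#' reflectance sets carry tag \code{"R"} and must lie in (0, 1]. Transformed
#' sets (derivatives, log chains, SNV, MSC, ...) may take any real values.
#'
#' The wavelength grid must be strictly increasing with uniform spacing.
#' The default instrument grid is 350-2500 nm at 1 nm (2151 bands).
#'
#' @seealso [SpectraSet()] for construction, [readSpectra()] /
#'   [writeSpectra()] for delimited-text I/O, [applyTransform()] for
#'   preprocessing.
#' @export
setClass("SpectraSet", contains = "SummarizedExperiment")

.checkGrid <- function(wl) {
    if (length(wl) == 0L) return(TRUE)
    if (anyNA(wl)) return("wavelength grid contains NA")
    if (length(wl) >= 2L) {
        d <- diff(wl)
        if (any(d <= 0)) return("wavelength grid is not strictly increasing")
        if (max(d) - min(d) > 1e-6 * max(d))
            return("wavelength grid spacing is not uniform")
    }
    TRUE
}

setValidity("SpectraSet", function(object) {
    msg <- character()
    if (!"spectra" %in% SummarizedExperiment::assayNames(object))
        return("assay 'spectra' is missing")
    m <- SummarizedExperiment::assay(object, "spectra")
    if (anyNA(m))
        msg <- c(msg, "reflectance matrix contains missing values")
    rd <- SummarizedExperiment::rowData(object)
    if (!"wavelength_nm" %in% colnames(rd))
        return("rowData must contain 'wavelength_nm'")
    g <- .checkGrid(rd$wavelength_nm)
    if (is.character(g)) msg <- c(msg, g)
    cd <- SummarizedExperiment::colData(object)
    need <- c("seedling_id", "treatment", "pair_position", "leaf_side",
              "chlorophyll")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("missing metadata column(s): ",
                             paste(miss, collapse = ", ")))
    if (is.null(S4Vectors::metadata(object)$transform_tag))
        msg <- c(msg, "metadata 'transform_tag' is missing")
    tag <- S4Vectors::metadata(object)$transform_tag
    if (identical(tag, "R") && length(m) && !anyNA(m)) {
        bad <- which(m <= 0 | m > 1)
        if (length(bad)) {
            ij <- arrayInd(bad[1], dim(m))
            msg <- c(msg, sprintf(
                paste0("raw reflectance outside (0,1]: %d offending ",
                       "value(s), first at wavelength %s nm, leaf %d ",
                       "(value %.6g)"),
                length(bad), rd$wavelength_nm[ij[1]], ij[2], m[bad[1]]))
        }
    }
    if ("chlorophyll" %in% colnames(cd) && length(cd$chlorophyll) &&
        !anyNA(cd$chlorophyll) && any(cd$chlorophyll <= 0))
        msg <- c(msg, "chlorophyll values must be > 0")
    if (all(c("treatment", "pair_position") %in% colnames(cd)) &&
        nrow(cd) > 0) {
        k <- as.integer(sub("^T", "", as.character(cd$treatment)))
        if (!anyNA(k) && any(cd$pair_position > k))
            msg <- c(msg, "pair_position exceeds treatment pair count")
    }
    if (length(msg)) msg else TRUE
})

#' Ordered wavelength selection with correlation provenance
#'
#' Result of correlation-based band screening ([selectTopK()],
#' [selectWithWater()]): selected wavelengths (nm), their Pearson
#' correlations with chlorophyll, and a provenance tag per band --
#' \code{"main"} for the whole-grid round, or \code{"window_1390_1490"} /
#' \code{"window_1870_1970"} for bands picked inside a water-absorption
#' window.
#'
#' @export
setClass("BandSelection",
    representation(bands = "numeric", r = "numeric",
                   provenance = "character"))

setValidity("BandSelection", function(object) {
    msg <- character()
    n <- length(object@bands)
    if (length(object@r) != n || length(object@provenance) != n)
        msg <- c(msg, "bands, r and provenance must have equal length")
    if (anyDuplicated(object@bands))
        msg <- c(msg, "duplicate bands in selection")
    if (length(object@r) && !anyNA(object@r) &&
        any(abs(object@r) > 1 + 1e-12))
        msg <- c(msg, "correlations must lie in [-1, 1]")
    ok <- object@provenance %in%
        c("main", "window_1390_1490", "window_1870_1970")
    if (!all(ok)) msg <- c(msg, "unknown provenance tag")
    if (length(msg)) msg else TRUE
})

#' Kaiser-rule principal component reduction of a spectra matrix
#'
#' Scores, loadings and eigenvalues of a PCA of the standardized band
#' matrix, retaining every component with eigenvalue > 1 (the Kaiser rule
#' applied to the correlation matrix). The training centering/scaling and
#' rotation are stored so held-out spectra are projected, never refit.
#'
#' @export
setClass("PCAReduction",
    representation(scores = "matrix", loadings = "matrix",
                   eigenvalues = "numeric", cumVariance = "numeric",
                   k = "integer", center = "numeric", scale = "numeric"))

setValidity("PCAReduction", function(object) {
    msg <- character()
    ev <- object@eigenvalues
    if (length(ev) >= 2 && any(diff(ev) > 1e-8))
        msg <- c(msg, "eigenvalues must be non-increasing")
    if (object@k > 0 && any(ev[seq_len(object@k)] <= 1))
        msg <- c(msg, "every retained eigenvalue must exceed 1")
    if (length(object@cumVariance) &&
        (object@cumVariance <= 0 || object@cumVariance > 1 + 1e-12))
        msg <- c(msg, "cumulative variance must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' Fitted PLS1 / least-squares regression model
#'
#' Centering values, latent-variable count and regression coefficients of a
#' univariate-response partial least squares fit (or an ordinary
#' least-squares fit, for index models, where \code{nlv} equals the number
#' of predictors). \code{coefficients} and \code{intercept} express the
#' model on the original predictor scale, y = a0 + sum(ai * xi), so
#' prediction is a single dot product.
#'
#' @export
setClass("PLSModel",
    representation(coefficients = "numeric", intercept = "numeric",
                   xMeans = "numeric", yMean = "numeric", nlv = "integer",
                   method = "character"))

setValidity("PLSModel", function(object) {
    msg <- character()
    if (object@nlv < 1L) msg <- c(msg, "nlv must be >= 1")
    if (length(object@coefficients) != length(object@xMeans))
        msg <- c(msg, "coefficients and xMeans lengths differ")
    if (length(msg)) msg else TRUE
})

#' Cross-validation and hold-out accuracy of one modeling strategy
#'
#' R2/RMSE of pooled out-of-fold predictions (cross-validation accuracy),
#' R2/RMSE on the held-out test seedlings (prediction accuracy), the same
#' metrics stratified by leaf pair position, and the max-min range of the
#' per-position metrics (uniformity). \code{details} keeps the audit trail
#' (selected bands, latent-variable counts, fold assignment, split).
#'
#' @export
setClass("AccuracyReport",
    representation(strategy = "character", transform = "character",
                   r2cv = "numeric", rmsecv = "numeric",
                   r2p = "numeric", rmsep = "numeric",
                   perPosition = "data.frame",
                   r2pRange = "numeric", rmsepRange = "numeric",
                   details = "list"))

#' The published water-window PLS regression equation
#'
#' The ten-band chlorophyll regression reported for the best
#' correlation-plus-water-band model: six green-peak bands (547-552 nm) and
#' four water-window bands (1464, 1465, 1933, 1944 nm) with fixed printed
#' coefficients and intercept. \code{inputTransform} records which
#' preprocessing is applied to reflectance before the dot product
#' (\code{"log_invR"} by default, \code{"R"} for the raw-reflectance
#' reading).
#'
#' @export
setClass("PublishedModel",
    representation(bands = "numeric", coefficients = "numeric",
                   intercept = "numeric", inputTransform = "character"))

setValidity("PublishedModel", function(object) {
    if (length(object@coefficients) != 10L)
        return("a published model has exactly ten coefficients")
    if (length(object@bands) != 10L)
        return("a published model has exactly ten bands")
    TRUE
})
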