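## Registry of the 14 spectral indices: 10 chlorophyll-sensitive
## vegetation indices and 4 water-sensitive indices, all computed from raw
## reflectance at named wavelengths.

.indexRegistry <- list(
    GNDVI = list(bands = c(750, 550), fun = function(R)
        (R[["750"]] - R[["550"]]) / (R[["750"]] + R[["550"]])),
    CIgreen = list(bands = c(800, 550), fun = function(R)
        R[["800"]] / R[["550"]] - 1),
    RVI = list(bands = c(810, 570), fun = function(R)
        R[["810"]] / R[["570"]]),
    `CIred edge` = list(bands = c(800, 720), fun = function(R)
        R[["800"]] / R[["720"]] - 1),
    VOG3 = list(bands = c(734, 747, 715, 720), fun = function(R)
        (R[["734"]] - R[["747"]]) / (R[["715"]] + R[["720"]])),
    RNDVI = list(bands = c(750, 705), fun = function(R)
        (R[["750"]] - R[["705"]]) / (R[["750"]] + R[["705"]])),
    NDVI = list(bands = c(800, 670), fun = function(R)
        (R[["800"]] - R[["670"]]) / (R[["800"]] + R[["670"]])),
    PRI = list(bands = c(531, 570), fun = function(R)
        (R[["531"]] - R[["570"]]) / (R[["531"]] + R[["570"]])),
    NPCI = list(bands = c(680, 430), fun = function(R)
        (R[["680"]] - R[["430"]]) / (R[["680"]] + R[["430"]])),
    TVI = list(bands = c(750, 500, 670), fun = function(R)
        60 * (R[["750"]] - R[["500"]]) - 100 * (R[["670"]] - R[["500"]])),
    WI = list(bands = c(900, 970), fun = function(R)
        R[["900"]] / R[["970"]]),
    WBI = list(bands = c(950, 900), fun = function(R)
        R[["950"]] / R[["900"]]),
    NDWI = list(bands = c(860, 1240), fun = function(R)
        (R[["860"]] - R[["1240"]]) / (R[["860"]] + R[["1240"]])),
    MSI = list(bands = c(1600, 820), fun = function(R)
        R[["1600"]] / R[["820"]]))

## The published TVI formula reads 60(R750-R500) - 100(R670-R500) taken
## literally; the canonical triangular form from its original source is
## 0.5 * [120(R750-R550) - 200(R670-R550)]. Both are available.
.tviCanonical <- list(bands = c(750, 550, 670), fun = function(R)
    0.5 * (120 * (R[["750"]] - R[["550"]]) - 200 * (R[["670"]] - R[["550"]])))

#' Names of the registered spectral indices
#'
#' @param which `"all"` (14 indices), `"vi"` (the 10 chlorophyll-sensitive
#'   vegetation indices), `"vi6"` (the six most chlorophyll-correlated:
#'   GNDVI, CIgreen, RVI, CIred edge, VOG3, RNDVI), or `"wi"` (the 4
#'   water-sensitive indices: WI, WBI, NDWI, MSI).
#' @return Character vector of index names.
#' @examples
#' indexNames("wi")
#' @export
indexNames <- function(which = c("all", "vi", "vi6", "wi")) {
    which <- match.arg(which)
    all <- names(.indexRegistry)
    switch(which,
        all = all,
        vi = all[1:10],
        vi6 = c("GNDVI", "CIgreen", "RVI", "CIred edge", "VOG3", "RNDVI"),
        wi = c("WI", "WBI", "NDWI", "MSI"))
}

#' Compute one spectral index per leaf
#'
#' @param name Registered index name (see [indexNames()]).
#' @param s A raw (`transformTag == "R"`) [SpectraSet-class] whose grid
#'   contains the index's required bands.
#' @param tviForm For TVI only: `"literal"` (default) evaluates
#'   60(R750-R500) - 100(R670-R500); `"canonical"` the triangular form
#'   0.5*(120(R750-R550) - 200(R670-R550)).
#' @return Numeric vector, one value per leaf.
#' @examples
#' s <- makeFixture("tiny")$spectra
#' head(computeIndex("GNDVI", s))
#' @export
computeIndex <- function(name, s, tviForm = c("literal", "canonical")) {
    tviForm <- match.arg(tviForm)
    if (!name %in% names(.indexRegistry))
        stop("unknown index: '", name, "'; see indexNames()")
    if (!identical(transformTag(s), "R"))
        stop("indices are defined on raw reflectance (transform tag 'R')")
    def <- if (name == "TVI" && tviForm == "canonical") .tviCanonical
           else .indexRegistry[[name]]
    vals <- lapply(def$bands, function(b) bandValue(s, b, nearest = TRUE))
    names(vals) <- as.character(def$bands)
    out <- def$fun(vals)
    if (any(!is.finite(out)))
        stop("index '", name, "' undefined (zero denominator) for leaf ",
             which(!is.finite(out))[1])
    unname(out)
}

#' Compute a leaves-by-indices predictor table
#'
#' @param s A raw [SpectraSet-class].
#' @param names Index names; column order follows this list. Defaults to
#'   all 14 registered indices.
#' @param tviForm Passed to [computeIndex()].
#' @return Numeric matrix, one row per leaf, one column per index.
#' @export
computeIndexTable <- function(s, names = indexNames("all"),
                              tviForm = c("literal", "canonical")) {
    tviForm <- match.arg(tviForm)
    out <- vapply(names, function(nm) computeIndex(nm, s, tviForm),
                  numeric(nLeaves(s)))
    if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                         dimnames = list(NULL, names))
    out
}
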