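#' Construct a uniform wavelength grid
#'
#' @param start,stop First and last wavelength in nm.
#' @param step Grid spacing in nm.
#' @return Numeric vector of wavelengths, strictly increasing with uniform
#'   spacing. The default 350-2500 nm at 1 nm yields exactly 2151 points.
#' @examples
#' length(wavelengthGrid())  # 2151
#' @export
wavelengthGrid <- function(start = 350, stop = 2500, step = 1) {
    if (step <= 0) stop("grid step must be positive")
    if (stop <= start) stop("grid stop must exceed start")
    seq(start, stop, by = step)
}

#' Create a SpectraSet
#'
#' @param reflectance Numeric matrix, one row per leaf, one column per
#'   wavelength (the orientation in which spectra files are laid out; it is
#'   transposed into the features-by-samples assay internally).
#' @param wavelengths Numeric wavelength grid in nm, length `ncol(reflectance)`.
#' @param leafData `data.frame` (or DataFrame) with one row per leaf and
#'   columns `seedling_id`, `treatment`, `pair_position`, `leaf_side`,
#'   `chlorophyll`.
#' @param transformTag Name of the preprocessing applied; `"R"` (the
#'   default) marks raw reflectance, which must lie in (0, 1].
#' @return A validated [SpectraSet-class] object.
#' @examples
#' wl <- wavelengthGrid(500, 600, 10)
#' m <- matrix(runif(2 * length(wl), 0.1, 0.5), nrow = 2)
#' md <- data.frame(seedling_id = c("s1", "s1"), treatment = "T1",
#'                  pair_position = 1L, leaf_side = 1:2,
#'                  chlorophyll = c(8, 9))
#' s <- SpectraSet(m, wl, md)
#' nLeaves(s)
#' @export
SpectraSet <- function(reflectance, wavelengths, leafData,
                       transformTag = "R") {
    reflectance <- as.matrix(reflectance)
    if (ncol(reflectance) != length(wavelengths))
        stop("ncol(reflectance) must equal length(wavelengths)")
    if (nrow(reflectance) != nrow(leafData))
        stop("nrow(reflectance) must equal nrow(leafData)")
    cd <- S4Vectors::DataFrame(leafData)
    assay <- t(reflectance)
    dimnames(assay) <- list(NULL, rownames(leafData))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(spectra = assay),
        rowData = S4Vectors::DataFrame(wavelength_nm = as.numeric(wavelengths)),
        colData = cd)
    S4Vectors::metadata(se)$transform_tag <- transformTag
    methods::validObject(out <- methods::as(se, "SpectraSet"))
    out
}

#' @describeIn SpectraSet Wavelength grid (nm) of a SpectraSet.
#' @param x A `SpectraSet`.
#' @export
setMethod("wavelengths", "SpectraSet", function(x, ...)
    as.numeric(SummarizedExperiment::rowData(x)$wavelength_nm))

#' @describeIn SpectraSet Leaves-by-wavelengths numeric matrix, columns
#'   named by wavelength.
#' @export
setMethod("spectraMatrix", "SpectraSet", function(x, ...) {
    m <- t(SummarizedExperiment::assay(x, "spectra"))
    colnames(m) <- as.character(wavelengths(x))
    m
})

#' @describeIn SpectraSet Measured chlorophyll content (mg/g), one value
#'   per leaf.
#' @export
setMethod("chlorophyll", "SpectraSet", function(x, ...)
    as.numeric(SummarizedExperiment::colData(x)$chlorophyll))

#' @describeIn SpectraSet Per-leaf metadata as a `data.frame`.
#' @export
setMethod("leafInfo", "SpectraSet", function(x, ...)
    as.data.frame(SummarizedExperiment::colData(x)))

#' @describeIn SpectraSet Name of the preprocessing applied ("R" = raw).
#' @export
setMethod("transformTag", "SpectraSet", function(x)
    S4Vectors::metadata(x)$transform_tag)

#' @describeIn SpectraSet Replace the transform tag (revalidates).
#' @param value New tag string.
#' @export
setReplaceMethod("transformTag", "SpectraSet", function(x, value) {
    S4Vectors::metadata(x)$transform_tag <- value
    methods::validObject(x)
    x
})

#' @describeIn SpectraSet Number of leaves (samples).
#' @export
setMethod("nLeaves", "SpectraSet", function(x) ncol(x))

#' @describeIn SpectraSet Number of wavelengths (bands).
#' @export
setMethod("nBands", "SpectraSet", function(x) nrow(x))

#' @describeIn SpectraSet Column index of a wavelength in
#'   `spectraMatrix(x)`: for the default 350-2500 nm 1 nm grid,
#'   `bandIndex(x, 550)` is 201 (1-based).
#' @param nm Wavelength in nm (vectorized).
#' @param nearest If `TRUE`, off-grid wavelengths resolve to the closest
#'   grid band (used by index computation on coarsened grids); otherwise
#'   an off-grid wavelength is an error.
#' @export
setMethod("bandIndex", "SpectraSet", function(x, nm, nearest = FALSE, ...) {
    wl <- wavelengths(x)
    step <- if (length(wl) > 1) wl[2] - wl[1] else 1
    near <- round((nm - wl[1]) / step) + 1
    near <- pmin(pmax(near, 1), length(wl))
    exact <- abs(wl[near] - nm) < 1e-6
    if (!nearest && !all(exact))
        stop("wavelength(s) not on grid: ",
             paste(nm[!exact], collapse = ", "))
    if (nearest && any(abs(wl[near] - nm) > step))
        stop("wavelength(s) outside grid range: ",
             paste(nm[abs(wl[near] - nm) > step], collapse = ", "))
    as.integer(near)
})

#' @describeIn SpectraSet Per-leaf values at one or more named wavelengths
#'   (e.g. `bandValue(s, 550)` is R_550).
#' @export
setMethod("bandValue", "SpectraSet", function(x, nm, nearest = FALSE, ...) {
    spectraMatrix(x)[, bandIndex(x, nm, nearest = nearest),
                     drop = length(nm) == 1]
})

setMethod("show", "SpectraSet", function(object) {
    wl <- wavelengths(object)
    cat("SpectraSet with", nLeaves(object), "leaves and",
        nBands(object), "bands\n")
    if (length(wl))
        cat(sprintf("  grid: %g-%g nm, step %g nm\n", wl[1], wl[length(wl)],
                    if (length(wl) > 1) wl[2] - wl[1] else NA))
    cat("  transform:", transformTag(object), "\n")
    tr <- table(SummarizedExperiment::colData(object)$treatment)
    if (length(tr))
        cat("  treatments:",
            paste(names(tr), tr, sep = "=", collapse = " "), "\n")
})

.metaCols <- c("seedling_id", "treatment", "pair_position", "leaf_side",
               "chlorophyll")

#' Read a SpectraSet from delimited text
#'
#' Expects a wide CSV: an optional leading comment line
#' `# transform: <tag>`, then a header with the five metadata columns
#' (`seedling_id`, `treatment`, `pair_position`, `leaf_side`,
#' `chlorophyll`) followed by one column per wavelength (numeric header,
#' nm). The wavelength grid is validated (strictly increasing, uniform
#' spacing) and raw reflectance is checked to lie in (0, 1].
#'
#' @param path Path to a CSV written by [writeSpectra()] (or compatible).
#' @param sep Field separator (default comma).
#' @return A validated [SpectraSet-class].
#' @export
readSpectra <- function(path, sep = ",") {
    first <- readLines(path, n = 1L)
    tag <- "R"
    skip <- 0L
    if (startsWith(first, "#")) {
        m <- regmatches(first, regexec("#\\s*transform:\\s*(.*)$", first))[[1]]
        if (length(m) == 2) tag <- trimws(m[2])
        skip <- 1L
    }
    df <- utils::read.csv(path, check.names = FALSE, skip = skip, sep = sep,
                          stringsAsFactors = FALSE)
    miss <- setdiff(.metaCols, colnames(df))
    if (length(miss))
        stop("missing metadata column(s): ", paste(miss, collapse = ", "))
    wlcols <- setdiff(colnames(df), .metaCols)
    wl <- suppressWarnings(as.numeric(wlcols))
    if (anyNA(wl))
        stop("non-numeric wavelength column header(s): ",
             paste(utils::head(wlcols[is.na(wl)], 3), collapse = ", "))
    g <- .checkGrid(wl)
    if (is.character(g)) stop("grid error: ", g)
    refl <- as.matrix(df[, wlcols, drop = FALSE])
    storage.mode(refl) <- "double"
    md <- df[, .metaCols, drop = FALSE]
    md$pair_position <- as.integer(md$pair_position)
    md$leaf_side <- as.integer(md$leaf_side)
    SpectraSet(refl, wl, md, transformTag = tag)
}

#' Write a SpectraSet to delimited text
#'
#' Inverse of [readSpectra()]: writes a `# transform:` comment line, the
#' metadata columns, then one column per wavelength at full double
#' precision (round trips to at least 6 significant digits).
#'
#' @param s A [SpectraSet-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeSpectra <- function(s, path) {
    stopifnot(methods::is(s, "SpectraSet"))
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(paste0("# transform: ", transformTag(s)), con)
    df <- cbind(leafInfo(s)[, .metaCols, drop = FALSE],
                as.data.frame(spectraMatrix(s), check.names = FALSE))
    utils::write.csv(df, con, row.names = FALSE)
    invisible(path)
}

#' Mean spectrum per leaf group
#'
#' Arithmetic mean reflectance at every wavelength within groups defined by
#' treatment and/or leaf pair position -- the per-leaf-position mean curves
#' used to locate the chlorophyll-sensitive green peak (near 550 nm) and
#' the water-sensitive troughs (near 1440 and 1920 nm).
#'
#' @param s A [SpectraSet-class].
#' @param groupKeys Character subset of `c("treatment", "pair_position")`.
#'   Empty (`character()`) yields a single global mean row.
#' @return A list with `groups` (data.frame of group keys, ordered by
#'   treatment then position, plus `n` leaves), `wavelengths`, and `means`
#'   (groups-by-wavelengths matrix).
#' @export
meanSpectrumByGroup <- function(s, groupKeys = c("treatment",
                                                 "pair_position")) {
    stopifnot(methods::is(s, "SpectraSet"))
    bad <- setdiff(groupKeys, c("treatment", "pair_position"))
    if (length(bad)) stop("unknown group key(s): ", paste(bad, collapse = ", "))
    m <- spectraMatrix(s)
    info <- leafInfo(s)
    if (length(groupKeys) == 0L) {
        groups <- data.frame(n = nrow(m))
        means <- matrix(colMeans(m), nrow = 1)
    } else {
        key <- interaction(info[groupKeys], drop = TRUE, lex.order = TRUE)
        idx <- split(seq_len(nrow(m)), key)
        idx <- idx[lengths(idx) > 0]
        groups <- unique(info[order(info$treatment, info$pair_position),
                              groupKeys, drop = FALSE])
        ord <- vapply(seq_len(nrow(groups)), function(i)
            which(names(idx) == paste(groups[i, ], collapse = "."))[1],
            integer(1))
        idx <- idx[ord]
        groups$n <- lengths(idx)
        rownames(groups) <- NULL
        means <- do.call(rbind, lapply(idx, function(i)
            colMeans(m[i, , drop = FALSE])))
        rownames(means) <- names(idx)
    }
    list(groups = groups, wavelengths = wavelengths(s), means = means)
}
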