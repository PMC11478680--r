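## Transform registry: 21 chemometric preprocessing recipes, each a fixed
## chain of primitive operators applied leaf-wise to a whole SpectraSet.
## Canonical names are ASCII; `label` carries the conventional notation.

.transformRegistry <- local({
    reg <- list(
        list(name = "R",           label = "R",            chain = character()),
        list(name = "R1",          label = "R'",           chain = "d1"),
        list(name = "R2",          label = "R''",          chain = "d2"),
        list(name = "sqrtR",       label = "sqrt(R)",      chain = "sqrt"),
        list(name = "d_sqrtR",     label = "(sqrt(R))'",   chain = c("sqrt", "d1")),
        list(name = "logR",        label = "logR",         chain = "log10"),
        list(name = "d_logR",      label = "(logR)'",      chain = c("log10", "d1")),
        list(name = "invR",        label = "1/R",          chain = "reciprocal"),
        list(name = "d_invR",      label = "(1/R)'",       chain = c("reciprocal", "d1")),
        list(name = "log_invR",    label = "log(1/R)",     chain = c("reciprocal", "log10")),
        list(name = "d_log_invR",  label = "(log(1/R))'",  chain = c("reciprocal", "log10", "d1")),
        list(name = "log_sqrtR",   label = "log(sqrt(R))", chain = c("sqrt", "log10")),
        list(name = "d_log_sqrtR", label = "(log(sqrt(R)))'",
             chain = c("sqrt", "log10", "d1")),
        list(name = "inv_logR",    label = "1/logR",       chain = c("log10", "reciprocal")),
        list(name = "d_inv_logR",  label = "(1/logR)'",
             chain = c("log10", "reciprocal", "d1")),
        list(name = "sqrt_invR",   label = "sqrt(1/R)",    chain = c("reciprocal", "sqrt")),
        list(name = "d_sqrt_invR", label = "(sqrt(1/R))'",
             chain = c("reciprocal", "sqrt", "d1")),
        list(name = "SNV",         label = "SNV",          chain = "snv"),
        list(name = "MSC",         label = "MSC",          chain = "msc"),
        list(name = "FD-SNV",      label = "FD-SNV",       chain = c("d1", "snv")),
        list(name = "FD-MSC",      label = "FD-MSC",       chain = c("d1", "msc")))
    names(reg) <- vapply(reg, `[[`, "", "name")
    reg
})

## Transforms whose all-band cross-validation accuracy matched or beat raw
## reflectance in the source study; they form the shortlist carried into
## the dimension-reduction and band-selection strategies.
.shortlistedTransforms <- c("R1", "sqrtR", "logR", "log_invR", "log_sqrtR", "R")

.transformAliases <- local({
    a <- c("R'" = "R1", "R′" = "R1", "R''" = "R2", "R″" = "R2",
           "sqrt(R)" = "sqrtR", "√R" = "sqrtR",
           "(sqrt(R))'" = "d_sqrtR", "(√R)′" = "d_sqrtR",
           "(logR)'" = "d_logR",
           "1/R" = "invR", "(1/R)'" = "d_invR",
           "log(1/R)" = "log_invR", "(log(1/R))'" = "d_log_invR",
           "log(sqrt(R))" = "log_sqrtR", "log√R" = "log_sqrtR",
           "(log(sqrt(R)))'" = "d_log_sqrtR",
           "1/logR" = "inv_logR", "(1/logR)'" = "d_inv_logR",
           "sqrt(1/R)" = "sqrt_invR", "√(1/R)" = "sqrt_invR",
           "(sqrt(1/R))'" = "d_sqrt_invR",
           "FDSNV" = "FD-SNV", "FDMSC" = "FD-MSC")
    a
})

#' Normalize a transform name to its canonical registry key
#'
#' Accepts the canonical ASCII names (`R`, `R1`, `log_invR`, ...) as well
#' as conventional notation (`"R'"`, `"log(1/R)"`, ...).
#' @param name Transform name or alias.
#' @return Canonical name (character scalar).
#' @export
normalizeTransformName <- function(name) {
    if (name %in% names(.transformRegistry)) return(name)
    if (name %in% names(.transformAliases))
        return(unname(.transformAliases[name]))
    stop("unknown transform: '", name, "'; see listTransforms()")
}

#' List the registered spectral preprocessing transforms
#'
#' @return A `data.frame` with the 21 registered transforms in canonical
#'   order: `name` (ASCII key), `label` (conventional notation), `chain`
#'   (primitive operators, collapsed with `+`), and `shortlisted` (whether
#'   the transform is in the six-member shortlist whose all-band
#'   cross-validation accuracy matched or beat raw reflectance).
#' @examples
#' nrow(listTransforms())  # 21
#' @export
listTransforms <- function() {
    data.frame(
        name = vapply(.transformRegistry, `[[`, "", "name"),
        label = vapply(.transformRegistry, `[[`, "", "label"),
        chain = vapply(.transformRegistry, function(t)
            if (length(t$chain)) paste(t$chain, collapse = "+") else "identity",
            ""),
        shortlisted = vapply(.transformRegistry, `[[`, "", "name") %in%
            .shortlistedTransforms,
        row.names = NULL)
}

.derivMatrix <- function(m, step, order = 1L) {
    p <- ncol(m)
    if (p < 3L) stop("derivative needs at least 3 bands")
    out <- m
    if (order == 1L) {
        out[, 2:(p - 1)] <- (m[, 3:p] - m[, 1:(p - 2)]) / (2 * step)
        out[, 1] <- (m[, 2] - m[, 1]) / step
        out[, p] <- (m[, p] - m[, p - 1]) / step
    } else {
        out[, 2:(p - 1)] <- (m[, 3:p] - 2 * m[, 2:(p - 1)] + m[, 1:(p - 2)]) /
            step^2
        out[, 1] <- (m[, 3] - 2 * m[, 2] + m[, 1]) / step^2
        out[, p] <- (m[, p] - 2 * m[, p - 1] + m[, p - 2]) / step^2
    }
    out
}

.snvMatrix <- function(m) {
    mu <- rowMeans(m)
    sdv <- apply(m, 1, stats::sd)
    if (any(sdv == 0))
        stop("SNV undefined for zero-variance row(s): ",
             paste(utils::head(which(sdv == 0), 5), collapse = ", "))
    (m - mu) / sdv
}

.mscMatrix <- function(m, reference = NULL) {
    if (is.null(reference)) {
        if (nrow(m) < 2)
            stop("MSC needs >= 2 spectra when no reference is supplied")
        reference <- colMeans(m)
    }
    if (length(reference) != ncol(m))
        stop("MSC reference length does not match band count")
    rc <- reference - mean(reference)
    denom <- sum(rc^2)
    if (denom == 0) stop("MSC reference has zero variance")
    b <- as.numeric(m %*% rc) / denom
    if (any(abs(b) < 1e-12))
        stop("MSC slope estimate ~0 for row(s): ",
             paste(utils::head(which(abs(b) < 1e-12), 5), collapse = ", "))
    a <- rowMeans(m) - b * mean(reference)
    out <- (m - a) / b
    attr(out, "reference") <- reference
    out
}

.checkDomain <- function(m, wl, what, test) {
    bad <- which(test(m))
    if (length(bad)) {
        ij <- arrayInd(bad[1], dim(m))
        stop(sprintf(
            "transform domain violation (%s): %d value(s), first at row %d, wavelength %s nm (value %.6g)",
            what, length(bad), ij[1], wl[ij[2]], m[bad[1]]))
    }
}

.applyPrimitive <- function(op, m, wl, context = NULL) {
    step <- if (length(wl) > 1) wl[2] - wl[1] else 1
    switch(op,
        d1 = .derivMatrix(m, step, 1L),
        d2 = .derivMatrix(m, step, 2L),
        sqrt = { .checkDomain(m, wl, "sqrt of negative", function(x) x < 0); sqrt(m) },
        log10 = { .checkDomain(m, wl, "log of non-positive", function(x) x <= 0); log10(m) },
        reciprocal = { .checkDomain(m, wl, "reciprocal of zero", function(x) x == 0); 1 / m },
        snv = .snvMatrix(m),
        msc = .mscMatrix(m, context$msc_reference),
        stop("unknown primitive: ", op))
}

#' Fit training statistics for a transform
#'
#' Most transforms are purely leaf-wise and need no fitted state; MSC (and
#' FD-MSC) estimate a reference spectrum -- the mean over training leaves
#' at the correction step -- which must come from training data only in any
#' cross-validation or hold-out context. This returns that state so
#' held-out spectra can be corrected against the training reference.
#'
#' @param name Transform name (canonical or alias).
#' @param s Training [SpectraSet-class].
#' @return A context list to pass to [applyTransform()] (or `NULL` when
#'   the transform is stateless).
#' @export
fitTransformContext <- function(name, s) {
    name <- normalizeTransformName(name)
    chain <- .transformRegistry[[name]]$chain
    if (!"msc" %in% chain) return(NULL)
    m <- spectraMatrix(s)
    wl <- wavelengths(s)
    for (op in chain) {
        if (op == "msc") return(list(msc_reference = colMeans(m)))
        m <- .applyPrimitive(op, m, wl)
    }
    NULL
}

#' Apply a registered spectral transform
#'
#' Applies the transform's primitive chain left to right (e.g. `log(1/R)`
#' is reciprocal then log10; `FD-SNV` is first derivative then SNV) and
#' updates the transform tag. Domain violations (log or reciprocal of a
#' non-positive value, `1/logR` at R = 1) fail loudly, reporting the first
#' offending row and wavelength.
#'
#' @param name Transform name (canonical or alias); `"R"` is the identity.
#' @param s A raw [SpectraSet-class].
#' @param context Training statistics from [fitTransformContext()]; used by
#'   MSC-containing chains so held-out leaves are corrected against the
#'   training reference. When `NULL`, MSC fits its reference on `s` itself.
#' @return A transformed [SpectraSet-class] (tag updated; raw-range
#'   validation applies only to tag `"R"`).
#' @examples
#' s <- makeFixture("tiny")$spectra
#' d <- applyTransform("log(1/R)", s)
#' transformTag(d)
#' @export
applyTransform <- function(name, s, context = NULL) {
    name <- normalizeTransformName(name)
    spec <- .transformRegistry[[name]]
    m <- spectraMatrix(s)
    wl <- wavelengths(s)
    for (op in spec$chain)
        m <- .applyPrimitive(op, m, wl, context = context)
    attr(m, "reference") <- NULL
    out <- SpectraSet(m, wl, leafInfo(s), transformTag = spec$label)
    out
}

#' First-derivative spectra
#'
#' Central finite differences over the nm grid at interior bands,
#' one-sided differences at the two endpoints; the grid is unchanged.
#' @param s A [SpectraSet-class] with at least 3 bands.
#' @return The differentiated [SpectraSet-class] (tag `R'`).
#' @export
firstDerivative <- function(s) applyTransform("R1", s)

#' Second-derivative spectra
#' @param s A [SpectraSet-class] with at least 3 bands.
#' @return The twice-differentiated [SpectraSet-class] (tag `R''`).
#' @export
secondDerivative <- function(s) applyTransform("R2", s)

#' Standard normal variate
#'
#' Each spectrum is independently centered to mean 0 and scaled to unit
#' standard deviation (n-1 divisor), removing per-leaf offset and
#' multiplicative scatter.
#' @param s A [SpectraSet-class]; every row must have nonzero variance.
#' @return The normalized [SpectraSet-class] (tag `SNV`).
#' @export
snv <- function(s) applyTransform("SNV", s)

#' Multiplicative scatter correction
#'
#' Each spectrum x is regressed on a reference spectrum by ordinary least
#' squares over wavelengths, x ~ a + b * ref, and corrected to (x - a)/b.
#' The reference defaults to the mean spectrum of `s`; supply the training
#' mean (via `reference` or [fitTransformContext()]) to correct held-out
#' leaves.
#' @param s A [SpectraSet-class] with n >= 2 when `reference` is absent.
#' @param reference Optional per-wavelength reference spectrum.
#' @return The corrected [SpectraSet-class] (tag `MSC`).
#' @export
msc <- function(s, reference = NULL) {
    ctx <- if (!is.null(reference)) list(msc_reference = reference) else NULL
    applyTransform("MSC", s, context = ctx)
}
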