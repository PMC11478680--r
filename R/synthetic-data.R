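## Synthetic leaf-spectra generator.
##
## Emulates the statistical structure of a drought-stress pot study: four
## treatments T1-T4 (T1 most severe) with 25 seedlings each, treatment Tk
## carrying leaf pairs 1..k (position 1 = first pair of top leaves), two
## leaves per pair with an occasional single-leaf lowest pair. Reflectance
## is a smooth leaf-like baseline plus a chlorophyll-controlled green peak
## near 550 nm, a chlorophyll-deepened red absorption well near 670 nm,
## and water-status-controlled absorption troughs (near 1440 and 1920 nm,
## with weak NIR features at 970 and 1200 nm), under additive and
## multiplicative noise.

#' Configuration of the synthetic leaf-spectra generator
#'
#' Slots hold the "truth" parameters of the simulated study. Chlorophyll
#' and water status are drawn per leaf from treatment-by-position normal
#' distributions (plus a shared per-seedling effect); their means are
#' parameterized on 4x4 matrices (rows = treatments T1-T4, columns = pair
#' positions, NA where a treatment lacks a position).
#'
#' Key structural choices, mirrored from the study design the generator
#' emulates: chlorophyll decreases with drought severity and with lower
#' (older) leaf position, so lower positions show a higher green peak;
#' water status decreases likewise, so lower positions reflect more near
#' 1440/1920 nm; and position 1 -- present in all four treatments --
#' receives the largest chlorophyll-spectrum decoupling
#' (`opticalMismatchSd`, plus green-amplitude jitter `positionJitterSd`),
#' making it the most heterogeneous and hardest-to-predict position.
#'
#' The green-peak amplitude is parameterized through
#' `greenResponse = c(y0, y1)` so that, noise off, the green normalized
#' difference (R750 - R550)/(R750 + R550) equals y0 + y1 * C exactly:
#' strictly increasing in chlorophyll, with R550 strictly decreasing.
#'
#' @export
setClass("GeneratorConfig",
    representation(
        nSeedlingsPerTreatment = "integer",
        seed = "integer",
        chlorophyllMean = "matrix",
        chlorophyllSd = "matrix",
        chlorophyllSeedlingSd = "numeric",
        waterMean = "matrix",
        waterSd = "matrix",
        waterSeedlingSd = "numeric",
        singleLeafProb = "numeric",
        greenPeakCenter = "numeric",
        greenPeakWidth = "numeric",
        greenResponse = "numeric",
        redWellCenter = "numeric",
        redWellWidth = "numeric",
        redWellDepth = "numeric",
        waterTroughCenters = "numeric",
        waterTroughWidths = "numeric",
        waterTroughDepths = "numeric",
        minorTroughCenters = "numeric",
        minorTroughWidths = "numeric",
        minorTroughDepths = "numeric",
        noiseAdditiveSd = "numeric",
        noiseMultiplicativeSd = "numeric",
        positionJitterSd = "numeric",
        opticalMismatchSd = "numeric",
        baselineParams = "numeric"))

setValidity("GeneratorConfig", function(object) {
    msg <- character()
    if (object@nSeedlingsPerTreatment < 1L)
        msg <- c(msg, "nSeedlingsPerTreatment must be >= 1")
    for (nm in c("chlorophyllSd", "waterSd"))
        if (any(methods::slot(object, nm) < 0, na.rm = TRUE))
            msg <- c(msg, paste(nm, "entries must be >= 0"))
    if (any(object@chlorophyllMean <= 0, na.rm = TRUE))
        msg <- c(msg, "chlorophyll means must be > 0")
    if (any(object@waterMean < 0 | object@waterMean > 1, na.rm = TRUE))
        msg <- c(msg, "water status means must lie in [0, 1]")
    if (object@singleLeafProb < 0 || object@singleLeafProb > 1)
        msg <- c(msg, "singleLeafProb must lie in [0, 1]")
    if (object@noiseAdditiveSd < 0 || object@noiseMultiplicativeSd < 0)
        msg <- c(msg, "noise sds must be >= 0")
    if (any(object@positionJitterSd < 0))
        msg <- c(msg, "positionJitterSd must be >= 0")
    if (any(object@opticalMismatchSd < 0))
        msg <- c(msg, "opticalMismatchSd must be >= 0")
    for (k in 1:4) for (p in 1:4) {
        has <- !is.na(object@chlorophyllMean[k, p])
        if (has != (p <= k))
            msg <- c(msg, sprintf(
                "chlorophyllMean[T%d, position %d] must be %s", k, p,
                if (p <= k) "set" else "NA (treatment lacks the position)"))
    }
    if (length(msg)) msg else TRUE
})

.positionMatrix <- function(base, treatStep, posStep) {
    m <- matrix(NA_real_, 4, 4,
                dimnames = list(paste0("T", 1:4), paste0("pos", 1:4)))
    for (k in 1:4) for (p in 1:k)
        m[k, p] <- base + treatStep * (k - 1) - posStep * (p - 1)
    m
}

#' Build a generator configuration
#'
#' All arguments default to the emulated study conditions: 25 seedlings per
#' treatment (~478 leaves once ~30% of the lowest pairs carry a single
#' leaf), chlorophyll means rising with watering (T1 -> T4) and falling
#' with leaf position, water status likewise, and noise levels that give a
#' chlorophyll / green-peak correlation magnitude near 0.8.
#'
#' @param nSeedlingsPerTreatment Seedlings per treatment (default 25).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param chlorophyllMean,chlorophyllSd 4x4 treatment-by-position matrices
#'   (mg/g); defaults from a base of 6 mg/g, +5 per watering level, -2.5
#'   per lower position, leaf-level sd 3.0 at position 1 and 2.2 below.
#' @param waterMean,waterSd 4x4 matrices of water status in `[0, 1]`.
#' @param singleLeafProb Probability the lowest pair of a T2-T4 seedling
#'   has a single leaf (default 0.3, matching ~478 of 500 possible leaves).
#' @param noiseAdditiveSd,noiseMultiplicativeSd Additive reflectance noise
#'   sd and sd of the log multiplicative scatter factor.
#' @param positionJitterSd Per-position sd of the green-amplitude jitter.
#' @param opticalMismatchSd Per-position sd (mg/g) of the gap between
#'   assayed chlorophyll and the optically effective chlorophyll at the
#'   measurement spot; largest at position 1 (the position present in all
#'   four treatments), which makes it the hardest-to-predict position.
#' @param greenResponse `c(y0, y1)`: noise-free green normalized
#'   difference as a linear function of chlorophyll.
#' @param ... Remaining spectral-shape slots (`greenPeakCenter`,
#'   `waterTroughCenters`, widths, depths, `baselineParams`); see slots of
#'   [GeneratorConfig-class].
#' @return A validated [GeneratorConfig-class].
#' @export
generatorConfig <- function(nSeedlingsPerTreatment = 25L,
                            seed = 1L,
                            chlorophyllMean = .positionMatrix(6, 5, 2.5),
                            chlorophyllSd = {
                                m <- .positionMatrix(2.6, 0, 0)
                                m[, 1] <- ifelse(is.na(m[, 1]), NA, 3.0)
                                m
                            },
                            waterMean = .positionMatrix(0.62, 0.07, 0.05),
                            waterSd = .positionMatrix(0.08, 0, 0),
                            singleLeafProb = 0.3,
                            noiseAdditiveSd = 0.003,
                            noiseMultiplicativeSd = 0.02,
                            positionJitterSd = c(0.15, 0.08, 0.08, 0.08),
                            opticalMismatchSd = c(2.8, 0.7, 0.7, 0.7),
                            greenResponse = c(0.13, 0.019),
                            ...) {
    dots <- list(...)
    defaults <- list(
        chlorophyllSeedlingSd = 1.0,
        waterSeedlingSd = 0.03,
        greenPeakCenter = 550, greenPeakWidth = 22,
        redWellCenter = 670, redWellWidth = 35,
        redWellDepth = c(0.02, 0.0008),
        waterTroughCenters = c(1440, 1920),
        waterTroughWidths = c(40, 50),
        waterTroughDepths = c(0.22, 0.18),
        minorTroughCenters = c(970, 1200),
        minorTroughWidths = c(35, 45),
        minorTroughDepths = c(0.03, 0.05),
        baselineParams = c(visible = 0.05, nirAmplitude = 0.40,
                           redEdgeCenter = 715, redEdgeWidth = 18,
                           swirDrop = 0.12, swirCenter = 1800,
                           swirWidth = 250))
    for (nm in names(defaults))
        if (is.null(dots[[nm]])) dots[[nm]] <- defaults[[nm]]
    args <- c(list("GeneratorConfig",
        nSeedlingsPerTreatment = as.integer(nSeedlingsPerTreatment),
        seed = as.integer(seed),
        chlorophyllMean = chlorophyllMean, chlorophyllSd = chlorophyllSd,
        waterMean = waterMean, waterSd = waterSd,
        singleLeafProb = singleLeafProb,
        noiseAdditiveSd = noiseAdditiveSd,
        noiseMultiplicativeSd = noiseMultiplicativeSd,
        positionJitterSd = positionJitterSd,
        opticalMismatchSd = opticalMismatchSd,
        greenResponse = greenResponse), dots)
    do.call(methods::new, args)
}

.baseline <- function(wl, p) {
    p["visible"] +
        p["nirAmplitude"] * stats::plogis((wl - p["redEdgeCenter"]) /
                                          p["redEdgeWidth"]) -
        p["swirDrop"] * stats::plogis((wl - p["swirCenter"]) /
                                      p["swirWidth"])
}

.gauss <- function(wl, center, width) exp(-(wl - center)^2 / (2 * width^2))

## Green-peak amplitude: chosen so (R750 - R550)/(R750 + R550) = y0 + y1*C
## noise-free (B750 taken as the baseline value at 750 nm).
.greenAmplitude <- function(C, cfg) {
    bp <- cfg@baselineParams
    b750 <- .baseline(750, bp)
    b550 <- .baseline(cfg@greenPeakCenter, bp)
    y <- pmin(pmax(cfg@greenResponse[1] + cfg@greenResponse[2] * C, 0.02),
              0.95)
    unname(b750 * (1 - y) / (1 + y) - b550)
}

#' Noise-free synthetic leaf spectrum
#'
#' Deterministic reflectance curve for given true chlorophyll and water
#' status -- the generator's mean model, exposed for monotonicity checks
#' and illustration.
#'
#' @param wl Wavelength grid (nm).
#' @param chlorophyll True chlorophyll content (mg/g), scalar.
#' @param water True water status in `[0, 1]`, scalar.
#' @param cfg A [GeneratorConfig-class].
#' @return Numeric reflectance vector over `wl`, clipped to (0.001, 0.999).
#' @export
syntheticSpectrum <- function(wl, chlorophyll, water,
                              cfg = generatorConfig()) {
    bp <- cfg@baselineParams
    r <- .baseline(wl, bp) +
        .greenAmplitude(chlorophyll, cfg) *
            .gauss(wl, cfg@greenPeakCenter, cfg@greenPeakWidth) -
        (cfg@redWellDepth[1] + cfg@redWellDepth[2] * chlorophyll) *
            .gauss(wl, cfg@redWellCenter, cfg@redWellWidth)
    wf <- 0.15 + 0.85 * water
    for (j in seq_along(cfg@waterTroughCenters))
        r <- r - cfg@waterTroughDepths[j] * wf *
            .gauss(wl, cfg@waterTroughCenters[j], cfg@waterTroughWidths[j])
    for (j in seq_along(cfg@minorTroughCenters))
        r <- r - cfg@minorTroughDepths[j] * wf *
            .gauss(wl, cfg@minorTroughCenters[j], cfg@minorTroughWidths[j])
    pmin(pmax(unname(r), 0.001), 0.999)
}

.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Generate a synthetic drought-study dataset
#'
#' Draws per-leaf true chlorophyll and water status from the configured
#' treatment-by-position distributions, renders each leaf's reflectance
#' spectrum (baseline + chlorophyll-controlled green peak and red well -
#' water-controlled absorption troughs, under multiplicative and additive
#' noise), and returns the spectra with an aligned truth table. The truth
#' table also carries extract absorbances (A646, A663, at a 1.6 A663/A646
#' ratio) consistent with each leaf's chlorophyll through the
#' spectrophotometric assay arithmetic ([chlorophyllTotal()], V = 25 mL,
#' M = 0.2 g).
#'
#' Deterministic given `cfg@seed`; the caller's RNG state is untouched.
#'
#' @param cfg A [GeneratorConfig-class].
#' @param grid Wavelength grid in nm (default 350-2500 at 1 nm).
#' @return A list with `spectra` (a raw [SpectraSet-class]) and `truth`
#'   (data.frame: leaf_id, seedling_id, treatment, pair_position,
#'   leaf_side, chlorophyll, water, A646, A663), aligned row for row.
#' @examples
#' d <- generateDataset(generatorConfig(nSeedlingsPerTreatment = 2L))
#' nLeaves(d$spectra)
#' @export
generateDataset <- function(cfg = generatorConfig(),
                            grid = wavelengthGrid()) {
    methods::validObject(cfg)
    .withSeed(cfg@seed, {
        rows <- list()
        for (k in 1:4) {
            for (sdl in seq_len(cfg@nSeedlingsPerTreatment)) {
                sid <- sprintf("T%d_s%02d", k, sdl)
                chlEff <- stats::rnorm(1, 0, cfg@chlorophyllSeedlingSd)
                watEff <- stats::rnorm(1, 0, cfg@waterSeedlingSd)
                for (p in seq_len(k)) {
                    nlv <- 2L
                    if (p == k && k > 1L &&
                        stats::runif(1) < cfg@singleLeafProb)
                        nlv <- 1L
                    for (side in seq_len(nlv)) {
                        C <- max(stats::rnorm(
                            1, cfg@chlorophyllMean[k, p] + chlEff,
                            cfg@chlorophyllSd[k, p]), 0.5)
                        W <- min(max(stats::rnorm(
                            1, cfg@waterMean[k, p] + watEff,
                            cfg@waterSd[k, p]), 0.02), 1)
                        rows[[length(rows) + 1L]] <- list(
                            seedling_id = sid, treatment = paste0("T", k),
                            pair_position = p, leaf_side = side,
                            chlorophyll = C, water = W,
                            jitter = stats::rnorm(
                                1, 0, cfg@positionJitterSd[p]),
                            optDelta = stats::rnorm(
                                1, 0, cfg@opticalMismatchSd[p]))
                    }
                }
            }
        }
        n <- length(rows)
        truth <- data.frame(
            leaf_id = sprintf("leaf%03d", seq_len(n)),
            seedling_id = vapply(rows, `[[`, "", "seedling_id"),
            treatment = vapply(rows, `[[`, "", "treatment"),
            pair_position = vapply(rows, function(r)
                as.integer(r$pair_position), 1L),
            leaf_side = vapply(rows, function(r)
                as.integer(r$leaf_side), 1L),
            chlorophyll = vapply(rows, `[[`, 1, "chlorophyll"),
            water = vapply(rows, `[[`, 1, "water"))

        bp <- cfg@baselineParams
        base <- .baseline(grid, bp)
        bumpG <- .gauss(grid, cfg@greenPeakCenter, cfg@greenPeakWidth)
        bumpR <- .gauss(grid, cfg@redWellCenter, cfg@redWellWidth)
        ## optically effective chlorophyll at the measurement spot: the
        ## assayed value plus a per-leaf mismatch, largest at position 1
        cOpt <- pmax(truth$chlorophyll +
                     vapply(rows, `[[`, 1, "optDelta"), 0.3)
        g <- .greenAmplitude(cOpt, cfg) *
            (1 + vapply(rows, `[[`, 1, "jitter"))
        dr <- cfg@redWellDepth[1] + cfg@redWellDepth[2] * cOpt
        wf <- 0.15 + 0.85 * truth$water
        refl <- matrix(rep(base, each = n), nrow = n) +
            outer(g, bumpG) - outer(dr, bumpR)
        for (j in seq_along(cfg@waterTroughCenters))
            refl <- refl - outer(cfg@waterTroughDepths[j] * wf,
                .gauss(grid, cfg@waterTroughCenters[j],
                       cfg@waterTroughWidths[j]))
        for (j in seq_along(cfg@minorTroughCenters))
            refl <- refl - outer(cfg@minorTroughDepths[j] * wf,
                .gauss(grid, cfg@minorTroughCenters[j],
                       cfg@minorTroughWidths[j]))
        m <- exp(stats::rnorm(n, 0, cfg@noiseMultiplicativeSd))
        eps <- matrix(stats::rnorm(n * length(grid), 0,
                                   cfg@noiseAdditiveSd), nrow = n)
        refl <- pmin(pmax(refl * m + eps, 0.001), 0.999)

        ## assay-consistent extract absorbances (A663 = 1.6 * A646)
        truth$A646 <- truth$chlorophyll * 1000 * 0.2 /
            (25 * (17.32 + 7.18 * 1.6))
        truth$A663 <- 1.6 * truth$A646

        md <- truth[, c("seedling_id", "treatment", "pair_position",
                        "leaf_side", "chlorophyll")]
        rownames(md) <- truth$leaf_id
        list(spectra = SpectraSet(refl, grid, md, transformTag = "R"),
             truth = truth)
    })
}

.fixtureCache <- new.env(parent = emptyenv())

#' Canonical synthetic fixtures
#'
#' `"tiny"`: 4 seedlings per treatment on a coarsened 350-2500 nm, 5 nm
#' grid (431 bands, <= 80 leaves) for fast tests; `"study"`: 25 seedlings
#' per treatment on the full 1 nm grid, reproducing the emulated study
#' scale (~478 leaves). Internal seeds are fixed, so fixtures are
#' reproducible across sessions; results are cached within a session.
#'
#' @param size `"tiny"` or `"study"`.
#' @return A list with `spectra` and `truth`, as [generateDataset()].
#' @export
makeFixture <- function(size = c("tiny", "study")) {
    size <- match.arg(size)
    if (!is.null(.fixtureCache[[size]])) return(.fixtureCache[[size]])
    out <- switch(size,
        tiny = generateDataset(
            generatorConfig(nSeedlingsPerTreatment = 4L, seed = 1003L),
            grid = wavelengthGrid(350, 2500, 5)),
        study = generateDataset(
            generatorConfig(nSeedlingsPerTreatment = 25L, seed = 1004L),
            grid = wavelengthGrid(350, 2500, 1)))
    .fixtureCache[[size]] <- out
    out
}
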