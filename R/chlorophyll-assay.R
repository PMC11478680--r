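## Acetone-extract spectrophotometric chlorophyll assay (80% acetone,
## absorbances read at 663 and 646 nm).

#' Chlorophyll a concentration from extract absorbances
#'
#' Ca = 12.21 * A663 - 2.81 * A646, in mg/L of extract.
#'
#' @param A663,A646 Absorbances at 663 and 646 nm (unitless, >= 0).
#' @return Chlorophyll a concentration (mg/L). A negative result (possible
#'   for physically implausible input) triggers a warning but is returned.
#' @examples
#' chlorophyllA(0.8, 0.5)  # 8.363
#' @export
chlorophyllA <- function(A663, A646) {
    stopifnot(all(A663 >= 0), all(A646 >= 0))
    ca <- 12.21 * A663 - 2.81 * A646
    if (any(ca < 0))
        warning("negative chlorophyll a concentration; check absorbances")
    ca
}

#' Chlorophyll b concentration from extract absorbances
#'
#' Cb = 20.13 * A646 - 5.03 * A663, in mg/L of extract.
#'
#' @inheritParams chlorophyllA
#' @return Chlorophyll b concentration (mg/L), with the same
#'   negative-result warning behavior as [chlorophyllA()].
#' @examples
#' chlorophyllB(0.8, 0.5)  # 6.041
#' @export
chlorophyllB <- function(A663, A646) {
    stopifnot(all(A663 >= 0), all(A646 >= 0))
    cb <- 20.13 * A646 - 5.03 * A663
    if (any(cb < 0))
        warning("negative chlorophyll b concentration; check absorbances")
    cb
}

#' Total chlorophyll content per gram of fresh leaf
#'
#' C = V * (Ca + Cb) / (1000 * M), identically
#' V * (17.32 * A646 + 7.18 * A663) / (1000 * M), with V the extraction
#' volume in mL and M the fresh leaf mass in grams. Note the combined
#' coefficients are exactly the sums of the a/b equations
#' (12.21 - 5.03 = 7.18 on A663; 20.13 - 2.81 = 17.32 on A646).
#'
#' M is taken in grams: a typical assay uses a 0.2 g aliquot brought to
#' 25 mL, and gram units make the output dimensionally consistent with
#' leaf chlorophyll contents of a few mg/g.
#'
#' @inheritParams chlorophyllA
#' @param V Extraction solution volume (mL, > 0).
#' @param M Fresh leaf mass (g, > 0).
#' @return Chlorophyll content (mg/g fresh mass).
#' @examples
#' chlorophyllTotal(A663 = 0.8, A646 = 0.5, V = 25, M = 0.2)  # 1.8005
#' @export
chlorophyllTotal <- function(A663, A646, V = 25, M = 0.2) {
    if (any(V <= 0)) stop("extraction volume V must be > 0")
    if (any(M <= 0)) stop("fresh leaf mass M must be > 0")
    stopifnot(all(A663 >= 0), all(A646 >= 0))
    V * (17.32 * A646 + 7.18 * A663) / (1000 * M)
}
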