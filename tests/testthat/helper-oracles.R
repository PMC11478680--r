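# Independent oracles, coded from first principles and kept separate from
# the implementation paths they check.

# textbook Pearson correlation
oraclePearson <- function(x, y) {
    mx <- sum(x) / length(x)
    my <- sum(y) / length(y)
    sum((x - mx) * (y - my)) /
        sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# difference-quotient derivative: central interior, one-sided ends
oracleDeriv1 <- function(row, step) {
    p <- length(row)
    out <- numeric(p)
    for (i in seq_len(p)) {
        out[i] <- if (i == 1) (row[2] - row[1]) / step
        else if (i == p) (row[p] - row[p - 1]) / step
        else (row[i + 1] - row[i - 1]) / (2 * step)
    }
    out
}

# normal-equations least squares: returns c(intercept, slopes)
oracleOLS <- function(X, y) {
    Xb <- cbind(1, as.matrix(X))
    as.numeric(solve(t(Xb) %*% Xb, t(Xb) %*% y))
}

# brute-force "evaluate all bands, sort by |r|, take k" selection
oracleTopK <- function(wl, r, k) {
    ord <- order(-abs(r), wl)
    wl[ord][seq_len(k)]
}

# small random raw SpectraSet for I/O and transform tests
randomSpectraSet <- function(n = 5, wl = wavelengthGrid(500, 595, 5),
                             seed = 42) {
    set.seed(seed)
    m <- matrix(runif(n * length(wl), 0.05, 0.6), nrow = n)
    md <- data.frame(
        seedling_id = paste0("s", rep(seq_len(max(1, n)), length.out = n)),
        treatment = "T4",
        pair_position = rep(1:2, length.out = n),
        leaf_side = 1L,
        chlorophyll = runif(n, 5, 20))
    SpectraSet(m, wl, md)
}

# correlation profile with a smooth |r| peak plus window structure
randomProfile <- function(seed, wl = seq(350, 2500, by = 10)) {
    set.seed(seed)
    r <- 0.8 * exp(-(wl - sample(400:2400, 1))^2 / (2 * 150^2)) +
        rnorm(length(wl), 0, 0.05)
    data.frame(wavelength = wl, r = pmax(pmin(r, 1), -1))
}
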