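---
title: "Methods: chlorophyll inversion from leaf reflectance"
author: "chlorospectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chlorophyll inversion from leaf reflectance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chlorospectra)
```

## The model

The package estimates leaf chlorophyll content $C$ (mg/g fresh mass)
from reflectance spectra $R_\lambda$ on a uniform 350–2500 nm grid
(1 nm by default, 2151 bands) using a linear regression fitted by
partial least squares,

$$ \hat C = a_0 + \sum_{i=1}^{n} a_i x_i, $$

where the predictors $x_i$ are, depending on the strategy: all
(transformed) bands (AB), Kaiser-rule principal component scores (PCA),
the ten most chlorophyll-correlated bands (CA), six such bands plus two
from each of two water-absorption windows (CA(W)), or vegetation-index
values (VI / single-index least squares). The physical premises are the
standard ones for leaf optics: chlorophyll absorption darkens the green
reflectance peak near 550 nm (so $R_{550}$ decreases with $C$), and leaf
water deepens the absorption troughs near 1440 and 1920 nm. Under
drought, chlorophyll and water decline together, which is why
water-sensitive bands — though nearly uncorrelated with chlorophyll in
well-watered plants — can add predictive value here.

PLS1 is fitted by NIPALS on centered data. With a univariate response
each component has a closed form ($w = X^\top y$ normalized, $t = Xw$,
then rank-one deflation), and the latent-space model is folded back into
the $a_0 + \sum a_i x_i$ form exactly, so prediction is a single dot
product. With as many components as the predictor rank, PLS1 reproduces
ordinary least squares; the test suite asserts both this and agreement
with an independent PLS implementation (mixOmics).

## Preprocessing registry

Twenty-one transforms are registered: identity (R); first and second
derivatives (R′, R″); √R, logR, 1/R, log(1/R), log√R, 1/logR, √(1/R);
the first derivative of each of those seven; SNV; MSC; and the
derivative-first composites FD-SNV and FD-MSC. Choices the notation
leaves open were resolved as follows.

* **Derivatives** use central finite differences over the nm grid at
  interior bands and one-sided differences at the two endpoints — no
  smoothing filter, as none is implied by the plain "first derivation".
* **Logarithms** are base 10, the chemometric absorbance convention for
  log(1/R). PLS predictions are invariant to the base (a global
  scaling), so this cannot change any model comparison; the identities
  log(1/R) = −logR and log√R = ½·logR make those three transforms one
  model in three notations, and the suite asserts their cross-validation
  metrics agree to ≤ 1e−8.
* **Composites** FD-SNV / FD-MSC are derivative-first (SNV/MSC applied
  to the first derivative), the common chemometric usage.
* **MSC** regresses each spectrum on a reference by least squares and
  inverts the fitted offset/slope. The reference is the mean spectrum of
  the *training* leaves; `fitTransformContext()` carries it into any
  held-out application, so resampling never leaks test information.
* **Degenerate inputs** (log or reciprocal of a non-positive value,
  1/logR at R = 1, zero-variance rows under SNV) raise errors naming the
  offending row and wavelength rather than imputing.

## Band selection

Pearson correlations between each band and chlorophyll are computed on
training data only in any resampling context. `selectTopK()` ranks by
|r| with exact ties broken by ascending wavelength — deterministic and
data-independent. `selectWithWater()` runs two rounds: six bands over
the whole grid, then the two strongest bands inside each of 1390–1490 nm
and 1870–1970 nm. If a window band already won a main-round seat it
keeps its "main" provenance and the window takes its next-best band, so
the selection size is always fixed (6 + 2 + 2); this dedup-and-backfill
rule matters only when the global |r| maximum falls inside a window,
which the intended data never produce, but the invariant "ten bands,
exactly four window-tagged" is guaranteed unconditionally.

PCA reduction standardizes bands (correlation-matrix PCA) because the
eigenvalue > 1 retention rule is only meaningful on that scale; the
training centering/scaling and rotation are stored and held-out spectra
are projected, never refit. Retained components never exceed
min(n − 1, p); if no eigenvalue exceeds 1 (near-spherical data) one
component is kept so a model always exists.

## Cross-validation and hold-out design

* **Folds are grouped by seedling** (all leaves of a seedling share a
  fold): the two leaves of a pair are near-duplicates, and splitting
  them would leak.
* **R²** is 1 − SS\_res/SS\_tot on *pooled* out-of-fold predictions,
  not a mean of per-fold R² — stable with small folds.
* **Latent-variable count** is chosen per training fold by an inner
  5-fold CV minimizing RMSE with the one-standard-error parsimony rule
  (the smallest count within one SE of the minimum), capped at
  min(20, p, n − 2). On pure-noise responses this collapses to one
  latent variable.
* **Hold-out**: 20% of seedlings per treatment (stratified, seeded), so
  every leaf position is represented in the test set; `runStrategy()`
  errors if position 1 is absent. Per-position metrics flag groups with
  fewer than five test leaves as `low_n` rather than dropping them.
* **Optimal-model ranking** is by hold-out R² at pair position 1 (the
  bottleneck subgroup), with ties within 1e−6 broken by the smallest
  per-position R² range. The full criterion trace is returned so the
  decision is auditable.

## Vegetation indices

The 14 registered indices use raw reflectance at named wavelengths; on
coarsened grids a named band resolves to the nearest grid band. One
formula is genuinely ambiguous in the common notation: TVI. The default
is the literal reading 60(R750 − R500) − 100(R670 − R500); the canonical
triangular form 0.5·[120(R750 − R550) − 200(R670 − R550)] is available
via `tviForm = "canonical"`. Normalized-difference indices are bounded
in [−1, 1] and all ratio/ND indices are invariant to a global reflectance
scaling; TVI scales linearly (so both readings vanish on a flat
spectrum).

## The published ten-band equation

`publishedCAWModel()` carries the fixed ten-band regression (six
green-peak bands 547–552 nm, four water bands 1464, 1465, 1933,
1944 nm; intercept 2.1754). Whether its $R_\lambda$ symbols denote raw
reflectance or log(1/R)-transformed values is not decidable from the
source text: the model is described as fitted on log(1/R) spectra but
written in reflectance symbols. Both readings are implemented
(`inputTransform = "log_invR"`, the default, or `"R"`); neither is
asserted as the original intent, and the arithmetic checks (intercept at
zero input, coefficient sum at unit input) are transform-independent.

## The chlorophyll assay

The spectrophotometric arithmetic is
$C_a = 12.21A_{663} - 2.81A_{646}$,
$C_b = 20.13A_{646} - 5.03A_{663}$,
$C = V(C_a + C_b)/(1000M) = V(17.32A_{646} + 7.18A_{663})/(1000M)$.
The combined coefficients are exactly the sums of the a/b equations. `M`
is taken in **grams** (a 0.2 g aliquot in 25 mL is typical): with M in
mg the output would be three orders of magnitude below plausible leaf
chlorophyll contents, so gram units are the dimensionally consistent
reading. `M` and `V` remain explicit arguments, so any aliquot
convention is expressible.

## The synthetic generator

The study whose design the generator emulates did not deposit its raw
spectra, so every downstream stage is exercised on synthetic data with
the same statistical structure: four drought treatments (T1 severest) of
25 seedlings; treatment Tk carries leaf pairs 1..k, two leaves per pair
with a 30% chance of a single leaf in the lowest pair of T2–T4, giving
~478 leaves out of 500 possible.

Reflectance is
$$ R(\lambda) = \mathrm{clip}\big( m\,[\,b(\lambda)
   + g(C_\mathrm{opt})\,G_{550}(\lambda)
   - d_r(C_\mathrm{opt})\,G_{670}(\lambda)
   - h(W)\sum_j D_j G_{c_j}(\lambda)\,] + \varepsilon(\lambda),\;
   0.001, 0.999\big), $$

with $b$ a fixed piecewise-smooth leaf-like baseline (visible ≈ 0.05,
red-edge sigmoid at 715 nm rising to a NIR plateau ≈ 0.45, mild SWIR
decline), Gaussian features $G$ (green peak at 550 nm, width 22 nm; red
absorption well at 670 nm; water troughs at 1440/1920 nm with weak NIR
features at 970/1200 nm), multiplicative scatter $m = e^{N(0, 0.02)}$
and additive noise $\varepsilon \sim N(0, 0.003)$ per band — included
specifically so SNV and MSC have exactly the effects they are built to
correct. $h(W) = 0.15 + 0.85W$ makes troughs shallower as water status
$W$ falls, so drier leaves reflect *more* at 1440/1920 nm, as lower
(older) leaf positions do.

The green amplitude is parameterized so that, noise off, the green
normalized difference (R750 − R550)/(R750 + R550) equals
$0.13 + 0.019\,C$ exactly — strictly increasing in chlorophyll, with
$R_{550}$ strictly decreasing; this makes the monotone-response
invariants exact and single-index linear models near-perfect on
noise-free draws.

Truth parameters follow the design: chlorophyll means 6 mg/g at the top
pair of T1, +5 per watering level, −2.5 per lower position (leaf sd
3.0 at position 1, 2.6 below, plus a 1.0 seedling effect); water-status
means 0.62 (T1, position 1) rising 0.07 per watering level and falling
0.05 per position. Two per-position decoupling terms make position 1 —
the only position present in all four treatments — the hardest
subgroup, as the emulated study found: the spectrum is rendered from an
*optically effective* chlorophyll $C_\mathrm{opt} = C + N(0, 2.8)$ mg/g
at position 1 (0.7 below), and the green amplitude carries relative
jitter of sd 0.15 at position 1 (0.08 below). These defaults were chosen
once to reproduce the planted structure — a chlorophyll/green-peak
correlation magnitude near 0.8–0.9, cross-validated R² near 0.8, and a
position-1 accuracy deficit — and are not tuned per analysis.

What the generator does **not** emulate: radiative transfer (no
PROSPECT-style physics), band-correlated instrument noise, detector
splice artifacts, red-edge position shifts with chlorophyll, or
physically calibrated water-index responses (the 970/1200 nm features
are weak, so WI/WBI/NDWI/MSI carry little signal). Passing tests
therefore demonstrate that the *pipeline* is correct and leak-free and
that it recovers planted structure of realistic strength — not that any
particular accuracy level will transfer to real leaves.

## Problem sizes and runtime choices

Tests run on two fixed-seed fixtures: `tiny` (4 seedlings/treatment,
5 nm grid → 431 bands, ≤ 80 leaves) for unit and equivalence tests, and
`study` (25 seedlings/treatment, full 1 nm grid, ~478 leaves — the
emulated modeling scale) for parameter-recovery and bottleneck checks.
Fixtures are generated in code at run time and cached per session;
nothing is stored on disk.

## Known limitations

* The transform registry is fixed at the 21 named recipes; it is
  extensible in code but deliberately does not invent further chains.
* `selectWithWater()` assumes the windows exist on the grid and hold at
  least as many bands as requested per window.
* PLS1 only (univariate response); no PLS2, kernel or sparse variants.
* The hold-out split is by seedling within treatment; other grouping
  structures (e.g. by pot bench) would need a custom split.
* Noisy instrument edge bands (near 350 or 2500 nm) are kept: no
  silent trimming is applied. When trimming is wanted, subset the
  `SpectraSet` by band index (`s[bandIndex(s, 400):bandIndex(s, 2400), ]`)
  before modeling.
* Correlation profiles computed on a full dataset are for reporting;
  inside any resampling loop the package recomputes them on training
  data, and only those selections should be interpreted as honest.
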