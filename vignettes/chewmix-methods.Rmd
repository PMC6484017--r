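---
title: "Methods: colour-mixing quantification and repeated-measures analysis of the two-coloured chewing-gum test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colour-mixing quantification and repeated-measures analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

The two-coloured chewing-gum mixing test quantifies masticatory performance
(MP): a subject chews a specimen made of one red and one green gum strip for a
fixed number of strokes, the bolus is pressed into a thin wafer, and both
sides are scanned.  The better the subject chews, the more thoroughly the two
dyes blend.  `chewmix` implements the computational half of that protocol:
isolating the bolus in the scan, scoring its colour mixture, and running the
longitudinal statistical analysis used to study how habitual gum consumption
and a prescribed increase in consumption affect the score.

## Bolus segmentation

Segmentation is a five-step colour-based procedure, a pure function of the
image and its configuration:

1. Convert the sRGB image to CIE L\*a\*b\* (D65).  The transform is the
   standard one (piecewise sRGB transfer function, sRGB/D65 primaries matrix,
   CIE cube-root lightness); we implement it directly because Euclidean
   distances in Lab drive everything downstream and the package-level tests
   pin the transform to reference values of the CIE standard at 3--4 decimals.
2. Run joint spatial--range mean-shift filtering (flat kernel) and merge
   4-connected pixels whose converged modes differ by less than half the range
   bandwidth into superpixels.  The superpixels containing the four image
   corners are background by construction of the scanning protocol; the
   background colour `bg` is the unweighted mean of their mean Lab colours.
   If a corner ever fell inside a bolus-coloured cluster the estimate would
   degrade gracefully rather than being special-cased.
3. Form the distance map `d_i = log(||x_i - bg|| + eps)`.  The logarithm
   compresses the large, heterogeneous distances inside the bolus while
   preserving the homogeneity of the near-zero background distances.
4. Split the scalar distance map into two clusters with k-means (k = 2) and
   take as bolus the cluster whose members lie closer, on average, to the
   image centre.
5. Keep the largest connected component, fill interior holes, and extract the
   bolus RGB pixels from the original image.

Numerical choices worth stating:

* **Stabilized logarithm.** The log of a zero distance is undefined, and
  background pixels can match `bg` exactly.  `d = log(||.|| + eps)` with
  `eps = 1e-6` keeps the map finite and preserves ordering.  The base of the
  logarithm is immaterial (it rescales the k-means input uniformly); the
  natural log is used.
* **Deterministic k-means.** The two centroids are initialized at the 10th
  and 90th percentiles of the distance map.  This removes the seed dependence
  of a nominally stochastic step, so repeated runs over the same batch are
  byte-identical — the package's systematic-error check (a paired t-test
  between two consecutive runs) returns p = 1 structurally, and the test
  suite asserts it.
* **Centre selection, tie-break.** "The cluster located in the centre" is
  operationalized as the smaller mean member distance to the geometric image
  centre; exact ties go to the smaller cluster, since a bolus occupies far
  less area than the scanner background.
* **Degenerate images.** A constant distance map, or two k-means centres
  closer than `min_separation` (1 log unit), means there is no
  foreground/background contrast — e.g. a blank scan — and segmentation
  stops with an explicit error instead of returning an arbitrary mask.
* **Bandwidths.** Mean-shift defaults are `spatial_bw = 8` px and
  `range_bw = 8` Lab units, exposed in `segment_config()`.  They give
  superpixels comfortably larger than dye patches while keeping the uniform
  background in one cluster.  Because the original study does not report its
  bandwidths or k-means initialization, per-pixel equality with any
  particular historical mask is not claimable — the package asserts
  property-level equivalence instead (overlap with ground truth,
  determinism, centre selection invariances).

## The VhH statistic

The MP score is the Variance of the Histogram of the Hue channel (VhH).
Bolus pixels are mapped to the HSI hue angle (red at 0°, green at 120°);
pixels whose channel spread is below `chroma_threshold` (8 of 255 by default)
are excluded, because hue is numerically unstable near the grey axis.  Hues
are binned into `B = 256` equal-width bins over [0°, 360°) — the 8-bit hue
convention, with no circular pooling — and

$$VhH = \frac{1}{B}\sum_{k}\left(c_k - \frac{n}{B}\right)^2$$

is the population variance of the bin-count vector.  "Variance of the
histogram" is read as the variance of the *counts*, not of the hue values:
a fully mixed bolus concentrates its `n` pixels in one hue band, which
maximizes the count variance, so better mixing scores higher, and for
10^5-pixel boluses the statistic sits at the 10^7 scale reported in clinical
applications of the method.  The statistic scales as the square of the pixel
count and is not normalized by bolus size; both facts are asserted in tests.

A sample is scanned on two sides; the package pools the bolus pixels of both
sides into one histogram for a single measurement (per-side values are kept
as diagnostics).  Pooling uses every pixel symmetrically and yields one MP
value per sample, the grain at which the statistics operate.

## The synthetic-data generator

Because absolute VhH values from re-rendered images cannot be compared to any
archived numbers (bin counts, achromatic handling and side aggregation are
conventions of this implementation), the generator exists to give the
pipeline inputs with *known* ground truth.

**Wafer images.** A circular bolus on a light-grey background (200,200,200),
default 160x160 px with radius 52 px.  The bolus is tiled into
`patch_scale_px = 12` px grid cells with a random global offset; each cell
draws one of the two dye hues (0° and 120°) with probability one half —
patch-based rather than pixel-i.i.d., because real unmixed boluses show
spatially coherent colour regions.  The mixing degree `m` moves both hues
along the shorter circular arc towards their midpoint (red and green blend
through yellow), and a per-patch hue jitter with standard deviation
`12(1 - m)` degrees shrinks as mixing completes.  The jitter term is what
makes VhH strictly monotone in `m`: with fixed-width hue clumps, the
transition from two clumps to one necessarily dips in the middle (the sum of
squared mixture weights is convex), whereas tone heterogeneity that dies out
with mixing — which is also what chewed boluses do — lifts the curve
monotonically.  Saturation and intensity are fixed (0.7 and 0.4, keeping the
dominant channel below clipping); i.i.d. Gaussian noise (SD 4 on the 8-bit
scale) is added per channel.  The renderer returns the exact bolus footprint
as a ground-truth mask, and identical specs with identical seeds render
byte-identical images.

The generator does **not** simulate press-thickness variation, scanner
optics, specular highlights, shadows, or gum sticking to the plastic sheets.
Passing segmentation tests on these images therefore demonstrates the
algorithm's behaviour under controlled contrast and noise, not robustness to
every artefact of physical scans.

**Cohorts.** A synthetic cohort draws, per subject, an age group (four
groups with marginal probabilities 71/53/70/71 out of 265, uniform integer
ages within group), sex (male probability 143/265), dental status and
consumption group (CGC) conditional on age group.  The CGC-given-age table
defaults to the strongly age-graded profile of the clinical sample the
analysis is designed around — essentially no high consumers among the oldest
group — and is tunable, e.g. flattened to test the eta-squared association
under the null.  VhH follows the additive model

$$vhh_{is} = \beta_0 + \beta_c(cgc_i) + \beta_s(s) + \beta_{age}\,age_i + b_i + \varepsilon_{is}$$

with defaults `beta_0 = 2.0e7` VhH units, session effects (8.5e5, 9.4e5) for
sessions 2 and 3, consumption effects (2.0e6, 3.2e6) for CGC 1 and 2, an age
slope of -4.5e4 per year, subject SD 1.2e6 and residual SD 8e5.  These values
place the simulated cell means, spreads and effect sizes at the scale of the
published descriptive tables for this design, and they keep every simulated
VhH positive.  The model is exactly the marginal structure the GEE estimates
and a compound-symmetric case of the mixed-ANOVA machinery; it contains no
CGC-by-session interaction, so interaction-specific behaviour is exercised
with explicitly constructed covariance structures instead.

## The statistical battery

All analyses operate on a long cohort table (three rows per subject).  The
battery mirrors the published analysis plan for this design:

* **Systematic error**: paired t-test between two runs over the same batch.
  Two degenerate cases are defined: all differences exactly zero gives
  t = 0, p = 1; constant non-zero differences are flagged with p = 0.
* **Normality**: Kolmogorov--Smirnov with the Lilliefors
  estimated-parameter correction (the default behaviour of the reference
  software's normality output) plus Shapiro--Wilk, per CGC-by-session group
  and pooled.  Groups below the Lilliefors minimum (n = 5) are skipped with
  a warning.
* **Age--CGC association**: eta-squared, `SS_between / SS_total`, age by
  consumption group with one row per subject.
* **Sphericity**: Mauchly's W from the pooled within-group covariance of the
  orthonormalized session contrasts (the pooled, between-design-aware
  convention of GLM repeated-measures software), with the chi-squared
  approximation on error degrees of freedom `N - g`.  Greenhouse--Geisser
  epsilon comes from the same matrix; Huynh--Feldt uses the original 1976
  split-plot estimator `(N(k-1)e - 2) / ((k-1)(N - g - (k-1)e))`, capped at
  1.  (Some modern implementations substitute the Lecoutre-corrected
  variant; the package's dual-route test pins W, GG and the sums of squares
  against an independent multivariate-GLM computation and checks HF against
  the closed form.)
* **Mixed ANOVA**: 3x3 split plot, SESSION within, CGC between, Type III
  (unweighted cell-mean) hypotheses so unequal group sizes are handled as the
  reference software handles them.  When Mauchly rejects at 0.05, the
  within-subject degrees of freedom are multiplied by the Huynh--Feldt
  epsilon if GG epsilon exceeds 0.75 and by the GG epsilon otherwise; the
  report records which correction fired.  Partial eta-squared accompanies
  every effect.
* **Bonferroni session comparisons**: estimated marginal means (unweighted
  across CGC cells, the EMM convention consistent with the Type III model),
  standard errors from the pooled within-group session covariance on
  `N - g` degrees of freedom, p-values multiplied by the number of pairs and
  capped at 1.  Whether the original analysis used pooled or per-stratum
  error terms is not documented; the pooled EMM-based choice is asserted
  only against the package's own closed forms and generative contrasts.
* **Levene, Welch, Games--Howell**: variance homogeneity (classic
  mean-centred Levene), then the heteroscedasticity-robust one-way battery
  with CGC as the factor.  These operate on all measurement rows (three per
  subject), not per-subject means: the published denominator degrees of
  freedom for this design are only attainable at that grain.  This pooling
  ignores the within-subject correlation and is therefore statistically
  anticonservative; it is reproduced deliberately, as a faithful mirror of
  the analysis being implemented, and documented as such.
* **GEE**: Gaussian family, identity link, subject clusters, robust
  (Liang--Zeger sandwich) standard errors without small-sample adjustment,
  Wald chi-squared tests and 95% Wald intervals.  The default working
  correlation is independence — under which the estimates coincide with
  OLS — with exchangeable and AR(1) available, since the original software's
  default is independence but the choice is not documented in the analysis
  being mirrored.  The scale is the Pearson dispersion `sum(r^2)/(N - p)`.
  Reference levels are CGC = 0 and Session = 1; sex and dental status are
  coded female = 0/male = 1 and natural = 0/artificial = 1.  Because the
  original coding direction for those two factors is not documented, the
  signs of their coefficients are not asserted anywhere.  Interaction dummies
  for structurally empty design cells (sparse clinical samples routinely
  lack artificial-denture high consumers) are dropped automatically; any
  further rank deficiency is an error naming the aliased columns.

## The deposited clinical dataset

The reader `read_supplementary()` ingests the per-subject dataset deposited
with the study this analysis mirrors (265 subjects, three sessions each).
The deposit's column layout is not documented in the article text, so the
reader is schema-driven: a `column_map` names the columns holding subject id,
age, sex, dental status, CGC, session and VhH, and categorical codes are
normalized from common dialects (`f`/`female`/`0`, `low`/`medium`/`high`,
`denture`, ...).  Comma-, semicolon- and tab-delimited files are sniffed from
the header; spreadsheet formats must be exported to delimited text first, as
the package deliberately carries no spreadsheet dependency.  The dataset
itself is not redistributed with the package; when a copy is placed at
`inst/extdata/supplementary_s1.csv`, the published-value reproduction in the
acceptance tests runs against it, and without it that reproduction reports
itself as unavailable rather than silently passing.

## Problem sizes and runtime envelope

The test suite chooses sizes that keep the full run in minutes while leaving
every statistical check at full strength: segmentation unit tests use
96x96 px wafers; the determinism check processes 50 full-size sample pairs
twice; the type-I-error simulation runs 500 replicates of 60-subject null
cohorts with a heterogeneous AR(1)-like session covariance (GG epsilon near
0.75); GEE recovery uses 100 replicates at the full 265-subject design; the
split-plot oracle comparison uses 50 random 12-subject balanced cohorts at
1e-8 relative tolerance.

## Known limitations

* Absolute VhH values are reproducible only in distributional shape from
  re-rendered images, not pixel-exactly, because bin count, achromatic
  handling, side aggregation and segmentation bandwidths are conventions of
  this implementation.
* One bolus per image; no multi-bolus support, shadow/glare correction or
  scanner colour calibration.
* The measurement-level Welch/Games--Howell battery inherits the
  anticonservative pooling described above by design.
* The cohort generator's additive model contains no CGC-by-session
  interaction and no dropout; studies with incomplete sessions are rejected
  by the cohort validator rather than imputed.
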