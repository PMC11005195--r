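---
title: "Quantifying ERK-biosensor FRET in zebrafish embryos: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ERK-biosensor FRET in zebrafish embryos: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretbench)
```

# Scope

`fretbench` implements the quantitative analysis chain for intramolecular
CFP/YPet ERK biosensors in zebrafish embryos — spectral separation of lambda
stacks, ratiometric FRET indexing, acceptor-photobleaching (AB) efficiency
and donor–acceptor distance estimation, embryo morphometry, densitometry and
the group statistics — together with a phantom generator that renders
synthetic embryos with known ground truth. This vignette documents the
models, the defaults and the numerical conventions; nothing here states a
result that the test-suite does not itself compute.

# The forward model

## Two-state sensor

Each pixel carries a sensor density $d(p) \ge 0$ and an active fraction
$a(p) \in [0, 1]$. The sensor is two-state: the effective FRET efficiency is

$$E_{\mathrm{eff}}(p) = a(p)\,E_{\mathrm{active}} + (1 - a(p))\,E_{\mathrm{inactive}},$$

with defaults $E_{\mathrm{inactive}} = 0.05$ and $E_{\mathrm{active}} = 0.35$.
Absolute molecular efficiencies of EKAREV-type sensors are not reliably
published, so these two numbers are placeholders that shape realism only:
every accuracy test in the package compares estimates against the stored
ground truth of the phantom at hand, never against these defaults.

## Spectral rendering

Under donor excitation, the expected photon count in detection band $b$ is

$$\mu_b(p) = d(p)\,N \left[(1 - E_{\mathrm{eff}})\,Q_D F_D(b) + E_{\mathrm{eff}}\,Q_A F_A(b)\right],$$

where $N$ is the photon budget (default 100 photons per unit density per
pixel, a realistic confocal regime where shot noise is visible but not
dominant), $Q_D/Q_A$ are quantum-yield scale factors (default 1; the
ratiometric readout is unitless so only their ratio matters) and $F_X(b)$ is
the fraction of fluorophore $X$'s unit-area emission spectrum inside band
$b$. Emission spectra default to Gaussians — CFP peak 476 nm, sd 18 nm; YPet
peak 530 nm, sd 14 nm — matching the published peak positions and widths of
these fluorophores to the precision that matters for window integrals; both
are replaceable by measured spectra via `emission_spectrum()`. Direct
acceptor excitation at the donor line defaults to zero: the sensor is
intramolecular, so donor and acceptor are stoichiometric and crosstalk would
add a constant offset rather than change orderings; it is available as
`acceptor_crosstalk` where needed.

Detection noise is Poisson shot noise on $\mu_b$ followed by additive
Gaussian read noise (default sd 2 photons), clipped at zero. `noise_free()`
switches both off and returns expected values, which the analytic test
oracles rely on.

Band edges are multiples of the step size from $\lambda_{\min}$, the last
band truncated at $\lambda_{\max}$; the band count is
$\lceil(\lambda_{\max} - \lambda_{\min})/\mathrm{step}\rceil$, which
reproduces both standard acquisitions over 462–572 nm: 22 bands at 5 nm and
16 at 7 nm. Band integrals are computed on a 0.25 nm refinement, making the
total intensity independent of the partition (5 nm and 7 nm grids agree to
about $10^{-6}$ relative).

## Bleaching

An AB series bleaches the acceptor inside an ROI over $n$ iterations with
per-iteration survival $s_1$; the surviving fraction is $s = s_1^n$ (default
$s_1 = 0.85$, so $s \approx 3\times10^{-4}$ after the standard 50 iterations
— effectively complete bleaching). Post-bleach the effective efficiency in
the ROI is $E\,s$, so the donor de-quenches from
$d N (1 - E) Q_D$ to $d N (1 - E s) Q_D$. Acceptor frames model direct
acceptor excitation and are proportional to the surviving acceptor amount.
Donor photobleaching during the series is excluded from the model by
default, because the downstream estimator assumes it negligible.

A consequence worth writing down: with the estimator
$E_{\mathrm{est}} = (D_\Omega - D_A)/D_\Omega$, a partially bleached series
gives *exactly*

$$E_{\mathrm{est}} = \frac{E (1 - s)}{1 - E s},$$

which the tests assert to $10^{-9}$. The convenient reading "the estimate is
biased low by the factor $(1 - s)$" is the first-order approximation of this
closed form; its error is $E^2 s (1 - s)/(1 - E s)$, negligible for
near-complete bleaching but not an identity, and the tests assert the
approximation only within that analytic bound.

# Estimators

## FRET index

`fret_index()` computes the raw integrated density (sum of pixel values, the
Fiji convention — not the mean) of the acceptor/donor ratio image within an
ROI. The default order is *ratio of sum projections*: each channel is
z-projected by summation first, then divided. The alternative order
(per-plane ratios, averaged across planes) is available behind the `order`
flag; which order vendor software applies is not recoverable from typical
method descriptions, so both are implemented and a sensitivity test bounds
their disagreement at 5% relative on noise-free phantoms.

Pixels whose donor signal falls below `donor_floor` (default 1% of the
projected donor maximum — no background threshold is standard in the
literature, so the default is deliberately conservative and recorded in each
measurement) are masked invalid and excluded from ROI sums; a fully-invalid
ROI yields an undefined index with an explicit flag rather than a number.

Group effects are reported as fold changes: each treated embryo's index over
the control mean, averaged — keeping per-embryo dispersion available for
SEM-style reporting — with a paired post/pre mode for within-embryo designs.

## Spectral separation

`band_window_separation()` assigns a band to a window when the band *centre*
lies inside the window (inclusive bounds). The centre rule is a documented
choice: it is simple, testable, and with 5 nm grids the standard windows
(465–500 nm donor, 525–570 nm acceptor, 7 and 9 bands respectively) are
insensitive to the alternative partial-overlap weighting.

`linear_unmix()` solves a per-pixel non-negative least-squares problem
against the band-integrated reference spectra. With exactly two fluorophores
(the supported case) the NNLS solution is computed exactly: the
unconstrained normal-equation solution where it is non-negative, otherwise
the best single-component or zero fit by residual norm. The unconstrained
pseudo-inverse solution and `pracma::lsqnonneg` serve as independent oracles
in the tests, never as the implementation. Both separation routes rank
activity levels identically on noise-free phantoms, which is the property
the ratiometric readout actually needs.

## AB-FRET

`ab_efficiency()` averages the two pre-bleach scans pixel-wise before taking
the ROI mean (the acquisition takes two scans without stating how they
combine; averaging is the variance-optimal symmetric choice). $E$ is
computed on ROI means, not per pixel: the two coincide under uniform
efficiency, and ROI means are far more robust at realistic photon budgets —
this choice is asserted by the estimator tests. Negative estimates are
reported as-is and flagged, never clamped; they participate in group
statistics on $E$ but are excluded from distance estimation, matching the
reporting convention for zero-efficiency ROIs. No background subtraction is
applied by default.

`distance_from_efficiency()` inverts the Förster relation with $R_0 = 4.7$
nm for the CFP–YFP pair; $E \ge 1$ returns the limit 0 with a warning,
$E \le 0$ is excluded (NA). The inverse map $E(R) = R_0^6/(R_0^6 + R^6)$
exists in the test-suite only, as the round-trip oracle.

`classify_by_threshold()` splits $E\%$ values at 7.53 by default; a value
exactly at the threshold counts as *low*, a documented tie rule for a
criterion stated with strict inequalities.

## Morphometry

`axis_lengths()` replaces hand-drawn axis lines with the
intensity-equivalent ellipse from second central moments (full axis length
$= 4\sqrt{\lambda}$ for each covariance eigenvalue, the regionprops
convention, plus the $1/12$ per-pixel variance term that stabilises thin
masks). For filled ellipses this recovers the true axes to well under the 2%
test tolerance and is rotation/translation invariant; for strongly bent
embryos the equivalent ellipse is an approximation to a manual axis — a
known limitation. Masks must contain exactly one 4-connected component;
anything else errors with the component count.

`body_length()` is the straight snout-to-tail distance (matching a manual
straight-line tool even for curved larvae): either two given endpoints or
the farthest pair of mask pixels, computed on the convex hull. Outputs are
in pixels unless a µm/px calibration is supplied, since no calibration is
assumed.

## Densitometry

`band_density()` sums a rectangular band ROI and subtracts the median of a
same-size flanking region (below the band, or above at the image edge) times
the pixel count; a uniform background cancels exactly. Whether published
blot analyses background-subtract at all is typically unstated, so the rule
is explicit here and `background_rule = "none"` disables it. Saturated
pixels raise a warning. The GAPDH-normalised ratio
$(\mathrm{pERK}/\mathrm{GAPDH})/(\mathrm{tERK}/\mathrm{GAPDH})$ is computed
literally in that order; its algebraic collapse to pERK/tERK is
property-tested, not assumed.

## Statistics

`compare_groups()` dispatches to established routines (`t.test`,
`wilcox.test`, `aov` + `multcomp::glht` Dunnett, `kruskal.test`) under a
declared design; the direction of one-tailed tests must be stated in the
design and is never inferred from the data. Two post hoc procedures are
implemented in-package because no installed library provides them: a
step-down Šidák (Holm–Šidák) adjustment and Dunn's rank comparison with tie
correction (Bonferroni-adjusted). The one-sided 2×2 chi-square uses the
signed square root of the uncorrected $X^2$ statistic against the normal
tail, with the exact hypergeometric probability as the test oracle. Both
Dunnett and Holm–Šidák are offered on the same ANOVA because published
analyses use both on like-for-like comparisons; neither is chosen
automatically.

`remove_outliers()` is a deliberate, simpler substitute for the proprietary
regression-based ROUT procedure: exclusion beyond 3 scaled MADs
(`stats::mad`, normal-consistent) from the median. Exclusions are always
returned, never silently dropped; on clean normal samples the rule excludes
under 2% of points.

# The cohort scenario

`noonan_cohort_config()` encodes the four-group study design: wild-type
Shp2, the gain-of-function D61G mutant, and the mutant under low
(0.25 µM, suppression factor 0.7) and high (1 µM, suppression factor 0.4)
MEK-inhibitor doses acting multiplicatively on margin activity. Defaults,
chosen once as the simulated study conditions:

| parameter | default | rationale |
|---|---|---|
| WT margin / bulk activity | 0.2 / 0.1 | margin is the high-FGF/ERK domain; mild baseline elsewhere |
| genotype effect | 4.0 | keeps the high-dose rescue group (0.4 × 4 = 1.6 × WT) *above* wild type — a partial molecular rescue — with adjacent-group separations of at least 60%, comfortably resolvable at n = 8 given the between-embryo variability below |
| dose suppression | 0.7 / 0.4 | low dose partial, high dose strong suppression |
| between-embryo variability | lognormal, sdlog 0.1 | ~10% biological scatter per embryo |
| photon budget / read noise | 100 / 2 | realistic confocal SNR |
| bleach survival per iteration | 0.85 | 50 iterations ≈ complete bleaching (3×10⁻⁴ surviving) |
| morphology truth (axis ratio) | 1.30 / 1.60 / 1.45 / 1.30 | mutant convergence-extension defect, partial rescue at low dose, full rescue at high dose |
| morphology truth (body length, px) | 110 / 88 / 99 / 107 | mutant shortening, dose-ordered rescue |

One master seed fans out to per-embryo and per-stage child seeds by a stable
string-hash derivation, so adding a stage or embryo never perturbs earlier
draws, and identical configurations are bit-identical.

## What the phantoms do and do not emulate

Emulated: domain-structured activity (gastrula margin ring; fore-, mid-,
hindbrain and tailbud at pharyngula stage), genotype and dose effects with
per-embryo variability, sensor-density texture, Poisson + Gaussian detector
noise, acceptor bleaching kinetics, elliptical morphology with rotation, gel
bands over uniform background.

Not emulated: realistic embryo anatomy and optics (scattering, depth
attenuation, PSF blur), autofluorescence, donor photobleaching during
acquisition, segmentation difficulty (masks are given, not estimated),
developmental time courses, pharmacokinetics. Passing tests therefore
demonstrate correctness of the *estimators and their algebra* under a
controlled imaging model — not robustness to every artefact of real confocal
data.

# Numerical conventions and degenerate inputs

* Coordinates are 0-based with half-open ROI rectangles throughout the file
  interfaces; in-memory masks are ordinary R logical matrices.
* Division guards: ratio pixels below the donor floor are invalid (NA), a
  zero post-bleach donor or zero tERK sum is an error, a fully-invalid ROI
  is a flagged measurement — never an Inf.
* Determinism: every stochastic function takes a seed; equal seeds give
  bit-identical outputs (asserted for phantoms, stacks, cohorts and the
  pipeline's CSVs).
* Lambda stacks are stored as multi-page 32-bit float TIFF with a JSON
  sidecar (band edges, excitation, stage, intensity scale); float TIFF
  samples live in [0, 1], so intensities are scaled by a recorded factor,
  and the round trip is exact to single-float precision. Third-party stacks
  load via the same documented sidecar.
* Test problem sizes: phantoms of 32–96 px for estimator checks, 200 noisy
  replicates for the bias suite, and 100 repeats of the four-group cohort at
  128 × 128 px, n = 8 per group, for the end-to-end recovery suite — sizes
  at which every asserted property is stable under the fixed seeds while the
  whole suite stays lightweight.

# Known limitations

* The equivalent-ellipse axis ratio diverges from a hand-drawn axis on
  strongly bent embryos.
* The two-state sensor efficiencies are placeholders (see above); absolute
  $E$ values from the phantom should not be read as molecular truth.
* Unmixing supports exactly two fluorophores; no blind unmixing or
  autofluorescence component.
* The MAD outlier rule is not ROUT; on skewed data the two can disagree.
* The chi-square one-sided p uses the normal approximation; for very small
  tables prefer the exact test.
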