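---
title: "Designing melanopsin-isolating metameric stimuli"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing melanopsin-isolating metameric stimuli}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silentsub)
```

## The problem

Intrinsically photosensitive retinal ganglion cells (ipRGCs) carry the
photopigment melanopsin and respond to light directly, alongside the input
they receive from cones and rods.  To ask whether ipRGCs contribute to color
discrimination one needs *metameric ipRGC stimuli*: pairs of spectra that
excite the L-, M-, S-cones and the rods identically while differing in
melanopsin excitation.  Because the melanopsin sensitivity overlaps all four
other curves, no wavelength region drives ipRGCs alone, and the isolating
direction has to be constructed in function space.

`silentsub` implements that construction for a multispectral projector that
can realize arbitrary spectral power distributions $p(\lambda)$ with
per-wavelength output between 0 and 100 % of its maximum drive, sampled on a
380–780 nm grid at 5 nm.

## The orthogonal-basis construction

Let $l, m, s, r, i$ be the five photoreceptor sensitivities
(peak-normalized, energy units) on the grid, with the rectangle-rule inner
product $\langle f, g \rangle = \sum_k f(\lambda_k) g(\lambda_k)\,
\Delta\lambda$.  Gram–Schmidt orthogonalization *in the fixed order L, M, S,
rod, melanopsin* produces basis vectors $e_1 \ldots e_5$ and an
upper-triangular coefficient matrix $\alpha$ with

$$[\,l\; m\; s\; r\; i\,] = [\,e_1\; e_2\; e_3\; e_4\; e_5\,]\,\alpha .$$

Stimuli are synthesized as weighted sums
$p = \omega_1 e_1 + \cdots + \omega_5 e_5$.  Because
$\langle e_5, l \rangle = \cdots = \langle e_5, r \rangle = 0$ while
$\langle e_5, i \rangle = \langle e_5, e_5 \rangle > 0$, changing
$\omega_5$ moves melanopsin excitation and nothing else — the *silencing*
property that every other result builds on.

Two Gram–Schmidt conventions exist.  `build_basis()` defaults to the
**unit-diagonal** convention (residuals are not renormalized, so
$\alpha_{jj} = 1$ exactly and
$\alpha_{ij} = \langle s_j, e_i\rangle / \langle e_i, e_i\rangle$); a
`"unit_norm"` convention (orthonormal $e_i$) is also provided.  The choice
is cosmetic: the silencing property and every feasible interval depend only
on the *span* of the basis, and the test suite asserts that both
conventions give identical intervals to $10^{-8}$.  The unit-diagonal form
is the default because it makes the decomposition identity above literally
true with ones on the diagonal, which is how the matrix is conventionally
tabulated.

```{r alpha}
obs <- load_standard_observer()
basis <- build_basis(obs)
round(basis$alpha, 4)
```

## Excitations in percent of flat white

All excitations use one convention: receptor $k$'s excitation of a spectrum
$p$ is

$$E_k(p) = 100\,\frac{\langle p, s_k\rangle}{\langle p_w, s_k\rangle},$$

where $p_w$ is the flat spectrum at 100 (the projector's "all channels
full" white).  Every receptor sees the reference white at exactly 100, any
spectrum bounded by $[0, 100]$ lands in $[0, 100]$, and the map is linear.
Excitations are *always* computed this way — from dot products with the
actual sensitivities — never by trusting a printed coefficient row, which
would require an orthonormality that the unit-diagonal convention does not
provide.

## The feasible melanopsin interval

The basis vectors take negative values, so not every coefficient vector is
a physical spectrum.  Fixing target cone and rod excitations
$(L, M, S, R)$ pins $\omega_1 \ldots \omega_4$ through a triangular linear
system; the candidate spectra are $q + \omega_5 e_5$ with
$q = \sum_{1}^{4}\omega_j e_j$.  Each wavelength contributes the constraint
$0 \le q(\lambda_k) + \omega_5 e_5(\lambda_k) \le \mathrm{cap}$, a half-line
or interval in $\omega_5$; their intersection, mapped through the linear
relation between $\omega_5$ and melanopsin excitation, is the **feasible
ipRGC interval** returned by `feasible_iprgc_interval()`.  This closed form
is the one-variable linear program solved exactly, and the suite checks it
against an explicit LP on random targets at $10^{-9}$.

```{r interval}
feasible_iprgc_interval(obs, c(47.9, 36.4, 5.86, 14.9))
```

An edge case worth knowing: the flat white itself is *not* in the span of
the five sensitivities, so asking for its excitation quadruple
$(100, 100, 100, 100)$ at cap 100 is infeasible — the only spectra with
those excitations leave the five-dimensional design space.  The function
reports infeasibility (a flag, not an error) rather than pretending a
degenerate interval exists.

## Global capacity and the chromaticity gamut

`max_metamer_range()` maximizes $I(p_1) - I(p_2)$ over pairs sharing
$\omega_1\ldots\omega_4$ (cone + rod matching) or $\omega_1\ldots\omega_3$
(cone matching only), subject to the per-wavelength output bounds — a
linear program whose optimum is the widest melanopsin-only modulation the
device can express anywhere in its gamut.  `scan_gamut()` repeats the
optimization with the first member pinned to each cell of an xy
chromaticity raster; `classify_bands()` reproduces the 1-percent-wide map
bands, and `select_stimulus_points()` picks, per hue direction in
$a^*b^*$, the most saturated cell supporting each target modulation width.

Two numerical choices matter here:

* **Linear programming.**  All LPs in the package have at most eight free
  variables against a few hundred bound constraints.  They are solved by an
  internal two-phase revised simplex applied to the dual problem (whose
  basis is the size of the variable count), with Bland's rule for
  termination on the heavily degenerate vertices these bound structures
  produce.  The solver is cross-checked in the tests against the
  closed-form interval on random targets; any optimum it reports is also
  verified against the constraints and the duality gap before being
  accepted.
* **Chromaticity constraint.**  The bundled color-matching functions are an
  exact linear transform of the bundled cone fundamentals, so the second
  pair member (which matches the first in L, M, S) shares its chromaticity
  automatically and the equality constraints are imposed on one member
  only.  For user-supplied CMFs outside the cone-fundamental span,
  `constrain_both = TRUE` applies them to both.

Scan resolution defaults to 0.005 in xy; the test suite and worked examples
use 0.02–0.03 rasters (hundreds of cells, a few seconds) which sample the
same per-cell optima more coarsely.

## Pentameric pairs

For individual-difference controls one wants pairs matching *all five*
excitations while differing spectrally.  `pentamer_pair()` searches the
receptor null space: perturbations $d$ with $\langle d, s_k\rangle = 0$ for
every $k$ (dimension $81 - 5 = 76$ on the default grid), maximizing the
spectral $L^1$ separation of $base \pm d/2$ under the output bounds.
Maximizing an $L^1$ norm is not itself a linear objective, so the package
iterates sign-linearization: fix a sign pattern, solve the resulting LP,
refresh the signs from the solution, stop when stable.  Each step cannot
decrease the objective; the result is a deterministic local optimum, which
is all the application needs (the tests require equal excitations to
$10^{-8}$ and strictly positive contrast for interior bases; a base at the
bounds correctly yields a zero-width pair).

## The bundled observer and its provenance

The official 1-nm tabulations of the cone fundamentals, the melanopic
sensitivity, and the cone-fundamental XYZ color-matching functions are not
redistributable inside this package, so the bundled observer is a
**reconstruction from public standard data**, generated by
`build_standard_observer()` and shipped as
`standard_observer_2deg_5nm_synthetic.csv` (the `synthetic` suffix marks
the reconstruction):

* **Cone fundamentals** — the CIE 1931 2° color-matching functions
  (transcribed at 10 nm) with the Judd 1951 correction to the luminosity
  curve and the Vos 1978 deep-blue corrections, pushed through the
  *inverse* of the published cone-fundamental→XYZ linear transform.  With
  exact cone-fundamental-based CMFs this inversion would recover the
  fundamentals exactly; with the corrected 1931 tables it is a close
  approximation.
* **Rod** — the CIE 1951 scotopic luminosity function $V'(\lambda)$.
* **Melanopsin** — the Govardovskii A1 pigment template at 480 nm, filtered
  by an ocular-media density *derived from* $V'$ itself (by equating $V'$
  with a self-screened rhodopsin template, which reproduces the standard
  lens density closely, about 1.79 at 400 nm) and converted to energy
  units.

How good is the reconstruction?  The package's own comparison report
(`compare_alpha()`) against the published coefficient tabulation shows the
first-column and rod-column entries agreeing to a few thousandths
(e.g. the weight of $e_1$ in the M-cone sensitivity, 0.810 vs the published
0.805), while entries involving the M- and S-residuals in the blue differ
by up to 0.12 — exactly the region where the Judd/Vos-corrected 1931 data
deviate most from the modern fundamentals.  Downstream, the rod-matched
global capacity and the worked feasible intervals reproduce published
values to a few tenths of a percent, while the *rod-free* capacity (which
leans hardest on the blue region) overshoots.  The comparison report is the
honest interface to this residual error: it is printed, not suppressed.

## Colorimetry

`xyz_from_spectrum()` integrates against a CMF table normalized so the
flat-100 white has $Y = 100$ (relative colorimetry; absolute cd/m² would
need a device calibration that is out of scope).  The bundled CMFs are the
exact linear transform of the bundled fundamentals, equal-energy
normalized, so metamer pairs designed by the engine have identical
tristimulus values and $\Delta L_{ab} < 10^{-6}$ by construction — asserted
in the tests.  CIELAB uses the standard cube-root transform with the
$(6/29)^3$ split and the flat equal-energy white as reference; the
transform is cross-checked against `grDevices::convertColor`.  Field sizes
other than 2° are supported by passing a user CMF table
(`read_cmf_csv()`), not by an age/field-size observer model.

## Discrimination analysis and the synthetic generator

Trial tables use fixed columns
(`participant, group, point, kind, delta_i_pct, response`).
`discrimination_rates()` computes raw per-pair percentages of "different"
responses among metamer trials, unweighted means per nominal
melanopsin-difference label and per hue group, and a separate dummy
(catch-trial) false-alarm rate — no false-alarm correction is applied,
matching how such experiments are conventionally reported; pooling dummies
into the denominators is available behind a flag.

`simulate_responses()` emulates the experiment design (default 5
participants, 2 trials per pair, dummies interleaved).  A metamer trial is
judged "different" with probability
$g + (1 - g)\,\sigma^*(k\,\Delta I)$ where $g$ is the guess rate and
$\sigma^*(u) = 2(\mathrm{logistic}(u) - \tfrac12)$ rises from 0 at zero
difference; dummies use $g$ alone.  The folded logistic is used rather than
a plain logistic so that a zero slope makes metamer and dummy trials
statistically indistinguishable — the natural null case, which a plain
logistic (value $\tfrac12$ at zero) would violate.  The generator emulates
independent Bernoulli observers with a shared psychometric function; it
does not model participant heterogeneity, learning, or response bias, so
passing recovery tests says the *analysis* is correct, not that real
observers behave this way.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| grid | 380–780 nm @ 5 nm | computation grid (81 samples) |
| `cap` | 100 % | per-wavelength output ceiling; without it percent modulation would be unbounded by scaling |
| `delta` | `"max"` | requested melanopsin difference of a pair, or the interval endpoints |
| `resolution` | 0.005 | xy raster pitch for the gamut scan |
| `hue_angles` | 0°–300° in 60° steps | hue-group directions in $a^*b^*$ (configurable; the published groups are stated only qualitatively) |
| orthogonality tolerance | $10^{-9}$ relative | basis self-check |
| excitation-equality tolerance | $10^{-8}$ | metamer/pentamer verification |
| coefficient-comparison tolerance | 0.05 | per-entry band for `compare_alpha()` |

## Known limitations

* The observer is a reconstruction; blue-region residuals propagate into
  quantities that depend on the S/M residual structure (see above).
* Only relative colorimetry; no chromatic adaptation or appearance
  modeling.
* The gamut scan maximizes over luminance implicitly (no fixed-luminance
  plane option).
* Device pipelines that resample the 5-nm design to other grids (e.g. a
  4-nm projector grid) are supported only through `resample()`; no device
  gamma or bit-depth model is included.
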