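## Physiological reconstruction of the five-photoreceptor standard observer.
##
## The package needs the five sensitivity curves l, m, s, r, i on the design
## grid.  Rather than shipping opaque numbers, the bundled observer table is
## generated by the functions below from two small transcribed standard
## tables (the CIE 1931 2-degree color-matching functions with the Judd 1951
## / Vos 1978 short-wavelength corrections, and the CIE 1951 scotopic
## luminosity function V'), the Govardovskii et al. (2000) A1 visual-pigment
## template, and the published linear transform between cone fundamentals and
## cone-fundamental-based XYZ color-matching functions.  See the methods
## vignette for the construction and its accuracy limits; the resulting
## tables are labelled "synthetic" because they are reconstructions, not the
## official 1-nm CIE tabulations.

#' Govardovskii A1 visual-pigment absorbance template
#'
#' Analytic template for the absorbance spectrum of a vitamin-A1 visual
#' pigment with peak absorbance at `lambda_max`, including the beta band.
#' Values are peak-normalized to 1.
#'
#' @param lambda wavelengths in nm.
#' @param lambda_max peak wavelength of the alpha band in nm.
#' @return numeric vector of absorbances in `[0, 1]`.
#' @export
pigment_template <- function(lambda, lambda_max) {
  x <- lambda_max / lambda
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  alpha_band <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                       exp(-14.9 * (1.104 - x)) + 0.674)
  lam_beta <- 189 + 0.315 * lambda_max
  b_beta <- -40.5 + 0.195 * lambda_max
  beta_band <- 0.26 * exp(-((lambda - lam_beta) / b_beta)^2)
  A <- alpha_band + beta_band
  A / max(A)
}

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "silentsub")
  if (!nzchar(p)) stop(sprintf("bundled table '%s' not found", file))
  p
}

## cubic-spline interpolation of a coarse standard table onto a grid
spline_to_grid <- function(wl, values, grid, log_domain = FALSE) {
  xout <- wavelengths(grid)
  if (min(xout) < min(wl) - 1e-9 || max(xout) > max(wl) + 1e-9)
    stop("grid extends outside the bundled table range (380-780 nm)")
  if (log_domain) {
    exp(stats::spline(wl, log(values), xout = xout, method = "fmm")$y)
  } else {
    pmax(stats::spline(wl, values, xout = xout, method = "fmm")$y, 0)
  }
}

#' Scotopic luminosity function V'(lambda)
#'
#' The CIE 1951 scotopic luminosity function, interpolated from the bundled
#' 10-nm tabulation (cubic spline in the log domain, where the curve is
#' nearly parabolic) and peak-normalized.
#'
#' @param grid target [wavelength_grid()].
#' @return a [sensitivity_fn()] named `"rod"`.
#' @export
scotopic_luminosity <- function(grid = wavelength_grid()) {
  tab <- utils::read.csv(extdata_path("scotopic_v_1951_10nm.csv"))
  v <- spline_to_grid(tab$wavelength_nm, tab$vprime, grid, log_domain = TRUE)
  sensitivity_fn(v, grid, name = "rod")
}

## Ocular media (lens + macula-free) optical density, derived by equating the
## scotopic luminosity function with a self-screened rhodopsin template:
##   V'(lambda)  =  k * (1 - 10^(-D * A_rh)) * 10^(-d_lens) * lambda
## solved for d_lens below 540 nm (where both sides are well determined) and
## tapered exponentially to zero above.  The derived density reproduces the
## standard ocular-media tabulations closely in the blue (about 1.79 at
## 400 nm).
lens_density <- function(grid = wavelength_grid(),
                         lambda_max_rh = 493, density_rh = 0.40,
                         anchor = 0.16) {
  wl <- wavelengths(grid)
  vp <- scotopic_luminosity(grid)$values
  A <- pigment_template(wl, lambda_max_rh)
  raw <- (1 - 10^(-density_rh * A)) * wl
  raw <- raw / max(raw)
  d <- log10(raw) - log10(vp)
  mid <- wl >= 520 & wl <= 560
  d <- d - mean(d[mid]) + anchor   # anchor mid-green density
  d <- ifelse(wl <= 540, d, anchor * exp(-(wl - 540) / 60))
  pmax(d, 0)
}

## Linear transform from peak-normalized cone fundamentals (l, m, s) to
## cone-fundamental-based XYZ color-matching functions.
lms_to_xyz_matrix <- function() {
  matrix(c(1.94735469, -1.41445123, 0.36476327,
           0.68990272,  0.34832189, 0.0,
           0.0,         0.0,        1.93485343),
         nrow = 3, byrow = TRUE)
}

## Judd/Vos-corrected 1931 CMFs on a grid (linear spline of the bundled
## 10-nm tabulation).
corrected_cmf_1931 <- function(grid = wavelength_grid()) {
  tab <- utils::read.csv(extdata_path("cie1931_judd_vos_cmf_2deg_10nm.csv"))
  list(xbar = spline_to_grid(tab$wavelength_nm, tab$xbar, grid),
       ybar = spline_to_grid(tab$wavelength_nm, tab$ybar, grid),
       zbar = spline_to_grid(tab$wavelength_nm, tab$zbar, grid))
}

#' Reconstructed 2-degree cone fundamentals
#'
#' Recovers approximate L-, M-, S-cone fundamentals (energy units,
#' peak-normalized) by inverting the published cone-fundamental-to-XYZ linear
#' transform on the bundled Judd/Vos-corrected 1931 color-matching functions.
#' With exact cone-fundamental-based CMFs this inversion would be exact; with
#' the corrected 1931 tables it is a close approximation (see the methods
#' vignette for validation against published summary quantities).
#'
#' @param grid target [wavelength_grid()].
#' @return list of three [sensitivity_fn()] named `"L"`, `"M"`, `"S"`.
#' @export
reconstruct_cone_fundamentals <- function(grid = wavelength_grid()) {
  cmf <- corrected_cmf_1931(grid)
  lms <- solve(lms_to_xyz_matrix(),
               rbind(cmf$xbar, cmf$ybar, cmf$zbar))
  lms <- pmax(lms, 0)
  list(L = sensitivity_fn(lms[1, ], grid, "L"),
       M = sensitivity_fn(lms[2, ], grid, "M"),
       S = sensitivity_fn(lms[3, ], grid, "S"))
}

#' Reconstructed melanopic sensitivity
#'
#' Melanopsin sensitivity at the cornea: the A1 pigment template at 480 nm
#' (the standard melanopsin peak) filtered by the ocular-media density and
#' converted to energy units, peak-normalized.  No macular pigment is
#' applied, as ipRGCs lie mainly outside the fovea.
#'
#' @param grid target [wavelength_grid()].
#' @return a [sensitivity_fn()] named `"ipRGC"`.
#' @export
reconstruct_melanopic <- function(grid = wavelength_grid()) {
  wl <- wavelengths(grid)
  v <- pigment_template(wl, 480) * 10^(-lens_density(grid)) * wl
  sensitivity_fn(v, grid, name = "ipRGC")
}

#' Assemble the reconstructed standard observer
#'
#' Builds the five-photoreceptor observer (L, M, S, rod, ipRGC) from the
#' bundled standard tables and templates.  This is the generator behind the
#' bundled `standard_observer_2deg_5nm_synthetic.csv`; [load_standard_observer()]
#' reads that table instead of recomputing.
#'
#' @param grid target [wavelength_grid()]; must lie within 380--780 nm.
#' @return a [photoreceptor_set()].
#' @export
build_standard_observer <- function(grid = wavelength_grid()) {
  cones <- reconstruct_cone_fundamentals(grid)
  photoreceptor_set(
    list(cones$L, cones$M, cones$S,
         scotopic_luminosity(grid), reconstruct_melanopic(grid)),
    provenance = paste("reconstructed 2-deg observer:",
                       "Judd/Vos-corrected CIE 1931 CMFs inverted through the",
                       "cone-fundamental XYZ transform; CIE 1951 V'; pigment",
                       "template melanopsin"))
}
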