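#' Color-matching function table
#'
#' Container for an XYZ color-matching function set on a wavelength grid.
#' The CMF table is a parameter throughout the colorimetry functions, so
#' field sizes other than the bundled 2 degrees (for example a 4.3-degree
#' set) can be supplied as user CSVs via [read_cmf_csv()].
#'
#' @param xbar,ybar,zbar non-negative numeric vectors on `grid`.
#' @param grid a [wavelength_grid()].
#' @param field_size_deg nominal field size in degrees.
#' @param provenance free text.
#' @return object of class `cmf_table`.
#' @export
cmf_table <- function(xbar, ybar, zbar, grid = wavelength_grid(),
                      field_size_deg = 2, provenance = "") {
  stopifnot(inherits(grid, "wavelength_grid"))
  for (v in list(xbar, ybar, zbar)) {
    if (length(v) != grid$n) stop("CMF length does not match the grid")
    if (anyNA(v) || any(v < -1e-9)) stop("CMFs must be non-negative")
  }
  structure(list(xbar = pmax(xbar, 0), ybar = pmax(ybar, 0),
                 zbar = pmax(zbar, 0), grid = grid,
                 field_size_deg = field_size_deg, provenance = provenance),
            class = "cmf_table")
}

#' @export
print.cmf_table <- function(x, ...) {
  cat(sprintf("<cmf_table %g deg on %g-%g nm @ %g nm>\n", x$field_size_deg,
              x$grid$start, x$grid$stop, x$grid$step))
  invisible(x)
}

#' Load the bundled 2-degree XYZ color-matching functions
#'
#' The bundled table is the exact linear transform of the bundled
#' reconstructed cone fundamentals into XYZ-like coordinates, so spectra that
#' match the package's L, M, S excitations automatically match in XYZ (and
#' hence chromaticity and CIELAB) under this table.
#'
#' @param grid target [wavelength_grid()].
#' @export
load_standard_cmf <- function(grid = wavelength_grid()) {
  tab <- utils::read.csv(extdata_path("xyz_cmf_2deg_5nm_synthetic.csv"))
  src <- wavelength_grid(tab$wavelength_nm[1], tab$wavelength_nm[nrow(tab)],
                         diff(tab$wavelength_nm)[1])
  rs <- function(v) resample_values(v, src, grid)
  cmf_table(rs(tab$xbar), rs(tab$ybar), rs(tab$zbar), grid,
            field_size_deg = 2,
            provenance = "bundled synthetic 2-deg CMFs (linear transform of the reconstructed cone fundamentals)")
}

#' Read a CMF table from CSV
#'
#' Expects columns `wavelength_nm, xbar, ybar, zbar` on a uniform grid.
#'
#' @param path file path.
#' @param field_size_deg nominal field size recorded on the table.
#' @export
read_cmf_csv <- function(path, field_size_deg = NA_real_) {
  df <- utils::read.csv(path)
  need <- c("wavelength_nm", "xbar", "ybar", "zbar")
  if (!all(need %in% names(df)))
    stop("CMF CSV must have columns wavelength_nm, xbar, ybar, zbar")
  wl <- df$wavelength_nm
  steps <- diff(wl)
  if (any(abs(steps - steps[1]) > 1e-6))
    stop("wavelength column is not a uniform grid")
  grid <- wavelength_grid(wl[1], wl[length(wl)], steps[1])
  cmf_table(df$xbar, df$ybar, df$zbar, grid, field_size_deg,
            provenance = path)
}

#' Tristimulus values of a spectrum
#'
#' Standard colorimetric integration with the normalization constant chosen
#' so the flat-100 reference white has `Y = 100` (relative colorimetry; no
#' absolute cd/m2).
#'
#' @param p an [spd()].
#' @param cmf a [cmf_table()]; resampled to the spectrum grid if needed.
#' @return named vector `c(X, Y, Z)`.
#' @export
xyz_from_spectrum <- function(p, cmf) {
  stopifnot(inherits(p, "spd"), inherits(cmf, "cmf_table"))
  if (!grids_equal(p$grid, cmf$grid)) {
    rs <- function(v) resample_values(v, cmf$grid, p$grid)
    cmf <- cmf_table(rs(cmf$xbar), rs(cmf$ybar), rs(cmf$zbar), p$grid,
                     cmf$field_size_deg, cmf$provenance)
  }
  step <- p$grid$step
  k <- 100 / (sum(rep(100, p$grid$n) * cmf$ybar) * step)
  c(X = k * sum(p$values * cmf$xbar) * step,
    Y = k * sum(p$values * cmf$ybar) * step,
    Z = k * sum(p$values * cmf$zbar) * step)
}

#' xy chromaticity coordinates
#'
#' @param t named tristimulus vector from [xyz_from_spectrum()].
#' @return named vector `c(x, y)`.
#' @export
xy_from_xyz <- function(t) {
  s <- sum(t[c("X", "Y", "Z")])
  if (s <= 0) stop("chromaticity undefined: X + Y + Z is zero")
  c(x = unname(t["X"] / s), y = unname(t["Y"] / s))
}

lab_f <- function(t) {
  d3 <- (6 / 29)^3
  ifelse(t > d3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
}

#' CIELAB coordinates
#'
#' Standard CIELAB transform with the cube-root/linear split at `(6/29)^3`.
#' The default white reference throughout the package is the flat
#' equal-energy spectrum at 100.
#'
#' @param t tristimulus vector of the stimulus.
#' @param white tristimulus vector of the reference white (strictly
#'   positive components).
#' @return named vector `c(L_star, a_star, b_star)`.
#' @export
lab_from_xyz <- function(t, white) {
  if (any(white[c("X", "Y", "Z")] <= 0))
    stop("white reference must have strictly positive tristimulus values")
  fx <- lab_f(t["X"] / white["X"])
  fy <- lab_f(t["Y"] / white["Y"])
  fz <- lab_f(t["Z"] / white["Z"])
  c(L_star = unname(116 * fy - 16),
    a_star = unname(500 * (fx - fy)),
    b_star = unname(200 * (fy - fz)))
}

#' CIELAB color difference between two spectra
#'
#' Euclidean distance in (L*, a*, b*) under a shared CMF table and white
#' reference.
#'
#' @param p1,p2 [spd()] objects.
#' @param cmf a [cmf_table()].
#' @param white reference white: an [spd()] or a tristimulus vector; default
#'   is the flat-100 white on the grid of `p1`.
#' @return scalar delta-Lab.
#' @export
delta_lab <- function(p1, p2, cmf, white = NULL) {
  if (is.null(white)) white <- flat_white(p1$grid)
  tw <- if (inherits(white, "spd")) xyz_from_spectrum(white, cmf) else white
  l1 <- lab_from_xyz(xyz_from_spectrum(p1, cmf), tw)
  l2 <- lab_from_xyz(xyz_from_spectrum(p2, cmf), tw)
  sqrt(sum((l1 - l2)^2))
}
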