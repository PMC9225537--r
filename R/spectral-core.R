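#' Uniform wavelength grid
#'
#' All spectral objects in silentsub live on a uniform wavelength grid.  The
#' canonical computation grid is 380--780 nm sampled every 5 nm (81 samples),
#' matching the resolution at which the stimulus spectra are designed.
#'
#' @param start first wavelength in nm.
#' @param stop last wavelength in nm; must exceed `start`.
#' @param step sampling interval in nm; `(stop - start)` must be an integer
#'   multiple of `step`.
#' @return An object of class `wavelength_grid` with fields `start`, `stop`,
#'   `step` and `n` (number of samples).
#' @examples
#' g <- wavelength_grid()
#' g$n  # 81
#' @export
wavelength_grid <- function(start = 380, stop = 780, step = 5) {
  if (!is.numeric(start) || !is.numeric(stop) || !is.numeric(step))
    stop("grid parameters must be numeric")
  if (start >= stop) stop("grid start must be below stop")
  if (step <= 0) stop("grid step must be positive")
  k <- (stop - start) / step
  if (abs(k - round(k)) > 1e-9)
    stop("(stop - start) must be an integer multiple of step")
  structure(list(start = start, stop = stop, step = step, n = round(k) + 1L),
            class = "wavelength_grid")
}

#' Wavelength samples of a grid
#' @param grid a `wavelength_grid`.
#' @return numeric vector of length `grid$n`.
#' @export
wavelengths <- function(grid) {
  stopifnot(inherits(grid, "wavelength_grid"))
  seq(grid$start, grid$stop, by = grid$step)
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid %g-%g nm @ %g nm (%d samples)>\n",
              x$start, x$stop, x$step, x$n))
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-9) {
  abs(a$start - b$start) < tol && abs(a$stop - b$stop) < tol &&
    abs(a$step - b$step) < tol
}

check_same_grid <- function(a, b) {
  if (!grids_equal(a, b))
    stop("wavelength grids do not match", call. = FALSE)
  invisible(TRUE)
}

#' Spectral power distribution
#'
#' A spectrum is a non-negative sampled function of wavelength in percent of
#' the device's maximum output per wavelength (so the reference white is the
#' constant 100 spectrum).  Negative values are rejected: a spectrum is
#' physically realizable by construction.  Signed intermediate combinations of
#' basis functions are plain numeric vectors, not `spd` objects.
#'
#' @param values numeric vector of non-negative values, one per grid sample.
#' @param grid a [wavelength_grid()].
#' @param label free-text label.
#' @return object of class `spd`.
#' @export
spd <- function(values, grid = wavelength_grid(), label = "") {
  stopifnot(inherits(grid, "wavelength_grid"))
  values <- as.numeric(values)
  if (length(values) != grid$n)
    stop(sprintf("expected %d values for this grid, got %d", grid$n,
                 length(values)))
  if (anyNA(values)) stop("spectrum contains missing values")
  if (any(values < -1e-9)) {
    bad <- which(values < -1e-9)
    stop(sprintf("spectrum has negative values at %d wavelength(s), e.g. %g nm",
                 length(bad), wavelengths(grid)[bad[1]]))
  }
  values[values < 0] <- 0
  structure(list(values = values, grid = grid, label = as.character(label)),
            class = "spd")
}

#' Flat (equal-energy) reference white
#'
#' The reference white drives every output channel at the same level; at
#' `level = 100` it is the spectrum against which all photoreceptor
#' excitations are normalized to 100.
#'
#' @param grid a [wavelength_grid()].
#' @param level constant output level in percent.
#' @export
flat_white <- function(grid = wavelength_grid(), level = 100) {
  spd(rep(level, grid$n), grid, label = sprintf("flat white %g", level))
}

#' @export
print.spd <- function(x, ...) {
  cat(sprintf("<spd%s on %g-%g nm @ %g nm; range [%.4g, %.4g]>\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              x$grid$start, x$grid$stop, x$grid$step,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Photoreceptor spectral sensitivity function
#'
#' @param values non-negative relative sensitivities, one per grid sample.
#' @param grid a [wavelength_grid()].
#' @param name receptor name; the standard observer uses
#'   `"L"`, `"M"`, `"S"`, `"rod"`, `"ipRGC"`.
#' @param normalize if `TRUE` (default) scale so the maximum is exactly 1.
#' @return object of class `sensitivity_fn`.
#' @export
sensitivity_fn <- function(values, grid = wavelength_grid(), name = "",
                           normalize = TRUE) {
  stopifnot(inherits(grid, "wavelength_grid"))
  values <- as.numeric(values)
  if (length(values) != grid$n)
    stop(sprintf("expected %d values for this grid, got %d", grid$n,
                 length(values)))
  if (anyNA(values)) stop("sensitivity contains missing values")
  if (any(values < -1e-9)) stop("sensitivity has negative values")
  values[values < 0] <- 0
  m <- max(values)
  if (m <= 0) stop("sensitivity is identically zero")
  if (normalize) values <- values / m
  structure(list(values = values, grid = grid, name = as.character(name)),
            class = "sensitivity_fn")
}

#' @export
print.sensitivity_fn <- function(x, ...) {
  pk <- wavelengths(x$grid)[which.max(x$values)]
  cat(sprintf("<sensitivity_fn '%s', peak at %g nm>\n", x$name, pk))
  invisible(x)
}

spectral_values <- function(x) {
  if (inherits(x, "spd") || inherits(x, "sensitivity_fn")) x$values
  else as.numeric(x)
}

spectral_grid <- function(x, default = NULL) {
  if (inherits(x, "spd") || inherits(x, "sensitivity_fn")) x$grid
  else default
}

#' Resample a spectral object onto a new grid
#'
#' Linear interpolation at the target wavelengths.  The source grid must cover
#' the full target range; extrapolation is refused.  Values are clipped at 0
#' from below.  The original object is not modified.
#'
#' @param x an `spd` or `sensitivity_fn`.
#' @param grid target [wavelength_grid()].
#' @return an object of the same class as `x` on the new grid.
#' @export
resample <- function(x, grid) UseMethod("resample")

resample_values <- function(values, from, to) {
  if (to$start < from$start - 1e-9 || to$stop > from$stop + 1e-9)
    stop(sprintf(
      "target grid %g-%g nm extends outside source grid %g-%g nm",
      to$start, to$stop, from$start, from$stop), call. = FALSE)
  out <- stats::approx(wavelengths(from), values, xout = wavelengths(to),
                       method = "linear", rule = 1)$y
  pmax(out, 0)
}

#' @export
resample.spd <- function(x, grid) {
  spd(resample_values(x$values, x$grid, grid), grid, label = x$label)
}

#' @export
resample.sensitivity_fn <- function(x, grid) {
  sensitivity_fn(resample_values(x$values, x$grid, grid), grid,
                 name = x$name, normalize = FALSE)
}

#' Rectangle-rule inner product of two spectral functions
#'
#' `sum(a * b) * step`: the discrete analogue of the integral of a product of
#' two spectral functions over wavelength.  Exactly proportional to the dot
#' product of the sample vectors, so every ratio of inner products taken on a
#' shared grid is independent of the step size.
#'
#' @param a,b `spd`, `sensitivity_fn`, or numeric vectors on `grid`.
#' @param grid the shared grid; may be omitted when `a` or `b` carries one.
#' @return a scalar.
#' @export
inner_product <- function(a, b, grid = NULL) {
  ga <- spectral_grid(a); gb <- spectral_grid(b)
  if (!is.null(ga) && !is.null(gb)) check_same_grid(ga, gb)
  grid <- if (!is.null(ga)) ga else if (!is.null(gb)) gb else grid
  if (is.null(grid)) stop("no wavelength grid supplied")
  va <- spectral_values(a); vb <- spectral_values(b)
  if (length(va) != grid$n || length(vb) != grid$n)
    stop("value lengths do not match the grid")
  sum(va * vb) * grid$step
}

#' Read spectra from CSV
#'
#' The CSV dialect is a `wavelength_nm` column followed by one column per
#' spectrum (header row required, comma-separated, `.` decimal).  The
#' wavelength column must form a uniform grid.
#'
#' @param path file path.
#' @return a list of [spd()] objects named after the CSV columns.
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2)
    stop("spectra CSV needs a wavelength column plus at least one spectrum")
  if (names(df)[1] != "wavelength_nm")
    stop("first column must be named 'wavelength_nm'")
  wl <- df[[1]]
  if (anyNA(wl)) stop("missing wavelength values")
  steps <- diff(wl)
  if (length(steps) < 1 || any(abs(steps - steps[1]) > 1e-6))
    stop("wavelength column is not a uniform grid")
  grid <- wavelength_grid(wl[1], wl[length(wl)], steps[1])
  out <- list()
  for (j in seq(2, ncol(df))) {
    v <- df[[j]]
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop(sprintf("missing value in column '%s', row %d", names(df)[j],
                   bad + 1L))  # +1 for the header row
    }
    if (any(v < 0)) {
      bad <- which(v < 0)
      stop(sprintf(
        "negative value(s) in column '%s' at row(s) %s",
        names(df)[j], paste(utils::head(bad + 1L, 5), collapse = ", ")))
    }
    out[[names(df)[j]]] <- spd(v, grid, label = names(df)[j])
  }
  out
}

#' Write spectra to CSV
#'
#' @param spectra a single [spd()] or list of them sharing one grid.
#' @param path file path.
#' @export
write_spectra_csv <- function(spectra, path) {
  if (inherits(spectra, "spd")) spectra <- list(spectra)
  stopifnot(length(spectra) >= 1)
  grid <- spectra[[1]]$grid
  cols <- list(wavelength_nm = wavelengths(grid))
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    stopifnot(inherits(s, "spd"))
    check_same_grid(s$grid, grid)
    nm <- names(spectra)[i]
    if (is.null(nm) || !nzchar(nm))
      nm <- if (nzchar(s$label)) s$label else sprintf("spectrum_%d", i)
    cols[[nm]] <- s$values
  }
  utils::write.csv(as.data.frame(cols, check.names = FALSE), path,
                   row.names = FALSE)
  invisible(path)
}
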