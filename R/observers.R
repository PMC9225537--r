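#' Photoreceptor set
#'
#' Bundle of photoreceptor sensitivity functions sharing one wavelength grid.
#' The standard observer holds exactly five in the fixed order L, M, S, rod,
#' ipRGC; this order is the orthogonalization order and must not be permuted.
#' Synthetic observers may hold 2--8 receptors.  All sensitivities are
#' peak-normalized to 1 on construction, and linear independence is checked
#' through the condition number of the Gram matrix.
#'
#' @param sensitivities list of [sensitivity_fn()] on a common grid.
#' @param provenance free-text description of where the curves come from.
#' @param condition_limit maximum admissible Gram-matrix condition number.
#' @return object of class `photoreceptor_set`.
#' @export
photoreceptor_set <- function(sensitivities, provenance = "",
                              condition_limit = 1e10) {
  stopifnot(is.list(sensitivities), length(sensitivities) >= 2,
            length(sensitivities) <= 8)
  grid <- sensitivities[[1]]$grid
  for (s in sensitivities) {
    stopifnot(inherits(s, "sensitivity_fn"))
    check_same_grid(s$grid, grid)
  }
  sens <- lapply(sensitivities, function(s)
    sensitivity_fn(s$values, grid, s$name, normalize = TRUE))
  S <- vapply(sens, function(s) s$values, numeric(grid$n))
  G <- crossprod(S) * grid$step
  cond <- kappa(G, exact = TRUE)
  if (!is.finite(cond) || cond > condition_limit)
    stop(sprintf(
      "sensitivities are numerically linearly dependent (Gram condition %.3g)",
      cond))
  structure(list(sensitivities = sens, grid = grid,
                 names = vapply(sens, function(s) s$name, character(1)),
                 provenance = provenance, gram_condition = cond),
            class = "photoreceptor_set")
}

#' @export
print.photoreceptor_set <- function(x, ...) {
  cat(sprintf("<photoreceptor_set: %s on %g-%g nm @ %g nm>\n",
              paste(x$names, collapse = ", "),
              x$grid$start, x$grid$stop, x$grid$step))
  if (nzchar(x$provenance)) cat(" ", x$provenance, "\n")
  invisible(x)
}

#' Number of receptors
#' @param obs a `photoreceptor_set`.
#' @export
n_receptors <- function(obs) length(obs$sensitivities)

## receptor sensitivities as an (n_wavelengths x n_receptors) matrix
sensitivity_matrix <- function(obs) {
  vapply(obs$sensitivities, function(s) s$values, numeric(obs$grid$n))
}

#' Load the bundled standard five-photoreceptor observer
#'
#' Reads the bundled reconstructed observer table (L-, M-, S-cone 2-degree
#' fundamentals, scotopic rod sensitivity, melanopic ipRGC sensitivity,
#' tabulated at 380--780 nm every 5 nm), resamples it onto `grid` and
#' peak-normalizes.  The table is a reconstruction from public standard data,
#' not the official CIE tabulation; see [build_standard_observer()] and the
#' methods vignette.
#'
#' @param grid target [wavelength_grid()]; must lie within 380--780 nm.
#' @return a [photoreceptor_set()] with receptors L, M, S, rod, ipRGC.
#' @examples
#' obs <- load_standard_observer()
#' sapply(obs$sensitivities, function(s) max(s$values))  # all exactly 1
#' @export
load_standard_observer <- function(grid = wavelength_grid()) {
  if (grid$start < 380 - 1e-9 || grid$stop > 780 + 1e-9)
    stop("standard observer tables cover 380-780 nm only")
  tab <- utils::read.csv(extdata_path("standard_observer_2deg_5nm_synthetic.csv"))
  src <- wavelength_grid(tab$wavelength_nm[1],
                         tab$wavelength_nm[nrow(tab)],
                         diff(tab$wavelength_nm)[1])
  nm <- c("L", "M", "S", "rod", "ipRGC")
  sens <- lapply(nm, function(k) {
    f <- sensitivity_fn(tab[[k]], src, name = k, normalize = FALSE)
    f <- resample(f, grid)
    sensitivity_fn(f$values, grid, name = k, normalize = TRUE)
  })
  photoreceptor_set(sens, provenance = paste(
    "bundled reconstructed 2-deg standard observer (synthetic tabulation;",
    "see package data README)"))
}

#' Synthetic observer for testing and simulation
#'
#' Smooth unimodal (log-normal shaped) sensitivity curves with given peak
#' wavelengths and bandwidths.  A seed adds a small deterministic skew to
#' each curve so that distinct seeds give distinct (but equally well-behaved)
#' observers.  All metamer machinery in this package works for any linearly
#' independent sensitivity set, which these fixtures exercise.
#'
#' @param n_receptors number of receptors (2--8).
#' @param peak_wavelengths peak positions in nm, inside the grid.
#' @param bandwidths log-domain standard deviations (dimensionless, e.g.
#'   0.04--0.10); recycled to `n_receptors`.
#' @param seed integer seed for the deterministic skew.
#' @param grid a [wavelength_grid()].
#' @return a [photoreceptor_set()].
#' @export
synthetic_observer <- function(n_receptors = 5,
                               peak_wavelengths = seq(440, 600,
                                                      length.out = n_receptors),
                               bandwidths = 0.06, seed = 1,
                               grid = wavelength_grid()) {
  stopifnot(n_receptors >= 2, n_receptors <= 8,
            length(peak_wavelengths) == n_receptors)
  wl <- wavelengths(grid)
  if (any(peak_wavelengths < grid$start | peak_wavelengths > grid$stop))
    stop("peak wavelengths must lie inside the grid")
  bandwidths <- rep_len(bandwidths, n_receptors)
  skew <- withr_seed_runif(seed, n_receptors, -0.15, 0.15)
  sens <- lapply(seq_len(n_receptors), function(k) {
    z <- log(wl / peak_wavelengths[k]) / bandwidths[k]
    v <- exp(-0.5 * (z + skew[k] * z^2 / (1 + abs(z)))^2)
    sensitivity_fn(v, grid, name = sprintf("R%d", k))
  })
  # stricter conditioning than for measured observers: a near-degenerate
  # fixture (e.g. coincident peaks) would make downstream tests meaningless
  photoreceptor_set(sens, provenance = sprintf("synthetic observer, seed %d",
                                               seed),
                    condition_limit = 1e4)
}

## uniform draws under a local, restored RNG state
withr_seed_runif <- function(seed, n, min, max) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  stats::runif(n, min, max)
}

#' Photoreceptor excitations in percent of flat white
#'
#' Excitation of receptor k is `100 * <p, s_k> / <pw, s_k>`, where `pw` is
#' the flat spectrum at 100: every receptor's response to the reference white
#' is defined as 100.  The map is linear in the spectrum, and every component
#' lies in `[0, 100]` whenever `0 <= p <= 100` everywhere.
#'
#' @param p an [spd()] on the observer's grid.
#' @param obs a [photoreceptor_set()].
#' @return named numeric vector of percent excitations (names are the
#'   receptor names; `L, M, S, R, I` for the standard observer).
#' @examples
#' obs <- load_standard_observer()
#' excitations_percent(flat_white(obs$grid), obs)  # all 100
#' @export
excitations_percent <- function(p, obs) {
  stopifnot(inherits(p, "spd"), inherits(obs, "photoreceptor_set"))
  check_same_grid(p$grid, obs$grid)
  S <- sensitivity_matrix(obs)
  num <- as.numeric(crossprod(S, p$values)) * obs$grid$step
  den <- as.numeric(crossprod(S, rep(100, obs$grid$n))) * obs$grid$step
  out <- 100 * num / den
  nm <- obs$names
  nm[nm == "rod"] <- "R"
  nm[nm == "ipRGC"] <- "I"
  names(out) <- nm
  out
}
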