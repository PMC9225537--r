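# Shared fixtures: small grids, smooth spectra, and observers built in code.

default_grid <- wavelength_grid()

# smooth bounded spectrum from a few random Gaussian bumps (values in [lo, hi])
random_smooth_spd <- function(grid = default_grid, seed = 1, lo = 5, hi = 95) {
  set.seed(seed)
  wl <- wavelengths(grid)
  v <- rep(0, grid$n)
  for (k in 1:4) {
    v <- v + stats::runif(1, 0.2, 1) *
      exp(-0.5 * ((wl - stats::runif(1, 400, 750)) / stats::runif(1, 30, 90))^2)
  }
  v <- lo + (hi - lo) * (v - min(v)) / (max(v) - min(v))
  spd(v, grid)
}

# observer with mutually disjoint supports (exactly orthogonal sensitivities)
disjoint_observer <- function(grid = default_grid, n = 3) {
  wl <- wavelengths(grid)
  edges <- seq(grid$start, grid$stop, length.out = n + 1)
  sens <- lapply(seq_len(n), function(k) {
    v <- numeric(grid$n)
    inside <- wl >= edges[k] & wl < edges[k + 1]
    mid <- (edges[k] + edges[k + 1]) / 2
    v[inside] <- exp(-0.5 * ((wl[inside] - mid) / 12)^2)
    sensitivity_fn(v, grid, name = sprintf("D%d", k))
  })
  photoreceptor_set(sens)
}

# standard observer / basis, computed once per test run
std_obs <- local({
  obs <- NULL
  function() {
    if (is.null(obs)) obs <<- load_standard_observer()
    obs
  }
})

std_basis <- local({
  b <- NULL
  function() {
    if (is.null(b)) b <<- build_basis(std_obs())
    b
  }
})

# printed reference values for the coefficient matrix of the standard
# orthogonalization (upper-triangular entries, row-major)
printed_alpha <- function() {
  m <- diag(5)
  m[1, 2] <- 0.8046
  m[1, 3] <- 0.0518; m[2, 3] <- 0.3310
  m[1, 4] <- 0.4946; m[2, 4] <- 1.5771; m[3, 4] <- 0.4435
  m[1, 5] <- 0.3296; m[2, 5] <- 1.3412; m[3, 5] <- 0.6118; m[4, 5] <- 1.1761
  m
}
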