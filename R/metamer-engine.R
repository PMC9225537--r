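#' Orthogonal spectral basis over the photoreceptor sensitivities
#'
#' Gram-Schmidt orthogonalization of the receptor sensitivities in their
#' fixed order (L, M, S, rod, ipRGC for the standard observer) under the
#' rectangle-rule inner product.  Two conventions are offered:
#'
#' * `"unit_diagonal"` (default): residuals are NOT renormalized, so each
#'   sensitivity decomposes as `s_j = sum_i alpha[i, j] e_i` with
#'   `alpha[j, j] = 1` exactly.  `alpha[i, j] = <s_j, e_i> / <e_i, e_i>` for
#'   `i < j`.
#' * `"unit_norm"`: classical orthonormalization; `<e_i, e_i> = 1` and
#'   `alpha[i, j] = <s_j, e_i>`, diagonal = residual norms.
#'
#' Every metamer quantity downstream (feasible intervals, maximal modulation
#' ranges) depends only on the span of the basis and is identical under both
#' conventions; only the printed `alpha` entries differ.
#'
#' @param obs a [photoreceptor_set()].
#' @param convention `"unit_diagonal"` or `"unit_norm"`.
#' @param degeneracy_tol relative residual norm below which a receptor is
#'   declared linearly dependent on its predecessors.
#' @return object of class `orthogonal_basis`: list with `vectors` (matrix,
#'   one column per basis function, signed), `alpha` (upper-triangular
#'   coefficient matrix), `convention`, `observer`.
#' @examples
#' b <- build_basis(load_standard_observer())
#' round(b$alpha, 4)
#' @export
build_basis <- function(obs, convention = c("unit_diagonal", "unit_norm"),
                        degeneracy_tol = 1e-7) {
  stopifnot(inherits(obs, "photoreceptor_set"))
  convention <- match.arg(convention)
  S <- sensitivity_matrix(obs)
  n <- ncol(S)
  step <- obs$grid$step
  E <- matrix(0, nrow(S), n)
  alpha <- diag(n)
  for (j in seq_len(n)) {
    v <- S[, j]
    for (i in seq_len(j - 1)) {
      # modified Gram-Schmidt: project the partially reduced vector
      c_ij <- sum(v * E[, i]) * step / (sum(E[, i]^2) * step)
      if (convention == "unit_norm")
        alpha[i, j] <- sum(S[, j] * E[, i]) * step
      else
        alpha[i, j] <- c_ij
      v <- v - c_ij * E[, i]
    }
    rn <- sqrt(sum(v^2) * step)
    if (rn < degeneracy_tol * sqrt(sum(S[, j]^2) * step))
      stop(sprintf(
        "receptor '%s' is (numerically) linearly dependent on its predecessors",
        obs$names[j]))
    if (convention == "unit_norm") {
      E[, j] <- v / rn
      alpha[j, j] <- rn
      # alpha[i, j] under unit norm uses the final normalized e_i
      for (i in seq_len(j - 1))
        alpha[i, j] <- sum(S[, j] * E[, i]) * step
    } else {
      E[, j] <- v
    }
  }
  colnames(E) <- paste0("e", seq_len(n))
  dimnames(alpha) <- list(paste0("e", seq_len(n)), obs$names)
  structure(list(vectors = E, alpha = alpha, convention = convention,
                 observer = obs),
            class = "orthogonal_basis")
}

#' @export
print.orthogonal_basis <- function(x, ...) {
  cat(sprintf("<orthogonal_basis (%s) over %d receptors>\n",
              x$convention, ncol(x$vectors)))
  print(round(x$alpha, 4))
  invisible(x)
}

## percent-excitation response of each receptor to one unit of each basis
## coefficient: response_matrix[j, i] = excitation of receptor j produced by
## the spectrum e_i, in the flat-white percent convention.  Lower triangular
## because <s_j, e_i> = 0 for i > j.
response_matrix <- function(basis) {
  obs <- basis$observer
  S <- sensitivity_matrix(obs)
  step <- obs$grid$step
  den <- as.numeric(crossprod(S, rep(100, obs$grid$n))) * step
  100 * (crossprod(S, basis$vectors) * step) / den
}

#' Weighted sum of basis vectors
#'
#' Returns the raw signed spectral vector `sum_i w[i] * e_i`; this is NOT an
#' [spd()] because the basis vectors take negative values.  Use [realize()]
#' to validate and convert.
#'
#' @param basis an [build_basis()] result.
#' @param w numeric coefficient vector, one weight per basis function.
#' @return numeric vector on the basis grid (signed).
#' @export
synthesize <- function(basis, w) {
  stopifnot(inherits(basis, "orthogonal_basis"),
            length(w) == ncol(basis$vectors))
  as.numeric(basis$vectors %*% w)
}

#' Validate a coefficient combination as a physical spectrum
#'
#' A projector cannot output negative power, nor exceed its maximum drive
#' (`cap`, in the same percent units as the spectra).  `realize` checks the
#' synthesized spectrum against `0 <= p <= cap` and either returns an
#' [spd()] or throws an error carrying per-wavelength diagnostics
#' (`data.frame` in the condition's `violations` field).
#'
#' @inheritParams synthesize
#' @param cap upper output bound in percent (default 100, the flat-white
#'   drive level).
#' @param tol numerical slack on the bounds.
#' @param label label for the returned spectrum.
#' @export
realize <- function(basis, w, cap = 100, tol = 1e-8, label = "") {
  p <- synthesize(basis, w)
  wl <- wavelengths(basis$observer$grid)
  low <- p < -tol
  high <- p > cap + tol
  if (any(low | high)) {
    bad <- which(low | high)
    viol <- data.frame(wavelength_nm = wl[bad], value = p[bad],
                       bound = ifelse(low[bad], 0, cap))
    cond <- structure(
      class = c("silentsub_realize_error", "error", "condition"),
      list(message = sprintf(
             "spectrum violates [0, %g] bounds at %d wavelength(s) (worst %.4g at %g nm)",
             cap, length(bad), p[bad][which.max(abs(p[bad] - viol$bound))],
             wl[bad][which.max(abs(p[bad] - viol$bound))]),
           call = sys.call(-1), violations = viol))
    stop(cond)
  }
  spd(pmin(pmax(p, 0), cap), basis$observer$grid, label = label)
}

#' Map basis coefficients to percent excitations, and back
#'
#' `coefficients_to_excitations` computes the excitations of the synthesized
#' spectrum under the flat-white percent convention (equivalent to, but
#' cheaper than, `excitations_percent(realize(...))`).
#' `excitations_to_coefficients` inverts the first `n - 1` rows: given the
#' target cone+rod percents it returns the unique `w[1..n-1]` reproducing
#' them, exploiting the triangular structure of the response matrix.
#'
#' @param basis an [build_basis()] result.
#' @param w full coefficient vector.
#' @return named excitation vector (see [excitations_percent()]).
#' @export
coefficients_to_excitations <- function(basis, w) {
  M <- response_matrix(basis)
  out <- as.numeric(M %*% w)
  nm <- basis$observer$names
  nm[nm == "rod"] <- "R"; nm[nm == "ipRGC"] <- "I"
  names(out) <- nm
  out
}

#' @rdname coefficients_to_excitations
#' @param target percent excitations of the first `n - 1` receptors
#'   (L, M, S, rod for the standard observer).
#' @export
excitations_to_coefficients <- function(basis, target) {
  n <- ncol(basis$vectors)
  stopifnot(length(target) == n - 1, all(is.finite(target)))
  M <- response_matrix(basis)
  A <- M[seq_len(n - 1), seq_len(n - 1), drop = FALSE]
  # lower triangular by orthogonality; forward substitution
  as.numeric(forwardsolve(A, as.numeric(target)))
}

#' Feasible ipRGC-excitation interval at fixed cone and rod excitations
#'
#' With the first four coefficients pinned by the target (L, M, S, rod)
#' percents, the spectrum is `q + w5 * e5`; the device bounds
#' `0 <= p <= cap` at each wavelength each cut a half-line or interval out of
#' the `w5` axis, and their intersection maps linearly onto an interval of
#' ipRGC excitation.  This closed form is exact (it is the one-variable
#' linear program solved analytically).
#'
#' @param obs a [photoreceptor_set()] or prebuilt [build_basis()] result.
#' @param target percent excitations for all receptors but the last
#'   (L, M, S, rod order for the standard observer).
#' @param cap upper output bound in percent.
#' @param tol tolerance for detecting active (binding) constraints.
#' @return object of class `feasible_interval`: `i_min`, `i_max`, `width`
#'   (percent ipRGC excitation), `feasible` flag, `omega_interval` (the
#'   underlying `w5` range), `binding_wavelengths` (nm at which an output
#'   bound is active at the endpoints), and `w14` (the pinned coefficients).
#'   Infeasible targets return `feasible = FALSE` and zero width, not an
#'   error.
#' @examples
#' obs <- load_standard_observer()
#' feasible_iprgc_interval(obs, c(47.9, 36.4, 5.86, 14.9))
#' @export
feasible_iprgc_interval <- function(obs, target, cap = 100, tol = 1e-9) {
  stopifnot(cap > 0)
  basis <- if (inherits(obs, "orthogonal_basis")) obs else build_basis(obs)
  n <- ncol(basis$vectors)
  w14 <- excitations_to_coefficients(basis, target)
  q <- as.numeric(basis$vectors[, seq_len(n - 1), drop = FALSE] %*% w14)
  e5 <- basis$vectors[, n]
  lo <- -Inf; hi <- Inf
  pos <- e5 > tol
  neg <- e5 < -tol
  if (any(pos)) {
    lo <- max(lo, max((0 - q[pos]) / e5[pos]))
    hi <- min(hi, min((cap - q[pos]) / e5[pos]))
  }
  if (any(neg)) {
    lo <- max(lo, max((cap - q[neg]) / e5[neg]))
    hi <- min(hi, min((0 - q[neg]) / e5[neg]))
  }
  flat <- !(pos | neg)
  if (any(q[flat] < -tol | q[flat] > cap + tol)) { lo <- Inf; hi <- -Inf }
  M <- response_matrix(basis)
  i_base <- sum(M[n, seq_len(n - 1)] * w14)
  c5 <- M[n, n]  # > 0: <e5, s_n> = <e5, e5> > 0
  wl <- wavelengths(basis$observer$grid)
  if (lo > hi + tol) {
    out <- list(feasible = FALSE, i_min = NA_real_, i_max = NA_real_,
                width = 0, omega_interval = c(NA_real_, NA_real_),
                binding_wavelengths = numeric(0), w14 = w14, basis = basis,
                cap = cap, target = target)
    return(structure(out, class = "feasible_interval"))
  }
  btol <- 1e-6 * cap
  binding <- function(w5) {
    p <- q + w5 * e5
    wl[p < btol | p > cap - btol]
  }
  i_lo <- i_base + c5 * lo
  i_hi <- i_base + c5 * hi
  out <- list(feasible = TRUE,
              i_min = min(i_lo, i_hi), i_max = max(i_lo, i_hi),
              width = abs(i_hi - i_lo),
              omega_interval = c(lo, hi),
              binding_wavelengths = sort(unique(c(binding(lo), binding(hi)))),
              w14 = w14, basis = basis, cap = cap, target = target)
  structure(out, class = "feasible_interval")
}

#' @export
print.feasible_interval <- function(x, ...) {
  if (!x$feasible) {
    cat("<feasible_interval: INFEASIBLE target>\n")
  } else {
    cat(sprintf(
      "<feasible_interval: ipRGC in [%.4g, %.4g] %% (width %.4g %%)>\n",
      x$i_min, x$i_max, x$width))
  }
  invisible(x)
}

#' Design a metameric ipRGC stimulus pair
#'
#' Two spectra sharing the target cone and rod excitations but differing in
#' ipRGC excitation.  With `delta = "max"` the pair sits at the endpoints of
#' the feasible interval (the maximum and minimum metameric ipRGC stimuli);
#' a numeric `delta` yields a pair symmetric about the interval midpoint with
#' exactly that ipRGC difference.
#'
#' @inheritParams feasible_iprgc_interval
#' @param delta `"max"` or a requested ipRGC difference in percent.
#' @return object of class `metamer_pair`: `spectrum_max`, `spectrum_min`
#'   ([spd()]s), `shared` (the common L, M, S, rod percents), `delta_i`, and
#'   `excitations` (2-row matrix of full excitation vectors).
#' @examples
#' obs <- load_standard_observer()
#' pr <- design_metamer_pair(obs, c(47.9, 36.4, 5.86, 14.9), delta = "max")
#' pr$delta_i
#' @export
design_metamer_pair <- function(obs, target, cap = 100, delta = "max") {
  fi <- feasible_iprgc_interval(obs, target, cap)
  if (!fi$feasible)
    stop("target excitations are infeasible under the output bounds")
  basis <- fi$basis
  n <- ncol(basis$vectors)
  c5 <- response_matrix(basis)[n, n]
  if (identical(delta, "max")) {
    w5 <- fi$omega_interval
  } else {
    delta <- as.numeric(delta)
    if (delta < 0) stop("requested delta must be non-negative")
    if (delta > fi$width + 1e-9)
      stop(sprintf(
        "requested ipRGC difference %.4g %% exceeds the achievable maximum %.4g %%",
        delta, fi$width))
    mid <- mean(fi$omega_interval)
    half <- (delta / c5) / 2
    w5 <- c(mid - half, mid + half)
  }
  w_lo <- c(fi$w14, min(w5)); w_hi <- c(fi$w14, max(w5))
  p_min <- realize(basis, w_lo, cap, label = "metamer: min ipRGC")
  p_max <- realize(basis, w_hi, cap, label = "metamer: max ipRGC")
  ex <- rbind(max_i = excitations_percent(p_max, basis$observer),
              min_i = excitations_percent(p_min, basis$observer))
  structure(list(spectrum_max = p_max, spectrum_min = p_min,
                 shared = ex[1, seq_len(n - 1)],
                 delta_i = unname(ex[1, n] - ex[2, n]),
                 excitations = ex, interval = fi),
            class = "metamer_pair")
}

#' @export
print.metamer_pair <- function(x, ...) {
  cat(sprintf("<metamer_pair: delta ipRGC = %.4g %%>\n", x$delta_i))
  print(round(x$excitations, 3))
  invisible(x)
}

## ---- linear programming -------------------------------------------------

## Maximize obj'x over signed x subject to A_ub x <= b_ub, and optionally
## equalities A_eq x = b_eq.  Equality constraints are eliminated by
## substituting x = x_p + N t with N a null-space basis of A_eq; the
## remaining free-variable inequality problem goes to the dual-simplex core
## (see lp-core.R).  The reported value is recomputed from the returned
## solution and the solution is verified against the constraints.
## solved: 1 = optimum, -1 = infeasible, -2 = numerical failure.
lp_max <- function(obj, A_ub, b_ub, A_eq = NULL, b_eq = NULL,
                   feas_tol = 1e-7) {
  N <- NULL
  x_p <- rep(0, length(obj))
  if (!is.null(A_eq)) {
    N <- MASS::Null(t(A_eq))   # columns span {x : A_eq x = 0}
    if (!is.null(b_eq) && any(b_eq != 0)) {
      x_p <- as.numeric(MASS::ginv(A_eq) %*% b_eq)
      if (max(abs(A_eq %*% x_p - b_eq)) > 1e-6)
        return(list(value = NA_real_, solution = x_p, solved = -1L))
    }
    if (NCOL(N) == 0 || length(N) == 0) {
      feasible <- all(A_ub %*% x_p <= b_ub + feas_tol * (1 + abs(b_ub)))
      return(list(value = sum(obj * x_p), solution = x_p,
                  solved = if (feasible) 1L else -1L))
    }
    obj_r <- as.numeric(crossprod(N, obj))
    A_r <- A_ub %*% N
    b_r <- b_ub - as.numeric(A_ub %*% x_p)
  } else {
    obj_r <- obj
    A_r <- A_ub
    b_r <- b_ub
  }
  res <- lp_free_max(obj_r, A_r, b_r)
  if (res$status != 1L)
    return(list(value = NA_real_, solution = x_p,
                solved = if (res$status == -1L) -1L else -2L))
  x <- x_p + if (is.null(N)) res$x else as.numeric(N %*% res$x)
  feasible <- all(A_ub %*% x <= b_ub + feas_tol * (1 + abs(b_ub)))
  list(value = sum(obj * x), solution = x,
       solved = if (feasible) 1L else -2L)
}

#' Maximum metameric ipRGC modulation range of the device
#'
#' Solves the linear program: maximize `I(p1) - I(p2)` over pairs of spectra
#' in the span of the five sensitivities with `0 <= p <= cap` at every
#' wavelength, where the pair shares the coefficients of the first four
#' basis functions (cone + rod matching) or only the first three
#' (`match_rod = FALSE`, cone matching only).  The optimum is the widest
#' ipRGC-only modulation the bounded-output device can produce anywhere in
#' its gamut.
#'
#' @param obs a [photoreceptor_set()] or [build_basis()] result.
#' @param match_rod require equal rod excitation in the pair (default TRUE).
#' @param cap upper output bound in percent.
#' @return object of class `metamer_range`: `width` (percent ipRGC), `pair`
#'   (list of the two [spd()]s), `excitations` (2-row matrix), `solved`.
#' @export
max_metamer_range <- function(obs, match_rod = TRUE, cap = 100) {
  basis <- if (inherits(obs, "orthogonal_basis")) obs else build_basis(obs)
  E <- basis$vectors
  n <- ncol(E)
  M <- response_matrix(basis)
  ns <- if (match_rod) n - 1 else n - 2
  free <- seq(ns + 1, n)
  nf <- length(free)
  nv <- ns + 2 * nf
  obj <- numeric(nv)
  obj[ns + seq_len(nf)] <- M[n, free]
  obj[ns + nf + seq_len(nf)] <- -M[n, free]
  nwl <- nrow(E)
  A_ub <- matrix(0, 4 * nwl, nv)
  b_ub <- numeric(4 * nwl)
  for (memb in 1:2) {
    block <- matrix(0, nwl, nv)
    block[, seq_len(ns)] <- E[, seq_len(ns), drop = FALSE]
    block[, ns + (memb - 1) * nf + seq_len(nf)] <- E[, free, drop = FALSE]
    r0 <- (memb - 1) * 2 * nwl
    A_ub[r0 + seq_len(nwl), ] <- block          # p <= cap
    b_ub[r0 + seq_len(nwl)] <- cap
    A_ub[r0 + nwl + seq_len(nwl), ] <- -block   # -p <= 0
  }
  res <- lp_max(obj, A_ub, b_ub)
  if (res$solved != 1)
    stop(sprintf("LP solver failed (status %d)", res$solved))
  x <- res$solution
  w_shared <- x[seq_len(ns)]
  w1 <- c(w_shared, x[ns + seq_len(nf)])
  w2 <- c(w_shared, x[ns + nf + seq_len(nf)])
  p1 <- realize(basis, w1, cap, tol = 1e-6, label = "max ipRGC member")
  p2 <- realize(basis, w2, cap, tol = 1e-6, label = "min ipRGC member")
  ex <- rbind(max_i = excitations_percent(p1, basis$observer),
              min_i = excitations_percent(p2, basis$observer))
  structure(list(width = res$value, pair = list(p1, p2), excitations = ex,
                 match_rod = match_rod, cap = cap, solved = res$solved),
            class = "metamer_range")
}

#' @export
print.metamer_range <- function(x, ...) {
  cat(sprintf(
    "<metamer_range: max delta ipRGC = %.4g %% (%s rod matching, cap %g)>\n",
    x$width, if (x$match_rod) "with" else "without", x$cap))
  invisible(x)
}

#' Pentameric metamer pair
#'
#' Two spectra whose excitations agree for ALL receptors (including ipRGC),
#' differing only within the null space of the receptor response map.  The
#' perturbation `d` satisfies `<d, s_k> = 0` for every receptor and the pair
#' is `base +/- d/2`, subject to `0 <= p <= cap`.  The spectral L1 separation
#' `sum |d|` is maximized by iterated sign-linearization: for a fixed sign
#' pattern the objective is linear and the problem is an LP over the
#' null-space coordinates; the sign pattern is then refreshed from the
#' solution until it stabilizes (a deterministic ascent; each iteration
#' cannot decrease the objective).
#'
#' @param obs a [photoreceptor_set()].
#' @param base an [spd()] on the observer grid: the spectrum around which the
#'   pair is built.
#' @param cap upper output bound in percent.
#' @param max_iter sign-refresh iterations.
#' @return object of class `pentamer_pair`: `spectrum_a`, `spectrum_b`,
#'   `l1_difference` (the achieved `sum |d| * step`), `excitations`.
#'   A base at the bounds yields a zero-width pair, not an error.
#' @export
pentamer_pair <- function(obs, base, cap = 100, max_iter = 6) {
  stopifnot(inherits(obs, "photoreceptor_set"), inherits(base, "spd"))
  check_same_grid(obs$grid, base$grid)
  S <- sensitivity_matrix(obs)
  nwl <- nrow(S)
  if (nwl <= ncol(S))
    stop("grid must have more samples than receptors for a non-trivial null space")
  N <- MASS::Null(S)   # columns orthonormal, t(S) %*% N = 0
  if (ncol(N) == 0) stop("receptor response map has no null space")
  half <- N / 2
  A_ub <- rbind(half, -half)            # base + Nz/2 <= cap ; -(base + Nz/2) <= 0
  b_ub <- c(cap - base$values, base$values)
  if (any(b_ub < 0)) stop("base spectrum violates the output bounds")
  s_pat <- sign(N[, 1])
  s_pat[s_pat == 0] <- 1
  best <- NULL
  for (it in seq_len(max_iter)) {
    obj <- as.numeric(crossprod(N, s_pat))
    res <- lp_max(obj, A_ub, b_ub)
    if (res$solved != 1)
      stop(sprintf("LP solver failed (status %d)", res$solved))
    d <- as.numeric(N %*% res$solution)
    l1 <- sum(abs(d)) * obs$grid$step
    if (!is.null(best) && l1 <= best$l1 + 1e-9) break
    best <- list(d = d, l1 = l1)
    s_new <- sign(d); s_new[s_new == 0] <- 1
    if (all(s_new == s_pat)) break
    s_pat <- s_new
  }
  d <- best$d
  pa <- spd(pmin(pmax(base$values + d / 2, 0), cap), base$grid,
            label = "pentamer A")
  pb <- spd(pmin(pmax(base$values - d / 2, 0), cap), base$grid,
            label = "pentamer B")
  ex <- rbind(a = excitations_percent(pa, obs),
              b = excitations_percent(pb, obs))
  structure(list(spectrum_a = pa, spectrum_b = pb,
                 l1_difference = best$l1, excitations = ex),
            class = "pentamer_pair")
}

#' @export
print.pentamer_pair <- function(x, ...) {
  cat(sprintf("<pentamer_pair: spectral L1 separation %.4g>\n",
              x$l1_difference))
  invisible(x)
}

#' Compare a computed coefficient matrix against reference values
#'
#' Entry-by-entry comparison of the upper-triangular coefficients of a
#' unit-diagonal basis against a reference matrix (for example a published
#' tabulation), reporting the signed difference and whether each entry falls
#' within the stated tolerance.  Reference-table provenance differences show
#' up here first, so the report is the package's canonical way to surface
#' them rather than hide them.
#'
#' @param basis an [build_basis()] result (unit-diagonal convention).
#' @param reference upper-triangular reference matrix of the same size.
#' @param tolerance per-entry absolute tolerance.
#' @return data.frame with one row per off-diagonal upper-triangular entry:
#'   `row`, `col`, `computed`, `reference`, `difference`, `within`.
#' @export
compare_alpha <- function(basis, reference, tolerance = 0.05) {
  stopifnot(inherits(basis, "orthogonal_basis"))
  a <- basis$alpha
  stopifnot(all(dim(reference) == dim(a)))
  idx <- which(upper.tri(a), arr.ind = TRUE)
  idx <- idx[order(idx[, "col"], idx[, "row"]), , drop = FALSE]
  out <- data.frame(row = idx[, "row"], col = idx[, "col"],
                    computed = a[idx], reference = reference[idx],
                    difference = a[idx] - reference[idx])
  out$within <- abs(out$difference) <= tolerance
  out
}
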