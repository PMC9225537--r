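## Chromaticity-plane scan of the metameric ipRGC modulation gamut.

## XYZ response of each basis vector, normalized so flat-100 white has Y=100
basis_xyz_responses <- function(basis, cmf) {
  grid <- basis$observer$grid
  if (!grids_equal(cmf$grid, grid)) {
    rs <- function(v) resample_values(v, cmf$grid, grid)
    cmf <- cmf_table(rs(cmf$xbar), rs(cmf$ybar), rs(cmf$zbar), grid,
                     cmf$field_size_deg, cmf$provenance)
  }
  k <- 100 / (sum(rep(100, grid$n) * cmf$ybar) * grid$step)
  list(X = k * as.numeric(crossprod(basis$vectors, cmf$xbar)) * grid$step,
       Y = k * as.numeric(crossprod(basis$vectors, cmf$ybar)) * grid$step,
       Z = k * as.numeric(crossprod(basis$vectors, cmf$zbar)) * grid$step,
       cmf = cmf)
}

#' Spectral locus polygon of a CMF table
#'
#' Chromaticities of the monochromatic stimuli at each grid wavelength, in
#' wavelength order (the polygon closes along the purple line).  Wavelengths
#' where the CMFs vanish are dropped.
#'
#' @param cmf a [cmf_table()].
#' @return data.frame with columns `wavelength_nm, x, y`.
#' @export
spectral_locus <- function(cmf) {
  s <- cmf$xbar + cmf$ybar + cmf$zbar
  keep <- s > 1e-7 * max(s)
  data.frame(wavelength_nm = wavelengths(cmf$grid)[keep],
             x = cmf$xbar[keep] / s[keep],
             y = cmf$ybar[keep] / s[keep])
}

#' Scan chromaticity space for the metameric ipRGC modulation width
#'
#' For each cell of an xy chromaticity raster inside the spectral locus,
#' solves the linear program: maximize `I(p1) - I(p2)` over spectrum pairs in
#' the five-sensitivity span with shared cone+rod coefficients,
#' `0 <= p <= cap` per wavelength, and `p1` constrained to the cell's
#' chromaticity through the two linear constraints
#' `X - x (X + Y + Z) = 0`, `Y - y (X + Y + Z) = 0`.  Because the bundled
#' CMFs are a linear transform of the cone fundamentals, `p2` (which matches
#' `p1` in L, M, S) automatically shares its chromaticity; if a user-supplied
#' CMF table is not in the cone-fundamental span the constraint is applied to
#' both members.
#'
#' @param obs a [photoreceptor_set()] or [build_basis()] result.
#' @param cmf a [cmf_table()]; default the bundled 2-degree table.
#' @param resolution xy cell size, in (0.001, 0.05).
#' @param cap upper output bound in percent.
#' @param xlim,ylim scan window.
#' @param constrain_both force the chromaticity constraint on both members.
#' @return data.frame of class `gamut_cells`, row-major in x then y, with
#'   columns `x, y, feasible, max_width_pct, Y_max, a_star, b_star` and
#'   attributes `resolution`, `cap`, `white_xy`.
#' @export
scan_gamut <- function(obs, cmf = NULL, resolution = 0.005, cap = 100,
                       xlim = c(0, 0.8), ylim = c(0, 0.9),
                       constrain_both = FALSE) {
  stopifnot(resolution > 0.001, resolution < 0.05)
  basis <- if (inherits(obs, "orthogonal_basis")) obs else build_basis(obs)
  n <- ncol(basis$vectors)
  if (is.null(cmf)) cmf <- load_standard_cmf(basis$observer$grid)
  resp <- basis_xyz_responses(basis, cmf)
  cmf <- resp$cmf
  E <- basis$vectors
  M <- response_matrix(basis)
  ns <- n - 1
  nv <- ns + 2
  obj <- numeric(nv)
  obj[ns + 1] <- M[n, n]
  obj[ns + 2] <- -M[n, n]
  nwl <- nrow(E)
  A_ub <- matrix(0, 4 * nwl, nv)
  b_ub <- numeric(4 * nwl)
  for (memb in 1:2) {
    block <- matrix(0, nwl, nv)
    block[, seq_len(ns)] <- E[, seq_len(ns)]
    block[, ns + memb] <- E[, n]
    r0 <- (memb - 1) * 2 * nwl
    A_ub[r0 + seq_len(nwl), ] <- block
    b_ub[r0 + seq_len(nwl)] <- cap
    A_ub[r0 + nwl + seq_len(nwl), ] <- -block
  }
  locus <- spectral_locus(cmf)
  wx <- xy_from_xyz(xyz_from_spectrum(flat_white(basis$observer$grid), cmf))
  xs <- seq(xlim[1] + resolution / 2, xlim[2], by = resolution)
  ys <- seq(ylim[1] + resolution / 2, ylim[2], by = resolution)
  cells <- expand.grid(y = ys, x = xs)[, c("x", "y")]  # row-major in x then y
  inside <- sp::point.in.polygon(cells$x, cells$y, locus$x, locus$y) > 0
  res_rows <- lapply(seq_len(nrow(cells)), function(i) {
    x <- cells$x[i]; y <- cells$y[i]
    if (!inside[i])
      return(c(feasible = 0, width = 0, Ym = NA, a = NA, b = NA))
    # chromaticity equalities on member 1 (columns 1..ns and ns+1)
    cx <- resp$X - x * (resp$X + resp$Y + resp$Z)
    cy <- resp$Y - y * (resp$X + resp$Y + resp$Z)
    row1 <- numeric(nv); row1[seq_len(ns)] <- cx[seq_len(ns)]
    row1[ns + 1] <- cx[n]
    row2 <- numeric(nv); row2[seq_len(ns)] <- cy[seq_len(ns)]
    row2[ns + 1] <- cy[n]
    A_eq <- rbind(row1, row2)
    if (constrain_both) {
      row3 <- numeric(nv); row3[seq_len(ns)] <- cx[seq_len(ns)]
      row3[ns + 2] <- cx[n]
      row4 <- numeric(nv); row4[seq_len(ns)] <- cy[seq_len(ns)]
      row4[ns + 2] <- cy[n]
      A_eq <- rbind(A_eq, row3, row4)
    }
    r <- tryCatch(lp_max(obj, A_ub, b_ub, A_eq),
                  error = function(e) list(solved = -1))
    if (r$solved < 0 || r$value < -1e-6)
      return(c(feasible = 0, width = 0, Ym = NA, a = NA, b = NA))
    w1 <- c(r$solution[seq_len(ns)], r$solution[ns + 1])
    xyz <- c(X = sum(resp$X * w1), Y = sum(resp$Y * w1), Z = sum(resp$Z * w1))
    lab <- lab_from_xyz(xyz, c(X = 100 * sum(cmf$xbar) / sum(cmf$ybar),
                               Y = 100,
                               Z = 100 * sum(cmf$zbar) / sum(cmf$ybar)))
    c(feasible = 1, width = max(r$value, 0), Ym = unname(xyz["Y"]),
      a = unname(lab["a_star"]), b = unname(lab["b_star"]))
  })
  m <- do.call(rbind, res_rows)
  out <- data.frame(x = cells$x, y = cells$y,
                    feasible = m[, "feasible"] > 0,
                    max_width_pct = m[, "width"],
                    Y_max = m[, "Ym"], a_star = m[, "a"], b_star = m[, "b"])
  attr(out, "resolution") <- resolution
  attr(out, "cap") <- cap
  attr(out, "white_xy") <- wx
  class(out) <- c("gamut_cells", class(out))
  out
}

#' Band classification of scanned cells
#'
#' Adds the band label `floor(max_width)` clipped to `[0, 4]` (half-open
#' bands: a width of exactly 1 falls in band 1) and attaches per-band counts.
#'
#' @param cells a [scan_gamut()] result.
#' @return the cells with a `band` column (NA for infeasible cells) and a
#'   `band_counts` attribute.
#' @export
classify_bands <- function(cells) {
  stopifnot(inherits(cells, "gamut_cells"))
  band <- ifelse(cells$feasible, pmin(floor(cells$max_width_pct), 4), NA)
  cells$band <- band
  attr(cells, "band_counts") <- table(factor(band, levels = 0:4))
  cells
}

#' Select hue-group stimulus points from a gamut scan
#'
#' Along each hue direction (angle in the a*b* plane, measured from the
#' white point), picks for each target modulation width the most saturated
#' (highest-chroma) feasible cell whose achievable width is at least the
#' target -- a greedy outward search emulating the selection of experiment
#' chromaticities from white towards the gamut edge.
#'
#' @param cells a [scan_gamut()] result.
#' @param hue_angles direction centers in degrees; default six groups at
#'   60-degree spacing.
#' @param targets required modulation widths in percent.
#' @return data.frame of class `stimulus_points` with one row per
#'   (group, target); unreachable targets have NA coordinates and are listed
#'   in the `gaps` attribute.
#' @export
select_stimulus_points <- function(cells, hue_angles = seq(0, 300, by = 60),
                                   targets = c(1, 2, 3, 4)) {
  stopifnot(inherits(cells, "gamut_cells"))
  ok <- cells$feasible & is.finite(cells$a_star) & is.finite(cells$b_star)
  cc <- cells[ok, ]
  hue <- (atan2(cc$b_star, cc$a_star) * 180 / pi) %% 360
  chroma <- sqrt(cc$a_star^2 + cc$b_star^2)
  half <- if (length(hue_angles) > 1)
    min(diff(sort(hue_angles))) / 2 else 180
  rows <- list()
  for (g in seq_along(hue_angles)) {
    ang <- hue_angles[g] %% 360
    d <- pmin(abs(hue - ang), 360 - abs(hue - ang))
    bin <- d <= half
    for (tg in targets) {
      cand <- which(bin & cc$max_width_pct >= tg)
      if (length(cand) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          group = g, hue_angle = ang, target_pct = tg,
          x = NA_real_, y = NA_real_, max_width_pct = NA_real_,
          chroma = NA_real_)
      } else {
        best <- cand[order(-chroma[cand], cc$x[cand], cc$y[cand])][1]
        rows[[length(rows) + 1]] <- data.frame(
          group = g, hue_angle = ang, target_pct = tg,
          x = cc$x[best], y = cc$y[best],
          max_width_pct = cc$max_width_pct[best], chroma = chroma[best])
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "gaps") <- out[is.na(out$x), c("group", "target_pct")]
  class(out) <- c("stimulus_points", class(out))
  out
}
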