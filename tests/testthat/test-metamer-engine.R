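test_that("the orthogonal basis satisfies its defining identities", {
  b <- std_basis()
  E <- b$vectors
  step <- b$observer$grid$step
  G <- crossprod(E) * step
  # pairwise orthogonality, relative to the vector norms
  for (i in 1:4) for (j in (i + 1):5)
    expect_lt(abs(G[i, j]) / sqrt(G[i, i] * G[j, j]), 1e-9)
  # unit diagonal, upper triangular
  expect_equal(diag(b$alpha), rep(1, 5))
  expect_equal(b$alpha[lower.tri(b$alpha)], rep(0, 10))
  # reconstruction: s_j = sum_i alpha[i, j] e_i
  S <- sapply(b$observer$sensitivities, function(s) s$values)
  expect_equal(E %*% b$alpha, S, ignore_attr = TRUE, tolerance = 1e-10)
  # e1 is the L-cone sensitivity itself
  expect_equal(E[, 1], S[, 1], ignore_attr = TRUE)
})

test_that("an already-orthogonal observer yields the identity coefficient matrix", {
  dobs <- disjoint_observer(n = 4)
  b <- build_basis(dobs)
  expect_equal(b$alpha, diag(4), ignore_attr = TRUE, tolerance = 1e-12)
  S <- sapply(dobs$sensitivities, function(s) s$values)
  expect_equal(b$vectors, S, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("Gram-Schmidt agrees with a QR-factorization oracle", {
  # independent route: QR of the sensitivity matrix; rescaling Q by the
  # diagonal of R gives the unit-diagonal residual vectors, and
  # R[i, j] / R[i, i] the coefficient matrix
  obs <- synthetic_observer(3, c(450, 520, 600), c(0.05, 0.07, 0.06),
                            seed = 5)
  b <- build_basis(obs)
  S <- sapply(obs$sensitivities, function(s) s$values)
  qrd <- qr(S)
  R <- qr.R(qrd); Q <- qr.Q(qrd)
  sgn <- sign(diag(R))
  R <- diag(sgn) %*% R; Q <- Q %*% diag(sgn)
  alpha_oracle <- R / diag(R)[row(R)]
  alpha_oracle[lower.tri(alpha_oracle)] <- 0
  E_oracle <- Q %*% diag(diag(R))
  expect_equal(b$alpha, alpha_oracle, ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(b$vectors, E_oracle, ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("degenerate sensitivity sets are reported by receptor", {
  g <- default_grid
  s1 <- sensitivity_fn(exp(-0.5 * ((wavelengths(g) - 500) / 40)^2), g, "A")
  s2 <- sensitivity_fn(0.5 * s1$values, g, "B", normalize = FALSE)
  expect_error(photoreceptor_set(list(s1, s2)), "dependent")
})

test_that("synthesize and realize enforce the device bounds", {
  b <- std_basis()
  expect_equal(synthesize(b, rep(0, 5)), rep(0, 81))
  # e1 = L-cone sensitivity is non-negative: scaling to peak 50 realizes
  w1 <- c(50 / max(b$vectors[, 1]), 0, 0, 0, 0)
  p <- realize(b, w1)
  expect_s3_class(p, "spd")
  expect_equal(max(p$values), 50)
  # large positive e5 weight drives some wavelength negative
  err <- tryCatch(realize(b, c(w1[1], 0, 0, 0, 40)), error = identity)
  expect_s3_class(err, "silentsub_realize_error")
  expect_true(nrow(err$violations) > 0)
  expect_true(all(c("wavelength_nm", "value", "bound") %in%
                    names(err$violations)))
})

test_that("coefficient and excitation maps are mutually consistent", {
  b <- std_basis()
  set.seed(10)
  for (k in 1:5) {
    # start from a realizable spectrum so the coefficients are feasible
    p <- random_smooth_spd(seed = k + 20)
    ex <- excitations_percent(p, std_obs())
    w14 <- excitations_to_coefficients(b, ex[1:4])
    # round trip to 1e-10
    expect_equal(coefficients_to_excitations(b, c(w14, 0))[1:4], ex[1:4],
                 tolerance = 1e-10)
    # the two computation paths agree: direct excitation vs coefficient map
    w <- c(w14, rnorm(1))
    pr <- try(realize(b, w), silent = TRUE)
    if (!inherits(pr, "try-error"))
      expect_equal(excitations_percent(pr, std_obs()),
                   coefficients_to_excitations(b, w), tolerance = 1e-9)
  }
})

test_that("only the melanopsin excitation depends on the last coefficient", {
  b <- std_basis()
  set.seed(2)
  w <- rnorm(5)
  for (d in c(-2, 0.5, 3)) {
    e0 <- coefficients_to_excitations(b, w)
    e1 <- coefficients_to_excitations(b, w + c(0, 0, 0, 0, d))
    expect_equal(e1[1:4], e0[1:4], tolerance = 1e-12)
    # I changes linearly in the perturbation
    e2 <- coefficients_to_excitations(b, w + c(0, 0, 0, 0, 2 * d))
    expect_equal(e2[5] - e0[5], 2 * (e1[5] - e0[5]), tolerance = 1e-9)
  }
})

test_that("the flat white decomposes to the all-100 excitation vector", {
  b <- std_basis()
  pw <- flat_white(b$observer$grid)
  step <- b$observer$grid$step
  w <- as.numeric(crossprod(b$vectors, pw$values) /
                    colSums(b$vectors^2))
  expect_equal(unname(coefficients_to_excitations(b, w)), rep(100, 5),
               tolerance = 1e-8)
})

test_that("the feasible interval matches a brute-force scan", {
  obs <- std_obs()
  b <- std_basis()
  targets <- list(c(47.9, 36.4, 5.86, 14.9),
                  c(44.2, 38.2, 49.1, 46.9),
                  c(40, 40, 30, 35))
  for (target in targets) {
    fi <- feasible_iprgc_interval(obs, target)
    expect_true(fi$feasible)
    # brute force over a fine omega5 grid checking bounds per wavelength
    q <- as.numeric(b$vectors[, 1:4] %*% fi$w14)
    e5 <- b$vectors[, 5]
    w5g <- seq(fi$omega_interval[1] - 2, fi$omega_interval[2] + 2,
               length.out = 10000)
    ok <- vapply(w5g, function(w5) {
      pv <- q + w5 * e5
      all(pv >= -1e-9) && all(pv <= 100 + 1e-9)
    }, logical(1))
    Mrow <- silentsub:::response_matrix(b)[5, ]
    i_vals <- sum(Mrow[1:4] * fi$w14) + Mrow[5] * w5g[ok]
    res <- diff(range(w5g)) / 9999 * Mrow[5]
    expect_lt(abs(min(i_vals) - fi$i_min), res * 2)
    expect_lt(abs(max(i_vals) - fi$i_max), res * 2)
  }
})

test_that("the closed-form interval equals an explicit linear program", {
  # independent route: LP over all five coefficients with the four target
  # excitations imposed as (inhomogeneous) equality constraints and the
  # per-wavelength output bounds as inequalities
  obs <- std_obs()
  b <- std_basis()
  M <- silentsub:::response_matrix(b)
  E <- b$vectors
  A_ub <- rbind(E, -E)
  b_ub <- c(rep(100, 81), rep(0, 81))
  A_eq <- M[1:4, ]
  for (seed in 1:100) {
    p <- random_smooth_spd(seed = seed + 2000)
    target <- unname(excitations_percent(p, obs)[1:4])
    fi <- feasible_iprgc_interval(obs, target)
    up <- silentsub:::lp_max(M[5, ], A_ub, b_ub, A_eq, target)
    lo <- silentsub:::lp_max(-M[5, ], A_ub, b_ub, A_eq, target)
    if (fi$feasible) {
      expect_equal(up$solved, 1L)
      expect_equal(lo$solved, 1L)
      expect_equal(sum(M[5, ] * up$solution), fi$i_max, tolerance = 1e-9)
      expect_equal(sum(M[5, ] * lo$solution), fi$i_min, tolerance = 1e-9)
    } else {
      expect_true(up$solved != 1L)
    }
  }
})

test_that("the feasible interval is independent of the basis convention", {
  obs <- std_obs()
  b_ud <- build_basis(obs, "unit_diagonal")
  b_un <- build_basis(obs, "unit_norm")
  # unit-norm basis vectors have unit norm under the step-weighted product
  expect_equal(unname(colSums(b_un$vectors^2)) * obs$grid$step, rep(1, 5))
  for (seed in c(4, 31, 77)) {
    target <- excitations_percent(random_smooth_spd(seed = seed), obs)[1:4]
    f1 <- feasible_iprgc_interval(b_ud, target)
    f2 <- feasible_iprgc_interval(b_un, target)
    expect_equal(f1$i_min, f2$i_min, tolerance = 1e-8)
    expect_equal(f1$i_max, f2$i_max, tolerance = 1e-8)
  }
})

test_that("targets whose only witnesses leave the spectral span are infeasible", {
  # the flat reference white is NOT in the span of the five sensitivities:
  # reproducing its cone+rod excitations with an in-span spectrum under the
  # cap is impossible, and the interval reports that rather than erroring
  obs <- std_obs()
  fi <- feasible_iprgc_interval(obs, c(100, 100, 100, 100))
  expect_false(fi$feasible)
  expect_equal(fi$width, 0)
  # an in-span witness, by contrast, always lies inside its own interval
  b <- std_basis()
  w <- c(silentsub:::excitations_to_coefficients(b, c(40, 40, 30, 35)), 0)
  p <- realize(b, w)
  ex <- excitations_percent(p, obs)
  fi2 <- feasible_iprgc_interval(obs, ex[1:4])
  expect_true(fi2$feasible)
  expect_gte(ex[5], fi2$i_min - 1e-8)
  expect_lte(ex[5], fi2$i_max + 1e-8)
})

test_that("widening the output cap never shrinks the feasible interval", {
  obs <- std_obs()
  for (seed in c(1, 5, 8, 12)) {
    target <- excitations_percent(random_smooth_spd(seed = seed), obs)[1:4]
    f50 <- feasible_iprgc_interval(obs, target, cap = 50)
    f100 <- feasible_iprgc_interval(obs, target, cap = 100)
    f200 <- feasible_iprgc_interval(obs, target, cap = 200)
    # feasibility is monotone in the cap
    expect_true(f100$feasible >= f50$feasible)
    expect_true(f200$feasible >= f100$feasible)
    if (f50$feasible && f100$feasible) {
      expect_lte(f100$i_min, f50$i_min + 1e-9)
      expect_gte(f100$i_max, f50$i_max - 1e-9)
    }
    if (f100$feasible && f200$feasible) {
      expect_lte(f200$i_min, f100$i_min + 1e-9)
      expect_gte(f200$i_max, f100$i_max - 1e-9)
    }
  }
})

test_that("metamer pairs share cone and rod excitations exactly", {
  obs <- std_obs()
  target <- c(47.9, 36.4, 5.86, 14.9)
  pr <- design_metamer_pair(obs, target, delta = "max")
  expect_equal(pr$excitations[1, 1:4], pr$excitations[2, 1:4],
               tolerance = 1e-8)
  expect_gte(pr$delta_i, 0)
  # zero-delta pair collapses to the midpoint spectrum
  pr0 <- design_metamer_pair(obs, target, delta = 0)
  expect_equal(pr0$spectrum_max$values, pr0$spectrum_min$values)
  # requesting more than the capacity is an informative error
  fi <- feasible_iprgc_interval(obs, target)
  expect_error(design_metamer_pair(obs, target, delta = fi$width + 1),
               "achievable maximum")
})

test_that("maximal modulation relaxes when rod matching is dropped", {
  obs <- std_obs()
  m_rod <- max_metamer_range(obs, match_rod = TRUE)
  m_free <- max_metamer_range(obs, match_rod = FALSE)
  expect_gte(m_free$width, m_rod$width - 1e-9)
  # the achieving pair respects the matching constraints
  expect_equal(m_rod$excitations[1, 1:4], m_rod$excitations[2, 1:4],
               tolerance = 1e-6)
  expect_equal(m_free$excitations[1, 1:3], m_free$excitations[2, 1:3],
               tolerance = 1e-6)
})

test_that("maximal modulation matches the closed form for a separable observer", {
  # fifth receptor disjoint from (hence orthogonal to) the first four:
  # e5 equals the sensitivity itself, the shared coefficients do not
  # interact, and the optimum is cap * <s5, s5> / (max(s5) * <pw1, s5>)
  # in percent units with pw the flat-100 white
  dobs <- disjoint_observer(n = 5)
  m <- max_metamer_range(dobs, match_rod = TRUE)
  s5 <- dobs$sensitivities[[5]]$values
  g <- dobs$grid
  width_closed <- 100 * (100 / max(s5)) * inner_product(s5, s5, g) /
    (100 * inner_product(rep(1, g$n), s5, g))
  expect_equal(m$width, width_closed, tolerance = 1e-6)
})

test_that("pentameric pairs match all five excitations with nonzero spectral contrast", {
  obs <- std_obs()
  pp <- pentamer_pair(obs, flat_white(obs$grid, 50))
  expect_equal(pp$excitations[1, ], pp$excitations[2, ], tolerance = 1e-8)
  expect_gt(pp$l1_difference, 0)
  expect_gt(max(abs(pp$spectrum_a$values - pp$spectrum_b$values)), 1)
  # base at the cap leaves no room: zero-width result, not an error
  pp100 <- pentamer_pair(obs, flat_white(obs$grid, 100))
  expect_lt(pp100$l1_difference, 1e-6)
})
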