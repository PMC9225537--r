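## Dense linear programming for the spectral design problems.
##
## Every LP in this package has a handful of free variables (basis
## coefficients) against hundreds of per-wavelength bound constraints:
##   maximize c'x  subject to  A x <= b,  x unrestricted in sign,
## with ncol(A) <= ~8 and nrow(A) ~ 100-400.  The textbook way to solve this
## shape is the revised simplex method applied to the dual
##   minimize b'y  subject to  A'y = c,  y >= 0,
## whose basis has the size of the primal variable count, so every pivot is
## a small dense solve.  Bland's rule guarantees termination on the heavily
## degenerate vertices these bound structures produce.  The primal solution
## is recovered from the active rows of the optimal dual basis and verified
## against the constraints and the duality gap.

## two-phase revised simplex for: min cost'z  s.t.  M z = rhs, z >= 0
## M is n_eq x n_var with n_eq small.  Returns z, basis, status.
simplex_eqform <- function(M, rhs, cost, tol = 1e-9, max_iter = 20000L) {
  n_eq <- nrow(M)
  n_var <- ncol(M)
  # flip rows so rhs >= 0, then append artificial identity columns
  flip <- rhs < 0
  M[flip, ] <- -M[flip, , drop = FALSE]
  rhs[flip] <- -rhs[flip]
  Mfull <- cbind(M, diag(n_eq))
  art <- n_var + seq_len(n_eq)
  basis <- art
  phase <- 1L
  cost1 <- c(rep(0, n_var), rep(1, n_eq))
  cost2 <- c(cost, rep(0, n_eq))
  cur_cost <- cost1
  scale <- max(1, abs(rhs))
  for (iter in seq_len(max_iter)) {
    Bm <- Mfull[, basis, drop = FALSE]
    xB <- tryCatch(solve(Bm, rhs), error = function(e) NULL)
    if (is.null(xB)) return(list(status = -2L))
    zdual <- tryCatch(solve(t(Bm), cur_cost[basis]),
                      error = function(e) NULL)
    if (is.null(zdual)) return(list(status = -2L))
    red <- cur_cost - as.numeric(zdual %*% Mfull)
    red[basis] <- 0
    if (phase == 2L) red[art] <- Inf   # artificials never re-enter
    cand <- which(red < -tol * scale)
    if (length(cand) == 0) {
      if (phase == 1L) {
        obj1 <- sum(cur_cost[basis] * xB)
        if (obj1 > 1e-7 * scale) return(list(status = -1L))  # infeasible
        phase <- 2L
        cur_cost <- cost2
        next
      }
      z <- numeric(n_var + n_eq)
      z[basis] <- xB
      return(list(status = 1L, z = z[seq_len(n_var)], basis = basis,
                  value = sum(cost * z[seq_len(n_var)])))
    }
    enter <- min(cand)            # Bland's rule
    d <- solve(Bm, Mfull[, enter])
    pos <- which(d > tol)
    if (length(pos) == 0) {
      if (phase == 1L) return(list(status = -2L))
      return(list(status = 2L))   # dual unbounded -> primal infeasible
    }
    ratios <- xB[pos] / d[pos]
    rmin <- min(ratios)
    leave_cand <- pos[ratios <= rmin + tol * (1 + abs(rmin))]
    leave <- leave_cand[which.min(basis[leave_cand])]  # Bland tie-break
    basis[leave] <- enter
  }
  list(status = -2L)
}

## maximize c'x s.t. A x <= b with x free, via the dual; returns the primal
## optimum and an exact-arithmetic-style recovery of x from the active set
lp_free_max <- function(c_obj, A, b, tol = 1e-9) {
  n <- length(c_obj)
  m <- nrow(A)
  if (all(abs(c_obj) < tol)) {
    # any feasible point will do: use least-squares center of the near-active
    # system; fall back to 0 if feasible
    x0 <- rep(0, n)
    if (all(A %*% x0 <= b + tol * (1 + abs(b))))
      return(list(status = 1L, x = x0, value = 0))
  }
  res <- simplex_eqform(t(A), c_obj, b)
  if (res$status == -1L) {
    # dual infeasible: primal unbounded (for our problems this indicates a
    # modelling error) -- report as failure
    return(list(status = -3L))
  }
  if (res$status == 2L) return(list(status = -1L))  # primal infeasible
  if (res$status != 1L) return(list(status = -2L))
  y <- res$z
  active <- which(y > tol)
  # the optimal dual basis marks at most n active primal constraints
  act <- res$basis[res$basis <= m]
  act <- sort(unique(c(act, active)))
  if (length(act) == 0) return(list(status = -2L))
  Aact <- A[act, , drop = FALSE]
  x <- tryCatch(as.numeric(MASS::ginv(Aact) %*% b[act]),
                error = function(e) NULL)
  if (is.null(x)) return(list(status = -2L))
  dual_val <- sum(b * y)
  feas <- all(A %*% x <= b + 1e-7 * (1 + abs(b)))
  gap <- abs(sum(c_obj * x) - dual_val) / (1 + abs(dual_val))
  if (!feas || gap > 1e-6) {
    # degenerate recovery: re-solve the active set including all rows the
    # dual prices as binding
    sl <- b - as.numeric(A %*% x)
    act2 <- sort(unique(c(act, which(sl < 1e-6 * (1 + abs(b))))))
    x2 <- tryCatch(as.numeric(MASS::ginv(A[act2, , drop = FALSE]) %*%
                                b[act2]), error = function(e) NULL)
    if (!is.null(x2) &&
        all(A %*% x2 <= b + 1e-7 * (1 + abs(b))) &&
        abs(sum(c_obj * x2) - dual_val) / (1 + abs(dual_val)) <= 1e-6) {
      x <- x2
    } else {
      return(list(status = -2L))
    }
  }
  list(status = 1L, x = x, value = dual_val)
}
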