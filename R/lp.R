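# Linear-programming engine for the FBA layer.
#
# Problem:   max/min  obj' v   s.t.  S v = 0,  lb <= v <= ub,
#            optionally extra rows  a' v >= rhs.
#
# A dense two-phase bounded-variable primal simplex with Bland's smallest-
# index anti-cycling rule. Deterministic, exact at the vertex, and robust to
# the degenerate, rank-deficient balance systems that routinely arise from
# reaction knockouts. Network sizes in scope are tens of reactions, so dense
# refactorisation of the basis each iteration is cheap and numerically safe.
# Infinite bounds are capped at a large finite box; unboundedness is then
# detected by re-solving with a 10x larger cap and comparing optima.

.lp_cap <- 1e6
.lp_tol <- 1e-9

# max cc'x  s.t.  A x = b,  lb <= x <= ub  (all finite).
# Returns list(status = "optimal"|"infeasible"|"failed", x, z).
bounded_simplex <- function(A, b, cc, lb, ub, max_iter = 50000L) {
  m <- nrow(A); n <- ncol(A)
  if (m == 0L) {
    x <- ifelse(cc > 0, ub, lb)
    return(list(status = "optimal", x = x, z = sum(cc * x)))
  }
  # structural variables start at the bound nearer zero
  x <- ifelse(abs(lb) <= abs(ub), lb, ub)
  at_upper <- abs(lb) > abs(ub)
  r <- as.numeric(b - A %*% x)
  sgn <- ifelse(r >= 0, 1, -1)
  Afull <- cbind(A, diag(sgn, nrow = m))
  nt <- n + m
  lbf <- c(lb, rep(0, m)); ubf <- c(ub, abs(r) + 1)
  xf <- c(x, abs(r))
  upperf <- c(at_upper, rep(FALSE, m))
  basis <- (n + 1L):nt
  in_basis <- rep(FALSE, nt); in_basis[basis] <- TRUE
  phase <- 1L
  cost <- c(rep(0, n), rep(-1, m))

  recompute_basics <- function() {
    B <- Afull[, basis, drop = FALSE]
    nb <- which(!in_basis)
    rhs <- b - if (length(nb)) Afull[, nb, drop = FALSE] %*% xf[nb] else 0
    sol <- tryCatch(solve(B, rhs), error = function(e) NULL)
    if (is.null(sol)) return(FALSE)
    xf[basis] <<- as.numeric(sol)
    TRUE
  }
  if (!recompute_basics()) return(list(status = "failed"))

  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) return(list(status = "failed"))
    B <- Afull[, basis, drop = FALSE]
    y <- tryCatch(solve(t(B), cost[basis]), error = function(e) NULL)
    if (is.null(y)) return(list(status = "failed"))
    nb <- which(!in_basis)
    dj <- cost[nb] - as.numeric(t(Afull[, nb, drop = FALSE]) %*% y)
    elig <- nb[(!upperf[nb] & dj > .lp_tol) | (upperf[nb] & dj < -.lp_tol)]
    # variables with a degenerate range can never improve; skip them
    elig <- elig[ubf[elig] - lbf[elig] > .lp_tol | FALSE]
    if (!length(elig)) {
      # optimal for current phase
      if (phase == 1L) {
        if (sum(xf[(n + 1L):nt]) > 1e-7) return(list(status = "infeasible"))
        ubf[(n + 1L):nt] <- 0; xf[(n + 1L):nt] <- 0
        cost <- c(cc, rep(0, m))
        phase <- 2L
        if (!recompute_basics()) return(list(status = "failed"))
        next
      }
      xs <- xf[seq_len(n)]
      return(list(status = "optimal", x = xs, z = sum(cc * xs)))
    }
    j <- min(elig)                       # Bland's rule: smallest index enters
    s <- if (upperf[j]) -1 else 1        # direction of change of x_j
    w <- tryCatch(solve(B, Afull[, j]), error = function(e) NULL)
    if (is.null(w)) return(list(status = "failed"))
    # x_basic(t) = x_basic - t * s * w ; find max t
    t_own <- ubf[j] - lbf[j]
    t_best <- t_own; leave <- 0L
    for (k in seq_len(m)) {
      swk <- s * w[k]
      bi <- basis[k]
      tk <- if (swk > .lp_tol) (xf[bi] - lbf[bi]) / swk
            else if (swk < -.lp_tol) (xf[bi] - ubf[bi]) / swk
            else next
      tk <- max(tk, 0)
      if (tk < t_best - .lp_tol || (tk < t_best + .lp_tol &&
          (leave == 0L || bi < basis[leave]))) {
        t_best <- tk; leave <- k
      }
    }
    if (!is.finite(t_best)) return(list(status = "unbounded"))
    # apply step
    xf[j] <- xf[j] + s * t_best
    xf[basis] <- xf[basis] - t_best * s * w
    if (leave == 0L) {
      upperf[j] <- !upperf[j]            # bound flip, basis unchanged
    } else {
      out <- basis[leave]
      swk <- s * w[leave]
      upperf[out] <- swk < 0             # leaving var rests at the bound it hit
      xf[out] <- if (upperf[out]) ubf[out] else lbf[out]
      in_basis[out] <- FALSE
      basis[leave] <- j
      in_basis[j] <- TRUE
      upperf[j] <- FALSE
      if (!recompute_basics()) return(list(status = "failed"))
    }
  }
}

solve_lp <- function(obj, S, lb, ub, maximize = TRUE, geq = NULL,
                     n_iter = NULL) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  S <- as.matrix(S)
  if (!nrow(S)) S <- matrix(0, 0, n)
  had_inf <- any(!is.finite(lb)) || any(!is.finite(ub))

  run <- function(cap) {
    l <- pmax(lb, -cap); u <- pmin(ub, cap)
    if (any(l > u)) return(list(status = "infeasible"))
    A <- S; rhs <- rep(0, nrow(S)); cc <- obj
    if (!is.null(geq) && length(geq)) {
      # a'v >= r  becomes  a'v - s = r  with surplus s in [0, big]
      for (g in geq) {
        A <- cbind(rbind(A, g$coef), 0)
        A[nrow(A), ncol(A)] <- -1
        rhs <- c(rhs, g$rhs)
        l <- c(l, 0); u <- c(u, 4 * cap)
        cc <- c(cc, 0)
      }
    }
    res <- bounded_simplex(A, rhs, if (maximize) cc else -cc, l, u)
    if (res$status != "optimal") return(res)
    v <- res$x[seq_len(n)]
    list(status = "optimal", v = v, z = sum(obj * v))
  }

  r1 <- run(.lp_cap)
  if (r1$status == "infeasible")
    return(list(status = "infeasible", z = NA_real_, v = NULL))
  if (r1$status %in% c("failed", "unbounded"))
    return(list(status = "failed", z = NA_real_, v = NULL))
  if (had_inf) {
    r2 <- run(10 * .lp_cap)
    ref <- max(1, abs(r1$z))
    if (r2$status == "optimal" &&
        abs(r2$z - r1$z) > 1e-7 * ref)
      return(list(status = "unbounded", z = NA_real_, v = NULL))
  }
  list(status = "optimal", z = r1$z, v = r1$v)
}
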