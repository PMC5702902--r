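# Independent oracles used across the suite. These deliberately avoid the
# package's own LP path: a brute-force vertex enumerator, a second LP
# implementation (pracma's simplex, where it converges), a scipy/HiGHS
# cross-check through the command-line python, and a direct R evaluator for
# GPR truth tables.

# Enumerate all basic feasible solutions (vertices) of
# {v : S v = 0, lb <= v <= ub} by fixing each subset of variables at a
# bound and solving the balance system for the rest; keep configurations
# with a unique, consistent, feasible solve. Exponential: networks <= 8
# reactions only.
oracle_vertices <- function(network, tol = 1e-8) {
  S <- build_stoichiometric_matrix(network, sparse = FALSE)
  lb <- network$reactions$lower_bound
  ub <- network$reactions$upper_bound
  n <- length(lb)
  stopifnot(n <= 9)
  verts <- matrix(numeric(0), nrow = 0, ncol = n)
  for (mask in 0:(3^n - 1)) {
    m <- mask
    code <- integer(n)
    for (j in seq_len(n)) { code[j] <- m %% 3; m <- m %/% 3 }
    v <- ifelse(code == 1, lb, ifelse(code == 2, ub, NA_real_))
    free <- which(code == 0)
    if (length(free)) {
      A <- S[, free, drop = FALSE]
      qa <- qr(A)
      if (qa$rank < length(free)) next
      rhs <- -S[, -free, drop = FALSE] %*% v[-free]
      if (!length(v[-free])) rhs <- matrix(0, nrow(S), 1)
      sol <- qr.coef(qa, rhs)
      if (anyNA(sol)) next
      v[free] <- sol
    }
    if (max(abs(S %*% v)) > tol) next
    if (any(v < lb - tol) || any(v > ub + tol)) next
    verts <- rbind(verts, pmin(pmax(v, lb), ub))
  }
  if (!nrow(verts)) return(list(feasible = FALSE))
  verts <- unique(round(verts, 8))
  list(feasible = TRUE, vertices = verts)
}

oracle_lp_max <- function(network, objective, tol = 1e-8) {
  vv <- oracle_vertices(network, tol)
  if (!vv$feasible) return(list(feasible = FALSE))
  obj <- numeric(nrow(network$reactions))
  names(obj) <- network$reactions$id
  obj[names(objective$coefficients)] <- objective$coefficients
  zs <- as.numeric(vv$vertices %*% obj)
  zmax <- max(zs)
  list(feasible = TRUE, z = zmax,
       n_optimal = sum(zs > zmax - 1e-8),
       optima = vv$vertices[zs > zmax - 1e-8, , drop = FALSE])
}

# Second, independent LP implementation (pracma); NA when it fails to
# converge on a degenerate instance.
pracma_lp_max <- function(network, objective) {
  if (!requireNamespace("pracma", quietly = TRUE)) return(NA_real_)
  S <- build_stoichiometric_matrix(network, sparse = FALSE)
  lb <- network$reactions$lower_bound
  ub <- network$reactions$upper_bound
  obj <- numeric(length(lb)); names(obj) <- network$reactions$id
  obj[names(objective$coefficients)] <- objective$coefficients
  free <- which(ub - lb > 1e-12)
  fixed <- setdiff(seq_along(lb), free)
  A3 <- S[, free, drop = FALSE]
  vfix <- ifelse(seq_along(lb) %in% fixed, lb, 0)
  b3 <- as.numeric(-S %*% vfix) - as.numeric(A3 %*% lb[free])
  r <- try(pracma::linprog(cc = obj[free], A = diag(length(free)),
                           b = (ub - lb)[free], Aeq = A3, beq = b3,
                           maximize = TRUE, maxiter = 5000), silent = TRUE)
  if (inherits(r, "try-error") || r$errno != 1) return(NA_real_)
  sum(obj[free] * (r$x + lb[free])) + sum(obj[fixed] * lb[fixed])
}

# scipy.optimize.linprog (HiGHS) cross-check through the system python.
# Returns NA if python/scipy is unavailable.
scipy_lp_max <- function(network, objective) {
  py <- Sys.which("python")
  if (!nzchar(py)) return(NA_real_)
  S <- build_stoichiometric_matrix(network, sparse = FALSE)
  obj <- numeric(nrow(network$reactions))
  names(obj) <- network$reactions$id
  obj[names(objective$coefficients)] <- objective$coefficients
  dir <- tempfile("lp"); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  utils::write.table(as.matrix(S), file.path(dir, "S.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(cbind(obj, network$reactions$lower_bound,
                           network$reactions$upper_bound),
                     file.path(dir, "clu.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  script <- sprintf("
import numpy as np
from scipy.optimize import linprog
S = np.loadtxt('%s/S.csv', delimiter=',', ndmin=2)
clu = np.loadtxt('%s/clu.csv', delimiter=',', ndmin=2)
c, lo, hi = clu[:,0], clu[:,1], clu[:,2]
r = linprog(-c, A_eq=S, b_eq=np.zeros(S.shape[0]),
            bounds=list(zip(lo, hi)), method='highs')
print(repr(-r.fun) if r.status == 0 else 'FAIL')
", dir, dir)
  out <- tryCatch(system2(py, "-", input = script, stdout = TRUE,
                          stderr = FALSE),
                  error = function(e) "FAIL", warning = function(w) "FAIL")
  val <- suppressWarnings(as.numeric(out[length(out)]))
  if (length(val) != 1 || is.na(val)) NA_real_ else val
}

# Truth-table oracle: evaluate a GPR string directly with R's own boolean
# operators (independent of the package parser).
r_eval_gpr <- function(gpr, states) {
  expr <- gsub("\\bAND\\b", "&", gpr, ignore.case = TRUE)
  expr <- gsub("\\bOR\\b", "|", expr, ignore.case = TRUE)
  eval(parse(text = expr), envir = as.list(states))
}
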