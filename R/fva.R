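#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux subject to the objective being held
#' at at least `optimality_fraction` of its maximum. A range wider than the
#' tolerance on a coupled flux flags non-uniqueness of the FBA solution: the
#' LP solver is then free to "flip" between alternative pathways with the
#' same objective value.
#'
#' @param network A `metabolic_network`.
#' @param objective An [fba_objective()].
#' @param optimality_fraction Fraction of `z_max` to enforce (default 1).
#' @param reactions Reactions to analyse (default: all).
#' @return Data frame with columns `reaction_id`, `min`, `max`. Per-reaction
#'   LP failures yield `NA` rows with a warning rather than a global error.
#' @export
flux_variability <- function(network, objective, optimality_fraction = 1,
                             reactions = NULL) {
  wt <- fba(network, objective)
  if (wt$status != "optimal")
    stop("flux variability requires an optimal wild-type FBA, got ", wt$status)
  obj <- objective_vector(network, objective)
  S <- build_stoichiometric_matrix(network, sparse = FALSE)
  lb <- network$reactions$lower_bound
  ub <- network$reactions$upper_bound
  rids <- if (is.null(reactions)) network$reactions$id else reactions
  idx <- match(rids, network$reactions$id)
  if (anyNA(idx))
    stop("unknown reaction id(s): ", paste(rids[is.na(idx)], collapse = ", "))
  zcut <- optimality_fraction * wt$z
  geq <- list(list(coef = unname(obj), rhs = zcut))
  n <- length(obj)
  one_dir <- function(j, maximize) {
    e <- numeric(n); e[j] <- 1
    res <- solve_lp(e, S, lb, ub, maximize = maximize, geq = geq)
    if (res$status != "optimal") {
      warning("FVA LP ", if (maximize) "max" else "min", " failed for '",
              network$reactions$id[j], "' (", res$status, ")")
      return(NA_real_)
    }
    res$z
  }
  data.frame(reaction_id = rids,
             min = vapply(idx, one_dir, numeric(1), maximize = FALSE),
             max = vapply(idx, one_dir, numeric(1), maximize = TRUE),
             stringsAsFactors = FALSE)
}

# Evaluate expr with a temporary, restorable RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Sample the feasible flux space
#'
#' Hit-and-run Markov-chain Monte Carlo over the flux polytope
#' `{v : S v = 0, l <= v <= u}` (plus optional extra inequality
#' constraints `a'v >= rhs`). Directions are drawn in the null space of `S`
#' restricted to non-fixed reactions, so every sample satisfies the balance
#' constraints to numerical precision; the chord within the bounds is then
#' sampled uniformly. Fixed reactions (`l == u`, e.g. knockouts) stay at
#' their fixed value exactly.
#'
#' @param network A `metabolic_network`.
#' @param n_samples Number of samples to return.
#' @param seed Integer seed; same seed reproduces the sample exactly.
#' @param constraints Optional list of `list(coef = named or full-length
#'   numeric, rhs =)` inequality constraints `coef' v >= rhs`.
#' @param thin Chain steps between retained samples.
#' @param burn_in Discarded initial steps.
#' @return `n_samples` x N matrix of feasible flux vectors (columns named by
#'   reaction id).
#' @export
sample_flux_space <- function(network, n_samples, seed = 1L,
                              constraints = NULL, thin = 10L, burn_in = 100L) {
  stopifnot(n_samples >= 1L)
  S <- build_stoichiometric_matrix(network, sparse = FALSE)
  lb <- network$reactions$lower_bound
  ub <- network$reactions$upper_bound
  n <- length(lb)
  geq <- NULL
  if (!is.null(constraints)) {
    geq <- lapply(constraints, function(g) {
      coef <- g$coef
      if (!is.null(names(coef))) {
        full <- stats::setNames(numeric(n), network$reactions$id)
        full[names(coef)] <- coef
        coef <- unname(full)
      }
      list(coef = coef, rhs = g$rhs)
    })
  }
  start <- solve_lp(rep(0, n), S, lb, ub, maximize = TRUE, geq = geq)
  if (start$status != "optimal")
    stop("feasible region is empty: ", start$status)
  v <- start$v
  free <- which(ub - lb > 1e-12)
  basis <- NULL
  if (length(free)) {
    Sf <- S[, free, drop = FALSE]
    if (nrow(Sf) == 0L) {
      basis <- diag(length(free))
    } else {
      sv <- svd(Sf, nu = 0, nv = length(free))
      r <- sum(sv$d > max(dim(Sf)) * max(sv$d, 0) * 1e-12)
      basis <- if (r < length(free)) sv$v[, seq(r + 1, length(free)), drop = FALSE]
               else NULL
    }
  }
  out <- matrix(rep(v, n_samples), nrow = n_samples, byrow = TRUE,
                dimnames = list(NULL, network$reactions$id))
  if (is.null(basis)) return(out)  # point polytope: only one feasible vector
  with_seed(seed, {
    total <- burn_in + n_samples * thin
    kept <- 0L
    for (step in seq_len(total)) {
      d <- numeric(n)
      d[free] <- basis %*% stats::rnorm(ncol(basis))
      nr <- sqrt(sum(d^2))
      if (nr < 1e-14) next
      d <- d / nr
      tmin <- -Inf; tmax <- Inf
      for (j in free) {
        if (abs(d[j]) < 1e-14) next
        t1 <- (lb[j] - v[j]) / d[j]; t2 <- (ub[j] - v[j]) / d[j]
        tmin <- max(tmin, min(t1, t2)); tmax <- min(tmax, max(t1, t2))
      }
      if (!is.null(geq)) {
        for (g in geq) {
          ad <- sum(g$coef * d)
          if (abs(ad) < 1e-14) next
          tc <- (g$rhs - sum(g$coef * v)) / ad
          if (ad > 0) tmin <- max(tmin, tc) else tmax <- min(tmax, tc)
        }
      }
      if (!is.finite(tmin) || !is.finite(tmax) || tmax < tmin) next
      v <- v + stats::runif(1, tmin, tmax) * d
      v <- pmin(pmax(v, lb), ub)
      if (step > burn_in && (step - burn_in) %% thin == 0L) {
        kept <- kept + 1L
        out[kept, ] <- v
      }
    }
  })
  out
}
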