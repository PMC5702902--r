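#' Define an FBA objective
#'
#' A linear combination of reaction fluxes representing the metabolic
#' capability of interest (e.g. glutathione production). Maximisation only,
#' matching the standard constraint-based formulation.
#'
#' @param coefficients Named numeric vector, reaction id -> coefficient.
#' @return An `fba_objective` object.
#' @export
fba_objective <- function(coefficients) {
  stopifnot(is.numeric(coefficients), length(coefficients) > 0L,
            !is.null(names(coefficients)))
  if (all(coefficients == 0))
    stop("objective needs at least one nonzero coefficient")
  structure(list(coefficients = coefficients, sense = "maximize"),
            class = "fba_objective")
}

objective_vector <- function(network, objective) {
  stopifnot(inherits(objective, "fba_objective"))
  unknown <- setdiff(names(objective$coefficients), network$reactions$id)
  if (length(unknown))
    stop("objective references unknown reaction(s): ",
         paste(unknown, collapse = ", "))
  obj <- stats::setNames(numeric(nrow(network$reactions)), network$reactions$id)
  obj[names(objective$coefficients)] <- objective$coefficients
  obj
}

#' Flux balance analysis
#'
#' Solves `max z = a'v` subject to `S v = 0` and `l <= v <= u` by linear
#' programming. The optimum `z` is guaranteed globally maximal (convex
#' problem); the returned flux vector is one optimal vertex and need not be
#' unique — use [flux_variability()] to diagnose alternative optima. An
#' optimal solution with `z = 0` means the metabolic function is
#' stoichiometrically infeasible even though the LP itself is feasible.
#'
#' @param network A `metabolic_network`.
#' @param objective An [fba_objective()].
#' @param tolerance Balance/feasibility tolerance (model flux units).
#' @return An `fba_solution`: list with `status`
#'   (`optimal`/`infeasible`/`unbounded`), `z`, `v` (named flux vector) and
#'   `residual` (max-norm of `S v`).
#' @export
fba <- function(network, objective, tolerance = 1e-6) {
  obj <- objective_vector(network, objective)
  S <- build_stoichiometric_matrix(network, sparse = FALSE)
  lb <- network$reactions$lower_bound
  ub <- network$reactions$upper_bound
  res <- solve_lp(obj, S, lb, ub, maximize = TRUE)
  if (res$status == "failed")
    stop("LP solver failed to converge")
  sol <- list(status = res$status, z = res$z, v = NULL, residual = NA_real_,
              objective = objective)
  if (res$status == "optimal") {
    v <- stats::setNames(res$v, network$reactions$id)
    resid <- if (nrow(S)) max(abs(S %*% v)) else 0
    if (resid > tolerance)
      warning(sprintf("balance residual %.3g exceeds tolerance %.3g",
                      resid, tolerance))
    if (any(v < lb - tolerance) || any(v > ub + tolerance))
      warning("solution violates flux bounds beyond tolerance")
    sol$v <- v
    sol$residual <- resid
  }
  structure(sol, class = "fba_solution")
}

#' @export
print.fba_solution <- function(x, ...) {
  cat("fba_solution: status =", x$status)
  if (x$status == "optimal")
    cat(sprintf(", z = %.6g, max|S v| = %.2g", x$z, x$residual))
  cat("\n")
  invisible(x)
}

#' Knock out reactions
#'
#' Setting a reaction's flux bounds to (0, 0) is equivalent to removing it
#' from the model. The input network is not modified.
#'
#' @param network A `metabolic_network`.
#' @param reaction_ids Reactions to disable; empty vector returns the network
#'   unchanged.
#' @return A modified copy of the network.
#' @export
knockout_reactions <- function(network, reaction_ids) {
  if (length(reaction_ids) == 0L) return(network)
  set_bounds(network, reaction_ids, 0, 0)
}

#' Knock out genes through GPR rules
#'
#' Each reaction's GPR rule is evaluated with the knocked genes `FALSE` and
#' all other genes `TRUE`; reactions whose rule evaluates `FALSE` get bounds
#' (0, 0). Reactions without a rule are untouched.
#'
#' @param network A `metabolic_network`.
#' @param gene_ids Genes to disable.
#' @return A modified copy of the network.
#' @export
gene_knockout <- function(network, gene_ids) {
  if (length(gene_ids) == 0L) return(network)
  states <- stats::setNames(rep(FALSE, length(gene_ids)), gene_ids)
  disabled <- character(0)
  for (i in seq_len(nrow(network$reactions))) {
    g <- network$reactions$gpr[i]
    if (!nzchar(g)) next
    if (!eval_gpr(parse_gpr(g), states))
      disabled <- c(disabled, network$reactions$id[i])
  }
  knockout_reactions(network, disabled)
}

#' Single-reaction essentiality scan
#'
#' Each reaction in turn is inactivated by setting its flux bounds to (0, 0)
#' and the objective is re-optimised — an in-silico screen for enzymes whose
#' inhibition or polymorphism degrades the metabolic capability. Knockouts
#' rendering the LP infeasible are reported with `z_knockout = 0`.
#'
#' @param network A `metabolic_network` with an optimal wild-type FBA.
#' @param objective An [fba_objective()].
#' @param influence_threshold A reaction influences the objective when
#'   `|z_relative - 1|` exceeds this relative threshold.
#' @return Data frame (class `essentiality_scan`) with columns
#'   `reaction_id`, `z_knockout`, `z_relative`, `influences_objective`;
#'   wild-type optimum in attribute `z_wildtype`.
#' @export
essentiality_scan <- function(network, objective, influence_threshold = 1e-6) {
  wt <- fba(network, objective)
  if (wt$status != "optimal")
    stop("essentiality scan refused: wild-type FBA status is ", wt$status)
  zwt <- wt$z
  rows <- lapply(network$reactions$id, function(rid) {
    ko <- fba(knockout_reactions(network, rid), objective)
    zko <- if (ko$status == "optimal") ko$z else 0
    zrel <- if (zwt != 0) zko / zwt else NA_real_
    data.frame(reaction_id = rid, z_knockout = zko, z_relative = zrel,
               influences_objective = is.finite(zrel) &&
                 abs(zrel - 1) > influence_threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "z_wildtype") <- zwt
  class(out) <- c("essentiality_scan", "data.frame")
  out
}

#' Write an essentiality scan as TSV
#'
#' @param scan Result of [essentiality_scan()].
#' @param path Output file.
#' @export
write_essentiality_tsv <- function(scan, path) {
  utils::write.table(as.data.frame(scan), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
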