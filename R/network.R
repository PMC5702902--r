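#' Create a metabolite
#'
#' Metabolites are the nodes of a metabolic network. External metabolites
#' mark sources and sinks of flux: they are treated as unbalanced and never
#' appear as rows of the steady-state balance system.
#'
#' @param id Unique short identifier, e.g. `"Glucose(c)"` or `"M1xt"`.
#' @param name Human-readable name; defaults to `id`.
#' @param compartment Compartment tag (e.g. `"c"`, `"m"`); `""` if none.
#' @param is_external Logical; `TRUE` for unbalanced source/sink species.
#' @return A `metabolite` object (named list).
#' @export
metabolite <- function(id, name = id, compartment = "", is_external = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  structure(list(id = id, name = name, compartment = compartment,
                 is_external = isTRUE(is_external)),
            class = "metabolite")
}

#' Create a reaction
#'
#' @param id Unique short identifier.
#' @param stoichiometry Named numeric vector mapping metabolite ids to signed
#'   stoichiometric coefficients (negative = consumed, positive = produced).
#' @param lower_bound,upper_bound Flux bounds (model flux units). An
#'   irreversible reaction must have `lower_bound >= 0`.
#' @param reversible Logical; defaults to `lower_bound < 0`.
#' @param gpr Gene-protein-reaction rule: a Boolean expression over gene ids
#'   using `AND`/`OR` and parentheses, or `""` for none.
#' @return A `reaction` object.
#' @export
reaction <- function(id, stoichiometry, lower_bound = 0, upper_bound = 1000,
                     reversible = lower_bound < 0, gpr = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (length(stoichiometry) == 0L)
    stop("reaction '", id, "': stoichiometry must be non-empty")
  if (is.null(names(stoichiometry)) || any(!nzchar(names(stoichiometry))))
    stop("reaction '", id, "': stoichiometry must be a named numeric vector")
  if (!is.numeric(stoichiometry) || any(!is.finite(stoichiometry)))
    stop("reaction '", id, "': stoichiometric coefficients must be finite numbers")
  if (lower_bound > upper_bound)
    stop("reaction '", id, "': lower_bound > upper_bound")
  if (!reversible && lower_bound < 0)
    stop("reaction '", id, "': irreversible reaction with negative lower bound")
  structure(list(id = id, stoichiometry = stoichiometry,
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound),
                 reversible = isTRUE(reversible),
                 gpr = as.character(gpr)),
            class = "reaction")
}

#' Assemble a metabolic network
#'
#' Validates structural invariants: unique ids, every stoichiometry key
#' resolving to a declared metabolite, bound ordering, and derives the gene
#' set as the union of all GPR variables.
#'
#' @param metabolites List of [metabolite()] objects.
#' @param reactions List of [reaction()] objects.
#' @return A `metabolic_network` object with elements `metabolites`
#'   (data frame), `reactions` (data frame), `stoichiometry` (named list of
#'   named numeric vectors) and `genes` (character vector).
#' @export
metabolic_network <- function(metabolites, reactions) {
  stopifnot(is.list(metabolites), is.list(reactions), length(reactions) > 0L)
  mets <- do.call(rbind, lapply(metabolites, function(m) {
    stopifnot(inherits(m, "metabolite"))
    data.frame(id = m$id, name = m$name, compartment = m$compartment,
               is_external = m$is_external, stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(mets$id))
    stop("duplicate metabolite id(s): ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  rxns <- do.call(rbind, lapply(reactions, function(r) {
    stopifnot(inherits(r, "reaction"))
    data.frame(id = r$id, lower_bound = r$lower_bound,
               upper_bound = r$upper_bound, reversible = r$reversible,
               gpr = r$gpr, stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(rxns$id))
    stop("duplicate reaction id(s): ",
         paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", "))
  stoich <- lapply(reactions, `[[`, "stoichiometry")
  names(stoich) <- rxns$id
  for (rid in rxns$id) {
    unknown <- setdiff(names(stoich[[rid]]), mets$id)
    if (length(unknown))
      stop("reaction '", rid, "' references undeclared metabolite(s): ",
           paste(unknown, collapse = ", "))
  }
  genes <- sort(unique(unlist(lapply(rxns$gpr, function(g) {
    if (!nzchar(g)) character(0) else gpr_genes(parse_gpr(g))
  }))))
  structure(list(metabolites = mets, reactions = rxns,
                 stoichiometry = stoich, genes = as.character(genes)),
            class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("metabolic_network:", nrow(x$reactions), "reactions,",
      sum(!x$metabolites$is_external), "internal +",
      sum(x$metabolites$is_external), "external metabolites,",
      length(x$genes), "genes\n")
  invisible(x)
}

reaction_ids <- function(network) network$reactions$id

internal_metabolite_ids <- function(network)
  network$metabolites$id[!network$metabolites$is_external]

#' Identify exchange reactions
#'
#' An exchange reaction connects the network to its environment: over the
#' internal (balanced) metabolites its stoichiometry is all-negative (sink),
#' all-positive (source), or empty (pure external transport).
#'
#' @param network A `metabolic_network`.
#' @return Named logical vector over reactions.
#' @export
is_exchange_reaction <- function(network) {
  internal <- internal_metabolite_ids(network)
  out <- vapply(network$stoichiometry, function(s) {
    si <- s[names(s) %in% internal]
    length(si) == 0L || all(si <= 0) || all(si >= 0)
  }, logical(1))
  names(out) <- network$reactions$id
  out
}

#' Build the stoichiometric matrix
#'
#' Rows are internal metabolites (external species are unbalanced sources and
#' sinks and are excluded), columns are reactions in network order. The
#' steady-state flux constraint is `S %*% v = 0`.
#'
#' @param network A `metabolic_network`.
#' @param sparse Return a `Matrix::sparseMatrix` (default) or base matrix.
#' @return M_internal x N matrix with dimnames (metabolite ids, reaction ids).
#' @export
build_stoichiometric_matrix <- function(network, sparse = TRUE) {
  internal <- internal_metabolite_ids(network)
  rids <- reaction_ids(network)
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (k in seq_along(rids)) {
    s <- network$stoichiometry[[rids[k]]]
    s <- s[names(s) %in% internal]
    if (!length(s)) next
    i <- c(i, match(names(s), internal))
    j <- c(j, rep.int(k, length(s)))
    x <- c(x, unname(s))
  }
  S <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(length(internal), length(rids)),
                            dimnames = list(internal, rids))
  if (sparse) S else as.matrix(S)
}

#' Replace flux bounds on selected reactions
#'
#' @param network A `metabolic_network`.
#' @param reaction_ids Character vector of reaction ids.
#' @param lower_bound,upper_bound Replacement bounds (recycled).
#' @return A modified copy of the network.
#' @export
set_bounds <- function(network, reaction_ids, lower_bound, upper_bound) {
  idx <- match(reaction_ids, network$reactions$id)
  if (anyNA(idx))
    stop("unknown reaction id(s): ",
         paste(reaction_ids[is.na(idx)], collapse = ", "))
  lb <- rep_len(as.numeric(lower_bound), length(idx))
  ub <- rep_len(as.numeric(upper_bound), length(idx))
  if (any(lb > ub)) stop("lower_bound > upper_bound")
  network$reactions$lower_bound[idx] <- lb
  network$reactions$upper_bound[idx] <- ub
  network
}
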