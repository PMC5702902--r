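# Plain tabular model dialect: TSV with columns id, formula, lower_bound,
# upper_bound, gpr. Formula grammar: coefficient? name "(" compartment ")",
# "+"-separated terms, arrow "->" (irreversible), "<-" (irreversible,
# written right-to-left) or "<=>" (reversible). Metabolite tokens whose name
# ends in "xt", or listed in `externals`, are unbalanced sources/sinks.

parse_met_token <- function(token) {
  m <- regmatches(token, regexec("^(.*?)(?:\\(([^()]+)\\))?$", token))[[1]]
  list(id = token, name = m[2], compartment = if (is.na(m[3])) "" else m[3])
}

parse_formula_side <- function(side, sign) {
  side <- trimws(side)
  if (!nzchar(side)) return(stats::setNames(numeric(0), character(0)))
  terms <- trimws(strsplit(side, "\\s+\\+\\s+")[[1]])
  out <- numeric(0)
  for (term in terms) {
    m <- regmatches(term,
      regexec("^([0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?\\s+)?(\\S.*)$", term))[[1]]
    if (length(m) == 0L || !nzchar(m[3]))
      stop("cannot parse formula term '", term, "'")
    coef <- if (nzchar(trimws(m[2]))) as.numeric(trimws(m[2])) else 1
    tok <- trimws(m[3])
    out[tok] <- (if (tok %in% names(out)) out[[tok]] else 0) + sign * coef
  }
  out
}

parse_reaction_formula <- function(formula) {
  arrow <- if (grepl("<=>", formula, fixed = TRUE)) "<=>"
    else if (grepl("->", formula, fixed = TRUE)) "->"
    else if (grepl("<-", formula, fixed = TRUE) ||
             grepl("<–", formula, fixed = TRUE)) "<-"
    else stop("no reaction arrow ('->', '<-' or '<=>') in formula '",
              formula, "'")
  pat <- if (arrow == "<-") "<-|<–" else arrow
  sides <- strsplit(formula, pat)[[1]]
  if (length(sides) != 2L)
    stop("formula must have exactly one arrow: '", formula, "'")
  if (arrow == "<-") sides <- rev(sides)
  lhs <- parse_formula_side(sides[1], -1)
  rhs <- parse_formula_side(sides[2], +1)
  stoich <- lhs
  for (tok in names(rhs))
    stoich[tok] <- (if (tok %in% names(stoich)) stoich[[tok]] else 0) + rhs[[tok]]
  stoich <- stoich[stoich != 0]
  if (!length(stoich))
    stop("formula '", formula, "' has empty net stoichiometry")
  list(stoichiometry = stoich, reversible = arrow == "<=>")
}

is_external_token <- function(token, externals) {
  tok <- parse_met_token(token)
  token %in% externals || tok$name %in% externals ||
    grepl("xt$", tok$name)
}

#' Read a metabolic network from the tabular dialect
#'
#' @param path TSV file with header `id`, `formula`, `lower_bound`,
#'   `upper_bound` and optionally `gpr`.
#' @param externals Extra metabolite names/ids to treat as external, in
#'   addition to the `xt`-suffix convention.
#' @return A `metabolic_network`.
#' @export
read_tabular <- function(path, externals = character(0)) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "#")
  need <- c("id", "formula", "lower_bound", "upper_bound")
  if (!all(need %in% names(tab)))
    stop("tabular model must have columns: ", paste(need, collapse = ", "))
  if (!"gpr" %in% names(tab)) tab$gpr <- ""
  tab$gpr[is.na(tab$gpr)] <- ""
  if (anyDuplicated(tab$id))
    stop("duplicate reaction id(s): ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  mets <- list(); rxns <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    parsed <- tryCatch(parse_reaction_formula(tab$formula[i]),
      error = function(e) stop("line ", i + 1L, " (reaction '", tab$id[i],
                               "'): ", conditionMessage(e), call. = FALSE))
    for (tok in names(parsed$stoichiometry)) {
      if (!tok %in% names(mets)) {
        info <- parse_met_token(tok)
        mets[[tok]] <- metabolite(tok, name = info$name,
                                  compartment = info$compartment,
                                  is_external = is_external_token(tok, externals))
      }
    }
    lbv <- as.numeric(tab$lower_bound[i]); ubv <- as.numeric(tab$upper_bound[i])
    if (is.na(lbv) || is.na(ubv))
      stop("line ", i + 1L, ": non-numeric bounds for reaction '", tab$id[i], "'")
    rxns[[i]] <- reaction(tab$id[i], parsed$stoichiometry,
                          lower_bound = lbv, upper_bound = ubv,
                          reversible = parsed$reversible || lbv < 0,
                          gpr = tab$gpr[i])
  }
  net <- metabolic_network(unname(mets), rxns)
  message(sprintf("read_tabular: %d reactions, %d metabolites from %s",
                  nrow(net$reactions), nrow(net$metabolites), path))
  net
}

format_formula <- function(stoich, reversible) {
  fmt_side <- function(s) {
    if (!length(s)) return("")
    paste(vapply(names(s), function(id) {
      co <- abs(s[[id]])
      if (co == 1) id else paste(format(co, scientific = FALSE), id)
    }, character(1)), collapse = " + ")
  }
  lhs <- fmt_side(stoich[stoich < 0])
  rhs <- fmt_side(stoich[stoich > 0])
  paste(lhs, if (reversible) "<=>" else "->", rhs)
}

#' Write a metabolic network in the tabular dialect
#'
#' Inverse of [read_tabular()]: `read_tabular(write_tabular(net, f))` yields
#' a structurally identical network.
#'
#' @param network A `metabolic_network`.
#' @param path Output TSV file.
#' @export
write_tabular <- function(network, path) {
  rows <- data.frame(
    id = network$reactions$id,
    formula = vapply(seq_len(nrow(network$reactions)), function(i) {
      format_formula(network$stoichiometry[[network$reactions$id[i]]],
                     network$reactions$reversible[i])
    }, character(1)),
    lower_bound = network$reactions$lower_bound,
    upper_bound = network$reactions$upper_bound,
    gpr = network$reactions$gpr,
    stringsAsFactors = FALSE)
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an exchange-flux bounds table
#'
#' Two layouts are accepted. Pre-reduced: columns `reaction`, `lower_bound`,
#' `upper_bound`. Per-observation: column `reaction` plus any number of
#' `consumption*` and `release*` columns (one per observation, e.g. per cell
#' line); with `reduction = "max_over_observations"` these collapse to the
#' extreme observed fluxes per reaction. Sign convention: exchange reactions
#' are written in the export direction, so consumption is a negative lower
#' bound and release a positive upper bound.
#'
#' @param path CSV file. An empty file yields an empty table.
#' @param reduction `"none"` (pass-through) or `"max_over_observations"`.
#' @return A `bounds_table` data frame; reduced tables carry columns
#'   `reaction`, `lower_bound`, `upper_bound`.
#' @export
read_bounds_csv <- function(path, reduction = c("none", "max_over_observations")) {
  reduction <- match.arg(reduction)
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) {
    out <- data.frame(reaction = character(0), lower_bound = numeric(0),
                      upper_bound = numeric(0), stringsAsFactors = FALSE)
    class(out) <- c("bounds_table", "data.frame")
    return(out)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"reaction" %in% names(tab))
    stop("bounds table must have a 'reaction' column")
  num_cols <- setdiff(names(tab), "reaction")
  for (cc in num_cols) {
    vals <- suppressWarnings(as.numeric(tab[[cc]]))
    bad <- which(is.na(vals) & !is.na(tab[[cc]]) & nzchar(trimws(tab[[cc]])))
    if (length(bad))
      stop("non-numeric value in column '", cc, "' for reaction '",
           tab$reaction[bad[1]], "'")
    tab[[cc]] <- vals
  }
  if (reduction == "max_over_observations") {
    cons <- grep("^consumption", names(tab), value = TRUE)
    rel <- grep("^release", names(tab), value = TRUE)
    if (!length(cons) && !length(rel))
      stop("max_over_observations needs consumption*/release* columns")
    max_row <- function(cols)
      if (!length(cols)) rep(0, nrow(tab))
      else apply(abs(as.matrix(tab[cols])), 1, max, na.rm = TRUE)
    tab <- data.frame(reaction = tab$reaction,
                      lower_bound = -max_row(cons),
                      upper_bound = max_row(rel),
                      stringsAsFactors = FALSE)
  }
  class(tab) <- c("bounds_table", "data.frame")
  tab
}

#' Apply exchange-flux bounds to a network
#'
#' Listed exchange reactions get the table's bounds (e.g. the maximum
#' consumption and release fluxes observed across cell lines). With
#' `restrict_to_listed = TRUE`, every exchange reaction *not* listed is
#' closed to (0, 0), restricting the network to a defined physiological
#' import/export set. Rows naming non-exchange or unknown reactions are
#' skipped with a warning.
#'
#' @param network A `metabolic_network`.
#' @param bounds_table A reduced `bounds_table` (columns `reaction`,
#'   `lower_bound`, `upper_bound`) or equivalent data frame.
#' @param restrict_to_listed Close unlisted exchange reactions.
#' @return A modified copy of the network.
#' @export
apply_exchange_bounds <- function(network, bounds_table,
                                  restrict_to_listed = FALSE) {
  stopifnot(is.data.frame(bounds_table))
  if (nrow(bounds_table) &&
      !all(c("reaction", "lower_bound", "upper_bound") %in% names(bounds_table)))
    stop("bounds table must be reduced to reaction/lower_bound/upper_bound")
  exch <- is_exchange_reaction(network)
  listed <- character(0)
  for (i in seq_len(nrow(bounds_table))) {
    rid <- bounds_table$reaction[i]
    if (!rid %in% network$reactions$id) {
      warning("bounds row skipped: unknown reaction '", rid, "'")
      next
    }
    if (!exch[[rid]]) {
      warning("bounds row skipped: '", rid, "' is not an exchange reaction")
      next
    }
    network <- set_bounds(network, rid, bounds_table$lower_bound[i],
                          bounds_table$upper_bound[i])
    listed <- c(listed, rid)
  }
  if (restrict_to_listed) {
    close_ids <- setdiff(names(exch)[exch], listed)
    if (length(close_ids))
      network <- set_bounds(network, close_ids, 0, 0)
  }
  network
}
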