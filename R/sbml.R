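# SBML Level 3 (+ FBC v2) reader on top of xml2. Only the constraint-based
# modelling subset is read: species (with boundaryCondition), reactions with
# stoichiometry and fbc flux-bound parameters, gene-product associations and
# the active flux objective.

xfind <- function(node, name) {
  xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", name))
}

xattr <- function(node, name) {
  # attribute lookup tolerant of namespace prefixes (e.g. fbc:lowerFluxBound)
  at <- xml2::xml_attrs(node)
  hit <- which(names(at) == name | grepl(paste0(":", name, "$"), names(at)))
  if (length(hit)) unname(at[hit[1]]) else NA_character_
}

sbml_gpa_to_string <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") return(xattr(node, "geneProduct"))
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, sbml_gpa_to_string, character(1))
  op <- switch(nm, and = " AND ", or = " OR ",
               stop("unsupported gene association element <", nm, ">"))
  paste0("(", paste(parts, collapse = op), ")")
}

#' Read an SBML Level 3 FBC model
#'
#' Parses species (boundary-condition species become external metabolites),
#' reactions with stoichiometry, FBC flux bounds (via the model's global
#' parameters), gene-product associations (mapped to the package's Boolean
#' GPR strings, using gene labels where available) and the active FBC
#' objective. Reactions lacking FBC bounds fall back to the conventional
#' defaults — (0, 1000) irreversible, (-1000, 1000) reversible — with a
#' warning.
#'
#' @param path SBML file.
#' @return A `metabolic_network`. If the model declares an active objective
#'   its coefficients are attached as attribute `"objective"` (an
#'   [fba_objective()]); otherwise the caller must supply one.
#' @export
read_sbml_fbc <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- xml2::read_xml(path)

  sp_nodes <- xfind(doc, "species")
  mets <- lapply(sp_nodes, function(s) {
    metabolite(id = xattr(s, "id"),
               name = { n <- xattr(s, "name"); if (is.na(n)) xattr(s, "id") else n },
               compartment = { cpt <- xattr(s, "compartment")
                               if (is.na(cpt)) "" else cpt },
               is_external = identical(xattr(s, "boundaryCondition"), "true"))
  })
  met_ids <- vapply(mets, `[[`, character(1), "id")

  params <- stats::setNames(
    vapply(xfind(doc, "parameter"), function(p) as.numeric(xattr(p, "value")),
           numeric(1)),
    vapply(xfind(doc, "parameter"), function(p) xattr(p, "id"), character(1)))

  gp_nodes <- xfind(doc, "geneProduct")
  gp_label <- stats::setNames(
    vapply(gp_nodes, function(g) {
      lab <- xattr(g, "label")
      if (is.na(lab)) xattr(g, "id") else lab
    }, character(1)),
    vapply(gp_nodes, function(g) xattr(g, "id"), character(1)))

  rx_nodes <- xfind(doc, "reaction")
  n_missing_bounds <- 0L
  rxns <- lapply(rx_nodes, function(r) {
    rid <- xattr(r, "id")
    stoich <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(r, sprintf(
        "./*[local-name()='%s']/*[local-name()='speciesReference']", side))
      for (sr in refs) {
        sp <- xattr(sr, "species")
        if (!sp %in% met_ids)
          stop("reaction '", rid, "' references undeclared species '", sp, "'")
        st <- xattr(sr, "stoichiometry")
        co <- if (is.na(st)) 1 else as.numeric(st)
        stoich[sp] <- (if (sp %in% names(stoich)) stoich[[sp]] else 0) + sgn * co
      }
    }
    rev <- !identical(xattr(r, "reversible"), "false")
    lb_id <- xattr(r, "lowerFluxBound"); ub_id <- xattr(r, "upperFluxBound")
    lb <- if (!is.na(lb_id) && lb_id %in% names(params)) params[[lb_id]] else NA
    ub <- if (!is.na(ub_id) && ub_id %in% names(params)) params[[ub_id]] else NA
    if (is.na(lb) || is.na(ub)) {
      n_missing_bounds <<- n_missing_bounds + 1L
      if (is.na(lb)) lb <- if (rev) -1000 else 0
      if (is.na(ub)) ub <- 1000
    }
    gpa <- xfind(r, "geneProductAssociation")
    gpr <- ""
    if (length(gpa)) {
      kids <- xml2::xml_children(gpa[[1]])
      if (length(kids)) {
        gpr <- sbml_gpa_to_string(kids[[1]])
        for (gid in names(gp_label))
          gpr <- gsub(paste0("\\b", gid, "\\b"), gp_label[[gid]], gpr)
      }
    }
    reaction(rid, stoich, lower_bound = lb, upper_bound = ub,
             reversible = rev || lb < 0, gpr = gpr)
  })
  if (n_missing_bounds > 0L)
    warning(n_missing_bounds,
            " reaction(s) lack FBC flux bounds; conventional defaults applied")

  net <- metabolic_network(mets, rxns)
  message(sprintf("read_sbml_fbc: %d reactions, %d metabolites from %s",
                  nrow(net$reactions), nrow(net$metabolites), path))

  # active objective, if declared
  lobj <- xfind(doc, "listOfObjectives")
  if (length(lobj)) {
    active <- xattr(lobj[[1]], "activeObjective")
    objs <- xfind(lobj[[1]], "objective")
    pick <- if (!is.na(active)) {
      ids <- vapply(objs, function(o) xattr(o, "id"), character(1))
      objs[which(ids == active)]
    } else objs
    if (length(pick)) {
      fo <- xfind(pick[[1]], "fluxObjective")
      if (length(fo)) {
        coefs <- stats::setNames(
          vapply(fo, function(f) {
            co <- xattr(f, "coefficient")
            if (is.na(co)) 1 else as.numeric(co)
          }, numeric(1)),
          vapply(fo, function(f) xattr(f, "reaction"), character(1)))
        attr(net, "objective") <- fba_objective(coefs)
      }
    }
  }
  net
}
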