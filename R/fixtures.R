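# Deterministic toy-network generators. Every fixture has an analytically
# derived ground truth (optimum, essential set, alternative-optima count)
# asserted against independent oracles in the test suite.

#' Linear-chain fixture
#'
#' `Sxt -> M1 -> ... -> Mk -> Pxt`, all bounds `[0, 1]`. Objective: the
#' terminal export. Every reaction lies on the single path, so all are
#' essential and every flux range has width zero.
#'
#' @param n_internal Number of internal metabolites (chain length).
#' @return `list(network, objective)`.
#' @export
make_linear_chain <- function(n_internal = 2) {
  stopifnot(n_internal >= 1)
  ids <- paste0("M", seq_len(n_internal))
  mets <- c(list(metabolite("Sxt", is_external = TRUE),
                 metabolite("Pxt", is_external = TRUE)),
            lapply(ids, metabolite))
  nodes <- c("Sxt", ids, "Pxt")
  rxns <- lapply(seq_len(n_internal + 1), function(i) {
    st <- stats::setNames(c(-1, 1), c(nodes[i], nodes[i + 1]))
    reaction(paste0("r", i), st, lower_bound = 0, upper_bound = 1)
  })
  net <- metabolic_network(mets, rxns)
  list(network = net,
       objective = fba_objective(stats::setNames(1, paste0("r", n_internal + 1))))
}

#' Two-parallel-paths fixture
#'
#' A shared import `Sxt -> A`, two equivalent branches `A -> B1 -> X` and
#' `A -> B2 -> X`, and a shared export `X -> Pxt`; branch reactions have
#' spare capacity so no single branch knockout changes the optimum, and at
#' the optimum the flux split across branches is fully degenerate (used to
#' exercise the alternative-optima diagnostics).
#'
#' @return `list(network, objective, branch_reactions)`.
#' @export
make_parallel_paths <- function() {
  mets <- list(metabolite("Sxt", is_external = TRUE),
               metabolite("Pxt", is_external = TRUE),
               metabolite("A"), metabolite("B1"), metabolite("B2"),
               metabolite("X"))
  rxns <- list(
    reaction("import", c(Sxt = -1, A = 1), 0, 1),
    reaction("b1a", c(A = -1, B1 = 1), 0, 1),
    reaction("b1b", c(B1 = -1, X = 1), 0, 1),
    reaction("b2a", c(A = -1, B2 = 1), 0, 1),
    reaction("b2b", c(B2 = -1, X = 1), 0, 1),
    reaction("export", c(X = -1, Pxt = 1), 0, 1))
  list(network = metabolic_network(mets, rxns),
       objective = fba_objective(c(export = 1)),
       branch_reactions = c("b1a", "b1b", "b2a", "b2b"))
}

#' Figure-1-style fixture
#'
#' A small network reproducing the canonical textbook illustration of FBA
#' degeneracy and robustness by its *stated properties* (its literal
#' stoichiometry is not published, so this is an engineered stand-in):
#' four external metabolites, one reversible transport, all bound magnitudes
#' 1, objective = total production of the external product `Xxt`. Ground
#' truth (verified by vertex enumeration in the tests): `z_max = 1`, exactly
#' three alternative optimal vertices (one per route), and exactly one
#' essential reaction — the single nutrient import `R1`.
#'
#' Routes from `A` (imported by `R1`) to `Xxt`: direct (`R2`), via `B` with
#' by-product `D` exported by the reversible transport `R7`, and via `C`
#' with by-product `E` exported by `R8`.
#'
#' @return `list(network, objective, essential)`.
#' @export
make_fig1_like <- function() {
  mets <- list(metabolite("M1xt", is_external = TRUE),
               metabolite("M2xt", is_external = TRUE),
               metabolite("M3xt", is_external = TRUE),
               metabolite("Xxt", is_external = TRUE),
               metabolite("A"), metabolite("B"), metabolite("C"),
               metabolite("D"), metabolite("E"))
  rxns <- list(
    reaction("R1", c(M1xt = -1, A = 1), 0, 1),
    reaction("R2", c(A = -1, Xxt = 1), 0, 1),
    reaction("R3", c(A = -1, B = 1, D = 1), 0, 1),
    reaction("R4", c(B = -1, Xxt = 1), 0, 1),
    reaction("R5", c(A = -1, C = 1), 0, 1),
    reaction("R6", c(C = -1, Xxt = 1, E = 1), 0, 1),
    reaction("R7", c(D = -1, M3xt = 1), -1, 1, reversible = TRUE),
    reaction("R8", c(E = -1, M2xt = 1), 0, 1))
  list(network = metabolic_network(mets, rxns),
       objective = fba_objective(c(R2 = 1, R4 = 1, R6 = 1)),
       essential = "R1")
}

#' Miniature liver glutathione network
#'
#' A ~16-reaction cytosolic/mitochondrial-flavoured toy of hepatic
#' glutathione (GSH) synthesis: glutamate (from glutamine or direct import),
#' cysteine (from cystine reduction, consuming NADPH) and glycine (from
#' serine via the serine hydroxymethyltransferase / folate cycle) condense
#' into GSH, which is exported (the objective). NADPH is regenerated by the
#' folate-cycle dehydrogenases. Ground truth, derived from the flux balance
#' and frozen in the tests:
#' * wild-type `z_max = 1` (set by the GSH export capacity);
#' * `MTHFD` (methylenetetrahydrofolate dehydrogenase step) is essential —
#'   its knockout abolishes both tetrahydrofolate recycling and NADPH supply,
#'   so `z = 0`;
#' * `FTHLDH` (formyltetrahydrofolate dehydrogenase step) is partially
#'   limiting — with it knocked out the only remaining 10-formyl-THF drain
#'   (`FTCD`, capacity 0.3) caps the folate cycle, so `z_relative = 0.3`.
#'
#' @return `list(network, objective, essential, partial, partial_z_relative)`.
#' @export
make_mini_liver <- function() {
  ext <- function(id) metabolite(id, is_external = TRUE)
  mets <- list(
    ext("Glnxt"), ext("Gluxt"), ext("CySSxt"), ext("Serxt"),
    ext("GSHxt"), ext("Formatext"), ext("CO2xt"),
    metabolite("Gln(c)", compartment = "c"),
    metabolite("Glu(c)", compartment = "c"),
    metabolite("CySS(c)", compartment = "c"),
    metabolite("Cys(c)", compartment = "c"),
    metabolite("Ser(c)", compartment = "c"),
    metabolite("Gly(c)", compartment = "c"),
    metabolite("THF(c)", compartment = "c"),
    metabolite("CH2THF(c)", compartment = "c"),   # 5,10-methylene-THF
    metabolite("CHTHF(c)", compartment = "c"),    # 5,10-methenyl-THF
    metabolite("CHOTHF(c)", compartment = "c"),   # 10-formyl-THF
    metabolite("NADP(c)", compartment = "c"),
    metabolite("NADPH(c)", compartment = "c"),
    metabolite("Formate(c)", compartment = "c"),
    metabolite("CO2(c)", compartment = "c"),
    metabolite("GSH(c)", compartment = "c"))
  r <- function(id, st, lb = 0, ub = 10, gpr = "")
    reaction(id, st, lb, ub, reversible = lb < 0, gpr = gpr)
  rxns <- list(
    r("EX_Gln", c("Glnxt" = -1, "Gln(c)" = 1)),
    r("EX_Glu", c("Gluxt" = -1, "Glu(c)" = 1)),
    r("GLS", c("Gln(c)" = -1, "Glu(c)" = 1), gpr = "GLS1 OR GLS2"),
    r("EX_CySS", c("CySSxt" = -1, "CySS(c)" = 1)),
    r("CYSR", c("CySS(c)" = -1, "NADPH(c)" = -1, "Cys(c)" = 2, "NADP(c)" = 1),
      gpr = "TXNRD1"),
    r("EX_Ser", c("Serxt" = -1, "Ser(c)" = 1)),
    r("SHMT", c("Ser(c)" = -1, "THF(c)" = -1, "Gly(c)" = 1, "CH2THF(c)" = 1),
      lb = -10, gpr = "SHMT1 OR SHMT2"),
    r("MTHFD", c("CH2THF(c)" = -1, "NADP(c)" = -1,
                 "CHTHF(c)" = 1, "NADPH(c)" = 1), gpr = "MTHFD1"),
    r("MTHFC", c("CHTHF(c)" = -1, "CHOTHF(c)" = 1), gpr = "MTHFD1"),
    r("FTHLDH", c("CHOTHF(c)" = -1, "NADP(c)" = -1,
                  "THF(c)" = 1, "CO2(c)" = 1, "NADPH(c)" = 1),
      ub = 1, gpr = "ALDH1L1"),
    r("FTCD", c("CHOTHF(c)" = -1, "THF(c)" = 1, "Formate(c)" = 1), ub = 0.3,
      gpr = "FTCD"),
    r("GSHS", c("Glu(c)" = -1, "Cys(c)" = -1, "Gly(c)" = -1, "GSH(c)" = 1),
      gpr = "GCLC AND GCLM AND GSS"),
    r("NADPHOX", c("NADPH(c)" = -1, "NADP(c)" = 1)),
    r("EX_GSH", c("GSH(c)" = -1, "GSHxt" = 1), ub = 1),
    r("EX_Formate", c("Formate(c)" = -1, "Formatext" = 1)),
    r("EX_CO2", c("CO2(c)" = -1, "CO2xt" = 1)))
  list(network = metabolic_network(mets, rxns),
       objective = fba_objective(c(EX_GSH = 1)),
       essential = "MTHFD", partial = "FTHLDH", partial_z_relative = 0.3)
}

#' Random feasible network
#'
#' A spanning path `Sxt -> M1 -> ... -> Mk -> Pxt` (guaranteeing a feasible,
#' nonzero optimum for the built-in objective, the terminal export) plus
#' random forward shortcut reactions with random bounds; some shortcuts are
#' reversible.
#'
#' @param n_reactions Total reaction count (>= 2).
#' @param seed Integer seed; same seed gives an identical network.
#' @return `list(network, objective)`.
#' @export
make_random_network <- function(n_reactions, seed = 1L) {
  stopifnot(n_reactions >= 2)
  with_seed(seed, {
    n_path <- max(2L, min(n_reactions, 2L + stats::rpois(1, 2)))
    n_int <- n_path - 1L
    ids <- paste0("M", seq_len(n_int))
    nodes <- c("Sxt", ids, "Pxt")
    mets <- c(list(metabolite("Sxt", is_external = TRUE),
                   metabolite("Pxt", is_external = TRUE)),
              lapply(ids, metabolite))
    rxns <- lapply(seq_len(n_path), function(i)
      reaction(paste0("p", i),
               stats::setNames(c(-1, 1), c(nodes[i], nodes[i + 1])),
               0, round(stats::runif(1, 1, 2), 2)))
    n_extra <- n_reactions - n_path
    for (k in seq_len(n_extra)) {
      ij <- sort(sample(seq_along(nodes), 2))
      rev <- stats::runif(1) < 0.3
      ub <- round(stats::runif(1, 0.5, 2), 2)
      rxns <- c(rxns, list(
        reaction(paste0("s", k),
                 stats::setNames(c(-1, 1), c(nodes[ij[1]], nodes[ij[2]])),
                 lower_bound = if (rev) -ub else 0, upper_bound = ub,
                 reversible = rev)))
    }
    net <- metabolic_network(mets, rxns)
    list(network = net,
         objective = fba_objective(stats::setNames(1, paste0("p", n_path))))
  })
}

#' Random consumption/release bounds table
#'
#' Emulates a per-cell-line exchange-flux measurement table: one row per
#' exchange reaction, one consumption and one release column per
#' observation.
#'
#' @param n_metabolites Rows.
#' @param n_observations Observation (e.g. cell line) count.
#' @param seed Integer seed.
#' @return Data frame with columns `reaction`, `consumption_1..k`,
#'   `release_1..k`.
#' @export
make_bounds_table <- function(n_metabolites, n_observations, seed = 1L) {
  stopifnot(n_metabolites >= 1, n_observations >= 1)
  with_seed(seed, {
    out <- data.frame(reaction = paste0("EX_met", seq_len(n_metabolites)),
                      stringsAsFactors = FALSE)
    for (k in seq_len(n_observations))
      out[[paste0("consumption_", k)]] <-
        round(stats::runif(n_metabolites, 0, 2), 3)
    for (k in seq_len(n_observations))
      out[[paste0("release_", k)]] <-
        round(stats::runif(n_metabolites, 0, 2), 3)
    out
  })
}
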