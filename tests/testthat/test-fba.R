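test_that("single-path chain saturates its bound and blocks when cut", {
  # Sxt -> A -> B -> Pxt, all bounds [0, 1], objective = export of P
  ch <- make_linear_chain(2)
  sol <- fba(ch$network, ch$objective)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$z, 1, tolerance = 1e-9)
  # removing the internal step (bounds (0,0)) drops the optimum to 0
  cut <- knockout_reactions(ch$network, "r2")
  sol2 <- fba(cut, ch$objective)
  expect_identical(sol2$status, "optimal")
  expect_equal(sol2$z, 0, tolerance = 1e-9)
})

test_that("optimal solutions satisfy balance and bound feasibility", {
  nets <- c(list(make_linear_chain(3), make_parallel_paths(),
                 make_fig1_like(), make_mini_liver()),
            lapply(1:6, function(s) make_random_network(6, seed = s)))
  for (fx in nets) {
    sol <- fba(fx$network, fx$objective)
    expect_identical(sol$status, "optimal")
    S <- build_stoichiometric_matrix(fx$network, sparse = FALSE)
    expect_lt(max(abs(S %*% sol$v)), 1e-6)
    expect_true(all(sol$v >= fx$network$reactions$lower_bound - 1e-6))
    expect_true(all(sol$v <= fx$network$reactions$upper_bound + 1e-6))
    expect_lte(sol$residual, 1e-6)
  }
})

test_that("FBA optimum equals the vertex-enumeration oracle on small networks", {
  nets <- c(list(make_linear_chain(2), make_parallel_paths(),
                 make_fig1_like()),
            lapply(1:8, function(s) make_random_network(sample(4:8, 1),
                                                        seed = s)))
  for (fx in nets) {
    zo <- oracle_lp_max(fx$network, fx$objective)
    z <- fba(fx$network, fx$objective)$z
    expect_true(zo$feasible)
    expect_equal(z, zo$z, tolerance = 1e-8 * max(1, abs(zo$z)))
    # second independent LP implementation, where it converges
    zp <- pracma_lp_max(fx$network, fx$objective)
    if (!is.na(zp))
      expect_equal(z, zp, tolerance = 1e-7 * max(1, abs(zp)))
  }
})

test_that("objective validation and unbounded problems are reported", {
  ch <- make_linear_chain(2)
  expect_error(fba(ch$network, fba_objective(c(nope = 1))),
               "unknown reaction")
  expect_error(fba_objective(c(r1 = 0)), "nonzero")
  # a reversible unbounded loop pumping the objective without limit
  net <- metabolic_network(
    list(metabolite("Sxt", is_external = TRUE),
         metabolite("Pxt", is_external = TRUE)),
    list(reaction("r1", c(Sxt = -1, Pxt = 1), 0, Inf)))
  sol <- fba(net, fba_objective(c(r1 = 1)))
  expect_identical(sol$status, "unbounded")
  expect_false(is.finite(sol$z) %in% TRUE)
})

test_that("knockouts zero bounds without touching the input network", {
  fig <- make_fig1_like()
  expect_identical(knockout_reactions(fig$network, character(0)),
                   fig$network)
  ko <- knockout_reactions(fig$network, "R1")
  expect_equal(ko$reactions$upper_bound[ko$reactions$id == "R1"], 0)
  expect_equal(fig$network$reactions$upper_bound[1], 1)
  expect_error(knockout_reactions(fig$network, "missing"), "unknown")
  # the single essential import abolishes production; others do not
  expect_equal(fba(ko, fig$objective)$z, 0, tolerance = 1e-9)
  for (rid in setdiff(fig$network$reactions$id, "R1"))
    expect_equal(fba(knockout_reactions(fig$network, rid), fig$objective)$z,
                 1, tolerance = 1e-9)
})

test_that("gene knockouts honour GPR semantics and commute with reaction knockouts", {
  mets <- list(metabolite("Sxt", is_external = TRUE),
               metabolite("Pxt", is_external = TRUE), metabolite("A"))
  net <- metabolic_network(mets, list(
    reaction("r_and", c(Sxt = -1, A = 1), 0, 1, gpr = "g1 AND g2"),
    reaction("r_or", c(Sxt = -1, A = 1), 0, 1, gpr = "g1 OR g2"),
    reaction("r_none", c(A = -1, Pxt = 1), 0, 2)))
  ko <- gene_knockout(net, "g1")
  ub <- stats::setNames(ko$reactions$upper_bound, ko$reactions$id)
  expect_equal(unname(ub["r_and"]), 0)   # subunit lost: complex dead
  expect_equal(unname(ub["r_or"]), 1)    # isoenzyme remains
  expect_equal(unname(ub["r_none"]), 2)  # no rule: untouched

  # commuting diagram on the mini liver: GPR-mediated knockout of the
  # trifunctional folate gene equals knocking its two reactions directly
  ml <- make_mini_liver()
  via_genes <- fba(gene_knockout(ml$network, "MTHFD1"), ml$objective)
  via_rxns <- fba(knockout_reactions(ml$network, c("MTHFD", "MTHFC")),
                  ml$objective)
  expect_equal(via_genes$z, via_rxns$z, tolerance = 1e-9)
})

test_that("essentiality scan matches per-case expectations and is order-invariant", {
  ch <- make_linear_chain(3)
  scan <- essentiality_scan(ch$network, ch$objective)
  expect_true(all(scan$z_relative == 0))  # every step on a path is essential
  expect_true(all(scan$influences_objective))

  pp <- make_parallel_paths()
  scan_pp <- essentiality_scan(pp$network, pp$objective)
  branch <- scan_pp[scan_pp$reaction_id %in% pp$branch_reactions, ]
  expect_true(all(branch$z_relative == 1))  # redundant branches
  expect_false(any(branch$influences_objective))

  # order invariance: reversing reaction order permutes but does not change
  # the records
  ml <- make_mini_liver()
  rev_net <- ml$network
  perm <- rev(seq_len(nrow(rev_net$reactions)))
  rev_net$reactions <- rev_net$reactions[perm, ]
  rev_net$stoichiometry <- rev_net$stoichiometry[rev_net$reactions$id]
  a <- essentiality_scan(ml$network, ml$objective)
  b <- essentiality_scan(rev_net, ml$objective)
  a <- a[order(a$reaction_id), ]; b <- b[order(b$reaction_id), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = 1e-9)

  # scan refused when the wild type cannot be solved
  broken <- set_bounds(ch$network, "r1", 2, 2)  # forces imbalance
  expect_error(essentiality_scan(broken, ch$objective), "refused")
})

test_that("tightening a bound never increases the optimum", {
  for (s in 1:12) {
    fx <- make_random_network(sample(4:8, 1), seed = s)
    z0 <- fba(fx$network, fx$objective)$z
    net <- fx$network
    set.seed(1000 + s)
    for (k in 1:3) {
      i <- sample(nrow(net$reactions), 1)
      shrink <- stats::runif(1)
      new_ub <- net$reactions$lower_bound[i] +
        shrink * (net$reactions$upper_bound[i] - net$reactions$lower_bound[i])
      net <- set_bounds(net, net$reactions$id[i],
                        net$reactions$lower_bound[i], new_ub)
      sol <- fba(net, fx$objective)
      z1 <- if (sol$status == "optimal") sol$z else 0
      expect_lte(z1, z0 + 1e-8)
      z0 <- z1
    }
  }
})

test_that("mini-liver FBA agrees with the scipy/HiGHS cross-check", {
  ml <- make_mini_liver()
  z_scipy <- scipy_lp_max(ml$network, ml$objective)
  expect_false(is.na(z_scipy))
  expect_equal(fba(ml$network, ml$objective)$z, z_scipy, tolerance = 1e-7)
  ko <- knockout_reactions(ml$network, "FTHLDH")
  z_scipy_ko <- scipy_lp_max(ko, ml$objective)
  expect_equal(fba(ko, ml$objective)$z, z_scipy_ko, tolerance = 1e-7)
})
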