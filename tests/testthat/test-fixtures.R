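test_that("the fig1-like fixture has its advertised ground truth", {
  fig <- make_fig1_like()
  # one reversible transport, all bound magnitudes 1, four externals
  expect_equal(sum(fig$network$reactions$reversible), 1)
  expect_true(all(abs(fig$network$reactions$lower_bound) <= 1))
  expect_true(all(fig$network$reactions$upper_bound == 1))
  expect_equal(sum(fig$network$metabolites$is_external), 4)
  # exactly three alternative optimal vertices at z_max = 1 (enumerated)
  o <- oracle_lp_max(fig$network, fig$objective)
  expect_equal(o$z, 1, tolerance = 1e-9)
  expect_equal(o$n_optimal, 3)
  # exactly one essential reaction
  scan <- essentiality_scan(fig$network, fig$objective)
  expect_identical(scan$reaction_id[scan$z_knockout == 0], "R1")
  expect_equal(sum(scan$influences_objective), 1)
  # deterministic optimum
  expect_equal(fba(fig$network, fig$objective)$z, 1, tolerance = 1e-12)
})

test_that("the mini liver reproduces its engineered knockout structure", {
  ml <- make_mini_liver()
  wt <- fba(ml$network, ml$objective)
  expect_identical(wt$status, "optimal")
  expect_gt(wt$z, 0)
  expect_equal(wt$z, 1, tolerance = 1e-9)  # capped by the GSH export

  # the designated essential reaction abolishes GSH production
  z_ess <- fba(knockout_reactions(ml$network, ml$essential), ml$objective)$z
  expect_equal(z_ess, 0, tolerance = 1e-9)
  # the designated partially-limiting reaction leaves 0 < z_rel < 1,
  # at the analytically derived value (alternative formyl-THF drain cap)
  z_part <- fba(knockout_reactions(ml$network, ml$partial), ml$objective)$z
  expect_gt(z_part / wt$z, 0)
  expect_lt(z_part / wt$z, 1)
  expect_equal(z_part / wt$z, ml$partial_z_relative, tolerance = 1e-9)
})

test_that("mini-liver essentiality equals the exhaustive knockout oracle", {
  ml <- make_mini_liver()
  scan <- essentiality_scan(ml$network, ml$objective)
  zwt <- attr(scan, "z_wildtype")
  # analytically derived knockout optima, frozen (flux-balance arithmetic:
  # folate cycle throughput = GSH flux; FTCD drain cap 0.3; NADPH from the
  # dehydrogenases; glutamate has two independent sources)
  expected <- c(EX_Gln = 1, EX_Glu = 1, GLS = 1, EX_CySS = 0, CYSR = 0,
                EX_Ser = 0, SHMT = 0, MTHFD = 0, MTHFC = 0, FTHLDH = 0.3,
                FTCD = 1, GSHS = 0, NADPHOX = 0, EX_GSH = 0,
                EX_Formate = 1, EX_CO2 = 0.3)
  for (rid in names(expected))
    expect_equal(scan$z_knockout[scan$reaction_id == rid],
                 unname(expected[rid]), tolerance = 1e-8, info = rid)
  # independent loop: exhaustive knockout + second LP implementation
  for (rid in ml$network$reactions$id) {
    zp <- pracma_lp_max(knockout_reactions(ml$network, rid), ml$objective)
    if (!is.na(zp))
      expect_equal(scan$z_knockout[scan$reaction_id == rid], zp,
                   tolerance = 1e-7, info = rid)
  }
  expect_equal(sum(scan$influences_objective),
               sum(abs(expected / 1 - 1) > 1e-6))
})

test_that("random networks are deterministic and feasible by construction", {
  a <- make_random_network(7, seed = 11)
  b <- make_random_network(7, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, make_random_network(7, seed = 12)))
  for (s in 1:5) {
    fx <- make_random_network(sample(3:9, 1), seed = s)
    sol <- fba(fx$network, fx$objective)
    expect_identical(sol$status, "optimal")
  }
})

test_that("bounds-table fixture maxima match a naive two-loop oracle", {
  tb <- make_bounds_table(6, 4, seed = 5)
  cons <- grep("^consumption", names(tb))
  for (i in seq_len(nrow(tb))) {
    m <- -Inf
    for (j in cons) m <- max(m, tb[i, j])
    expect_equal(max(as.numeric(tb[i, cons])), m)
  }
  expect_identical(make_bounds_table(6, 4, seed = 5), tb)
})
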