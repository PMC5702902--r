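test_that("competitive inhibition activity matches the closed form", {
  expect_equal(competitive_inhibition_activity(0, 50), 1)     # no inhibitor
  expect_equal(competitive_inhibition_activity(100, 50), 0.5) # I = 2 Ki
  expect_equal(competitive_inhibition_activity(50, 50), 2 / 3)
  # maps any non-negative concentration into (0, 1]
  for (i in c(0, 1e-6, 1, 1e3, 1e9)) {
    a <- competitive_inhibition_activity(i, 50)
    expect_gt(a, 0); expect_lte(a, 1)
  }
  expect_error(competitive_inhibition_activity(1, 0))
})

test_that("feedforward scales wild-type bounds without compounding", {
  ml <- make_mini_liver()
  pb <- pbpk_parameters()
  st <- pbpk_init_state(pb)
  # activity 50% turns bounds [0, 1] into [0, 0.5] exactly
  link <- feedforward_link("FTHLDH", transform = function(conc) 0.5)
  out <- apply_feedforward(ml$network, list(link), st, pb)
  idx <- out$network$reactions$id == "FTHLDH"
  expect_identical(out$network$reactions$lower_bound[idx], 0)
  expect_identical(out$network$reactions$upper_bound[idx], 0.5)
  # activity 1.0 leaves bounds untouched
  link1 <- feedforward_link("FTHLDH", transform = function(conc) 1)
  expect_equal(apply_feedforward(ml$network, list(link1), st,
                                 pb)$network$reactions$upper_bound,
               ml$network$reactions$upper_bound)
  # two consecutive applications stay at 0.5, not 0.25
  again <- apply_feedforward(out$network, list(link), st, pb,
                             wildtype_network = ml$network)
  expect_identical(again$network$reactions$upper_bound[idx], 0.5)
  # negative lower bounds scale symmetrically
  linkS <- feedforward_link("SHMT", transform = function(conc) 0.5)
  outS <- apply_feedforward(ml$network, list(linkS), st, pb)
  iS <- outS$network$reactions$id == "SHMT"
  expect_identical(outS$network$reactions$lower_bound[iS], -5)
  expect_identical(outS$network$reactions$upper_bound[iS], 5)
  # unknown target is a configuration error
  bad <- feedforward_link("nope", ki = 50)
  expect_error(apply_feedforward(ml$network, list(bad), st, pb),
               "unknown reaction")
})

test_that("scaling tables are monotone and audit-consistent", {
  tab <- scaling_table("proportional", z_ref = 2)
  expect_equal(scaling_factor(tab, 2), 1)
  expect_equal(scaling_factor(tab, 1), 0.5)
  expect_equal(scaling_factor(tab, 0), 0)
  lk <- scaling_table("lookup",
                      breakpoints = data.frame(z = c(0, 0.5, 1),
                                               sf = c(0, 0.6, 1)))
  zs <- seq(-0.2, 1.4, by = 0.05)
  sfs <- scaling_factor(lk, zs)
  expect_true(all(diff(sfs) >= -1e-12))
  expect_true(all(sfs >= 0))
  st <- scaling_table("lookup", interpolation = "step",
                      breakpoints = data.frame(z = c(0, 0.5, 1),
                                               sf = c(0, 0.6, 1)))
  expect_equal(scaling_factor(st, 0.75), 0.6)
  expect_error(scaling_table("proportional", z_ref = 0))
})

test_that("uniqueness guard fires on degenerate coupled fluxes only", {
  # objective-value feedback is always safe; single-path fluxes are unique
  ch <- make_linear_chain(2)
  g <- uniqueness_guard(ch$network, ch$objective, "r2")
  expect_true(attr(g, "ok"))
  # symmetric two-path fixture with flux-level coupling: guard fires
  pp <- make_parallel_paths()
  expect_warning(g2 <- uniqueness_guard(pp$network, pp$objective,
                                        pp$branch_reactions),
                 "alternative optima")
  expect_false(attr(g2, "ok"))
  expect_error(uniqueness_guard(pp$network, pp$objective,
                                pp$branch_reactions, strict = TRUE),
               "alternative optima")
})

test_that("feedback-only coupling reproduces the plain PBPK run", {
  ml <- make_mini_liver()
  pb <- pbpk_parameters(dosing = list(route = "iv_bolus", dose = 500,
                                      times = 0))
  m <- multiscale_model(ml$network, ml$objective, pb,
                        config = coupling_config(dt = 5 / 60,
                                                 mode = "feedback_only"))
  tr <- simulate_multiscale(m, 6)
  expect_true(all(tr$z == tr$z[1]))       # constant network: one LP value
  expect_true(all(tr$sf == 1))            # wild-type z maps to SF = 1
  pl <- pbpk_simulate(pb, seq(0, 6, by = 5 / 60))
  i <- match(round(tr$time, 9), round(pl$time, 9))
  expect_lt(max(abs(tr$c_liver_met - pl$c_liver_met[i])), 1e-5)
})

test_that("feedforward-only coupling logs z without feeding it back", {
  ml <- make_mini_liver()
  pb <- pbpk_parameters(dosing = list(route = "iv_bolus", dose = 500,
                                      times = 0))
  # an aggressive transform so the objective visibly responds
  link <- feedforward_link("FTHLDH", transform = function(conc)
    competitive_inhibition_activity(conc, 0.001))
  m <- multiscale_model(ml$network, ml$objective, pb, feedforward = list(link),
                        config = coupling_config(dt = 5 / 60,
                                                 mode = "feedforward_only"))
  tr <- simulate_multiscale(m, 6)
  expect_gt(diff(range(tr$z)), 0.01)      # z(t) varies with the inhibitor
  expect_true(all(tr$sf == 1))            # but is never fed back
  pl <- pbpk_simulate(pb, seq(0, 6, by = 5 / 60))
  i <- match(round(tr$time, 9), round(pl$time, 9))
  expect_lt(max(abs(tr$c_liver_met - pl$c_liver_met[i])), 1e-5)
})

test_that("neutral links make full coupling equal the uncoupled co-simulation", {
  ml <- make_mini_liver()
  pb <- pbpk_parameters(dosing = list(route = "iv_bolus", dose = 500,
                                      times = 0))
  g <- grn_parameters()
  link <- feedforward_link("FTHLDH", transform = function(conc) 1)
  m <- multiscale_model(ml$network, ml$objective, pb, grn = g,
                        feedforward = list(link),
                        config = coupling_config(dt = 5 / 60, mode = "full"))
  tr <- simulate_multiscale(m, 6)
  expect_true(all(tr$sf == 1))
  expect_true(all(tr$activity_FTHLDH == 1))
  # uncoupled reference: plain PBPK (GRN holds CYP3A4 at reference)
  pl <- pbpk_simulate(pb, seq(0, 6, by = 5 / 60))
  i <- match(round(tr$time, 9), round(pl$time, 9))
  expect_lt(max(abs(tr$c_liver_met - pl$c_liver_met[i])), 1e-4)
})

test_that("z(t) is non-increasing while the inhibitor concentration rises", {
  ml <- make_mini_liver()
  pb <- pbpk_parameters(dosing = list(route = "iv_bolus", dose = 500,
                                      times = 0))
  link <- feedforward_link("FTHLDH", transform = function(conc)
    competitive_inhibition_activity(conc, 0.001))
  m <- multiscale_model(ml$network, ml$objective, pb, feedforward = list(link),
                        config = coupling_config(dt = 5 / 60, mode = "full"))
  tr <- simulate_multiscale(m, 6)
  # z at step k responds to the concentration at the step's start (k - 1),
  # so a rise in concentration between rows k and k+1 bounds diff(z)[k+1]
  conc <- tr$c_liver_met
  dz_next <- diff(tr$z)[which(diff(conc) > 0) + 1L]
  expect_true(all(dz_next <= 1e-9, na.rm = TRUE))
  # audit trail: every logged SF re-derives from the logged z
  expect_equal(tr$sf, scaling_factor(m$feedback$table, tr$z),
               tolerance = 1e-12)
})

test_that("simulation aborts with a bounds snapshot when FBA turns infeasible", {
  ch <- make_linear_chain(2)
  pb <- pbpk_parameters(dosing = list(route = "iv_bolus", dose = 500,
                                      times = 0))
  # a network rendered infeasible at positive inhibitor concentration:
  # force the import to run at 1 while the transform closes the export
  net <- set_bounds(ch$network, "r1", 1, 1)
  link <- feedforward_link("r3", transform = function(conc)
    if (conc > 0) 0.2 else 1)
  m <- multiscale_model(net, ch$objective, pb, feedforward = list(link),
                        config = coupling_config(dt = 5 / 60, mode = "full"))
  expect_error(simulate_multiscale(m, 2), "step")
})

test_that("zero dose stays at zero in every coupling mode", {
  ml <- make_mini_liver()
  pb <- pbpk_parameters(dosing = list(route = "iv_bolus", dose = 0,
                                      times = 0))
  for (mode in c("full", "feedforward_only", "feedback_only")) {
    m <- multiscale_model(ml$network, ml$objective, pb,
                          config = coupling_config(dt = 0.25, mode = mode))
    tr <- simulate_multiscale(m, 2)
    expect_true(all(tr$c_liver_met == 0), info = mode)
    expect_true(all(tr$c_liver_parent == 0), info = mode)
  }
})
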