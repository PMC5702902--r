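test_that("GSH conjugation rate follows clearance times unbound concentration", {
  expect_equal(gsh_conjugation_rate(1, 10, 5, 1.8, 0.1),
               10 * (5 / 1.8) * 0.1)   # 2.777... mg/h
  expect_equal(gsh_conjugation_rate(1, 10, 0, 1.8, 0.1), 0)  # no metabolite
  expect_equal(gsh_conjugation_rate(0, 10, 5, 1.8, 0.1), 0)  # SF = 0 shuts
  expect_equal(gsh_conjugation_rate(0.5, 10, 5, 1.8, 0.1),
               0.5 * gsh_conjugation_rate(1, 10, 5, 1.8, 0.1))
  expect_error(gsh_conjugation_rate(1, 10, 5, 0, 0.1))
})

test_that("one-compartment collapse matches the closed-form exponential", {
  p <- pbpk_parameters_onecomp(volume = 40, cl_phase1 = 8, clmet = 0,
                               fup = 1,
                               dosing = list(route = "iv_bolus", dose = 100,
                                             times = 0))
  tr <- pbpk_simulate(p, seq(0, 12, by = 0.25))
  c_num <- tr$p_central / 40
  c_ref <- (100 / 40) * exp(-(8 / 40) * tr$time)
  expect_lt(max(abs(c_num - c_ref) / c_ref), 1e-6)
})

test_that("with all clearances zero the dose is conserved for 24 h", {
  p <- pbpk_parameters(cl_phase1 = 0, clmet = 0, cl_renal = 0,
                       dosing = list(route = "iv_bolus", dose = 500,
                                     times = 0))
  tr <- pbpk_simulate(p, seq(0, 24, by = 1))
  total <- rowSums(tr[, grep("^(depot|p_|m_)", names(tr))])
  expect_lt(max(abs(total - 500) / 500), 1e-8)
  expect_true(all(tr$m_liver == 0))   # no phase-I formation at scale 0 CL
})

test_that("mass reconciles against administered dose within 0.5%", {
  for (dosing in list(
    list(route = "iv_bolus", dose = 500, times = c(0, 12)),
    list(route = "oral", dose = 500, times = 0, ka = 1.2),
    list(route = "iv_infusion", dose = 500, times = 0, duration = 2))) {
    p <- pbpk_parameters(dosing = dosing)
    tr <- pbpk_simulate(p, seq(0, 24, by = 0.5))
    expect_lt(max(tr$mass_balance_error), 0.005)
    expect_true(all(as.matrix(tr[grep("^(depot|p_|m_)", names(tr))]) > -1e-6))
  }
})

test_that("no CYP3A4 activity means no metabolite anywhere", {
  p <- pbpk_parameters(dosing = list(route = "iv_bolus", dose = 200,
                                     times = 0))
  sc <- data.frame(time = 0, cyp3a4_scale = 0, gsh_scale = 1)
  tr <- pbpk_simulate(p, seq(0, 12, by = 0.5), scale_series = sc)
  expect_true(all(abs(as.matrix(tr[grep("^m_", names(tr))])) < 1e-9))
  expect_true(all(tr$cum_formed == 0))
})

test_that("zero dose gives identically zero trajectories", {
  p <- pbpk_parameters(dosing = list(route = "iv_bolus", dose = 0, times = 0))
  tr <- pbpk_simulate(p, seq(0, 6, by = 0.5))
  expect_true(all(as.matrix(tr[grep("^(depot|p_|m_)", names(tr))]) == 0))
})

test_that("faster oral absorption brings the parent peak earlier", {
  tmax <- vapply(c(0.3, 1, 3), function(ka) {
    p <- pbpk_parameters(dosing = list(route = "oral", dose = 500, times = 0,
                                       ka = ka))
    tr <- pbpk_simulate(p, seq(0, 24, by = 0.1))
    tr$time[which.max(tr$p_venous)]
  }, numeric(1))
  expect_true(all(diff(tmax) < 0))
})

test_that("halving the integrator step cap changes Cmax by well under 0.1%", {
  p1 <- pbpk_parameters(solver = list(rtol = 1e-8, atol = 1e-8, hmax = 0.1),
                        dosing = list(route = "iv_bolus", dose = 500,
                                      times = 0))
  p2 <- p1; p2$solver$hmax <- 0.05
  t_grid <- seq(0, 24, by = 0.25)
  cmax1 <- max(pbpk_simulate(p1, t_grid)$c_liver_met)
  cmax2 <- max(pbpk_simulate(p2, t_grid)$c_liver_met)
  expect_lt(abs(cmax1 - cmax2) / cmax2, 1e-3)
})

test_that("weaker GSH conjugation raises the liver metabolite peak", {
  p <- pbpk_parameters(dosing = list(route = "iv_bolus", dose = 500,
                                     times = 0))
  cmax <- vapply(c(1, 0.5, 0.1, 0), function(g) {
    sc <- data.frame(time = 0, cyp3a4_scale = 1, gsh_scale = g)
    max(pbpk_simulate(p, seq(0, 36, by = 0.5), scale_series = sc)$c_liver_met)
  }, numeric(1))
  expect_true(all(diff(cmax) > 0))  # non-decreasing as gsh_scale decreases
})

test_that("piecewise-constant scale series is honoured at step boundaries", {
  p <- pbpk_parameters_onecomp(volume = 40, cl_phase1 = 8, clmet = 0,
                               fup = 1,
                               dosing = list(route = "iv_bolus", dose = 100,
                                             times = 0))
  sc <- data.frame(time = c(0, 4), cyp3a4_scale = c(1, 0), gsh_scale = 1)
  tr <- pbpk_simulate(p, seq(0, 8, by = 0.5), scale_series = sc)
  # formation stops at t = 4: parent amount constant afterwards
  after <- tr$p_central[tr$time >= 4]
  expect_lt(max(abs(after - after[1])), 1e-8)
})
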