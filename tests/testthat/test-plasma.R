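test_that("infusion_rate is the piecewise-constant sum of active events", {
  reg <- regimen_mgkg("IV", dose_mg_per_kg = 4, start = 0, duration = 240,
                      body_weight = 0.25)
  expect_equal(infusion_rate(reg, 100), 4166.667, tolerance = 1e-6)
  expect_equal(infusion_rate(reg, 300), 0)
  # superposition of simultaneous events
  reg2 <- dose_regimen("IV", data.frame(amount = c(1000, 500), start = c(0, 0),
                                        duration = c(10, 10)))
  expect_equal(infusion_rate(reg2, 5), 150)
  # bolus events do not contribute to the rate
  reg3 <- dose_regimen("IV", data.frame(amount = 1000, start = 0, duration = 0))
  expect_equal(infusion_rate(reg3, 0), 0)
})

test_that("constant-infusion plateau matches rate/CL after >= 7 half-lives", {
  pk <- plasma_pk_params(cl_cen = 72.3, v_cen = 11700)
  thalf <- log(2) * 11700 / 72.3
  t_end <- ceiling(8 * thalf)
  reg <- dose_regimen("IV", data.frame(amount = 4166.667 * t_end, start = 0,
                                       duration = t_end))
  sim <- simulate_plasma(pk, reg, seq(0, t_end, length.out = 60))
  expect_equal(tail(sim$conc, 1), css_constant_infusion(4166.667, 72.3),
               tolerance = 0.005)
  expect_equal(css_constant_infusion(4166.67, 72.3), 57.63, tolerance = 1e-4)
  expect_equal(css_constant_infusion(0, 5), 0)
  expect_equal(css_constant_infusion(3.7, 3.7), 1)
})

test_that("bolus into one compartment declines mono-exponentially", {
  pk <- plasma_pk_params(cl_cen = 50, v_cen = 2000)
  reg <- dose_regimen("IV", data.frame(amount = 1e6, start = 0, duration = 0))
  tt <- c(0, 5, 20, 60, 120)
  sim <- simulate_plasma(pk, reg, tt)
  expect_equal(sim$conc, 1e6 / 2000 * exp(-50 / 2000 * tt), tolerance = 1e-7)
})

test_that("the linear system superposes loading and maintenance responses", {
  pk <- plasma_pk_params(cl_cen = 29.2, v_cen = 2053)
  grid <- seq(0, 480, by = 8)
  load_ev <- data.frame(amount = 2e5, start = 0, duration = 1)
  maint_ev <- data.frame(amount = 1e6, start = 0, duration = 240)
  both <- simulate_plasma(pk, dose_regimen("IV", rbind(load_ev, maint_ev)), grid)
  l <- simulate_plasma(pk, dose_regimen("IV", load_ev), grid)
  m <- simulate_plasma(pk, dose_regimen("IV", maint_ev), grid)
  expect_equal(both$conc, l$conc + m$conc, tolerance = 1e-6)
})

test_that("plasma mass balance closes for multi-compartment SC dosing", {
  pk <- plasma_pk_params(cl_cen = 77, v_cen = 5250, q_cen_per1 = 20,
                         v_per1 = 800, ka = 0.03)
  reg <- regimen_mgkg("SC", 3, body_weight = 0.25)
  sim <- simulate_plasma(pk, reg, seq(0, 600, by = 10))
  total <- sim$depot + sim$cen + sim$per1 + sim$per2 + sim$elim
  err <- abs(sim$delivered - total) / pmax(sim$delivered, .Machine$double.eps)
  expect_lt(max(err[-1]), 1e-6)
})

test_that("parameter invariants are enforced", {
  expect_error(plasma_pk_params(cl_cen = 0, v_cen = 10), "positive")
  expect_error(plasma_pk_params(cl_cen = 1, v_cen = 10, q_cen_per1 = 5),
               "nonzero")
  expect_error(dose_regimen("IV", data.frame(amount = -1, start = 0,
                                             duration = 0)), "positive")
})

test_that("bundled continuous-infusion PK rows match their fixtures", {
  b <- test_bundle()
  pinned <- list(paliperidone = c(29.2, 2053), quinidine = c(250, 7314),
                 risperidone = c(370, 3799), verapamil = c(72.3, 11700))
  for (drug in names(pinned)) {
    pk <- plasma_from_bundle(b, drug, "continuous")
    expect_equal(c(pk$cl_cen, pk$v_cen), pinned[[drug]])
    expect_equal(pk$q_cen_per1, 0)
  }
})
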