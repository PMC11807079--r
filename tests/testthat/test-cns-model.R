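test_that("the brainECF balance reproduces its terms one by one", {
  spec <- simple_spec(cl_passive = 1, cl_pgp = 3, fup = 1)
  st <- c(depot = 0, cen = 0, per1 = 0, per2 = 0,
          mv = 1 * spec$physiology$v_mv, ecf = 0, bc = 0,
          sink_ecf = 0, elim = 0)
  spec$physiology$q_ecf <- 1e-300  # isolate the barrier terms
  d <- cns_rhs(500, st, spec)     # t past the infusion: no input
  # C_MV = 1, C_ECF = 0: V_ECF dC_ECF/dt = CL_passive * fup * C_MV = 1
  expect_equal(unname(d["ecf"]), 1, tolerance = 1e-12)
  # efflux returns to the microvasculature: at C_ECF = 1, C_MV = 0
  st2 <- st; st2["mv"] <- 0; st2["ecf"] <- spec$physiology$v_ecf
  d2 <- cns_rhs(500, st2, spec)
  expect_equal(unname(d2["ecf"]), -(1 + 3), tolerance = 1e-9)
  expect_equal(unname(d2["mv"]), (1 + 3), tolerance = 1e-9)
})

test_that("an empty, clearance-free system is at equilibrium", {
  spec <- simple_spec()
  st <- c(depot = 0, cen = 0, per1 = 0, per2 = 0, mv = 0, ecf = 0, bc = 0,
          sink_ecf = 0, elim = 0)
  d <- cns_rhs(500, st, spec)
  expect_true(all(d == 0))
})

test_that("passive equilibrium sits at unity unbound ratio", {
  # CL_Pgp = 0, Q_ECF = 0, no membrane terms: dC_ECF/dt = 0 at C_ECF = fup*C_MV
  spec <- simple_spec(cl_passive = 0.5, cl_pgp = 0, fup = 0.4)
  spec$physiology$q_ecf <- 1e-300
  st <- c(depot = 0, cen = 0, per1 = 0, per2 = 0,
          mv = 2 * spec$physiology$v_mv,
          ecf = 0.4 * 2 * spec$physiology$v_ecf, bc = 0,
          sink_ecf = 0, elim = 0)
  d <- cns_rhs(500, st, spec)
  expect_equal(unname(d["ecf"]), 0, tolerance = 1e-12)
})

test_that("zero dose stays identically zero and doubling the dose doubles everything", {
  spec <- simple_spec(cl_passive = 0.3, cl_pgp = 1)
  grid <- seq(0, 240, by = 10)
  reg0 <- dose_regimen("IV", data.frame(amount = numeric(0), start = numeric(0),
                                        duration = numeric(0)))
  sim0 <- simulate_brain_ecf(
    cns_model_spec(spec$physiology, spec$drug, spec$clearances, spec$plasma, reg0),
    grid)
  expect_true(all(sim0$series$c_ecf == 0))
  expect_true(all(sim0$series$c_plasma == 0))

  sim1 <- simulate_brain_ecf(spec, grid)
  spec2 <- spec
  spec2$regimen <- dose_regimen("IV", data.frame(amount = 2e6, start = 0,
                                                 duration = 10))
  sim2 <- simulate_brain_ecf(spec2, grid)
  expect_equal(sim2$series$c_ecf, 2 * sim1$series$c_ecf, tolerance = 1e-7)
  expect_equal(sim2$series$c_plasma, 2 * sim1$series$c_plasma, tolerance = 1e-7)
})

test_that("global mass balance holds to 1e-6 on every simulation", {
  grid <- seq(0, 480, by = 12)
  specs <- list(
    simple_spec(cl_passive = 0.3, cl_pgp = 2),
    simple_spec(cl_passive = 0.05, cl_pgp = 0, cl_bc_in = 0.4, cl_bc_out = 0.04),
    quinidine_spec("average"))
  for (spec in specs) {
    sim <- simulate_brain_ecf(spec, grid)
    expect_lt(max(abs(mass_balance_error(sim))), 1e-6)
  }
})

test_that("steady-state Kp_uu matches the closed form, membrane terms cancel", {
  expect_equal(steady_state_kpuu(1, 3, 0), 0.25)
  expect_equal(steady_state_kpuu(0.7), 1)
  expect_equal(steady_state_kpuu(0.1367, 0, 0.0003), 0.9978, tolerance = 1e-4)
  expect_error(steady_state_kpuu(0), "cl_passive")

  base <- quinidine_spec("average")
  kss <- steady_state_kpuu(base$clearances$cl_passive,
                           base$clearances$cl_pgp, base$physiology$q_ecf)
  long <- dose_regimen("IV", data.frame(amount = 1e6, start = 0,
                                        duration = 2e4))
  for (with_bc in c(FALSE, TRUE)) {
    spec <- base
    spec$regimen <- long
    if (with_bc) { spec$drug$cl_bc_in <- 0.5; spec$drug$cl_bc_out <- 0.05 }
    sim <- simulate_brain_ecf(spec, seq(0, 2e4, length.out = 80))
    expect_equal(tail(sim$series$kpuu, 1), kss, tolerance = 0.01)
  }
  expect_true(kss > 0 && kss <= 1)
})

test_that("pointwise brainECF concentration is non-increasing in CL_Pgp", {
  grid <- seq(0, 300, by = 10)
  sims <- lapply(c(0, 0.5, 2, 8), function(clp) {
    simulate_brain_ecf(simple_spec(cl_passive = 0.3, cl_pgp = clp), grid)
  })
  for (i in seq_len(length(sims) - 1)) {
    expect_true(all(sims[[i + 1]]$series$c_ecf <=
                      sims[[i]]$series$c_ecf + 1e-10))
  }
})

test_that("numerical solution matches the eigen-decomposition closed form", {
  spec <- simple_spec(cl_passive = 0.3, cl_pgp = 0, fup = 0.4,
                      cl_cen = 50, v_cen = 2000,
                      regimen = dose_regimen("IV", data.frame(
                        amount = 1e6, start = 0, duration = 0)))
  times <- c(0, 1, 5, 15, 30, 60, 120, 240)
  sim <- simulate_brain_ecf(spec, times)
  oracle <- analytic_bolus_solution(spec, 1e6, times)
  scale <- apply(abs(oracle), 2, max)
  for (j in 1:3) {
    num <- sim$series[[c("cen", "mv", "ecf")[j]]]
    expect_lt(max(abs(num - oracle[, j])) / scale[j], spec$rtol * 10)
  }
})

test_that("Kp_uu-scaled plasma profiles are pointwise products", {
  expect_equal(kpuu_scaled_profile(c(1, 2, 3), 1), c(1, 2, 3))
  expect_equal(kpuu_scaled_profile(rep(100, 4), 0.147), rep(14.7, 4))
  expect_equal(kpuu_scaled_profile(numeric(0), 0.23), numeric(0))
  expect_equal(kpuu_scaled_profile(c(0, 0), 0.23), c(0, 0))
  expect_error(kpuu_scaled_profile(1, 0), "positive")
})

test_that("sensitivity sweep: permeability sets the rate, efflux the extent", {
  spec <- simple_spec(cl_passive = 0.3, cl_pgp = 0, fup = 0.3)
  grid <- seq(0, 360, by = 2)
  papp_grid <- c(2, 8, 25, 80)
  erc_grid <- c(1, 2, 5, 10)
  sw <- sensitivity_sweep(spec, papp_grid, erc_grid, grid, ref = 1)
  s <- sw$summary
  # ER_c = 1 column is the passive-only prediction
  expect_true(all(s$cl_pgp[s$erc == 1] == 0))
  for (e in erc_grid) {
    col <- s[s$erc == e, ]
    col <- col[order(col$papp), ]
    expect_true(all(diff(col$tmax_ecf) <= 0))
  }
  for (p in papp_grid) {
    row <- s[s$papp == p, ]
    row <- row[order(row$erc), ]
    expect_true(all(diff(row$auc_ecf) < 0))
  }
  expect_error(sensitivity_sweep(spec, numeric(0), 1, grid), "non-empty")
})
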