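# Shared builders for test scenarios. Everything is constructed in code; the
# only files read are the package's own bundled fixtures.

test_bundle <- local({
  b <- NULL
  function() {
    if (is.null(b)) b <<- load_bundle()
    b
  }
})

# Reference P-gp substrate scenario: quinidine, continuous infusion,
# MDCKII-MDR1 transport data, average in vitro expression.
quinidine_spec <- function(level = "average") {
  spec_from_bundle(test_bundle(), "quinidine", "continuous", "MDCKII-MDR1",
                   "Feng2008", level)
}

# Minimal bespoke spec: one-compartment plasma, passive-only barrier unless
# cl_pgp given; short 10-min infusion of 1 mg unless regimen given.
simple_spec <- function(cl_passive = 0.3, cl_pgp = 0, fup = 0.5,
                        cl_cen = 72.3, v_cen = 11700,
                        regimen = NULL, cl_bc_in = 0, cl_bc_out = 0, ...) {
  if (is.null(regimen))
    regimen <- dose_regimen("IV", data.frame(amount = 1e6, start = 0,
                                             duration = 10))
  cns_model_spec(
    physiology = physiology_params(),
    drug = drug_properties("testdrug", fup = fup, pka = 8.5, species = "base",
                           cl_bc_in = cl_bc_in, cl_bc_out = cl_bc_out),
    clearances = list(cl_passive = cl_passive, cl_pgp = cl_pgp, ref = 1),
    plasma = plasma_pk_params(cl_cen = cl_cen, v_cen = v_cen),
    regimen = regimen, ...)
}

# Closed-form solution of the coupled central-MV-ECF system for a bolus dose,
# one-compartment plasma, passive-only barrier: eigen-decomposition of the
# (lower-dimensional) rate matrix, fully independent of the ODE solver.
analytic_bolus_solution <- function(spec, dose, times) {
  p <- spec$plasma; phys <- spec$physiology
  clp <- spec$clearances$cl_passive
  fup <- spec$drug$fup
  stopifnot(spec$clearances$cl_pgp == 0, p$v_per1 == 0, p$v_per2 == 0)
  A <- rbind(
    c(-(p$cl_cen + phys$q_cbf) / p$v_cen, phys$q_cbf / phys$v_mv, 0),
    c(phys$q_cbf / p$v_cen, -(phys$q_cbf + clp * fup) / phys$v_mv,
      clp / phys$v_ecf),
    c(0, clp * fup / phys$v_mv, -(clp + phys$q_ecf) / phys$v_ecf))
  eg <- eigen(A)
  V <- eg$vectors
  coef <- solve(V, c(dose, 0, 0))
  t(vapply(times, function(tt) Re(V %*% (coef * exp(eg$values * tt)))[, 1],
           numeric(3)))  # columns: cen, mv, ecf amounts (ng)
}
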