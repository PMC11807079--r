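#' CNS compartmental model
#'
#' Coupled linear ODE system: plasma mammillary sub-system (see
#' [simulate_plasma()]), brain microvasculature (MV), brain extracellular
#' fluid (ECF) and brain cell membranes (BC). The brainECF mass balance is
#' \deqn{V_{ECF}\frac{dC_{ECF}}{dt} = CL_{passive} f_{up} C_{MV}
#'   - (CL_{Pgp} + CL_{passive}) C_{ECF} - Q_{ECF} C_{ECF}
#'   - CL_{BC,in} C_{ECF} PHF_{ECF} + CL_{BC,out} C_{BC}}
#' The microvasculature exchanges with plasma by flow (Q_CBF) and with the ECF
#' across the barrier (effluxed drug returns to the MV); the ECF bulk flow
#' Q_ECF drains to a terminal sink whose amount is tracked for mass balance.
#' fup applies on the vascular side only; brainECF is treated as fully unbound.
#' The state is integrated in amounts (ng); concentrations are derived.
#' @name cns_model
NULL

#' Full CNS simulation specification
#'
#' @param physiology a [physiology_params] object.
#' @param drug a [drug_properties] object.
#' @param clearances a [clearance_set] (or list with `cl_passive`, `cl_pgp`,
#'   `ref`), mL/min.
#' @param plasma a [plasma_pk_params] object.
#' @param regimen a [dose_regimen].
#' @param rtol,atol solver tolerances (stiff-capable lsoda).
#' @param hmax optional maximum solver step, min.
#' @return object of class `cns_model_spec`.
#' @export
cns_model_spec <- function(physiology, drug, clearances, plasma, regimen,
                           rtol = 1e-8, atol = 1e-10, hmax = NULL) {
  stopifnot(inherits(physiology, "physiology_params"),
            inherits(drug, "drug_properties"),
            inherits(plasma, "plasma_pk_params"),
            inherits(regimen, "dose_regimen"))
  if (rtol <= 0 || atol <= 0) stop("cns_model_spec: tolerances must be positive")
  if (is.null(clearances$cl_passive) || clearances$cl_passive <= 0)
    stop("cns_model_spec: 'cl_passive' must be positive")
  if (clearances$cl_pgp < 0) stop("cns_model_spec: 'cl_pgp' must be >= 0")
  structure(list(physiology = physiology, drug = drug,
                 clearances = clearances, plasma = plasma, regimen = regimen,
                 rtol = rtol, atol = atol, hmax = hmax),
            class = "cns_model_spec")
}

# full right-hand side; state (ng): depot, cen, per1, per2, mv, ecf, bc,
# sink_ecf, elim
.cns_rhs <- function(t, state, parms) {
  p <- parms$pk; phys <- parms$phys
  c_pl <- state[["cen"]] / p$v_cen
  c_mv <- state[["mv"]] / phys$v_mv
  c_ecf <- state[["ecf"]] / phys$v_ecf
  c_bc <- if (phys$v_bc > 0) state[["bc"]] / phys$v_bc else 0
  abs_rate <- if (!is.na(p$ka)) p$ka * state[["depot"]] else 0
  ex1 <- if (p$v_per1 > 0) p$q_cen_per1 * (c_pl - state[["per1"]] / p$v_per1) else 0
  ex2 <- if (p$v_per2 > 0) p$q_cen_per2 * (c_pl - state[["per2"]] / p$v_per2) else 0
  rate_cen <- if (parms$route == "IV") parms$rate else 0
  rate_dep <- if (parms$route == "SC") parms$rate else 0
  flow_mv <- phys$q_cbf * (c_pl - c_mv)
  pass_in <- parms$cl_passive * parms$fup * c_mv
  barrier_out <- (parms$cl_passive + parms$cl_pgp) * c_ecf
  bc_in <- parms$cl_bc_in * parms$phf * c_ecf
  bc_out <- parms$cl_bc_out * c_bc

  d_depot <- rate_dep - abs_rate
  d_cen <- rate_cen + parms$bioavailability * abs_rate -
    p$cl_cen * c_pl - ex1 - ex2 - flow_mv
  d_mv <- flow_mv - pass_in + barrier_out
  d_ecf <- pass_in - barrier_out - phys$q_ecf * c_ecf - bc_in + bc_out
  d_bc <- bc_in - bc_out
  d <- c(d_depot, d_cen, ex1, ex2, d_mv, d_ecf, d_bc,
         phys$q_ecf * c_ecf, p$cl_cen * c_pl)
  if (any(!is.finite(d)))
    stop("CNS ODE produced non-finite derivative at t=", t, "; state: ",
         paste(names(state), signif(state, 6), sep = "=", collapse = ", "))
  list(d)
}

#' Time derivatives of the CNS system (exposed for testing)
#'
#' @param t time, min.
#' @param state named amounts vector (ng): `depot`, `cen`, `per1`, `per2`,
#'   `mv`, `ecf`, `bc`, `sink_ecf`, `elim`.
#' @param spec a [cns_model_spec].
#' @return named numeric vector of derivatives, ng/min.
#' @export
cns_rhs <- function(t, state, spec) {
  parms <- .cns_parms(spec)
  parms$rate <- infusion_rate(spec$regimen, t)
  d <- .cns_rhs(t, state, parms)[[1]]
  names(d) <- names(state)
  d
}

.cns_parms <- function(spec) {
  list(pk = spec$plasma, phys = spec$physiology,
       cl_passive = spec$clearances$cl_passive,
       cl_pgp = spec$clearances$cl_pgp,
       fup = spec$drug$fup,
       cl_bc_in = spec$drug$cl_bc_in, cl_bc_out = spec$drug$cl_bc_out,
       phf = phf_ecf(spec$drug, spec$physiology),
       route = spec$regimen$route,
       bioavailability = spec$plasma$bioavailability,
       rate = 0)
}

#' Simulate the brainECF concentration time course
#'
#' Integrates the full plasma-MV-ECF-BC system on the requested grid with a
#' stiff-capable solver, restarting at dose-event boundaries. Output is
#' evaluated exactly at the requested times (they are solver mesh points, not
#' interpolated), so observation times can simply be included in `grid`.
#'
#' @param spec a [cns_model_spec].
#' @param grid strictly increasing times, min, starting at 0.
#' @return object of class `cns_simulation`: data.frame `series` with columns
#'   `time`, `c_plasma`, `c_mv`, `c_ecf`, `c_bc` (ng/mL), `kpuu`
#'   (= c_ecf / (fup * c_plasma)), amounts and sinks (ng), `delivered` (ng);
#'   plus scalars `auc_ecf` (ng min/mL, trapezoid) and the generating `spec`.
#' @export
simulate_brain_ecf <- function(spec, grid) {
  stopifnot(inherits(spec, "cns_model_spec"))
  state0 <- c(depot = 0, cen = 0, per1 = 0, per2 = 0, mv = 0, ecf = 0,
              bc = 0, sink_ecf = 0, elim = 0)
  out <- .integrate_piecewise(.cns_rhs, state0, spec$regimen, grid,
                              .cns_parms(spec), spec$rtol, spec$atol,
                              spec$hmax)
  phys <- spec$physiology
  out$c_plasma <- out$cen / spec$plasma$v_cen
  out$c_mv <- out$mv / phys$v_mv
  out$c_ecf <- out$ecf / phys$v_ecf
  out$c_bc <- if (phys$v_bc > 0) out$bc / phys$v_bc else 0
  out$kpuu <- ifelse(out$c_plasma > 0,
                     out$c_ecf / (spec$drug$fup * out$c_plasma), NA_real_)
  out$delivered <- delivered_dose(spec$regimen, out$time)
  res <- list(series = out, auc_ecf = auc_trapezoid(out$time, out$c_ecf),
              spec = spec)
  class(res) <- "cns_simulation"
  res
}

#' Trapezoidal area under a curve
#' @param time,conc paired vectors.
#' @return ng min/mL for a concentration series.
#' @export
auc_trapezoid <- function(time, conc) {
  if (length(time) < 2) return(0)
  sum(diff(time) * (utils::head(conc, -1) + conc[-1]) / 2)
}

#' Relative mass-balance error of a simulation
#'
#' `(delivered - (amounts in all compartments + sinks)) / delivered` at each
#' output time with a delivered dose; the undelivered part of an ongoing
#' infusion is excluded on both sides by construction.
#' @param sim a `cns_simulation`.
#' @return numeric vector of signed relative errors (0/0 at t = 0 reported as 0).
#' @export
mass_balance_error <- function(sim) {
  s <- sim$series
  total <- s$depot + s$cen + s$per1 + s$per2 + s$mv + s$ecf + s$bc +
    s$sink_ecf + s$elim
  ifelse(s$delivered > 0, (s$delivered - total) / s$delivered, 0)
}

#' Steady-state unbound brain/plasma partition coefficient
#'
#' Closed-form consequence of the brainECF balance at steady state (the
#' membrane-partitioning terms cancel):
#' `Kp_uu = cl_passive / (cl_passive + cl_pgp + q_ecf)`. Always in (0, 1]:
#' the model has no influx mechanism, so it cannot produce Kp_uu > 1.
#' @param cl_passive passive BBB clearance, mL/min (> 0).
#' @param cl_pgp P-gp efflux clearance, mL/min (>= 0).
#' @param q_ecf ECF bulk flow, mL/min (>= 0).
#' @return unitless Kp_uu.
#' @export
steady_state_kpuu <- function(cl_passive, cl_pgp = 0, q_ecf = 0) {
  if (any(cl_passive <= 0)) stop("steady_state_kpuu: 'cl_passive' must be > 0")
  if (any(cl_pgp < 0) || any(q_ecf < 0))
    stop("steady_state_kpuu: 'cl_pgp' and 'q_ecf' must be >= 0")
  cl_passive / (cl_passive + cl_pgp + q_ecf)
}

#' Kp_uu-scaled plasma comparison profile
#'
#' The naive "extent-only" prediction: the unbound plasma profile multiplied by
#' an observed steady-state partition coefficient,
#' `C_ECF = C_plasma,u * Kp_uu,BBB`.
#' @param c_plasma_unbound unbound plasma concentrations, ng/mL.
#' @param kpuu_observed observed Kp_uu,BBB (> 0).
#' @return ng/mL series of the same length.
#' @export
kpuu_scaled_profile <- function(c_plasma_unbound, kpuu_observed) {
  if (kpuu_observed <= 0)
    stop("kpuu_scaled_profile: 'kpuu_observed' must be positive")
  c_plasma_unbound * kpuu_observed
}

#' Sensitivity sweep over passive permeability and corrected efflux ratio
#'
#' Re-derives the BBB clearances for every (P_app, ER_c) pair at a fixed REF
#' and simulates each, characterizing how permeability governs the rate (time
#' of the ECF maximum) and efflux the extent (AUC) of brain distribution.
#'
#' @param spec template [cns_model_spec]; its clearances are replaced per pair.
#' @param papp_grid passive permeabilities, 1e-6 cm/s (positive).
#' @param erc_grid corrected efflux ratios (positive; 1 = passive only).
#' @param grid simulation times, min.
#' @param ref relative expression factor held fixed (default: the template's).
#' @return list with `summary` (data.frame: papp, erc, cl_passive, cl_pgp,
#'   tmax_ecf, cmax_ecf, auc_ecf) and `results` (list of `cns_simulation`,
#'   in row order of `summary`).
#' @export
sensitivity_sweep <- function(spec, papp_grid, erc_grid, grid,
                              ref = spec$clearances$ref %||% 1) {
  if (length(papp_grid) == 0 || length(erc_grid) == 0 ||
      any(papp_grid <= 0) || any(erc_grid <= 0))
    stop("sensitivity_sweep: grids must be non-empty and positive")
  combos <- expand.grid(papp = papp_grid, erc = erc_grid,
                        KEEP.OUT.ATTRS = FALSE)
  results <- vector("list", nrow(combos))
  summ <- combos
  summ$cl_passive <- summ$cl_pgp <- summ$tmax_ecf <- summ$cmax_ecf <-
    summ$auc_ecf <- NA_real_
  for (i in seq_len(nrow(combos))) {
    papp <- combos$papp[i]; erc <- combos$erc[i]
    cl <- list(cl_passive = passive_clearance(papp, spec$physiology$sa_bbb),
               cl_pgp = if (erc > 1)
                 pgp_clearance(erc, papp, spec$physiology$sa_bbb_trans, ref)
               else 0,
               ref = ref)
    sp <- spec; sp$clearances <- cl
    sim <- simulate_brain_ecf(sp, grid)
    results[[i]] <- sim
    imax <- which.max(sim$series$c_ecf)
    summ$cl_passive[i] <- cl$cl_passive
    summ$cl_pgp[i] <- cl$cl_pgp
    summ$tmax_ecf[i] <- sim$series$time[imax]
    summ$cmax_ecf[i] <- sim$series$c_ecf[imax]
    summ$auc_ecf[i] <- sim$auc_ecf
  }
  list(summary = summ, results = results)
}

#' @export
print.cns_simulation <- function(x, ...) {
  s <- x$series
  cat("CNS brainECF simulation:", nrow(s), "time points over",
      max(s$time), "min\n")
  cat("  Cmax,ECF:", signif(max(s$c_ecf), 4), "ng/mL at t =",
      s$time[which.max(s$c_ecf)], "min\n")
  cat("  AUC,ECF :", signif(x$auc_ecf, 5), "ng*min/mL\n")
  invisible(x)
}
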