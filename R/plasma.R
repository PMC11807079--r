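#' Empirical plasma PK forcing model
#'
#' The systemic plasma concentration that drives the CNS model is described by
#' a 1-3 compartment linear mammillary model with optional first-order
#' absorption (subcutaneous dosing). Parameters are empirical (taken as given,
#' not estimated here). Internal units: minutes, mL, ng, ng/mL, mL/min.
#' @name plasma_pk
NULL

#' Plasma PK parameters
#'
#' @param cl_cen central elimination clearance, mL/min (> 0).
#' @param q_cen_per1,q_cen_per2 intercompartmental clearances, mL/min (>= 0).
#' @param v_cen central volume, mL (> 0).
#' @param v_per1,v_per2 peripheral volumes, mL (>= 0). A peripheral clearance
#'   may be nonzero only when the corresponding volume is nonzero.
#' @param ka first-order absorption rate from the subcutaneous depot, 1/min
#'   (`NA` for intravenous-only parameter sets).
#' @param bioavailability fraction of a subcutaneous dose reaching the central
#'   compartment (default 1).
#' @return object of class `plasma_pk_params`.
#' @export
plasma_pk_params <- function(cl_cen, v_cen, q_cen_per1 = 0, q_cen_per2 = 0,
                             v_per1 = 0, v_per2 = 0, ka = NA_real_,
                             bioavailability = 1) {
  if (cl_cen <= 0 || v_cen <= 0)
    stop("plasma_pk_params: 'cl_cen' and 'v_cen' must be positive")
  if (q_cen_per1 < 0 || q_cen_per2 < 0 || v_per1 < 0 || v_per2 < 0)
    stop("plasma_pk_params: peripheral clearances and volumes must be >= 0")
  if ((q_cen_per1 > 0 && v_per1 == 0) || (q_cen_per2 > 0 && v_per2 == 0))
    stop("plasma_pk_params: nonzero peripheral clearance requires nonzero volume")
  if (!is.na(ka) && ka <= 0)
    stop("plasma_pk_params: 'ka' must be positive when given")
  structure(list(cl_cen = cl_cen, v_cen = v_cen,
                 q_cen_per1 = q_cen_per1, q_cen_per2 = q_cen_per2,
                 v_per1 = v_per1, v_per2 = v_per2, ka = ka,
                 bioavailability = bioavailability),
            class = "plasma_pk_params")
}

#' Dosing regimen
#'
#' A regimen is a set of dose events. Each event delivers `amount` ng starting
#' at `start` min; `duration > 0` means a zero-order infusion over that time,
#' `duration = 0` a bolus (added instantaneously to the depot for subcutaneous
#' routes, to the central compartment for intravenous).
#'
#' @param route `"IV"` or `"SC"`.
#' @param events data.frame with columns `amount` (ng), `start` (min),
#'   `duration` (min).
#' @param body_weight rat body weight in kg, recorded for provenance of mg/kg
#'   conversions.
#' @return object of class `dose_regimen`.
#' @export
dose_regimen <- function(route = c("IV", "SC"), events, body_weight = 0.25) {
  route <- match.arg(route)
  stopifnot(is.data.frame(events),
            all(c("amount", "start", "duration") %in% names(events)))
  # zero rows = no dose (useful for null scenarios); amounts, when present, > 0
  if (any(events$amount <= 0)) stop("dose_regimen: amounts must be positive")
  if (any(events$start < 0) || any(events$duration < 0))
    stop("dose_regimen: times must be non-negative")
  structure(list(route = route, events = events, body_weight = body_weight),
            class = "dose_regimen")
}

#' Build a regimen from mg/kg doses
#'
#' Convenience wrapper converting the dosing-table convention (loading +
#' maintenance doses in mg/kg body weight) into ng amounts.
#' @param route `"IV"` or `"SC"`.
#' @param dose_mg_per_kg vector of doses, mg/kg.
#' @param start vector of start times, min.
#' @param duration vector of infusion durations, min (0 = bolus).
#' @param body_weight kg; default typical rat, 0.25 kg.
#' @export
regimen_mgkg <- function(route, dose_mg_per_kg, start = 0, duration = 0,
                         body_weight = 0.25) {
  amount_ng <- dose_mg_per_kg * body_weight * 1e6
  ev <- data.frame(amount = amount_ng,
                   start = rep_len(start, length(amount_ng)),
                   duration = rep_len(duration, length(amount_ng)))
  dose_regimen(route, ev, body_weight)
}

#' Total infusion rate of a regimen at time t
#'
#' Sum of `amount / duration` over all infusion events active at `t`
#' (start <= t < start + duration). Bolus events (duration 0) contribute to
#' initial conditions / state jumps, not to the rate. Vectorized over `t`.
#' @param regimen a [dose_regimen].
#' @param t time(s), min.
#' @return rate(s), ng/min.
#' @export
infusion_rate <- function(regimen, t) {
  ev <- regimen$events[regimen$events$duration > 0, , drop = FALSE]
  vapply(t, function(tt) {
    act <- ev$start <= tt & tt < ev$start + ev$duration
    sum(ev$amount[act] / ev$duration[act])
  }, numeric(1))
}

# Event-boundary times at which the piecewise-constant input changes or a
# bolus fires; integration is restarted at each.
.regimen_breaks <- function(regimen, t_end) {
  ev <- regimen$events
  sort(unique(c(0, ev$start, ev$start + ev$duration, t_end)))
}

# Bolus amounts firing exactly at time tt
.bolus_at <- function(regimen, tt) {
  ev <- regimen$events
  sum(ev$amount[ev$duration == 0 & ev$start == tt])
}

# Piecewise integration shared by the plasma-only and CNS systems.
# rhs(t, state, parms) must accept parms$rate (constant segment input, ng/min).
.integrate_piecewise <- function(rhs, state0, regimen, grid, parms,
                                 rtol, atol, hmax = NULL) {
  if (is.unsorted(grid, strictly = TRUE) || grid[1] < 0)
    stop("simulation grid must be strictly increasing and start at t >= 0")
  t_end <- max(grid)
  breaks <- .regimen_breaks(regimen, t_end)
  breaks <- breaks[breaks <= t_end]
  if (max(breaks) < t_end) breaks <- c(breaks, t_end)
  state <- state0
  depot_ix <- which(names(state0) == "depot")
  cen_ix <- which(names(state0) == "cen")
  out <- matrix(NA_real_, nrow = length(grid), ncol = length(state0) + 1,
                dimnames = list(NULL, c("time", names(state0))))
  for (i in seq_len(length(breaks) - 1)) {
    b0 <- breaks[i]; b1 <- breaks[i + 1]
    bol <- .bolus_at(regimen, b0)
    if (bol > 0) {
      tgt <- if (regimen$route == "SC") depot_ix else cen_ix
      state[tgt] <- state[tgt] + bol
    }
    seg_times <- sort(unique(c(b0, grid[grid >= b0 & grid <= b1], b1)))
    parms$rate <- infusion_rate(regimen, (b0 + b1) / 2)
    sol <- deSolve::lsoda(y = state, times = seg_times, func = rhs,
                          parms = parms, rtol = rtol, atol = atol,
                          hmax = if (is.null(hmax)) Inf else hmax)
    if (attr(sol, "istate")[1] < 0)
      stop("ODE solver failed on [", b0, ", ", b1, "] min (rtol=", rtol,
           ", atol=", atol, ")")
    for (r in seq_len(nrow(sol))) {
      tt <- sol[r, 1]
      hit <- which(abs(grid - tt) < 1e-12)
      if (length(hit)) out[hit, ] <- matrix(rep(sol[r, ], length(hit)),
                                            nrow = length(hit), byrow = TRUE)
    }
    state <- sol[nrow(sol), -1]
  }
  as.data.frame(out)
}

# plasma-only right-hand side; state: depot, cen, per1, per2, elim (ng)
.plasma_rhs <- function(t, state, parms) {
  p <- parms$pk
  c_pl <- state[["cen"]] / p$v_cen
  abs_rate <- if (!is.na(p$ka)) p$ka * state[["depot"]] else 0
  ex1 <- if (p$v_per1 > 0) p$q_cen_per1 * (c_pl - state[["per1"]] / p$v_per1) else 0
  ex2 <- if (p$v_per2 > 0) p$q_cen_per2 * (c_pl - state[["per2"]] / p$v_per2) else 0
  rate_cen <- if (parms$route == "IV") parms$rate else 0
  rate_dep <- if (parms$route == "SC") parms$rate else 0
  d_depot <- rate_dep - abs_rate
  d_cen <- rate_cen + parms$bioavailability * abs_rate -
    p$cl_cen * c_pl - ex1 - ex2
  d <- c(d_depot, d_cen, ex1, ex2, p$cl_cen * c_pl)
  if (any(!is.finite(d)))
    stop("plasma ODE produced non-finite derivative at t=", t,
         "; state: ", paste(signif(state, 6), collapse = ", "))
  list(d)
}

#' Simulate the plasma concentration time course
#'
#' Integrates the linear compartmental system under the regimen and returns the
#' central (total) plasma concentration on the requested grid. Integration is
#' restarted at every dose-event boundary so the piecewise-constant input is
#' handled exactly.
#'
#' @param params a [plasma_pk_params] object.
#' @param regimen a [dose_regimen].
#' @param grid strictly increasing times from 0, min.
#' @return data.frame: `time` (min), `conc` (ng/mL, central), plus compartment
#'   amounts (`depot`, `cen`, `per1`, `per2`, `elim`, ng) and `delivered` (ng).
#' @export
simulate_plasma <- function(params, regimen, grid, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "plasma_pk_params"), inherits(regimen, "dose_regimen"))
  state0 <- c(depot = 0, cen = 0, per1 = 0, per2 = 0, elim = 0)
  parms <- list(pk = params, route = regimen$route,
                bioavailability = params$bioavailability, rate = 0)
  out <- .integrate_piecewise(.plasma_rhs, state0, regimen, grid, parms,
                              rtol, atol)
  out$conc <- out$cen / params$v_cen
  out$delivered <- delivered_dose(regimen, out$time)
  out[, c("time", "conc", "depot", "cen", "per1", "per2", "elim", "delivered")]
}

#' Cumulative dose delivered by a regimen up to each time
#'
#' @param regimen a [dose_regimen].
#' @param t times, min.
#' @return ng delivered (boluses count at their start time; infusions pro rata).
#' @export
delivered_dose <- function(regimen, t) {
  ev <- regimen$events
  vapply(t, function(tt) {
    bol <- sum(ev$amount[ev$duration == 0 & ev$start <= tt])
    inf <- ev[ev$duration > 0, , drop = FALSE]
    frac <- pmin(pmax((tt - inf$start) / inf$duration, 0), 1)
    bol + sum(inf$amount * frac)
  }, numeric(1))
}

#' Steady-state concentration under a constant-rate infusion
#'
#' Closed-form check for the ODE path: `Css = rate / cl_cen`.
#' @param rate infusion rate, ng/min.
#' @param cl_cen elimination clearance, mL/min.
#' @return ng/mL.
#' @export
css_constant_infusion <- function(rate, cl_cen) {
  if (cl_cen <= 0) stop("css_constant_infusion: 'cl_cen' must be positive")
  if (rate < 0) stop("css_constant_infusion: 'rate' must be non-negative")
  rate / cl_cen
}
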