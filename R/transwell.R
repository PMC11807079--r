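#' Transwell transport arithmetic and in vitro - in vivo clearance scaling
#'
#' The functions in this file turn literature transwell measurements (apparent
#' permeability P_app in 1e-6 cm/s and corrected efflux ratio ER_c) into in
#' vivo blood-brain-barrier clearances:
#' \deqn{CL_{passive} = P_{app,A:B}[I] \cdot SA_{BBB} \cdot 60}
#' \deqn{CL_{Pgp} = (ER_c - 1) \cdot 2 P_{app,A:B}[I] \cdot SA_{BBB,trans} \cdot REF \cdot 60}
#' with the relative expression factor
#' \deqn{REF = \frac{\textrm{P-gp expression in vivo}}{\textrm{P-gp expression in vitro}}}
#' Permeabilities are exchanged in units of 1e-6 cm/s throughout the package;
#' the 1e-6 factor is applied exactly once, inside the two clearance functions,
#' so the results are in mL/min.
#' @name ivive
NULL

.check_pos <- function(x, what, fn) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop(fn, ": '", what, "' must be positive and finite")
  invisible(x)
}

#' Efflux ratio from directional permeabilities
#'
#' @param papp_ba basolateral-to-apical apparent permeability, 1e-6 cm/s.
#' @param papp_ab apical-to-basolateral apparent permeability, 1e-6 cm/s.
#' @return unitless efflux ratio `papp_ba / papp_ab`.
#' @export
efflux_ratio <- function(papp_ba, papp_ab) {
  .check_pos(papp_ba, "papp_ba", "efflux_ratio")
  .check_pos(papp_ab, "papp_ab", "efflux_ratio")
  papp_ba / papp_ab
}

#' Corrected efflux ratio
#'
#' Divides the efflux ratio by the efflux ratio measured with P-gp inhibited
#' (or in the parental line), isolating P-gp's contribution from other
#' transporters.
#' @param er efflux ratio with P-gp active.
#' @param er_inh efflux ratio under P-gp inhibition.
#' @return unitless corrected efflux ratio `er / er_inh`.
#' @export
corrected_efflux_ratio <- function(er, er_inh) {
  .check_pos(er, "er", "corrected_efflux_ratio")
  .check_pos(er_inh, "er_inh", "corrected_efflux_ratio")
  er / er_inh
}

#' Relative expression factor (REF)
#'
#' Ratio of in vivo to in vitro P-gp abundance (fmol/ug total protein).
#' A "no REF" scenario is represented by `REF = 1`.
#' @param expr_in_vivo in vivo P-gp abundance, fmol/ug total protein.
#' @param expr_in_vitro in vitro P-gp abundance, fmol/ug total protein.
#' @return unitless scaling factor.
#' @export
relative_expression_factor <- function(expr_in_vivo, expr_in_vitro) {
  .check_pos(expr_in_vivo, "expr_in_vivo", "relative_expression_factor")
  .check_pos(expr_in_vitro, "expr_in_vitro", "relative_expression_factor")
  expr_in_vivo / expr_in_vitro
}

#' Passive diffusion clearance across the BBB
#'
#' @param papp_ab_inh apical-to-basolateral apparent permeability with P-gp
#'   inhibited (or from a parental cell line), 1e-6 cm/s.
#' @param sa_bbb BBB surface area, cm^2.
#' @return passive clearance, mL/min.
#' @examples
#' passive_clearance(31.9, 155)  # 0.29667 mL/min
#' @export
passive_clearance <- function(papp_ab_inh, sa_bbb) {
  if (any(is.na(papp_ab_inh)))
    stop("passive_clearance: missing P_app,A:B[I]")
  .check_pos(papp_ab_inh, "papp_ab_inh", "passive_clearance")
  .check_pos(sa_bbb, "sa_bbb", "passive_clearance")
  papp_ab_inh * 1e-6 * sa_bbb * 60
}

#' P-gp mediated efflux clearance across the BBB
#'
#' Kalvass-type scaling of the corrected efflux ratio. A corrected efflux
#' ratio below 1 (possible with noisy inputs) is clamped to no net efflux with
#' a warning: the method defines efflux only, never influx.
#' @param er_c corrected efflux ratio, unitless.
#' @param papp_ab_inh passive permeability, 1e-6 cm/s.
#' @param sa_bbb_trans transcellular BBB surface area, cm^2.
#' @param ref relative expression factor (1 = "no REF" scenario).
#' @return P-gp efflux clearance, mL/min.
#' @export
pgp_clearance <- function(er_c, papp_ab_inh, sa_bbb_trans, ref = 1) {
  .check_pos(er_c, "er_c", "pgp_clearance")
  .check_pos(papp_ab_inh, "papp_ab_inh", "pgp_clearance")
  .check_pos(sa_bbb_trans, "sa_bbb_trans", "pgp_clearance")
  .check_pos(ref, "ref", "pgp_clearance")
  cl <- (er_c - 1) * 2 * papp_ab_inh * 1e-6 * sa_bbb_trans * ref * 60
  if (any(cl < 0)) {
    warning("pgp_clearance: ER_c < 1 clamped to CL_Pgp = 0 (no influx mechanism)")
    cl <- pmax(cl, 0)
  }
  cl
}

#' Mean and population standard deviation
#'
#' Literature summary statistic used for reporting P_app and ER_c values across
#' sources. The SD uses divisor n (population form), which reproduces the
#' printed literature summaries, unlike the sample (n - 1) form.
#' @param values non-empty numeric vector.
#' @return named numeric vector `c(mean, sd)`.
#' @export
summarize_values <- function(values) {
  if (length(values) == 0L || any(!is.finite(values)))
    stop("summarize_values: need a non-empty vector of finite values")
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  c(mean = m, sd = s)
}

#' Fold-range of a set of positive values
#'
#' @param values non-empty positive numeric vector.
#' @return `max(values) / min(values)`.
#' @export
fold_range <- function(values) {
  if (length(values) == 0L) stop("fold_range: empty input")
  .check_pos(values, "values", "fold_range")
  max(values) / min(values)
}

#' Scale one transwell record to in vivo BBB clearances
#'
#' Applies the passive and P-gp clearance scalings to a single transwell
#' record, returning a `clearance_set` that the CNS model consumes.
#' @param record one-row data.frame (or list) with at least `papp_ab_inh`
#'   (1e-6 cm/s) and `er_c`; typically a row of the bundled transport table.
#' @param physiology a [physiology_params] object (supplies the surface areas).
#' @param ref relative expression factor; 1 for the "no REF" scenario.
#' @return object of class `clearance_set` with fields `cl_passive`, `cl_pgp`
#'   (mL/min), `ref` and `provenance`.
#' @export
clearance_set <- function(record, physiology, ref = 1) {
  papp <- record$papp_ab_inh
  if (is.null(papp) || is.na(papp))
    stop("clearance_set: record '", record$source %||% "?",
         "' has no P_app,A:B[I] value")
  cl_pass <- passive_clearance(papp, physiology$sa_bbb)
  cl_pgp <- if (!is.null(record$er_c) && !is.na(record$er_c) && record$er_c > 1)
    pgp_clearance(record$er_c, papp, physiology$sa_bbb_trans, ref) else 0
  structure(list(cl_passive = cl_pass, cl_pgp = cl_pgp, ref = ref,
                 provenance = list(source = record$source %||% NA_character_,
                                   drug = record$drug %||% NA_character_,
                                   cell_line = record$cell_line %||% NA_character_)),
            class = "clearance_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Literature summary statistics for transwell measurements
#'
#' Reproduces the across-source summaries reported for the bundled transport
#' table: per-drug mean, population SD, n and fold-range of either the passive
#' permeability or the corrected efflux ratio, optionally restricted to a set
#' of cell lines and/or excluding sources.
#'
#' @param transwell data.frame with columns `drug`, `cell_line`,
#'   `papp_ab_inh`, `er_c`, `source`.
#' @param drug drug name to summarize.
#' @param metric `"papp"` or `"erc"`.
#' @param cell_lines optional character vector restricting the rows. Values may
#'   be full cell-line names or prefixes (e.g. `"LLC-PK1"` matches both the
#'   mdr1a and MDR1 transfections).
#' @param exclude_sources optional character vector of source keys to drop.
#' @return one-row data.frame: `drug`, `metric`, `n`, `mean`, `sd`,
#'   `fold_range`.
#' @export
lit_summary <- function(transwell, drug, metric = c("papp", "erc"),
                        cell_lines = NULL, exclude_sources = NULL) {
  metric <- match.arg(metric)
  rows <- transwell[transwell$drug == drug, , drop = FALSE]
  if (!is.null(cell_lines)) {
    keep <- Reduce(`|`, lapply(cell_lines, function(cl)
      startsWith(rows$cell_line, cl)))
    rows <- rows[keep, , drop = FALSE]
  }
  if (!is.null(exclude_sources))
    rows <- rows[!rows$source %in% exclude_sources, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("lit_summary: no records for drug '", drug, "' under the given filters")
  vals <- if (metric == "papp") rows$papp_ab_inh else rows$er_c
  vals <- vals[!is.na(vals)]
  st <- summarize_values(vals)
  data.frame(drug = drug, metric = metric, n = length(vals),
             mean = unname(st["mean"]), sd = unname(st["sd"]),
             fold_range = fold_range(vals))
}
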