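#' Prediction-error framework
#'
#' Predictions are scored with the symmetrized relative error
#' \deqn{PE = \frac{Y_{pred} - Y_{obs}}{(Y_{pred} + Y_{obs})/2}}
#' which is antisymmetric in its arguments and bounded in (-2, 2). A k-fold
#' discrepancy between prediction and observation corresponds to
#' |PE| = 2(k - 1)/(k + 1); a prediction is deemed accurate when the median PE
#' falls within twofold error, i.e. |median PE| <= 2/3 (displayed as 0.67).
#' @name pe_framework
NULL

#' Symmetrized prediction error
#'
#' @param y_pred predicted concentration(s), >= 0, ng/mL.
#' @param y_obs observed concentration(s), > 0, ng/mL.
#' @return unitless PE in (-2, 2); vectorized.
#' @examples
#' prediction_error(2, 1)  # 0.667, the twofold boundary
#' @export
prediction_error <- function(y_pred, y_obs) {
  if (any(y_pred < 0)) stop("prediction_error: 'y_pred' must be >= 0")
  if (any(y_obs <= 0)) stop("prediction_error: 'y_obs' must be > 0 (PE is undefined at 0)")
  (y_pred - y_obs) / ((y_pred + y_obs) / 2)
}

#' PE magnitude corresponding to a k-fold error
#'
#' Closed form of the PE at `y_pred = k * y_obs`: `2(k - 1)/(k + 1)`.
#' @param k fold level, >= 1.
#' @return PE magnitude in \[0, 2).
#' @export
fold_threshold <- function(k) {
  if (any(k < 1)) stop("fold_threshold: 'k' must be >= 1")
  2 * (k - 1) / (k + 1)
}

#' Classify a median PE into fold-error bands
#'
#' Half-open intervals on |median PE|: within twofold `[0, t2)`, two-to-three
#' `[t2, t3)`, three-to-five `[t3, t5)`, beyond fivefold `[t5, 2)`, with
#' `t_k = 2(k - 1)/(k + 1)`.
#' @param pe median PE value(s).
#' @return factor with levels `"<2-fold"`, `"2-3-fold"`, `"3-5-fold"`, `">5-fold"`.
#' @export
fold_class <- function(pe) {
  cuts <- c(0, fold_threshold(c(2, 3, 5)), 2)
  cut(abs(pe), breaks = cuts, right = FALSE, include.lowest = TRUE,
      labels = c("<2-fold", "2-3-fold", "3-5-fold", ">5-fold"))
}

#' Observation series constructor / validator
#'
#' @param data data.frame with columns `animal_id`, `time_min`,
#'   `conc_ng_per_mL` (all concentrations > 0 --- PE is undefined at 0).
#' @param drug,regimen_class,provenance metadata keys carried as attributes;
#'   `provenance` is `"real"` or `"synthetic"`.
#' @return data.frame of class `observation_series`.
#' @export
observation_series <- function(data, drug = NA_character_,
                               regimen_class = NA_character_,
                               provenance = c("real", "synthetic")) {
  provenance <- match.arg(provenance)
  need <- c("animal_id", "time_min", "conc_ng_per_mL")
  if (!all(need %in% names(data)))
    stop("observation_series: missing columns: ",
         paste(setdiff(need, names(data)), collapse = ", "))
  if (any(data$conc_ng_per_mL <= 0))
    stop("observation_series: concentrations must be positive")
  if (any(data$time_min < 0))
    stop("observation_series: times must be >= 0")
  structure(data, drug = drug, regimen_class = regimen_class,
            provenance = provenance,
            class = c("observation_series", "data.frame"))
}

#' Read / write observation CSV (animal_id, time_min, conc_ng_per_mL)
#' @param path CSV file.
#' @param ... passed to [observation_series()].
#' @export
read_observations <- function(path, ...) {
  observation_series(utils::read.csv(path), ...)
}

#' @rdname read_observations
#' @param obs an `observation_series`.
#' @export
write_observations <- function(obs, path) {
  utils::write.csv(as.data.frame(obs), path, row.names = FALSE)
  invisible(path)
}

#' Median prediction error of a model against observations
#'
#' The model is evaluated at the exact observation times (the simulation is run
#' on a grid containing them). PEs are pooled across animals before taking the
#' median (even counts use the midpoint of the central pair); per-animal
#' medians are available as an option.
#'
#' @param predictions data.frame `time`, `conc` of model predictions, or a
#'   `cns_simulation` (its `c_ecf` is used).
#' @param observations an [observation_series] (or conforming data.frame).
#' @param per_animal if `TRUE`, return a median per animal instead of pooling.
#' @return pooled median PE (scalar), or a named vector per animal.
#' @export
median_pe <- function(predictions, observations, per_animal = FALSE) {
  pe <- pe_values(predictions, observations)
  if (per_animal) {
    tapply(pe, observations$animal_id, stats::median)
  } else {
    stats::median(pe)
  }
}

#' Per-observation prediction errors
#' @inheritParams median_pe
#' @return numeric vector of PEs aligned with the observation rows.
#' @export
pe_values <- function(predictions, observations) {
  if (inherits(predictions, "cns_simulation"))
    predictions <- data.frame(time = predictions$series$time,
                              conc = predictions$series$c_ecf)
  if (nrow(observations) == 0L) stop("pe_values: no observations")
  ix <- match(observations$time_min, predictions$time)
  if (any(is.na(ix)))
    stop("pe_values: predictions missing at observation times: ",
         paste(unique(observations$time_min[is.na(ix)]), collapse = ", "),
         " (include them in the simulation grid)")
  prediction_error(predictions$conc[ix], observations$conc_ng_per_mL)
}

#' Full PE report for one prediction/observation pair
#'
#' @inheritParams median_pe
#' @param keys named list of stratification keys (e.g. drug, cell_line,
#'   source, expression_level, regimen).
#' @return object of class `pe_report`: list with `pe` (per-observation),
#'   `median_pe`, `fold_class`, `n`, and `keys`.
#' @export
pe_report <- function(predictions, observations, keys = list()) {
  pe <- pe_values(predictions, observations)
  med <- stats::median(pe)
  structure(list(pe = pe, median_pe = med,
                 fold_class = as.character(fold_class(med)),
                 n = length(pe), keys = keys),
            class = "pe_report")
}

#' Fraction of predictions within twofold, stratified
#'
#' For each stratum defined by the requested keys, the fraction of reports
#' whose |median PE| <= 2/3 (the exact twofold bound; 0.67 is display-only),
#' with the underlying counts.
#' @param reports list of [pe_report] objects.
#' @param stratify_by character vector of key names present in every report's
#'   `keys`.
#' @return data.frame with the key columns, `n_within`, `n_total`,
#'   `pct_within` (percent).
#' @export
summarize_within_twofold <- function(reports, stratify_by = "drug") {
  if (length(reports) == 0L) stop("summarize_within_twofold: no reports")
  rows <- lapply(reports, function(r) {
    missing <- setdiff(stratify_by, names(r$keys))
    if (length(missing))
      stop("summarize_within_twofold: unknown stratification key(s): ",
           paste(missing, collapse = ", "))
    cbind(as.data.frame(r$keys[stratify_by], stringsAsFactors = FALSE),
          median_pe = r$median_pe)
  })
  df <- do.call(rbind, rows)
  df$within <- abs(df$median_pe) <= 2 / 3
  groups <- split(df, df[, stratify_by, drop = FALSE], drop = TRUE)
  agg <- do.call(rbind, lapply(groups, function(g)
    cbind(g[1, stratify_by, drop = FALSE],
          n_within = sum(g$within), n_total = nrow(g))))
  rownames(agg) <- NULL
  agg$pct_within <- 100 * agg$n_within / agg$n_total
  agg
}

#' Expression-bandwidth brainECF predictions
#'
#' Simulates the model once per reported in vitro P-gp expression level
#' (lowest / average / highest) for a cell line and returns the pointwise
#' envelope. Higher in vitro expression gives a lower REF, hence lower CL_Pgp
#' and the upper concentration curve; a cell line with a single reported
#' expression value yields a degenerate band (lower = central = upper). With
#' `no_ref = TRUE` a single REF = 1 curve independent of expression is
#' returned.
#'
#' @param spec template [cns_model_spec] (clearances replaced per level).
#' @param record transwell record (one row: `papp_ab_inh`, `er_c`, ...).
#' @param expression_records data.frame with columns `cell_line`, `level`
#'   (`highest`/`average`/`lowest`), `expression` (fmol/ug) for ONE cell line.
#' @param expr_in_vivo in vivo P-gp abundance, fmol/ug (e.g. 19.4).
#' @param grid simulation times, min.
#' @param no_ref bypass expression scaling (REF = 1 scenario).
#' @return object of class `prediction_band`: list with `time`, `lower`,
#'   `central`, `upper` (ng/mL), `levels` (data.frame level, expression, ref,
#'   cl_pgp), and `simulations`.
#' @export
bandwidth_predictions <- function(spec, record, expression_records,
                                  expr_in_vivo, grid, no_ref = FALSE) {
  if (no_ref) {
    lv <- data.frame(level = "no_ref", expression = NA_real_, ref = 1)
  } else {
    if (nrow(expression_records) == 0L)
      stop("bandwidth_predictions: need at least one expression record")
    lv <- data.frame(level = expression_records$level,
                     expression = expression_records$expression)
    lv$ref <- relative_expression_factor(expr_in_vivo, lv$expression)
  }
  sims <- vector("list", nrow(lv))
  lv$cl_pgp <- NA_real_
  for (i in seq_len(nrow(lv))) {
    sp <- spec
    sp$clearances <- clearance_set(record, spec$physiology, ref = lv$ref[i])
    lv$cl_pgp[i] <- sp$clearances$cl_pgp
    sims[[i]] <- simulate_brain_ecf(sp, grid)
  }
  curves <- sapply(sims, function(s) s$series$c_ecf)
  curves <- matrix(curves, nrow = length(grid))
  central_ix <- if (nrow(lv) == 1L) 1L else {
    ia <- which(lv$level == "average")
    if (length(ia)) ia[1] else which.min(abs(lv$cl_pgp - stats::median(lv$cl_pgp)))
  }
  structure(list(time = grid,
                 lower = apply(curves, 1, min),
                 central = curves[, central_ix],
                 upper = apply(curves, 1, max),
                 levels = lv, simulations = sims),
            class = "prediction_band")
}
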