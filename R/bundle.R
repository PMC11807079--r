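#' Literature data bundle
#'
#' The package ships the literature parameter tables as plain-text fixtures:
#' transwell transport records, in vitro P-gp expression levels, plasma PK
#' parameters, dosing regimens, drug properties, default physiology and scalar
#' constants (in vivo P-gp abundance, observed Kp_uu values). `load_bundle()`
#' reads and validates them; failures name the file, row and violated rule.
#' @name bundle
NULL

.drug_vocab <- c("acetaminophen", "raclopride", "morphine", "paliperidone",
                 "quinidine", "risperidone", "verapamil")
.cell_line_vocab <- c("Caco-2", "MDCKII-MDR1", "LLC-PK1-mdr1a", "LLC-PK1-MDR1")
.level_vocab <- c("highest", "average", "lowest")

.check_vocab <- function(values, vocab, file, column) {
  bad <- which(!values %in% vocab)
  if (length(bad))
    stop("load_bundle: ", file, " row ", bad[1], ": ", column, " '",
         values[bad[1]], "' not in {", paste(vocab, collapse = ", "), "}")
}

#' Load and validate the literature bundle
#'
#' @param path directory containing the fixture files; defaults to the
#'   bundled copies under the package's `extdata`.
#' @return object of class `literature_bundle`: list with data.frames
#'   `transwell`, `expression`, `plasma_pk`, `regimens`; named list `drugs` of
#'   [drug_properties]; [physiology_params] `physiology`; and `constants`.
#' @export
load_bundle <- function(path = system.file("extdata", package = "cnsivive")) {
  rd <- function(f) {
    fp <- file.path(path, f)
    if (!file.exists(fp)) stop("load_bundle: missing fixture file ", fp)
    utils::read.csv(fp, stringsAsFactors = FALSE)
  }
  tw <- rd("transwell.csv")
  .check_vocab(tw$drug, .drug_vocab, "transwell.csv", "drug")
  .check_vocab(tw$cell_line, .cell_line_vocab, "transwell.csv", "cell_line")
  if (any(tw$papp_ab_inh <= 0))
    stop("load_bundle: transwell.csv row ", which(tw$papp_ab_inh <= 0)[1],
         ": non-positive permeability")
  if (any(tw$er_c <= 0))
    stop("load_bundle: transwell.csv row ", which(tw$er_c <= 0)[1],
         ": non-positive ER_c")

  ex <- rd("pgp_expression.csv")
  .check_vocab(ex$cell_line, .cell_line_vocab, "pgp_expression.csv", "cell_line")
  .check_vocab(ex$level, .level_vocab, "pgp_expression.csv", "level")
  if (any(ex$expression <= 0))
    stop("load_bundle: pgp_expression.csv: non-positive expression")
  for (cl in unique(ex$cell_line)) {
    sub <- ex[ex$cell_line == cl, ]
    get <- function(lv) sub$expression[match(lv, sub$level)]
    hi <- get("highest"); av <- get("average"); lo <- get("lowest")
    ord <- stats::na.omit(c(hi, av, lo))
    if (length(ord) > 1 && any(diff(ord) > 0))
      stop("load_bundle: pgp_expression.csv: levels for ", cl,
           " not ordered highest >= average >= lowest")
  }

  pk <- rd("plasma_pk.csv")
  .check_vocab(pk$drug, .drug_vocab, "plasma_pk.csv", "drug")
  rg <- rd("regimens.csv")
  .check_vocab(rg$drug, .drug_vocab, "regimens.csv", "drug")
  miss <- !paste(rg$drug, rg$regimen_class) %in% paste(pk$drug, pk$regimen_class)
  if (any(miss))
    stop("load_bundle: regimens.csv row ", which(miss)[1],
         ": no matching plasma PK parameter set")

  constants <- yaml::read_yaml(file.path(path, "constants.yaml"))
  physiology <- read_physiology(file.path(path, "physiology.yaml"))
  drugs <- read_drugs(file.path(path, "drugs.yaml"))
  .check_vocab(names(drugs), .drug_vocab, "drugs.yaml", "drug")

  structure(list(transwell = tw, expression = ex, plasma_pk = pk,
                 regimens = rg, drugs = drugs, physiology = physiology,
                 constants = constants, path = path),
            class = "literature_bundle")
}

#' Serialize a bundle back to fixture files
#'
#' Writes the tabular members in the same CSV schema `load_bundle()` reads,
#' so load -> serialize -> load round-trips.
#' @param bundle a `literature_bundle`.
#' @param dir output directory (created if needed).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$transwell, file.path(dir, "transwell.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(bundle$expression, file.path(dir, "pgp_expression.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$plasma_pk, file.path(dir, "plasma_pk.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$regimens, file.path(dir, "regimens.csv"),
                   row.names = FALSE)
  for (f in c("constants.yaml", "physiology.yaml", "drugs.yaml"))
    file.copy(file.path(bundle$path, f), file.path(dir, f), overwrite = TRUE)
  invisible(dir)
}

#' Resolve one transwell record
#'
#' @param bundle a `literature_bundle`.
#' @param drug,cell_line,source keys; must resolve to exactly one record.
#' @return one-row data.frame.
#' @export
resolve_record <- function(bundle, drug, cell_line, source) {
  tw <- bundle$transwell
  hit <- tw$drug == drug & tw$cell_line == cell_line & tw$source == source
  if (sum(hit) != 1L) {
    avail <- tw[tw$drug == drug, c("drug", "cell_line", "source")]
    stop("resolve_record: (", drug, ", ", cell_line, ", ", source, ") matches ",
         sum(hit), " records; available for ", drug, ": ",
         paste(paste(avail$cell_line, avail$source, sep = "/"), collapse = "; "))
  }
  tw[hit, , drop = FALSE]
}

#' Build a dosing regimen from the bundled dosing table
#'
#' Maintenance doses are zero-order infusions over the tabulated time; loading
#' doses are delivered over `loading_duration` min (default from the bundle
#' constants, ~bolus); subcutaneous doses with no infusion time are boluses
#' into the absorption depot.
#' @param bundle a `literature_bundle`.
#' @param drug,regimen_class keys into the dosing table.
#' @param loading_duration min; overrides the bundle default.
#' @return a [dose_regimen].
#' @export
regimen_from_bundle <- function(bundle, drug, regimen_class,
                                loading_duration = NULL) {
  rg <- bundle$regimens
  row <- rg[rg$drug == drug & rg$regimen_class == regimen_class, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("regimen_from_bundle: no unique regimen for (", drug, ", ",
         regimen_class, ")")
  bw <- bundle$constants$body_weight_kg
  ld <- loading_duration %||% bundle$constants$loading_dose_duration_min %||% 1
  ev <- data.frame(amount = row$dose_mg_per_kg * bw * 1e6,
                   start = 0, duration = row$infusion_min)
  if (!is.na(row$loading_mg_per_kg))
    ev <- rbind(data.frame(amount = row$loading_mg_per_kg * bw * 1e6,
                           start = 0, duration = ld), ev)
  dose_regimen(row$route, ev, body_weight = bw)
}

#' Plasma PK parameters from the bundle
#' @param bundle a `literature_bundle`.
#' @param drug,regimen_class keys into the plasma PK table.
#' @return a [plasma_pk_params].
#' @export
plasma_from_bundle <- function(bundle, drug, regimen_class) {
  pk <- bundle$plasma_pk
  row <- pk[pk$drug == drug & pk$regimen_class == regimen_class, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("plasma_from_bundle: no unique parameter set for (", drug, ", ",
         regimen_class, ")")
  plasma_pk_params(cl_cen = row$cl_cen, v_cen = row$v_cen,
                   q_cen_per1 = row$q_cen_per1, q_cen_per2 = row$q_cen_per2,
                   v_per1 = row$v_per1, v_per2 = row$v_per2, ka = row$ka)
}

#' Assemble a full CNS model spec from the bundle
#'
#' Resolves the transwell record, expression level and REF, the plasma PK
#' parameter set and the dosing regimen for one run scenario.
#'
#' @param bundle a `literature_bundle`.
#' @param drug,regimen_class,cell_line,source scenario keys.
#' @param level `"highest"`, `"average"`, `"lowest"`, or `"no_ref"` (REF = 1).
#' @param ... passed to [cns_model_spec()] (solver options).
#' @return a [cns_model_spec]; the resolved REF and clearances are in
#'   `$clearances`.
#' @export
spec_from_bundle <- function(bundle, drug, regimen_class, cell_line, source,
                             level = "average", ...) {
  record <- resolve_record(bundle, drug, cell_line, source)
  if (level == "no_ref") {
    ref <- 1
  } else {
    ex <- bundle$expression
    hit <- ex$cell_line == cell_line & ex$level == level
    if (sum(hit) != 1L)
      stop("spec_from_bundle: expression level '", level,
           "' not reported for ", cell_line, " (available: ",
           paste(ex$level[ex$cell_line == cell_line], collapse = ", "), ")")
    ref <- relative_expression_factor(bundle$constants$pgp_expression_in_vivo,
                                      ex$expression[hit])
  }
  cl <- clearance_set(record, bundle$physiology, ref = ref)
  cns_model_spec(physiology = bundle$physiology,
                 drug = bundle$drugs[[drug]],
                 clearances = cl,
                 plasma = plasma_from_bundle(bundle, drug, regimen_class),
                 regimen = regimen_from_bundle(bundle, drug, regimen_class),
                 ...)
}
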