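#' Rat CNS physiological parameters
#'
#' Container for the physiological constants that enter the blood-brain-barrier
#' clearance scaling and the brainECF ODE system. All values are user-overridable;
#' the defaults describe a typical 0.25 kg rat and are also shipped as a YAML
#' config (`system.file("extdata", "physiology.yaml", package = "cnsivive")`).
#'
#' @param sa_bbb BBB surface area, cm^2. Default 155.
#' @param trans_fraction fraction of `sa_bbb` available for transcellular
#'   transport (P-gp sits in the apical endothelial membrane), unitless in (0, 1].
#'   Default 0.998, so the derived `sa_bbb_trans` is 154.69 cm^2.
#' @param v_mv brain microvascular volume, mL.
#' @param v_ecf brain extracellular fluid volume, mL.
#' @param v_bc brain-cell-membrane compartment volume, mL.
#' @param q_cbf cerebral blood flow, mL/min.
#' @param q_ecf brainECF bulk flow (towards the ventricles), mL/min.
#' @param ph_ecf brainECF pH.
#' @param body_weight typical rat body weight, kg; used to convert mg/kg doses.
#' @return object of class `physiology_params`, a validated list with the
#'   derived field `sa_bbb_trans = trans_fraction * sa_bbb`.
#' @export
physiology_params <- function(sa_bbb = 155, trans_fraction = 0.998,
                              v_mv = 0.06, v_ecf = 0.29, v_bc = 0.007,
                              q_cbf = 1.2, q_ecf = 3e-4, ph_ecf = 7.3,
                              body_weight = 0.25) {
  p <- list(sa_bbb = sa_bbb, trans_fraction = trans_fraction,
            v_mv = v_mv, v_ecf = v_ecf, v_bc = v_bc,
            q_cbf = q_cbf, q_ecf = q_ecf, ph_ecf = ph_ecf,
            body_weight = body_weight)
  for (f in c("sa_bbb", "v_mv", "v_ecf", "v_bc", "q_cbf", "q_ecf",
              "ph_ecf", "body_weight")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("physiology_params: '", f, "' must be a single positive number")
  }
  if (!is.numeric(trans_fraction) || trans_fraction <= 0 || trans_fraction > 1)
    stop("physiology_params: 'trans_fraction' must lie in (0, 1]")
  p$sa_bbb_trans <- trans_fraction * sa_bbb
  structure(p, class = "physiology_params")
}

#' Drug-specific properties
#'
#' @param name drug identifier.
#' @param fup unbound fraction in plasma, in (0, 1].
#' @param pka dissociation constant; may be `NA` for neutral species.
#' @param species one of `"base"`, `"acid"`, `"neutral"`; governs the
#'   Henderson-Hasselbalch unionized fraction used for brain-cell partitioning.
#' @param cl_bc_in,cl_bc_out clearances into / out of brain cell membranes,
#'   mL/min (default 0 disables the membrane compartment).
#' @param observed_kpuu_bbb optional literature unbound brain/plasma partition
#'   coefficient, used only for Kp_uu-scaled comparison profiles.
#' @param phf_ecf optional fixed override for the unionized fraction in
#'   brainECF; when `NULL` it is computed from `pka`/`species` and the
#'   physiological pH at simulation time.
#' @return object of class `drug_properties`.
#' @export
drug_properties <- function(name, fup, pka = NA_real_,
                            species = c("base", "acid", "neutral"),
                            cl_bc_in = 0, cl_bc_out = 0,
                            observed_kpuu_bbb = NULL, phf_ecf = NULL) {
  species <- match.arg(species)
  if (!is.numeric(fup) || length(fup) != 1L || fup <= 0 || fup > 1)
    stop("drug_properties: 'fup' must lie in (0, 1]")
  if (cl_bc_in < 0 || cl_bc_out < 0)
    stop("drug_properties: membrane clearances must be non-negative")
  if (species != "neutral" && !is.finite(pka) && is.null(phf_ecf))
    stop("drug_properties: finite 'pka' required for species '", species, "'")
  if (!is.null(observed_kpuu_bbb) && observed_kpuu_bbb <= 0)
    stop("drug_properties: 'observed_kpuu_bbb' must be positive when present")
  if (!is.null(phf_ecf) && (phf_ecf < 0 || phf_ecf > 1))
    stop("drug_properties: 'phf_ecf' override must lie in [0, 1]")
  structure(list(name = as.character(name), fup = fup, pka = pka,
                 species = species, cl_bc_in = cl_bc_in,
                 cl_bc_out = cl_bc_out,
                 observed_kpuu_bbb = observed_kpuu_bbb,
                 phf_ecf = phf_ecf),
            class = "drug_properties")
}

#' Fraction of drug unionized at a given pH
#'
#' Monoprotic Henderson-Hasselbalch relation. Neutral species are fully
#' unionized; bases give `1/(1 + 10^(pka - ph))`, acids `1/(1 + 10^(ph - pka))`.
#' Used as PHF_ECF, the fraction available for partitioning into brain cell
#' membranes from the ECF.
#'
#' @param pka dissociation constant (finite for acids/bases).
#' @param ph ambient pH, in (0, 14).
#' @param species `"acid"`, `"base"` or `"neutral"`.
#' @return unionized fraction in \[0, 1\].
#' @examples
#' fraction_unionized(8.3, 7.3, "base")  # 1/(1 + 10) = 0.0909
#' @export
fraction_unionized <- function(pka, ph, species) {
  if (!species %in% c("acid", "base", "neutral"))
    stop("fraction_unionized: unknown species '", species, "'")
  if (!is.numeric(ph) || ph <= 0 || ph >= 14)
    stop("fraction_unionized: 'ph' must lie in (0, 14)")
  if (species == "neutral") return(1)
  if (!is.finite(pka)) stop("fraction_unionized: 'pka' must be finite")
  if (species == "base") 1 / (1 + 10^(pka - ph)) else 1 / (1 + 10^(ph - pka))
}

#' Effective unionized fraction for a drug in brainECF
#'
#' Returns the user override when set, otherwise the Henderson-Hasselbalch
#' value at the brainECF pH of the supplied physiology.
#' @param drug a [drug_properties] object.
#' @param physiology a [physiology_params] object.
#' @export
phf_ecf <- function(drug, physiology) {
  if (!is.null(drug$phf_ecf)) return(drug$phf_ecf)
  fraction_unionized(drug$pka, physiology$ph_ecf, drug$species)
}

#' Read physiology or drug parameters from a YAML config
#'
#' One YAML document per physiology set / drug; fields as in
#' [physiology_params()] and [drug_properties()].
#' @param path YAML file path.
#' @return for `read_physiology`, a `physiology_params` object; for
#'   `read_drugs`, a named list of `drug_properties` objects.
#' @export
read_physiology <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(physiology_params, raw[names(raw) %in% names(formals(physiology_params))])
}

#' @rdname read_physiology
#' @export
read_drugs <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    spec <- raw[[nm]]
    spec$name <- nm
    do.call(drug_properties, spec[names(spec) %in% names(formals(drug_properties))])
  })
  names(out) <- names(raw)
  out
}
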