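# Parameter registry and parameter-file I/O.
#
# A parameter set is a named numeric vector covering all three model scales.
# Names follow the field convention of prefixing each parameter with the
# scale it belongs to: "pbpk_" (whole-body), "cc3d_" (sinusoid/tissue) and
# "sc_" (subcellular reaction network).

#' Molar masses used for dose and unit conversions
#'
#' Internal bookkeeping is molar (mmol) so that Phase II conversion of APAP
#' into its conjugates is 1:1.  Molar masses (g/mol) are needed only to
#' convert an oral dose in mg into mmol and to report concentrations in
#' ug/mL: APAP 151.16, APAP-glucuronide 327.29, APAP-sulfate 231.23.
#'
#' @return Named numeric vector with elements `APAP`, `APAPG`, `APAPS`.
#' @export
#' @examples
#' hepapk_molar_masses()
hepapk_molar_masses <- function() {
  c(APAP = 151.16, APAPG = 327.29, APAPS = 231.23)
}

#' Compound identifiers
#' @return Character vector `c("APAP", "APAPG", "APAPS")`.
#' @keywords internal
compounds <- function() c("APAP", "APAPG", "APAPS")

# Reference bw (kg) at which the REFSIM flows/volumes are tabulated.
.bw_ref <- 70

#' Reference parameter set (REFSIM)
#'
#' The built-in reference parameter set for a 70 kg human given oral
#' acetaminophen.  Whole-body flows and volumes are allometrically scaled
#' values for a 70 kg male; tissue-scale entries describe a single
#' representative sinusoid (200 um lumen, 20 hepatocytes in 10 axial ranks
#' of 2, blood speed 200 um/s); subcellular entries are the Michaelis-Menten
#' constants of the glucuronidation, sulfation and CYP2E1 pathways plus
#' glutathione turnover.
#'
#' `pbpk_CLmetab` is the lumped liver clearance used only by the standalone
#' whole-body model; it is zero in the coupled model, where hepatic
#' elimination is carried by the sinusoid/hepatocyte scales.
#'
#' @return Named numeric vector (a `ParameterSet`).
#' @export
#' @examples
#' p <- refsim_params()
#' p["pbpk_QCardiac"]
refsim_params <- function() {
  c(
    # -- whole body: compound independent ------------------------------
    pbpk_bw       = 70,      # kg
    pbpk_hemat    = 0.45,    # RBC volume fraction of blood
    pbpk_QCardiac = 363.01,  # L/h
    pbpk_QGut     = 74.42,
    pbpk_QLiver   = 19.42,
    pbpk_QKidney  = 80.37,
    pbpk_QRest    = 188.80,
    pbpk_VArt     = 1.50,    # L
    pbpk_VVen     = 3.41,
    pbpk_VGut     = 1.10,
    pbpk_VLiver   = 1.71,
    pbpk_VKidney  = 0.29,
    pbpk_VLung    = 0.51,
    pbpk_VRest    = 33.47,
    # -- whole body: compound dependent --------------------------------
    pbpk_kGutabs  = 1.5,     # 1/h
    pbpk_Fup      = 0.8,
    pbpk_FupG     = 1,
    pbpk_FupS     = 1,
    pbpk_Kr2p     = 1.6,
    pbpk_Kr2pG    = 0.4,
    pbpk_Kr2pS    = 0.2,
    pbpk_Kk2p     = 1,
    pbpk_Kk2pG    = 1,
    pbpk_Kk2pS    = 1,
    pbpk_Kl2p     = 1,
    pbpk_Kl2pG    = 1,
    pbpk_Kl2pS    = 1,
    pbpk_Rb2p     = 1.09,
    pbpk_Rb2pG    = 0.55,
    pbpk_Rb2pS    = 0.55,
    pbpk_Qgfr     = 0.714,   # L/h
    pbpk_QgfrG    = 7.86,
    pbpk_QgfrS    = 9.96,
    pbpk_CLmetab  = 0,       # L/h; standalone-only lumped liver clearance
    # -- sinusoid: geometry and cadence (compound independent) ---------
    cc3d_l_SIN            = 200,    # um
    cc3d_d_SIN            = 20,     # um
    cc3d_h_SIN            = 4,      # um
    cc3d_Vol_HEP          = 8000,   # um^3 (20 x 20 x 20)
    cc3d_Vol_RBC          = 400,    # um^3 (100 x 4)
    cc3d_Vol_SP           = 100,    # um^3 (25 x 4)
    cc3d_n_hepatocytes    = 20,
    cc3d_flow_speed       = 200,    # um/s
    cc3d_arterial_fraction = 0.25,  # arterial:venous = 1:3
    cc3d_lumen_fraction   = 0.074,  # sinusoid-lumen fraction of liver volume
    cc3d_mcs2sec          = 1 / 600, # s per Monte Carlo step
    cc3d_freq_bloodInflow = 20,     # mcs
    cc3d_freq_transport   = 10,     # mcs
    cc3d_freq_SBML        = 10,     # mcs
    # -- sinusoid: transfer kinetics (compound dependent) --------------
    cc3d_k_AT_APAPG   = 0.00045,  # 1/s
    cc3d_k_AT_APAPS   = 0.0019,   # 1/s
    cc3d_Km_AT_APAP   = 0.01,     # mmol/L
    cc3d_Vmax_AT_APAP = 0.01,     # mmol/L/s
    cc3d_k_PD_R2R     = 0.001,    # 1/s
    cc3d_k_PD_R2S     = 0.001,
    cc3d_k_PD_R2H     = 0.001,
    cc3d_k_PD_S2R     = 0.0012,
    cc3d_k_PD_S2S     = 0.010,
    cc3d_k_PD_S2H     = 0.001,
    cc3d_k_PD_H2R     = 0.001,
    cc3d_k_PD_H2S     = 0.001,
    cc3d_k_PD_H2H     = 0.001,
    # -- subcellular ----------------------------------------------------
    sc_Vmax_GLUC    = 0.001,     # mmol/L/s
    sc_Km_GLUC      = 1,         # mmol/L
    sc_Vmax_SULF    = 0.000175,
    sc_Km_SULF      = 0.2,
    sc_Vmax_2E1_APAP = 0.00002,
    sc_Km_2E1_APAP  = 1.29,
    sc_kNAPQIGSH    = 0.1,       # L/mmol/s (second order)
    sc_kGsh         = 0.0001,    # 1/s on the GSH deficit
    sc_GSH0         = 9.9,       # mmol/L
    sc_GSHmax       = 10,        # mmol/L
    sc_zonation_lo  = 0.8,       # periportal CYP2E1 Vmax fraction
    sc_zonation_hi  = 1.0        # pericentral CYP2E1 Vmax fraction
  )
}

#' Default sensitivity / population parameter subset
#'
#' All compound-dependent parameters of the three scales plus body weight
#' and hematocrit.  The exact membership used for published heat maps is not
#' recoverable, so this subset is the package default and can be overridden
#' by name anywhere a subset is accepted.
#'
#' @return Character vector of parameter names.
#' @export
default_sensitivity_subset <- function() {
  c(
    "pbpk_bw", "pbpk_hemat",
    "pbpk_kGutabs",
    "pbpk_Fup", "pbpk_FupG", "pbpk_FupS",
    "pbpk_Kr2p", "pbpk_Kr2pG", "pbpk_Kr2pS",
    "pbpk_Kk2p", "pbpk_Kk2pG", "pbpk_Kk2pS",
    "pbpk_Kl2p", "pbpk_Kl2pG", "pbpk_Kl2pS",
    "pbpk_Rb2p", "pbpk_Rb2pG", "pbpk_Rb2pS",
    "pbpk_Qgfr", "pbpk_QgfrG", "pbpk_QgfrS",
    "cc3d_k_AT_APAPG", "cc3d_k_AT_APAPS",
    "cc3d_Km_AT_APAP", "cc3d_Vmax_AT_APAP",
    "cc3d_k_PD_R2R", "cc3d_k_PD_R2S", "cc3d_k_PD_R2H",
    "cc3d_k_PD_S2R", "cc3d_k_PD_S2S", "cc3d_k_PD_S2H",
    "cc3d_k_PD_H2R", "cc3d_k_PD_H2S", "cc3d_k_PD_H2H",
    "sc_Vmax_GLUC", "sc_Km_GLUC",
    "sc_Vmax_SULF", "sc_Km_SULF",
    "sc_Vmax_2E1_APAP", "sc_Km_2E1_APAP",
    "sc_kNAPQIGSH", "sc_kGsh",
    "sc_GSH0", "sc_GSHmax"
  )
}

#' Validate a parameter set
#'
#' Checks completeness against the reference set, positivity, hematocrit in
#' (0, 1) and warns when an unbound fraction exceeds 1 (possible for
#' population-perturbed sets, where multipliers are applied blindly).
#'
#' @param params Named numeric vector.
#' @param warn_extra Warn about unknown names (default `TRUE`).
#' @return `params`, invisibly, if valid; otherwise an error enumerating
#'   every problem found.
#' @export
validate_params <- function(params, warn_extra = TRUE) {
  ref <- refsim_params()
  problems <- character()
  if (is.null(names(params)) || any(!nzchar(names(params)))) {
    stop("parameter set must be a fully named numeric vector", call. = FALSE)
  }
  missing <- setdiff(names(ref), names(params))
  if (length(missing)) {
    problems <- c(problems, paste0("missing parameter(s): ",
                                   paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(params), names(ref))
  if (length(extra) && warn_extra) {
    warning("ignoring unknown parameter(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  known <- params[intersect(names(params), names(ref))]
  bad <- names(known)[!is.finite(known)]
  if (length(bad)) {
    problems <- c(problems, paste0("non-finite value for: ",
                                   paste(bad, collapse = ", ")))
  }
  # CLmetab may legitimately be zero; everything else must be positive.
  may_be_zero <- c("pbpk_CLmetab")
  pos <- known[setdiff(names(known), may_be_zero)]
  neg <- names(pos)[is.finite(pos) & pos <= 0]
  if (length(neg)) {
    problems <- c(problems, paste0("non-positive value for: ",
                                   paste(neg, collapse = ", ")))
  }
  if (!is.na(known["pbpk_hemat"]) &&
      (known[["pbpk_hemat"]] <= 0 || known[["pbpk_hemat"]] >= 1)) {
    problems <- c(problems, "pbpk_hemat must lie strictly between 0 and 1")
  }
  if (length(problems)) {
    stop("invalid parameter set:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  for (fp in c("pbpk_Fup", "pbpk_FupG", "pbpk_FupS")) {
    if (!is.na(known[fp]) && known[[fp]] > 1) {
      warning(fp, " > 1; accepted, but fractions unbound are nominally <= 1",
              call. = FALSE)
    }
  }
  invisible(params)
}

#' Load a parameter set by name or from a key-value file
#'
#' Accepts the registered name `"refsim"` (case-insensitive) or a path to a
#' flat key-value file in JSON or YAML, keyed by the canonical parameter
#' names (e.g. `pbpk_QCardiac`, `sc_Km_2E1_APAP`).
#'
#' @param source Registry name or file path.
#' @return Named numeric vector, validated.
#' @export
#' @examples
#' p <- load_parameter_set("refsim")
load_parameter_set <- function(source) {
  stopifnot(is.character(source), length(source) == 1)
  if (tolower(source) %in% c("refsim", "ref")) {
    return(refsim_params())
  }
  if (!file.exists(source)) {
    stop("unknown parameter set or missing file: ", source, call. = FALSE)
  }
  vals <- if (grepl("\\.ya?ml$", source, ignore.case = TRUE)) {
    yaml::read_yaml(source)
  } else {
    jsonlite::read_json(source, simplifyVector = TRUE)
  }
  if (is.data.frame(vals)) vals <- stats::setNames(as.list(vals$value), vals$name)
  params <- vapply(vals, function(v) as.numeric(v)[1], numeric(1))
  validate_params(params)
  params[names(refsim_params())]
}

#' Save a parameter set to a key-value file
#'
#' @param params Named numeric vector.
#' @param path Output path; format chosen by extension (`.json`, `.yaml`).
#' @return `path`, invisibly.
#' @export
save_parameter_set <- function(params, path) {
  validate_params(params)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(as.list(params), path, precision = 17)
  } else {
    jsonlite::write_json(as.list(params), path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

# ---- internal extractors ------------------------------------------------

# Whole-body physiology with allometric bw scaling.  REFSIM flows and
# volumes are tabulated at 70 kg; flows scale as (bw/70)^0.75 and volumes
# as bw/70, which preserves the flow-balance identity under bw changes.
body_from_params <- function(params) {
  bw <- params[["pbpk_bw"]]
  fq <- (bw / .bw_ref)^0.75
  fv <- bw / .bw_ref
  list(
    bw = bw,
    hematocrit = params[["pbpk_hemat"]],
    QCardiac = params[["pbpk_QCardiac"]] * fq,
    QGut     = params[["pbpk_QGut"]] * fq,
    QLiver   = params[["pbpk_QLiver"]] * fq,
    QKidney  = params[["pbpk_QKidney"]] * fq,
    QRest    = params[["pbpk_QRest"]] * fq,
    VArt  = params[["pbpk_VArt"]] * fv,
    VVen  = params[["pbpk_VVen"]] * fv,
    VGut  = params[["pbpk_VGut"]] * fv,
    VLiver = params[["pbpk_VLiver"]] * fv,
    VKidney = params[["pbpk_VKidney"]] * fv,
    VLung = params[["pbpk_VLung"]] * fv,
    VRest = params[["pbpk_VRest"]] * fv
  )
}

# Compound-dependent PBPK parameters for one compound.
compound_from_params <- function(params, compound = c("APAP", "APAPG", "APAPS")) {
  compound <- match.arg(compound)
  sfx <- switch(compound, APAP = "", APAPG = "G", APAPS = "S")
  g <- function(base) params[[paste0("pbpk_", base, sfx)]]
  list(
    compound = compound,
    kGutabs = params[["pbpk_kGutabs"]],  # metabolites start with empty gut
    Fup  = g("Fup"),
    Kr2p = g("Kr2p"),
    Kk2p = g("Kk2p"),
    Kl2p = g("Kl2p"),
    Rb2p = g("Rb2p"),
    Qgfr = g("Qgfr"),
    CLmetab = if (compound == "APAP") params[["pbpk_CLmetab"]] else 0
  )
}

subcell_from_params <- function(params) {
  list(
    Vmax_GLUC = params[["sc_Vmax_GLUC"]], Km_GLUC = params[["sc_Km_GLUC"]],
    Vmax_SULF = params[["sc_Vmax_SULF"]], Km_SULF = params[["sc_Km_SULF"]],
    Vmax_2E1 = params[["sc_Vmax_2E1_APAP"]], Km_2E1 = params[["sc_Km_2E1_APAP"]],
    kNAPQIGSH = params[["sc_kNAPQIGSH"]], kGsh = params[["sc_kGsh"]],
    GSH0 = params[["sc_GSH0"]], GSHmax = params[["sc_GSHmax"]]
  )
}
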