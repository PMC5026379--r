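# Whole-body PBPK compartment model.
#
# Ten states per compound, all expressed as molar amounts (mmol):
# AGutlumen (volume-less gut lumen), CGut, CLiver, CVen, CLung, CArt,
# CKidney, CRest, plus the two pure sinks CTubules (urine) and
# CMetabolized.  Every transfer appears once as a loss in its source and
# once as a gain in its sink, so the total derivative is identically zero.

.pbpk_states <- c("AGutlumen", "CGut", "CLiver", "CVen", "CLung", "CArt",
                  "CKidney", "CRest", "CTubules", "CMetabolized")

#' Construct a PBPK state vector
#'
#' @param ... Named amounts in mmol; unnamed compartments default to 0.
#' @return Named numeric vector over the ten whole-body compartments.
#' @export
#' @examples
#' pbpk_state(AGutlumen = 9.262)
pbpk_state <- function(...) {
  st <- stats::setNames(numeric(length(.pbpk_states)), .pbpk_states)
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), .pbpk_states)
    if (length(bad)) stop("unknown compartment(s): ", paste(bad, collapse = ", "))
    st[names(dots)] <- dots
  }
  st
}

#' Gut uptake model
#'
#' First-order absorption (the default) or a saturable, lagged variant that
#' reproduces near-zero-order uptake: no absorption before `lag` hours
#' (gastric emptying; 9 min in the reference fit), then Michaelis-Menten
#' uptake whose `Km_gut` is small against the lumen amount so the rate is
#' approximately constant at `Vmax_gut` until the lumen is nearly empty.
#'
#' @param variant `"first_order"` or `"zero_order_lagged"`.
#' @param kGutabs First-order absorption rate (1/h); used by `first_order`.
#' @param Vmax_gut Maximal uptake rate (mmol/h); `zero_order_lagged` only.
#' @param Km_gut Half-saturation lumen amount (mmol); `zero_order_lagged` only.
#' @param lag Delay before uptake starts (h); `zero_order_lagged` only.
#' @return An object of class `gut_uptake_model`.
#' @export
gut_uptake_model <- function(variant = c("first_order", "zero_order_lagged"),
                             kGutabs = 1.5, Vmax_gut = 9, Km_gut = 0.05,
                             lag = 0.15) {
  variant <- match.arg(variant)
  stopifnot(lag >= 0, kGutabs >= 0, Vmax_gut >= 0, Km_gut >= 0)
  structure(list(variant = variant, kGutabs = kGutabs, Vmax_gut = Vmax_gut,
                 Km_gut = Km_gut, lag = lag),
            class = "gut_uptake_model")
}

#' Gut absorption rate
#'
#' @param AGutlumen Amount in the gut lumen (mmol).
#' @param uptake A [gut_uptake_model()].
#' @param t Time since dosing (h); only the lagged variant uses it.
#' @return Absorption rate in mmol/h.
#' @export
#' @examples
#' gut_uptake_rate(2, gut_uptake_model(kGutabs = 1.5), t = 0)
gut_uptake_rate <- function(AGutlumen, uptake = gut_uptake_model(), t = 0) {
  stopifnot(AGutlumen >= 0)
  if (uptake$variant == "first_order") {
    return(uptake$kGutabs * AGutlumen)
  }
  if (t < uptake$lag) return(0)
  uptake$Vmax_gut * AGutlumen / (uptake$Km_gut + AGutlumen)
}

# Core rate evaluation shared by the scalar API and the vectorised solver.
# `state` is a 10 x n matrix (one column per compound replicate); `cp` a
# list of compound-parameter lists; returns the 10 x n derivative matrix.
.pbpk_deriv_matrix <- function(state, body, cp, uptake, t,
                               divert_liver = FALSE) {
  n <- ncol(state)
  d <- matrix(0, nrow = nrow(state), ncol = n,
              dimnames = dimnames(state))
  for (j in seq_len(n)) {
    s <- state[, j]
    p <- cp[[j]]
    upt <- uptake
    upt$kGutabs <- p$kGutabs
    r_abs      <- gut_uptake_rate(max(s[["AGutlumen"]], 0), upt, t)
    r_art_gut  <- body$QGut * s[["CArt"]] / body$VArt
    r_art_kid  <- body$QKidney * s[["CArt"]] / body$VArt
    r_art_rest <- body$QRest * s[["CArt"]] / body$VArt
    r_ven_lung <- body$QCardiac * s[["CVen"]] / body$VVen
    r_lung_art <- body$QCardiac * s[["CLung"]] / body$VLung
    r_kid_ven  <- body$QKidney * s[["CKidney"]] * p$Rb2p /
      (p$Kk2p * p$Fup * body$VKidney)
    r_kid_tub  <- p$Qgfr * s[["CKidney"]] / (p$Kk2p * body$VKidney)
    r_rest_ven <- body$QRest * s[["CRest"]] * p$Rb2p /
      (p$Kr2p * p$Fup * body$VRest)
    if (divert_liver) {
      # Coupled mode: the CGut -> CLiver and CArt -> CLiver flows are
      # intercepted by the sinusoid model, and the liver compartment's
      # own outflow/metabolism ODEs are disabled.  The interception
      # itself is booked by the coupler, not here.
      r_gut_liv <- 0; r_art_liv <- 0; r_liv_ven <- 0; r_liv_met <- 0
    } else {
      r_gut_liv <- body$QGut * s[["CGut"]] / body$VGut
      r_art_liv <- body$QLiver * s[["CArt"]] / body$VArt
      r_liv_ven <- (body$QLiver + body$QGut) * s[["CLiver"]] * p$Rb2p /
        (p$Kl2p * p$Fup * body$VLiver)
      r_liv_met <- p$CLmetab * s[["CLiver"]] / (p$Kl2p * p$Fup)
    }
    d[, j] <- c(
      AGutlumen = -r_abs,
      CGut      = r_abs + r_art_gut - r_gut_liv,
      CLiver    = r_gut_liv + r_art_liv - r_liv_ven - r_liv_met,
      CVen      = r_liv_ven + r_kid_ven + r_rest_ven - r_ven_lung,
      CLung     = r_ven_lung - r_lung_art,
      CArt      = r_lung_art - r_art_gut - r_art_liv - r_art_kid - r_art_rest,
      CKidney   = r_art_kid - r_kid_ven - r_kid_tub,
      CRest     = r_art_rest - r_rest_ven,
      CTubules  = r_kid_tub,
      CMetabolized = r_liv_met
    )
  }
  d
}

#' Whole-body PBPK derivatives for one compound
#'
#' Evaluates the compartmental rate equations: first-order (or lagged
#' saturable) gut absorption, flow-limited organ exchange with
#' tissue-to-plasma partitioning, glomerular filtration into the tubules
#' and lumped hepatic metabolism.  The sum over all ten derivatives is zero
#' by construction.
#'
#' @param state Named amount vector from [pbpk_state()] (mmol).
#' @param params Full parameter set (named vector), or `NULL` to pass
#'   `body`/`compound` directly.
#' @param compound `"APAP"`, `"APAPG"` or `"APAPS"`.
#' @param uptake A [gut_uptake_model()].
#' @param t Time (h).
#' @param body,cp Optional pre-extracted physiology / compound parameters
#'   (internal use).
#' @return Named derivative vector (mmol/h).
#' @export
#' @examples
#' st <- pbpk_state(AGutlumen = 9.262)
#' pbpk_derivatives(st, refsim_params())[["CGut"]]
pbpk_derivatives <- function(state, params = refsim_params(),
                             compound = "APAP",
                             uptake = gut_uptake_model(), t = 0,
                             body = NULL, cp = NULL) {
  if (any(state < 0)) stop("negative state amounts are not allowed")
  if (is.null(body)) body <- body_from_params(params)
  if (any(unlist(body[-1]) <= 0)) stop("non-positive flow or volume")
  if (is.null(cp)) cp <- compound_from_params(params, compound)
  m <- matrix(state, ncol = 1, dimnames = list(names(state), NULL))
  drop(.pbpk_deriv_matrix(m, body, list(cp), uptake, t))
}

#' Simulate the standalone whole-body PBPK model
#'
#' Runs the three linked compound replicates (APAP and its glucuronide and
#' sulfate conjugates).  The full molar dose is placed in the APAP gut
#' lumen at t = 0; metabolite replicates start empty.  In this standalone
#' configuration the APAP `CMetabolized` flux is fed into the metabolite
#' replicates' liver compartments at fractions `fG` and `fS` (the remainder
#' is untracked minor metabolism), so standalone metabolite curves require
#' a nonzero `pbpk_CLmetab`.
#'
#' @param params Full parameter set.
#' @param dose_mg_per_kg Oral dose (mg APAP per kg body weight).
#' @param duration_h Simulated time span (h).
#' @param times Optional output grid (h); default `seq(0, duration_h, by = 0.02)`.
#' @param uptake A [gut_uptake_model()]; its `kGutabs` is taken from
#'   `params` for the first-order variant.
#' @param metabolite_split Named fractions `c(fG =, fS =)` of metabolized
#'   APAP routed to APAPG and APAPS; `fG + fS <= 1`.
#' @param dose_mg Optional total dose in mg, overriding
#'   `dose_mg_per_kg * bw` (used by runners that fix the absolute dose).
#' @param rtol,atol Solver tolerances (relative; absolute, mmol).
#' @return A tibble (class `hepapk_pbpk`) with columns `time_h`,
#'   `compartment`, `compound`, `amount_mmol`, `concentration_mmol_per_L`
#'   (NA for volume-less compartments).  Attributes: `params`, `dose_mmol`,
#'   `wide` (list of time-by-compartment amount matrices per compound).
#' @export
#' @examples
#' sim <- simulate_pbpk(duration_h = 2, times = seq(0, 2, 0.1))
#' head(sim)
simulate_pbpk <- function(params = refsim_params(), dose_mg_per_kg = 20,
                          duration_h = 8, times = NULL,
                          uptake = NULL,
                          metabolite_split = c(fG = 0.60, fS = 0.33),
                          dose_mg = NULL, rtol = 1e-8, atol = 1e-10) {
  stopifnot(dose_mg_per_kg >= 0, duration_h > 0)
  fG <- unname(metabolite_split[["fG"]]); fS <- unname(metabolite_split[["fS"]])
  stopifnot(fG >= 0, fS >= 0, fG + fS <= 1)
  if (is.null(times)) times <- seq(0, duration_h, by = 0.02)
  stopifnot(all(diff(times) > 0))
  body <- body_from_params(params)
  cps <- lapply(compounds(), function(cm) compound_from_params(params, cm))
  if (is.null(uptake)) uptake <- gut_uptake_model(kGutabs = params[["pbpk_kGutabs"]])
  if (is.null(dose_mg)) dose_mg <- dose_mg_per_kg * body$bw
  dose_mmol <- dose_mg / hepapk_molar_masses()[["APAP"]]

  y0 <- rep(0, 30)
  y0[1] <- dose_mmol  # APAP gut lumen; metabolite replicates start at zero
  deriv <- function(t, y, parms) {
    st <- matrix(y, nrow = 10, dimnames = list(.pbpk_states, compounds()))
    d <- .pbpk_deriv_matrix(st, body, cps, uptake, t)
    # 1:1 molar routing of metabolized APAP into the conjugate replicates
    flux_met <- d["CMetabolized", "APAP"]
    d["CLiver", "APAPG"] <- d["CLiver", "APAPG"] + fG * flux_met
    d["CLiver", "APAPS"] <- d["CLiver", "APAPS"] + fS * flux_met
    # keep CMetabolized as the untracked remainder so moles stay auditable
    d["CMetabolized", "APAP"] <- (1 - fG - fS) * flux_met
    list(as.vector(d))
  }
  sol <- deSolve::lsoda(y0, times, deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("PBPK integration failed near t = ", max(sol[, 1]), " h")
  }
  amounts <- sol[, -1, drop = FALSE]
  if (min(amounts) < -1e3 * atol - 1e-12 * dose_mmol) {
    stop("integration produced negative amounts beyond tolerance (min = ",
         format(min(amounts)), " mmol)")
  }
  amounts[amounts < 0] <- 0

  wide <- lapply(seq_along(compounds()), function(j) {
    m <- amounts[, (j - 1) * 10 + seq_len(10), drop = FALSE]
    colnames(m) <- .pbpk_states
    m
  })
  names(wide) <- compounds()

  vols <- c(AGutlumen = NA, CGut = body$VGut, CLiver = body$VLiver,
            CVen = body$VVen, CLung = body$VLung, CArt = body$VArt,
            CKidney = body$VKidney, CRest = body$VRest,
            CTubules = NA, CMetabolized = NA)
  out <- tidyr::expand_grid(
    compound = compounds(), compartment = .pbpk_states, time_h = times
  )
  out$amount_mmol <- unlist(lapply(compounds(), function(cm) {
    as.vector(wide[[cm]])
  }), use.names = FALSE)
  out$concentration_mmol_per_L <- out$amount_mmol / vols[out$compartment]
  out <- out[, c("time_h", "compartment", "compound",
                 "amount_mmol", "concentration_mmol_per_L")]
  structure(tibble::as_tibble(out),
            params = params, dose_mmol = dose_mmol, wide = wide,
            body = body,
            class = c("hepapk_pbpk", class(tibble::tibble())))
}

#' Venous serum (plasma) concentration curves from a simulation
#'
#' Converts venous-compartment amounts into plasma concentrations,
#' `(CVen / VVen) / Rb2p`, the quantity compared with clinical serum data.
#'
#' @param sim A `hepapk_pbpk` or `hepapk_multiscale` result.
#' @return Tibble with `time_h`, `compound`, `conc_mmol_per_L`, `conc_ug_per_mL`.
#' @export
serum_concentrations <- function(sim) {
  UseMethod("serum_concentrations")
}

#' @export
serum_concentrations.hepapk_pbpk <- function(sim) {
  params <- attr(sim, "params")
  body <- attr(sim, "body")
  mm <- hepapk_molar_masses()
  rb <- c(APAP = params[["pbpk_Rb2p"]], APAPG = params[["pbpk_Rb2pG"]],
          APAPS = params[["pbpk_Rb2pS"]])
  ven <- dplyr::filter(tibble::as_tibble(sim), .data$compartment == "CVen")
  conc <- unname(ven$amount_mmol / body$VVen / rb[ven$compound])
  tibble::tibble(
    time_h = ven$time_h,
    compound = ven$compound,
    conc_mmol_per_L = conc,
    conc_ug_per_mL = conc * unname(mm[ven$compound])
  )
}
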