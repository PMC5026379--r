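# Per-hepatocyte Phase I/II metabolism and glutathione turnover.
#
# Six species (mmol/L) in one well-stirred hepatocyte: APAP, NAPQI, GSH,
# NAPQI_GSH, APAPG, APAPS.  Five reactions: CYP2E1 oxidation of APAP to
# NAPQI (Michaelis-Menten, Vmax scaled by lobular zonation), second-order
# NAPQI + GSH conjugation, glucuronidation, sulfation, and first-order GSH
# synthesis on the deficit (GSHmax - GSH).  Every reaction except GSH
# synthesis conserves APAP equivalents.

.subcell_species <- c("APAP", "NAPQI", "GSH", "NAPQI_GSH", "APAPG", "APAPS")

#' Construct a subcellular state vector
#'
#' @param ... Named concentrations (mmol/L); `GSH` defaults to 9.9, other
#'   species to 0.
#' @return Named numeric vector over the six species.
#' @export
#' @examples
#' subcell_state(APAP = 0.1)
subcell_state <- function(...) {
  st <- stats::setNames(numeric(6), .subcell_species)
  st["GSH"] <- 9.9
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), .subcell_species)
    if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
    st[names(dots)] <- dots
  }
  st
}

# Vectorised reaction rates: `conc` is a 6 x n matrix (one column per
# cell), `zone` a length-n vector of CYP2E1 Vmax scale factors.  Returns
# the 6 x n derivative matrix in mmol/L/s.
.subcell_deriv_matrix <- function(conc, p, zone) {
  apap <- conc["APAP", ]
  v_cyp  <- zone * p$Vmax_2E1 * apap / (p$Km_2E1 + apap)
  v_conj <- p$kNAPQIGSH * conc["NAPQI", ] * conc["GSH", ]
  v_gluc <- p$Vmax_GLUC * apap / (p$Km_GLUC + apap)
  v_sulf <- p$Vmax_SULF * apap / (p$Km_SULF + apap)
  v_syn  <- p$kGsh * (p$GSHmax - conc["GSH", ])
  rbind(
    APAP      = -(v_cyp + v_gluc + v_sulf),
    NAPQI     = v_cyp - v_conj,
    GSH       = v_syn - v_conj,
    NAPQI_GSH = v_conj,
    APAPG     = v_gluc,
    APAPS     = v_sulf
  )
}

#' Subcellular reaction derivatives
#'
#' @param state Named concentration vector from [subcell_state()] (mmol/L).
#' @param params Full parameter set (the `sc_` entries are used).
#' @param zone_scale CYP2E1 Vmax scale for this cell's lobular position,
#'   in (0, 1].
#' @return Named derivative vector (mmol/L/s).
#' @export
#' @examples
#' subcell_derivatives(subcell_state(APAP = 1.29))[["NAPQI"]]
subcell_derivatives <- function(state, params = refsim_params(),
                                zone_scale = 1) {
  if (any(state < 0)) stop("negative concentrations are not allowed")
  stopifnot(zone_scale > 0, zone_scale <= 1)
  p <- subcell_from_params(params)
  m <- matrix(state, ncol = 1, dimnames = list(names(state), NULL))
  drop(.subcell_deriv_matrix(m, p, zone_scale))
}

#' CYP2E1 zonation scale for a hepatocyte
#'
#' CYP2E1 expression rises linearly along the periportal-to-pericentral
#' axis from `lo` (80%) to `hi` (100%) of the tabulated Vmax.  Hepatocytes
#' are ordered in axial rank pairs (the two cells facing each other across
#' the sinusoid share a rank), so `cell_index` 0 and 1 are the most
#' periportal pair.  A degenerate single-rank sinusoid uses `hi`.
#'
#' @param cell_index 0-based cell index, `0 <= cell_index < n_cells`.
#' @param n_cells Total hepatocyte count (2 per axial rank).
#' @param lo,hi Periportal and pericentral Vmax fractions.
#' @return Dimensionless scale in `[lo, hi]`.
#' @export
#' @examples
#' zonation_scale(0, 20)   # periportal: 0.8
#' zonation_scale(19, 20)  # pericentral: 1.0
zonation_scale <- function(cell_index, n_cells, lo = 0.8, hi = 1.0) {
  stopifnot(n_cells >= 2, lo > 0, hi >= lo)
  if (any(cell_index < 0 | cell_index >= n_cells)) {
    stop("cell_index out of range [0, ", n_cells - 1, "]")
  }
  n_ranks <- n_cells %/% 2
  rank <- cell_index %/% 2
  if (n_ranks <= 1) return(rep(hi, length(cell_index)))
  lo + (hi - lo) * rank / (n_ranks - 1)
}

#' Integrate one hepatocyte's reaction network
#'
#' Advances the six-species network by `dt` seconds with a stiff-capable
#' adaptive solver.  When APAP and NAPQI are both absent only the linear
#' GSH deficit law is active and the closed-form solution
#' `GSHmax - (GSHmax - GSH0) exp(-kGsh t)` is used directly.
#'
#' @param state Named concentration vector (mmol/L).
#' @param params Full parameter set.
#' @param zone_scale CYP2E1 zonation scale.
#' @param dt Step length (s); `dt = 0` returns the state unchanged.
#' @param rtol,atol Solver tolerances.
#' @return Named concentration vector after `dt` seconds.
#' @export
#' @examples
#' integrate_subcell(subcell_state(), dt = 3600)[["GSH"]]
integrate_subcell <- function(state, params = refsim_params(),
                              zone_scale = 1, dt,
                              rtol = 1e-9, atol = 1e-12) {
  stopifnot(dt >= 0)
  if (dt == 0) return(state)
  p <- subcell_from_params(params)
  if (state[["APAP"]] == 0 && state[["NAPQI"]] == 0) {
    # analytic substep: only GSH synthesis is active
    out <- state
    out["GSH"] <- p$GSHmax - (p$GSHmax - state[["GSH"]]) * exp(-p$kGsh * dt)
    return(out)
  }
  deriv <- function(t, y, parms) {
    m <- matrix(pmax(y, 0), ncol = 1, dimnames = list(.subcell_species, NULL))
    list(as.vector(.subcell_deriv_matrix(m, p, zone_scale)))
  }
  sol <- deSolve::lsoda(unname(state), c(0, dt), deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) stop("subcellular integration failed")
  y <- pmax(sol[nrow(sol), -1], 0)
  stats::setNames(y, .subcell_species)
}

#' Simulate a standalone hepatocyte time course
#'
#' @param params Full parameter set.
#' @param apap0 Initial APAP concentration (mmol/L); 0.1 is the standard
#'   standalone scenario.
#' @param duration_h Simulated span (h).
#' @param times Output grid (h); default 200 evenly spaced points.
#' @param zone_scale CYP2E1 zonation scale.
#' @return Tibble (class `hepapk_subcell`) with `time_h`, `species`,
#'   `conc_mmol_per_L`.
#' @export
#' @examples
#' sim <- simulate_subcell(apap0 = 0.1, duration_h = 2)
simulate_subcell <- function(params = refsim_params(), apap0 = 0.1,
                             duration_h = 24, times = NULL, zone_scale = 1) {
  stopifnot(apap0 >= 0, duration_h > 0)
  if (is.null(times)) times <- seq(0, duration_h, length.out = 200)
  p <- subcell_from_params(params)
  y0 <- subcell_state(APAP = apap0, GSH = p$GSH0)
  deriv <- function(t, y, parms) {
    m <- matrix(pmax(y, 0), ncol = 1, dimnames = list(.subcell_species, NULL))
    list(as.vector(.subcell_deriv_matrix(m, p, zone_scale)))
  }
  sol <- deSolve::lsoda(unname(y0), times * 3600, deriv, parms = NULL,
                        rtol = 1e-9, atol = 1e-12)
  conc <- pmax(sol[, -1, drop = FALSE], 0)
  colnames(conc) <- .subcell_species
  out <- tibble::tibble(
    time_h = rep(times, times = 6),
    species = rep(.subcell_species, each = length(times)),
    conc_mmol_per_L = as.vector(conc)
  )
  structure(out, params = params,
            class = c("hepapk_subcell", class(tibble::tibble())))
}
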