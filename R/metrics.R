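# Model-output metrics: RMSE against reference ADME data, Cmax/Tmax/AUC,
# the excreted metabolic ratio, zonal summaries and the 15-entry output
# vector consumed by the sensitivity and population analyses.

.output_names <- c("RMSEa", "RMSEg", "RMSEs", "RMSEsum",
                   "CmaxA", "CmaxG", "CmaxS",
                   "TmaxA", "TmaxG", "TmaxS",
                   "AUCA", "AUCG", "AUCS",
                   "metabRatio", "NAPQIGSH_Sum")

#' Root-mean-square error of a simulated curve against reference data
#'
#' `sqrt(mean((y_sim - y_ref)^2))` over the reference time points, with the
#' simulated curve interpolated linearly onto them.  Reference
#' concentrations in ug/mL are converted to mmol/L with the compound's
#' molar mass before comparison.
#'
#' @param sim Data frame with `time_h`, `compound` and a concentration
#'   column (`conc_mmol_per_L`), e.g. from [serum_concentrations()].
#' @param ref Reference table with `time_h`, `compound`, `concentration`,
#'   `unit` (`"mmol_per_L"` or `"ug_per_mL"`).
#' @param compound Compound to score.
#' @return RMSE in mmol/L.
#' @export
#' @examples
#' sim <- tibble::tibble(time_h = 0:3, compound = "APAP",
#'                       conc_mmol_per_L = c(0, 1, 2, 1))
#' ref <- tibble::tibble(time_h = c(1, 2), compound = "APAP",
#'                       concentration = c(1, 2), unit = "mmol_per_L")
#' rmse(sim, ref, "APAP")
rmse <- function(sim, ref, compound = "APAP") {
  s <- sim[sim$compound == compound, ]
  r <- ref[ref$compound == compound, ]
  if (nrow(r) == 0) stop("no reference points for ", compound)
  if (any(diff(r$time_h) <= 0)) stop("reference times must be increasing")
  if (min(r$time_h) < min(s$time_h) - 1e-9 ||
      max(r$time_h) > max(s$time_h) + 1e-9) {
    stop("reference time outside simulated span")
  }
  y_ref <- r$concentration
  if (!is.null(r$unit)) {
    ug <- r$unit == "ug_per_mL"
    y_ref[ug] <- y_ref[ug] / hepapk_molar_masses()[[compound]]
  }
  y_sim <- stats::approx(s$time_h, s$conc_mmol_per_L, xout = r$time_h,
                         rule = 1)$y
  sqrt(mean((y_sim - y_ref)^2))
}

#' ADME descriptors of a concentration-time curve
#'
#' @param series Data frame with `time_h` and a concentration column
#'   (first non-time numeric column is used).
#' @return Tibble with one row: `Cmax` (maximum), `Tmax` (earliest time of
#'   the maximum) and `AUC` (trapezoidal, over the full window).
#' @export
#' @examples
#' adme_descriptors(tibble::tibble(time_h = 0:2, conc = c(0, 2, 0)))
adme_descriptors <- function(series) {
  stopifnot(nrow(series) >= 1)
  t <- series$time_h
  ycols <- setdiff(names(series)[vapply(series, is.numeric, logical(1))],
                   c("time_h"))
  y <- series[[ycols[1]]]
  cmax <- max(y)
  tmax <- t[which(y == cmax)[1]]  # tie-break: earliest
  auc <- if (length(t) > 1) sum(diff(t) * (utils::head(y, -1) +
                                             utils::tail(y, -1)) / 2) else 0
  tibble::tibble(Cmax = cmax, Tmax = tmax, AUC = auc)
}

#' Excreted metabolic ratio
#'
#' Fraction of kidney-tubule (urinary) content that is conjugated:
#' `(APAPG + APAPS) / (APAP + APAPG + APAPS)`.
#'
#' @param amounts Named vector or separate amounts (mmol) in the tubules.
#' @param APAPG,APAPS Amounts when `amounts` is the APAP scalar.
#' @return Ratio in `[0, 1]`.
#' @export
#' @examples
#' metab_ratio(c(APAP = 1, APAPG = 1, APAPS = 1))
metab_ratio <- function(amounts, APAPG = NULL, APAPS = NULL) {
  if (!is.null(APAPG)) {
    amounts <- c(APAP = unname(amounts), APAPG = unname(APAPG),
                 APAPS = unname(APAPS))
  }
  stopifnot(all(amounts >= 0))
  tot <- sum(amounts[c("APAP", "APAPG", "APAPS")])
  if (tot == 0) stop("metabolic ratio undefined: all tubule amounts zero")
  unname((amounts[["APAPG"]] + amounts[["APAPS"]]) / tot)
}

#' Zonal summary of per-hepatocyte traces
#'
#' Groups one side's hepatocytes into periportal (PP), midzonal (MZ) and
#' perivenous (PV) regions of four axial ranks each (with 10 ranks the
#' mid group shares its boundary ranks with its neighbours) and reports
#' the group mean and SD per species and time point.
#'
#' @param cells Per-cell trace tibble from [run_multiscale()] (`$cells`).
#' @param side Which side of the channel to monitor (0 or 1).
#' @return Tibble with `zone`, `species`, `time_h`, `mean_conc`, `sd_conc`,
#'   `n_cells`.
#' @export
zonal_summary <- function(cells, side = 0) {
  n_ranks <- max(cells$rank) + 1L
  if (n_ranks * 2L < 12L) stop("zonal summary needs at least 12 cells")
  zones <- list(
    PP = 0:3,
    MZ = seq.int((n_ranks - 4L) %/% 2L, length.out = 4L),
    PV = seq.int(n_ranks - 4L, n_ranks - 1L)
  )
  one_side <- cells[cells$side == side, ]
  out <- purrr::map_dfr(names(zones), function(z) {
    sub <- one_side[one_side$rank %in% zones[[z]], ]
    agg <- dplyr::summarise(
      dplyr::group_by(sub, .data$species, .data$time_h),
      mean_conc = mean(.data$conc_mmol_per_L),
      sd_conc = stats::sd(.data$conc_mmol_per_L),
      n_cells = dplyr::n_distinct(.data$cell_id),
      .groups = "drop"
    )
    agg$zone <- z
    agg
  })
  out[, c("zone", "species", "time_h", "mean_conc", "sd_conc", "n_cells")]
}

# tubule amounts (mmol) per compound at the last recorded time
.tubule_amounts <- function(result) {
  tbl <- if (inherits(result, "hepapk_multiscale")) result$pbpk else
    tibble::as_tibble(result)
  tub <- tbl[tbl$compartment == "CTubules", ]
  tend <- max(tub$time_h)
  last <- tub[tub$time_h == tend, ]
  stats::setNames(last$amount_mmol, last$compound)[compounds()]
}

#' Urinary (kidney-tubule) composition at end of simulation
#'
#' @param result A `hepapk_multiscale` result.
#' @return Tibble with `compound`, `amount_mmol`, `fraction` (shares of
#'   total tubule content; sums to 1).
#' @export
urinary_fractions <- function(result) {
  amt <- .tubule_amounts(result)
  tibble::tibble(compound = names(amt), amount_mmol = unname(amt),
                 fraction = unname(amt) / sum(amt))
}

#' The 15-entry model-output vector
#'
#' Computes, from a coupled simulation, the outputs used by the
#' sensitivity and population analyses: RMSE against a reference ADME data
#' set for each compound and their sum (NA when no reference is supplied;
#' such entries are excluded downstream), Cmax/Tmax/AUC of the venous
#' serum curve per compound, the excreted metabolic ratio, and the
#' liver-scaled total NAPQI-GSH formed across all hepatocytes (mmol).
#'
#' @param result A `hepapk_multiscale` (or, without `NAPQIGSH_Sum`, a
#'   `hepapk_pbpk`) result.
#' @param ref Optional reference ADME table (see [rmse()]).
#' @return Named numeric vector of length 15.
#' @export
model_outputs <- function(result, ref = NULL) {
  ser <- serum_concentrations(result)
  out <- stats::setNames(rep(NA_real_, 15), .output_names)
  sfx <- c(APAP = "A", APAPG = "G", APAPS = "S")
  for (cm in compounds()) {
    s <- ser[ser$compound == cm, c("time_h", "conc_mmol_per_L")]
    d <- adme_descriptors(s)
    out[paste0("Cmax", sfx[cm])] <- d$Cmax
    out[paste0("Tmax", sfx[cm])] <- d$Tmax
    out[paste0("AUC", sfx[cm])] <- d$AUC
    if (!is.null(ref)) {
      out[paste0("RMSE", tolower(sfx[cm]))] <- rmse(ser, ref, cm)
    }
  }
  if (!is.null(ref)) {
    out["RMSEsum"] <- out["RMSEa"] + out["RMSEg"] + out["RMSEs"]
  }
  amt <- .tubule_amounts(result)
  out["metabRatio"] <- if (sum(amt) > 0) metab_ratio(amt) else 0
  out["NAPQIGSH_Sum"] <- if (inherits(result, "hepapk_multiscale")) {
    cells <- result$cells
    last <- cells[cells$time_h == max(cells$time_h) &
                    cells$species == "NAPQI_GSH", ]
    vh_L <- result$params[["cc3d_Vol_HEP"]] * .um3_to_L
    result$S * sum(last$conc_mmol_per_L) * vh_L
  } else 0
  out
}
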