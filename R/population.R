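# Virtual population simulation: every parameter of every individual is
# the base value times an independent multiplier drawn from a normal
# distribution with mean 1 and CV 25%, truncated to keep all parameters
# positive and within +/- 3 SD.

#' Sample a virtual population of parameter sets
#'
#' @param base Base parameter set.
#' @param n Number of individuals.
#' @param cv Coefficient of variation of the multipliers (default 0.25).
#' @param seed RNG seed; sampling uses the inverse-CDF method so the same
#'   seed always regenerates the same population.
#' @param bounds Truncation bounds on the multipliers; default
#'   `c(max(0.25, 1 - 3 cv), 1 + 3 cv)`.
#' @param subset Parameter names to perturb; default
#'   [default_sensitivity_subset()].
#' @return List of `n` parameter sets, with the multiplier matrix attached
#'   as attribute `"multipliers"`.
#' @export
#' @examples
#' pop <- sample_population(refsim_params(), n = 3, seed = 1)
sample_population <- function(base, n, cv = 0.25, seed = 1,
                              bounds = NULL, subset = NULL) {
  stopifnot(n >= 1, cv > 0)
  if (is.null(bounds)) bounds <- c(max(0.25, 1 - 3 * cv), 1 + 3 * cv)
  stopifnot(length(bounds) == 2, bounds[1] > 0, bounds[2] > bounds[1])
  if (is.null(subset)) {
    subset <- intersect(default_sensitivity_subset(), names(base))
  }
  p_lo <- stats::pnorm(bounds[1], 1, cv)
  p_hi <- stats::pnorm(bounds[2], 1, cv)
  u <- .with_seed(seed, matrix(stats::runif(n * length(subset), p_lo, p_hi),
                               nrow = n, dimnames = list(NULL, subset)))
  mult <- stats::qnorm(u, 1, cv)
  sets <- lapply(seq_len(n), function(i) {
    p <- base
    p[subset] <- p[subset] * mult[i, ]
    p
  })
  attr(sets, "multipliers") <- mult
  sets
}

#' Run a virtual population through the coupled model
#'
#' Independent coupled simulations for `n` individuals (fixed total dose
#' in mg, computed once from the base parameter set, so body-weight
#' multipliers change the physiology but not the administered dose).
#' Individual run failures are logged and excluded, with the count
#' reported.
#'
#' @inheritParams sample_population
#' @param dose_mg_per_kg Dose relative to the *base* body weight (mg/kg).
#' @param duration_h Simulated span per individual (h).
#' @param mode Coupling mode (see [scale_bridge()]); `"qss"` recommended.
#' @param dt_out Output grid spacing (h).
#' @return Object of class `hepapk_population`: list with `individuals`
#'   (one row per successful run: outputs, urinary fractions), `serum`
#'   (per-individual serum APAP/metabolite curves), `summary_curves`
#'   (population mean and SD per compound and time), `urinary` (population
#'   mean fractions), `multipliers`, `n_failed`, `base_run`.
#' @export
run_population <- function(base = refsim_params(), n = 20,
                           dose_mg_per_kg = 20, duration_h = 8, cv = 0.25,
                           seed = 1, bounds = NULL, subset = NULL,
                           mode = "qss", dt_out = 0.1) {
  sets <- sample_population(base, n, cv = cv, seed = seed, bounds = bounds,
                            subset = subset)
  dose_mg <- dose_mg_per_kg * base[["pbpk_bw"]]
  runs <- vector("list", n)
  failed <- integer(0)
  for (i in seq_len(n)) {
    runs[[i]] <- tryCatch(
      run_multiscale(sets[[i]], duration_h = duration_h,
                     bridge = scale_bridge(sets[[i]], mode = mode),
                     dt_out = dt_out, dose_mg = dose_mg),
      error = function(e) {
        warning(sprintf("individual %d failed: %s", i, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    if (is.null(runs[[i]])) failed <- c(failed, i)
  }
  ok <- setdiff(seq_len(n), failed)
  if (!length(ok)) stop("all population individuals failed")

  indiv <- purrr::map_dfr(ok, function(i) {
    out <- model_outputs(runs[[i]])
    uf <- urinary_fractions(runs[[i]])
    row <- tibble::as_tibble(as.list(out))
    row$individual <- i
    row$frac_APAP <- uf$fraction[uf$compound == "APAP"]
    row$frac_APAPG <- uf$fraction[uf$compound == "APAPG"]
    row$frac_APAPS <- uf$fraction[uf$compound == "APAPS"]
    row
  })

  serum <- purrr::map_dfr(ok, function(i) {
    s <- runs[[i]]$serum
    s$individual <- i
    s
  })
  summary_curves <- dplyr::summarise(
    dplyr::group_by(serum, .data$compound, .data$time_h),
    mean_conc = mean(.data$conc_mmol_per_L),
    sd_conc = stats::sd(.data$conc_mmol_per_L),
    .groups = "drop"
  )
  urinary <- tibble::tibble(
    compound = compounds(),
    mean_fraction = c(mean(indiv$frac_APAP), mean(indiv$frac_APAPG),
                      mean(indiv$frac_APAPS)),
    sd_fraction = c(stats::sd(indiv$frac_APAP), stats::sd(indiv$frac_APAPG),
                    stats::sd(indiv$frac_APAPS))
  )
  structure(list(
    individuals = indiv, serum = serum, summary_curves = summary_curves,
    urinary = urinary, multipliers = attr(sets, "multipliers"),
    n = n, n_failed = length(failed), failed = failed,
    cv = cv, seed = seed, duration_h = duration_h
  ), class = "hepapk_population")
}

#' @export
print.hepapk_population <- function(x, ...) {
  cat(sprintf("<hepapk population> n = %d (%d failed), cv = %.2f\n",
              x$n, x$n_failed, x$cv))
  cat("mean urinary fractions at end of run:\n")
  print(as.data.frame(x$urinary), row.names = FALSE)
  invisible(x)
}

#' Most extreme individuals of a population
#'
#' Ranks individuals by the signed area between their serum APAP curve and
#' the population mean curve; returns the highest and lowest individuals
#' with their parameter multipliers.
#'
#' @param pop A `hepapk_population` result with at least 3 individuals.
#' @return List with `index_high`, `index_low`, `deviation` (named vector
#'   of signed areas, mmol/L * h) and `multipliers_high`/`multipliers_low`.
#' @export
find_outliers <- function(pop) {
  stopifnot(inherits(pop, "hepapk_population"))
  ids <- sort(unique(pop$serum$individual))
  if (length(ids) < 3) stop("outlier detection needs at least 3 individuals")
  mean_apap <- pop$summary_curves[pop$summary_curves$compound == "APAP", ]
  dev <- vapply(ids, function(i) {
    s <- pop$serum[pop$serum$individual == i &
                     pop$serum$compound == "APAP", ]
    d <- s$conc_mmol_per_L - mean_apap$mean_conc[
      match(s$time_h, mean_apap$time_h)]
    t <- s$time_h
    sum(diff(t) * (utils::head(d, -1) + utils::tail(d, -1)) / 2)
  }, numeric(1))
  names(dev) <- ids
  index_high <- ids[which(dev == max(dev))[1]]  # ties: lowest index
  index_low <- ids[which(dev == min(dev))[1]]
  list(index_high = index_high, index_low = index_low, deviation = dev,
       multipliers_high = pop$multipliers[index_high, ],
       multipliers_low = pop$multipliers[index_low, ])
}
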