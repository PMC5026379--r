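# File I/O: reference ADME tables, time-series exports, run manifests,
# and the built-in synthetic reference generator.

#' Generate a synthetic reference ADME data set
#'
#' Runs the model for the given parameter set and samples the venous serum
#' curves at the requested times, optionally multiplying each point by
#' unit-mean lognormal noise with the given coefficient of variation.
#' With `noise_cv = 0` the reference equals the model output exactly, so
#' RMSE against the generating parameter set is zero -- the basis for
#' parameter-recovery and self-consistency checks when no in vivo table
#' is available.
#'
#' @param params Parameter set used to generate the reference.
#' @param dose_mg_per_kg Oral dose (mg/kg).
#' @param times Sampling times (h).
#' @param noise_cv Lognormal noise CV (0 = noise free).
#' @param seed RNG seed for the noise.
#' @param model `"pbpk"` (standalone whole-body run; fast) or
#'   `"multiscale"` (full coupled run).
#' @param ... Passed to [simulate_pbpk()] or [run_multiscale()].
#' @return Reference tibble with `time_h`, `compound`, `concentration`
#'   (mmol/L), `unit`.
#' @export
#' @examples
#' ref <- generate_reference(times = c(0.5, 1, 2), model = "pbpk")
generate_reference <- function(params = refsim_params(), dose_mg_per_kg = 20,
                               times = seq(0.5, 8, by = 0.5), noise_cv = 0,
                               seed = 1, model = c("pbpk", "multiscale"),
                               ...) {
  model <- match.arg(model)
  stopifnot(all(times >= 0), noise_cv >= 0)
  duration <- max(times)
  ser <- if (model == "pbpk") {
    sim <- simulate_pbpk(params, dose_mg_per_kg, duration_h = duration,
                         times = sort(unique(c(0, times))), ...)
    serum_concentrations(sim)
  } else {
    sim <- run_multiscale(params, dose_mg_per_kg, duration_h = duration, ...)
    sim$serum
  }
  out <- purrr::map_dfr(compounds(), function(cm) {
    s <- ser[ser$compound == cm, ]
    y <- stats::approx(s$time_h, s$conc_mmol_per_L, xout = times,
                       rule = 2)$y
    tibble::tibble(time_h = times, compound = cm, concentration = y,
                   unit = "mmol_per_L")
  })
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    fac <- .with_seed(seed, stats::rlnorm(nrow(out), -sdlog^2 / 2, sdlog))
    out$concentration <- out$concentration * fac
  }
  out
}

#' Read / write reference ADME tables
#'
#' Delimited text with header `time_h,compound,concentration,unit`.
#'
#' @param path File path.
#' @param ref Reference tibble (for writing).
#' @return The reference tibble (read) or `path` invisibly (write).
#' @export
read_reference_adme <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "compound", "concentration", "unit")
  if (!all(need %in% names(df))) {
    stop("reference file must have columns: ", paste(need, collapse = ", "))
  }
  tibble::as_tibble(df[, need])
}

#' @rdname read_reference_adme
#' @export
write_reference_adme <- function(ref, path) {
  utils::write.csv(as.data.frame(ref), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a whole-body time series as delimited text
#'
#' Header: `time_h,compartment,compound,amount_mmol,concentration_mmol_per_L`.
#'
#' @param sim A `hepapk_pbpk` tibble or `hepapk_multiscale` result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(sim, path) {
  tbl <- if (inherits(sim, "hepapk_multiscale")) {
    x <- sim$pbpk
    x$concentration_mmol_per_L <- NA_real_
    x
  } else tibble::as_tibble(sim)
  utils::write.csv(as.data.frame(tbl), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run bit-for-bit in the
#' deterministic modes: resolved parameters, seeds, mode flags, package
#' version and a timestamp.
#'
#' @param path Output JSON path.
#' @param params Resolved parameter set.
#' @param seed Seed(s) used.
#' @param mode Mode flags (character or list).
#' @param extra Optional named list of additional fields.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, params, seed = NA, mode = "qss",
                               extra = list()) {
  manifest <- c(list(
    tool = "hepapk",
    version = as.character(utils::packageVersion("hepapk")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, mode = mode,
    parameters = as.list(params)
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
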