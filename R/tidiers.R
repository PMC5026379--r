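# broom-style tidiers for the package's result classes.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a multiscale simulation into its serum curves
#' @param x A `hepapk_multiscale` object.
#' @param ... Unused.
#' @return Tibble of venous plasma concentrations per compound and time.
#' @export
tidy.hepapk_multiscale <- function(x, ...) x$serum

#' One-row summary of a multiscale simulation
#' @param x A `hepapk_multiscale` object.
#' @param ... Unused.
#' @return Tibble with the ADME descriptors, metabolic ratio, scaled
#'   NAPQI-GSH total and the worst conservation error.
#' @export
glance.hepapk_multiscale <- function(x, ...) {
  out <- model_outputs(x)
  tb <- tibble::as_tibble(as.list(out[!is.na(out)]))
  tb$max_conservation_error <- max(x$conservation$rel_error)
  tb$dose_mmol <- x$dose_mmol
  tb$mode <- x$mode
  tb
}

#' One-row ADME summary of a standalone whole-body simulation
#' @param x A `hepapk_pbpk` tibble.
#' @param ... Unused.
#' @export
glance.hepapk_pbpk <- function(x, ...) {
  out <- model_outputs(x)
  tibble::as_tibble(as.list(out[!is.na(out)]))
}

#' Tidy a sensitivity matrix into long format
#' @param x A `hepapk_sensitivity` object.
#' @param ... Unused.
#' @return Tibble with `output`, `parameter`, `sensitivity`.
#' @export
tidy.hepapk_sensitivity <- function(x, ...) {
  m <- x$matrix
  tibble::tibble(
    output = rep(rownames(m), times = ncol(m)),
    parameter = rep(colnames(m), each = nrow(m)),
    sensitivity = as.vector(m)
  )
}

#' Ranked average-sensitivity summary
#' @param x A `hepapk_sensitivity` object.
#' @param ... Unused.
#' @return Tibble with one row per parameter, ranked by `|Average J|`.
#' @export
glance.hepapk_sensitivity <- function(x, ...) {
  avg <- x$matrix["Average", ]
  tb <- tibble::tibble(parameter = names(avg), average_J = unname(avg),
                       abs_average_J = abs(unname(avg)))
  dplyr::arrange(tb, dplyr::desc(.data$abs_average_J))
}

#' Tidy a population result into per-individual outputs
#' @param x A `hepapk_population` object.
#' @param ... Unused.
#' @export
tidy.hepapk_population <- function(x, ...) x$individuals

#' One-row summary of a population simulation
#' @param x A `hepapk_population` object.
#' @param ... Unused.
#' @export
glance.hepapk_population <- function(x, ...) {
  uf <- x$urinary
  tibble::tibble(
    n = x$n, n_failed = x$n_failed, cv = x$cv,
    mean_frac_APAP = uf$mean_fraction[uf$compound == "APAP"],
    mean_frac_APAPG = uf$mean_fraction[uf$compound == "APAPG"],
    mean_frac_APAPS = uf$mean_fraction[uf$compound == "APAPS"],
    mean_CmaxA = mean(x$individuals$CmaxA),
    sd_CmaxA = stats::sd(x$individuals$CmaxA)
  )
}
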