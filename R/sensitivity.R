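# Local parameter sensitivity analysis.
#
# The sensitivity coefficient of output y_k to parameter x_i is the
# one-sided log-scale finite difference
#
#   J_k(x_i) = [(y_k(x_i + d) - y_k(x_i)) / d] * [x_i / y_k(x_i)],
#   d = delta_frac * x_i (25% by default),
#
# an approximation of d ln(y_k) / d ln(x_i).  A "runner" maps a parameter
# set (named numeric vector) to a named vector of model outputs, usually
# [model_outputs()] of a coupled simulation.

#' Single-parameter sensitivity coefficients
#'
#' @param base Base parameter set (named numeric vector).
#' @param param_name Name of the parameter to perturb.
#' @param runner Function `params -> named numeric output vector`.
#' @param delta_frac Fractional perturbation (default 0.25, i.e. +25%).
#' @param base_outputs Optional precomputed `runner(base)`.
#' @param central Use the optional central-difference variant
#'   (`(y(x+d) - y(x-d)) / (2d) * x/y(x)`); off by default.
#' @return Named vector of sensitivities; entries where the base output is
#'   zero or undefined are `NA` (excluded from averages downstream).
#' @export
#' @examples
#' single_param_sensitivity(c(a = 2), "a", function(p) c(y = p[["a"]]^2))
single_param_sensitivity <- function(base, param_name, runner,
                                     delta_frac = 0.25, base_outputs = NULL,
                                     central = FALSE) {
  stopifnot(param_name %in% names(base), delta_frac > 0)
  if (is.null(base_outputs)) base_outputs <- runner(base)
  up <- base
  up[param_name] <- up[param_name] * (1 + delta_frac)
  y_up <- runner(up)
  y0 <- base_outputs[names(y_up)]
  if (central) {
    dn <- base
    dn[param_name] <- dn[param_name] * (1 - delta_frac)
    y_dn <- runner(dn)
    j <- (y_up - y_dn) / (2 * delta_frac) / y0
  } else {
    j <- (y_up - y0) / delta_frac / y0
  }
  j[!is.finite(j)] <- NA_real_
  j
}

#' Sensitivity matrix over a parameter subset
#'
#' One perturbed model evaluation per parameter (+25% by default), giving
#' the outputs-by-parameters coefficient matrix plus an `"Average"` row of
#' column means over the defined entries.
#'
#' @inheritParams single_param_sensitivity
#' @param subset Parameter names to scan; default
#'   [default_sensitivity_subset()] intersected with `names(base)`.
#' @param progress Print parameter names as they are scanned.
#' @return Object of class `hepapk_sensitivity`: list with `matrix`
#'   (outputs + Average row, by parameters), `base_outputs`, `delta_frac`,
#'   and `failures` (parameters whose run failed; their column is NA).
#' @export
sensitivity_matrix <- function(base, runner,
                               subset = NULL, delta_frac = 0.25,
                               progress = FALSE) {
  if (is.null(subset)) {
    subset <- intersect(default_sensitivity_subset(), names(base))
  }
  stopifnot(all(subset %in% names(base)))
  y0 <- runner(base)
  J <- matrix(NA_real_, nrow = length(y0), ncol = length(subset),
              dimnames = list(names(y0), subset))
  failures <- character()
  for (pn in subset) {
    if (progress) message("  sensitivity: ", pn)
    res <- tryCatch(
      single_param_sensitivity(base, pn, runner, delta_frac,
                               base_outputs = y0),
      error = function(e) {
        failures <<- c(failures, pn)
        rep(NA_real_, length(y0))
      })
    J[, pn] <- res[rownames(J)]
  }
  avg <- colMeans(J, na.rm = TRUE)
  avg[!is.finite(avg)] <- NA_real_
  out <- list(matrix = rbind(J, Average = avg), base_outputs = y0,
              delta_frac = delta_frac, failures = failures)
  class(out) <- "hepapk_sensitivity"
  out
}

#' @export
print.hepapk_sensitivity <- function(x, ...) {
  cat("<hepapk sensitivity matrix> ", nrow(x$matrix) - 1, " outputs x ",
      ncol(x$matrix), " parameters (+Average row)\n", sep = "")
  ranked <- sort(abs(x$matrix["Average", ]), decreasing = TRUE)
  cat("top |Average J|:\n")
  print(utils::head(round(ranked, 4), 8))
  invisible(x)
}

#' Pairwise parameter interaction coefficient
#'
#' Deviation from additivity of two +25% single-parameter perturbations on
#' one output: `PPV(i,j) = relD(i and j together) - relD(i) - relD(j)`,
#' where `relD` is the relative output change.  Zero for additively
#' separable responses; symmetric in the pair by construction.
#'
#' @inheritParams single_param_sensitivity
#' @param param_i,param_j Names of the (distinct) parameters.
#' @param output Which output entry to analyse (default `"RMSEsum"`).
#' @param cache Optional environment for memoising single runs across
#'   repeated calls.
#' @return Interaction coefficient (dimensionless).
#' @export
#' @examples
#' pairwise_interaction(c(a = 1, b = 1), "a", "b",
#'                      function(p) c(y = p[["a"]] * p[["b"]]), output = "y")
pairwise_interaction <- function(base, param_i, param_j, runner,
                                 output = "RMSEsum", delta_frac = 0.25,
                                 cache = NULL) {
  if (identical(param_i, param_j)) {
    stop("pairwise interaction is undefined on the diagonal")
  }
  stopifnot(all(c(param_i, param_j) %in% names(base)))
  run1 <- function(pnames) {
    key <- paste0("run_", paste(sort(pnames), collapse = "|"))
    if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
    p <- base
    p[pnames] <- p[pnames] * (1 + delta_frac)
    y <- runner(p)[[output]]
    if (!is.null(cache)) cache[[key]] <- y
    y
  }
  y0 <- run1(character(0))
  if (!is.finite(y0) || y0 == 0) stop("base output zero or undefined")
  rel <- function(y) (y - y0) / y0
  rel(run1(c(param_i, param_j))) - rel(run1(param_i)) - rel(run1(param_j))
}

#' Log-normal global parameter scan
#'
#' Rescales each parameter in the subset by `10^eps`,
#' `eps ~ Normal(0, sigma_log10)`, independently per parameter and
#' replicate, spreading the scan across orders of magnitude.
#'
#' @param base Base parameter set.
#' @param sigma_log10 SD of the exponent (decades).
#' @param n Number of replicates.
#' @param seed RNG seed (the scan is reproducible under a fixed seed).
#' @param subset Parameter names to rescale; default
#'   [default_sensitivity_subset()].
#' @return List of `n` parameter sets; the exponent matrix is attached as
#'   attribute `"eps"`.
#' @export
lognormal_scan <- function(base, sigma_log10 = 1, n = 1, seed = 1,
                           subset = NULL) {
  stopifnot(n >= 1, sigma_log10 >= 0)
  if (is.null(subset)) {
    subset <- intersect(default_sensitivity_subset(), names(base))
  }
  rng <- .with_seed(seed, matrix(stats::rnorm(n * length(subset), 0,
                                              sigma_log10),
                                 nrow = n,
                                 dimnames = list(NULL, subset)))
  sets <- lapply(seq_len(n), function(i) {
    p <- base
    p[subset] <- p[subset] * 10^rng[i, ]
    p
  })
  attr(sets, "eps") <- rng
  sets
}

# evaluate `expr` under a local RNG seed without disturbing the caller's
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Correlation between two sensitivity matrices
#'
#' Pearson correlation (and its square) of the flattened entries of two
#' sensitivity matrices sharing row/column labels.
#'
#' @param A,B `hepapk_sensitivity` objects or plain labelled matrices.
#' @param mode `"all"` (the output rows), `"average_row"` (just the
#'   Average row) or `"without_rmse_rows"` (drops the four RMSE rows and
#'   Average).
#' @return Tibble with `mode`, `r`, `r_squared`, `n_entries`.
#' @export
matrix_correlation <- function(A, B,
                               mode = c("all", "average_row",
                                        "without_rmse_rows")) {
  mode <- match.arg(mode)
  MA <- if (inherits(A, "hepapk_sensitivity")) A$matrix else A
  MB <- if (inherits(B, "hepapk_sensitivity")) B$matrix else B
  if (!identical(dim(MA), dim(MB)) ||
      !identical(dimnames(MA), dimnames(MB))) {
    stop("sensitivity matrices must share shape and labels")
  }
  rows <- switch(mode,
    all = setdiff(rownames(MA), "Average"),
    average_row = "Average",
    without_rmse_rows = setdiff(
      rownames(MA),
      c("RMSEa", "RMSEg", "RMSEs", "RMSEsum", "Average"))
  )
  a <- as.vector(MA[rows, , drop = FALSE])
  b <- as.vector(MB[rows, , drop = FALSE])
  ok <- is.finite(a) & is.finite(b)
  r <- stats::cor(a[ok], b[ok])
  tibble::tibble(mode = mode, r = r, r_squared = r^2, n_entries = sum(ok))
}
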