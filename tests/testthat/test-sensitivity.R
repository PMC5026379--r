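# Log-scale sensitivity coefficients, pairwise interactions, scans and
# matrix correlations, checked against closed-form analytic responses.

test_that("power-law responses give the closed-form coefficient", {
  base <- c(a = 2)
  for (p in c(-1, 0.5, 1, 2)) {
    runner <- local({
      pw <- p
      function(x) c(y = x[["a"]]^pw)
    })
    j <- single_param_sensitivity(base, "a", runner)
    expect_equal(unname(j["y"]), (1.25^p - 1) / 0.25, tolerance = 1e-12)
  }
  # y = x^2 at +25%: ((1.25^2 - 1)/1) / 0.25 = 2.25
  j2 <- single_param_sensitivity(c(a = 3), "a", function(x) c(y = x[["a"]]^2))
  expect_equal(unname(j2["y"]), 2.25, tolerance = 1e-12)
  # linear responses score 1 regardless of the constant
  j1 <- single_param_sensitivity(c(a = 0.37), "a",
                                 function(x) c(y = 17 * x[["a"]]))
  expect_equal(unname(j1["y"]), 1, tolerance = 1e-12)
  # responses independent of the parameter score 0
  j0 <- single_param_sensitivity(c(a = 1), "a", function(x) c(y = 5))
  expect_equal(unname(j0["y"]), 0)
  # zero base output is flagged undefined
  jz <- single_param_sensitivity(c(a = 1), "a", function(x) c(y = 0))
  expect_true(is.na(jz["y"]))
})

test_that("the central-difference variant matches its definition", {
  j <- single_param_sensitivity(c(a = 2), "a",
                                function(x) c(y = x[["a"]]^2),
                                central = TRUE)
  expect_equal(unname(j["y"]), ((1.25^2 - 0.75^2) / 0.5), tolerance = 1e-12)
})

test_that("the sensitivity matrix carries an Average row over defined entries", {
  base <- c(a = 1, b = 2)
  runner <- function(x) c(y1 = x[["a"]], y2 = x[["a"]]^2, y3 = 0)
  sm <- sensitivity_matrix(base, runner, subset = c("a", "b"))
  expect_equal(dim(sm$matrix), c(4, 2))  # 3 outputs + Average
  expect_equal(unname(sm$matrix[, "a"]),
               c(1, 2.25, NA, mean(c(1, 2.25))), tolerance = 1e-12)
  expect_equal(unname(sm$matrix[1:2, "b"]), c(0, 0))
  # all-constant responses give an all-zero matrix
  sm0 <- sensitivity_matrix(base, function(x) c(y = 3), subset = c("a", "b"))
  expect_equal(unname(sm0$matrix["y", ]), c(0, 0))
  long <- tidy(sm)
  expect_equal(nrow(long), 8)
})

test_that("pairwise interactions vanish for additive responses", {
  base <- c(a = 2, b = 5)
  add <- function(x) c(RMSEsum = 3 * x[["a"]] + 7 * x[["b"]])
  expect_equal(pairwise_interaction(base, "a", "b", add), 0,
               tolerance = 1e-12)
  prod_runner <- function(x) c(RMSEsum = x[["a"]] * x[["b"]])
  expect_equal(pairwise_interaction(base, "a", "b", prod_runner),
               (1.25^2 - 1) - 2 * 0.25, tolerance = 1e-12)
  expect_equal(pairwise_interaction(base, "a", "b", prod_runner), 0.0625)
  # symmetric in the pair, and undefined on the diagonal
  cache <- new.env()
  ab <- pairwise_interaction(base, "a", "b", prod_runner, cache = cache)
  ba <- pairwise_interaction(base, "b", "a", prod_runner, cache = cache)
  expect_identical(ab, ba)
  expect_error(pairwise_interaction(base, "a", "a", prod_runner),
               "diagonal")
})

test_that("log-normal scans are reproducible and centred on the base", {
  base <- refsim_params()
  s0 <- lognormal_scan(base, sigma_log10 = 0, n = 3, seed = 9)
  expect_identical(s0[[1]], base)
  expect_identical(s0[[3]], base)
  s1 <- lognormal_scan(base, sigma_log10 = 1, n = 5, seed = 4)
  s2 <- lognormal_scan(base, sigma_log10 = 1, n = 5, seed = 4)
  expect_identical(s1, s2)
  # geometric mean of a scanned parameter stays within 3 SE of its base
  n <- 1e4
  s3 <- lognormal_scan(base, sigma_log10 = 0.5, n = n, seed = 2,
                       subset = "pbpk_kGutabs")
  vals <- vapply(s3, function(p) p[["pbpk_kGutabs"]], numeric(1))
  gm <- exp(mean(log(vals)))
  se <- 0.5 * log(10) / sqrt(n)  # SE of the mean log
  expect_lt(abs(log(gm) - log(1.5)), 3 * se)
})

test_that("matrix correlations respect the row-selection modes", {
  rows <- c("RMSEa", "RMSEg", "RMSEs", "RMSEsum", "CmaxA", "metabRatio")
  A <- matrix(rnorm(6 * 4), 6, 4, dimnames = list(rows, paste0("p", 1:4)))
  A <- rbind(A, Average = colMeans(A))
  expect_equal(matrix_correlation(A, A)$r, 1)
  expect_equal(matrix_correlation(A, -A)$r, -1)
  expect_equal(matrix_correlation(A, 2 * A + 3)$r, 1)  # affine invariance
  expect_equal(matrix_correlation(A, A)$r_squared, 1)
  m <- matrix_correlation(A, A, mode = "without_rmse_rows")
  expect_equal(m$n_entries, 2 * 4)  # only CmaxA and metabRatio rows remain
  m2 <- matrix_correlation(A, A, mode = "average_row")
  expect_equal(m2$n_entries, 4)
  B <- A[1:6, ]
  expect_error(matrix_correlation(A, B), "shape")
})
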