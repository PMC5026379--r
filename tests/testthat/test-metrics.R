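# ADME metrics and the model-output vector.

test_that("rmse matches hand-computed values and handles units", {
  sim <- tibble::tibble(time_h = 0:3, compound = "APAP",
                        conc_mmol_per_L = c(1, 2, 3, 3))
  ref_same <- tibble::tibble(time_h = 0:2, compound = "APAP",
                             concentration = c(1, 2, 3), unit = "mmol_per_L")
  expect_equal(rmse(sim, ref_same, "APAP"), 0)
  # constant offset d at all points gives RMSE = d
  ref_off <- ref_same; ref_off$concentration <- ref_off$concentration + 0.5
  expect_equal(rmse(sim, ref_off, "APAP"), 0.5)
  ref3 <- tibble::tibble(time_h = 0:2, compound = "APAP",
                         concentration = c(1, 2, 4), unit = "mmol_per_L")
  expect_equal(rmse(sim, ref3, "APAP"), sqrt(1 / 3))
  expect_equal(round(rmse(sim, ref3, "APAP"), 4), 0.5774)
  # ug/mL references are converted with the molar mass
  mm <- hepapk_molar_masses()[["APAP"]]
  ref_ug <- tibble::tibble(time_h = 0:2, compound = "APAP",
                           concentration = c(1, 2, 3) * mm,
                           unit = "ug_per_mL")
  expect_equal(rmse(sim, ref_ug, "APAP"), 0, tolerance = 1e-12)
  # reference times outside the simulated span are an error
  ref_out <- tibble::tibble(time_h = c(1, 5), compound = "APAP",
                            concentration = c(1, 1), unit = "mmol_per_L")
  expect_error(rmse(sim, ref_out, "APAP"), "span")
})

test_that("ADME descriptors follow the geometry of the curve", {
  const <- tibble::tibble(time_h = seq(0, 8, 0.5), conc = 2)
  d <- adme_descriptors(const)
  expect_equal(c(d$Cmax, d$Tmax, d$AUC), c(2, 0, 16))
  tri <- tibble::tibble(time_h = c(0, 1, 2), conc = c(0, 2, 0))
  d2 <- adme_descriptors(tri)
  expect_equal(c(d2$Cmax, d2$Tmax, d2$AUC), c(2, 1, 2))
  # equal double peak: earliest time wins
  twin <- tibble::tibble(time_h = 0:4, conc = c(0, 3, 1, 3, 0))
  expect_equal(adme_descriptors(twin)$Tmax, 1)
})

test_that("AUC is additive over intervals and Cmax survives regridding", {
  t <- seq(0, 4, 0.25)
  y <- exp(-t) * t
  full <- adme_descriptors(tibble::tibble(time_h = t, conc = y))
  left <- adme_descriptors(tibble::tibble(time_h = t[t <= 2],
                                          conc = y[t <= 2]))
  right <- adme_descriptors(tibble::tibble(time_h = t[t >= 2],
                                           conc = y[t >= 2]))
  expect_equal(full$AUC, left$AUC + right$AUC, tolerance = 1e-12)
  # refining the grid by linear interpolation cannot change the maximum
  tf <- seq(0, 4, 0.05)
  fine <- adme_descriptors(tibble::tibble(time_h = tf,
                                          conc = approx(t, y, tf)$y))
  expect_equal(fine$Cmax, full$Cmax)
})

test_that("the excreted metabolic ratio is a conjugate fraction", {
  expect_equal(metab_ratio(c(APAP = 1, APAPG = 0, APAPS = 0)), 0)
  expect_equal(metab_ratio(c(APAP = 1, APAPG = 1, APAPS = 1)), 2 / 3)
  expect_equal(round(metab_ratio(c(APAP = 1, APAPG = 1, APAPS = 1)), 4),
               0.6667)
  expect_equal(metab_ratio(c(APAP = 0, APAPG = 0.3, APAPS = 0.1)), 1)
  expect_error(metab_ratio(c(APAP = 0, APAPG = 0, APAPS = 0)), "undefined")
  # invariant to uniform rescaling
  a <- c(APAP = 0.2, APAPG = 1.1, APAPS = 0.6)
  expect_equal(metab_ratio(a), metab_ratio(7.3 * a))
})

test_that("zonal summary groups four ranks per region", {
  cells <- tidyr::expand_grid(time_h = c(0, 1), cell_id = 0:19,
                              species = c("APAP", "NAPQI_GSH"))
  cells$rank <- cells$cell_id %/% 2L
  cells$side <- cells$cell_id %% 2L
  cells$conc_mmol_per_L <- 1  # identical cells
  zs <- zonal_summary(cells)
  expect_equal(sort(unique(zs$zone)), c("MZ", "PP", "PV"))
  expect_true(all(zs$n_cells == 4))
  expect_true(all(zs$sd_conc == 0))
  expect_true(all(zs$mean_conc == 1))
  expect_error(zonal_summary(cells[cells$rank < 5, ]), "12")
})

test_that("the output vector is consistent with its parts", {
  res <- cached_run8h()
  ref <- generate_reference(model = "pbpk", times = seq(1, 8, 1))
  out <- model_outputs(res, ref = ref)
  expect_equal(length(out), 15)
  expect_equal(unname(out["RMSEsum"]),
               unname(out["RMSEa"] + out["RMSEg"] + out["RMSEs"]))
  # no reference: RMSE entries are NA sentinels, the rest computed
  out2 <- model_outputs(res)
  expect_true(all(is.na(out2[c("RMSEa", "RMSEg", "RMSEs", "RMSEsum")])))
  expect_true(all(!is.na(out2[5:15])))
  # a reference generated from the run itself scores zero error
  self_ref <- tibble::tibble(
    time_h = rep(res$times[res$times > 0], 3),
    compound = rep(c("APAP", "APAPG", "APAPS"),
                   each = sum(res$times > 0)))
  ser <- res$serum
  self_ref$concentration <- ser$conc_mmol_per_L[
    match(paste(self_ref$time_h, self_ref$compound),
          paste(ser$time_h, ser$compound))]
  self_ref$unit <- "mmol_per_L"
  out3 <- model_outputs(res, ref = self_ref)
  expect_equal(unname(out3["RMSEsum"]), 0, tolerance = 1e-12)
})

test_that("a zero dose yields identically zero descriptors", {
  res0 <- run_multiscale(dose_mg_per_kg = 0, duration_h = 0.5)
  out <- model_outputs(res0)
  expect_equal(unname(out[c("CmaxA", "CmaxG", "CmaxS",
                            "AUCA", "AUCG", "AUCS")]), rep(0, 6))
  expect_equal(unname(out["metabRatio"]), 0)  # nothing excreted
})
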