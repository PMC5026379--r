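# Multiscale coupling: scale bridge, conservation, and the coupled
# 8 h scenario.

test_that("the liver scale factor is volume fraction over sinusoid volume", {
  expect_equal(liver_scale_factor(1.71, 0.074, 1.6e-11), 7.909e9,
               tolerance = 1e-4)
  expect_equal(liver_scale_factor(1.71, 0, 1.6e-11), 0)
  expect_equal(liver_scale_factor(2, 0.1, 0.2), 1)
  expect_error(liver_scale_factor(1.71, 0.074, 0), "positive")
  br <- scale_bridge()
  expect_equal(br$S, 1.71 * 0.074 / 1.6e-11, tolerance = 1e-12)
  expect_gt(br$dt_coupling, 0)
})

test_that("an undosed system is a fixed point of the coupling step", {
  st <- multiscale_init(dose_mg_per_kg = 0)
  st2 <- step_multiscale(st, dt = 5)
  expect_equal(sum(abs(st2$pbpk)), 0)
  expect_equal(st2$cells["APAP", ], st$cells["APAP", ])
  expect_equal(unname(st2$cells["GSH", 1]),
               10 - 0.1 * exp(-1e-4 * 5), tolerance = 1e-6)
  res0 <- run_multiscale(dose_mg_per_kg = 0, duration_h = 0.2)
  expect_equal(max(abs(res0$serum$conc_mmol_per_L)), 0)
})

test_that("single steps and the full 8 h course conserve moles", {
  st <- multiscale_init()
  tot0 <- 1400 / 151.16
  for (i in 1:5) st <- step_multiscale(st)
  drift <- abs(hepapk:::.mstate_total(st) - tot0) / tot0
  expect_lt(drift, 1e-9)
  res <- cached_run8h()
  expect_lt(max(res$conservation$rel_error), 1e-9)
})

test_that("with all transfer silenced the sinusoid is a one-second pipe", {
  p <- refsim_params()
  p[grep("^cc3d_k_", names(p))] <- 0
  p["cc3d_Vmax_AT_APAP"] <- 0
  st <- multiscale_init(p, bridge = scale_bridge(p, mode = "explicit"))
  dt <- st$bridge$dt_coupling
  for (i in 1:60) st <- step_multiscale(st, dt)   # one transit time
  expect_equal(sum(st$returned_mmol), 0)          # nothing has exited yet
  expect_gt(sum(st$diverted_mmol), 0)
  expect_equal(sum(st$cells[c("APAP", "APAPG", "APAPS"), ]), 0)
  for (i in 1:120) st <- step_multiscale(st, dt)  # two more transits
  expect_gt(sum(st$returned_mmol), 0)
  expect_equal(sum(st$cells[c("APAP", "APAPG", "APAPS"), ]), 0)
  # everything diverted is either back in the vein or still in the lumen
  resident <- sum(st$sin$p_conc * st$sin$p_vol) * 1e-15 * st$bridge$S
  expect_equal(sum(st$diverted_mmol),
               sum(st$returned_mmol) + resident, tolerance = 1e-12)
})

test_that("metabolite serum peaks lag the parent compound", {
  res <- cached_run8h()
  out <- model_outputs(res)
  expect_lt(out[["TmaxA"]], out[["TmaxG"]])
  expect_lt(out[["TmaxA"]], out[["TmaxS"]])
  # serum APAP rises then falls
  apap <- res$serum$conc_mmol_per_L[res$serum$compound == "APAP"]
  expect_gt(which.max(apap), 2)
  expect_lt(which.max(apap), length(apap))
  expect_lt(apap[length(apap)], max(apap) / 2)
})

test_that("most recovered material is conjugated by eight hours", {
  out <- model_outputs(cached_run8h())
  expect_gt(out[["metabRatio"]], 0.8)
})

test_that("cumulative NAPQI-GSH increases along the lobular axis", {
  res <- cached_run8h()
  cells <- res$cells
  last <- cells[cells$species == "NAPQI_GSH" &
                  cells$time_h == max(cells$time_h) & cells$side == 0, ]
  prof <- last$conc_mmol_per_L[order(last$rank)]
  expect_true(all(diff(prof) >= 0))
  zs <- zonal_summary(cells[cells$species == "NAPQI_GSH", ])
  at_end <- zs[zs$time_h == max(zs$time_h), ]
  m <- setNames(at_end$mean_conc, at_end$zone)
  expect_true(m[["PV"]] >= m[["MZ"]] && m[["MZ"]] >= m[["PP"]])
})

test_that("quasi-steady-state and explicit coupling agree on the outputs", {
  p <- refsim_params()
  rese <- run_multiscale(duration_h = 0.5,
                         bridge = scale_bridge(p, mode = "explicit"),
                         dt_out = 0.1)
  resq <- run_multiscale(duration_h = 0.5,
                         bridge = scale_bridge(p, mode = "qss"),
                         dt_out = 0.1)
  oe <- model_outputs(rese)
  oq <- model_outputs(resq)
  ok <- !is.na(oe) & abs(oe) > 0
  rel <- abs(oq[ok] - oe[ok]) / abs(oe[ok])
  expect_lt(max(rel), 0.01)
  expect_lt(max(rese$conservation$rel_error), 1e-9)
})

test_that("coupled runs are bit-identical on repetition", {
  a <- run_multiscale(duration_h = 0.3)
  b <- run_multiscale(duration_h = 0.3)
  expect_identical(a$serum, b$serum)
  expect_identical(a$cells, b$cells)
})
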