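# Whole-body PBPK compartment model.

# Independent transcription of the whole-body rate table, written directly
# from the published transfer list as a flat sum per compartment.  This is
# the oracle the packaged derivative function is checked against.
oracle_pbpk_deriv <- function(s, b, p) {
  rate <- list(
    gutabs   = p$kGutabs * s["AGutlumen"],
    gut_liv  = b$QGut * s["CGut"] / b$VGut,
    liv_ven  = (b$QLiver + b$QGut) * s["CLiver"] * p$Rb2p /
      (p$Kl2p * p$Fup * b$VLiver),
    liv_met  = p$CLmetab * s["CLiver"] / (p$Kl2p * p$Fup),
    ven_lung = b$QCardiac * s["CVen"] / b$VVen,
    lung_art = b$QCardiac * s["CLung"] / b$VLung,
    art_gut  = b$QGut * s["CArt"] / b$VArt,
    art_liv  = b$QLiver * s["CArt"] / b$VArt,
    art_kid  = b$QKidney * s["CArt"] / b$VArt,
    art_rest = b$QRest * s["CArt"] / b$VArt,
    kid_ven  = b$QKidney * s["CKidney"] * p$Rb2p /
      (p$Kk2p * p$Fup * b$VKidney),
    kid_tub  = p$Qgfr * s["CKidney"] / (p$Kk2p * b$VKidney),
    rest_ven = b$QRest * s["CRest"] * p$Rb2p / (p$Kr2p * p$Fup * b$VRest)
  )
  with(rate, c(
    AGutlumen = -gutabs,
    CGut = gutabs + art_gut - gut_liv,
    CLiver = gut_liv + art_liv - liv_ven - liv_met,
    CVen = liv_ven + kid_ven + rest_ven - ven_lung,
    CLung = ven_lung - lung_art,
    CArt = lung_art - art_gut - art_liv - art_kid - art_rest,
    CKidney = art_kid - kid_ven - kid_tub,
    CRest = art_rest - rest_ven,
    CTubules = kid_tub,
    CMetabolized = liv_met
  ))
}

test_that("derivatives match an independent transcription of the rate table", {
  params <- refsim_params()
  params["pbpk_CLmetab"] <- 7.3
  b <- list(QCardiac = 363.01, QGut = 74.42, QLiver = 19.42,
            QKidney = 80.37, QRest = 188.80, VArt = 1.50, VVen = 3.41,
            VGut = 1.10, VLiver = 1.71, VKidney = 0.29, VLung = 0.51,
            VRest = 33.47)
  cp <- list(kGutabs = 1.5, Fup = 0.8, Kr2p = 1.6, Kk2p = 1, Kl2p = 1,
             Rb2p = 1.09, Qgfr = 0.714, CLmetab = 7.3)
  set.seed(42)
  for (i in 1:100) {
    st <- pbpk_state()
    st[] <- runif(10, 0, 5)
    got <- pbpk_derivatives(st, params)
    want <- oracle_pbpk_deriv(st, b, cp)
    expect_equal(names(got), sub("\\..*$", "", names(want)))
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
    expect_lt(abs(sum(got)), 1e-10 * max(abs(got)))
  }
})

test_that("a gut-lumen bolus absorbs at kGutabs * AGutlumen", {
  st <- pbpk_state(AGutlumen = 1400 / 151.16)  # 1.4 g oral dose in mmol
  d <- pbpk_derivatives(st, refsim_params())
  expect_equal(d[["CGut"]], 1.5 * 1400 / 151.16, tolerance = 1e-12)
  expect_equal(d[["AGutlumen"]], -d[["CGut"]])
  expect_equal(unname(d[setdiff(names(d), c("AGutlumen", "CGut"))]),
               rep(0, 8))
})

test_that("the zero state is a fixed point and negatives are rejected", {
  expect_equal(unname(pbpk_derivatives(pbpk_state(), refsim_params())),
               rep(0, 10))
  st <- pbpk_state(); st["CVen"] <- -0.1
  expect_error(pbpk_derivatives(st, refsim_params()), "negative")
})

test_that("gut uptake variants behave as specified", {
  expect_equal(gut_uptake_rate(2, gut_uptake_model(kGutabs = 1.5)), 3.0)
  zo <- gut_uptake_model("zero_order_lagged", Vmax_gut = 9, Km_gut = 0.05,
                         lag = 0.15)
  expect_equal(gut_uptake_rate(5, zo, t = 0.1), 0)       # 9 min lag
  expect_equal(gut_uptake_rate(5, zo, t = 0.2), 9 * 5 / 5.05)
  # saturation limit: rate -> Vmax when the lumen amount dominates Km
  expect_equal(gut_uptake_rate(1e6, zo, t = 1), 9, tolerance = 1e-4)
})

test_that("dosing places the full molar dose in the gut lumen", {
  sim <- simulate_pbpk(duration_h = 1, times = c(0, 0.5, 1))
  w <- attr(sim, "wide")
  expect_equal(unname(w$APAP[1, "AGutlumen"]), 1400 / 151.16,
               tolerance = 1e-12)
  expect_equal(unname(sum(w$APAP[1, ]) - w$APAP[1, "AGutlumen"]), 0)
  expect_equal(sum(w$APAPG[1, ]), 0)  # metabolite replicates start empty
  expect_equal(sum(w$APAPS[1, ]), 0)
})

test_that("the closed system conserves moles and sinks are monotone", {
  p <- refsim_params()
  p[c("pbpk_Qgfr", "pbpk_QgfrG", "pbpk_QgfrS", "pbpk_CLmetab")] <- 0
  sim <- simulate_pbpk(p, duration_h = 8, times = seq(0, 8, 0.25))
  w <- attr(sim, "wide")
  tot <- rowSums(w$APAP) + rowSums(w$APAPG) + rowSums(w$APAPS)
  expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-6)

  p2 <- refsim_params(); p2["pbpk_CLmetab"] <- 10
  sim2 <- simulate_pbpk(p2, duration_h = 4, times = seq(0, 4, 0.1))
  w2 <- attr(sim2, "wide")
  for (cm in c("APAP", "APAPG", "APAPS")) {
    expect_true(all(diff(w2[[cm]][, "CTubules"]) >= -1e-12))
  }
  expect_true(all(diff(w2$APAP[, "CMetabolized"]) >= -1e-12))
  # metabolite split conserves total moles across the three replicates
  tot2 <- rowSums(w2$APAP) + rowSums(w2$APAPG) + rowSums(w2$APAPS)
  expect_lt(max(abs(tot2 - tot2[1])) / tot2[1], 1e-6)
})

test_that("instantaneous absorption empties the gut and the body then drains", {
  p <- refsim_params()
  p["pbpk_kGutabs"] <- 1000
  sim <- simulate_pbpk(p, duration_h = 2, times = seq(0, 2, 0.005),
                       rtol = 1e-10, atol = 1e-12)
  w <- attr(sim, "wide")
  cgut <- w$APAP[, "CGut"]
  expect_lt(sim$time_h[which.max(cgut)][1] * 60, 5)  # peak within minutes
  # once absorption is over, total body burden declines monotonically
  burden <- rowSums(w$APAP[, c("CGut", "CLiver", "CVen", "CLung", "CArt",
                               "CKidney", "CRest")])
  late <- sim$time_h[!duplicated(sim$time_h)] > 0.25
  expect_true(all(diff(burden[late]) < 1e-10))
})

test_that("serum concentrations convert venous amounts by Rb2p and VVen", {
  p <- refsim_params(); p["pbpk_CLmetab"] <- 10
  sim <- simulate_pbpk(p, duration_h = 2, times = seq(0, 2, 0.1))
  ser <- serum_concentrations(sim)
  w <- attr(sim, "wide")
  expect_equal(ser$conc_mmol_per_L[ser$compound == "APAP"],
               unname(w$APAP[, "CVen"]) / 3.41 / 1.09, tolerance = 1e-12)
  expect_equal(ser$conc_ug_per_mL, ser$conc_mmol_per_L *
                 unname(hepapk_molar_masses()[ser$compound]))
})
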