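# Shared fixtures.  Expensive simulations are computed once per test run
# and cached; everything is generated in code (no stored data).

.fixture_cache <- new.env(parent = emptyenv())

# the standard 8 h coupled reference simulation (20 mg/kg, 70 kg, qss)
cached_run8h <- function() {
  if (is.null(.fixture_cache$run8h)) {
    .fixture_cache$run8h <- run_multiscale(duration_h = 8)
  }
  .fixture_cache$run8h
}

# a 20-individual virtual population over the full 8 h course
cached_population <- function() {
  if (is.null(.fixture_cache$pop)) {
    .fixture_cache$pop <- run_population(n = 20, duration_h = 8,
                                         cv = 0.25, seed = 1)
  }
  .fixture_cache$pop
}

# a small sinusoid state holding a single serum parcel at a given
# position/concentration, for hand-computed transfer oracles
one_parcel_state <- function(conc_apap, x = 50, kind = 2L,
                             params = refsim_params()) {
  st <- build_sinusoid(params)
  st$p_x <- x
  st$p_vol <- if (kind == 1L) params[["cc3d_Vol_RBC"]] else
    params[["cc3d_Vol_SP"]]
  st$p_kind <- kind
  st$p_prov <- 2L
  st$p_birth <- 0
  st$p_id <- 1L
  st$p_conc <- matrix(c(conc_apap, 0, 0), 1, 3,
                      dimnames = list(NULL, c("APAP", "APAPG", "APAPS")))
  st
}
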