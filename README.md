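# hepapk

Liver-centric multiscale pharmacokinetics of acetaminophen (APAP) in R.

Most whole-body pharmacokinetic models treat the liver as a single
well-stirred compartment. That is enough to fit serum curves, but it
erases exactly the thing hepatotoxicity depends on: *where* along the
liver's microcirculation a dose is taken up and metabolised. hepapk is
for modellers who want both views at once. It couples three scales into
one mass-conserving simulation:

1. **Whole body** — a physiologically based pharmacokinetic (PBPK)
   compartment model (gut lumen, gut, liver, venous/arterial blood,
   lung, kidney, rest-of-body, urine), replicated for APAP and its
   glucuronide (APAPG) and sulfate (APAPS) conjugates. Transfer rates
   follow standard flow-limited kinetics, e.g. gut absorption
   `kGutabs · AGutlumen` and venous return
   `Q · C · Rb2p / (K2p · Fup · V)`.
2. **Tissue** — one representative hepatic sinusoid: red-blood-cell and
   serum parcels advected at 200 µm/s past 20 hepatocytes in 10 axial
   ranks, exchanging solute by neighbour-scaled passive transfer, a
   saturable active APAP import
   `Vmax_AT · C / (C + Km_AT · Fup)`, and first-order conjugate export.
   The parcel scheme is fully deterministic: identical inputs give
   bit-identical trajectories.
3. **Cell** — inside each hepatocyte, Michaelis–Menten glucuronidation,
   sulfation and CYP2E1 oxidation to the reactive metabolite NAPQI
   (with CYP2E1 expression zonated 80→100% along the portal→central
   axis), second-order NAPQI+GSH conjugation and first-order
   glutathione synthesis `kGsh · (GSHmax − [GSH])`.

On top of the coupled simulator sit the analysis layers used to study
such models: local +25% log-scale parameter sensitivities
(`J = ∂ln y/∂ln x`), pairwise parameter-interaction coefficients,
log-normal global parameter scans, and virtual populations built from
truncated-normal parameter multipliers (CV 25%). Results come back as
tibbles with `tidy()`/`glance()` methods and `autoplot()` graphics;
SBML export and a small CLI (`inst/cli/hepapk`) are included.

## Worked example

A therapeutic oral dose — 20 mg/kg in a 70 kg adult (1.4 g) — followed
for 8 hours with the quasi-steady-state coupling:

```r
library(hepapk)

res <- run_multiscale(refsim_params(), dose_mg_per_kg = 20,
                      duration_h = 8)
res
#> <hepapk multiscale simulation>
#>   mode: qss | dose: 9.262 mmol APAP | span: 8 h
#>   liver scale S: 7.909e+09 (flow-matched diagnostic: 1.629e+09)
#>   max conservation error: 4.22e-15 relative

round(glance(res)[, c("CmaxA", "TmaxA", "TmaxG", "TmaxS",
                      "metabRatio", "NAPQIGSH_Sum")], 3)
#> # A tibble: 1 × 6
#>   CmaxA TmaxA TmaxG TmaxS metabRatio NAPQIGSH_Sum
#>   <dbl> <dbl> <dbl> <dbl>      <dbl>        <dbl>
#> 1 0.149  1.36  5.27  4.32      0.954        0.077

urinary_fractions(res)
#> # A tibble: 3 × 3
#>   compound amount_mmol fraction
#>   <chr>          <dbl>    <dbl>
#> 1 APAP           0.314   0.0458
#> 2 APAPG          4.00    0.584
#> 3 APAPS          2.54    0.370
```

Reading the numbers: serum APAP peaks at 0.149 mmol/L (≈ 22.6 µg/mL)
1.4 h after dosing, the conjugates peak hours later, and by 8 h 95% of
the excreted material is conjugated — with the urinary split
(≈ 58% glucuronide, 37% sulfate, 5% unchanged) matching the pattern
reported in humans. `NAPQIGSH_Sum` is the liver-scaled total of the
detoxified reactive metabolite, the model's marker of hepatotoxic load;
per-cell traces (`res$cells`, summarised by `zonal_summary()`) show it
rising from periportal to pericentral cells, the zonation signature of
APAP injury. `plot_serum_curves(res)` draws the curves; add a reference
table to overlay data points.

A virtual population and its extremes:

```r
pop <- run_population(n = 20, cv = 0.25, seed = 1)
glance(pop)
find_outliers(pop)$multipliers_low[c("pbpk_bw")]
```

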