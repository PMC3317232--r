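# radonaero

Exposure analysis for radon short-lived decay products (RnDP) coupled to
nanoaerosol size distributions.

Indoor radon (²²²Rn) decays through ²¹⁸Po → ²¹⁴Pb → ²¹⁴Bi → ²¹⁴Po, and it is
these short-lived progeny — not radon itself — that deliver most of the lung
dose. The dose per unit exposure depends strongly on the *unattached
fraction* f<sup>un</sup>: the share of progeny activity riding on free
molecular clusters (< ~5 nm) rather than on the background aerosol.
`radonaero` is for researchers in environmental health physics and aerosol
science who work with the two instrument streams this problem produces —
mobility-spectrometer (SMPS) number size distributions and gross-alpha
progeny records — and need the standard metrics, the kinetics, and a way to
test an analysis end to end without measured data.

## What it computes

**Exposure metrics** (all vectorised, tibble-in/tibble-out):

- equilibrium equivalent concentration
  `EEC = 0.1065 C_Po218 + 0.515 C_Pb214 + 0.379 C_Bi214` (Bq m⁻³)
- equilibrium factor `F = EEC / C_Rn`
- unattached activity fraction `f_un = EEC_un / EEC` and number fraction
  `x_un` (atom-number ratio via `C_A = λ C_N`)
- potential alpha-energy
  `E_α = 3690 C_Po218 + 17830 C_Pb214 + 13120 C_Bi214` (MeV m⁻³)
- exposure in working-level-months (1 WLM = 170 h at 1.3×10⁸ MeV m⁻³) and
  the empirical dose conversion `D_CF = 11.35 + 43 f_un` (mSv WLM⁻¹)
- the classical inverse predictor `f_un = 400 / C_tot`, exposed as a
  diagnostic to compare against measured values

**Kinetics and instruments:**

- closed-form Bateman ingrowth of the ²²²Rn chain (`bateman_ingrowth()`)
- SMPS spectrum summaries: totals, number-weighted geometric-mean diameter,
  sub-cutoff fractions x(<10), x(<20), dN/dln d, and number- vs
  surface-area partitions about a cutoff (`summarize_spectrum()`,
  `surface_partition()`)
- GM/GSD lognormal summary statistics, time-binned Pearson correlations,
  diurnal profiles
- a forward model and linear inversion of three-interval gross-alpha
  counting (`forward_counts()`, `invert_counts()`)
- a Jacobi-type synthetic room (`simulate_room()`): ventilation,
  surface-area-driven attachment, deposition, recoil, scripted household
  events (candle, toaster, cooking, boiling, window), emitting
  instrument-style CSV streams with seeded measurement noise
- an end-to-end pipeline (`analyze_run()`) aligning both streams and
  producing QC, summary and event tables

## Worked example

Derive the metric set from one progeny record (activities in Bq m⁻³):

```r
library(radonaero)
library(dplyr)

rec <- tibble::tibble(rn = 229,
                      po218_un = 5,  pb214_un = 8,  bi214_un = 6,
                      po218_att = 45, pb214_att = 72, bi214_att = 54)
progeny_metrics(rec) %>%
  select(eec, f_equilibrium, f_un, x_un, e_alpha, dcf)
#> # A tibble: 1 × 6
#>     eec f_equilibrium  f_un  x_un e_alpha   dcf
#>   <dbl>         <dbl> <dbl> <dbl>   <dbl> <dbl>
#> 1  69.3         0.302   0.1   0.1 2398100  15.6
```

69.3 Bq m⁻³ of equilibrium-equivalent progeny in 229 Bq m⁻³ of radon gives
an equilibrium factor of 0.30; one tenth of the progeny activity is
unattached, which lifts the dose-conversion factor from its 11.35 intercept
to 15.6 mSv WLM⁻¹.

Simulate a quiescent day in a basement room and summarise it the way an
indoor-air campaign table would:

```r
run <- simulate_room(room_config(seed = 42), duration_h = 24)
rep <- analyze_run(run$smps, run$eqf)
rep$summary %>% select(parameter, min, max, gm, gsd)
#> # A tibble: 9 × 5
#>   parameter            min        max         gm   gsd
#>   <chr>              <dbl>      <dbl>      <dbl> <dbl>
#> 1 c_tot         3610.      5945.      5280.       1.14
#> 2 d_gm_nm         56.7       56.8       56.8      1.00
#> 3 x_lt_10          0.00407    0.00417    0.00411  1.01
#> 4 x_lt_20          0.0588     0.0601     0.0594   1.01
#> 5 c_rn           220.       302.       244.       1.11
#> 6 eec             50.8       65.6       57.4      1.08
#> 7 f_equilibrium    0.168      0.275      0.236    1.14
#> 8 f_un             0.126      0.200      0.167    1.14
#> 9 x_un             0.0920     0.150      0.123    1.15
```

The emitted records scatter around the configured quiescent state: a total
aerosol concentration near 5120 cm⁻³ at d_GM ≈ 57 nm, radon near 229 Bq m⁻³,
and an unattached fraction near the closed-form steady state
`steady_state_fun(room_config())` = 0.160. Event studies script bursts with
`event_script()` and read the before/during/after tables from
`rep$events`; `autoplot()` methods and `plot_spectrum()` give quick ggplot2
views of any of these objects.

A thin CLI over the same functions lives at `inst/cli/radonaero.R`
(`simulate` / `analyze` / `report`; see `inst/cli/config.example`).

## Package layout

- `R/nuclides.R`, `R/bateman.R` — chain constants, conversions, ingrowth
- `R/progeny-metrics.R` — EEC, F, f_un/x_un, E_α, WLM, dose conversion
- `R/size-distribution.R` — grids, spectrum summaries, GM/GSD, correlation
- `R/gross-alpha.R` — counting schedule, forward model, inversion
- `R/room-config.R`, `R/room-sim.R` — synthetic room generator
- `R/pipeline.R`, `R/io.R`, `R/plots.R` — alignment, reports, CSV dialects,
  figures
- `vignettes/radon-progeny-methods.Rmd` — models, assumptions, parameter
  provenance, limitations
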