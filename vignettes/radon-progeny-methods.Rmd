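---
title: "Radon progeny and nanoaerosol exposure analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radon progeny and nanoaerosol exposure analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radonaero)
library(dplyr)
```

## The problem

Radon (^222^Rn) seeps from soil into indoor air, where its short-lived decay
products (RnDP) — ^218^Po, ^214^Pb, ^214^Bi and the effectively instantaneous
^214^Po — deliver most of the lung dose the public receives from natural
radioactivity. The dose per unit exposure depends strongly on the *unattached
fraction* f^un^: the share of progeny activity carried by free molecular
clusters (below roughly 5 nm) rather than by the background aerosol. Newly
formed progeny atoms attach to whatever particle surface the room offers, so
f^un^ is coupled to the number **and size distribution** of the ambient
nanoaerosol. This package provides the full computational chain for studying
that coupling: decay-chain kinetics, the standard exposure metrics, spectrum
summaries from mobility-spectrometer (SMPS) records, a forward/inverse model
of gross-alpha progeny counting, and a synthetic room-kinetics generator that
produces coupled instrument-style data streams for testing every stage
without measured data.

## Decay-chain kinetics

The chain constants live in `rn_nuclides()`: half-lives 3.82 d (^222^Rn),
3.05 min (^218^Po), 26.8 min (^214^Pb), 19.7 min (^214^Bi) and 164 µs
(^214^Po), with λ = ln 2 / t~1/2~. ^214^Po is never integrated as a state
variable: at a 164 µs half-life its activity equals that of ^214^Bi at all
times and it is reported as an alias. The per-atom *potential alpha-energy*
uses the standard evaluated alpha energies 6.00 MeV (^218^Po) and 7.69 MeV
(^214^Po); these are not derivable from half-lives and are adopted from
standard nuclear data. ^214^Pb and ^214^Bi are beta/gamma emitters and carry
only the ^214^Po alpha still owed downstream.

`bateman_ingrowth()` evaluates the closed-form Bateman solution of the
serial chain. Internally every chain quantity is represented as an
exponential sum (a constant plus coefficients on e^−λ~l~t^), which also
yields exact time-integrals for the counting model below. The four decay
constants of this chain are well separated; should a caller ever supply a
chain with two rates within 10^−9^ relative, the closed form is numerically
singular and the routine falls back to stiff ODE integration. Units are
explicit throughout: activities in Bq m^−3^, atom numbers in cm^−3^
(`activity_to_number()` divides by λ and by 10^6^), time grids in seconds
internally with mandatory units at the interface — a bare number is an
error, because a silently misread unit corrupts rate constants by orders of
magnitude.

A worked anchor: 1 Bq m^−3^ of radon corresponds to 1/λ ≈ 476 000 atoms
m^−3^ ≈ 0.476 atoms cm^−3^ with the 3.82 d half-life (0.477 with the
unrounded 3.8235 d — the package keeps the 3-digit half-life convention
consistently and treats the third decimal of the conversion as a rounding
artefact).

## Exposure metrics

For measurable progeny activity concentrations the package implements the
standard set:

* `eec()` — equilibrium equivalent concentration,
  C^A^~RnDP~ = 0.1065 C~Po218~ + 0.515 C~Pb214~ + 0.379 C~Bi214~;
* `equilibrium_factor()` — F = EEC / C~Rn~;
* `potential_alpha_energy()` — E~α~ = 3690 C~Po218~ + 17830 C~Pb214~ +
  13120 C~Bi214~ MeV m^−3^;
* `unattached_fractions()` — the activity fraction f^un^ (ratio of EECs) and
  the number fraction x^un^ (ratio of atom numbers);
* `exposure_wlm()` — working-level-months, 1 WLM = 170 h at
  1.3×10^8^ MeV m^−3^;
* `dose_conversion_empirical()` — D~CF~ = 11.35 + 43 f^un^ mSv WLM^−1^;
* `predicted_fun()` — the classical inverse relation f^un^ = 400 / C~tot~.

One numerical choice deserves its own paragraph. The ^214^Bi coefficient of
the potential alpha-energy formula circulates in print as 113 120, which is
inconsistent by a factor of ~10 with the EEC weights (0.379 × 34 640 ≈
13 129) and with the per-atom arithmetic (7.69 MeV × 1/λ~Bi~ ≈ 13 114 MeV
per Bq). The package defaults to the self-consistent 13 120 — with that
value the three energy coefficients normalised by their sum reproduce the
EEC weights to the printed precision — and keeps the 113 120 variant
selectable (`bi214_coefficient = "printed"`) with a warning, so either
convention can be reproduced deliberately rather than accidentally.

Records with all six activities zero raise an error from
`unattached_fractions()` rather than returning 0: a 0/0 silently mapped to
zero would bias every downstream time average. The `progeny_metrics()` verb
applies the whole set to a table of records and accumulates WLM exposure
using each record's duration (2 h by default, the progeny monitor's
cadence).

## Size-distribution processing

SMPS-style spectra are handled in long form (`timestamp`, `d_nm`, `n_cm3`)
on a 44-channel log-spaced grid (`size_grid()`: 5–350 nm "medium" or
10–1100 nm "long"). Instruments report channel centers only, so bin edges
are reconstructed at geometric midpoints, with half a log-step added outside
the end channels; `dndlnd()` divides by the resulting Δln d.
`summarize_spectrum()` returns the total concentration, the
number-weighted geometric-mean diameter d~GM~ = exp(Σ n~i~ ln d~i~ / Σ n~i~)
(weighted over raw channel counts — weighting over dN/dln d instead would
change d~GM~ only through the end-channel widths, and raw counts are what
the instrument totals), and the sub-cutoff number fractions x(<10), x(<20).
A channel belongs below a cutoff iff its *center* is strictly smaller, so
C(<c) + C(≥c) always equals C~tot~ and no channel is counted twice.

`surface_partition()` splits a spectrum about a cutoff and reports both the
number ratio and the surface-area ratio, with spherical surface π d² per
particle — the minimal shape assumption, stated rather than hidden. The two
ratios deliberately answer different questions: a nucleation burst can hold
twice the number of particles below 10 nm yet several-fold less surface
area than the accumulation mode above it, and it is surface area that
competes for attaching progeny clusters.

`gm_gsd()` computes the lognormal summary convention (GM = exp mean ln x,
GSD = exp sd ln x) plus the arithmetic variant used for sign-changing
quantities such as solar radiation. Zeros and negatives are dropped and
counted, never imputed. `correlate_series()` averages both series onto a
common half-hour bin before computing Pearson's R, and refuses fewer than
three pairs or zero variance. `diurnal_profile()` aggregates by hour of day
and requires at least 24 h of coverage.

## Gross-alpha counting and inversion

The progeny monitor pumps air for 6 min at 2.4 dm³ min^−1^ through a
screen/filter pair separating unattached (<5 nm, treated as a sharp cut)
from attached progeny, each deposit sitting on its own 150 mm² detector;
gross alpha counts are accumulated over three consecutive intervals within
110 min after pumping. The reference estimator used by the instrument's
firmware is not public, so the package implements its own, clearly labelled
model: atoms deposit at a constant rate during the pump (decaying and
ingrowing as they sit — sampling-period ingrowth is modelled, not ignored),
then decay freely; expected counts integrate λ~Po218~N~Po218~ +
λ~Po214~N~Po214~ over each interval, all in closed form via the
exponential-sum machinery. Because the map from the three airborne
activities to expected counts is exactly linear, `invert_counts()` solves
the 3×3 system directly and propagates Poisson count variances through the
inverse map for 1-σ uncertainties; negative solutions under noise are
clipped to zero and flagged.

Default interval boundaries (0–30, 30–70, 70–110 min) are a design choice,
not an instrument constant: the early interval is ^218^Po-dominated, the
late one ^214^Po-dominated, which keeps the design matrix well conditioned
(κ ≈ 76). Clustering all intervals late makes the columns nearly collinear;
the fit object reports the condition number, and a numerically singular
schedule raises an error instead of returning garbage. The default counting
efficiency 0.25 cancels in round trips and is configurable.

## The synthetic room

`simulate_room()` integrates a Jacobi-type linear balance for each progeny
nuclide, split into unattached and attached pools (atoms cm^−3^):

* production: radon decay feeds unattached ^218^Po at C~Rn~/10^6^ atoms
  cm^−3^ s^−1^; decay of an unattached parent stays unattached; decay of
  attached ^218^Po sends the new ^214^Pb back to the unattached pool with
  recoil probability 0.5;
* removal: radioactive decay, ventilation λ~v~, deposition (λ~d~^un^ = 20
  h^−1^ for clusters, λ~d~^att^ = 0.2 h^−1^ for carrier particles), and
  attachment at rate X = β S~tot~.

Attachment is driven by the *total aerosol surface area* S~tot~ (nm²
cm^−3^) through a single coefficient β — the minimal model in which surface
area, not number concentration, controls f^un^; a size-resolved attachment
kernel is the natural extension point. The aerosol spectrum itself relaxes
toward a quiescent lognormal baseline (restoration rate 2 h^−1^, matching
the observed ~1 h recovery after cooking), exchanges with an outdoor
boundary spectrum by ventilation, and receives scripted event injections
(`event_script()`): candle 1.32×10^6^ cm^−3^ at 8 nm, toaster 3×10^5^
cm^−3^, cooking 5×10^4^ cm^−3^, boiling a 25/85 nm bimodal pair, window
opening a ventilation switch from 0.3 to 3 h^−1^.

Parameter provenance, stated once: the quiescent radon level (229 Bq m^−3^),
the baseline total concentration (5120 cm^−3^) and the stationary d~GM~
(57 nm) are the observed indoor geometric means; event magnitudes are the
observed peaks; the ventilation, deposition and recoil rates are standard
indoor-air values since none are measured in this setting; and β = 1.17×10^−7^
h^−1^ per nm² cm^−3^ is calibrated once, through the closed-form steady
state, so that the quiescent baseline yields f^un^ = 0.16 — the observed
geometric mean, inside the observed 0.09–0.28 range. The spectral width of
the baseline (GSD 1.9) is a typical indoor accumulation-mode value; the
tabulated 1.50 is the *temporal* spread of the total concentration, which
the generator reproduces through its per-record measurement noise instead.

Two deliberate structural choices:

* **The configured baseline is the stationary spectrum.** The relaxation
  target is internally offset so that baseline restoration and
  closed-window outdoor exchange balance exactly at the configured
  spectrum. Without this, the advertised quiescent state would drift with
  every change of the outdoor spectrum, and the closed-form
  `steady_state_fun()` would disagree with the simulator by construction
  rather than by error.
* **Deterministic kinetics, seeded measurement noise.** The ODE system is
  integrated with fixed-step RK4 (dt ≤ 60 s; the stiffest retained rate,
  ^218^Po's ~37 h^−1^ total loss, gives λ·dt ≈ 0.6 at the default 30 s,
  comfortably inside RK4's stability region; a negative state aborts with
  advice to reduce dt). Only the emitted records are random: a common
  per-record lognormal factor (GSD 1.5) plus small per-channel noise (GSD
  1.05) on spectra, and per-activity noise (GSD 1.15) on progeny records,
  all under one seed. Two runs with the same configuration and seed are
  bit-identical; changing only the seed changes the records but not the
  true state.

`steady_state_fun()` solves the same balance analytically (the system is
lower-triangular in chain order, so the steady state is a short cascade of
closed-form ratios) and is the simulator's cross-check: a 48 h run started
from progeny-free air lands on the closed form within 1%. With β = 0 the
entire chain stays unattached and f^un^ = 1 exactly; f^un^ decreases
strictly in S~tot~, and two spectra with equal number but different surface
yield different f^un^. After a step increase in surface area (a candle),
f^un^ traverses half its change only after tens of minutes — the attached
pools fill on the progeny mean-lives, much slower than the aerosol itself
equilibrates — which is why a 2-h progeny cadence blurs fast aerosol events
and why instantaneous inverse relations like 400/C~tot~ fail in such data.

### What the generator does and does not emulate

It reproduces the statistical structure the analysis pipeline assumes:
lognormal quiescent baselines at the observed GM/GSD, the two instrument
cadences (4 min / 2 h), multiplicative measurement noise, scripted event
bursts of the observed magnitudes and mode diameters, surface-area-
controlled attachment, and the delayed f^un^ response. It does **not**
model coagulation, condensational growth (2–3 nm h^−1^ would matter over
hours), nucleation chemistry, humidity-dependent neutralisation, spatial
inhomogeneity, or diurnal forcing of the outdoor boundary. Passing tests on
synthetic runs therefore demonstrate the pipeline's correctness and
internal consistency — not that the room model captures every process
shaping real indoor aerosol.

## Pipeline

`analyze_run()` aligns the 4-min spectrum stream onto the 2-h progeny bins
(half-open `[start, end)`, labelled by interval start), and produces the QC
table (records, cadence, gaps, zero/negative counts — every input record is
either used or accounted for), the aligned metric series, a GM/GSD summary
over caller-specified quiescent windows for the nine standard indoor
parameters, before/during/after event tables (`segment_events()`, 2 h
flanks), and the measured-vs-predicted f^un^ comparison with residuals.
Quiescent windows are explicit annotations: the package does not attempt to
infer "undisturbed" periods from the data, because that judgement belongs
to the observer's activity diary. Report generation is pure — identical
inputs give byte-identical tables. Timestamps are timezone-naive local
clock time (ISO-8601) or plain seconds.

A thin command-line wrapper (`inst/cli/radonaero.R`, subcommands
`simulate` / `analyze` / `report`; exit codes 0/2/3 for ok/config/data
errors) exists for shell use; the R functions are the primary interface.

## Problem sizes and determinism of the checks

The package's own validation uses: 48 h simulated runs at 30–60 s steps for
steady-state and statistics checks, 10^4^ lognormal draws for GM/GSD
parameter recovery (recovery within 2%), 500 Poisson replicates for the
counting round trip (mean recovery within 5% at ≥10³ counts per interval),
and ODE-oracle comparisons at 10^−6^ relative on multi-hour grids. All
random checks run under fixed seeds.

## Known limitations

* The counting model is a documented stand-in for the instrument's
  unpublished estimator; absolute efficiencies and true interval boundaries
  may differ.
* The attachment coefficient is a single scalar; real attachment kernels
  are size-dependent, which matters when comparing spectra of equal surface
  but very different shape.
* The screen's 5-nm separation is treated as sharp; real penetration curves
  are gradual.
* The empirical dose conversion is a linear fit; the package exposes the
  conventional 4 / 5 mSv WLM^−1^ values as constants and deliberately does
  not implement dosimetric lung-model internals.
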