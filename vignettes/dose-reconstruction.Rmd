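---
title: "Reconstructing preconception gonadal doses with two-dimensional Monte Carlo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing preconception gonadal doses with two-dimensional Monte Carlo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gonadose)
```

## The problem

Studies of germline effects in children of Chornobyl cleanup workers
(liquidators) and Pripyat evacuees need the absorbed dose to the parents'
gonads — testes for fathers, ovaries for mothers — accumulated over an
*individually defined preconception window*.  `gonadose` reconstructs these
doses from questionnaire-style exposure histories for four pathways:

1. **Cleanup mission** — external irradiation at the Chornobyl site and in
   the 30-km zone, by the time-and-motion (RADRUE-style) method;
2. **Residence in Pripyat** — external irradiation from the passing
   radioactive cloud and ground deposits until evacuation;
3. **Residential external** — ground-shine from the multi-radionuclide
   fallout in settlements other than Pripyat;
4. **Residential ingestion** — intake of ^134^Cs and ^137^Cs with locally
   produced foodstuffs.

Every dose is integrated from the accident origin (1986-04-26, treated as
the start of that day) to two endpoints: 51 and 38 weeks before the child's
date of birth.  DOB-38 captures the whole preconception period; DOB-51
marks three months earlier, bracketing the window during which paternal
spermatids could be exposed.  Children are eligible if born at least 46
weeks (322 days) after the accident.

## Windowing conventions

All dates are whole days.  The window is `[1986-04-26, DOB - 7*w)` with an
*exclusive* end: exposure on the end date is not counted.  The sources this
model follows do not state inclusivity; exclusivity was chosen because it
makes the DOB-51 to DOB-38 difference exactly 91 days for every child.  If
`DOB - 51 weeks` precedes the accident the window has zero length and all
DOB-51 doses are zero (this happens for the earliest eligible children; the
package clips rather than erroring).  Mission doses additionally truncate
at the end of the parent's cleanup activity and at 1990-12-31, the last
legal date of cleanup activities — `mission_cutoff()` takes the earliest of
the three.

## External dose models

The mission and Pripyat engines share one kernel,

$$D = C_g \sum_{i}\sum_{j} \mathrm{AKR}(t_{ij})\,\Delta t_{ij}\,\mathrm{LF}_j ,$$

the product of the air kerma rate at the location and date of each activity
(mGy/h), the activity duration (h) and the location factor (the ratio of
the kerma rate at the exposure point to that over undisturbed open ground,
encoding shielding), converted from air kerma to gonadal absorbed dose by
the sex-specific coefficient $C_g$ = 0.710 (male) / 0.586 (female) for
isotropic 0.3 MeV photons.  Air-kerma-rate grids are supplied as explicit
(location, date) tables and interpolated piecewise-constant in time (the
interpolation scheme of the historical exposure-rate databases is not
public; a step function is the least-assuming choice and is exact for the
monthly grids the synthetic generator emits).

Pripyat occupancy is an hour-by-hour timeline.  Indoor location factors for
apartments are given as daytime / sleeping / daily-averaged triples; the
daily average assumes 8 h sleeping,
`((24-8)*day + 8*night)/24` (`daily_average_lf()`).  For the 1st and 5th
floors of a five-storey building this reproduces the reference daily values
0.049 and 0.025 to two significant figures.  The tabulated 3rd-floor daily
value (0.0322) is *not* reproduced by this weighting (it computes to
0.0317); the package implements the stated 8-h weighting and leaves the
discrepancy visible rather than fitting an ad-hoc rule.

## Residential external dose

For residence in a contaminated settlement,

$$D = BF_m\, IV \sum_i DC_i \int_{t_1}^{t_2}
\sigma_{137}\,R_i\,e^{-\lambda_i t}\,p(t)\,dt ,$$

with $\sigma_{137}$ the settlement's ^137^Cs deposition density (kBq/m²),
$R_i$ the deposition-activity ratio of nuclide $i$ to ^137^Cs at the
accident date, $DC_i$ the sex-specific dose-rate coefficient (mGy/day per
kBq/m²), $BF_m$ the behaviour factor (occupancy-weighted shielding of the
dwelling type), $IV$ an individual outdoor-time variability factor, and
$p(t) = p_1 e^{-\lambda_1 t} + (1-p_1) e^{-\lambda_2 t}$ the
soil-migration attenuation function, applied to the long-lived ^134^Cs and
^137^Cs terms only (central values $p_1 = 0.4$,
$\lambda_1 = 1.27\times10^{-3}$/day, $\lambda_2 = 3.8\times10^{-5}$/day).

The inventory covers 19 gamma emitters.  The decay products ^95^Nb,
^132^I and ^140^La use the Bateman solution in activity units, with both an
initial daughter deposit and ingrowth from the parent deposit; the daughter
dose-rate coefficient is applied to the *total* daughter areal activity
(the normalization *per parent deposit* vs *per daughter deposit* is not
printed anywhere authoritative; total areal activity is the physically
meaningful choice).  Half-lives are embedded from standard decay data.
Deposition ratios and dose-rate coefficients come from non-public
databases in the original studies; the package ships *representative*
defaults in a single editable table (`nuclide_table()`), and every
correctness test in the package (closed-form integrals, Bateman vs ODE,
linearity) is independent of their absolute magnitudes.

Integration is analytic: every integrand is a finite sum of exponentials,
so the exact sum-of-exponential-integrals is evaluated directly.  An
adaptive-quadrature path (relative tolerance $10^{-10}$) exists purely as a
cross-check and agrees with the closed form to better than $10^{-6}$
relative in the test suite.

## Ingestion dose

$$D = \sigma_{137} \sum_{k \in \{134,137\}} DF_k \int_{t_1}^{t_2} I_k(t)\,dt,
\qquad I_k(t) = \sum_f \mathrm{rate}_f\, CF_f\, c_{\mathrm{milk},k}(t),$$

where $DF_k$ is the gonadal dose per unit ingested activity and $CF_f$
converts the radiocesium concentration in foodstuff $f$ to the private-milk
concentration (shop milk 0.9–1, milk products 0.5–0.9, meat 0.8–1,
potatoes/root vegetables 0.12–0.24, mushrooms 5–15).  Two intake periods
are modelled.  Until 1986-07-31, vegetation is contaminated by direct
surface deposition and only milk, milk products and meat contribute; from
1986-08-01 root uptake dominates, potatoes, root vegetables and mushrooms
are added, and the milk concentration scales with the settlement's
soil-to-milk transfer factor.  The time shapes of the two normalized
concentration curves are cited to external intake studies and not printed;
the package accepts tabulated daily curves and ships synthetic defaults — a
14-day effective half-time exponential for the surface period, a slowly
declining (550-day half-time) curve for the root-uptake period.  All dose
identities are linear in these curves, so no correctness result depends on
their shape.  ^134^Cs intake is derived from the ^137^Cs intake via the
initial deposition activity ratio (default 0.5, coupled deterministically
to the ^137^Cs deposition) and the decay-constant difference.

Curves are daily step functions and the integral is the exact step sum
(with proportional handling of fractional end days), so splitting an
integral at the period boundary — or anywhere else — reproduces the whole
to machine precision.  Whether non-milk foods follow the milk curve with a
lag is not stated; conversion factors are applied synchronously.  Doses
for urban residents derived directly from whole-body counting are out of
computational scope; such records can carry a directly supplied dose.

## Uncertainty model

Parameter uncertainties follow four families — `U(min,max)`,
`TR(min,mode,max)`, `TN(AM,SD,min,max)`, `TLN(GM,GSD,min,max)` — sampled by
inverse CDF on the truncated quantile range.  Inverse-CDF (rather than
rejection) sampling consumes a deterministic number of uniforms per draw,
which is what makes hierarchical substreams (`substream_seed()`,
`with_substream()`) reproducible: every (subject, pathway, set) key yields
the same sequence on every run, and a full cohort reconstruction is
bit-identical under a fixed master seed.

Two conventions deserve attention:

* **AM-to-GM conversion.**  For a lognormal with arithmetic mean AM and
  geometric SD, the standard relation is
  $GM = AM\,e^{-(\ln GSD)^2/2}$.  Some parameter tables in this literature
  print the variant without the ½ factor; `gm_from_am_gsd()` defaults to
  the standard relation and exposes the printed variant behind a flag,
  recorded in the run manifest.
* **Truncation shrinkage.**  A lognormal truncated at $GM \cdot GSD^{\pm2}$
  (i.e. ±2 log-SD) has log-SD $0.8796\,\ln GSD$, so the realized GSD of
  draws is $GSD^{0.8796}$ — 1.68 for a nominal 1.8.  The package reports
  empirical GSDs of what was actually sampled; tests assert the analytically
  correct truncated value, and parameter-recovery checks that target the
  nominal GSD use wide truncation bounds where lognormal moments apply.

The empirical GSD itself is `exp` of the *population* (1/n) standard
deviation of log realizations; zero doses (structurally unexposed
pathways, zero-length windows) carry no GSD.

**Mission/Pripyat: plain Monte Carlo.**  All parameters carry unshared
(subject-dependent) errors — the shared component of cleanup-site exposure
is known from the RADRUE validation literature to contribute under 1% of
dose — so each of the realizations (study-scale default 10 000) redraws
every duration, air kerma rate, location factor and $C_g$ independently.
$C_g$ is drawn once per realization: it is a property of the person's
anatomy, not of the location.

**Residential pathways: two-dimensional Monte Carlo.**  The outer loop
draws one value per *shared* parameter — deposition density and
soil-to-milk transfer per settlement, deposition ratios per area (default
scoping key: oblast), behaviour factors, attenuation parameters, conversion
factors and intake-curve scales globally — and every subject resolving the
same scope key sees the identical realized value within that set.  The
inner step draws the *unshared* parameters (outdoor-time variability,
consumption rates, ingestion dose factors) per subject.  The study-scale
default is 1000 sets.  Correlated deposition ratios (e.g. ^95^Nb with
^95^Zr at r = 0.95) are coupled through a Gaussian copula with the stated
r and inverse-transformed to their triangular marginals; the copula itself
is a package choice (the sources state r but no joint law), and Gaussian
is the minimal one.  The r = 1.0 coupling of ^134^Cs/^136^Cs to the
^137^Cs deposition is implemented as a deterministic fixed ratio.

**Common random numbers across windows.**  Both windows are evaluated from
the same substream, with itinerary entries sorted by date so a shorter
cutoff consumes a prefix of the draw sequence.  Consequently the DOB-38
dose dominates the DOB-51 dose *realization by realization*, and the
91-day nesting holds at the level of central estimates too.  A simulation
that redraws per window would instead show small Monte Carlo
fluctuations between the two window means; we prefer the stronger
invariant and note the difference.

The central estimate of every pathway dose is the arithmetic mean of its
realizations; the total parental dose is the sum of the pathway means.

## The synthetic cohort generator

`generate_cohort()` emulates the *inputs* the questionnaires would
provide: category counts (71/51/59/51/66 across A–E), one-to-three
children per family (242/52/4 weighting), births over 1987-03-14 to
2005-07-15 with 40% born by 1990, mission itineraries (fathers ~30 days
median, mothers ~10, category E starting within days of the accident on
high-rate fields), Pripyat timelines evacuated 30–40 h after the accident,
gap-free residence histories with ~23% of parents in more than one
settlement, deposition densities spanning the per-region ranges (Kyiv
Oblast 3–6040 kBq/m², Gomel up to 18 530), and diet records.  Dose-scale
targeting is *input-side only*: configured median doses are converted to
air-kerma-rate base magnitudes through the central product model
(including a factor 0.6 for typical fallout decay at mission dates) —
doses are never back-solved.  Two optional extreme trios exercise tail
behaviour (an emergency worker at the damaged unit; a Pripyat mother who
walked near the plant).

What the generator does **not** emulate: recall error and interview
heterogeneity, within-mission spatial correlation of air-kerma-rate errors
(each entry's rate is drawn independently, so generated mission-dose GSDs
are smaller than grids with correlated errors would produce), seasonality
of occupancy, demographic structure, or relocation behaviour.  Passing
tests on synthetic cohorts therefore demonstrates the *mechanics* of the
dose models and the shared/unshared uncertainty propagation — not the
realism of any particular dose distribution.

## Numerical choices and degenerate inputs

* Truncated samplers error on zero-mass truncation intervals; `GSD = 1` or
  `SD = 0` degrade gracefully to point masses.
* Dose-interval bins are left-closed (`[3, 10)` is labelled "3.0-9.99"),
  matching the printed labels; `1000+` is unbounded.  Percentages round
  half-up to one decimal; medians use the lower-interpolation convention
  for even n.
* Empty itineraries, zero-length windows, zero deposition and empty
  intersections all return exactly 0; a missing diet record is zero
  consumption with a warning.
* Residence intervals are end-exclusive, so gap-free histories may share
  boundary dates without double counting.
* A parent who is both a Pripyat resident and a cleanup worker has the
  residence dose folded into the mission pathway (the two components are
  operationally inseparable in the interview data this mirrors).

## Problem sizes

The test suite and the bundled acceptance script run the full pipeline at
50 trios with 500 mission realizations and 100 shared-parameter sets —
sizes chosen so a complete reconstruction plus its repeat-run
bit-identity check finishes in about a minute and a half on one core while
still exercising every code path at cohort scale.  Study-scale runs
(10 000 / 1000) use the same code with different arguments.

## Known limitations

* Deposition ratios, dose-rate coefficients, ingestion dose factors and
  intake-curve shapes are representative defaults, not measured values;
  absolute residential doses should be interpreted only after substituting
  measured tables.
* The air-kerma-rate error model treats each itinerary entry independently;
  mission-dose GSDs are accordingly conservative (small).
* No inhalation pathway (a minor contributor to gonadal dose), no
  ground-shine spectral modelling, no snow-cover seasonality.
* Variance decomposition into shared vs unshared components is not
  implemented (the 2D structure would support it).
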