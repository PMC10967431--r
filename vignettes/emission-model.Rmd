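---
title: "A mechanistic model of methane and ammonia emissions from fattening-pig houses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mechanistic model of methane and ammonia emissions from fattening-pig houses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigemit)
```

## What the model does

`pigemit` simulates, at daily resolution, the chain that links what a
fattening pig eats to what its house emits: growth and intake curves
determine excretion; excretion loads the manure pit; the pit's contents,
temperature and surface area drive ammonia volatilization and
methanogenesis; removal schedules interrupt both. Two manure-management
systems are built in as presets: **LS** (long storage: a deep pit under
the slatted floor, emptied roughly every 45 days) and **SS** (short
storage: a shallow sloped-wall pit flushed daily, plus a front water
channel with partial dilution). The purpose of the model is comparative:
to quantify how much manure-management design changes CH~4~ and NH~3~
emission per pig place, and to validate such predictions against
measured concentration/ventilation data.

## Growth, feed and water: Gompertz curves

Body weight and cumulative feed and water intake all follow the
four-parameter Gompertz curve

$$y(t) = A + M\,e^{-e^{-B\,(t - t^*)}}$$

with $t$ the age in days, $M$ the asymptote, $B$ the rate and $t^*$ the
age of maximal growth. The shipped defaults (weight: $M = 164.2$ kg,
$B = 0.0146$ d$^{-1}$, $t^* = 110.4$ d; feed: $A = -41.9$, $M = 608$ kg,
$B = 0.0111$, $t^* = 154.7$; water: $A = -149$, $M = 1432$ L,
$B = 0.0103$, $t^* = 147.4$) are regression estimates for Dutch
fattening pigs. Asymptotes are treated as free: `fit_endpoints()` solves
for the $M$ and entry age $t_0$ that pass the weight curve through the
scenario's start and end weights (the entry age has a closed-form
inverse, so only $M$ needs a bracketed root search over
$[1.0001\,W_{end},\,10\,W_{end}]$), and `fit_total()` rescales the feed
and water asymptotes so the period increment equals the recorded totals
— a closed form, because the increment is linear in $M$. Daily values
are first differences of the cumulative curves; since differences cancel
the offset, the negative feed/water offsets never produce negative daily
intakes in practice, but a zero clamp guards the degenerate corner.

One average pig is simulated and multiplied by the headcount; there is
no between-animal variation (a deliberate non-goal).

## Excretion mass balances

Nitrogen: intake is crude protein / 6.25; faecal N is the undigested
share $(1 - d_{CP})$; retention is body protein deposition (default
0.16 kg protein per kg gain, protein 16% N) capped at digestible N;
urinary N closes the balance. The balance identity
$N_{in} = N_{faecal} + N_{retained} + N_{urinary}$ is enforced pre-clamp
and tested on random inputs.

Solids: excreted dry matter combines undigested feed organic matter,
non-retained ash, and urinary solids parameterised as 2.14 kg per kg
urinary N (urea stoichiometry, CO(NH$_2$)$_2$/2N = 60/28). Excreted
organic matter (OM$_{exc}$ = volatile solids, VS) is the faecal OM plus
the organic share of urinary solids — default 0.85, reflecting
urea-dominated urinary dry matter. This VS stream is the single source
of truth consumed by the methane module.

Water: pit water = drinking water + feed moisture + metabolic water
(0.4 L per kg DM digested) − body water retention (0.70 L/kg gain) −
respiratory/evaporative loss (default 25% of drinking water) − floor
evaporation. Floor evaporation uses a reference coefficient of
0.05 L m$^{-2}$ h$^{-1}$ at 20 °C / 60% RH scaled by the saturation
deficit of the room air (Magnus form), applied to the fouled solid-floor
area. Slurry mass is dry matter plus water minus gas losses during
hydrolysis (default: 5% of OM$_{exc}$ as biogas plus 0.733 kg per kg
urea-N as net CO$_2$ loss); all of these coefficients are exposed
because the original retention and evaporation regressions are not
public. With the default diet (88% DM, 16.5% CP, 5.5% ash, OM
digestibility 0.85) the simulated slurry runs at about 70 g VS per kg —
the right range for fattening-pig slurry and within 2% of the published
model's 68.5 g/kg.

The urea share of urinary N (default 0.75) is assumed fully hydrolysed
to TAN (total ammoniacal nitrogen) within the day — urease is in excess
on fouled floors and in the pit.

## Pit geometry, loading, removal

Each channel is a trapezoidal prism: length, top width, depth, and 0–2
long walls sloping at $\theta$ degrees from horizontal. Volume at height
$h$ is $V(h) = L(w_b h + n h^2 / (2\tan\theta))$; `height_from_volume()`
inverts this analytically (quadratic positive root), and the inversion
is verified against a bisection oracle on 1000 random geometries to
10$^{-9}$. The emitting surface is the plan area for straight walls and
$L(w_b + n h/\tan\theta)$ for sloped walls — the physical mechanism by
which the SS design cuts pit NH~3~: at low fill the sloped channel
exposes only a narrow strip of liquid.

The pit is treated as well mixed: removals take volume, VS and TAN out
proportionally (conservation is asserted exactly), leaving a configured
residual height (default 0.05 m for LS — the emptying is never perfectly
clean; 0.02 m for the daily-flushed SS back channel). The SS front water
channel receives dilution water (default 200 L/d) plus a plan-area share
of the slurry, and is emptied once per growing period *or* whenever an
inflow would overflow it; the overflow-triggered emptying keeps the
simulation well posed for any dilution rate and mirrors the irregular
farm practice for that channel. Simulations start with the residual
height of aged manure at the long-run slurry composition.

## Indoor climate

Mechanically ventilated rooms hold a set point (default 20 °C) and track
the outside temperature with a +3 °C ventilation offset above it. Manure
temperature is a linear map of room temperature (default
$T_m = 0.88\,T_{room}$, placing manure a few degrees below room air);
room RH is 85% of outside RH clamped to [30, 90]%; air velocity over
emitting surfaces is constant at 0.15 m/s. These are deliberately simple
configurable parameterisations: the empirical relations they stand for
were calibrated on unpublished farm data, and the model's sensitivity to
them is exactly why they are exposed in the scenario config. Driven by
Dutch-like weather the defaults give annual mean room temperatures of
20–21 °C and manure temperatures near 18 °C, consistent with the 19–23 °C
range reported for such rooms.

## Ammonia

Each emitting surface (pit liquid, floor urine puddles) contributes

$$E_{NH_3} = k \, A \, f \, [TAN] / H$$

in mol/s, with $k = 2\times10^{-3} (v/0.15)^{0.8} (T/293.15)$ m/s the
mass-transfer coefficient, $f = (1 + 10^{pK_a(T) - pH})^{-1}$ the
unionized ammonia fraction ($pK_a = 0.09018 + 2729.92/T$), and
$H = 1431 \cdot 1.053^{(293-T)}$ the dimensionless liquid/gas Henry
constant. Pit TAN accumulates from excretion and is depleted by the
emitted N; its concentration is TAN mass / 0.014 / volume. Surface pH is
bulk pH + 0.5 (the surface is CO$_2$-depleted relative to the bulk; the
offset stands in for an unpublished laboratory regression and is
flagged as such in the config). Floor puddles take the urine TAN
concentration (urinary urea-N over the urine volume, default 55% of
drinking water) with the same surface-pH map; fouled fractions default
to 0.10 of the solid floor and 0.05 of each slatted element, and fouled
concrete slats are assumed to emit like the solid floor per m$^2$.
Emission from soiled pigs and pen partitions is folded into the
solid-floor term rather than parameterised separately.

## Methane

The specific methanogenesis rate follows an Arrhenius law on volatile
solids,

$$F_T = (VS_d + 0.01\,VS_{nd})\, e^{\ln A - E_a/(RT)}$$

in g CH~4~ kg VS$^{-1}$ h$^{-1}$, with defaults $VS_d = 0.83$,
$\ln A = 31.3$, $E_a = 81.0$ kJ/mol ($\approx 0.12$ g kg$^{-1}$ h$^{-1}$
at 20 °C). Daily pit emission is the rate at the *manure* temperature
(chosen over air temperature because storage temperature is what drives
methanogenesis) times the stored VS times 24 h — emission is linear in
the stored manure. The degradable pool loses the emitted carbon
(12/16 of the CH~4~ mass; a flag, default on, because the effect is
small over 45-day storages). Enteric methane adds a constant
1.5 kg pig$^{-1}$ yr$^{-1}$. Under daily flushing the pit term nearly
vanishes and the total approaches this enteric floor — the central
mitigation mechanism of the short-storage design.

## Daily loop and annualization

The fixed order within each simulated day is: climate → growth/intake →
excretion → channel loading (and dilution water) → NH~3~ flux (with TAN
depletion) → CH~4~ flux (with pool depletion) → scheduled removal at end
of day. A year comprises four growing periods starting 8 Oct, 21 Jan,
27 Apr and 27 Jul; each runs for `period_days` (default 90) or until
three days before the next start, whichever is shorter, and the pit
state carries across the vacancy days (stored manure keeps emitting; no
excretion, no enteric CH~4~). Annualization pools the daily series:
mean daily emission × 365 / animal places × (1 − vacancy), with a 3%
vacancy factor. Pooling daily data (rather than averaging four
period-level means) was an open choice; pooling weights each housed day
equally and matches how the daily outputs are produced.

Mass closure — volume, VS and TAN each satisfying
inflow = removed + in store + gas losses — holds to machine precision
over a full year and is asserted at 10$^{-6}$ relative in the tests.

## The weather generator

`weather_fixture()` emulates a Dutch annual cycle: temperature
$10.5 + 7\sin(2\pi(d - 105)/365) + \mathcal{N}(0, 3^2)$ °C (peak
mid-July), RH $80 - 8\sin(\cdot) + \mathcal{N}(0, 5^2)$% clamped to
[30, 100]. It reproduces the seasonal contrast that makes summer growing
periods emit more CH~4~, and it is fully seed-deterministic. What it
does *not* emulate: weather fronts with multi-day autocorrelation,
diurnal cycles (the model is daily), or the actual 2020–2021 series the
published measurements experienced. Consequently the simulations here
reproduce the *structure* of the measured results — system contrasts,
source splits, seasonality, sawtooth removal dynamics — not the exact
published emission levels, which also depended on unpublished farm
records (actual feed deliveries, measured pH, fouling observations,
irregular emptyings).

## Scenario presets and their feed inputs

The LS and SS presets carry the two experimental rooms' dimensions
verbatim (54/78 places, growth ranges 23.6–115.6 and 22.6–114.0 kg, six
pens of 5.10 × 1.88 / 5.22 × 2.59 m, 60/40 vs 38/62% slatted/solid
floor, pit depth 1.20/0.50 m, wall slope 90°/45°, removal interval
45/1 d). Feed and water totals per pig are not part of the room
description; the presets use 240 kg feed and 560 L water over 90 days —
a feed conversion near 2.6 against the ~92 kg gain, typical for Dutch
fattening — and the measured slurry pH enters as an input (default 7.0)
because the model deliberately does not predict pH.

Problem sizes used throughout the examples and checks — 365-day years,
90-day periods, 1000-draw property sweeps — keep a full paired-system
comparison under a few seconds.

## Known limitations

* The pit is depth-uniform; temperature stratification and VS
  degradability ageing during storage are not modelled.
* pH is an input, not a prediction; the bulk-to-surface offset is a
  placeholder constant.
* Air velocity over surfaces is constant; no air-flow modelling.
* Hourly urination dynamics are out of scope; floor puddles are a
  daily-average pool.
* Outside-storage emissions after removal are not followed.
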