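---
title: "Threshold-based green-on-brown detection: model, simulator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-based green-on-brown detection: model, simulator and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greenonbrown)
```

## The detection model

A single-pixel multispectral sensor looks straight down from height $h$
and reports, every cycle $T$ (default 2 s), one 18-band relative
responsivity vector over 410–940 nm. Its field of view is a cone with
half-angle $\theta = 20.5^\circ$, so the reading is the average spectrum
of a ground disc of radius $r = h\tan\theta$. Responsivity is treated as
an arbitrary-scale nonnegative quantity: nothing in the method depends on
absolute radiometry, which is why the two ratio-of-sums indices below are
invariant under uniform rescaling of a reading.

Detection is a two-phase threshold procedure:

1. **Calibration.** The rig sits stationary over bare soil for about 30 s
   (15 cycles at the default clock). The chosen vegetation index is
   computed for each soil sample and aggregated — arithmetic mean by
   default, maximum selectable — into a baseline $b$. The detection
   threshold is $b + \delta$ with a guard offset $\delta \ge 0$
   (default 0.05 index units) that suppresses false positives from soil
   and illumination jitter. Raising $\delta$ can only shrink the set of
   detections (a property the tests check).
2. **Operation.** Every cycle computes the index of the current reading
   and compares it to the threshold. Detection — and the relay output that
   would drive a sprayer — fires exactly when the index is *strictly*
   greater than the threshold ("crossing" it); a value exactly at the
   threshold does not trigger. There is no hysteresis: the relay mirrors
   the per-cycle verdict. Changed light or soil means restarting the run
   and recalibrating; no online drift correction is attempted.

The indices are ENDVI (default), NDVI, EVI, PSND, and arbitrary
user-registered functions of the reading. ENDVI, NDVI and PSND are
normalized differences, hence bounded in $[-1, 1]$ for nonnegative
readings; EVI's $+1$ denominator term fixes an absolute scale, so it is
*not* scale invariant and can leave $[-1, 1]$. PSND's formula is the
NIR/pigment normalized difference $(R_{810} - R_{645})/(R_{810} +
R_{645})$; the 645 nm pigment band (near the chlorophyll-b red
absorption) is the package's choice, made so PSND is distinct from NDVI,
which already pairs 810 with 680 nm — the pairing is configurable.

### Degenerate inputs

A zero index denominator raises a typed `gob_undefined_index` condition
rather than returning `NaN`. The detector maps this to "no detection plus
a warning flag" during operation (fail safe while moving) and to a hard
calibration error during the soil window (fail loud while stationary,
since the baseline must be well defined). EVI's denominator
$R_{810} + 6R_{680} - 7.5R_{435} + 1$ can cross zero for nonphysical band
combinations, so it is guarded by a configurable epsilon (default
$10^{-9}$).

## Deployment geometry

`radius_of_detection()` reports $100\,h\tan\theta$ centimetres, both
exactly and floored to an integer; `max_speed()` reports the no-overlap
speed limit $v = 2r/T$ the same way. The exact values satisfy $vT = 2r$
identically, and with the default 2-s cycle the integer speed in cm/s
equals the integer radius in cm. Floor reporting reproduces the validated
rows at $h = 0.30$ m (11.22 → 11 cm) and $h = 0.41$ m (15.33 → 15 cm).
Published tables of this geometry sometimes contain rows consistent with
unit-converted imperial heights rather than with $\lfloor 100 h \tan
\theta \rfloor$ (e.g. a nominal 0.62 m that floors to 23, not 22, unless
it was originally 24 in = 0.6096 m); the package therefore always exposes
the exact value alongside the floored one and treats only the
0.30/0.41 m rows as ground truth. `check_deployment()` evaluates the
three feasibility rules: plant spacing must exceed the footprint diameter
$2r$, the sensor must clear the tallest expected plant, and plant width
should be at least half the radius (narrower plants were not validated).

## The scene simulator

`simulate_transect()` is the software twin of a rolling field trial: a
rectangular soil surface carrying axis-aligned rectangular vegetation
patches, a stationary calibration window at the transect start (refused
if any vegetation lies in the footprint), then one packet per cycle while
advancing $vT$ metres per packet along a straight path.

Per packet the simulator computes the vegetation area fraction $f$ of the
footprint disc and mixes the two endmember spectra linearly band by band,
$(1-f)\,\mathrm{soil} + f\,\mathrm{veg}$, then applies multiplicative
Gaussian noise $(1+\varepsilon)$, $\varepsilon \sim N(0, \sigma)$, drawn
once per band, clipping at zero. Defaults mirror the physical trials: a
$2.1 \times 1.5$ m soil surface, a $7.6 \times 7.6$ cm grass sample,
heights 0.30/0.41 m, roll speed 0.10 m/s (the protocol's "no faster than
10 cm/s"), and $\sigma = 0.01$, a packet-to-packet jitter of about 1% per
band, matching the visibly small scatter of logged field spectra. The
built-in endmembers are shaped like the logged field spectra: both
materials peak in the 810/860 nm NIR, vegetation with strong NIR and the
chlorophyll absorption pattern, soil flat-ish and brighter in blue/red,
giving a wide soil/vegetation index separation.

Ground truth is geometric: a packet is "vegetation present" when $f$
meets an occupancy threshold, default 0.25 of the footprint area. The
binary field ground truth ("the device was above vegetation") has no
stated geometric meaning, so this is a free parameter of the simulator,
not a claim about the physical system; the half-radius plant-width
deployment rule motivates a fraction-based definition. Note a geometric
consequence the tests exercise as stated: at 0.30/0.41 m the footprint
disc is much larger than a 7.6 cm sample, so no packet over such a sample
can reach $f \ge 0.25$ (maximum area ratios 0.147 and 0.078) — the
sensitivity clause of the end-to-end check is then vacuous while the
specificity clause (no detection over bare soil) is substantive. With the
default endmembers the mixture index is monotone in $f$, so detection of
partial covers behaves monotonically too.

**What the simulator does not emulate:** radiative transfer, shadows,
specular soil facets, BRDF and view-angle effects, within-footprint
response nonuniformity (the disc is uniformly weighted, following the
same disc model the geometry table uses), plant 3-D structure, wind
motion, or drifting illumination. Passing tests therefore demonstrate the
correctness and internal consistency of the algorithmic chain — indices,
calibration, thresholding, geometry, logging — under the stated mixing
model, not field performance of any hardware.

### Footprint fraction numerics

`footprint_fraction()` rasterizes the disc at a configurable cell size
(default 2 mm). Cells are weighted by their exact rectangular overlap
with each patch (union via the per-cell maximum) and by a linear
anti-aliasing weight across the disc boundary, which keeps the error well
below one part in $10^2$ even for footprints as small as 5 cm; agreement
with an independent $10^5$-point Monte-Carlo estimate within 0.01
absolute is part of the test suite. Exact full/empty covers snap to
exactly 1 and 0.

## Log format

One packet is one CSV row: packet number, timestamp
(`MM/DD/YYYY,HH:MM:SS`, quoted because of the embedded comma,
timezone-naive), the 18 band responsivities in ascending wavelength
order, then ENDVI, EVI, NDVI — 23 columns. Indices are computed in double
precision and formatted only at write time, with `%.10g`; ten significant
digits keep stored indices self-consistent with stored bands to much
better than $10^{-6}$ even for EVI magnitudes above 1, where six digits
would not. Writing is byte-stable (fixed column order and float format),
and reading verifies the schema, cites the row of an unparseable
timestamp, and warns about any record whose stored indices disagree with
recomputation from its bands beyond a mixed tolerance
($10^{-6} \cdot \max(1, |v|)$ — absolute for the bounded indices,
relative where EVI blows up near its denominator zero). When a custom
index drives detection its values go to a sidecar, keeping the canonical
schema stable. `reanalyze()` rebuilds the detection trace of any log from
raw bands alone — simulated runs log their calibration packets too, so a
log plus a soil window reproduces the live trace exactly.

## Parameters at a glance

| Parameter | Default | Units | Notes |
|---|---|---|---|
| index | `endvi` | — | most consistent soil/vegetation separation; soil-window sd is reported to compare candidates |
| offset $\delta$ | 0.05 | index units | firmware default unprinted; small vs. the observed separation, surfaced in config and logs |
| cycle $T$ | 2 | s | sensor sampling rate |
| calibration | 30 | s | 15 samples at default clock; configurable |
| aggregator | mean | — | `max` selectable; mean matches the offset's false-positive rationale |
| FOV half-angle $\theta$ | 20.5 | degrees | sensor datasheet |
| noise $\sigma$ | 0.01 | — | per-band multiplicative sd in the simulator |
| occupancy threshold | 0.25 | footprint fraction | ground-truth definition, free parameter |
| raster cell | 2 | mm | footprint integration resolution |
| EVI guard $\epsilon$ | $10^{-9}$ | — | undefined-index boundary |

## Test problem sizes

The suite checks each index against independently hand-coded formula
evaluations on 1000 random readings ($10^{-12}$ relative), footprint
rasters against $10^5$-point Monte-Carlo sampling on 20 random scenes
(0.01 absolute), calibration convergence at $n = 15$ vs $n = 1500$ soil
samples over 40 replicates (root-mean-square error ratio near
$\sqrt{100} = 10$), and full transects at both validated heights. All
randomness is seeded; simulated runs are bit-reproducible from their
seeds.

## Known limitations

The detector distinguishes live vegetation from bare soil, not weed
species from crops; it is meant for fallow ground. A single global
threshold assumes illumination and soil are stable within a run.
Actuation latency and sprayer placement relative to the sensor are out of
scope of the geometry rules. The simulator's linear mixing is the
simplest model consistent with a one-pixel averaging sensor; real canopy
radiometry is richer, so simulator results bound algorithmic, not
agronomic, performance.
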