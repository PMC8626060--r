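---
title: "Methods: ranking hyperspectral acquisition conditions for nitrogen phenotyping"
author: "leafspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ranking hyperspectral acquisition conditions for nitrogen phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Close-range hyperspectral imaging of single wheat organs (spike, flag leaf,
second uppermost leaf) can diagnose nitrogen status non-destructively, but
the result depends on *how* the image is acquired: which organ is imaged,
which part of the organ is read out, and at what angle the camera views the
sample. `leafspec` implements the full analysis chain for such experiments —
ENVI cube I/O, reflectance calibration, organ masking, five-region
partitioning, vegetation indices, regime statistics — and a synthetic-data
generator that encodes the biological structure a six-level nitrogen trial
produces, so the chain can be validated end to end without field data.

The trial design is six nitrogen regimes N1..N6 sharing a basal dressing of
36.4 kg N/ha plus two equal top dressings, for totals of 145.6, 109.2, 91,
72.8, 54.6 and 36.4 kg N/ha (160 %..40 % of the recommended 91 kg N/ha);
`regime_design()` returns this table and all regressions on "fertilization
level" default to total kg N/ha (the regime rank 1..6 is available via
`predictor = "regime_index"`, since levels are equally spaced in neither).

## Pipeline stages and their conventions

**Calibration.** Raw counts become reflectance via
$(raw - dark)/(white - dark)$ per band. The white plate is treated as 100 %
reflectance (its nominal 99 % can be imposed through `plate_reflectance`);
the dark reference defaults to zero when no dark frame exists. Reflectance
is clipped to $[0, 1.5]$ — negative values are noise, while values slightly
above 1 are genuine specular pixels that downstream glint diagnostics should
see, so they are preserved up to 1.5.

**Wavelength grid.** The emulated camera samples 204 bands over 400–1000 nm.
Band centers are taken as uniform (spacing 600/203 ≈ 2.96 nm); the camera's
optical FWHM (nominally 7 nm) is wider than the sampling interval and is not
modelled, because only band *selection* matters here. A header-supplied grid
always overrides the default. Index bands are chosen by nearest band center,
with ties resolved toward the lower wavelength; no spectral resampling or
band averaging is performed.

**Masking and regions.** Organs are imaged on black paper, so the mask is a
NIR threshold (default: reflectance 0.25 at the band nearest 800 nm),
keeping the largest 8-connected component and filling interior holes.
EBImage supplies hole filling; its component labeling is 4-connected, so the
package merges its labels across diagonal contacts to get 8-connectivity
(a thin tilted leaf can be diagonally connected for long stretches).
"Five parts proportional to the area" is read literally as *equal-area*
quintiles of the projection onto the mask's first principal axis: pixels are
ranked by projection (ties broken by pixel order so the split is
deterministic) and cut into five rank blocks whose sizes never deviate from
area/5 by more than one pixel, with remainders assigned from the apex side.
An equal-*length* alternative (`partition = "equal_length"`) slices the axis
extent instead; it differs on tapered organs and is provided because the
delimitation used at the bench could have been either. The apex cannot be
recovered from an excised-leaf image by geometry alone, so `apex_end =
"auto"` assigns it to the narrower end (smaller cross-axis spread of the
terminal 10 % of projections — leaf tips taper harder than bases), with
explicit overrides for curated data. Spikes are partitioned by the same axis
rule. Perfectly round masks (tied eigenvalues) fall back to the image
vertical axis.

**Indices.** The four indices use standard literature band positions, as no
formula variant is implied by the data they are computed from:

* NDVI $= (R_{800} - R_{670}) / (R_{800} + R_{670})$
* GNDVI $= (R_{800} - R_{550}) / (R_{800} + R_{550})$
* MRE-NDVI (mND705 form) $= (R_{750} - R_{705}) / (R_{750} + R_{705} - 2 R_{445})$
* PSSRc $= R_{800} / R_{470}$

All eight wavelengths are overridable (`vi_wavelengths()`). Indices are
computed from the *region-mean spectrum* (one value per region per plant),
matching ROI-style workflows and damping glint, rather than averaging
per-pixel indices; the two orders differ on gradients, and the test suite
quantifies that gap on synthetic data instead of pretending they agree.

**Statistics.** Regime effects use classical one-way ANOVA (`stats::aov`),
with the zero-within-variance edge reported as $F = \infty, p = 0$. Duncan's
multiple range test is computed from studentized-range quantiles at
protection level $1 - (1-\alpha)^{p-1}$ for a span of $p$ ranked means
(critical range $R_p = q \cdot \sqrt{MSE / n_h}$, harmonic-mean $n_h$ for
unbalanced groups), rather than from digitized Duncan tables — the quantile
route is reproducible and testable, and at $k = 2$ collapses exactly onto
the pooled two-sample $t$ test, which the suite verifies on 200 random data
sets. Letters come from the standard recursive sweep in which a
non-significant range is never subdivided. Coefficients of determination are
plain OLS $R^2$ with $F$-test stars at 0.05/0.01/0.001; no multiple-testing
correction is applied across the condition grid, matching how such star
matrices are conventionally reported, and the wavelength sensitivity table
uses the sample SD (n−1) across regime means expressed as a percentage of
their mean.

**Ranking.** The best overall condition is the argmax of the *mean* $R^2$
across the four indices — an explicit aggregation rule is needed where a
reader would otherwise eyeball four panels. Ties are broken in the order
second leaf → flag leaf → spike, apex → base, 105° → 125°, and flagged.

## The synthetic generator

The generator's job is to give the pipeline a *recoverable truth* with the
regime structure real trials show, not to be a radiative-transfer model.

**Spectral model.** Reflectance is a Beer–Lambert style surrogate,
$R(\lambda) = 0.03 + R_{struct}(\lambda)\, e^{-A(\lambda)}$, where
$R_{struct}$ rises logistically across the red edge (center 715 nm, width
12 nm) from 0.08 to the NIR plateau $P_{nir}$, and $A$ sums unit-height
Gaussian absorption bands: chlorophyll at 430 nm ($\sigma$ 80 nm) and
670 nm ($\sigma$ 25 nm, weight 0.9), carotenoids at 470 nm, water at
970 nm. The broad blue term is deliberate: chlorophyll absorption in real
leaves has a blue-green shoulder, and it is that shoulder which makes the
green peak (550 nm) respond to chlorophyll content. A narrow blue band
would leave 550 nm numerically inert and the generator could not reproduce
the empirical pattern that 550/650 nm are the most nitrogen-sensitive
bands while 450 nm (saturated absorption) and the NIR are not. The output
is bounded in $(0, 1)$ by construction since $0.03 + P_{nir} < 1$.

**Regime and within-organ structure.** Chlorophyll decreases linearly in
total N between per-organ anchors; visible reflectance therefore *rises*
as fertilization drops. Within an organ, the effective chlorophyll is
$C_{ab}(regime)\,(1 + d_{organ}\, w(s)\, \delta(regime))$ with axis
position $s$ (0 = apex, 1 = base), deficit severity $\delta$ (0 at N1,
−0.75 at N6), and a sensitivity profile $w(s)$: $(1-s)^4$ for the flag
leaf (apex senesces first), $s^4$ for the second leaf (its base loses
nitrogen first during remobilization to the spike), 0 for spikes. The
quartic concentrates the effect in the terminal region, which is how a
senescence front behaves, and gives the ranking stage a clear optimum. The
second leaf additionally carries a regime-dependent NIR plateau
(0.70–0.80); the flag leaf's NIR is regime-flat. Spike pigments are
regime-independent — spikes genuinely carry no signal, so any spike
"detection" downstream is a false positive. Carotenoid absorbance follows
chlorophyll affinely (slope 0.25, base 0.5), keeping 450 nm close to
saturation in every regime.

**Noise.** Three sources, all seeded: (i) plant-level biology — a
log-normal multiplier on chlorophyll (CV 4 %) shared by all organs and
both angles of one plant; (ii) specular glint — a spectrally *flat
additive* component $|N(0, \sigma_{angle})|$ with an acquisition-level
draw plus weaker row-coherent patches ($\sigma/3$), $\sigma_{105} = 0.004$
vs $\sigma_{125} = 0.08$. Glint is additive because surface reflection
bypasses the pigments and carries the illuminant spectrum; a purely
multiplicative glint would cancel in ratio indices and could not degrade
the unfavourable angle. (iii) additive per-pixel-band noise (SD 0.01).
Background pixels sit at 0.03–0.06. Organ outlines taper harder at the
apex ($h(s) \propto s^{0.7}(1-s)^{0.25}$), so the auto apex detector has
something to detect.

**Calibration anchors.** `calibrate_visible_ratio()` rescales an organ's N1
chlorophyll anchor by bisection (tolerance $10^{-4}$) until the noise-free
500–700 nm mean-reflectance ratio N1/N6 hits the configured target
(defaults: 0.808 for the flag leaf, 0.753 for the second leaf), holding N6
fixed; intermediate regimes re-interpolate between the calibrated
endpoints so monotonicity survives. The noise-free "organ mean" used here
weights axis positions by outline width, which matches the pixel mean of a
rendered mask to within discretization error.

**Growth records.** Each trait is drawn from
$N(\mu_{regime}, (CV \cdot \mu)^2)$ truncated at zero (CV 0.06 by
default; CV = 0 returns the means exactly). The mean table anchors leaf
nitrogen at 2.1 % (N1, N2) falling to 1.2 % (N6) with a monotone fill
between, and fixes N6/N1 ratios of 85.6 % (height), 44.1 % (LAI), 64.9 %
(SPAD) and 44.9 % (seed weight, with N6/N3 = 54 %). Absolute N1 anchors
(100 cm, LAI 5, SPAD 50, 10 g/plant) are arbitrary scale choices — only
the ratios are meaningful — and intermediate regimes are interpolated
linearly in regime index (seed weight piecewise through its N3 anchor).

## What the synthetic data does and does not show

Passing tests demonstrate that the analysis stack *recovers what the
generator encodes*: the regime ordering of visible reflectance, the
calibrated N1/N6 ratios through the full image pipeline (within 2 points at
default noise, 10 plants/regime), the within-leaf sensitivity geometry
(best condition: base of the second leaf at 105°), the null behaviour of
spikes, and the band-sensitivity ordering (550/650 above 450/850 for both
leaf organs). They do not demonstrate performance on real leaves: the
surrogate has no BRDF, no specular geometry tied to actual sun-sensor
angles, no within-row pigment texture for leaves, no soil or canopy
background, and its angle effect is a noise model rather than physics. The
spike-null check is itself statistical: with 40 spike cells tested at
$\alpha = 0.05$, occasional spurious stars are expected even from a perfect
null — the star probability is exactly the test's size — so that check is
evaluated as a pass *rate* over seeds, and sits near its theoretical
ceiling by construction.

## Numerical choices and problem sizes

Cubes default to 128×128×204 in `sim_params()` (512×512 is supported
throughout, including I/O); the experiment driver defaults to 64×64 and the
test suite runs at 48×48 with 10 plants per regime — the smallest geometry
at which masks comfortably exceed the 200-pixel organ minimum and regions
hold ≈ 80 pixels, which keeps region means stable while letting the
20-seed ranking check complete in minutes. ENVI files default to float32
little-endian (`data type = 4`) with the header's declared type honored on
read; bit-exact round-trips use `data_type = 5`. All randomness flows
through explicit seeds; per-cube seeds derive arithmetically from the
experiment seed, and plant-level biology is seeded separately from
acquisition noise so the same plant can be imaged at both angles.

## Known limitations

Single organ per scene (no overlap separation, no midrib/petiole
modelling); no red-edge inflection fitting, continuum removal or derivative
spectra; no chlorophyll inversion; no mixed models or multiplicity
correction beyond the conventions above; no canopy or UAV scales. The
regression treats angle as a categorical acquisition label — no radiometric
angle model is attempted.
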