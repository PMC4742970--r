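---
title: "Models and methods behind curtainr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind curtainr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curtainr)
```

`curtainr` analyses single-molecule fluorescence data from DNA curtains:
arrays of λ-phage DNA molecules (48,502 bp) stretched between tether points
13 μm apart and imaged by TIRF microscopy at 0.2 s per frame. This vignette
documents the models the package implements, the conventions and parameters
that matter, the design choices that were genuinely open, and what the
synthetic ground truth can and cannot validate.

## Coordinates and geometry

All positions live on a 1D axis along the DNA, in continuous base pairs on
[0, 48,502], origin at the barrier-tethered (biotin) end. Conversions between
bp and μm always go through `dna_geometry()` using the *curtain extension*
(13 μm / 48,502 bp ≈ 0.268 nm/bp, about 80% of the 0.34 nm/bp B-form rise).
A 750 bp window therefore corresponds to ≈ 200 nm in the image, not 255 nm.
Hard-coding the crystallographic rise anywhere would silently inflate every
distance threshold by ~25%, which is why the conversion is centralized.

## The sliding + hopping simulator

`simulate_trajectory()` implements facilitated diffusion as:

* **Sliding** — Euler–Maruyama steps at the frame interval with variance
  2 D Δt. An exact Brownian bridge is not needed because every observable in
  the pipeline is defined at frame resolution; sub-frame excursions only
  matter through the hop mechanism below.
* **Hopping** — a Poisson number of instantaneous micro-dissociation events
  per frame (rate `hop_rate_per_s`), each relocating the molecule by
  Normal(0, `hop_sigma_bp`) and escaping into solution with probability
  `p_escape_per_hop`. Hops are resolved at sub-frame times drawn uniformly.
  The hop rate and excursion length are free parameters of the simulator:
  they are not identifiable from frame-resolution data and are not fitted.
* **Roadblocks** — sliding always reflects at a roadblock; only hop landings
  may cross, accepted against a per-roadblock permeability. This
  operationalizes the clamp-opening picture of obstacle bypass without
  asserting its molecular mechanism. Every encounter outcome is logged.
* **DNA ends** — reflecting by default (double-tethered mode); either end can
  be flagged open so the molecule slides off (single-tether mode), recorded
  as a distinct exit mode.
* **Lesion capture** — a site (default 20 kb) captures a visiting molecule
  with a per-frame probability and freezes its position.
* **Blinking** — a two-state telegraph process; dark frames are photophysics,
  the molecule keeps diffusing. No richer photophysics (spectral jumps,
  bleaching) is modelled because quantum dots do not bleach on these time
  scales.
* **Localization noise** — Gaussian with s.d. 250 bp, chosen so that three
  standard deviations equal the 750 bp collision zone used by the event
  classifier.

Reproducibility: per-trajectory seeds are derived from the population seed by
a counter, so trajectory *k* is identical whether the population holds 5 or
500 molecules.

What the generator does **not** emulate: 3D excursion paths during hops (only
their landing statistics), nucleosome breathing or sliding, flow-extension
mechanics, uneven illumination, camera read noise and EM gain statistics, or
drift. Tests that pass against this ground truth therefore validate the
estimators and classifiers under their stated noise model, not robustness to
every instrumental artefact of real curtains data.

## Localization and tracking

Spots are localized by nonlinear least squares of a symmetric 2D Gaussian
with constant background (`minpack.lm::nlsLM`). The frame background is
estimated as median + MAD, which is robust to the spots themselves. A fit
whose amplitude falls below 3× the robust noise is a "no spot" result, not an
error. Detections closer than one PSF σ merge into one spot — two emitters
within a PSF are reported as a single molecule, a stated resolution limit.

Linking is greedy nearest-neighbour: at each frame, open tracks claim their
nearest detection, closest pairs first, with deterministic tie-breaking
towards the lower spot index. Defaults: `max_jump_um` = 4·sqrt(2·D·Δt) at
D = 0.5 μm²/s ≈ 1.8 μm (wide enough for blinking jitter, narrow enough not
to bridge neighbouring DNA molecules at ~1 μm lateral spacing) and
`max_gap_frames` = 5. Both are exposed as arguments; the upstream tracking
parameters of the original acquisition software are not published, so these
defaults are declared choices, not inferred ones.

The trajectory filter keeps tracks with at least 50 *detected* frames (10 s
at 0.2 s/frame), inclusive at exactly 50. Flow-response validation of tracks
is an experimental control that cannot be automated from the image data; a
metadata flag lets users exclude tracks manually.

## Diffusion estimation

For a track y₁…y_N the time-averaged MSD at lag nΔt is the overlapping
average Σᵢ(y_{i+n} − y_i)²/(N−n), computed for the first 10 lags (0.2–2 s).
For gapped tracks only pairs with both endpoints detected contribute, and the
denominator is the actual pair count. The diffusion coefficient is
slope/2 of an ordinary least-squares line through the MSD (1D convention,
MSD = 2DΔt).

The line has a **free intercept** by default: i.i.d. localization noise of
variance σ² adds ≈ 2σ² to every lag, which the intercept absorbs while the
slope stays unbiased. A through-origin fit is available for sensitivity
analysis. Noise-dominated tracks can produce D ≤ 0; these are flagged and
retained in diagnostics, but excluded (with a reported count) from log-scale
statistics, which use a two-tailed t-test on log₁₀(D) with Welch degrees of
freedom. Welch is the default because the variances of diffusion-coefficient
populations differ strongly between conditions; the pooled test is a flag.

`rotational_sliding_limit()` evaluates the theoretical ceiling for a protein
that tracks the helical pitch while sliding: friction
ζ = 6πηr + (2π/pitch)²(8πηr³ + 6πηr·R_oc²) with pitch 3.57 nm per 10.5 bp
turn, following Schurr's rotation-coupled drag model as used by Blainey and
colleagues for 1D sliding proteins. With r = 5 nm in water at 25 °C the limit
is ≈ 0.27 μm²/s.

## Ionic strength and screened charges

Ionic strength is I = ½ Σ cᵢzᵢ². For the standard imaging buffer (40 mM
Tris-HCl pH 8.0, 2 mM MgCl₂, 25–150 mM NaCl; DTT and BSA treated as
non-ionic), the published worked decomposition assigns 9 mM to TrisH⁺ (from a
"45% charged" fraction), 11 mM to the titration chloride, 6 mM to MgCl₂, and
the nominal NaCl concentration — totals of 51 to 176 mM.

These Tris terms are mutually inconsistent under electroneutrality: at
pH 8.0 with pKa 8.1, Henderson–Hasselbalch gives a *protonated* (charged)
fraction of 0.557, so the 45% figure matches the *deprotonated* fraction
while the 11 mM chloride follows the protonated one. Whether that was
intentional cannot be determined from the text, so the module has two modes:
`"paper"` reproduces the printed decomposition (whole-mM arithmetic, totals
51/176), and `"consistent"` applies Henderson–Hasselbalch to both ions
(electroneutral, ~2.3 mM higher) and is the default for new analyses.

The salt-dependence fit is OLS of log₁₀(D) on log₁₀(I); dividing the slope by
the counterion condensation parameter ψ = 0.88 for double-stranded DNA
converts it into the number of charge–charge contacts screened at increasing
ionic strength (slope 1.3 → 1.5 charges). No activity-coefficient or Debye
length corrections are applied: the slope, not the absolute I, carries the
physical content.

## Dwell times and survival fits

A dwell spans first to last detected frame; blinking gaps are bridged because
a dark fluorophore is not a dissociated protein. Tracks alive at the movie
end are right-censored and excluded from the dissociation-locus tally.
Dissociation loci are classed "end" within 1,000 bp of a DNA end: the
end-vs-internal distinction in curtains work is reported without an explicit
threshold, and 1 kb matches the ~1 kb granularity at which sliding distances
are quoted; the value is an argument.

The default survival fit mirrors a plotted single-exponential decay: the
empirical survival function is built by Kaplan–Meier (censored records
contribute up to their censoring time) and fit by least squares to
exp(−t·ln2/t½). The curve is evaluated at the *midpoint* of each
Kaplan–Meier step (Hazen plotting position): fitting the post-drop step value
instead biases the half-life low by ~3% at n = 50, which matters at the
package's own acceptance tolerances. The alternative `"mle"` method uses the
closed-form censored-exponential estimate rate = events / total observed
time, with s.e. t½/√events; the two routes agree within a few percent on
clean data and serve as mutual cross-checks. The least-squares s.e. comes
from the fit covariance; whether the published ±1 s-type uncertainties are
fit or bootstrap errors is not stated, so the package reports the fit s.e.
and does not claim equivalence.

## Event classification

**Collisions and bypass.** The collision zone is the roadblock position
± 375 bp (750 bp wide = 3 × the 250 bp localization s.d.; the s.d. is a
config constant that should be recomputed from stationary-spot jitter when
such tracks are available). The scorer requires `min_outside_frames = 3`
consecutive detections outside the zone to confirm which side the protein is
"clearly diffusing" on — without this persistence rule, localization noise at
the zone edge fabricates ~8% false bypasses against a fully reflecting
roadblock. Each maximal zone visit between confirmed sides is one collision:
bypass if the sides differ, same-side return otherwise, unresolved if the
track ends in the zone; two opposite confirmed sides with no intervening
detection also count as a bypass (a hop can span the zone within one frame).
Collisions are counted per maximal zone episode, so one trajectory can
contribute several collisions at the same roadblock. Bypass frequency is
bypasses / resolved collisions with a Wilson 95% interval.

Note a direction-of-monotonicity fact about the zone: *enlarging* the
halfwidth can only decrease the bypass count (every wide-zone traversal
implies a narrow-zone traversal, not vice versa); the suite tests this
direction.

**Transfers.** Detections are assigned to the nearest DNA axis within a
register tolerance (default 0.2 μm ≈ 3 × the localization s.d., mirroring
the collision-zone logic). An event requires > 4 s in register before, a
switch completed in at most one frame, and ≥ 4 s in register after. The
package does not attempt to distinguish hopping from intersegmental transfer:
the events themselves cannot discriminate the mechanisms.

**Lesion recognition.** A track that ends within 300 bp of the lesion and is
stationary (displacements below the localization s.d.) over its last 10
frames is an arrest. It is `direct-3D` if its first detection is already
within 300 bp and arrest is immediate, `sliding-1D` if the cumulative
pre-arrest path is ≥ 1,000 bp, otherwise `ambiguous`. The 300 bp
direct-binding resolution and the 250 bp localization s.d. are close but not
identical quantities; both are independent arguments rather than a single
unified constant. The 10-frame arrest window distinguishes binding from a
slow excursion at the 0.2 s cadence.

## Numerical and interface choices

* Nonlinear fits use Levenberg–Marquardt (`nlsLM`) with bound constraints;
  non-convergence yields flagged results (no-spot, fit-failed histograms),
  never exceptions, so batch pipelines do not die on one bad molecule.
* Linking ties are broken deterministically (lower spot index), making runs
  reproducible.
* Trajectories are CSV with a schema-version comment (inspectable,
  desk-scale); images are uncompressed 16-bit grayscale TIFF; reports and
  ground-truth sidecars are JSON stamped with the seed and a config hash.
* The `curtainlab` script (in `inst/exec`) is a thin optparse wrapper over
  the exported functions; all analysis logic lives in the package.

## Problem sizes in the test suite

The suite validates estimator consistency at the published sample sizes
(n = 72 and n = 49 molecules of 150 frames for diffusion recovery; n = 50
dwells for half-life recovery at 76 s and 25 s) and uses ensembles where
single realizations would be dominated by sampling noise: 3,000 exact
Brownian paths for the MSD intercept property, 100 confined trajectories for
the L²/6 plateau, and ≥ 500 simulated collisions for classifier–oracle
equality. Recovery checks accept deviations within two standard errors of
the relevant sampling distribution.

## Known limitations

* The tracker handles one spectral channel; two-colour experiments are two
  tracked channels joined by time downstream.
* Greedy linking can swap identities when two molecules approach within the
  jump radius; the simulator's ground truth makes such events measurable but
  the linker does not resolve them.
* Sub-frame hop excursions are instantaneous by construction, so quantities
  that depend on the 3D excursion path (e.g. true hop dwell in solution) are
  outside the model.
* Survival fits assume a single exponential; heterogeneous or
  multi-exponential dissociation is out of scope.
* Histogram Gaussian fits flag degenerate inputs (uniform or constant
  positions) rather than estimating a peak from them.
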