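---
title: "Tracking nanotube condensation in droplets: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking nanotube condensation in droplets: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropletcondense)
```

# The measurement problem

Water-in-oil droplets encapsulating fluorescently labelled DNA tiles are
imaged over hours while the tiles polymerize into nanotubes. Counting or
measuring individual nanotubes inside a droplet is impractical — bundles
curve, wrap the inner surface, and overlap in projection — but the
*pixel-brightness distribution* of each droplet interior carries a robust
signature of assembly. Before polymerization the interior is a smooth
dispersed background and the distribution is narrow and nearly
symmetric. As tiles condense into a few bright curvilinear structures, a
heavy right tail appears: the skewness and excess kurtosis of the
distribution rise. Both are standardized moments, so they are unchanged
by linear changes of the intensity scale — exposure time, gain — as long
as no pixel saturates; this makes them comparable across time points and
instruments.

This package implements the full measurement chain (synthetic image
generation with ground truth, droplet detection, per-droplet moments,
population aggregation) and a kinetic model of the chemistry that drives
the condensation signal.

# Condensation statistics

Per droplet we report the bias-corrected sample skewness

$$G_1 = \frac{n^2}{(n-1)(n-2)}\,\frac{m_3}{s^3}$$

and excess kurtosis

$$G_2 = \frac{n(n+1)}{(n-1)(n-2)(n-3)}\frac{\sum d_i^4}{s^4}
        - 3\frac{(n-1)^2}{(n-2)(n-3)},$$

the conventions of the common data-analysis libraries, so values are
directly comparable with published droplet timecourses. Plain moment
estimators are available behind `bias_correct = FALSE`.

Two **modes** are provided and never mixed within a summary:

* `pixels` — ordinary occupancy-weighted moments over all interior
  pixels. Statistically conventional; exactly affine-invariant, and the
  mode to use when comparing against analytic distributions.
* `unique` (default) — the pixel sample is first reduced to the sorted
  list of *occupied histogram bins* (bin width 1 gray level, bins
  anchored at zero, left-edge representatives), each occupied bin
  contributing once regardless of how many pixels fall in it. This
  emphasizes the appearance of new bright intensity levels over their
  pixel counts. The two modes genuinely differ whenever occupancy is
  uneven, which is exactly the condensed regime.

A caveat the test suite makes explicit: the unique reduction at a
*fixed* bin width is **not** exposure-invariant, because rescaling the
intensities changes which values share a bin. Invariance is recovered
when the bin width is scaled with the gain (bin width 2 at twice the
exposure reproduces the same bin list). The `pixels` mode needs no such
adjustment. When comparing unique-mode values across acquisitions with
different exposure settings, scale `bin_width` accordingly.

Aggregation is deliberately simple, matching how droplet experiments
are reported: per time point, the unweighted mean and sample standard
deviation (n−1) of each moment over all valid droplets. Droplets whose
reduced sample is degenerate (fewer than 4 values, zero variance) are
excluded and counted, with the reason recorded. A single-droplet time
point reports SD 0 with a `single_droplet` flag rather than NA, keeping
exported tables numeric. Droplets are re-detected independently in every
frame; there is no tracking, so timecourses describe the population, not
individual droplets.

# The synthetic droplet generator

The generator exists to give every stage of the analysis a ground truth.
It emulates the statistical structure the analysis relies on; it is not
a physical microscope simulator.

**Population.** Radii are log-uniform over 1–20 µm (the vortex
"shaken" emulsification protocol constrains only this range; log-uniform
spreads droplets evenly across size decades). Centers are rejection-
sampled so that disks never overlap nor touch the frame border, placing
large droplets first; an impossible packing fails with an error naming
how many droplets were placed. Per-droplet tile loads are jittered by a
multiplicative lognormal factor (`partition_sdlog`, default 0.2),
emulating partitioning noise — the unequal encapsulation of reagents
that dominates droplet-to-droplet variability in small volumes.

**Photometry.** A droplet is a fluorophore-filled sphere imaged in
widefield. The free-tile (dispersed) signal at a pixel at distance $r$
from the center of a droplet of radius $R$ is split into an in-focus
equatorial slab — $\min(2\sqrt{R^2-r^2},\, t_{dof})$ with
`focal_depth_um` $t_{dof} = 2$ µm — rendered sharp, plus the remainder
of the spherical chord rendered as a defocused halo (Gaussian blur of
sigma $0.25R$). The two parts sum to the full chord before blurring, so
the total signal per droplet is exactly proportional to its tile budget
and independent of how far assembly has proceeded (condensation
redistributes signal; it neither creates nor destroys it — this
invariant is tested). The slab gives the sharp rim the detector needs
and an essentially flat interior; a pure chord projection would make the
interior distribution substantially left-skewed at fraction zero, which
neither the flat-interior appearance of real droplets nor the
near-zero baseline moments of real timecourses support.

**Filaments.** Nanotube bundles are worm-like chains: turning angles are
Gaussian with variance $2\,\delta s/\ell_p$ per step $\delta s$, giving
the 2D tangent correlation $\langle\cos\theta\rangle =
e^{-\delta s/\ell_p}$, with persistence length default 4.5 µm; chains
reflect specularly off the droplet boundary, and a surface-localized
mode confines them to the outer 15% annulus (bundles wrapping the inner
droplet surface). The *visible contour length* per droplet follows a
coarsening law,
$L = V\rho\,\frac{f}{f+0.05}(1-0.7f)$ (peak density
$\rho = 0.004\,\mu m/\mu m^3$): a network of thin nanotubes appears
quickly at low assembled fraction, and further assembled mass then
thickens and bundles existing structures more than it extends the
network, so bundles grow brighter while their footprint slowly shrinks.
This choice matters: if contour length simply grew linearly with
assembled mass, the bright-tail pixel fraction would grow while the
filament/background contrast saturates, and the interior skewness would
mathematically plateau and then *fall* with assembled fraction —
qualitatively wrong for a condensation readout. The coarsening law is a
modeling choice (how nanotube number and length scale with assembled
mass is not experimentally constrained); it reflects the observed
elongating, joining, and bundling of encapsulated nanotubes. Half of
the filament fluorescence is rendered as a defocused halo
(`filament_halo_frac`), since a three-dimensional tangle does not lie
in a single focal slab.

**Camera.** The expected image (background 200 + gain × signal) receives
Poisson shot noise and Gaussian read noise (SD 10), is rounded to
integer gray levels, and must stay below 90% of the 16-bit ceiling —
renders that would saturate abort with advice to lower the gain, since
the entire moment analysis presumes an unsaturated, linear camera. The
default gain 0.15 leaves roughly 1.6× headroom over the brightest
bundles produced under default conditions. All randomness flows from a
single seed through documented substream derivation
(`derive_seed`); identical seeds give bit-identical frames.

**What passing tests on this generator do *not* show.** Real droplet
images contain out-of-focus droplets from other z-planes, rim
adsorption artifacts, aggregates that the moments cannot distinguish
from ordered nanotubes, illumination gradients, and drift. None of these
are emulated. The generator validates the pipeline's statistical logic
and its detector on images with a known answer; it cannot certify
performance on any particular microscope's data.

# Droplet detection

The detector is a gradient-direction circular Hough transform with
heavy validation, operating on a normalized copy of the frame so that
its behavior is invariant under positive affine rescaling of the
intensities:

1. *Median prefilter* (radius 3): removes thin bright filaments and hot
   pixels so they cannot distort rim geometry. All geometry is estimated
   on the filtered image; pixel statistics are always extracted from the
   original.
2. *Edges*: Gaussian smoothing (sigma 2), central-difference gradients,
   and a threshold at the 90th magnitude percentile with a noise floor
   of 3× the median magnitude (the floor matters on sparse frames, where
   a pure quantile would flood the edge set with background noise).
3. *Voting*: each edge pixel votes one radius along its gradient
   direction (droplet interiors are brighter than oil, so rim gradients
   point inward), weighted by gradient magnitude — the sharp rim outvotes
   the weak interior gradient of the defocused dome, which would
   otherwise spawn concentric phantom circles. Accumulator peaks are
   scored per unit circumference in units of the edge threshold.
4. *Refinement*: radius from the 50% crossing of the radial intensity
   profile between the near-rim interior level and the global
   background (the image-wide median — droplets cover a small area
   fraction), searched outward so concentric phantoms get rescued to the
   true rim; sub-pixel center from a robust algebraic circle fit to
   rim-aligned edges (fit, trim outliers, refit).
5. *Validation*: azimuthal coverage (a real rim is voted for from ≥ 60%
   of 16 angular sectors), circle-fit residual, and interior support (a
   real droplet is filled — ≥ 90% of the annulus just inside the rim
   must sit above background; phantom circles through the rim arcs of
   adjacent droplets span oil gaps and fail).
6. *Suppression*: strongest-first non-maximum suppression — candidates
   are dropped when centers are closer than half the radius sum, and
   also when a candidate's center falls inside an accepted circle (real
   droplets cannot overlap; knots of bright filaments inside a large
   droplet can masquerade as small circles).
7. *Extraction*: detections touching the border margin are discarded;
   each survivor carries the pixels of its disk shrunk by
   `rim_shrink_fraction` (default 0.1, excluding the bright rim and
   surface-adsorption artifacts), with a minimum of 50 pixels so moment
   estimates are stable (hence the 5 px minimum radius).

A simple fallback (`method = "threshold"`: Otsu, connected components,
circularity ≥ 0.8) is provided for low-contrast frames where the
gradient stages find nothing.

Known limitations: isolated very large droplets dense with filaments can
still bias the fitted center by a few pixels; droplets lying out of
focus are not filtered (no focus criterion in this version); and at high
assembled fraction (≥ 0.8 of the fluorophore condensed) the rim contrast
from residual free tiles becomes weak and precision degrades. The
validation experiments therefore measure detector recovery on
early-assembly frames (fraction 0.15, where every droplet rim has SNR
≥ 5), and measure the condensation-monotonicity property of the
*statistics* on ground-truth geometry, so that detector errors at high
fraction do not confound a property of the moments. The closed-loop
experiment (simulate → render → analyze blind) still exercises the full
untouched pipeline.

# The kinetic model

The model is a minimal deterministic ODE description of isothermal,
RNA-triggered tile assembly in the presence of transcription and
degradation machinery. Species (nM): inactive tiles `Ti` (annealed
without one sticky-end strand), active tiles `Ta`, polymerized tiles
`P`, filament number density `N`, free trigger RNA `R`, waste `W`;
plus the dimensionless RNAP activity `a`.

* **Transcription**: trigger RNA is produced at `k_tx · G · a` from `G`
  nM of synthetic gene template; RNAP activity decays exponentially
  (`delta`), an experimentally motivated loss of enzyme activity over
  the hours-long experiments.
* **Activation**: free RNA hybridizes to an inactive tile, completing
  its sticky end (attempt rate `k_act · Ti · R`, one RNA consumed per
  attempt). The nascent tile:RNA hybrid is itself an RNase H substrate,
  so only a fraction `1/(1 + kappa·H)` of attempts completes; failures
  destroy the trigger and leave the tile inactive. This interception is
  what *delays* (rather than merely attenuates) assembly at high
  RNase H: it slows the activation clock while RNAP decay keeps running.
* **Nucleation–elongation**: active tiles nucleate cooperatively with
  order `n_nuc` (default 3) driven by the supersaturation above the
  critical concentration `c* = k_off/k_on` — subcritical nuclei
  dissolve, so no filaments form while `Ta < c*`. Filaments elongate at
  `k_on · Ta · N` and release tiles at
  `k_off · N · P/(P + 0.1)`; the saturating factor only shuts the flux
  off smoothly as the polymer pool empties, preventing negative states.
  Depolymerized tiles return to the active pool, where RNase H can reach
  them — this recycling, against decaying transcription, is what turns
  the pulse downward.
* **Degradation**: RNase H deactivates *free* active tiles at
  `k_deg · H · Ta` (polymerized tiles are protected inside the lattice);
  a fraction `w_frac` (default 0.2) of deactivation events strands the
  tile in an inert waste complex (incomplete degradation products), the
  rest return to the re-activatable inactive pool.

Units are nM and minutes; RNase H stays in U/µL with `k_deg` absorbing
the conversion, because enzyme activity is specified in units, not
molarity. PEG crowding enters only as an optional multiplicative preset
on `k_nuc` and `k_on` (`peg_factor`); no crowding physics is modeled.

Defaults (`k_tx` 0.05 /min/nM, `delta` 0.01 /min, `k_act` 1e-3 /nM/min,
`n_nuc` 3, `k_nuc` 2e-7, `k_on` 0.02 /nM/min, `k_off` 0.2 /min so
`c*` = 10 nM, `k_deg` 0.3, `kappa` 10 /(U/µL), `T_total` 500 nM, `G`
100 nM) are order-of-magnitude choices selected once so that the model
reproduces the system's qualitative regimes — they are **not** fitted to
experimental data, and none of the package's claims depend on their
precise values. The regime suite that defines the model's contract is
part of the test suite: no assembly without gene; monotone assembly with
increasing final fraction under gene titration when degradation is
absent; a pulse whose height decreases and whose half-rise time
increases with RNase H over 0.025–0.1 U/µL; tile conservation to
floating-point accuracy; and agreement with the closed-form exponential
solution of the pure-elongation limit.

Whether the original system is better described by an explicit filament
number density or a coarser two-state model cannot be decided from
macroscopic observations alone; the regime suite, not the specific state
space, is the contract this module maintains.

# Numerical choices

* Integration: `deSolve::ode` (`lsoda`), rtol 1e-8, atol 1e-10;
  negative excursions beyond 10×atol are clipped to zero with a warning;
  integrator failures raise an error echoing the parameter set.
* Pulse metrics: peak, peak time, time above a threshold (default f =
  0.1), and half-rise time (first crossing of half the peak), all by
  linear interpolation on the output grid; a trajectory still above
  threshold at the end of the window reports a right-censored duration.
* Moments: undefined moments (n < 3 for skewness, < 4 for kurtosis, or
  zero variance) are errors at the estimator level and recorded
  exclusions at the pipeline level.
* Coordinates are 1-based `(row, col)` matching R matrix indexing;
  droplet disks use the half-open convention "pixel center strictly
  inside the (shrunken) radius"; radii are kept real-valued.
* Ties in detection ranking are effectively broken by the circle-fit
  residual term; NMS processes candidates strongest-first.
* Seeds: every stage derives independent substreams from one master
  seed via an integer hash (`derive_seed`), and library code restores
  the caller's RNG state.

# Validation problem sizes

The end-to-end validation suite uses: 1,000 random samples against a
direct-formula moment oracle plus analytic limits at n = 10^6; a
20-frame × 50-droplet recovery experiment (768×768 px, radii 5–20 px,
fraction 0.15); five fraction levels × 100 droplets (1024×1024 px) for
condensation monotonicity; the full kinetic regime grid; and a
six-frame closed simulate–render–analyze loop (40 droplets,
640×640 px). These sizes give stable population statistics while
keeping a full run in the minutes range on a single core.

# Configuration files

Pipeline runs (`run_synthesize`, `run_analyze`, `run_simulate`, and the
CLI wrapper in `inst/cli/`) are driven by YAML configurations with
blocks mirroring the constructor arguments (`population`, `imaging`,
`model`, `detection`, `sweep`, `render`). Every run writes its fully
resolved configuration and seed as JSON next to its outputs, and the
synthesizer's TIFF/truth/manifest outputs are bit-reproducible from
config plus seed.
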