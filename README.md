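# dropletcondense

Quantifying the self-assembly of DNA nanotubes inside water-in-oil
microemulsion droplets from fluorescence time-lapse microscopy, and
modelling the reaction kinetics that drive it.

When fluorescently labelled DNA tiles polymerize into nanotubes inside a
droplet, the fluorescent signal *condenses*: it redistributes from a
smooth dispersed background into a few bright curvilinear structures.
The shape of the droplet's pixel-brightness distribution records this —
its skewness (asymmetry) and excess kurtosis (tailedness) rise as
nanotubes grow — and, because both are standardized moments, the readout
is insensitive to exposure settings as long as no pixel saturates.
`dropletcondense` implements this analysis end to end for people
studying compartmentalized nucleic-acid self-assembly (DNA
nanotechnology, synthetic cells, cytoskeleton mimics):

* **Synthetic data generator** — seeded, ground-truth-annotated
  fluorescence frames of droplet populations: log-uniform radii
  (~1–20 µm, emulating vortex emulsification), spherical-projection
  photometry with finite depth of field, worm-like-chain nanotube
  bundles (persistence length ~4–5 µm, optional surface-wrapping mode),
  lognormal partitioning noise, Poisson shot noise plus Gaussian read
  noise, 16-bit quantization with a saturation guard.
* **Droplet detection** — gradient-direction circular Hough transform
  with rim-coverage validation, robust circle refinement, non-maximum
  suppression, and per-droplet interior pixel extraction (rim-shrunken
  disks); an Otsu-threshold fallback for low-contrast frames.
* **Condensation statistics** — bias-corrected sample skewness `G1` and
  excess kurtosis `G2` per droplet, in two modes: ordinary
  occupancy-weighted moments (`pixels`) and the unique-binned-value
  variant (`unique`) in which moments are taken over the sorted list of
  occupied histogram bins; population mean ± SD per time point.
* **Assembly kinetics** — a deterministic ODE model of RNA-triggered
  tile activation (trigger RNA transcribed from a synthetic gene by T7
  RNAP whose activity decays), cooperative nucleation and elongation of
  nanotubes above a critical tile concentration, and RNase H-mediated
  deactivation of free active tiles, with pulse metrics and parameter
  sweeps.

## The model at the core

State (nM; `a` dimensionless): inactive tiles `Ti`, active free tiles
`Ta`, polymerized tiles `P`, filament number density `N`, free trigger
RNA `R`, waste `W`, RNAP activity `a`. With attempt flux
`att = k_act·Ti·R`, interception survival `σ = 1/(1 + κH)`,
supersaturation nucleation `nuc = k_nuc·max(Ta − c*, 0)^n` (critical
concentration `c* = k_off/k_on`), elongation `elo = k_on·Ta·N`,
depolymerization `dep = k_off·N·P/(P+0.1)`, and deactivation
`deg = k_deg·H·Ta`:

```
dR/dt  =  k_tx·G·a − att            da/dt = −δ·a
dTi/dt = −σ·att + (1 − w)·deg       dW/dt = w·deg
dTa/dt =  σ·att − deg − n·nuc − elo + dep
dP/dt  =  n·nuc + elo − dep         dN/dt = nuc
```

Tiles are conserved exactly (`Ti + Ta + P + W = T_total`); RNA is not
(activation consumes it, RNase H destroys it on free tiles and on the
nascent activation hybrid). The readout is the assembled fraction
`f = P/T_total`. Defaults are order-of-magnitude choices that reproduce
the system's qualitative regimes — gene-titration speedup, and an
RNase H-tunable assembly/disassembly pulse that is both attenuated and
*delayed* by more enzyme — not fits to any dataset.

## Worked example

Simulate a transcription-versus-degradation pulse, render a droplet
time series that follows it, and analyze the images blind:

```r
library(dropletcondense)

p   <- rate_params(G = 100, H = 0.05)      # 100 nM gene, 0.05 U/uL RNase H
sim <- simulate_assembly(p, t_end = 900)
pulse_metrics(sim)
#> pulse: peak f = 0.344 at t = 333.0 min; 831.4 min above f = 0.10
#> (right-censored); half-rise at 93.5 min

pop    <- sample_droplet_population(25, c(512, 512), c(5, 18), seed = 11)
frames <- render_timeseries(sim, pop, imaging_params(rng_seed = 11),
                            frame_times = c(0, 120, 300, 600, 900),
                            seed = 11)
res <- analyze_frames(frames)
res$timecourse[, c("time_min", "n_droplets", "mean_skewness",
                   "sd_skewness", "mean_kurtosis")]
#>   time_min n_droplets mean_skewness sd_skewness mean_kurtosis
#> 1        0         25        -0.036       0.098        -1.083
#> 2      120         25         0.952       0.468         0.548
#> 3      300         25         1.107       0.407         0.663
#> 4      600         25         1.105       0.438         0.744
#> 5      900         25         0.949       0.416         0.567
```

All 25 droplets are re-detected in every frame. At t = 0 the droplet
interiors are featureless (skewness ≈ 0, kurtosis ≈ −1.1, the flat-top
signature of a uniform interior); as the simulated assembled fraction
pulses up to 0.34 around t ≈ 330 min, the recovered mean skewness and
kurtosis rise and then relax as RNase H disassembles the nanotubes —
the image statistics track the hidden kinetic trajectory.

A command-line wrapper over the same functions is installed at
`inst/cli/dropletcondense.R` (`synthesize`, `analyze`, `simulate`
subcommands with YAML configurations).

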