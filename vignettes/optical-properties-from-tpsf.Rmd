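---
title: "Estimating tissue optical properties from time-resolved reflectance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating tissue optical properties from time-resolved reflectance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem and the model

When an ultrashort laser pulse is launched into a strongly scattering
medium such as brain tissue, the light detected a short distance away
arrives spread over tens to hundreds of picoseconds.  The shape of this
temporal point spread function (TPSF) encodes the medium's absorption
coefficient $\mu_a$ and reduced scattering coefficient
$\mu_s' = \mu_s(1-g)$: scattering controls how long photons dwell near the
detector, absorption controls how strongly late (long-path) photons are
suppressed, via Beer-Lambert's $e^{-\mu_a L}$ along a path of length $L$.

At a source-detector separation of 1.25 mm — chosen so that the probed
volume stays within a millimetre-thick cortical layer — the diffusion
approximation to the radiative transfer equation is not valid: the
separation is only about two transport mean free paths.  `tpsfit`
therefore models the measurement with a transport-accurate Monte Carlo
simulation of photon packets in a semi-infinite homogeneous medium:

* packets are launched over a 50 µm source spot into an 11.5° cone,
* free paths are exponential with mean $1/\mu_s$,
* scattering angles follow the Henyey–Greenstein phase function with
  anisotropy $g$,
* the refractive-index mismatch at the boundary causes Fresnel
  reflection/refraction,
* a packet is detected when it exits inside the detector fiber's spot and
  numerical aperture, and
* arrival times are histogrammed in 0.3125 ps bins up to 300 ps.

The model assumes a homogeneous medium, unpolarized light, no
fluorescence, and ignores the physical presence of the fibers in the
medium (their faces neither block nor reflect light).  The inverse
problem is solved by grid search: a look-up table (LUT) of simulated
TPSFs over a $(\mu_s', \mu_a)$ grid is compared, after convolution with
the instrument response function (IRF), against the peak-normalized
measured curve, and the cell with the minimum RMSE over a
fraction-of-peak fitting range wins.

```{r pipeline}
library(tpsfit)

lut <- simulate_lut(seq(1.2, 2.2, by = 0.1), seq(0.03, 0.07, by = 0.001),
                    config = sim_config(n_launched = 2.5e5, seed = 101))
irf <- synthesize_irf(fwhm = 3.44)
ps  <- preset("fig3a_rat")
m   <- forward_measurement(ps$props, ps$probe, irf,
                           noise_model("shot", 1e6, seed = 11),
                           shift_bins = 5L,
                           config = sim_config(n_launched = 1.2e6, seed = 202))
fit <- fit_optical_properties(m, irf, lut, fit_config(0.1, 0.1))
tidy(fit)
autoplot(fit)
```

## White Monte Carlo and the absorption axis

Simulating one run per $(\mu_s', \mu_a)$ cell would waste effort: in a
homogeneous medium, absorption only reweights each detected packet by
$W = W_0\,e^{-\mu_a L}$.  All transport is therefore simulated once per
$\mu_s'$ at $\mu_a = 0$ ("white" Monte Carlo), per-packet path lengths are
stored, and [rescale_to_mua()] generates the whole absorption axis
analytically.  A default-sized table (35 × 101 cells) costs 35 runs, not
3535.  Because $L = t\,c/n$ exactly in a homogeneous medium, per-record
reweighting and analytic bin-level reweighting agree to within one bin of
path discretization — a property the test suite asserts at the
$e^{\mu_a c\,\Delta t/n} - 1 < 0.7\%$ level.

## The scattering axis: similarity scaling

With $g$ and $n$ fixed, two media that differ only in $\mu_s$ produce
*identical* photon walks up to a spatial scale factor: free paths scale as
$1/\mu_s$ while every angular and boundary draw coincides.
`run_white_mc_scaled()` exploits this exactly: one walk ensemble at the
largest requested $\mu_s'$ is evaluated against one detector annulus per
target, scaled by $k_j = \mu_{s,j}/\mu_{s,\mathrm{ref}}$, and each
target's records are expressed in its own units.  Every LUT column then
benefits from the full photon budget, and neighbouring columns are
perfectly correlated — their differences are physical, not statistical,
which is what makes a 0.1 mm⁻¹ scattering grid resolvable at all.  The
single approximation is the source spot, whose 25 µm radius is not
rescaled (against a 1.25 mm separation); an immersed-probe geometry
introduces a fixed depth scale and is therefore excluded from scaling
(the phantom LUT uses one run per column with a common seed instead).

## Detection estimators and variance reduction

Detection of a 50 µm spot within an NA 0.2 cone at 1.25 mm is a
$\sim 10^{-6}$-per-photon event; the package layers four estimators/
techniques, all switchable in [sim_config()]:

* **Ring detector** (`detector = "ring"`, default): by azimuthal symmetry
  of the half-space problem, exits anywhere in the annulus at the
  source-detector distance stand in for the spot, reweighted by the
  spot/annulus area ratio $r_d/4\rho$.  The literal `"spot"` mode is kept
  as the reference oracle.
* **Escape estimator** (`estimator = "escape"`, default): at every
  scattering vertex near the surface, the expected weight escaping
  straight into the detection cone and landing on the detector —
  phase-function value × Fresnel transmission × $e^{-\mu_s d}$ integrated
  over the cone with `k_cone` directional samples — is credited as a
  detected record.  The analog `"crossing"` rule (detect on boundary
  exit) is the reference; the two agree in expectation, which the test
  suite checks directly.
* **Hot-zone splitting** (`n_split`, default 10): the first time a
  lineage scatters near the detector it splits into `n_split` copies of
  proportionally smaller weight.
* **One-step branching** (`n_branch`, default 16): at each vertex in the
  detection band, the *next* vertex's escape credit is averaged over
  `n_branch` virtual scatter-and-fly continuations, after which the walk
  adopts one of them unweighted (splitting with immediate
  Russian-roulette recombination).  This averages out the alignment
  lottery of the strongly forward-peaked ($g=0.9$) phase function, the
  dominant noise source, and improves information per CPU second by
  roughly an order of magnitude.  Both multiplicities were tuned by
  measuring replicate-to-replicate curve noise at fixed wall time.

Packets terminate on escape, on exceeding the 300 ps time of flight, or
as soon as the detection region is no longer reachable within the
remaining path budget (tallied as truncated — by construction such
packets can never contribute).  No Russian roulette acts on the walk
itself, so at $\mu_a = 0$ the detected/escaped/truncated weights sum to
the launched weight exactly in crossing mode; in escape mode the detected
weight is an expectation credit and the physical packet is still tallied
escaped or truncated.  Forced first interaction, sometimes used in
reflectance simulations, is a no-op here: the launch cone points into the
half-space, so the first flight cannot cross the interface.

Stored records are compressed above `max_records` by an unbiased weight
roulette (records below a floor are kept with probability $w/F$ at weight
$F$), which preserves every binned expectation while bounding memory.

Random numbers come from per-photon xoshiro256++ substreams derived from
the run seed, with separate walk and estimator streams; runs are
bit-reproducible for a given seed, and walk streams consume only
scale-invariant draws so that same-seed runs at different $\mu_s$ remain
spatially rescaled copies of each other.

## Fitting: convolution, registration, range, RMSE

Each candidate LUT curve is convolved with the IRF, peak-normalized, and
registered to the measurement by an integer bin-shift search
(`shift_search_halfwidth`, default ±16 bins = ±5 ps) because a measured
TPSF carries an arbitrary trigger offset.  The objective is the RMSE over
the fraction-of-peak range derived from the measured curve — the segment
between the 10 % (or 40 %) crossings on the leading and falling edges,
evaluated at bin resolution with no sub-bin interpolation, so RMSE values
are bit-reproducible.  The 40/40 range exists because a humped IRF (a
streak-camera lens reflection trailing the main response) contaminates
the falling edge below ~40 % of the peak.  Ties break toward smaller
$\mu_a$, then smaller $\mu_s'$, making the output deterministic.  A fit
is flagged accepted when its minimum RMSE is below `rmse_threshold`
(default 0.025).  Convolving first and normalizing second matches how
simulated curves are overlaid on peak-normalized measurements; the raw
LUT stores peak-normalized curves and the fit re-normalizes after
convolution, so the order cannot change the result.

## What the synthetic generator emulates — and what it does not

[forward_measurement()] composes the same physics forward: a white run at
the medium's scattering properties, Beer-Lambert rescaling to its
$\mu_a$, IRF convolution, an embedded integer bin shift (the trigger
offset the fitter must recover), shot noise, and peak normalization.
Shot noise is Poisson on bin counts scaled to a target total (default
protocols use $10^6$ counts), clipped at zero — streak-camera analog
effects (shading, jitter residuals, background) are not modelled.
[synthesize_irf()] produces a unit-peak Gaussian of 3.44 ps FWHM,
optionally with a falling-edge hump (default delay 10 ps, relative
amplitude 0.2, FWHM 3 ps) emulating the lens-reflection shape.

Two realism caveats matter when interpreting passing round trips.
First, a real measurement integrates billions of pulses, so its
pre-shot-noise curve is essentially the exact physical TPSF; a synthetic
measurement carries residual Monte Carlo noise from its finite photon
budget.  The measurement ensembles are therefore sized (about $10^6$
launched packets) so that this residual noise sits well below the
0.006–0.008 RMSE separating adjacent scattering columns; an opt-in
smoothing-spline projection (`smooth_df`) is available but is not part of
the default protocols, because the dominant residual noise is
low-frequency and survives smoothing.  Second, the generator shares the
package's own transport model, so round trips validate the inverse
machinery (including IRF handling, registration, noise robustness) but
cannot detect model error shared by both directions — fiber-face
reflections, layered media, polarization.  The liquid-phantom
configuration reproduces exactly the known instance of such model error:
with fibers immersed deeper than about 1 mm, light reflected at the
fiber/liquid interface contaminates real measurements, which is why the
tabulated protocol keeps the immersion at 0.5 mm.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `separation` | 1.25 | mm | ferrule-limited fiber spacing of the probe |
| `source_half_angle` | 11.5 | deg | launch cone, applied in the medium |
| `detector_na` | 0.2 | — | in-air acceptance sine of the 50 µm fiber |
| `bin_width` | 0.3125 | ps | streak-camera temporal resolution |
| `t_max` | 300 | ps | time-of-flight cutoff of the accumulation |
| `g` (tissue) | 0.9 | — | brain-tissue anisotropy used by the model |
| `n` (tissue) | 1.4 | — | brain-tissue refractive index |
| LUT $\mu_s'$ grid | 0.6–4.0 / 0.1 | mm⁻¹ | scattering search range |
| LUT $\mu_a$ grid | 0–0.1 / 0.001 | mm⁻¹ | absorption search range |
| `leading/falling_fraction` | 0.1/0.1 | — | fitting range (0.4/0.4 for humped IRFs) |
| `rmse_threshold` | 0.025 | — | fit acceptance bound |
| `shift_search_halfwidth` | 16 | bins | ±5 ps trigger-offset search |

The phantom preset uses its tabulated $g = 0.836$ and $\mu_s = 15.6$
mm⁻¹ ($\mu_s' \approx 2.56$ mm⁻¹), $\mu_a = 0.0231$ mm⁻¹, fibers immersed
0.5 mm; the liquid's refractive index is not tabulated and is taken as
1.33 (water), recorded in the preset's provenance.

## Numerical and design choices

* Time bins are half-open $[k\Delta t,(k+1)\Delta t)$ with
  $t = L n / c$, $c = 0.299792458$ mm/ps; curves carry bin centres.
* The Henyey–Greenstein cosine uses the closed-form inverse CDF; azimuths
  use Marsaglia rejection (draw counts depend only on the stream itself,
  preserving the similarity correspondence of same-seed walks).
* Threshold crossings, shifts and grid search are all evaluated at bin
  and grid resolution — no interpolation anywhere, by design, so every
  reported number is exactly reproducible.
* The detection cone is expressed in the medium as
  $\sin\theta \le \mathrm{NA}/n$; for surface contact this is equivalent
  to testing the refracted exit angle in air against the NA, and for
  immersed probes (detection plane inside the liquid, no refraction) the
  same in-medium criterion applies.
* For immersed probes the detection plane is crossed many times; in the
  analog mode a qualifying crossing absorbs the packet (it enters the
  fiber), while non-qualifying crossings pass freely since the fiber body
  is not modelled.
* Serialization (LUTs, white runs) uses schema-versioned JSON with
  17-significant-digit numbers, which round-trips doubles bit-exactly.
* Degenerate inputs are rejected early with named errors: zero curves,
  non-uniform time grids, mismatched bin widths, off-grid LUT queries,
  absorption in a white run.

## Problem sizes of the shipped protocols

The round-trip experiments use one similarity-scaled tissue ensemble
(2.5–3 × 10⁵ packets) for the 11-column LUT ($\mu_s'$ 1.2–2.2 mm⁻¹), a
2-target scaled ensemble of 1.2–1.5 × 10⁶ packets for the rat/monkey
measurement curves, four runs of 1.5–3 × 10⁵ packets for the phantom
LUT columns ($\mu_s'$ 2.4–2.7 mm⁻¹) and 6–7 × 10⁵ packets for the
phantom measurement; every ensemble stores well over 10⁵ detected
records.  These sizes fill the runtime the protocols are given.  Even
so, measured replicate noise of a processed curve (~0.010 RMSE per 10⁵
packets, shrinking as $1/\sqrt{N}$) and the per-column noise of the
look-up table remain comparable to the 0.006–0.010 separation between
adjacent scattering columns, so single-measurement round trips recover
the generating cell to within about one $\mu_s'$ grid step, with the
$\mu_a$ estimate displaced along the fit's ridge when the scattering
column is off by a step.  Grid-exact recovery would require both the
measurement and every column at several million packets.  This mirrors
the physical measurement: the study this protocol emulates reports a
$\mu_s'$ standard deviation of 65 % of the mean across animals against
~30 % for $\mu_a$ — the scattering axis is simply the weakly identified
one.

## Known limitations

* Homogeneous medium only: the gray/white layering of real cortex means
  estimates at depth mix layers (the depth-contribution analysis
  quantifies how much of the detected light stayed within the first
  millimetre).
* The scattering axis is intrinsically weakly identified by a single
  peak-normalized, freely-shifted curve: adjacent 0.1 mm⁻¹ columns differ
  by under 1 % RMS over the 10/10 range.  Recovery to one grid step
  therefore demands the noise control described above; real single
  measurements should be expected to carry substantially larger
  $\mu_s'$ uncertainty than $\mu_a$ uncertainty.
* No interpolation between grid cells: off-grid truths (the phantom's
  $\mu_s' = 2.56$) map to the nearest column.
* The diffusion-theory curve is an oracle for late times only; its
  failure near the source at early times is expected and is precisely the
  reason the forward model is Monte Carlo.
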