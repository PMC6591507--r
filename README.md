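# tpsfit

Estimation of tissue optical properties — the absorption coefficient
μa and the reduced scattering coefficient μs′ — from femtosecond
time-resolved reflectance measured with two optical fibers about a
millimetre apart, as used for in situ probing of cortical gray matter
and liquid phantoms.

At a source–detector separation of ρ = 1.25 mm the diffusion
approximation fails (the separation is ~2 transport mean free paths),
so the forward model is a variance-reduced Monte Carlo simulation of
photon packets in a semi-infinite homogeneous medium: exponential free
paths with mean 1/μs, Henyey–Greenstein scattering with anisotropy g,
Fresnel reflection/refraction at the boundary, detection by the fiber's
spot and numerical aperture, arrival times histogrammed in 0.3125 ps
bins up to 300 ps.  Transport is simulated once per μs′ at μa = 0
("white" Monte Carlo); each detected packet's stored path length L then
yields its weight at any absorption via Beer–Lambert,

  W = W₀ · exp(−μa · L),

so a look-up table (LUT) of temporal point spread functions (TPSFs)
over a (μs′, μa) grid — by default 0.6–4.0 mm⁻¹ in steps of 0.1 and
0–0.1 mm⁻¹ in steps of 0.001 — costs one simulation per μs′ only.
The inverse step convolves every LUT curve with the instrument response
function (IRF), peak-normalizes, registers by an integer bin-shift
search, and returns the grid cell minimising

  RMSE = sqrt( mean over the fitting range of (measured − simulated)² )

over the segment between the 10 % (or 40 %) of-peak crossings on the
leading and falling edges; a fit is accepted when RMSE < 0.025.

The package also provides a synthetic measurement generator (white MC →
Beer–Lambert → IRF convolution → trigger shift → shot noise), tabulated
scenario presets (rat/monkey gray and white matter, a latex/dye liquid
phantom), a time-resolved diffusion-theory oracle, a depth-contribution
analysis of the detected light, and a command-line front end.

## A worked example

Fit a synthetic rat-gray-matter measurement (μa = 0.052 mm⁻¹,
μs′ = 1.70 mm⁻¹) against a reduced LUT:

```r
library(tpsfit)

lut <- simulate_lut(seq(1.5, 1.9, by = 0.1), seq(0.04, 0.06, by = 0.001),
                    config = sim_config(n_launched = 3e5, seed = 101))
irf <- synthesize_irf(fwhm = 3.44)
ps  <- preset("fig3a_rat")
m   <- forward_measurement(ps$props, ps$probe, irf,
                           noise_model("shot", 1e6, seed = 11),
                           shift_bins = 5L,
                           config = sim_config(n_launched = 1.2e6, seed = 202))
fit <- fit_optical_properties(m, irf, lut, fit_config(0.1, 0.1))
fit
#> <op_fit> mua = 0.053 mm^-1, musp = 1.6 mm^-1
#>   RMSE 0.00825 over bins 53..166 (16.4..51.7 ps), shift +5 bins, accepted (< 0.025)
tidy(fit)
#> # A tibble: 2 x 3
#>   term  estimate unit
#>   <chr>    <dbl> <chr>
#> 1 mua      0.053 mm^-1
#> 2 musp     1.6   mm^-1
```

The fit reports the grid cell with the minimum RMSE, the fitting range
it used (here 10 %-of-peak to 10 %-of-peak), the recovered trigger
shift (the +5 bins embedded in the synthetic measurement), and whether
the RMSE clears the 0.025 acceptance bound.  At this problem size the
recovered cell sits within one μs′ grid step of the generating values
with the μa deviation coupled along the fit's ridge — the scattering
axis is intrinsically weakly identified by a single peak-normalized
curve (adjacent 0.1 mm⁻¹ columns differ by well under 1 % RMS over the
fitting range), so grid-exact recovery demands far larger photon
budgets; the vignette quantifies this.

`autoplot(fit)` overlays the measured and best-fit curves with the
fitting range shaded; `depth_contribution()` shows how much of the
detected weight stayed within the first millimetre below the fiber
tips:

```r
white <- attr(m, "white_run")
depth_contribution(white, mua = 0.052, time_window = c(0, 85))
#> # A tibble: 4 x 4
#>   depth_lo depth_hi  weight fraction
#>      <dbl>    <dbl>   <dbl>    <dbl>
#> 1        0        1 1.16     0.646
#> 2        1        2 0.542    0.301
#> 3        2        3 0.0857   0.0476
#> 4        3      Inf 0.00990  0.00550
```

## Command line

A thin launcher is installed at
`system.file("exec", "tpsfit", package = "tpsfit")`:

```sh
tpsfit synth --preset fig3a_rat --noise shot:1e6 --seed 7 \
       --out measured.tsv --irf-out irf.tsv
tpsfit build-lut --config config.yaml --musp-range 1.2 2.2 \
       --mua-range 0.03 0.07 --out lut.json
tpsfit fit --measured measured.tsv --irf irf.tsv --lut lut.json \
       --range 10 10 --threshold 0.025 --out report.yaml
```

Every run writes a machine-readable provenance block
(`<out>.prov.json`) with the command, arguments, seed and package
version.

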