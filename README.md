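# thzcryst

Quantifying crystalline polymorph content in drug tablets from terahertz
time-domain spectroscopy (THz-TDS) transmission scans, and tracking how it
evolves during accelerated aging.

## The problem

Amorphous nifedipine — a model for poorly soluble drugs formulated in their
glassy state — crystallizes in storage via a two-step route: the glass
first forms the metastable **beta** polymorph, which then converts to the
stable **alpha** polymorph, faster at higher temperature. THz-TDS resolves
the intermolecular phonon modes that tell these packings apart: alpha-NIF
absorbs at 1.09, 1.20 and 1.36 THz, beta-NIF (more weakly) at 0.95, 1.25
and 1.50 THz, and the amorphous form shows only a featureless rising
background.

`thzcryst` implements the full analysis chain from raw field transients to
time-resolved polymorph coefficients, plus a synthetic instrument so the
whole pipeline is testable without hardware:

1. **Conditioning** — DC-offset removal over the first 5 ps, Tukey
   windowing, zero-padded FFT (`remove_dc()`, `apply_window()`,
   `to_spectrum()`).
2. **Optics** — transfer function, phase unwrapping with branch
   correction, then
   `n(ν) = 1 + c Δφ / (2πνd)` and
   `α(ν) = −(2/d) ln[ ((n+1)²/4n) |T̃(ν)| ]`
   (`extract_optical_constants()`).
3. **Decomposition** — pure-form spectra fitted as three Gaussians plus a
   quadratic background (`fit_reference()`); aged spectra fitted as
   `f(ν) = A·Σ Gα exp(−((ν−ν₀α)/Δνα)²) + B·Σ Gβ exp(−((ν−ν₀β)/Δνβ)²) + O(2)`
   with all peak shapes frozen, solved as constrained linear least squares
   with `A, B ≥ 0` (`fit_crystallinity()`).
4. **Kinetics** — per-tablet series of A(t), B(t), every-4th decimation,
   replicate mean ± sd aggregation, reproducible beta-peak times
   (`build_series()`, `decimate_series()`, `aggregate_replicates()`,
   `peak_time()`).
5. **Synthetic studies** — closed-form sequential first-order kinetics
   with Q10 temperature scaling, slab transmission forward model, averaged
   detector noise, written to disk with a ground-truth manifest
   (`simulate_kinetics()`, `compose_absorption()`,
   `synthesize_waveform_pair()`, `generate_study()`).

## Worked example

Simulate a three-temperature aging study (48 h at 15-min cadence, five
replicate tablets per temperature) and run the complete pipeline on it:

```r
library(thzcryst)

study <- tempfile("study"); out <- tempfile("results")
cfg <- run_config(list(
  seed = 1,
  paths = list(study_dir = study, out_dir = out),
  simulate = list(duration_h = 48, cadence_min = 15),
  monitor = list(keep_every = 4)))
report <- run_study_pipeline(cfg)

report$beta_peak_times
#> # A tibble: 3 x 2
#>   temperature_C beta_peak_time_h
#>           <int>            <dbl>
#> 1            24               42
#> 2            30               28
#> 3            35               11

agg <- read.delim(file.path(out, "aggregate.tsv"))
agg[agg$time_h == 48, c("temperature_C", "A_mean", "B_mean")]
#>     temperature_C     A_mean    B_mean
#> 49             24 0.09857012 0.3039754
#> 98             30 0.50060072 0.3535463
#> 147            35 0.93255222 0.0612484
```

The beta coefficient peaks earlier the warmer the storage arm (28 h at
30 °C, 11 h at 35 °C; at 24 °C it is still rising when the 48-h window
ends), and by the end of the run the stable alpha form dominates in the
two warmer arms — the expected two-step amorphous → beta → alpha
crystallization. `plot_kinetics(agg)` draws the A/B time courses with
replicate sd ribbons; `autoplot()` methods exist for waveforms and
absorption spectra.

Single-scan analysis is one call deep:

```r
pair <- synthesize_waveform_pair(1.7, function(f) predict(nif_reference_alpha(), f),
                                 d_mm = 1.3, pulse = pulse_params(noise_std_au = 0))
oc <- extract_optical_constants(pair$sample, pair$reference)
fit_reference(oc, "alpha")$peaks
#> # A tibble: 3 x 3
#>   G_cm1 nu0_THz dnu_THz
#>   <dbl>   <dbl>   <dbl>
#> 1  4.00    1.09  0.0501
#> 2  3.00    1.20  0.0499
#> 3  6.00    1.36  0.0800
```

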