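# fdflim

Simulation, demodulation, restoration and analysis for high-speed two-photon
**frequency-domain fluorescence lifetime imaging (FD-FLIM)** with extended
depth-of-field volumetric projection.

Conventional 3-D FLIM scans a femtosecond Gaussian focus (axial extent ≈2 µm)
plane by plane; volumetric projection microscopy swaps in an axially extended
Bessel-type excitation (tens of µm) and acquires a whole shallow volume in a
single 2-D scan. FD-FLIM recovers lifetimes by modulating detection at the
80 MHz laser repetition rate and demodulating four phase-shifted channels into
per-pixel **phasor** coordinates. Fast, low-dwell acquisitions are noisy, so a
learned restoration network maps them toward slow, frame-averaged ground
truth. This package implements that entire chain on synthetic data:

- **Phasor core** — closed-form multi-exponential phasors, universal
  semicircle, phase/modulation lifetimes, reference-fluorophore calibration
  (`phasor_from_decay()`, `lifetimes_from_phasor()`, `estimate_calibration()`).
- **Instrument simulator** — four-phase analog homodyne mixing with
  Poisson–Gaussian noise, gain, dark offset, instrument phase/modulation
  error, frame averaging, fast (2 µs, 256², 1 frame) and ground-truth
  (10 µs, 512², 5 frames) protocols — a 100× pixel-time ratio
  (`simulate_acquisition()`, `demodulate_four_phase()`).
- **Optics** — Gaussian two-photon axial response (paraxial pupil integral)
  and flat-top Bessel profiles; exact phasor-space projection of labelled
  3-D volumes (`gaussian_axial_profile()`, `project_volume()`).
- **Scenes & dynamics** — seeded phantoms (rods, network, vessels, somata),
  calcium-sensor decays, transient/bleaching/drift time series, paired
  fast/slow datasets (`make_phantom()`, `make_timeseries()`,
  `render_paired_dataset()`).
- **Restoration** — attention-augmented encoder–decoder with 2× pixel-shuffle
  head and bicubic skip, trained per channel (CoBi loss for `g`, random
  perceptual loss for `s`/intensity) with hand-verified backpropagation
  (`build_network()`, `train_model()`, `enhance_and_reanalyze()`).
- **Analysis** — phasor histograms and elliptical gating, Lorentzian
  lifetime-histogram fits, ΔF/F, trace smoothing, kymographs
  (`phasor_histogram()`, `lorentz_fit()`, `delta_f_over_f()`).
- **IO / CLI** — float TIFF stacks with JSON sidecars, validated YAML run
  configs, and a `fdflim` command-line tool (`write_stack()`, `run_cli()`).

## Worked example

Phasor of a 4 ns mono-exponential decay at 80 MHz — it falls exactly on the
universal semicircle:

```r
library(fdflim)
mod <- modulation_context(80e6)
p <- phasor_from_decay(decay_spec(1, 4000), mod)
# g = 0.1983108, s = 0.3987275
(p$g - 0.5)^2 + p$s^2 - 0.25
# 0
```

Recover a rhodamine 6G standard (4080 ps) through the full noisy chain,
calibrating against rhodamine B (1680 ps), at ~10⁴ photons/pixel with
injected instrument error (phase 0.12 rad, modulation loss 0.85):

```r
err <- instrument_error(phase_offset = 0.12, modulation_loss = 0.85)
noise <- noise_model(gain = 1.5, read_noise_sigma = 2, dark_offset = 10)
protocol <- acquisition_protocol(dwell_time_us = 2, image_size = 64L)
map_emit <- uniform_emission_map(64L, 5000, decay_spec(1, 4080))
map_ref  <- uniform_emission_map(64L, 5000, decay_spec(1, 1680))
frame_emit <- simulate_acquisition(map_emit, protocol, mod, err = err,
                                   noise = noise, seed = 1L)
frame_ref  <- simulate_acquisition(map_ref, protocol, mod, err = err,
                                   noise = noise, seed = 2L)
cal <- estimate_calibration(demodulate_four_phase(frame_ref), 1680, mod)
# <calibration_factors> phase 0.120054 rad, modulation 0.850057 (ref 1680 ps)
field <- apply_calibration(demodulate_four_phase(frame_emit), cal)
lt <- lifetimes_from_phasor(field, mod)
ok <- lt$valid & is.finite(lt$tau_phase)
weighted.mean(lt$tau_phase[ok], field$intensity[ok])
# 4079.2 ps over 4096 pixels (truth 4080)
```

Optics sanity numbers:

```r
spec <- beam_spec("gaussian", numerical_aperture = 0.75, wavelength_nm = 920,
                  refractive_index = 1)
axial_fwhm(gaussian_axial_profile(spec, seq(-6, 6, 0.01)))
# 2.0864 um
axial_fwhm(bessel_axial_profile(beam_spec("bessel"), seq(-40, 40, 0.05)))
# 35 um
speed_ratio(protocol_gt(), protocol_fast())
# 100
```

## Restoration at a glance

The scaled-down training recipe exercised by the test suite (200 synthetic
64²→128² pairs, 50 epochs, 16² crops, g trained with
`loss_config(pixel_term_weight = 10)`, ~11 min on one CPU) beats the bicubic
2× baseline on every held-out pair, all three channels (median PSNR/SSIM):

| channel   | network        | bicubic        |
|-----------|----------------|----------------|
| intensity | 37.1 dB / 0.993 | 19.3 dB / 0.756 |
| g         | 20.0 dB / 0.873 | 17.4 dB / 0.824 |
| s         | 20.6 dB / 0.911 | 17.6 dB / 0.823 |

On a held-out pair, τ_φ dispersion over uniform-lifetime regions shrinks
from 130.1 to 122.7 ps while the lifetime-histogram mode stays at 2530 ps
against a 2500 ps truth. See `tests/testthat/test-acceptance.R` (criterion 7)
for the exact reproducible run.

## Documentation

The methods vignette (`vignettes/fdflim-methods.Rmd`) derives every model in
the pipeline: phasor algebra, the homodyne mixing and noise model,
calibration, axial profiles and projection, scene dynamics, the network and
losses, and the analysis layer.

## License

MIT — see `LICENSE`.
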