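# echopatch

Simulation, beamforming and cardiac-function analysis for wearable
conformal ultrasound arrays.

Wearable ultrasound patches — small, skin-conforming phased arrays worn
on the chest — promise continuous echocardiography: B-mode views of the
left ventricle, M-mode wall tracking, and beat-by-beat stroke volume,
ejection fraction and cardiac output, without a sonographer holding a
probe. Evaluating such a device raises questions that are naturally
studied in silico: how do plane-wave, mono-focus and wide-beam
compounding transmit strategies trade off resolution and signal-to-noise
ratio on a 32-element, 3 MHz, 12.4 mm aperture? How much does chest
curvature distort the phase of a flexible array, and how completely does
knowing the element positions repair it? How faithfully can cardiac
indices be recovered from segmentation masks of a beating ventricle?

`echopatch` is an R toolkit for those questions, aimed at ultrasound and
biomedical-imaging researchers. It provides:

- **Array geometry** — flat linear arrays (default: 32 elements, 0.4 mm
  pitch = 0.78 wavelengths, 0.3 x 2.3 mm elements, 3 MHz, 55%
  bandwidth), orthogonal Mills-cross configurations, and mapping onto
  measured surface profiles (cylinders or sampled arc-length/height
  CSV) with arc-length-preserving element placement.
- **Transmit design** — plane-wave, mono-focus and wide-beam
  (virtual-source diverging wave) delay laws; compounding sequences such
  as the 97 angles spanning ±37.5° (exact step 0.78125°).
- **Forward simulation** — Born single-scattering RF channel data with
  element directivity, spherical spreading and seeded noise; RMS
  transmitted-pressure field maps
  (`x_RMS = sqrt((x_1^2 + ... + x_n^2)/n)`).
- **Image formation** — delay-and-sum receive beamforming on analytic
  signals with curvature-corrected element positions, coherent
  compounding, log compression `I_new = 20 log10(I_old)`, sector scan
  conversion, and M-mode extraction.
- **Characterization metrics** — FWHM resolutions (axial, lateral,
  elevational), distance accuracy `1 - |d/d_truth - 1|`, dynamic range by
  linear extrapolation of grey value vs contrast to 0 and 255,
  `CNR = |mu_in - mu_out| / sqrt(sigma_in^2 + sigma_out^2)`, SNR vs
  depth, 6-dB penetration depth, fractional bandwidth, insertion loss,
  and relative resistance R/R0.
- **Cardiac pipeline** — M-mode interface tracking, LVIDd/LVIDs and
  fractional shortening `(LVIDd - LVIDs)/LVIDd`, Simpson method-of-disks
  LV volumes from mask stacks, per-cycle EDV/ESV/SV/EF/HR/CO, and
  Bland–Altman agreement (limits `mean ± 1.96 sd`).

Results come back as tibbles with `tidy()`/`glance()` methods and
`autoplot()` figures; the hot loops (channel simulation, beamforming,
field maps) are in C++ via Rcpp.

## Worked example

Image a 50 mm wire with the full 97-angle wide-beam compounding
sequence, then recover cardiac indices from a beating-ventricle mask
stack:

```r
library(echopatch)

array <- linear_array() # 32 el, 0.4 mm pitch, 3 MHz, 55% bw
round(pitch_in_wavelengths(array$pitch, array$centre_frequency), 2)
#> [1] 0.78

seq97 <- compounding_sequence(array) # 97 angles over +/-37.5 deg
wires <- wire_phantom(tibble::tibble(x = 0, z = 50e-3))
rf    <- simulate_channel_data(wires, array, seq97)
grid  <- pixel_grid(8e-3, 10e-3, 161, 101, z_min = 46e-3)
bmode <- envelope_logcompress(beamform_compound(rf, grid))
resolution_set(bmode, wires)
#> # A tibble: 1 x 7
#>    x_mm  z_mm peak_x_mm peak_z_mm axial_fwhm_mm lateral_fwhm_mm detected
#> 1     0    50         0        50         0.414            2.76 TRUE

lv  <- beating_lv(edv = 120, esv = 50, heart_rate = 75,
                  frame_rate = 30, n_cycles = 4)
vol <- volume_waveform(lv$masks, lv$pixel_mm, lv$frame_dt)
glance(indices_from_waveform(vol))
#> # A tibble: 1 x 7
#>   n_cycles edv_ml esv_ml sv_ml ef_pct hr_bpm co_lpm
#> 1        2   120.   50.0  69.9   58.3     75   5.25

dynamic_range(c(-15, 15), c(38.7, 159.8))$dynamic_range_db
#> [1] 63.2
```

The wire localizes exactly at its true position; the axial FWHM
(0.41 mm) is set by the pulse bandwidth while the lateral FWHM (2.8 mm)
reflects diffraction from the 12.4 mm aperture at 50 mm depth. The
cardiac block recovers the generator's ground truth (EF 58.3%, SV 70 ml,
HR 75 bpm) from rasterized masks alone; `glance()` averages the two full
cycles bounded by detected end-diastolic peaks.

A command-line wrapper over the same pipeline lives at
`inst/cli/echopatch.R`:

```sh
Rscript inst/cli/echopatch.R --config inst/extdata/demo_config.yaml \
  --stage all --out out/
```

## Documentation

The methods vignette (`vignettes/echopatch.Rmd`) describes the acoustic
model and its assumptions, the beamforming and apodization choices, the
synthetic phantoms and what passing tests on them do and do not show
about real hardware, and the package's numerical conventions.
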