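---
title: "Simulating and characterizing a wearable cardiac ultrasound imager"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and characterizing a wearable cardiac ultrasound imager}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echopatch)
```

`echopatch` models the imaging chain of a small wearable phased-array
echocardiography patch: array geometry, transmit sequencing, pulse-echo
simulation, delay-and-sum image formation, image-quality metrics, and
derivation of cardiac performance indices. This vignette is the
package's account of the underlying science: the models, their
assumptions, the tunable parameters, and the design decisions taken
where more than one defensible choice existed.

## Coordinate and unit conventions

One convention is used everywhere: x lateral, y elevational, z axial
and positive into tissue, origin at the aperture centre; SI units
internally (metres, seconds, Hz), with millimetres only at I/O
boundaries and in printed tables. The default speed of sound is
1540 m/s (standard soft-tissue value, configurable). The default array
is the wearable-imager aperture: 32 elements at 0.4 mm pitch
(0.78 wavelengths at 3 MHz — fine enough to keep grating lobes out of a
±37.5° steered sector), element width 0.3 mm, elevational element
length 2.3 mm, 55% fractional −6 dB bandwidth. The long elevational
element is modelled as a single rectangle whose directivity narrows the
beam out of plane; its internal subdivision into wired sub-elements is
a hardware detail with no acoustic consequence at this level of
modelling.

## Acoustic model

The forward model is Born single scattering. A transmit event is a set
of per-element delays (minimum zero) and apodization weights. Three
laws are provided: plane waves (`delay = (x sin θ + z cos θ)/c`),
mono-focus (arrivals coincide at the focal point; default focal depth
60 mm, a mid-ventricular choice, configurable), and wide beams
generated by a virtual point source a distance `z_v` behind the
aperture. The default `z_v = (A/2)/tan(span/2)` (8.08 mm for a 75°
span) opens the geometric cone of the 0° event just wide enough to
cover the full steered sector, which is what a compounding sequence
needs from every event. The compounding sequence defaults to 97 angles
from −37.5° to +37.5°; 97 inclusive points make the exact step
75/96 = 0.78125°, which prints as 0.78°.

The excitation pulse is a Gaussian-modulated cosine whose Gaussian
spectral envelope has the stated −6 dB fractional bandwidth; the
waveform is truncated at ±4 temporal standard deviations and evaluated
through a dense lookup table (about 1000 points per carrier period,
interpolation error ~1e−5 of peak) in the compiled inner loops.

For a scatterer p, the transmit arrival time is
`t_tx(p) = min_e(delay_e + |p − r_e|/c)` — the first arrival of the
transmitted wavefront. This single definition covers plane, focused and
diverging laws on flat or curved arrays without per-law wavefront
algebra; the transmit amplitude uses the spreading and directivity of
the element attaining the minimum, keeping the cost linear in the
element count. Echo amplitude is
`reflectivity × (1/r_tx)(1/r_rx) × D_tx × D_rx`, with D the far-field
rectangular-aperture factor `sinc(w sinθ_x/λ) sinc(L sinθ_y/λ)` times a
soft-baffle obliquity term. There is no multiple scattering and no
frequency-dependent tissue attenuation: the model's purpose is
point-spread, contrast and geometry behaviour, not calibrated
pressures. Dead-zone and ring-down effects are likewise out of scope.

Field maps report the root mean square
`x_RMS = sqrt((x_1² + ... + x_n²)/n)` of the superposed element pulses
over a common time record; multi-event sequences pool the squared sums
of all events before the square root, so the compound field is the
overall effect of all transmissions.

Sampling defaults: RF records at 20 MHz (≥ 4× the carrier), record
lengths rounded up to FFT-friendly sizes (the Hilbert transform of a
prime-length record costs quadratic time), linear interpolation
whenever a continuous arrival time meets a sampled trace.

## Image formation

Receive beamforming is delay-and-sum on analytic signals: each trace is
Hilbert-transformed once, and each pixel sums
`w_e · s_e(t_tx(p) + |p − r_e|/c)` over elements. Supplying the true
(curved) element positions of a conformal array is exactly the phase
correction a flexible patch requires; beamforming the same data under
the nominal flat positions shows the cost of ignoring curvature.
Compounding is coherent (pre-envelope, uniform weights by default);
envelope detection takes the magnitude of the complex sum, normalizes
to the frame maximum, compresses as `I_new = 20 log10(I_old)` and clips
at a −60 dB display floor. Pixel spacings follow the inclusive-extent
convention `Δy = depth/(N_vertical − 1)`, `Δx = width/(N_lateral − 1)`.
A polar-to-Cartesian scan converter (bilinear, default 5× upsampling,
out-of-sector pixels masked at the floor) is provided for sector data;
Cartesian-grid beamforming is the default path because it feeds the
metrics directly while implementing identical physics.

**Receive aperture (a deliberate deviation).** The natural first choice
for receive apodization — a dynamic aperture with f-number 1.5 and Hann
taper — was implemented and found unfit for this device's sector
geometry: with a 12.4 mm aperture, any pixel beyond |x| ≈ z/3 (for
example wires 30–40 mm off axis at 50 mm depth, which the nine-wire
characterization row contains) has *no* element within an f/1.5
acceptance cone, and pixels near the cone edge see a fragmented,
asymmetric aperture that splits the point spread. The default is
therefore phased-array practice: the full aperture with a fixed Hann
window. The angle-based f-number cone (acceptance
`|tan θ| ≤ 1/(2f#)`, Hann-tapered, with a full-aperture fallback for
pixels outside every cone) remains available via the `f_number`
argument for linear-array-style studies.

**PSF measurement on steered beams.** For an off-axis wire the point
spread function is oriented along the beam, not along the image axes: a
horizontal cut through a wire imaged at 38.7° steering mostly measures
the projected *axial* lobe and would paradoxically report the sharpest
"lateral" width at the sector edge. `resolution_set()` therefore
measures the axial profile along the range direction (aperture centre
towards the peak) and the lateral profile along the cross-range
direction perpendicular to it; on axis these reduce to the usual
vertical and horizontal cuts. Elevational resolution is measured by
sweeping a point scatterer in y at fixed depth and taking the FWHM of
the peak-amplitude-versus-offset curve — the in-silico analogue of the
rotated-wire bench method, probing the same elevational beam profile.

## Phantoms and what they do (and do not) show

`wire_phantom()` models sub-resolution monofilament wires as ideal unit
point scatterers, with presets for a nine-wire lateral row at 50 mm
(offsets 0, ±10, ±20, ±30, ±40 mm) and an on-axis depth ladder. Exact
depths of the corresponding bench layouts vary between phantoms; the
presets are representative, not metrologically matched.

`inclusion_phantom()` fills the field with uniformly random scatterers
whose Gaussian reflectivities are scaled by `10^(contrast_dB/20)`
inside cylindrical inclusions. Density is expressed per nominal
resolution cell (1.0 mm lateral × 0.5 mm axial, the mid-depth cell of
the default aperture); the default 20 per cell is comfortably in the
fully-developed-speckle regime (≥ 10). The six-object contrast set
defaults to {−15, −6, −3, +3, +6, +15} dB: extremes and lowest pair as
in typical greyscale targets, middle pair chosen symmetric.

`beating_lv()` renders an apical long-axis section of a prolate
spheroid (fixed 2:1 long-to-short axis ratio) whose volume follows a
smooth periodic cycle: cosine contraction over 30% of the cycle, a 10%
end-systolic plateau, cosine filling over 30%, and a 30% end-diastolic
diastasis. Only EDV, ESV and heart rate are treated as recoverable
truth — the cycle *shape* is invented for realism, and the plateaus
guarantee that frame sampling hits the extreme volumes. Defaults
(EDV 120 ml, ESV 50 ml, 75 bpm, 30 Hz, 4 cycles, 0.5 mm pixels) are
textbook resting values for a healthy adult and standard echo frame
rates.

Passing tests on these generators shows that the *pipeline* is correct
under its own physics: that compounding, curvature correction, CNR
ordering and index recovery behave as the theory predicts. It does not
certify hardware numbers — transducer sensitivity, real chest-wall
aberration, reverberation clutter and segmentation-model errors are all
absent — which is why bench-measured quantities (absolute resolutions,
~35 dB transducer SNR, measured accuracies, penetration beyond 16 cm)
are treated as property targets for the simulation analogue, not as
values to reproduce.

## Metrics conventions

FWHM uses linear interpolation between the samples straddling half
maximum, walking outward from the peak (ties broken toward the peak);
profiles with two equal maxima or boundary peaks are rejected rather
than guessed. CNR is computed on linear (pre-compression) intensities —
the dB-domain alternative is a display-referred quantity and is left to
the caller via `linear_intensity()`. Dynamic range fits grey value
against contrast by least squares over all provided points (with two
points this is the exact line) and reports `255/slope`, the contrast
span between the extrapolated grey levels 0 and 255. SNR is
peak-amplitude over noise-ROI RMS in dB — the definition is stated
explicitly because the bench convention is often left implicit.
Penetration depth is the deepest wire whose peak exceeds the local
same-depth background mean by 6 dB. Insertion loss applies the
quartz-reflection (1.9 dB) and water-attenuation
(2.2×10⁻⁴ dB mm⁻¹ MHz⁻², two-way) corrections with d in mm and f in
MHz, as conventionally printed.

## Cardiac pipeline

The M-mode interface tracker is deliberately simple and fully
documented: per frame, each interface is the intensity-weighted
centroid of the pixels within 6 dB of the local ridge maximum inside a
search window around the previous position; jumps are clamped to the
window, and frames with no ridge 6 dB above the display floor are
flagged and linearly interpolated. LVID(t) = far − near; cycles are
delimited by end-diastolic peaks.

LV volume uses the single-plane Simpson method of disks (clinical
convention, n = 20 disks by default): the long axis is the principal
axis of the mask pixels, and each slab's disk diameter is estimated
from the slab's pixel area divided by its thickness. The area-based
diameter was chosen over the min–max extent because extent widths are
biased upward by roughly one pixel per edge, which at 0.5 mm pixels
inflates volumes by several percent; the area estimator is unbiased to
well under 1%. An area–length alternative (`8A²/(3πL)`) is available
behind a flag. Peak detection for cycle delimitation collapses runs of
tied samples (rasterized volumes tie exactly on plateaus) and requires
a prominence of 10% of the waveform range. Bland–Altman agreement
reports the mean difference, limits `mean ± 1.96 sd` (sample sd), and
the fraction of points within the limits.

## Numerical choices and degenerate inputs

- Delays are normalized to minimum zero within each event; arrival
  times at a focus agree to 1e−12 s.
- All-zero frames cannot be log-compressed (no normalization exists)
  and are rejected; empty phantoms simulate to all-zero records, which
  is valid.
- Empty masks yield volume 0 with a flag; multi-component masks are
  processed whole rather than silently cropped.
- Pixels whose round-trip time exceeds the record contribute zero and
  are counted in a coverage mask.
- Scan conversion clamps fractional indices at the sector boundary with
  a 1e−9 tolerance so exact-edge samples are kept.
- Seeded operations (speckle phantoms, additive channel noise) require
  explicit integer seeds; identical seeds give bit-identical output.

## Problem sizes used in the test suite

The shipped tests run the full 97-angle compounding sequence
throughout. Resolution studies beamform localized windows (typically
6–8 mm × 10–18 mm at 50 µm axial sampling) around each wire; the CNR
study simulates one 4 mm inclusion per contrast at 30 mm depth in a
16 × 16 mm speckle field at density 20 per resolution cell; the
curvature study uses a 100 mm cylinder, a mid-range chest-curvature
scale. The whole suite completes in a few minutes on one CPU.

## Known limitations

- Single scattering only: no reverberation, no clutter, no harmonic
  propagation, hence contrast metrics are optimistic relative to tissue.
- No attenuation model by default; depth-dependent gain effects are
  absent.
- The elevational dimension enters only through element directivity;
  imaging grids live in the y = 0 plane.
- The interface tracker assumes the two walls remain the brightest
  ridges inside their search windows; it is a reference implementation,
  not a robust clinical tracker.
- Segmentation itself (the neural-network stage that produces LV masks
  from images in a deployed system) is out of scope; mask stacks are
  inputs, whether generated or user-supplied.
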