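---
title: "Models and methods behind osteoraman"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind osteoraman}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteoraman)
```

`osteoraman` analyzes polarized Raman measurements of the apatite ν1
phosphate band (~960 cm⁻¹) around osteons in cortical bone. This
vignette is the package's own account of the science it implements: the
models and their assumptions, the parameters that matter, the numerical
choices, and what the synthetic validation does and does not establish.

## 1. Spectral preprocessing

Spectra are two-column wavenumber/intensity series; scans and maps are
long CSV tables keyed by stage position (μm). Three preprocessing steps
are provided.

**Wavenumber calibration** (`calibrate_wavenumber()`). High-resolution
acquisitions drift; a reference lamp recorded alongside each measurement
pins the axis. One reference line fixes an offset; two or more fix an
affine correction (offset plus dispersion rescale) by least squares.
Affine is the minimal model covering both drift and a linear dispersion
error; higher-order axis distortion is out of scope. Re-applying the
same line list is the identity — the fitted transform and line list are
recorded in the spectrum metadata, and calibration is skipped when the
incoming list matches.

**Background subtraction** (`subtract_background()`). The baseline is
estimated only from the window's edge regions (default: the outer 10% at
each end), either as the straight line through the edge means
(`"linear-endpoints"`) or as a polynomial fitted to the edge samples.
Fitting only the edges keeps the peak itself out of the baseline; the
edges must therefore be chosen peak-free. Negative residuals are
permitted — clipping would bias subsequent fits.

**FFT smoothing** (`smooth_fft()`). An ideal low-pass: Fourier
components above `cutoff` × Nyquist are zeroed. The DC bin is never
touched, so the mean is preserved exactly. The FFT requires uniform
sampling; non-uniform axes are linearly resampled to their median
spacing first (opt-in, because resampling is itself a mild smoother).

## 2. Pseudo-Voigt sub-band deconvolution

The ν1 region (fit window 920–990 cm⁻¹ by default) is modelled as a sum
of 1–4 pseudo-Voigt profiles, each the *linear combination*
`amplitude · [η L + (1−η) G]` of a Lorentzian and a Gaussian sharing one
centre and one FWHM, both unit peak height. This form — rather than the
convolutive Voigt — is the common reading of "Lorentzian–Gaussian"
deconvolution in the bone-Raman literature, and it makes the reported
height, FWHM and η directly testable: the profile equals `amplitude` at
the centre and `amplitude/2` at centre ± FWHM/2 for every η.

Defaults encode the three-component structure of the osteonal ν1 band:
start centres at 948.9 / 958.0 / 971.9 cm⁻¹ with the dominant component
at 958.0. Bounds keep centres inside the window, FWHM in [1, 40] cm⁻¹,
heights ≥ 0 and η in [0, 1]. The optimizer is Levenberg–Marquardt
(`minpack.lm`), with 5 jittered restarts (centres ±1.5 cm⁻¹, widths
±20%, fixed RNG seed); the lowest residual wins and ties prefer fewer
parameters pinned at a bound. "Intensity" means fitted peak height, the
quantity used in rotation series; integrated areas are also reported
(`band_area()` has the closed form).

Per-position map layers (`extract_scan_layers()`) fit every spectrum in
a scan and report height/centre/FWHM for one chosen sub-band. Cells
whose *total* fitted ν1 amplitude falls below 5% of the scan's median
are marked empty: these are cavity cells (Haversian canal, lacunae)
where the mineral signal vanishes and band parameters would be noise.
The 5% floor is a deliberate explicit rule where practice is usually
implicit; it is configurable.

Statistical note: with 1% relative noise the two stronger components'
centres are recovered to well under ±0.3 cm⁻¹, while the weak 971.9 cm⁻¹
shoulder (height ~1/7 of the main band) carries proportionally larger
uncertainty (~0.2 cm⁻¹ median error) — a Cramér–Rao limitation, not an
optimizer one.

## 3. Orientation from polarized rotation series

### Forward model

In the laboratory frame (z along the Haversian canal axis, incident
polarization fixed along y), the backscattering geometries are
"parallel" (analyzer ∥ y, z(yy)z̄) and "cross" (analyzer ∥ x, z(xy)z̄).
The ν1 mode of hexagonal apatite has the uniaxial tensor diag(a, a, b)
in the crystal frame, so a crystallite with unit c-axis **c** scatters

> I = (e_s · T e_i)², T = a I + (b − a) **c c**ᵀ.

Only b/a matters for relative intensities. A population is described by
its mean-axis Euler angles — out-of-plane tilt θ ∈ [0°, 90°] from the
canal axis and in-plane azimuth ψ ∈ (−90°, 90°], measured from the
incident polarization at zero stage rotation — plus the maximum-entropy
ODF of the misorientation β between individual c-axes and the mean axis:

> f(β) = A exp(−λ₂P₂(cos β) − λ₄P₄(cos β)), ∫₀^{π/2} f sin β dβ = 1.

With this sign convention negative multipliers mean alignment; the
convention was fixed by verifying that it maps each tabulated (λ₂, λ₄)
pair onto its printed Hermans parameters before any fitting machinery
was built. The azimuth of crystallites *about* the mean axis is taken
uniform (a transversely isotropic population, consistent with
fibril-wound texture); the third Euler angle φ is unobservable under a
uniaxial tensor and fixed at 0. Both `psi` and `psi + 180°` describe the
same director; ψ is reported wrapped into (−90°, 90°].

Because the intensity is quartic in **c**, the orientation average
depends on the ODF only through its second and fourth Legendre moments —
the Hermans parameters P₂⟨cos β⟩ and P₄⟨cos β⟩. Two consequences:
(i) the moments, not the raw multipliers, are the physically constrained
outputs (the fitter reports the unique max-entropy preimage of the
fitted moments); (ii) no higher-order texture information is accessible
from this band.

### Identifiability and the tensor ratio

The relative modulation of the parallel and cross rotation curves
constrains a *combination* of tilt θ, ODF spread and tensor anisotropy
b/a. Treating b/a as a free parameter leaves θ on a near-flat likelihood
ridge: in simulation at 2% noise, equally good fits placed θ anywhere
between ~10° and ~76° for a true 20.9°, with the alternative optima's
curves differing from the truth's by less than 0.007 relative units.
`fit_angular_series()` therefore takes `b_over_a` as a *known* input —
the practical workflow takes the ν1 tensor ratio from single-crystal
selection-rule calibrations — and defaults to 2.5, a representative
apatite ν1 anisotropy. With b/a known, simulated recovery at 2% noise is
sharp (median errors ≈ 0.3° in θ, 0.2° in ψ, 0.005 in P₂ in the
package's validation study). Passing `b_over_a = NULL` restores the
fully free fit for exploratory use; the report then carries
`tensor_free = TRUE` and θ should not be over-interpreted.

A second degeneracy is flagged rather than fitted through: when the
fitted curves carry essentially no angular modulation (near-isotropic
ODF, or a mean axis lying along the canal axis so rotation changes
nothing), or when per-series constants explain the data nearly as well
as the full model, the report sets `degenerate = TRUE` — the Euler
angles are then arbitrary and the flag says so.

### Numerics

The orientation average uses Gauss–Legendre quadrature in cos β
(64 nodes on [0, 1], where the sin β solid-angle weight is absorbed by
the substitution) × a uniform periodic 32-node azimuth grid —
trapezoidal rules are spectrally accurate for periodic integrands. An
optional convergence check doubles both orders and accepts the doubled
result if they disagree by more than 10⁻⁶ relative. Hermans moments use
adaptive quadrature (`integrate`, tolerances below 10⁻⁸) with the
maximum exponent subtracted before exponentiation, so multipliers of any
magnitude are overflow-safe. The ODF normalization constant A is
reported as the reciprocal of ∫₀^{π/2} e^{−λ₂P₂−λ₄P₄} sin β dβ; other
conventions (solid-angle 2π factors, degree measures) rescale A without
affecting moments, so A values from other software need not match.

Fitting is joint Levenberg–Marquardt over (θ, ψ, λ₂, λ₄) plus one free
scale per series; each model curve, like each data series, is normalized
to its own maximum ("relative Raman intensity"), with the scales
absorbing acquisition differences. Multi-start covers θ ∈ {15°, 45°,
75°} × two ψ candidates read off the parallel-series extremum (the
incident polarization aligns with the c-axis projection there when
b > a, or is normal to it when b < a).

## 4. Probe response function

The confocal probe is modelled as the in-plane Gaussian kernel
exp(−2r²/R²). All convolutions are *normalized* Gaussian-weighted
averages, so constants pass through exactly and the finite grid is
handled by renormalizing over available support; masked cells (cavity
interiors) are excluded from numerator and denominator alike. The
written infinite integration limits of the kernel average are not
executable on finite grids — renormalization over support is the
implementable reading, and it is exactly what the normalizing
denominator does.

"Probe diameter" is *defined* as 2R under this kernel convention. Other
conventions (full width at 1/e², FWHM = R√(2 ln 2)) differ by fixed
factors; any comparison of diameters across instruments or publications
must check which convention is in use.

A Gaussian PRF crossing a step (bulk mineral level to zero inside a
cavity) produces an error-function edge,
I(x) = I_in + (I_out − I_in)/2 · (1 + erf(√2 (x − x₀)/R)), and
`fit_prf_from_edge()` fits exactly that. The intensity approach to a
canal is often described loosely as exponential decay; the erf form is
what the Gaussian kernel mathematically produces, and fitting the true
form is what lets R be recovered without bias (noiseless round-trip bias
≈ 0.1% in the validation study). Profiles without a flat plateau on each
side of the transition are rejected — without plateaus the bulk level
and hence R are unconstrained.

Numerically, the 1-D convolution samples the field on a grid anchored at
multiples of the spacing (default R/12, kernel truncated at 4R) rather
than centred on each evaluation point; anchoring matters when the field
has sharp features, which would otherwise be sampled inconsistently
across evaluation points and bias edge fits. Against the closed-form
attenuation of a cosine, exp(−B²R²/8), the operator is accurate to
better than 10⁻⁶ relative at spacing R/10.

## 5. Twisted/oscillating plywood mixture

Out-of-plane tilt profiles θ(x) along a radial coordinate (x = 0 at the
canal wall) are modelled as

> θ(x) = Vt(x) · At cos(Bt x + Dt) + (1 − Vt(x)) · [A₀ cos(B₀ x + C₀) + D₀]

with twisted-fraction envelope Vt(x) = ht e^{−gt x} ∈ [0, 1]. The
symbol roll of the source model also lists a constant `Ct` that never
appears in the printed expression; the implementation uses Dt as the
twisted phase and omits Ct. Units: amplitudes At, A₀ and offset D₀ in
degrees (matching tilt-angle axes), phases Dt, C₀ in radians (keeping
cosine arguments dimensionless), frequencies in rad/μm. The reported
motif levels θ_t and θ₀ are the mean of each motif's term over the
fitted range (≈ 0 and ≈ D₀ respectively for full periods).

`fit_plywood()` fits the *probe-convolved* mixture to raw profiles —
whether measured profiles should be deconvolved before model fitting is
ambiguous in practice, and fitting the convolved model to raw data is
the statistically cleaner direction (no noise amplification). In-depth
variation is neglected: tilt is nearly constant along the confocal axis.

Initialization is the crux: frequencies come from the profile's
periodogram (quadratic detrend to remove the decaying-envelope baseline,
Hann window against leakage, zero-padding to 2048, top 3 distinct
peaks), and for each candidate frequency pair the amplitudes, phases and
offset are solved *linearly* (the model is linear in At cos Dt,
−At sin Dt, A₀ cos C₀, −A₀ sin C₀, D₀ at fixed envelope and
frequencies) before the nine-parameter Levenberg–Marquardt polish.
Among near-equal optima (within 5% in residual) the fit prefers
solutions with fewer parameters at bounds — a motif parked at a bound
usually signals a label-swapped or saturated representation of the same
curve.

Two identifiability guards: the profile must span ≥ 2 periods of the
coarser *contributing* oscillation (an absent motif's frequency is
unconstrained and does not count); and `twisted_identifiable = FALSE`
when the twisted fraction is below 0.05 everywhere, contributes no
visible amplitude, or is a small non-decaying constant — in the last
case any cosine can live in either slot and the two-motif split is
arbitrary. No universal parameter set across osteons is expected or
encoded; profiles are fitted individually.

## 6. Synthetic scenes and what validation shows

The generators produce every input with known truth: ν1 spectra on a
920–990 cm⁻¹ grid at 0.1 cm⁻¹ (triple-monochromator resolution) with
additive Gaussian noise; 1 μm-resolution maps with a circular canal,
a first lamella carrying a −1.5 cm⁻¹ centre shift, FWHM broadening and a
2.7× enhancement of the 948.9 cm⁻¹ sub-band, and lamellar intensity
modulation (default period 5 μm, the midpoint of the 3–7 μm lamella
range); rotation-series pairs with multiplicative noise and an optional
depth-dependent ψ lag; and probe-convolved tilt profiles with additive
angular noise. Noise models are conventional minimal choices (additive
on counts, multiplicative on relative intensities, additive in degrees);
no instrument noise characterization is encoded, and Poisson photon
statistics are deliberately not emulated. Tilt presets: the `"x-axis"`
scene stays inside a 10–30° envelope, the `"y-axis"` scene inside
16–26° and is oscillating-dominated; the `"mixed"` scene (Vt(0) = 0.6)
is the benchmark for parameter recovery, where both motifs carry
identifiable amplitude. The default tensor ratio b/a = 2.5 and the ODF
multipliers used in examples are representative of strongly textured
bone apatite.

Validation study sizes, chosen to characterize estimator behaviour at
realistic noise: 20 seeds per recovery study (orientation: 19 angles
over 180°, 2% multiplicative noise; bands: 1% additive noise; probe:
2% noise on a 65-point edge scan; plywood: 1° noise on a 61-point,
30 μm profile), with *median* errors compared to tolerance — medians
characterize the estimator without letting a single unlucky noise draw
dominate. The quadrature moments are independently cross-checked against
10⁷-draw Monte-Carlo sampling of the ODF, and the orientation average
against brute-force Monte-Carlo orientation draws.

What passing these studies does **not** show: real spectra contain
collagen/amide bands, fluorescence backgrounds, cosmic rays and
instrument drift that the generators do not emulate (despiking and
dark-current correction are out of scope); real lamellar geometry is not
circularly symmetric; and real ODFs need not be of maximum-entropy form
— the moments remain well-defined descriptors, but the fitted λ pair is
then a summary, not the true distribution.

## 7. Known limitations

- θ recovery requires a trusted b/a; with `b_over_a = NULL` the tilt is
  effectively unidentifiable from a single rotation-series pair.
- Carbonate substitution modes, E-symmetry analysis and absolute
  intensity calibration are out of scope; so is the defect-chemistry
  interpretation of band shifts (the package maps positions and widths,
  it does not model why they move).
- The PRF is in-plane only; no z-resolved deconvolution is attempted
  (the in-depth extent, ~10 μm, is carried as metadata).
- Proprietary instrument file formats are not read; plain two-column
  text and long CSV are the interchange floor.
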