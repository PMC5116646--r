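---
title: "Dual-energy kV/MV metal artifact reduction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-energy kV/MV metal artifact reduction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Kilovoltage CT of a patient or phantom with a large metal implant is
corrupted by beam hardening and photon starvation: rays through the metal
arrive at the detector with (nearly) zero counts, their log-projections are
wrong, and filtered back projection (FBP) spreads the damage into dark and
bright bands around the implant. With the elliptical steel insert modelled
here, dark bands form along the ellipse's long axis, bright bands along its
short axis, and the cylindrical air hole at the centre of the insert
disappears entirely — it reads above 3000 HU and is indistinguishable from
metal. Megavoltage cone-beam CT (MVCBCT) of the same anatomy penetrates the
metal and resolves the hole, but is noisier and softer, with less accurate
soft-tissue HU.

`dualmar` corrects the kV image using the MV image as side information.
The pipeline is:

1. **Calibrate** MV HU to pseudo-kV HU through a piecewise-linear curve
   fitted to paired rod measurements on a density phantom
   (`fit_calibration()`, `apply_calibration()`).
2. **Register** the MV slice rigidly onto the kV grid when the inputs are
   not already aligned (`resample_to_grid()`, `rigid_register()`).
3. **Segment** metal on the (pseudo-kV) MV image by thresholding at
   3000 HU (`segment_metal()`) — the MV image shows the metal without
   artifacts, so its threshold mask is trustworthy.
4. **Fuse** the two modalities into a prior image (`fuse()`), replace its
   metal with water (`make_prior()`).
5. **Replace** the metal trace of the measured kV sinogram with the
   forward-projected prior, blended so the corrected sinogram is
   continuous with the measured data at both ends of every trace segment
   (`metal_trace()`, `replace_trace()`).
6. **Reconstruct** by FBP and re-insert the metal HU from the MV image
   (`fbp()`, `reinsert_metal()`).

`mar_correct()` orchestrates all of it and returns every intermediate.

## The fusion model

Per pixel, with $I_{KV}$ the kV image and $I_{MV}$ the calibrated,
registered MV image:

$$R(i,j) = \frac{|I_{KV} - I_{MV}|}{|I_{KV} + I_{MV}|}, \qquad
  \text{denominator replaced by } 1 \text{ where } I_{KV}+I_{MV}=0,$$

$$w(R) = \mathrm{clamp}\!\left(\frac{R - R_{lo}}{R_{hi} - R_{lo}},\,0,\,1\right),$$

$$I_{fused} = w_d\,[\,w\,I_{MV} + (1-w)\,I_{KV}\,] + (1-w_d)\,I_{KV},$$

so the MV share of a pixel is $w_d\,w$. The deviation weight $w$ grows
where the modalities disagree — which near metal means the kV value is
artifact-corrupted and the MV value is right. The distance weight $w_d$ is
a Gaussian low-pass of the binary metal mask, rescaled to 1 on the metal,
confining the MV contribution to the metal neighbourhood where artifacts
live; far away the fused image reverts to the sharper, quieter kV image.

### Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `threshold_hu` | 3000 | HU | metal segmentation threshold (on the MV image) |
| `r_lo`, `r_hi` | 0.05, 0.40 | — | deviation-weight ramp: agreement below `r_lo` keeps kV, disagreement above `r_hi` takes MV |
| `sigma_mm` | 30 | mm | Gaussian width of the distance weight |
| `fill_hu` | 0 | HU | tissue value written into the prior's metal region |
| `filter` | `"hann"` | — | FBP apodisation for noisy data (`"ramp"` for noise-free oracles) |
| `trace_epsilon` | half pixel diagonal | cm | minimal metal path length flagging a sinogram bin |

**Why `sigma_mm = 30`.** The surrogate datum for a trace bin is the line
integral of the prior along the whole ray, so the prior must be trustworthy
across the entire artifact zone (which extends 2–3 cm from the metal), not
just at its edge. A width of 10 mm leaves $w_d < 0.1$ beyond ~1.7 cm and
the prior stays close to the streaky kV values across most of that zone;
with 30 mm the weight covers it. An experiment with an oracle prior (the
true phantom with metal removed) confirms the mechanism: the oracle prior
removes ~94 % of the band error, a 10 mm fusion prior ~32 %, a 30 mm
fusion prior ~64 %. Because $w$ vanishes wherever kV and MV agree, the
wider support does not degrade accurate regions: far-field error is
unchanged. The cost of a wide $w_d$ is bounded injection of MV noise into
pixels whose deviation ratio is noise-triggered (around 0 HU the ratio
$R$ is ill-conditioned: tiny sums inflate it); that effect is visible but
small compared to the artifact it removes.

### Trace replacement

For each view, the trace segments are maximal runs of bins whose metal
path length exceeds `trace_epsilon`. Within a segment spanning bins
$jj+1, \dots, jj+\Delta$:

$$P^{cor}_b = P^{prior}_b + \frac{(jj+\Delta+1-b)\,(P^{KV}_{jj} -
  P^{prior}_{jj}) + (b-jj)\,(P^{KV}_{jj+\Delta+1} -
  P^{prior}_{jj+\Delta+1})}{\Delta+1}.$$

The two boundary offsets are linearly blended across the segment, so the
corrected sinogram joins the measured data continuously at both ends and no
step artifact is introduced at the trace boundary. Bins outside the trace
are never touched (bit-exact data fidelity; tested). A segment that touches
the detector edge has only one usable boundary bin and falls back to a
one-sided constant offset; the case is counted on the result's
`edge_segments` attribute. Multiple segments per view (non-convex or
multiple implants) are replaced independently, each with its own boundary
bins.

### Baselines

* **LIMAR** interpolates the kV sinogram linearly across each trace
  segment using only the boundary bins (equivalent to the blend above with
  a zero prior — the package implements both routes independently and
  tests their algebraic identity).
* **NMAR** divides the kV sinogram by a prior's sinogram (floored at
  `epsilon`), interpolates the normalised trace, and multiplies back. The
  kV-only prior is a three-class segmentation (air < −500 HU < soft
  tissue < 500 HU ≤ bone kept as-is, classes set to class means) of the
  LIMAR reconstruction *before* metal re-insertion.
* **NMAR-MV** is NMAR with the registered pseudo-kV MV image used directly
  as the prior; keeping the metal (and hole) in the prior is what lets the
  normalisation carry the hole structure through the trace.

Both kV-only baselines re-insert metal from the kV image's own threshold
mask — which, since the kV image cannot see the hole, re-inserts metal-like
values over it. That is the behaviourial signature the package's
acceptance tests check: LIMAR and NMAR leave the hole region above
3000 HU; fusion MAR and NMAR-MV restore it.

## The scanner simulator

Every stage is testable without any external data because the package
ships a parallel-beam CT simulator.

* **Geometry.** 2D parallel beam, views uniformly spaced over 180°,
  detector bins covering the grid diagonal at the pixel pitch. The method
  operates per reconstructed slice, where fan/cone geometry adds nothing
  to the correction math.
* **Attenuation model.** Per material,
  $\mu(E) = \rho\,(a\,E^{-3} + b\,\sigma_{KN}(E))$: a photoelectric term
  and a Klein–Nishina Compton term, with water anchored at 0.20 cm⁻¹ at
  70 keV and steel (ρ = 7.8 g/cm³) given the strong photoelectric
  component that makes its kV attenuation an order of magnitude above its
  MV attenuation. This is the minimal model that produces genuine beam
  hardening without attenuation tables.
* **kV beam.** A six-point discrete spectrum between 45 and 100 keV
  standing in for a filtered 120 kV tube spectrum, 10⁵ photons per bin.
  The top of the spectrum matters: leaving several percent of fluence at
  ≥105 keV lets enough photons through 2–3 cm of steel that the central
  hole becomes partially visible, which real 120 kV scans of this insert
  do not show. With the default spectrum the hole region reconstructs
  near 3900 HU — lost in the metal, as it should be.
* **MV beam.** A single 1000 keV effective energy, 400 photons per bin,
  1.5 mm Gaussian detector blur. The photon budget is deliberately small:
  MV imaging at a few MU on a low-DQE panel detects orders of magnitude
  fewer quanta than diagnostic kV CT, and the package targets a
  reconstructed MV noise of 2–4× the kV noise in uniform regions
  (measured ≈ 2.1–2.4×).
* **Photon starvation.** Poisson counts that come out zero are clamped to
  0.5 counts before the log (standard practice), which caps measurable
  line integrals at $\ln(2 N_0) \approx 12.2$ — the mechanism that erases
  the hole.
* **Units.** Forward projection and FBP convert HU to attenuation through
  $\mu = \mu_{ref}(1 + HU/1000)$ with $\mu_{ref}$ the fluence-weighted
  water attenuation of the beam (recorded on each sinogram), so simulated
  sinograms and prior projections live on one scale.

### What the generator does not emulate

No scatter, no detector afterglow or electronic noise floor, no 3D
cone-beam effects, no real tube spectra, no patient anatomy (the phantom
is piecewise constant). Passing the end-to-end tests therefore shows that
the correction machinery behaves as designed under the physics the
simulator does contain — beam hardening, starvation, Poisson noise,
detector blur — not that it is clinically validated. In particular the
homogeneous phantom flatters interpolation-based baselines (LIMAR/NMAR
band errors are small here); their known failure mode, complex anatomy
crossing the trace, is outside what this phantom can show.

## Numerical choices

* FBP uses the band-limited discrete ramp kernel (frequency response
  $2\,\mathrm{Re}\,\mathcal{F}[h]$ of the classical spatial kernel),
  optionally apodised by Shepp–Logan or Hann windows, with projections
  zero-padded to a power of two ≥ 2× the bin count.
* The forward projector averages 3 sub-rays across each detector bin
  aperture (box response); without it, sharp-edged objects project with
  view-dependent edge errors above 1 %.
* Ray sampling step is half the pixel pitch; line integrals use bilinear
  interpolation. Both kernels are compiled (Rcpp).
* Registration is an exhaustive coarse grid (±10 mm / ±10°, 2 mm / 2°
  steps) refined by halving down to 0.1; deterministic, derivative-free,
  and sufficient for rigid phantom alignment. Metal can be masked out of
  the MSE metric because artifacts differ between modalities.
* Calibration extrapolates linearly beyond the outermost rods — metal HU
  lies far above the densest rod, and clamping would destroy its pseudo-kV
  value.
* Degenerate inputs: an empty metal mask short-circuits every MAR variant
  to a plain round-trip reconstruction; an empty distance-weight mask
  returns an all-zero map with a warning.

## Problem sizes

The study conditions mirror a 512 × 512 slice at 0.59 mm pitch; the
package's tests and the acceptance script run the same phantom at
256 × 256 / 1.18 mm with 360 views, where every qualitative and
quantitative property of interest (band deficits/excesses, hole loss and
recovery, noise ratios) is stable across seeds and a full four-method
comparison completes in well under two minutes. The calibration phantom is
simulated noise-free at 160 × 160 (the rod means are means over ~450
pixels each; noise-free beams make the fitted knots exact).

## Known limitations

* The pseudo-kV calibration is fitted on tissue-range rods and linearly
  extrapolated to metal; the pseudo-kV steel HU (~6200) underestimates the
  photoelectric-heavy true kV steel HU (~22600). The corrected image's
  metal region therefore reports the MV-derived value, not the kV one —
  consistent with re-inserting the segmented MV metal, but a known bias if
  absolute metal HU is needed downstream.
* $R$ is ill-conditioned where $I_{KV}+I_{MV}\approx 0$ (water); the
  deviation weight can fire on noise there. The distance weight bounds the
  blast radius to the metal neighbourhood.
* One metal object per slice is assumed by the geometric evaluation
  regions (not by the correction itself, which handles any mask).
* 2D parallel-beam only; DICOM I/O is not provided — images travel in the
  package's plain-text fixture format.
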