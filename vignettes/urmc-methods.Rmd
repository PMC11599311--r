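---
title: "Unified respiratory motion correction for TOF PET/CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unified respiratory motion correction for TOF PET/CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Respiratory motion degrades thoracoabdominal PET/CT in three coupled ways:
it blurs lesions over 10–20 mm of diaphragm travel, it breaks the match
between the emission data and the CT-derived attenuation map (producing the
"banana" artifacts at the liver dome), and it leaves the final PET image
misaligned with the CT it is fused with. `urmc` implements a unified,
data-driven correction chain for all three at desk scale, together with the
synthetic ground truth needed to test every link of that chain:

1. **respiratory signal** — extracted from TOF list-mode events alone,
2. **amplitude gating** — equal-count rebinning into `G = 4` gates,
3. **gated NAC reconstruction and per-gate attenuation maps**,
4. **reference-gate selection** — mutual information against the CT,
5. **gated AC reconstruction, non-rigid gate-to-reference registration and
   consolidation** (the motion-corrected image),
6. **single-modal PET–CT alignment** in attenuation-map space,
7. **evaluation** — SUV metrics per lesion, per-organ motion amplitudes.

This vignette records the models, the tunable parameters and the design
decisions behind each stage; everything quantitative it mentions is computed
by the package's test-suite or by `scripts/acceptance.R`, never asserted
from memory.

## The 4D breathing phantom

The phantom is a parametric thoracoabdominal model on a 64×64×96 grid of
4-mm voxels (X lateral, +Y anterior, +Z superior; world coordinates in mm
from the scanner FOV centre). An elliptic-cylinder torso (semi-axes
110×80 mm) carries a wall rind (chest wall above the diaphragm, abdominal
wall below), two lungs, liver, spleen, stomach and kidneys as ellipsoids,
plus spherical lesions; an optional FDG-avid brain analog sits superior to
the torso, outside any respiratory region of interest. Attenuation is
rendered directly at 511 keV (soft tissue 0.096 cm⁻¹, lung 0.03 cm⁻¹, air
0 — standard values; no Hounsfield simulation) and activities are FDG-like
concentrations (soft tissue 5 kBq/mL, liver/spleen 6, kidneys 8, lungs 1,
lesions `uptake_ratio` × soft tissue, 8× by default).

**Breathing model.** The normalised phase is
\(s(t) = \left(\tfrac{1-\cos 2\pi t/T}{2}\right)^k\) with period `T = 4` s
and shape exponent `k = 2`, which lengthens end-expiration the way free
breathing does; `s = 0` is the end-expiration reference and `s = 1` peak
inspiration. Optional seeded per-cycle amplitude jitter and a slow
superior–inferior drift (mm/min) are available but default to zero so the
programmed motion is exactly reproducible. The motion itself is a
*separable analytic pulling field*: organs below the diaphragm (and
diaphragm-adjacent lesions, purely, so lesion activity is conserved
exactly) translate inferiorly by `si_amplitude · s(t)` (default 20 mm);
lung tissue stretches linearly between the displaced diaphragm and the
static apex; the anterior wall advances by `ap_amplitude · s(t)` (default
10 mm) with a ramp across the wall band. Because every frame is re-rendered
analytically at the displaced geometry, the stored truth field *is* the
rendering map: warping the reference frame by it reproduces any phase frame
to interpolation accuracy (the suite checks ≤ 5% normalised RMSE).

The choice of 10 mm anterior wall excursion, the organ layout and the
activity values are plausible mid-range figures for an adult torso; the
waveform is a clean model of free breathing, not a fit to any patient
population — real traces show cycle-to-cycle variability, apnoeas and
cardiac contamination that the default phantom does not emulate. Passing
the suite therefore demonstrates correctness of the chain under controlled
motion, not clinical performance.

## TOF list-mode simulation

The scanner is a cylinder (ring radius 300 mm, axial half-length 200 mm)
with a Gaussian TOF kernel of 45 mm FWHM positional resolution quantised to
10-mm bins — representative numbers, all configurable. Emissions are drawn
per 10-ms step (finer than the 100-ms signal binning, so intra-bin motion
is negligible) from the phase frame nearest the programmed phase,
isotropically directed, intersected with the cylinder, and thinned by the
Beer–Lambert survival `exp(-∫μ)` along the full chord, so NAC images carry
genuine attenuation artifacts. `mean_rate_cps` is the *accepted* trues
rate: per-step accepted counts are Poisson at that rate and emissions are
rejection-sampled until each step's target is met, so the realised count
concentrates at `rate × duration` with no pilot bias. There are no randoms
or scatter (documented limitation), and timestamps are uniform within their
step. The file format is a JSON header plus fixed-width 60-byte records
(int32 ms timestamp + 7 little-endian doubles), with a CSV debug dialect;
round trips are bit exact and the TOF sign convention (positive toward
detector 2) is stated in the header.

A desk-scale bed position is 60 s at 10 kcps ≈ 6×10⁵ trues. That is two to
three orders of magnitude below a clinical acquisition; it keeps the full
chain runnable in minutes on one CPU, at the price of count-starved images.
Several numerical choices below exist specifically to behave well in that
regime.

## Reconstruction

List-mode TOF MLEM/OSEM with a matched projector pair: the forward model is
a fixed-step (2 mm) ray integral weighted by the Gaussian TOF kernel
(truncated at 3.5σ) centred on the event's TOF position; the backprojector
scatters with the identical sampling, so the two are exact adjoints (the
suite verifies ⟨Ax, y⟩ = ⟨x, Aᵀy⟩ to 10⁻⁶). Attenuation enters through the
sensitivity image, a Monte-Carlo backprojection of 10⁵ LORs sampled
uniformly on the cylinder, weighted by `exp(-∫μ)` — an approximation to the
true geometric sensitivity, smoothed (σ 8 mm) because the underlying
quantity is smooth while the MC estimate is not. Voxels below 2% of the
peak sensitivity (the ill-conditioned axial FOV edges) are frozen at zero:
their multiplicative update would divide by almost nothing and diverge.
Trilinear interpolation treats each voxel as extending half a voxel beyond
its centre (nearest clamp in the rim), so uniform-slab line integrals match
Beer–Lambert over the physical thickness.

Defaults are 3 iterations × 8 subsets (time-interleaved events) and a
Gaussian post-filter of σ 2.5 mm (≈ 6 mm FWHM, the usual clinical noise
control); with one subset the Poisson log-likelihood is non-decreasing, and
a two-voxel toy system converges to the brute-force maximum-likelihood
solution. A global calibration rescales each image so its total activity
matches the acquisition's cross-calibration constant (the phantom's total
activity, carried in the list-mode header the way a scanner calibration
factor would be); every method in a comparison shares the factor, so method
contrasts are shape-driven, not scale-driven.

## Respiratory signal

Events are TOF-positioned (LOR midpoint plus the signed offset) and only
those inside the **rROI** contribute: the body cavity — largest connected
non-air component of the CT μ map, hole-filled, eroded by a 15-mm rind and
restricted axially from the lung apex to 350 mm below the lung base (the
abdominopelvic extent) — dilated 50 mm anteriorly so the breathing wall
stays inside. The cavity rule is a deliberately simple, phantom-tuned
surrogate for a learned segmenter and is pluggable
(`pipeline_config(cavity_fn = ...)`); an FDG-avid structure outside the
rROI (the brain analog) measurably degrades the unrestricted signal, which
is the rROI's purpose.

The COD trace averages in-rROI positions every 100 ms; empty bins are
flagged and linearly interpolated. Conditioning of `C_y` (the
anterior–posterior component, the one that tracks the chest wall):
subtract a slow baseline (linear trend plus a zero-phase Butterworth
low-pass at 1.5/30 Hz — a moving median distorts a clean sinusoid by ~20%
RMS over non-integer cycle counts, so it was rejected), then a zero-phase
Butterworth low-pass (order 3) at 0.6 Hz, which passes all physiological
breathing rates while suppressing the COD count noise that dominates at
desk-scale rates; finally median-centre and fix polarity so larger
amplitude = more inspiration (+Y wall motion raises `C_y`; the convention
is recorded, and gating is invariant to it). Traces shorter than 30 s of
valid bins, or with variance below 0.01 mm², are rejected as containing no
respiratory signal.

## Gating

Amplitude-based equal-count gating at bin granularity: bins sorted by
conditioned amplitude (ties by time), cumulative *total* event counts cut
at the quartile targets, with each boundary chosen among the few candidate
bin edges nearest its quantile to minimise the maximum pairwise gate-count
difference (ties toward the lower edge) — a deterministic rule an
independent sort-and-accumulate oracle reproduces exactly. Exactly equal
counts are impossible at bin granularity; the imbalance stays within the
largest single-bin count under the study conditions. Gate 0 is
end-expiration; flipping the signal's sign permutes labels but not the
partition. A device-signal arm (`signal_source = "device"`) feeds the
programmed waveform directly, emulating a hardware respiration monitor for
the data-driven-vs-device comparison.

## Attenuation maps and the reference gate

The per-gate μ estimator is a two-tissue rule behind a pluggable interface
(`mu_estimator`): body = threshold at 20% of the robust maximum of the
(σ 4 mm smoothed) gated NAC image, largest component, hole-filled, set to
soft-tissue μ; lung = connected low-activity components (< 0.65 × the
median body activity) in the eroded thoracic interior larger than 50 mL.
The thresholds are tuned on the phantom — NAC images suppress deep tissue,
which is why the lung search is restricted axially — and a phantom-truth
oracle (`oracle_mu`) stands in wherever downstream stages should be tested
in isolation from μ-estimation error. The reference gate maximises the
joint-histogram mutual information (32 bins over the robust intensity
range, natural log) between each gated μ map and the CT μ map; ties break
to the lower index. With a deep-inspiration CT this selects the
top-amplitude gate.

## Registration, consolidation, alignment

Both registration problems are single-modal, so a demons-style SSD method
is appropriate: multi-resolution (3 levels), symmetric forces (mean of the
fixed and warped-moving gradients, which handles the ~15-mm gate
displacements better than fixed-only forces), per-iteration step cap of one
voxel, fluid smoothing σ 0.5 voxel and field regularisation σ 1.25 voxels,
on robust-max-normalised, lightly smoothed images. The returned field is
the *pulling* convention (output voxel x samples the moving image at
x + d(x)) in world mm; the best-SSD field over the iteration history is
kept, so the result never increases the SSD, and non-overlapping supports
yield a zero field with a warning.

Gate-to-reference fields are estimated on lightly filtered copies of the
gated AC images and applied to the raw ones (estimate-on-smoothed,
apply-on-raw); consolidation is the count-weighted voxelwise mean — with
equal-count gates essentially the plain mean, keeping activity units — and
the single clinical post-filter is applied at the end of the chain rather
than per gate. The PET–CT alignment registers the reference-gate μ map to
the CT μ map and warps the consolidated image into CT space; because the
expected residual field is small and smooth, the alignment uses a coarser,
more heavily regularised setting (2 levels, σ 4 voxels) — with a
deep-inspiration CT the surrogate μ's diaphragm uncertainty otherwise
imprints spurious local deformations. Mutual information between the warped
reference μ and the CT never decreases. Field inversion (needed to reslice
CT-space organ masks into the reference frame) is the standard fixed-point
iteration to 0.1 mm.

## Evaluation

Body-weight SUV with the dose decay-corrected to scan start (configurable
off); lesion size categories small (0.1–5 mL], medium (5–10 mL], large
(> 10 mL), with the shared 5-mL endpoint closed on the small side and
volumes ≤ 0.1 mL excluded; paired two-sided t-tests between methods
(all-zero differences → t = 0, p = 1; zero-variance nonzero differences →
p → 0). Lesion ROIs default to the phantom truth mask rendered at the CT
phase; a 41%-of-peak threshold segmenter is available as a surrogate for a
learned lesion segmenter. The axial FWHM measure averages profiles over the
ROI's in-plane footprint before measuring the half-maximum width — a
single-column profile is noise-dominated at these counts.

Per-organ motion amplitude follows the inverse-alignment protocol: organ
masks in CT space are resliced into the reference-gate frame with the
inverted alignment field, and the amplitude is the maximum magnitude of the
inspiration–expiration field inside the deformed mask, one value per organ
per subject, then averaged across subjects. The extremes field is the
registration between gate 0 and gate G−1, anchored on whichever extreme is
nearer the reference gate so the field lives in the frame the masks are
resliced into. Note a structural property of the statistic: gate images are
time averages, so the extremes field measures the *difference of gate mean
positions* (≈ 0.85–0.9 of the programmed amplitude for this waveform with
four equal-count gates), before any registration loss.

## Problem sizes and known limitations

The suite and `scripts/acceptance.R` use: one 60-s, 10-kcps bed position
for the signal/gating/motion-correction checks and the motion-free
reference; twenty-second, 4–5-kcps acquisitions for the ten reference-gate
recovery runs and the auxiliary alignment runs; and a cohort of default
60-s subjects (five in the suite, three in the acceptance script) for the
amplitude statistic. These sizes were chosen as the smallest that leave
each check limited by the method rather than by counts.

Honest limitations worth restating: trues-only simulation (no randoms,
scatter or PSF); a two-tissue μ surrogate without bone; desk-scale counts
mean all lesion statistics are noisy at the single-ROI level; and the
middle amplitude gates retain intra-gate motion (the time-in-phase
distribution is bimodal, so the central quartiles each span a wide
amplitude band), which bounds how much lesion SUV any consolidation of four
gates can recover relative to a static acquisition — the package measures
that gap rather than hiding it.

## A worked example

```{r example}
library(urmc)

run <- run_pipeline(pipeline_config(seed = 1), verbose = TRUE)
glance(run)        # event counts, gate balance, reference gate, MI gain
tidy(run)          # per-lesion, per-method SUV table
autoplot(run)      # coronal NMC vs uRMC

# device-signal arm and method comparison over the same lesions
dev <- run_pipeline(pipeline_config(seed = 1, signal_source = "device"))
compare_methods(list(
  NMC = dplyr::filter(tidy(run), method == "NMC"),
  uRMC = dplyr::filter(tidy(run), method == "uRMC"),
  `VSM-uRMC` = dplyr::filter(tidy(dev), method == "uRMC")))
```
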