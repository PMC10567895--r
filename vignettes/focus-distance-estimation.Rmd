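---
title: "Estimating camera-to-subject focus distance from face photographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating camera-to-subject focus distance from face photographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facefd)
library(dplyr)
```

## The problem

In craniofacial superimposition, a skull is photographed and compared
against an antemortem face photograph. The comparison is only anatomically
meaningful when the camera geometry matches, and the hardest component to
match is the focus distance (FD): the distance from the camera's image
receptor (sensor) plane to the subject, here referenced to the outer eye
corner (exocanthion). FD is the sole driver of perspective distortion when
the face is centred in the field of view, and the antemortem photograph's
FD is almost never documented. `facefd` estimates it from measurements
that *are* available in the photograph itself.

## The estimator

A fronto-parallel feature of physical length $L$ (mm), photographed at
focus distance $d$ (mm) through a lens of focal length $f$ (mm) onto a
sensor with pixel pitch $y$ (mm), subtends approximately

$$x = \frac{f\,L}{d\,y} \quad \text{pixels},$$

by similar triangles. Inverting this for the frontal view with the
palpebral fissure length (PFL, the endocanthion-exocanthion distance) as
the feature gives

$$\hat d = \frac{f\,A}{x\,y},$$

where $x$ is the *measured* PFL in pixels and $A$ the *population mean*
PFL in mm. The substitution of $A$ for the subject's unknown true PFL is
what makes the method usable on photographs of deceased or unavailable
subjects, and it works because the trait's population standard deviation
is small (about 1.2 mm against a mean of roughly 31 mm). The price is an
irreducible per-subject error analysed below.

Profile photographs do not show the palpebral fissure, so the profile
chain uses the pupil-chord-to-stomion (PCS) distance, the near-vertical
span from the inter-pupil line to the mouth midpoint, which survives a
partial head rotation. A paired frontal photograph of the same subject
with the same camera calibrates the subject's real-life PCS through the
ratio rule

$$\widehat{PCS}_{mm} = A \cdot \frac{pcs_{px}}{pfl_{px}},$$

(both pixel lengths from the one frontal image, both features treated as
lying in one fronto-parallel plane), and the profile FD follows by the
same inversion with $(A, x)$ replaced by
$(\widehat{PCS}_{mm}, pcs_{px}^{profile})$. Algebraically the two
estimates coincide exactly on noiseless same-geometry pairs — both reduce
to $d \cdot A / PFL_{true}$ — which the test suite verifies to machine
precision; in practice the profile chain accumulates three pixel
measurements' noise instead of one.

```{r worked}
cam <- camera_spec("demo", focal_length_mm = 100, pixel_size_mm = 0.005)
pri <- anatomical_priors() # A = 30.7 mm, SD = 1.2 mm
estimate_fd_frontal(200, cam, pri)
estimate_fd_profile(400, estimate_pcs_mm_from_frontal(205, 410, pri), cam)
```

### Model variants

The field convention measures FD from the sensor plane, but published
descriptions of the estimator do not state whether the image distance is
accounted for. Both defensible readings are implemented and recorded in
every estimate:

* `"simple"` (default): the similar-triangles form above, identifying the
  lens-to-object distance with the FD — the $d \gg f$ approximation.
* `"thin_lens"`: the FD is the object-to-sensor distance $d + v$ with
  $1/f = 1/d + 1/v$ and magnification $m = v/d$, giving
  $d_{FD} = f\,(2 + m + 1/m)$, solved in closed form (the demagnifying
  root $m = 2/(q + \sqrt{q^2 - 4})$, $q = d_{FD}/f - 2$, numerically
  stable for $q \gg 2$). It requires $d_{FD} > 4f$, the closest focusing
  geometry with a real solution, and rejects magnifications $\ge 1$.

The two differ by roughly twice the focal length — irrelevant at portrait
distances with short lenses, visible for a 120 mm lens at 1 m. Neither is
asserted to be "the" published implementation; the default is the simple
form that matches the method's usual similar-triangles description.

### Parameters that matter

| Parameter | Symbol | Default | Why |
|---|---|---|---|
| mean PFL (mm) | $A$ | 30.7 | nominal adult value; configurable because sex/ancestry-specific means exist and the method's accuracy hinges on it |
| PFL population SD (mm) | — | 1.2 | drives the irreducible anatomical error; used by the subject generator |
| PCS distribution (mm) | — | $N(65, 3.5)$ | nominal adult eye-line-to-mouth span; only its *pixel magnitude* matters downstream (the true PCS cancels from the profile estimate) |
| pixel pitch (mm) | $y$ | per camera | manufacturer value; loaders accept µm and reject pitches outside 0.5–20 µm |
| focal length (mm) | $f$ | per camera | actual, not 35 mm-equivalent; `actual_focal_from_equivalent()` converts via the sensor diagonal over 43.2666 mm |
| depth extent (mm) | $\delta$ | 100 | axial near-to-far feature separation in the tolerance metric (below); nominal, artifact-defined |

## Error anatomy

With noiseless pixels, the signed relative FD error is exactly
$A/PFL_{true} - 1$ per subject — the anatomical floor. Its mean absolute
value over $PFL \sim N(A, 1.2)$ is about 3.1% (the package checks a
$10^5$-subject Monte Carlo against direct quadrature of
$E\,|A/P - 1| \cdot 100$). Measurement noise adds a term proportional to
the *inverse* pixel length of the feature, and the pixel length shrinks
linearly with FD: long distances plus short focal lengths mean a
palpebral fissure a dozen pixels long, where half-pixel landmark
uncertainty alone is several percent. This is the mechanism behind the
characteristic error-vs-distance growth of the method, steepest for
wide-angle (24 mm) lenses beyond 6 m.

## The synthetic validation study

No photograph corpus ships with the package. Instead, a generator
reproduces the *design* of a two-part validation protocol and the
*measurement* process, so every downstream stage is testable end to end:

* **DSLR study** — 10 participants, three full-frame bodies (pixel
  pitches 6.55, 5.67 and 5.90 µm), five focal-length configurations per
  body (primes 50/85/100 or 105 mm; a zoom used at both ends, 24 mm and
  105 or 120 mm), distances 1, 2, 3, 4, 6 and 10 m, frontal + profile
  views, duplicate exposures: 120 photographs per body per participant,
  360 across bodies, 3600 in all.
* **Smartphone study** — five phones; all back cameras
  (0.3–10 m set, 8 distances) and four front cameras (0.2–1.3 m set,
  9 distances); one phone's front camera is omitted for lack of published
  specifications, and two participants each miss one back camera,
  mirroring realistic dropout. 2976 photographs.

Subjects are drawn once per study from the anatomical priors
(non-positive draws redrawn — a formality at 25 SDs from zero). True
lengths are projected through each camera at each design distance and
degraded by the noise model: Gaussian landmark jitter (default 0.5 px)
plus rounding to the pixel grid. Noise acts on derived pixel *lengths*,
not on 2D landmark coordinates — a simplification that preserves the
error structure of interest while keeping the generator analytic. The
42° profile head rotation is not modelled geometrically; PCS is treated
as fronto-parallel in both views, with an optional scalar foreshortening
factor for sensitivity analyses. Duplicate exposures are resolved by an
explicit deterministic rule (first usable replicate per station and
view); since simulated noise is i.i.d. this introduces no bias, and
blink-ruined frames are represented simply as missing required pixel
fields.

What passing these tests shows — and does not show. The synthetic study
validates the estimator's geometry, the error-propagation structure and
the analysis pipeline. It cannot certify real-world accuracy: real
measurement error includes operator landmarking behaviour,
shape-from-shading ambiguity at low resolution, lens distortion, and (for
phones) undisclosed on-device image processing, none of which are
modelled. Simulated MAE% values (~3% for DSLRs) are accordingly an
optimistic floor relative to errors reported on real photograph corpora.

```{r study, message=FALSE}
res <- run_pipeline(dslr_study_config(), seed = 1, quiet = TRUE)
summarize_errors(res$estimates, group_by = "view")
```

### Quantization aliasing

One sharp-edged numerical phenomenon deserves note. With quantization as
the *only* noise source, the measured pixel length of every subject
rounds to one of a handful of integers. If the population-mean pixel
length $fA/(dy)$ happens to sit near an integer, most subjects collapse
onto the same measured value and every one of their estimates lands near
$fA/(ky)$ for that integer $k$ — which is then close to the true FD, so
the apparent error *falls below* the anatomical floor. The effect is real
(a property of the estimator, not a bug), disappears as soon as landmark
jitter is present, and is why quantize-only experiments must be
interpreted against the grid position of the mean, not as a generic
"longer FD, larger error" dial.

## The perspective tolerance

Superimposition practice accepts an FD mismatch when it changes apparent
physiognomical facial height by at most about 1%. The package
operationalises this as the change in the near/far projected-scale ratio:
features separated axially by $\delta$ project with relative scale
$(d + \delta)/d$, and the metric is

$$100 \cdot \left|\frac{(d_{est} + \delta)/d_{est}}{(d_{true} + \delta)/d_{true}} - 1\right| .$$

This is a declared stand-in: the literature's exact landmark and depth
choices for the criterion are not public, so $\delta$ must be supplied
(fixtures use 100 mm) and conclusions should be read as relative, not
forensic-grade absolutes. The threshold comparison is inclusive
(`<=`). The metric is zero iff the distances agree, grows monotonically
with the FD gap, and — because perspective flattens with distance — a
fixed *relative* error passes more easily at long FD:

```{r tolerance}
dm <- face_depth_model(100)
facial_height_change_pct(1000, 900, dm) # ~1.01%: just outside a 1% limit
within_tolerance(4000, 3600, dm)        # same -10% error at 4 m: passes
```

## Numerical and design choices

* **Error statistics.** "MSE" follows the validation-study convention of
  *mean signed error*, `mean(est - true)` — not a squared error; negative
  values mean systematic underestimation. MAE% is the mean of
  per-observation absolute percent errors (not MAE over the mean truth);
  SEE is $\sqrt{\sum e^2 / n}$, an RMSE about the ground truth, since no
  regression is fitted — an $(n-2)$-denominator variant is available
  behind a flag. Both conventions are stated because neither is uniquely
  standard.
* **Replicate selection** is first-usable-by-replicate-id — explicit and
  deterministic rather than an unreproducible "best image" judgement.
* **Units.** Millimetres everywhere internally; configs accept µm pixel
  pitches and metre distance sets and convert at load.
* **Determinism.** All randomness flows from explicit seeds
  (`withr::with_seed`, global RNG untouched); pipeline stage seeds are
  derived as seed + 1 (subjects) and seed + 2 (noise). Output CSVs carry
  a provenance comment (version, seed, config MD5) and contain no
  timestamps, so identical runs are byte-identical.
* **Degenerate inputs.** Geometry is rejected, not clamped: non-positive
  lengths, FD below the focal length (or below $4f$ in the thin-lens
  model), magnification ≥ 1. Simulated measured lengths are floored at
  1 px (a sub-pixel-length feature is not measurable at all).
* **Problem sizes.** Unit tests run the protocol-scale studies (seconds).
  The error-trend analysis uses $10^5$ participants with a single
  replicate: adjacent short distances differ in expected MAE% by only
  ~0.003 percentage points for long primes, and this size puts roughly
  four standard errors on the smallest gap so the monotonicity of the
  trend is resolved rather than left to sampling luck.

## Known limitations

* The estimator assumes a centred subject, distortion-free optics and a
  fronto-parallel feature; none of these are corrected for.
* The profile chain applies no pose/foreshortening correction for the
  partial rotation; the optional scalar factor is a sensitivity knob, not
  a model.
* The population-mean substitution caps accuracy at the ~3% anatomical
  floor for any individual; populations whose PFL mean differs from the
  configured $A$ bias all estimates multiplicatively.
* Smartphone manufacturer optics data are often 35 mm-equivalent only and
  of uncertain provenance; the conversion helper is exact, but its inputs
  may not be.
* EXIF reading covers the FocalLength tag of plain JPEG/TIFF structures
  only — enough to populate a camera config, not a general metadata
  parser.
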