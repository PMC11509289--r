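---
title: "Assessing cup-placement precision of CT-based hip navigation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing cup-placement precision of CT-based hip navigation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In computer-navigated total hip arthroplasty (THA), the navigation display
tells the surgeon where the acetabular cup currently sits — its operative
anteversion, operative inclination and depth — relative to a pelvic
coordinate system planned on the pre-operative CT. Whether that display can
be trusted is an empirical question: the displayed pose is the product of a
chain of steps (probing bone points, registering them to the CT-derived
surface model, tracking the instruments), and each step contributes error.
The accepted way to audit the chain is to compare, per surgery, the
guide-tool readout against the cup pose measured independently from a
post-operative CT transformed back into the pre-operative frame, and to
summarise the differences as mean ± SD navigation errors.

`hipnav` re-implements that audit as a fully simulated, fully seeded
pipeline. Real cadaver or patient CT data cannot be shipped or re-measured,
so the package generates synthetic pelvis scenes with known ground truth and
checks the pipeline by *properties*: a noiseless scene must produce exactly
zero navigation error, error spread must scale with injected probing noise,
deliberately injected biases must be recovered, and every geometric step
must be equivariant under rigid motions of the world.

## Coordinate frames and angle conventions

The anterior pelvic plane (APP) is the standard reference: the plane through
both anterior superior iliac spines (ASIS) and the pubic landmarks. The
frame is built with

* origin at the ASIS midpoint,
* lateral axis along the inter-ASIS line, pointing toward the operated side,
* anterior axis normal to the plane, pointing forward,
* superior axis completing the triad in-plane, pointing cranially.

Pointing the lateral axis at the operated side lets one angle formula serve
both hips. The price is handedness: a right-hip frame is right-handed
(`lateral × anterior = superior`), a left-hip frame is left-handed. The
angle formulas below use only axis *components*, never cross products, so
they are unaffected. Note also that all four APP landmarks lie in the APP
itself, so the left/right labels are the only source of orientation — the
landmark coordinates alone cannot distinguish anterior from posterior.

The functional pelvic plane (FPP) is the APP rotated about the lateral
(inter-ASIS) axis by the patient's pelvic tilt. We take positive tilt as
anterior tilt (superior axis leaning forward); the convention is stated here
because tools in the field disagree and the sign changes the FPP readout.

With unit cup-axis components $(l, a, s)$ on (lateral, anterior, superior),
the three standard angle conventions are

* operative: $\mathrm{OI} = \arcsin l$, $\mathrm{OA} = \operatorname{atan2}(a, s)$
* radiographic: $\mathrm{RI} = \operatorname{atan2}(l, s)$, $\mathrm{RA} = \arcsin a$
* anatomic: $\mathrm{AI} = \arccos s$, $\mathrm{AA} = \operatorname{atan2}(a, l)$

Conversions go through the shared axis representation, so the classical
identities $\tan \mathrm{RI} = \tan \mathrm{OI} / \cos \mathrm{OA}$ and
$\sin \mathrm{RA} = \sin \mathrm{OA} \cos \mathrm{OI}$ hold by construction;
the tests verify them over a grid. The navigation readout uses the operative
convention. At the classical 40° inclination / 15° anteversion (radiographic)
target the operative pair is ≈ 38.39° / 19.28° — the two conventions differ
by a degree or two exactly where clinical targets live, which is why the
convention is always carried alongside the numbers.

Cup depth differences are signed: the displacement of one cup centre
relative to another is projected onto the cup opening axis, positive when
the first sits lateral (shallower). Unlike a 3D distance this keeps the
clinical direction of the error. We project onto the *guide* cup's axis,
making the displayed navigation value self-referential; at the sub-degree
axis errors involved, projecting on the post-op axis instead changes the
depth by a negligible second-order amount.

## Registration

Patient alignment — matching the ~26 probed bone points to the CT-derived
surface — is sparse point-to-surface rigid registration. The engine is ICP
with exact closest-point-on-triangle correspondences (computed in C++ with
centroid-distance culling; vertex snapping would bias sparse points on a
coarse mesh), a Kabsch least-squares update with an SVD sign guard so a bone
surface can never be mirrored, and an objective (RMS point-to-surface
distance) that is asserted non-increasing at every iteration.

Two refinements matter in practice:

* **Multi-start.** ICP is local; the commercial system's global search is
  proprietary. We run ICP from a coarse alignment (Kabsch on per-region
  point/surface centroids) plus `n_starts − 1` randomly perturbed starts
  (default 16 starts, ±15° / ±20 mm) and keep the best RMS. Deterministic
  given a seed.
* **Point-to-plane polish.** Point-to-point ICP converges linearly and can
  stall at facet-scale local minima of a triangulated surface, which would
  put a false floor under the zero-noise exactness property. After the
  point-to-point phase, a few Gauss–Newton steps against the foot-point
  tangent planes settle the fit to machine precision; steps are accepted
  only if the true point-to-surface RMS does not increase, and the top few
  starts (not just the winner) are polished, because the polish can rescue
  a basin that ranks behind on the unpolished objective.

The post-op-to-pre-op step uses the same machinery densely: post-op mesh
vertices (an even subsample, default 400) registered to the pre-op surface.
The original study aligns CT volumes by intensity; on a rigid bone the
surface formulation optimises the same geometric agreement and is scored the
same way — by the mean distance between the aligned surfaces — so it is the
natural desk-scale replacement. A configurable ceiling (default 1 mm) on
that accuracy raises a warning flag, mirroring the quality gate a clinical
workflow would apply. The control-screw check (re-probing a fixed screw
after alignment; default tolerance 1.0 mm, inclusive) is implemented as in
the workflow it models.

## The synthetic scene generator

The generator is the package's study population, so its defaults *are* the
study conditions: 26 registration points per alignment in four regions
(iliac crest 8, anterior wall 6, posterior wall 6, acetabular rim 6 —
region shares are configurable), three raters per side in inter-rater mode,
a 15°/40° operative cup target, and cadaver/patient batch sizes of 15 and
18 measurements.

The pelvis is parametric: a smoothly deformed ellipsoidal iliac blade
(seeded low-frequency radial deformation, so every seed is a different
"anatomy") with a hemispherical acetabular socket of configurable radius
(default 26 mm) carved about a centre just lateral of the surface on the
cavity axis. The carve moves surface vertices axially onto the sphere's
medial hemisphere — a height-field operation that cannot fold triangles.
Within the ~30° cup-seating cone the cavity radius is accurate to < 2%;
near the superior rim, where the blade rises, the axial carve steepens the
wall relative to a true boolean subtraction. Landmarks sit at fixed
parametric sites; left hips are exact sagittal mirror images of right hips.

Noise model and magnitudes (chosen once, as assumptions, since the study
reports none):

* probing noise: isotropic Gaussian, σ = 0.5 mm per point — the scale of
  optical-tracker point probing;
* post-op scan pose: a random rigid displacement within 8° / 15 mm about
  the mesh centroid;
* post-op surface noise: σ = 0.1 mm per vertex — sub-voxel segmentation
  jitter; it reproduces sub-half-millimetre mean surface agreement after
  registration, the scale clinical audits report;
* manual template-overlay noise on the post-op cup pose: default 0 (the
  original workflow does not quantify it; it is exposed as a configurable
  σ in degrees/mm).

What the simulator does **not** emulate: real pelvic morphology (no
statistical shape model, no dysplastic anatomies), CT intensities and
segmentation failures, tracker-camera drift, soft-tissue probe error, or
correlated probing errors. Passing tests therefore demonstrate that the
*analysis chain* is exact, unbiased and correctly calibrated under its
stated noise model — not that a clinical system achieves any particular
accuracy on real patients.

## Statistics

Per-case navigation errors (guide minus post-op, matching the convention
that a positive depth difference means the guide showed the cup more
lateral than it was) aggregate into mean, sample SD (n−1), min, max and
absolute-value mean/SD per metric, plus exceedance percentages — the share
of cases with |error| strictly over a threshold (default 5° and 10°,
reflecting the ±10° safe-zone framing). Box-plot quantiles (median,
quartiles, Tukey whiskers) and scatter pairs are exported as CSV; figures
are left to the caller so headless runs stay file-based. No inferential
statistics are computed, deliberately: the emulated study design reports
descriptive precision only.

An interesting emergent property of the geometry, visible in every
simulated sweep: anteversion errors spread roughly twice as wide as
inclination errors under identical probing noise. The operative anteversion
axis is the least constrained direction of a sparse registration against
this surface — the same asymmetry clinical audits report.

## Numerical choices and degenerate inputs

* ICP stops when the RMS change falls below `tol_mm` (default 10⁻⁶ mm, cap
  200 iterations); the dense post-op stage uses a coarser 10⁻⁴ mm with the
  polish supplying final precision. The polish stops on a 10⁻¹⁰ step in
  parameter space (radians + mm).
* Kabsch requires ≥ 3 non-collinear correspondences and rejects rank-< 2
  covariances with a named error; reflections are repaired by flipping the
  smallest singular vector.
* Angle conversions are undefined at 90° inclination and error there;
  a cup axis with a negative lateral component errors as medially pointing.
* Region labelling errors out when a region has fewer than 3 faces
  ("resolution too low") rather than silently sampling a degenerate region.
* All lengths are mm and all angles degrees at API boundaries; radians are
  internal only.

Reproducibility: every stochastic step draws from a seed derived
deterministically from the scene seed and a stream label (a small string
hash kept within 32-bit range), and the RNG state of the caller is always
restored. Identical configurations produce byte-identical CSV/JSON outputs;
numeric fields are serialised through a fixed `%.10g` format to keep file
bytes stable.

## Problem sizes used by the test-suite

The shipped tests run the full pipeline at two mesh resolutions: the
default 64×48 sphere grid (≈ 3 000 vertices) for single-case checks and a
reduced 32×20 grid (≈ 650 vertices) for Monte-Carlo sweeps — 300 cases per
noise level for the spread calibration, 100 seeds for the multi-start
comparison, 60 cases per injected offset. Exactness and equivariance
properties are resolution-independent; the reduced grids keep the suite's
total runtime in the minutes range on one CPU. The acceptance script runs
the two headline study designs (15 inter-rater measurements, 18 patient
cases) at the default resolution.

## Known limitations

* The parametric pelvis is a geometric stand-in; absolute error magnitudes
  from the simulator characterise the pipeline under its noise model, not
  any clinical device.
* The multi-start search is a reproducible surrogate for an undisclosed
  proprietary global search; no claim of equivalence is made beyond sharing
  the same objective.
* Dense surface registration replaces intensity-based volume registration;
  on non-rigid or artefact-laden scans the two would differ.
* With vertex noise, the dense-ICP optimum on a faceted surface is defined
  only to the facet scale: re-posing the post-op scan can shift navigation
  errors by ~10⁻³ degrees (the noiseless case is invariant to 10⁻⁶).
* Inter-rater mode varies only the probed points and rater pose between
  raters, matching a repeated-alignment protocol; real raters would also
  differ in probing technique and region preference.
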