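---
title: "Geometry and methods of the metatarso-phalangeal-sesamoid ICR model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry and methods of the metatarso-phalangeal-sesamoid ICR model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpsjc)
```

## The model and its assumptions

`mpsjc` treats the sesamoids and proximal phalanx as one functionally
stationary platform over which the first metatarsal head rotates. All
coordinates are platform-frame: +x distal, +y dorsal, +z medial (right
foot); a "proximal shift" is a decrease in x. The model is plane-wise, in
three parallel sagittal planes — the fibular sesamoid plane, the crista
(inter-sesamoidal ridge) plane, and the tibial sesamoid plane — at fixed
z-offsets. This mirrors how the joint is characterised from serial 0.5-mm
sagittal sections, where the crista section is circular and the groove-trough
sections are elliptical (flattened).

Assumptions worth stating plainly:

* the only moving body is the metatarsal; contacts are frictionless
  tangency, with no force model;
* each sagittal plane is idealised with the full head-circle radius plus its
  groove, rather than the true (slightly smaller) section radius — the
  plane-wise construction needs comparable circles, and the kinematic
  conclusions depend on the groove relief, not the absolute section radius;
* the normal at the phalanx contact A is treated as functionally fixed over
  the sweep. The implementation recomputes it at every step and asserts the
  drift stays below a tolerance (default 5°; the default model stays below
  1°) rather than hard-coding it.

## Contact, pose, and the centres of rotation

At declination angle θ the bone's rotation is fixed and its translation is
closed by simultaneous tangency to the phalanx support and the plane's
sesamoid. Because contact A always rides the dorsal circular arc, the
phalanx constraint is exactly "head centre at distance R + r_p from the
phalanx centre"; the sesamoid tangency is then a one-dimensional root in the
angle of the head centre about the phalanx centre, with the closest-point
subproblem solved by bracketing plus a secant polish on the normal-foot
condition (Brent alone leaves ~1e-7 mm of tangential error; the polish
brings the spherical-degeneracy checks to 1e-14 of the radius).

The plane's centre of rotation is the intersection of the inward normals at
A and at the sesamoid contact. Parallel normals (the regime in which the
on-ridge and in-groove contact normals coincide) are reported as a status,
and the sweep layer then uses the spherical centre. For the
three-dimensional shared centre, each sesamoid plane's normal is drawn in 3D
from its contact point towards that plane's own centre placed in the
inter-sesamoid mid-plane; for a spherical head all three normals then pass
through the 3D sphere centre, so the least-squares common point (closed-form
normal equations; point-to-line distances via cross products to avoid
catastrophic cancellation) has zero residual exactly in the spherical case.

## Groove geometry

A groove is a convex flattened region between its proximal inception and
distal termination, built from two double-contact conic (elliptical) arcs
that meet C¹ at the trough and join the head circle C¹ at the junctions.
Key numerical facts that shaped the design:

* **Feasibility.** A convex arc leaving a flat trough can rejoin the circle
  only if its depth is at most R(1 − cos w) for a wall of angular width w.
  The `flattening` parameter is therefore the fraction of this maximal
  convex-compatible depth, so every value below 1 yields a convex profile by
  construction.
* **Asymmetry decides the shift direction.** A single conic with C¹ contact
  at both junctions is forced symmetric about the chord bisector, which is
  why the groove uses two sub-arcs with a free trough position. At the
  working depths (~0.1–0.2 mm of relief) the steep wall is where contact
  normals deviate most from radial: a trough near the inception (tibial
  type) produces a dominant proximal excursion of the plane centre; a trough
  near the termination (fibular type) a dominant distal one. At much
  shallower depths (below roughly 0.4 of the convex-compatible maximum) the
  dominance reverses to the wide flattened stretch, so the directional
  claims are properties of the default morphology, not of every conceivable
  groove.
* **Root selection.** Rays from the head centre can cross a groove ellipse
  twice; the admissible intersection is the one on the arc side of the
  tangency chord, which each groove arc stores alongside its implicit
  coefficients.

## Parameters, defaults, and provenance

Published quantities: initial declination range 12–20° (default θ₀ = 15°),
terminal range 65–75° (default θ_M = 70°), landmark sections 15 (fibular
trough), 23 (crista), 31 (tibial trough), the tibial sesamoid more distal
than the fibular, and the tibial groove inception more distal than the
fibular. Everything else is illustrative and centralised in
`mpsjc_defaults`: head radius 11 mm (transverse dome 12 mm, slightly
longer), sesamoid radii 3.5 mm at platform angles −88° (tibial, z = +4 mm)
and −100° (fibular, z = −4 mm), phalanx support radius 6 mm on the distal
axis, grooves spanning [−62°, −22°] (tibial, trough fraction 0.30) and
[−69°, −33°] (fibular, trough fraction 0.70) with flattening 0.75 of the
convex-compatible depth. The flattening default was chosen so that the
dominant excursion lobe exceeds the counter-lobe by about 1.5× in both
planes, making the directional classification robust; the groove placements
put engagement inside the sweep with both centres returned to their
spherical positions before θ_M. The classification tolerance defaults to
0.005 R and the sweep grid to 200 steps, which resolves the ~5° onset
separation between the planes.

Angle units are degrees at every interface (radians internally); lengths are
millimetres.

## The synthetic section stack

`generate_stack()` emulates a 48-section stack at exactly 0.5-mm spacing:
section radii follow a dorsal dome (transverse radius 13 mm), each groove's
flattening tapers as a cosine-squared bump over ±7 sections about its trough
index, contours are open arcs over [−110°, 60°] sampled at 150 points with
isotropic Gaussian noise (default 0.5% of the head radius), and a cubic
"metaphyseal flare" (0.6 mm + 0.03 mm/section) contaminates the proximal
non-articular tail of every non-crista section so that the crista is
genuinely the most circular section rather than one of many perfect circles.
The generator's groove spans are wider (50°) and deeper (flattening 0.65,
trough fractions 0.35/0.65) than the default model's so the trough relief
(~0.3 mm) stands clearly above the noise floor.

What the stack does *not* emulate: CT imaging physics, segmentation error
structure (noise is white, not correlated), cartilage-bone distinction, and
per-section centre drift (all sections share the head axis). Passing the
recovery tests therefore demonstrates the pipeline's correctness on
idealised digitised contours, not robustness to real imaging artefacts.

`locate_landmarks()` takes the crista as the section minimising the
circle-fit rms residual, and each trough as the section maximising the
plantar deficit *area* below the dorsal reference circle on its side of the
crista (normalised by the section's dorsal radius and refined with a
parabolic vertex over ±6 sections; the area statistic has roughly twice the
signal-to-noise of the peak depth and localises the trough index exactly
across all tested seeds). Troughs below 4× the crista noise floor raise a
missing-landmark condition, which is how a groove-less spherical stack is
reported.

`stack_to_model()` reconstructs the head: circle fit at the crista
(radius recovered well within 1% at the default noise), dorsal-radius drops
of flanking sections for the transverse dome, and, per trough plane, a
template estimated from the *pooled* deficit curves of the trough section
and its ±3 neighbours — window edges from two-threshold flank crossings
extrapolated to zero deficit, trough side from a grid-plus-golden-section
fit of the one-dimensional deficit family — followed by a geometric
least-squares profile fit of the trough section. Pooling is essential: the
trough side is weakly identified from a single section at this noise, but
the pooled curve's noise is low enough to identify it reliably.

## Numerical choices

* Circle fitting: algebraic (Kasa) seed plus Levenberg–Marquardt refinement
  of the radial residuals; collinear input raises a degenerate-fit error.
  Noiseless recovery is exact to ~1e-9; noisy round-trip accuracy of the
  composite-profile fit is limited by the finite-difference Jacobian to
  ~1e-5 relative.
* The trough-position parameter is kinked and multimodal in the residual
  surface, so it is searched by grid plus golden-section with the smooth
  parameters refit exactly at each node, each node starting fresh (a pegged
  node must not seed the next).
* Line intersections flag parallelism below 1e-8 rad; the sweep interprets
  parallel contact normals as "centre unchanged at the spherical centre".
* All sweeps are deterministic; the only randomness in the package is the
  stack generator's noise, seeded explicitly and restoring the caller's RNG
  state.

## Variant morphologies

Each shipped preset encodes a parameter edit plus a qualitative prediction
for the shared centre. The realisations worth explaining:

* *Proximally positioned sesamoids* are repositioned along the articular arc
  (0.15 R of arc) rather than translated: under tangency closure a pure
  translation mostly lowers the bone plantarward, whereas arc repositioning
  delays groove engagement into end-range declination, truncating the distal
  return and pulling the sweep-mean centre strictly proximal — the
  restricted end-range mechanism associated with these positions.
* *Everted position* counter-rotates the platform about the long axis; this
  changes the sesamoid planes' z-offsets, so the least-squares centre moves
  genuinely medial (and the label maps to medial-plantar).
* *Distal tibial sesamoid* obliques the trans-sesamoid x-axis. In the
  plane-wise model the least-squares centre's z-component is the mean of the
  plane offsets, so purely in-plane edits cannot move it laterally; the
  lateral component of the compound label is carried by the obliquity
  change (scaled by the sesamoid plane half-separation, and only when it
  exceeds 1°, since the mapping from displacement vectors to compound labels
  has no published thresholds).
* *Flattened head* washes out groove relief (flattening × 0.3); its check is
  the mobility claim — the sagittal spread of the centre trajectory
  decreases — with the displacement prediction vacuously "none".
* *Short metatarsal* ships with a mobility-only prediction and no geometric
  edit: its mechanism runs through ground-reactive force, which this
  geometric model deliberately excludes.

## Problem sizes

The shipped tests and the acceptance script run the default 200-step sweep
(a few seconds), 80–120-step sweeps for comparative checks, 20-seed recovery
and 1000-circle oracle suites, and 8-seed noise-monotonicity scans at four
noise levels; these sizes resolve every claim being tested while keeping the
whole suite a few minutes long.

## Known limitations

* No forces, pressures, or dynamics; "mobility" claims are purely geometric.
* The plane-wise 3D representation cannot produce out-of-plane normal
  components from in-plane edits (see the obliquity discussion above); a
  full articular surface model would.
* The directional shift claims hold for the default (deep-regime) groove
  morphology; very shallow grooves genuinely reverse the dominant lobe.
* The declination angle is measured to the A-normal. Where the alternative
  ground-plane definition is wanted, pose the model externally and use
  `declination_angle()` with the axis of choice.
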