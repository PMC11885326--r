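---
title: "Methods: synthetic hemodynamics of the post-switch neo-aorta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic hemodynamics of the post-switch neo-aorta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What this package models

After the arterial switch operation (ASO) for transposition of the great
arteries, the native pulmonary root becomes the systemic "neo-aortic" root
and tends to dilate over the following decades. CFD studies of such
patients stratify cohorts into severe dilation (any root Z-score >= 4),
mild dilation (2 < Z < 4) and normal controls (Z <= 2), and report three
robust qualitative findings: controls show wall shear stress (WSS) lowest
at the aortic root, peaking at the distal ascending aorta and falling
distally; severely dilated patients lose that distal peak, show their WSS
maximum in the arch, and exhibit a recirculation pocket in the transverse
arch (between the measurement planes flanking the head vessels); and the
severe group has markedly more acute ("gothic") arch angles.

Patient CT images, pressure recordings and 3-D finite-element solutions
are not reproducible at desk scale. This package therefore rebuilds the
*analysis* around synthetic stand-ins with controllable, oracle-verifiable
structure: parametric geometries, a 0-D lumped-parameter pressure model,
and constructed velocity fields whose every metric-relevant feature
(near-wall shear, slice vorticity, reverse flow) is an explicit parameter.
Passing tests therefore demonstrate that the measurement apparatus is
correct and that the stated group-level findings follow from the modeled
anatomy and flow features - not that a Navier-Stokes solution was
reproduced.

## Geometry

`build_synthetic_aorta()` sweeps a circular-section tube along a planar
candy-cane centerline. The diameter profile is a natural cubic spline
through the four measured levels (annulus, sinus of Valsalva, sino-tubular
junction, mid-ascending aorta), giving a smooth sinus bulge; beyond the
mid-ascending landmark the diameter is constant, so equal level inputs
degenerate to an exact cylinder. A short constant-diameter stub precedes
the annulus so its cross-section can be cut cleanly from the mesh.

The arch apex is a circular arc of radius `R_c = d / (2 cos^2(theta/2))`,
where `d` is the apex diameter and `theta` the target arch angle. With the
angle measured as in the source methodology - tangent at the highest
centerline point, a parallel line displaced one apex diameter downward,
and the angle subtended by its first crossings with the centerline - this
radius makes the measured angle *exactly* `theta` by circle-chord
geometry. Acute gothic angles imply an apex arc that overhangs slightly;
each arc end is blended by a small fillet onto a straight limb. The
ascending limb leans 12 degrees away from the descending limb so that a
severely dilated sinus (41 mm at a 68.5 degree arch, the extreme corner of
the cohort ranges) still clears the descending aorta. Branch ostia
(brachiocephalic, left carotid, left subclavian) are arclength landmarks
on the arch; branch lumens are not meshed, because downstream flow
division lives entirely in the 0-D network and the wall regions exclude
branch territory by construction.

"Highest point" needs a height axis. A chord- or centroid-derived axis is
biased whenever the two limbs have different lengths (the chord tilts by
tens of degrees), so `measure_arch_angle()` takes the axis explicitly and
defaults to +z, the generator's anatomical orientation; imported
centerlines should follow the same convention or pass their own axis.

Planes 0-4 follow the published arclength rules ("one diameter" always
means the local equivalent diameter at the reference slice; "just
before/after" an ostium is a fixed 0.1 diameter). Wall regions are
arclength bands of half-width 0.5 local diameter around planes 1-4, plus
the root band from one local diameter proximal of the STJ to the STJ;
planes 1 and 2 are 0.9 diameters apart by their defining rules, so those
two bands always overlap by 0.1 diameter and the overlap strip is split by
nearest plane. Level diameters are measured from the mesh: the cut contour
is collected edge-wise (robust when the cut lands exactly on a vertex
ring), its area gives the equivalent-circle diameter, and the
mid-ascending level reports the mean of the minimum and maximum caliper
widths, as clinical practice does at that level.

## Cohort and body-size normalization

Body surface area uses the Haycock formula
`0.024265 w^0.5378 h^0.3964` (w in kg, h in cm). Z-scores are
`(d - mean(BSA)) / sd(BSA)` against a pluggable reference; the bundled
reference is affine in BSA with constant SD per level, calibrated so
adolescent control diameters score near zero. It is explicitly synthetic
and non-clinical - published pediatric coefficient sets are not reprinted
here - and tabulated references load from CSV with linear interpolation.
Class boundaries follow the printed inequalities exactly: Z = 4 is severe,
Z = 2 is normal.

`generate_cohort()` samples ages uniformly on 8-18 years with
age-increasing height and weight, cardiac output uniformly on 3.8-6 L/min
(the published estimate range; the original age/BSA estimation rule is not
specified, so output is drawn directly), and systolic/diastolic targets on
100-130 / 60-80 mmHg. Level diameters are drawn by anchoring the
class-determining level in Z-space inside its class window and scaling the
group's median level profile to the anchor with 2% jitter, capping the
remaining levels below the class boundary. This guarantees 100% label
fidelity *and* preserves each phenotype's anatomical shape; independent
per-level draws were rejected because they can produce "controls" with no
sinus bulge, whose root is then not the regional WSS minimum for purely
anatomical reasons. Arch angles are drawn uniformly within each group's
observed range.

## 0-D hemodynamics

Each outlet carries a 3-element Windkessel: proximal resistance Rp in
series with a parallel capacitance C and distal resistance Rd, distal
reference pressure 0. Inlet flow is divided among outlets by the modified
Murray law with exponent 2 (area-proportional), applied uniformly to all
outlets as the simplest consistent 0-D closure. The single capacitor state
per outlet is integrated with its exact exponential update, so the scheme
is unconditionally stable at the 0.001 s default step; simulation proceeds
in whole cardiac cycles until systolic and diastolic root pressure change
by no more than 1% versus the previous cycle, with a minimum of eight
cycles, and only the final cycle is reported. The root pressure is the
flow-weighted mean of outlet proximal pressures, which coincides with each
outlet's pressure once resistances are distributed inversely to the Murray
fractions.

The default inflow waveform is analytic: a half-sine systolic ejection of
duration T/3, a small reverse lobe (5% amplitude, T/10) at valve closure,
and zero diastolic flow, normalized to unit mean and scaled to the
subject's cardiac output; measured waveforms load from CSV.

`tune_rcr()` matches systolic/diastolic targets with two knobs: total
resistance is scaled by the ratio of target to simulated mean pressure -
with "mean" taken as the systolic/diastolic average *on both sides*, so
the fixed point matches both targets simultaneously - and total
capacitance by the ratio of simulated to target pulse pressure. The Rp:Rd
ratio is held fixed and defaults to 0.04. This value is a design choice
driven by reachability: the proximal resistor alone produces a pulse
pressure of about `Rp_eff * (Qmax - Qmin)`, and with this waveform's
peak-to-mean ratio a larger split (e.g. 0.09) places that floor near
35 mmHg, above the narrowest physiologic targets in the sampled box
(100/80 gives a 20 mmHg pulse); 0.04 keeps the whole box reachable. The
ratio is configurable for users who prefer a different split.

## The synthetic velocity field

`generate_field()` builds a time-periodic analytic field in tube
coordinates (projected arclength s, radius rho) on the geometry's
centerline:

* **Axial profile.** A power-law generalization of Poiseuille flow,
  `u = U(s,t) (m+2)/m (1 - (rho/r)^m)`, scaled so the cross-sectional flux
  equals Q(t) at *every* station and instant. With the default exponent
  map `m = 2` this is exact quasi-steady Poiseuille flow, which is what
  every oracle test uses.
* **Shear envelope.** The exponent map `m(s)` raises near-wall shear at
  fixed flux (wall shear scales with `(m+2)/4`). The per-subject pipeline
  installs a Gaussian bump emulating the impingement peak of developed
  aortic flow: centered on the distal ascending aorta with amplitude
  `2.5 (1 - strength)` for normal and mild phenotypes, and migrated into
  the arch (amplitude 2.0, the distal peak gone) for the severe phenotype.
  This is the explicit, documented mechanism by which the generator
  realizes the observed WSS topology; it is a modeling control, not a
  solved flow feature.
* **Recirculation bubble.** On the proximal part of the plane 2-3
  interval (the transverse arch, clear of the plane-3 averaging band), an
  axial deficit reverses flow near the outer-curvature wall with peak
  reverse velocity `strength` times the local mean velocity, plus a
  tangential swirl. The removed flux is restored by a forward component
  weighted by `(1 - g)`, where `g` is the outer-wall angular weight - the
  compensation hugs the inner curvature, as the real jet does, and cannot
  cancel the reversal it is compensating. All bubble integrals are closed
  form, so slice flux stays exact. Group defaults are strength 1.2
  (severe), 0.3 (mild), 0 (normal); they were fixed while designing the
  generator against its phenotype contract (reversed-flow fraction above
  0.05 for severe fields, below 0.01 for controls, pattern labels as
  observed).

Because the whole field is linear in Q(t), time averages are quasi-steady;
Womersley profiles were deliberately omitted - every reported metric is
time-averaged, and an oscillatory profile would change no conclusion while
losing the closed-form oracles.

## Metrics

* **WSS** is estimated per wall triangle as
  `mu |u(x - eps n) - u(x)| / eps`, a one-sided difference anchored at the
  wall point; the anchor subtraction makes the estimator exact at `eps = 0`
  and insensitive to the small radial inset of triangle centroids. The
  default offset is local radius / 50, for which the Poiseuille bias is
  about 1%. **TAWSS** time-averages over uniform frames, then
  area-averages with triangle-area weights.
* **Slice vorticity** samples the plane on a masked grid, forms the full
  3-D curl by central differences (offset diameter/400 along the plane
  basis and normal, stencil confined to the lumen) and averages the
  magnitude over masked cells; a streamwise-component switch exists
  because visualization practice sometimes uses only that component. The
  metric is the cycle average over frames.
* **Recirculation fraction** is the fraction of a deterministic,
  volume-uniform (s, radius, angle) sample grid between planes 2 and 3
  with negative tangent-projected velocity at peak systole (the frame of
  maximum inflow); the presence flag uses an operational 0.02 cutoff,
  configurable, since the source methodology reports recirculation
  visually from streamlines.
* **Pattern labels** classify subjects by the argmax TAWSS region, ties
  broken toward the more distal region.

## Pipeline, statistics and problem sizes

`run_cohort()` is a pure function of its `run_config()`: cohort ->
geometry -> planes/regions -> waveform scaling -> RCR tuning -> field ->
metrics, with per-subject quarantine on failure. Group comparison uses
medians and ranges with pairwise two-sided Wilcoxon rank-sum tests,
Kruskal-Wallis overall, and Fisher's exact test for flags; raw p-values
are reported without multiple-testing correction, matching the thin
off-the-shelf statistics stage of the source analysis.

Default problem sizes were chosen once as the package's study conditions:
600 centerline points; a 160 x 32 surface loft (level diameters then
round-trip within 1%, band areas within 5%); 40-point slice grids;
24 frames per cycle for TAWSS and 12 for vorticity (the field is linear in
Q(t), so frame counts converge fast); dt = 0.001 s with at least 8 cycles.
A 5+5+5 cohort runs in about two minutes on one core; halving dt or
doubling all spatial resolutions changes reported metrics by well under
the 3% / 10% acceptance envelopes.

## Known limitations

The velocity field is constructed, not solved: pressure fields, secondary
flows beyond the parameterized bubble, turbulence and wall compliance are
out of scope, and vorticity magnitudes should be compared across groups,
not against absolute published values (whose axis normalization is not
stated). The bundled normative reference is synthetic, so absolute
Z-scores are not clinically meaningful - only the class structure is. All
mild-group subjects share one recirculation strength, so the "minority of
mild patients show recirculation" nuance is not reproduced. Imported
anatomies must be oriented arch-up (+z) or supply their own height axis
for the arch angle.
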