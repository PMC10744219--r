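---
title: "Inward displacement: model, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inward displacement: model, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvind)
```

## The measurement model

Inward displacement (InD) measures, for every endocardial point of a
long-axis view, the component of its end-diastole to end-systole motion
directed toward a ventricular *centre of contraction*, normalised by the
distance the point would have to travel to reach that centre. Unlike
segmental strain — a differential of displacements between nearby points,
dominated by annular motion and sensitive to local tracking error — InD is
an absolute displacement averaged over all points of a segment, so
point-level errors attenuate rather than amplify in the segmental value.

The analysis frame is fixed at end-diastole: the LV axis runs from the
midpoint of the two mitral-annulus insertions (first and last contour
points) to the apex, identified as the contour point farthest from that
midpoint — parameter-free and correct for convex ventricular shapes. The
centre of contraction for a point with longitudinal fraction *f* (its
clamped projection onto the axis, 0 at base, 1 at apex) sits on the axis at
fraction *g(f)* of the base-to-apex length. Basal points aim at the
mid-axis point (*g* = 1/2) and apical points at two thirds, reflecting that
normal contraction moves base toward apex much more than the reverse.
Because only the basal and apical anchors of this rule are physically
constrained, both a continuous interpolation
*g(f) = 1/2 + f·(2/3 − 1/2)* (the default) and a three-level discrete
variant are provided (`center_rule(mode = )`). ES positions are compared
against centres and axes computed from the ED contour only: InD is defined
as motion toward the *end-diastolic* centre, and normalising by the ED
point-to-centre distance makes 100 % coincide with the ventricle shrinking
onto its centreline.

Point correspondence between the ED and ES contours is taken from the input
when tracked pairs are supplied (`paired = TRUE` contour sets) and is
otherwise established by resampling both contours at `n_resample` equal
fractions of arc length from the first annulus. Arc-length correspondence
is deterministic and exact for similarity motions of the wall; its error
against a known construction is quantified below.

## Bullseye mapping

Each view's polyline is split at the apex into two walls; each wall's arc
is divided at fractions 1/3 and 2/3 into basal, mid-cavity and apical
bands, and the 10 % of arc adjacent to the apex on every wall forms the
apical cap (segment 17). Wall-arc fractions (rather than axis-projection
thirds) are used because they remain well behaved under strong apical
curvature. The binding of walls to AHA segments follows common vendor
triplane conventions — 4CH: inferoseptal 3/9/14, anterolateral 6/12/16;
2CH: inferior 4/10/15, anterior 1/7/13; 3CH: anteroseptal 2/8 (apically
13), inferolateral 5/11 (apically 16) — and is overridable in YAML because
neither the AHA statement nor vendor documentation fixes it; coverage of
all 17 segments is asserted at configuration load. Segments fed by several
views (13, 16, 17 by default) are fused as the unweighted mean of the view
means, mirroring the unweighted averaging within segments; point-count
weighting is available (`shared_weighting = "points"`). Regional summaries
are arithmetic means over segments 1–6 (base), 7–12 (mid), 13–17 (apex) and
1–17 (overall), reported at one decimal.

## Volumes, EF, GLS, indexing

Volumes use a triplane method of disks: 250 slabs (configurable) at
fractional positions along each view's axis, cavity half-widths measured
perpendicular to the axis on both sides of every available view, disk
radius the mean of all half-widths at that level, and slab thickness from
the longest view axis. The 250-disk default changes the semi-ellipsoid
result by under 0.2 % relative to 500 disks. GLS is endocardial
contour-length strain per view, averaged over views, negative for
shortening — the conventional feature-tracking definition; for a contour
pair scaled by *k* it equals 100·(k − 1) exactly. BSA uses Du Bois
(0.007184·W^0.425^·H^0.725^), the most common CMR convention, with
Mosteller available by configuration. These are stated conventions of this
package: vendor workstations do not publish their exact volume or strain
formulas, so no bit-agreement with any particular product is claimed.

## Reference comparison and statistics

The packaged normal ranges (per-segment and per-region mean ± SD of InD in
120 healthy adults, balanced over sex and six age decades) support
z-scoring (`zscore_bullseye`, flagging |z| > 1.96) and wall-motion
classification. Only two anchors of the classification are externally
fixed — 0 % is akinesis and negative values are dyskinesis — so the
remaining thresholds are package choices: values in [0, 2) % count as
akinetic, and hypokinesis is z < −1.96; both are configurable. At load the
regional rows are re-derived from the segmental rows and must agree within
rounding, a self-consistency check of the shipped table.

Agreement between observers uses Pearson correlation (via `cor.test`, with
the two-sided t test) and Bland–Altman bias with 95 % limits of agreement
(bias ± 1.96·SD of differences, sample SD). Adjusted associations (e.g.
volume indices vs InD, adjusted for age and sex) use ordinary least squares
with t-based 95 % confidence intervals; the regression coefficient is
reported as such throughout. Cohort normative tables report, per stratum
and segment, both the 95 % CI of the mean (mean ± 1.96·SD/√n) and the 95 %
reference interval (mean ± 1.96·SD), since published normative tables use
either; cells with fewer than two subjects are omitted with a warning.

## The phantom and what it does (not) validate

`generate_phantom()` builds half-ellipse ED contours (default equatorial
radius 22 mm, length 90 mm — a normal-sized adult LV) identical in the
three views, and moves every point a known fraction *s* of the way toward
its own continuous-rule centre, so the construction's segmental InD is
100·s % by definition. Per-segment fractions are blended linearly over a
5 % arc band at segment boundaries to keep the ES contour smooth; the
stored truth is always computed from the actual (blended) construction.
Optional annular descent and isotropic Gaussian contour noise are
available, and all stochastic paths require a seed, with identical seeds
giving bit-identical output. When `n_points` is even it is increased by
one so the exact apex lies on the contour; the fitted axis then coincides
with the construction axis, which is what makes the paired-mode oracle
exact to machine precision. The phantom's reference EF comes from a dense
functional integration of the constructed half-width profiles
(trapezoidal, 4000 levels), a code path independent of the slab-crossing
disk summation it validates.

Measured under the package's own test conditions (uniform s = 0.33, zero
noise, 200 points/view): paired-mode segmental InD equals truth to machine
precision; resampled-mode (arc-length tracking substitution) stays within
0.8 percentage points of truth in every segment; disk volumes agree with
the semi-ellipsoid closed form within 1 % and the phantom EF with its
construction value well within 1.5 %.

The phantom emulates geometry, not images: no myocardial texture, torsion,
through-plane motion, or realistic spatially-correlated contouring error.
Two consequences matter when transferring the validation to real data.
First, arc-length correspondence degrades when contraction is strongly
heterogeneous (systole then redistributes arc length between segments, so
equal-fraction pairing mixes neighbouring segments): with one segment at
s = 0.48 against 0.30 elsewhere the resampled-mode error can reach several
percentage points, which is why externally tracked pairs are accepted as
first-class input. Second, independent per-point noise at high sampling
density inflates polyline arc length and therefore biases GLS upward
(a 0.5 mm jitter on ~1.4 mm point spacing is enough to flip its sign);
real contouring errors are spatially smooth, so this artifact is a
property of the noise model, not of the strain estimator — segmental InD,
an average of displacements, is far more robust to the same jitter
(simulated two-observer correlations stay near 0.9 at 1 mm jitter).

## Numerical choices and degenerate inputs

Contours must be open polylines of at least 20 finite points with positive
arc length. Degenerate axes (coincident points) and points coinciding with
their centre of contraction raise errors rather than propagate NaN. The
apex argmax rounds squared distances to 10⁻⁶ mm² before comparison so that
near-exact ties on symmetric shapes resolve identically in any rigid pose,
keeping the whole pipeline invariant under rotation and translation of its
input (verified to 10⁻⁹). Missing views produce a partial analysis: only
segments covered by a remaining view are reported, the rest are flagged
missing, never silently zero. A slab not crossed by a contour contributes
a zero half-width, with a warning once more than 5 % of half-widths are
missing. Test and acceptance problem sizes — 200 points/view, 250–500
disks, 40 simulated subjects for agreement, 1000 replicates for CI
coverage, 120-subject synthetic cohorts — were chosen to bound Monte-Carlo
error well below the tolerances being checked.

## Known limitations

The method analyses two phases only (no time curves), in-plane motion only,
and presumes roughly standard view orientation (y increasing toward the
apex). The view-to-segment binding and the continuous centre rule are
documented conventions, not published vendor facts. Reference ranges come
from a healthy cohort balanced by design, so they describe normality, not
the spectrum of disease.
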