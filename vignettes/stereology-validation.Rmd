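---
title: "Design-based stereology of capillary networks: model, probes and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design-based stereology of capillary networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereovasc)
```

## The problem

Capillaries form a three-dimensional network whose biologically meaningful
quantities — total length, total volume, total surface area within a
reference region such as hippocampal CA1 or the dentate gyrus — cannot be
read off a single micrograph. Design-based stereology infers them from
counts made on two-dimensional sections, using probes whose sampling
geometry, not any model of the tissue, guarantees unbiasedness:

* **Cavalieri volume.** A region cut into parallel slabs of thickness $t$
  with a uniformly random phase, each cut face point-counted with a grid of
  area $a(p)$ per point, gives $\hat V = t \, a(p) \sum P$ (a further
  factor 2 converts a one-hemisphere count to a whole structure; the
  phantom pipeline models a single region and uses factor 1).
* **Length density.** On isotropic uniform random (IUR) sections, each
  capillary transect is counted once; $\hat L_V = 2 \sum Q / \sum A$.
* **Volume fraction.** Points hitting capillary profiles versus points
  hitting the reference section (Delesse): $\hat V_V = \sum P_{cap} /
  \sum P_{ref}$.
* **Surface density.** Intersections of test lines with capillary
  boundaries per test line length: $\hat S_V = 2 \sum I / \sum L$.

Totals are densities multiplied by the Cavalieri volume. Because the rat
tissue behind the original measurements is unrecoverable, this package
validates the machinery on *synthetic phantoms with exact closed-form
ground truth*, and replays the published group comparison from the printed
summary statistics shipped in `inst/extdata/`.

## The phantom: a stated world

`generate_network()` fills a convex reference region (box, ellipsoid or
sphere, built by `reference_region()`) with straight cylindrical segments
until the summed centre-line length hits `target_length_density * volume`
exactly (the last segment is truncated). Its defaults are the conditions
the reconstructed study states or implies:

* **Length density** ~300–400 mm/mm³ (`3e-4` to `4e-4` in µm⁻²): the
  published control CA1 values give 11.7 m / 33.9 mm³ ≈ 345 mm/mm³.
* **Radius: constant 2 µm.** The published totals imply a diameter close
  to 4 µm twice over: volume/length (0.157 mm³ over 11.7 m → d ≈ 4.1 µm)
  and surface/length (1.40 cm² over 11.7 m → d ≈ 3.8 µm). Every vessel
  therefore passes the capillary criterion (diameter strictly < 10 µm),
  which `filter_capillary_profiles()` still enforces.
* **Segment length uniform in [50, 200] µm.** The study gives no
  microarchitecture; segment length affects estimator variance, never its
  expectation, so any reasonable range serves. Segments are straight
  cylinders without end caps, keeping the truth closed-form:
  $L = \sum \ell_i$, $V = \sum \pi r_i^2 \ell_i$,
  $S = \sum 2 \pi r_i \ell_i$.
* **Orientation isotropic** (uniform on the sphere), matching the IUR
  design assumption; an `axial` mode exists to demonstrate what anisotropy
  does to section-based estimates.
* **Boundary handling: segments wholly inside.** Candidates whose cylinder
  would protrude are rejected (the region is eroded by the radius; exact
  for boxes and spheres, a conservative semi-axis shrink for ellipsoids).
  This leaves a thin depleted layer at the boundary. It does not bias the
  estimators — a transect's sampling probability depends only on its
  length and direction, and the capillary phase stays nested in the
  reference phase — but it is a feature real cortex does not have.
* **`no_overlap = TRUE`** rejects candidates whose centre-line comes
  closer than the sum of radii to an accepted segment, so cylinder volumes
  are disjoint and the Delesse ground truth is exact. It is off by default
  (dense phantoms would reject heavily); the volume-fraction validation
  switches it on.

What a green validation on this phantom establishes: the counting rules,
the section geometry and the four formulas are implemented without bias.
What it does not establish: robustness to features of real tissue — vessel
tortuosity and branching, section thickness (see below), staining and
segmentation error, anisotropic microvasculature.

## The virtual microtome

`iur_plane()` draws the normal area-uniformly on the unit sphere, the
position uniformly over the region's support interval along that normal,
and an extra uniform in-plane rotation — the mathematical target of the
physical "isector/sector" randomization. `cut_slabs()` produces the
Cavalieri stack with a uniform random phase in $[0, t)$.

`section_network()` intersects each cylinder with the plane: a transect
exists iff the axis crossing lies within the segment, and its profile is
an ellipse with semi-axes $(r, r/|\cos\theta|)$, $\theta$ the angle
between axis and normal. Segments lying in the plane
($|\cos\theta| < 10^{-9}$) are skipped and logged via the
`n_parallel_skipped` attribute — a measure-zero event under IUR sampling.

**Sections are idealized zero-thickness planes.** The study cut 4-µm
physical sections; projecting a slab onto one image overcounts profiles
(overprojection / Holmes effect). The plane formulas above are exactly the
ones the study used, so the package deliberately models the plane, and
this bias channel is out of scope — a documented limitation, not an
accident.

**Counting against the 3D phantom.** The pipeline's per-section tallies
(`section_counts()`) test probe points and lines against the cylinders
themselves rather than against full analytic ellipses. Near a segment end
an oblique cut is a truncated ellipse; for nearly in-plane cylinders the
idealized full ellipse becomes enormous (semi-major $r/|\cos\theta|$ with
$|\cos\theta| \to 0$) while the visible profile stays bounded by the
vessel's length. Counting the idealized ellipse would make point and
intersection counts heavy-tailed and badly biased upward; the 3D test
reproduces exactly what is visible on the section. Transect counts are
unaffected by this distinction.

**Whole-section counting.** Counting is exhaustive over each section —
the limit of a complete unbiased-frame tiling — so $\sum A$ is the
analytic section area (polygon clipping for boxes, conic algebra for
ellipsoids and spheres) and $\sum L$ is the in-region chord length of each
test line. The frame-level machinery (`counting_frame()`,
`count_profiles_in_frame()`, `frame_tiles()`, `sample_fields()`) is
exercised and validated separately; sampling a subset of fields per
section would only add variance on a phantom this small, and partial
frames at the region boundary would need area-weighting the whole-section
route avoids.

## The counting rules

* **Unbiased frame (default).** A profile is counted iff it meets the
  closed frame and does not touch the forbidden set: left edge, bottom
  edge, the upward extension above the top-left corner and the downward
  extension below the bottom-right corner. The study's figure legend
  ("counted if completely inside or touching the solid lines") omits the
  forbidden-line clause in words, but the figure draws solid and dashed
  lines and calls the frame unbiased; without forbidden edges the
  frame-tiling identity fails and the count is biased upward, so the
  Gundersen rule is the default and the literal reading is available as
  `rule = "inclusive"` for comparison.
* **Ties count.** A point on a profile boundary is a hit; a tangent line
  counts one intersection; a profile touching an inclusion edge is
  counted. Consistency matters more than the measure-zero cases
  themselves.
* **Strict capillary criterion.** Profiles with true diameter (twice the
  semi-minor axis, which equals the cylinder diameter regardless of
  obliquity) of 10 µm or more are excluded — strictly "less than 10 µm".

## Statistics

Group comparisons mirror the published analysis: per-group mean ± sample
SD (n − 1), one-way ANOVA, and pairwise two-sample t tests with the strict
p < 0.05 criterion. The published tables report only ANOVA and starred
pairwise claims without naming a post-hoc procedure; the unadjusted
pooled-variance t test is the default reconstruction device (its p values
match the published stars), with Welch and Tukey-HSD variants behind
`method =` flags for robustness checks. ANOVA and the t tests are computed
exactly from summary statistics — between-group sums of squares from the
means, within-group from the SDs — which is identical to the raw-data
computation. Whether "±" is SD or SEM matters enormously here; the source
states SD, and that is assumed throughout.

## The calibrated synthetic study

`default_study_config()` builds a three-group (control / CUS-standard /
CUS-running, n = 10) study whose per-animal truths are drawn from the
published tables:

* True length densities are the published total length / region volume
  ratios (densities are scale-free).
* Region volumes are scaled so the control CA1 mean is a (500 µm)³ box —
  about 1/271 of the real 33.9 mm³ — keeping a full study tractable on
  one CPU. All densities and statistical contrasts are unaffected by the
  scale choice.
* The between-animal SD of the length density is set so the induced CV of
  total length matches the published CV, after removing the volume CV in
  quadrature (with a 3% floor where the published volume CV alone already
  reaches the length CV, as happens in DG).
* The radius is constant at 2 µm, so the phantom's capillary volume and
  surface effects mirror its length effects exactly — slightly tighter
  coupling than the published tables, which imply mild radius variation.

Two honesty notes. First, the published SDs include the original study's
own estimation noise; using them as *truth* SDs and then adding this
package's estimation noise (≈4% CV on total length at 50 sections/animal
with the sparse probe settings used in the acceptance run) double-counts
noise, making the synthetic detection test slightly conservative —
measured detection power is around 0.6 against ≈0.7 for noise-free truths.
Second, the slab thickness is scaled to 25 µm so the slab count across a
phantom region (~20) resembles the real 1-mm slabs across a hemisphere;
keeping 1 mm at phantom scale would leave ~5 slabs and a 6% quantization
CV that real Cavalieri designs do not have.

Whether the published capillary parameters refer to one hemisphere or the
whole brain is not stated in the source; the phantom models a single
region and sets the hemisphere factor to 1, so all comparisons are
internally consistent regardless.

## Numerical choices

* Parallel-plane tolerance $10^{-9}$ on $|\cos\theta|$; quadratic
  discriminants within a relative $10^{-10}$ of zero count as tangencies
  (one intersection).
* Ellipsoid section geometry uses the conic form
  $u^\top Q u + 2 b^\top u + c \le 0$ in plane coordinates; box sections
  use Sutherland–Hodgman polygon clipping and shoelace areas; chords use
  slab clipping (box) or the quadratic (ellipsoid/sphere).
* Monte-Carlo validation uses pooled ratio estimators $\sum y / \sum x$
  with linearized (Taylor) standard errors; the empirical spread of the
  pooled estimator over independent batches matches this SE (checked for
  the surface estimator, the most heavy-tailed of the three, where rare
  near-tangential sections dominate the variance).
* All randomness flows through R's RNG under explicit seeds; a fixed
  configuration reproduces byte-identical study reports.

## Known limitations

* Straight, unbranched, non-overlapping (optionally) cylinders; no
  tortuosity, no bifurcations, no diameter taper.
* Zero-thickness sections: no overprojection or lost-caps modelling.
* The ellipsoid inset used to keep cylinders inside is conservative, not
  an exact erosion.
* Degenerate pairwise tests (both SDs zero) return p ∈ {0, 1} by
  convention rather than failing.
* The reconstruction can only be as good as the printed summaries; one
  published claim (control vs running, DG capillary surface) is marginal
  under the pooled t (p ≈ 0.056) and is deliberately not asserted either
  way.
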