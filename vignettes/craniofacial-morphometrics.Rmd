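---
title: "Dense 3D craniofacial phenotyping with symmetric pseudo-landmarks"
author: "craniomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dense 3D craniofacial phenotyping with symmetric pseudo-landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(craniomorph)
```

# The problem

Fish crania are anatomically dense: many small, closely apposed bones whose
shape differences under a mutation are subtle, three-dimensional, and often
asymmetric. Sparse manually placed landmarks miss variation between
homologous points, and manual placement does not scale to screening designs.
This package implements an atlas-based alternative: a dense, bilaterally
symmetric set of *pseudo-landmarks* is generated once on a template
(atlas) surface, transferred automatically to every specimen mesh by
point-cloud registration, and analyzed with the standard machinery of
geometric morphometrics — generalized Procrustes analysis (GPA) with sliding
surface semilandmarks, a bilateral object-symmetry decomposition, and
permutation inference. A parallel track validates atlas-based segmentation by
propagating label volumes (otoliths) through per-specimen displacement
fields and comparing volumes against manual segmentations.

Because the kind of MicroCT data this targets is rarely redistributable, the
package ships a fully parameterized synthetic-study generator with exact
ground truth, and every statistical claim in the test suite is made against
that generator or against independent numerical oracles.

# Shape analysis

## Superimposition

A configuration is a $k\times 3$ matrix $X$ of landmark coordinates (mm).
Size is measured by centroid size
$\mathrm{CS}(X)=\sqrt{\sum_i\lVert x_i-\bar x\rVert^2}$; *normalized*
centroid size divides by $k$ so that landmarking schemes with different
point counts are comparable. Pairwise superimposition is the classical
least-squares Procrustes fit: centering, optional scaling, and the
Kabsch/Umeyama rotation from the SVD of the cross-covariance, with the
determinant sign forced to $+1$ — reflections are never admitted, which
matters in a package whose central operation is comparing a shape with its
mirror image. The Procrustes distance between two configurations is the
residual norm after centering, scaling both to unit centroid size, and
optimal proper rotation.

GPA iterates: center (and optionally rescale) each configuration, rotate
each onto the running consensus, re-estimate the consensus, until the total
Procrustes sum of squares changes by less than `tol` (default $10^{-10}$,
relative; at most 100 iterations, non-convergence is flagged rather than
silent). The consensus is initialized from the first configuration. For
samples of similar shapes — the only regime in which GPA coordinates mean
anything biologically — the superimposition objective has one relevant
basin and the initialization is immaterial. For deliberately heterogeneous
inputs (e.g. unrelated random clouds, which the test suite uses to probe
the optimizer) several basins exist; `run_gpa(n_inits = m)` tries the first
$m$ configurations as consensus seeds and keeps the lowest-objective fit.
The final orientation is standardized by rotating the consensus onto its
principal axes, with each axis sign fixed by the third moment of the
projected coordinates — a statistic of the shape itself, so the output does
not depend on the pose in which the data arrived.

## Sliding semilandmarks

Pseudo-landmarks carry no point-to-point homology along the surface, so
after each GPA convergence they are allowed to slide within their local
tangent planes before the GPA is re-run (default 3 rounds). Tangent planes
come from supplied per-vertex surface normals when a mesh is available, or
from a local plane fit through the `surface_neighbors = 8` nearest
semilandmarks otherwise. Two sliding criteria are available:

* `bending_energy` (default, the convention of the surface-semilandmark
  literature): displacements minimize the thin-plate-spline bending energy
  against the consensus, using the 3D kernel $U(r)=-r$ and the bending
  energy matrix $E$ (the upper-left $k\times k$ block of the inverse
  bordered TPS system built on the consensus). Sliding a specimen solves
  one quadratic program in the $2k_s$ tangent coefficients with Hessian
  $H_{(ia),(jb)} = E_{ij}\,(w_{ia}\cdot w_{jb})$; a relative ridge of
  $10^{-10}$ guards the solve against the (theoretically PSD, numerically
  borderline) spectrum of $E$.
* `procrustes_distance`: minimizes the summed squared distance to the
  consensus; per landmark this reduces to the closed-form projection of the
  residual onto the tangent plane, and the combined slide-then-GPA
  iteration is plain coordinate descent on the Procrustes objective, hence
  monotone.

Displacements are exactly in-plane by construction — points never drift off
their tangent anchors. With an empty sliding set the code path reduces to
plain GPA bit for bit.

## Bilateral object symmetry

The skull is one structure with internal left/right correspondence,
described by a `bilateral_map` (paired indices plus midline indices).
Reflection-relabeling mirrors a configuration across the sagittal plane
(an arbitrary-plane Householder map, so imported data with any plane fit
works) and swaps side labels; it is an involution, and the canonical
synthetic-data plane is $x=0$.

`decompose_object_symmetry` doubles the sample with reflected-relabeled
copies, runs a joint GPA on all $2n$ configurations, and then standardizes
the frame so that the consensus is *exactly* plane-symmetric about $x=0$:
the best improper orthogonal alignment of the relabeled consensus onto
itself yields the plane normal (the eigenvector of its symmetric part with
eigenvalue near $-1$), the frame is rotated to put that normal on the
$x$-axis, the left/right sign is fixed by requiring the first off-plane
pair to sit at $x\ge 0$, and the in-plane orientation is fixed by the
in-plane principal axes with the third-moment sign rule. In this frame the
reflection operator $S$ is a fixed linear involution, and each aligned
specimen decomposes as

$$\mathrm{sym}_i=\tfrac12\bigl(a_i+S(a_i)\bigr),\qquad
  \mathrm{asym}_i=\tfrac12\bigl(a_i-S(a_i)\bigr),$$

which makes the advertised invariants *identities*: reconstruction is exact
addition, symmetric components are themselves symmetric, the two components
are orthogonal, and applying reflection-relabeling to all inputs negates
the asymmetric components. The mean asymmetric component is the sample's
directional asymmetry; per-specimen fluctuating-asymmetry scores are the
Procrustes norms of the deviations from it. One caveat documented rather
than hidden: alignment measures asymmetry net of similarity transforms, so
the component of a constant asymmetric offset that a rigid rotation can
absorb (a few percent for a generic offset) does not appear in the
directional-asymmetry estimate.

# Permutation inference

`procrustes_anova` is the distance-based one-factor shape ANOVA with
residual randomization: $SS_{\text{effect}}$ from group means versus the
grand mean, $F=(SS_e/df_e)/(SS_r/df_r)$, and a null distribution obtained
by permuting the residual vectors of the reduced (intercept) model —
for a single factor, equivalently the rows of the centered data. The
p-value uses the add-one rule $p=(1+\#\{F^\ast\ge F\})/(B+1)$ with the
observed statistic included in the null set ($B=999$ by default), so $p$ is
never zero; the effect size is
$Z=(\log F-\overline{\log F^\ast})/\mathrm{sd}(\log F^\ast)$, a
distribution-standardized quantity that can legitimately be negative for
sub-null effects. When the number of distinct group assignments is at most
10,000 the full enumeration replaces sampling and $p$ is exact. Per-PC
group tests are the same machinery applied to one column of PC scores.

`morphological_disparity` reports per-group Procrustes variance (mean
squared distance from the group mean) and tests pairwise absolute variance
differences. The randomized units are the residual vectors of the
*reduced* (grand-mean) model — under the null hypothesis these rows are
exchangeable, which makes the permutation level exact — while the variance
statistic re-centers vectors within whatever group they land in, so group
mean differences cannot masquerade as dispersion differences. (Randomizing
full-model residuals, the seemingly obvious alternative, is measurably
liberal at these sample sizes because group-centered rows are not
exchangeable.)

The univariate battery used by the validation analyses delegates where
delegation is right: Welch's $t$ via `stats::t.test` (with explicit
degenerate-variance conventions), the parametric one-way ANOVA via
`stats::aov` plus a permutation p-value from the shared machinery, and a
paired signed-rank test implemented here because the exact null under ties
requires enumerating sign assignments, which `stats::wilcox.test` declines
to do ($\le 15$ non-zero pairs enumerate all $2^n$ patterns; beyond that, a
normal approximation with tie and continuity correction).

Shape PCA is the SVD of centered flattened coordinates; axes with singular
values below $10^{-8}$ of the leading one are treated as null, fractions
are reported over the retained axes, and axis signs are fixed by making the
largest-magnitude loading positive. Heat-map fields place the end shape at
`extent` score standard deviations along an axis and report per-landmark
displacement vectors and magnitudes; with unit loadings the summed squared
magnitudes equal $\text{extent}^2\times\mathrm{var(scores)}$ identically.

# Pseudo-landmarks and transfer

`generate_pseudo_landmarks` samples one side of the template by
farthest-point sampling at a target spacing, mirrors the sample across the
plane and snaps each image to the nearest vertex (on an exactly symmetric
template this lands on the mirror partner, making the set an exact
reflect-relabel fixed point), and adds midline points from the on-plane
vertex ring (falling back to plane-projected band vertices, band half-width
$0.25\times$ spacing, for meshes without one). A final symmetric pruning
pass enforces a minimum inter-point distance of $0.5\times$ spacing,
dropping bilateral pairs jointly so symmetry survives. `target_count`
drives a bisection on spacing; the default target of 372 reproduces the
operating point of the emulated study. Region filtering removes points
whose nearest template vertex carries an excluded label — jaws and pectoral
girdle by default, structures dominated by post-mortem handling variation —
again dropping partners jointly.

Transfer to a specimen runs rigid-then-deformable point-cloud
registration. Both clouds are voxel-grid downsampled to roughly
`target_points` (default $\approx 800$; registration accuracy on these
meshes saturates well below dense sampling, and density equalization is
what actually matters — coherent point drift chases density gradients on a
raw UV-grid mesh). The rigid stage is ICP with a closed-form
proper-rotation fit; scaling is off by default, the right choice when
specimens are of similar size. Its initialization is two-stage: a coarse
centroid-shift pass — which presumes roughly pre-aligned specimens, the
only reliable way to choose among the four 180-degree impostor alignments
a bilaterally and fore-aft pseudo-symmetric skull admits without feature
matching — selects the symmetry branch, and the reported fit then runs
from the corresponding canonical principal-axes start, a function of each
cloud's own geometry, which makes the whole transfer exactly equivariant
under rigid motions of the specimen. The deformable stage is coherent point
drift: the template cloud is a Gaussian mixture with outlier weight
$w=0.1$, displacement expressed as a Gaussian-kernel expansion
$T(y)=y+G(y,Y)W$ with kernel width $\beta = 2\times$ the pseudo-landmark
spacing and smoothness weight $\lambda=2$. EM stops on relative
$\sigma^2$ change below `tol`, at `max_iter`, or at a variance floor
($10^{-9}$ of the target spread) below which the M-step ridge
$\lambda\sigma^2$ would vanish and the solve would lose conditioning.
Landmarks ride the same kernel interpolant (exact at control points);
projection onto the target surface is available but off by default, since
raw deformed points are the convention of the transfer pipeline emulated.

# Label-volume propagation

Label maps are categorical, so warping is pull-back with nearest-neighbor
sampling: the output label at voxel center $x$ is the atlas label at the
voxel nearest to $x+u(x)$, with rounding to nearest (ties to even),
out-of-bounds mapped to background, and therefore no invented labels.
Geometry is axis-aligned (`origin + index * spacing`); no direction matrix
in this version. Volumes are voxel counts times voxel volume. A fixed-point
field inverter supports composition sanity checks. The comparison report
follows the validation design: pooled manual-versus-automated Welch test,
per-label manual-versus-automated tests, and per-label group tests on the
manual volumes.

# The synthetic study

The generator's defaults are the study conditions, chosen once:

* Design: 12 mutant and 14 wild-type specimens (the analysis pool), a
  notional 23-specimen wild-type template pool, 23 manual landmarks
  digitized twice.
* Template: a closed, watertight, exactly mirror-symmetric skull-like
  surface — an ellipsoid (semi-axes $1.5\times2.5\times1.2$ mm, roughly an
  adult zebrafish neurocranium) with bilateral opercular lobes, frontal and
  parietal dorsal ridges, jaw and pectoral-girdle protrusions, each vertex
  carrying a region label.
* Deformations: smooth analytic fields (sums of radially directed Gaussian
  bumps anchored on the surface) rather than image-registration output, so
  the ground-truth image of any template point is exact and cheap. The
  individual field is bilaterally symmetric (mirrored bump pairs, amplitude
  sd 0.02 mm, six pairs); fluctuating asymmetry is a one-sided field
  (amplitude sd 0.008 mm, four bumps); mutants add a symmetric effect
  (mirrored bumps on the anterior frontal and dorsal operculum, amplitude
  0.04 mm — twice the individual amplitude sd), a *purely antisymmetric*
  effect (a bump pair with opposite signs on the posterior parietal and
  ventral operculum, 0.04 mm; a one-sided bump would leak half its
  amplitude into the symmetric component), a $5\%$ size increase, and
  individual size variation of $2\%$ log-sd for everyone (specimens of
  similar but not identical size). Digitization noise is isotropic with
  sd 0.021 mm, one CT voxel.
* Otoliths: three bilateral ellipsoid pairs (lapillus, sagitta,
  asteriscus — the largest) in a $96^3$ grid at 15 µm spacing, individual
  volume CV $8\%$, mutant multipliers 1.10/1.10/1.25, and per-specimen
  displacement fields that are exact local similarities around each otolith
  blended smoothly to zero (positive Jacobian by construction), regenerated
  on demand rather than stored.

Every stochastic draw descends from one study seed through named
substreams, so any stage reruns identically. What the generator does *not*
emulate — and what passing tests therefore do not certify on real data —
includes CT intensity and segmentation error, non-smooth or folding
deformations, anatomically realistic covariance beyond the low-rank bump
structure, clutch effects (two clutches exist in the design but carry no
injected effect), and landmark placement error that correlates with local
anatomy.

A landmark-level twin (`simulate_symmetry_study`) draws whole studies
directly in shape space — a symmetric base configuration, individual
variation as random loadings on ten fixed symmetric modes, fluctuating
asymmetry on ten antisymmetric modes, group shifts along one additional
unit mode per component, isotropic noise, random rigid motions — cheap
enough for the 500-replicate type-I and 100-replicate power studies in the
acceptance suite. Its convention for "effect at $2\times$ the
individual-field sd" is a shift of amplitude $2\sigma$ along one mode,
matching the mesh generator's bump-amplitude convention; a full-rank
isotropic reading would make any realistic effect undetectable at $n=26$
in 300 coordinates.

# The end-to-end pipeline

`run_study` chains the stages: pseudo-landmark generation with the target
count re-tuned after region filtering (so the final filtered count lands on
the target), transfer to every specimen, sliding GPA, symmetry
decomposition, group Procrustes ANOVAs on both components, a Welch test on
fluctuating-asymmetry scores, separate PCAs with per-PC tests and heat-map
fields, the manual-landmark validation battery (digitization error, method
ANOVA, per-landmark signed-rank tests, joint GPA with method factor,
disparity, normalized centroid size), and the otolith volume analysis.
Every statistical entry carries its statistic, $Z$ where applicable, $p$,
permutation count and seed; all stage seeds derive from the single
configuration seed, and a rerun is bit-identical. Stage failures abort with
the stage name and offending specimen.

Known limitation worth stating plainly: transfer error scales with
deformation magnitude, so a large *symmetric* group effect (or a size
effect, with scaling disabled in the rigid stage) increases registration
noise in the mutant group, and that noise is not itself symmetric — at the
pipeline level a symmetric-only injection can therefore nudge the
asymmetric-component test away from its nominal level. The decomposition
itself separates the components exactly (the statistical-layer tests show
clean separation in both directions); the leakage is a property of
landmark transfer, as it would be for any registration-based pipeline.

# Problem sizes and numerical choices, summarized

Test-suite simulations use $k=100$ landmarks (46 pairs, 8 midline) at the
study's $12+14$ design for calibration (500 null replicates, 999
permutations; 100 replicates per power direction, 199 permutations), and
the full mesh pipeline at its native size (about 4,500 template vertices,
372 pseudo-landmarks, clouds of about 800 points) for end-to-end checks.
GPA tolerance $10^{-10}$ (joint symmetry GPA $10^{-12}$), CPD tolerance
$10^{-6}$ with at most 60 iterations, TPS ridge $10^{-10}$, PCA null-axis
threshold $10^{-8}$ of the leading singular value, permutation defaults
$B=999$ with exhaustive enumeration under 10,000 assignments, no
multiple-testing correction by default (the volume report takes a
`p_adjust` method, Holm included, and the per-landmark p-vectors the other
reports expose feed `stats::p.adjust` directly). Degenerate inputs — zero centroid size,
single-level factors, zero residual variance, all-zero paired differences —
raise errors rather than returning NaN, because silent NaNs poison
permutation loops.
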