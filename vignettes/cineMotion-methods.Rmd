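---
title: "Contour registration and swallowing motion estimation: models, parameters and design choices"
author: "cineMotion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contour registration and swallowing motion estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cineMotion)
```

## The problem

A sagittal 2D MR cine sequence of a swallow shows seven structures —
pharyngeal constrictor, epiglottis, base of tongue, geniohyoid, hyoid, soft
palate, larynx — each contoured on every frame of the cycle. The quantity of
clinical interest is, per structure and per anatomical direction (superior,
inferior, anterior, posterior), how far the structure is displaced at each
frame relative to the pre-swallow rest frame, summarised by the maximum over
the cycle. The contours are the only input: pixel data never enter the
pipeline. The structures deform non-rigidly, the point count changes from
frame to frame, and manual contours carry delineation noise and occasional
spurious vertices, so the registration step must be non-rigid, be
correspondence-free and tolerate outliers in both point sets.

## The matching model

### Thin-plate-spline transform

The per-pair warp is a 2D thin-plate spline,

$$f(x) = x L + t + \sum_{j=1}^{K} w_j\, U(\lVert x - v_j \rVert),
\qquad U(r) = r^2 \log r,$$

anchored at the (resampled) source contour points $v_j$, subject to the side
conditions $\sum_j w_j = 0$ and $\sum_j w_j v_j = 0$ that make the warp
affine at infinity and give it a finite bending energy
$E = \mathrm{tr}(W^\top \Phi W)$, $\Phi_{jk} = U(\lVert v_j - v_k\rVert)$.
Given soft correspondences, the transform update minimises

$$\sum_j \omega_j \lVert f(v_j) - y_j \rVert^2
  + \lambda\, E(f) + \lambda_2 \lVert L - I \rVert_F^2,$$

where $y_j$ is the correspondence-weighted mean of the target points claimed
by $v_j$ and $\omega_j$ its total correspondence mass. `tpsSolve()` solves
this in closed form: the warp coefficients are parameterised in the null
space of the side conditions via a QR decomposition of $[\,1\;V\,]$ and the
normal equations for (warp, affine) are one dense symmetric solve. The
$\lambda_2$ ridge on the linear part is essential and deserves its own
paragraph below.

### Softassign with two-sided outlier bins

Correspondence is a non-negative $(N{+}1)\times(K{+}1)$ matrix whose first
row and column are outlier bins. Inner entries are initialised as Gaussian
affinities $\exp(-\lVert x_i - f(v_j)\rVert^2/2T)/T$ at the current
temperature $T$; the bins use a fixed hot temperature $T_0$ (the initial
temperature) and are centred at the opposing set's centroid. Alternating
row/column (Sinkhorn) normalisation of the non-outlier rows and columns
drives the matrix towards doubly stochastic form (tolerance `sinkhornTol =
1e-3`, at most `sinkhornMaxSweeps = 30` sweeps). Because the bins are
excluded from normalisation, they retain a structural soft share of a few
percent even for perfectly matched sets; the diagnostics therefore report
both the soft bin mass and the operational quantity — the number of points
whose *strongest* assignment is a bin — and the latter is zero for clean
matched sets and exactly the spurious-point count in the two-sided outlier
stress test.

### Deterministic annealing

The outer loop cools $T$ geometrically from $T_{\mathrm{init}}$ (the mean
squared source–target distance in the unit box, factor `tInitFactor = 1`) to
$T_{\mathrm{final}}$, with `innerIters = 3` correspondence/transform
alternations per temperature, and both penalties annealed with temperature:
$\lambda = \lambda_0\, T K$ and $\lambda_2 = \lambda_{2,0}\, T K$. Early
(hot) iterations therefore behave near-rigidly and the transform relaxes as
the correspondence hardens, which is what lets the matcher survive the large
deformations of a swallow. The loop runs the full schedule — no early
stopping — so results are bit-for-bit reproducible.

## Parameters, defaults, and why

| parameter | default | units | rationale |
|---|---|---|---|
| resampling spacing | 1 | mm | the in-plane pixel size; makes point densities comparable across frames |
| `tInitFactor` | 1 | – | mean squared pair distance is the conventional hot start |
| `tFinalFactor` | 0.04 | – | see below |
| `rate` | 0.93 | – | standard geometric cooling; ~100–130 outer levels per pair |
| `innerIters` | 3 | – | alternations per level; more buys little once cooling is slow |
| `lambdaInit` | 1 | – | bending weight $\lambda = \lambda_0 T K$; keeps hot iterations near-rigid |
| `lambda2Init` | 0.01 | – | affine-identity ridge, annealed like $\lambda$ |
| grid spacing / margin | 1 / 2 | mm | pixel-sized motion sampling with a small halo |
| `suspectMm` / `failMm` | 1 / 2 | mm | registrations are normally accurate to ~1 mm; tuned difficult cases to ~2 mm |

**Why the final temperature sits well below the squared point spacing.** At
$T \approx s^2$ (squared resampling spacing $s$), the Gaussian affinity of a
point's *neighbours* along the contour is still $e^{-1/2} \approx 0.6$, so
virtual targets are blends of adjacent target points. On a curved contour
that blend sits inside the curve, leaving a curvature-dependent bias of
order $10^{-2}$ unit-box units. Cooling to a few percent of $s^2$
(`tFinalFactor = 0.04`) makes correspondences effectively binary; measured
known-warp recovery error drops from about $10^{-2}$ to $10^{-4}$ unit-box
units for roughly 12% more outer iterations.

**Why the affine ridge exists.** With the affine part unconstrained, any
linear map that carries a contour onto itself costs nothing in the data term
and nothing in bending. Ellipse-like contours admit a one-parameter family
of such maps (conjugated rotations), and the plain alternation happily
drifts into them: the registered *contour* is perfect while every individual
point has slid tangentially — for an ellipse translated 5 mm superiorly we
observed per-point displacement errors above 20 mm at a contour error of
0.04 mm. Since the deformation field, not the contour overlap, is the
product of interest, the solver anchors the linear part to the identity with
a ridge that anneals away with temperature: it breaks the tie early, biases
nothing at convergence (where $\lambda_2 \to 0$), and restored per-point
translation recovery to under 0.1 mm. This is also why the solve uses the QR
null-space parameterisation rather than a single bordered system: with the
ridge, warp and affine parts no longer decouple through the side-condition
trick.

## Preprocessing conventions

Closed contours are resampled by arc length with a deterministic start
(counter-clockwise orientation, start at the lowest-y-then-lowest-x vertex),
so repeated runs are identical. The actual separation is $L/\mathrm{round}(L/s)$
for perimeter $L$. The unit box is **shared by the pair** (union bounding
box) and **isotropic** (one scale, the longer side): per-set or per-axis
scaling would warp the anatomical axes and inject spurious relative motion
between frames. The estimated unit-box transform is conjugated back to mm
analytically — the TPS family is closed under similarity conjugation because
the side conditions absorb the kernel's $\log$-scale cross terms into the
translation — so the returned transform is an ordinary mm-space TPS.

## From transforms to motion

Motion between non-adjacent frames concatenates the consecutive-pair
transforms by pushing each grid point through them in order. Because each
transform is analytic and globally defined, composition re-evaluates at the
moved position; interpolating gridded vectors instead would add resampling
error at every hop and was rejected for that reason. The inside mask is
taken from the contour of the *initial* frame — the frame whose ROI the
motion describes — using the even-odd rule with boundary points counted
inside (the contour itself must contribute to motion). Displacements are
rectified per grid point before averaging: each point contributes only to
the direction it actually moves in. For coherently moving ROIs this equals
rectifying the mean; for shearing ROIs the two differ and per-point
rectification is the one consistent with averaging "motion in direction
$d$" over grid points. The sign conventions are fixed by requiring contours
in a right-handed mm frame with +y superior and +x anterior; the reader's
`flipRows` argument converts pixel-row input into this frame.

## Validation and the reflex failure mode

The registration error is the symmetric mean closest-point distance between
the deformed source contour and the target contour (index-wise pairing is
meaningless after resampling). Errors at or below 1 mm are `ok`, up to 2 mm
`suspect`, above `failed`; boundary values take the lower status, and
flagged cases are listed for manual schedule adjustment rather than retried.

Narrow elongate contours have a characteristic failure mode: a *reflex*
solution that registers one long side onto the opposite side. `reflexCase()`
makes this mode concrete — a bowed 10:1 band pair together with the TPS
fitted to the side-swapped correspondence — and the validation check flags
the reflex solution at about 5.5 mm error. Notably, in extensive stress
testing (aspect ratios to 20:1, rotations to 180°, strong constrictions, bow
flips, cold starts) the default annealed schedule never converged to the
reflex itself; the annealing and the identity ridge are precisely the
safeguards against it. The failure mode is therefore demonstrated on the
explicitly constructed reflex solution, which is also the honest statement
of what the validation layer can and cannot see: it flags solutions whose
*contour* is wrong, and a tangentially slid solution with a perfect contour
overlap passes it.

## The synthetic generator

`generateSequence()` emulates what the pipeline consumes: per-frame closed
contours of parametric shapes (ellipse, harmonic blob, crescent, narrow
band with aspect ≥ 8:1 standing in for the pharyngeal constrictor) carried
by a smooth displacement — a directional translation rising to a peak frame
and optionally rebounding past rest, plus a low-order TPS perturbation
scaled by the same activation — with Gaussian jitter applied along the local
contour normal and optional spurious vertices. Normal-directed jitter was a
deliberate choice: delineation uncertainty acts across the boundary, and
isotropic jitter at 1 mm vertex spacing routinely self-intersects the
polygon. Ground truth is computed from the noise-free motion model on the
same grid the estimator uses. The default seven-ROI scene uses per-direction
amplitudes near the cohort means reported for each structure (e.g. larynx
≈ 18 mm superior, geniohyoid the smallest overall) over 22 frames, the
typical contoured cycle length.

What passing synthetic tests does **not** show: real contours have
frame-to-frame delineation inconsistencies that are neither Gaussian nor
normal-directed, shapes change topology-adjacent features (the air column
opens and closes), and real outliers are structured. The synthetic suite
validates the machinery — recovery of known warps, error calibration,
failure flagging — not clinical accuracy.

## Numerical choices and degenerate inputs

* Points with correspondence mass below `1e-8` are dropped from the solve
  (pure outliers would otherwise make the weighted system ill-conditioned).
* Collinear or duplicate control points at $\lambda = 0$ raise an error
  advising a positive $\lambda$; fewer than three weighted points is an
  error.
* Contours shorter than twice the resampling spacing, coincident point
  clouds, non-finite coordinates and empty inside masks are all rejected
  with specific messages rather than coerced.
* Ties in the nearest-neighbour limit need no explicit tie-break: Sinkhorn
  splits mass symmetrically and the transform update uses weighted means.
* The kernel is evaluated as $\tfrac12 r^2 \log r^2$ with $U(0)=0$, avoiding
  a square root.

## Problem sizes

The shipped tests register contours of 40–150 points; the benchmark suites
use 50 smooth-shape pairs and 20 elongate-shape pairs with deformation
amplitudes up to 15 mm and jitter sd 0.2 mm, and the end-to-end recovery
sequences use 6–8 frames. A consecutive-pair registration takes a few
seconds in pure R; a full 7-ROI, 22-frame scene is a few hundred
registrations and runs unattended via `runBatch()`.

## Known limitations

* Sagittal plane only: left–right motion needs coronal or axial cines and is
  out of scope, as is any image-based (intensity) registration.
* Point-level correspondence on near-symmetric contours is not identifiable
  from geometry alone; the estimated *fields* are accurate where the
  contour constrains them, but tangential components on symmetric arcs are
  regularisation-determined.
* The soft outlier-bin mass never reaches zero (structural to un-normalised
  bins); use the hard assignment count for outlier detection.
* Motion is reported against the first contoured frame and is not aligned to
  physiologic events (peak constriction, post-swallow rest); temporal
  alignment is future work.
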