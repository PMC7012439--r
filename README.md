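# cineMotion

Swallowing-structure motion estimation from 2D MR cine contours.

Radiotherapy for head-and-neck cancer puts swallowing structures — the
pharyngeal constrictor, epiglottis, base of tongue, geniohyoid, hyoid, soft
palate and larynx — at risk, and quantifying how far each structure moves
during a swallow is the basis both for personalised treatment margins and
for tracking radiation-associated dysphagia. Sagittal 2D MR cine sequences
(1 × 1 mm² pixels, one frame every 160 ms) capture the swallow, and the
structures are contoured frame by frame; what remains, and what this package
automates, is turning those per-frame contours into directional motion
estimates with a built-in quality check, with no interaction after the
contours are drawn.

## Method

For each region of interest (ROI), consecutive-frame contours are registered
with a modified **thin-plate-spline robust point matching** (TPS-RPM)
algorithm:

* contours are resampled to uniform arc length at the pixel size and the
  pair is mapped into a shared unit box;
* **softassign** maintains a fuzzy correspondence matrix
  `m[i, j] ∝ exp(−‖x_i − f(v_j)‖²/2T)`, with an outlier row *and* column so
  spurious points in either set can opt out, kept near doubly stochastic by
  alternating row/column normalisation;
* the transform `f(x) = xL + t + Σ_j w_j U(‖x − v_j‖)`, `U(r) = r² log r`,
  is re-fit in closed form to the correspondence-weighted virtual targets
  under the bending-energy penalty `λ tr(WᵀΦW)`;
* **deterministic annealing** lowers the temperature `T` geometrically while
  `λ ∝ T`, so matching is near-rigid while correspondence is fuzzy and
  increasingly non-rigid as matches harden.

The recovered analytic warps are composed across frames and sampled on a
1 mm grid over the initial-frame ROI; displacement vectors of grid points
inside the contour are rectified along the superior–inferior and
anterior–posterior axes and averaged, giving per-frame motion magnitudes
relative to the pre-swallow rest frame and a per-direction maximum over the
cycle. Every registration is validated by the symmetric mean closest-point
distance between the deformed and the reference contour; errors above 1 mm
are flagged `suspect`, above 2 mm `failed`, and flagged cases are reported
for manual schedule tuning, never retried silently.

No patient data ships with the package: a synthetic generator builds contour
sequences (including a narrow elongate pharyngeal-constrictor-like band)
with known ground-truth motion, so the whole pipeline is testable end to
end.

## Worked example

```r
library(cineMotion)

spec <- syntheticSpec("larynx", shape = "ellipse",
                      shapeParams = list(a = 14, b = 11),
                      amplitudes = c(superior = 18, inferior = 12, anterior = 7),
                      nFrames = 8, peakFrame = 5,
                      warpSd = 0.8, noiseSd = 0.2, seed = 42)
gen  <- generateSequence(spec)
gen$sequence
#> ContourSequence 'larynx': 8 frames (79-79 points/frame)
#>   pixel spacing 1 x 1 mm, frame interval 160 ms, frames 1..8

regs <- registerSequence(gen$sequence)     # 7 consecutive-pair registrations
tab  <- motionTimecourse(gen$sequence, regs)
tab
#> MotionTable 'larynx': 8 frames
#>   max over frames (mm):
#>  superior  inferior  anterior posterior
#>    17.950    12.090     7.304     0.583

classifyRun(regs)$counts
#>      ok suspect  failed
#>       7       0       0

round(motionSummary(gen$truth), 2)
#>  superior  inferior  anterior posterior
#>     17.47     12.53      7.54      0.01
```

The estimated maxima (17.95 / 12.09 / 7.30 mm superior / inferior /
anterior) recover the generator's ground truth (17.47 / 12.53 / 7.54 mm —
the nominal amplitudes modulated by the smooth non-rigid perturbation) to a
few tenths of a millimetre, and all seven registrations pass the 1 mm
quality gate. `writeMotionTable()` exports the table as CSV;
`plotMotion()` draws the direction-versus-frame curves used to locate the
peak swallow.

For unattended batch runs over many ROI files, see `runBatch()` (or the
thin CLI wrapper in `inst/scripts/cinemotion.R`), which writes per-ROI
motion CSVs, a per-registration error report and a JSON summary.

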