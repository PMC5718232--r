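---
title: "Calculation-based IMRT QA: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calculation-based IMRT QA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imrtqa)
```

## The problem

Patient-specific QA of intensity-modulated radiotherapy (IMRT) traditionally
means delivering the plan to a measurement phantom. A calculation-based
alternative verifies the delivery from the machine's own log files — the
linac records beam state, gantry/collimator angles, jaw positions, cumulative
meterset and per-leaf MLC positions every 50 ms — and verifies the dose by
comparing two independent dose calculations of the same plan. `imrtqa`
implements that paradigm as a toolkit: log integrity and identity checks,
delivered-vs-planned parameter comparison under clinical tolerances, fluence
reconstruction from logs, 2D gamma analysis between dose planes, and DVH
index comparison between dose grids, plus a synthetic generator so the whole
pipeline is exercisable with no clinical data.

## Data model and conventions

Positions are signed millimetres projected to the isocenter plane, beam's-eye
view, with X the leaf-travel axis: bank A holds the negative-X leaf tips,
bank B the positive-X tips, and leaf pair $i$ is open on $(a_i, b_i)$.
Angles are IEC 61217 degrees normalized to $[0, 360)$; angular deviations are
computed on the circle, $\min(|a-b|, 360-|a-b|)$, so a plan at 359.95° logged
at 0.05° deviates by 0.1°, not 359.9°. The default leaf geometry is a
Millennium-120-style bank (10 outer 10 mm pairs, 40 central 5 mm pairs, 10
outer 10 mm pairs), fully configurable down to 3-pair toys for tests.

Plans and logs travel in documented, versioned plain-text dialects
(`IMRTQA-PLAN 1`, `IMRTQA-LOG 1`) with fixed decimal precision, chosen so
that read/write round-trips are byte-exact and fixtures can live in version
control. A log whose row count disagrees with its declared header count
parses successfully and is flagged `TRUNCATED` by `check_integrity()` —
corrupt logs must still produce a report, not an exception.

## Parameter comparison and tolerances

`compare_beam()` evaluates, over beam-on samples only (parameters are
dosimetrically relevant only while dose is delivered):

* gantry and collimator angle: maximal circular deviation, tolerance 0.1°;
* each jaw: maximal linear deviation, tolerance 1 mm;
* MLC: maximal $|$actual $-$ expected$|$ over samples, banks and leaves (the
  machine's own servo error), tolerance 2 mm;
* delivered MU: final cumulative meterset × log MU vs planned MU, default
  tolerance 1% (no established clinical value; configurable);
* segment count: beam-on runs in the log vs plan segments.

A check is `WARNING` exactly when its deviation strictly exceeds its
tolerance, so a deviation sitting exactly at tolerance passes. A second,
independent MLC figure — the *transfer error* — compares the log's expected
leaf channel against the plan control points, catching data-transfer
corruption that the servo loop cannot see. At a segment boundary the closing
sample of one segment and the opening sample of the next share a meterset
value while legitimately holding different shapes, so the plan aperture at a
boundary meterset is taken as the better-matching of the two bracketing
segment shapes; tie-breaking to one side would flag every clean boundary.

## Fluence reconstruction

The fluence map is deliberately scatter-free: monitor units through a binary
aperture, with no leaf transmission, tongue-and-groove or rounded leaf ends.
For the plan, each control-point pair $(k, k{+}1)$ deposits
$\Delta f_k \cdot \mathrm{MU}$ through the aperture of control point $k{+}1$
(step-and-shoot: the shape is held while its dose is delivered); for the log,
each consecutive beam-on sample pair deposits its meterset increment through
the *actual* aperture at the later sample. Pixel weights are exact
area-overlap fractions (products of 1D overlaps, exact for axis-aligned
rectangles), so MU × open area is conserved to rounding. The default grid is
1 mm pixels over the jaw rectangle padded by 10 mm.

The difference map is thresholded at 2% and 3% of the planned map's maximum
(strict `<`, per the passing-rate definition), over the union of pixels
non-zero in either map — full-grid analysis is available but inflates pass
rates with trivially agreeing empty pixels. Which beam's maximum normalizes
the error is ambiguous in principle; the planned (reference) maximum is the
default and the choice is configurable.

## Gamma analysis

For reference pixel $r$ at dose $D_r$, with dose tolerance $\delta$ (% of the
normalization dose $D_n$) and distance-to-agreement $\Delta$:

$$\gamma(r) = \min_{c} \sqrt{\frac{\lVert c - r\rVert^2}{\Delta^2} +
  \frac{(D_e(c) - D_r)^2}{(\delta D_n)^2}}$$

minimized over evaluated-plane positions $c$. Defaults are the clinical
3%/3 mm with global normalization to the reference maximum; a pixel passes
when $\gamma \le 1$ (ties at exactly 1 count as passes; the comparison
carries a $10^{-9}$ guard so analytic boundary cases — e.g. a uniform +3%
offset — do not flip on floating-point noise). The low-dose cutoff defaults
to 10% of $D_n$; it has no standard value and tests set it to 0.

The minimization is an exhaustive search on a $\Delta/10$ lattice within a
$3\Delta$ radius, with bilinear interpolation of the evaluated plane — simple
enough to verify against a brute-force 0.05 mm search. Two refinements keep
the exhaustive search within 0.02 of that oracle everywhere: candidates
falling outside the evaluated plane are projected onto its boundary (edge
pixels otherwise converge one order slower), and a second pass searches a
step/10 sublattice around each pixel's best coarse candidate (small-γ minima
between lattice points are otherwise overestimated). Reference and evaluated
planes may sit on different grids; the reference grid defines the γ map, as
in the standard asymmetric formulation. Both the pass rate and the mean γ
are reported, since summary practice varies.

## DVH indices

`compute_dvh()` builds cumulative curves on uniform dose bins (default
0.01 Gy): volume at edge $e$ is the percentage of structure voxels with dose
$\ge e$. `dvh_index()` derives V-type indices (volume at or above a dose,
relative to prescription or absolute), D-type indices ($D_{v\%}$, the dose to
the hottest $v\%$, linearly interpolated between bracketing edges with ties
toward the lower dose), voxel-exact MIN/MAX/MEAN, and the homogeneity spread
$(D_{p\%} - D_{q\%})/\mathrm{Rx} \times 100$ — the quantity usually written
D5%–95% — which is 0 for a perfectly uniform dose up to one bin width of
interpolation. `compare_plans()` resamples the comparison grid trilinearly
onto the reference frame (different calculation grids, e.g. 3 mm vs 2.5 mm,
are the norm), tabulates both values per structure × index with ratio and
percent difference, and flags mean-dose disagreements beyond 3% — the
threshold used to gate a plan on the agreement between primary and
independent calculations.

## The synthetic generator

`make_plan()` draws step-and-shoot beams with 4–12 segments (the typical
clinical range), smoothly varying connected apertures, and strictly
increasing meterset fractions. `simulate_delivery()` replays a plan under
strict step-and-shoot semantics: leaves move only during beam holds, each
segment delivers at 400 MU/min sampled every 50 ms, the last sample of each
segment lands exactly on the segment's cumulative meterset, and the log's
expected channels carry the plan trajectory. `error_model()` injects one
error per channel — constant gantry/collimator/jaw offsets, i.i.d. Gaussian
leaf noise on the actual channel, per-leaf systematic offsets, MU rescaling,
a dropped segment, truncation, a wrong patient ID — with the noise stream
seeded per beam independently of every other error class, so toggling one
class provably perturbs only its own check. `make_phantom()` supplies
analytic dose fields (uniform, gradient, Gaussian blobs) and geometric
structures evaluated at voxel centers, standing in for patient data.

What the generator does *not* emulate: servo dynamics with realistic
temporal correlation, leaf transmission and scatter, VMAT/dynamic-leaf
motion, real DICOM quirks, and patient anatomy. Passing tests therefore
demonstrate the correctness of the analysis chain on known ground truth, not
clinical performance on real logs.

## Numerical choices and problem sizes

* Fixed serialization precision: positions/angles $10^{-4}$ (0.1 µm),
  meterset fractions $10^{-6}$; round-trips are byte-exact by construction.
* Identity-delivery fluence differences are asserted at $10^{-9}$ MU per
  pixel: per-sample meterset increments telescope only to floating point.
* Degenerate inputs are coded conditions, not crashes: `PARSE_ERROR` vs
  `INVARIANT_ERROR` on reading, `EMPTY_BEAM`, `GRID_MISMATCH`,
  `EMPTY_STRUCTURE`, `ALL_EXCLUDED`, `NO_OVERLAP`.
* Test and acceptance problem sizes are desk-scale by design: 3-pair toy
  beams and ≤ 61×61 dose planes keep the full suite under a minute while
  every oracle (0.05 mm rasterization, exhaustive gamma search, direct
  recounts) stays brute-force honest.

## Known limitations

Fixed-gantry step-and-shoot only; 2D gamma (a 3D extension would catch
discrepancies outside contoured structures); no DICOM I/O (documented text
dialects instead); no couch parameters in the log model; the MU tolerance
and low-dose cutoff defaults are package choices, not clinical standards.
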