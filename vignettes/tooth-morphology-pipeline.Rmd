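---
title: "Automated internal tooth morphology from micro-CT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated internal tooth morphology from micro-CT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toothct)
```

## The problem

Desktop micro-CT scanners image extracted teeth at ~10 µm isometric voxels,
producing thousands of axial gray-scale slices per tooth. For endodontic
research two descriptions of each tooth matter: the **root canal
configuration** — how many canal lumina run through the root at defined
levels, summarized by a 4-digit code `a-b-c/d` (three canal counts plus the
number of main foramina, e.g. `1-2-2/2` for a canal that bifurcates and
exits through two main openings) — and the **physiological foramen
geometry**, the calibre of the apical openings, where openings of 0.20 mm
diameter or more count as physiological (main) foramina and narrower ones as
accessory. At cohort scale (a hundred or more teeth) these descriptions must
come from an automated, reproducible pipeline, not from manual slice-by-slice
reading.

`toothct` implements that pipeline: volume ingestion and chunked storage,
cropping, per-slice root-canal segmentation, enamel–dentin-border (EDB)
detection, configuration coding, and distance-transform-based foramen
measurement, plus a synthetic phantom generator that provides exact ground
truth for every stage.

## Pipeline stages and their assumptions

### Ingestion and storage

Slice stacks (PNG or TIFF, 8-bit; 16-bit input is linearly rescaled with a
warning) are read in strict lexicographic file-name order — scanner output is
zero-padded, so this reproduces acquisition order deterministically and
independently of file-system enumeration. Scanner logs are INI-style
`Key=Value` text; keys are matched case-insensitively against a synonym list
(`"Source Voltage (kV)"`, `"Pixel Size (um)"`, …). Scanner vendors do not
share a log schema, so the synonym list is a maintained guess and a log
without a recognizable voxel-size entry is rejected rather than defaulted.
Volumes are persisted as a chunked, gzip-compressed array store (one axial
slice group per chunk, plus a JSON attribute sidecar) because nearly every
downstream operation is per-slice.

### Cropping

The tooth is separated from air with one **common fixed gray threshold**
across all datasets (default 25 of 255, strict `>`). A fixed threshold keeps
the segmentation comparable across a cohort; 25 sits below dentin and above
air for typical 8-bit reconstructions but is data-dependent and therefore a
first-class parameter. Components smaller than 1000 voxels (strict) are
discarded as speckle, and the volume is cropped to the bounding box of the
largest 26-connected component. Ties between equal-sized components go to
the smaller axial start, purely for determinism. Metal-filling streaks that
reach the volume border are not special-cased: the crop may then be the full
volume, which costs disk space but nothing else.

### Root-canal extraction

Each axial slice is processed independently: Otsu's threshold splits tooth
from background; the mask is inverted ("all that is not tooth"); every
inverted component touching the slice border (the surrounding air) is
cleared; components of area < 64 px (strict) are removed as speckle; enclosed
holes of area < 100 px (strict) are filled. Components and border clearing
use 8-connectivity; holes are 4-connected background regions — the
conventional dual pairing, pinned so the test oracles are unambiguous.
Per-slice (rather than 3D) Otsu is deliberate: the tooth's attenuation varies
along its axis, and the per-slice threshold adapts. A slice whose histogram
is degenerate (pure air after cropping) yields an empty canal mask instead of
an error so batches never die on edge slices. Near the apex, a slice where
the lumen opens into outside air in-plane is deleted by border clearing; the
foramen measurement below anchors on the lowest *closed* cross-section for
exactly this reason.

Otsu's threshold is computed by exhaustive maximization of the between-class
variance over the 256-bin histogram with ties toward the smaller threshold,
and the foreground convention is strict (`gray > t`). The test suite checks
it against an independent, literal minimization of the within-class variance
over all 255 splits.

### EDB detection and slice planning

The mean gray value per axial slice forms a brightness profile; the enamel
cap is markedly brighter than dentin, so the profile drops sharply at the
EDB. The profile is smoothed with LOWESS (span fraction 0.05 of the axis by
default — wide enough to suppress slice noise at the ~2700-slice scale of
real reconstructions, narrow enough not to blur the enamel edge) and the EDB
is the index of maximal absolute first difference of the smoothed curve,
ties toward the crown. The absolute value also covers upside-down stacks.
LOWESS's robust re-weighting iterations have a useful side effect observed on
the validation phantoms: one or two residual air slices at the crop boundary
are treated as outliers rather than generating a spurious edge. The cost is
that a step edge can be displaced by a couple of slices; recovery within
±3 slices is the design tolerance. Teeth with metal fillings defeat the
automatic detector (the strongest gradient sits at the filling's bottom), so
a manual EDB index can be supplied (`edb_slice` in the configuration /
`--edb-slice`); the report records whether the border was automatic or
manual.

Four classification slices are planned at the EDB, the bottom of the tooth
(the lowest slice containing foreground), and equidistantly between:
`e + round(k(b−e)/3)`, k = 0…3, so the gaps differ by at most one slice. On
the published landmark pair (EDB 911, bottom 2341) this yields
911/1388/1864/2341. Around each planned slice a minimum-gray projection over
a 400 µm window (total width, i.e. ±200 µm; 40 slices at 10 µm) is rendered
for the report figures — the minimum carries fine dark accessory canals into
the image. Counting, however, uses the canal mask at the exact planned slice;
the window is a visualization aid.

The three code digits are the 8-connected canal counts at the EDB slice and
the two intermediate slices; the fourth digit is the number of physiological
foramina. Which of the four extracted slices feed the three digits is a
convention (the bottom slice largely duplicates the foramen analysis); this
mapping is documented rather than claimed canonical. The automatic code is
advisory — it aids a trained observer and does not attempt expert-grade
sub-typing of lateral canals or apical deltas.

### Foramen geometry

The canal mask's exact Euclidean distance transform (EDT; Felzenszwalb &
Huttenlocher's separable algorithm, exact squared distances) labels every
canal voxel with its distance to the canal wall in µm, so twice the maximum
over a cross-section is the largest inscribed-sphere diameter there. The
apical 3.5 mm of the tooth (350 slices at 10 µm, clipped at the top for short
volumes) is extracted, and an overlay volume is written in which non-canal
voxels keep their reconstruction gray value while canal voxels carry
`200 + round(EDT in voxels)` — a reserved high gray band that makes the local
canal radius readable in any image viewer — reformatted into sagittal slices
that show the whole apical course at once.

Foramina are detected per 26-connected canal component whose lowest slice
lies in the apical window. A canal that bifurcates above the apex is a
*single* 3D component with several openings, so the component's lowest-slice
cross-section is split into its 8-connected in-plane parts and each part is
one exit; the number of measurements then always equals the number of apical
exit cross-sections. The exit diameter is twice the maximum **in-plane (2D)**
EDT over the exit cross-section — the largest inscribed circle, which is what
an operator measures when scrolling axial slices. The 3D EDT is the wrong
quantity at an open end: immediately above an open foramen it measures the
one-voxel distance to the air below the exit, not the canal calibre (the
package exposes it as an optional `sphere_diameter_um` column for interior
points, where the two agree). Whether a foramen diameter should be in-plane
or oblique-3D is genuinely open; the in-plane convention is the documented
choice. The physiological/accessory rule is inclusive: diameter ≥ 0.20 mm is
physiological. The distance between physiological and anatomical foramina is
not computed automatically — the sagittal overlay supports reading it
manually — and canal curvature metrics are likewise out of scope.

## The phantom generator

Every stage is validated on synthetic tooth phantoms with analytic ground
truth: a bright enamel cap (gray 220) over a dentin frustum (gray 120)
tapering toward the apex, canal tubes near background intensity (canal 10,
air 5) with piecewise-linear paths and branch/merge topology, optional
truncated Gaussian noise, surrounded by air. The gray ordering mimics what
X-ray attenuation imposes, with headroom for noise. Ground truth — canal
mask, EDB slice, bottom slice, configuration code, exit diameters — is
computed from the tube geometry, never by segmenting the rendered image,
so tests against it are not circular. Canal axes sit on integer voxel
coordinates so a tube of integer radius r voxels has an exact inscribed
radius of r, letting the 0.20 mm rule be exercised at exact equality.

The default suite covers six configuration codes (1-1-1/1, 1-2-1/1, 1-2-2/2,
2-2-2/2, 2-1-1/1, 1-1-2/2), each rendered at noise σ = 0 and σ = 10 gray
levels under fixed seeds. Phantom volumes are 170 × 100 × 100 voxels at
10 µm — the full gray-level structure of a real reconstruction at roughly
1/16 linear scale, chosen so the twelve-phantom suite renders and processes
in well under a minute; branch points are placed with ≥ 3-voxel in-plane
clearance of the planned counting slices so analytic counts are unambiguous.
What the phantoms do **not** emulate: beam hardening, ring artifacts, metal
fillings, partial-volume blur at the dentin–canal interface, anatomical
curvature, and the pulp chamber's irregular shape. Passing the suite
therefore demonstrates the correctness of the algorithms under the stated
image model, not segmentation accuracy on pathological real scans; the
manual EDB override and the advisory status of the automatic code exist
precisely because real cohorts contain teeth the image model excludes.

## Numerical choices and degenerate inputs

* All size rules are strict inequalities (a 1000-voxel speckle, a 64-px
  component and a 100-px hole all survive); the foramen rule is inclusive
  (200 µm is physiological).
* Connectivity is pinned: 26 in 3D, 8 in 2D, 4 for hole interiors.
* Component labels are assigned in storage scan order; bounding-box ties go
  to the smaller axial start; Otsu and EDB ties go to the smaller index.
* The EDT seeds foreground scan lines with a large finite constant (1e15)
  rather than infinity so the lower-envelope arithmetic stays well defined on
  all-foreground lines; an all-true mask is an error ("no background").
* Constant slices yield empty canal masks, not errors; an empty crop mask
  ("no foreground") and inverted axis landmarks are errors.
* LOWESS output is clamped to the raw profile's range so local linear fits
  cannot overshoot the physical gray range.
* The per-tooth cache stamp is the canonical JSON of the configuration;
  any change of any threshold invalidates the cache.

## Parameters at a glance

| parameter | default | unit | role |
|---|---|---|---|
| `crop_threshold` | 25 | gray (8-bit) | fixed tooth/air split; data-dependent, must sit between air and dentin |
| `crop_min_voxels` | 1000 | voxels | 3D speckle cutoff before the bounding box |
| `min_area_px` | 64 | px | per-slice canal speckle cutoff |
| `max_hole_px` | 100 | px | per-slice hole-filling cutoff |
| `lowess_frac` | 0.05 | fraction of axis | EDB profile smoother span |
| `window_um` | 400 | µm | total width of the min-gray projection window |
| `bottom_mm` | 3.5 | mm | apical window height (350 slices at 10 µm) |
| `min_diameter_um` | 200 | µm | physiological/accessory foramen rule (inclusive) |
| `edb_slice` | unset | slice index | manual EDB override for metal-filled crowns |

## A worked phantom example

```{r example, eval = FALSE}
library(toothct)

sp <- phantom_spec(canal_tree = toothct:::.suite_canal_tree("1-2-2/2"),
                   noise_sigma = 10, seed = 7)
ph <- generate_phantom(sp)

dir <- file.path(tempdir(), "tooth_122")
write_phantom_stack(ph, dir)

report <- process_tooth(dir)
report$code        # "1-2-2/2"
report$foramina    # two physiological exits, 200 um each
```

## Known limitations

* The fixed crop threshold and the log-key synonym list are documented
  guesses that real scanner deployments will need to adjust.
* The automatic configuration code counts cross-section components only; it
  does not sub-type lateral canals or apical deltas and is advisory by
  design.
* Apex slices whose lumen opens in-plane to air are removed by border
  clearing (faithful to the per-slice procedure); foramen geometry therefore
  anchors one closed cross-section above the opening.
* The EDB detector assumes an intact enamel cap; implants and fillings
  require the manual override.
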