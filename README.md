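# toothct

Automated segmentation and description of the internal morphology of
single-rooted teeth from micro-CT reconstruction stacks.

Endodontic research needs two descriptions of every tooth in a cohort: the
**root canal configuration** — a 4-digit code `a-b-c/d` giving the number of
canal lumina at three levels along the root plus the number of main foramina
(e.g. `1-2-2/2` for a canal that bifurcates and exits through two main
openings) — and the **physiological foramen geometry**, the calibre of the
apical openings, where a diameter of 0.20 mm or more marks a physiological
(main) foramen and anything narrower an accessory one. `toothct` computes
both, fully automatically, from a directory of reconstructed axial
gray-scale slices per tooth (8-bit PNG/TIFF, isometric voxels, nominally
10 µm).

The pipeline per tooth:

1. **Ingest** — read slices in strict lexicographic order, parse the scanner
   log (`Key=Value` text) for acquisition metadata and voxel size, persist
   as a chunked compressed array store.
2. **Crop** — fixed gray threshold (default 25/255, strict `>`), removal of
   3D speckles < 1000 voxels, crop to the bounding box of the largest
   26-connected object.
3. **Overview** — middle slices, maximum-intensity projections and montages
   for visual QC.
4. **Canal extraction** — per axial slice: Otsu tooth/background split,
   inversion, clearing of border-connected air, removal of speckles < 64 px,
   filling of holes < 100 px; stacked into a binary canal volume.
5. **Classification** — LOWESS-smoothed axial brightness profile; the
   enamel–dentin border (EDB) at the maximal absolute derivative (manual
   override available for metal-filled crowns); four slices planned at
   `e + round(k(b−e)/3)`; 400 µm minimum-gray windows for the report figure;
   canal counts at the planned slices give the code digits.
6. **Foramen geometry** — exact 3D Euclidean distance transform of the
   canal; apical 3.5 mm window; per-exit inscribed-circle diameter and the
   inclusive 0.20 mm physiological/accessory rule; an EDT/reconstruction
   overlay reformatted to sagittal slices for manual reading.

A synthetic tooth-phantom generator (`phantom_spec()`,
`generate_phantom()`, `default_phantom_suite()`) renders enamel/dentin/canal
tubes with branch–merge topology and exact analytic ground truth, so the
whole pipeline is testable with no scan data.

## Worked example

Render a noisy bifurcating phantom, write it as a slice stack, and process
it like a scanned tooth:

```r
library(toothct)

sp <- phantom_spec(canal_tree = toothct:::.suite_canal_tree("1-2-2/2"),
                   noise_sigma = 10, seed = 7)
ph <- generate_phantom(sp)

dir <- file.path(tempdir(), "tooth_122")
write_phantom_stack(ph, dir)

report <- process_tooth(dir)
report$code
#> [1] "1-2-2/2"
report$slice_indices
#> [1]  40  83 127 170
report$foramina
#>   exit_slice exit_row exit_col diameter_um          kind
#> 1        168       39       27         200 physiological
#> 2        168       39       51         200 physiological
```

The code `1-2-2/2` reads: one canal at the enamel–dentin border (slice 40),
two at each of the intermediate levels (slices 83 and 127), exiting through
two main foramina — both with an inscribed diameter of exactly 200 µm, i.e.
right at the inclusive physiological threshold. All artifacts (chunked
stores, overview and classification-window images, the sagittal apical
overlay, `report.json`) land in `tooth_122/output/`.

Batch a cohort and collect one row per tooth:

```r
tab <- batch("/data/teeth")   # one subdirectory per tooth
```

Completed teeth are skipped on re-runs (the report is stamped with the
configuration), so the batch can be re-invoked while a scanner is still
filling the cohort. A thin command-line front end wraps the same functions:

```sh
inst/cli/toothct phantom --code 1-2-2/2 --noise 10 --seed 7 --out tooth_a
inst/cli/toothct process tooth_a
inst/cli/toothct batch /data/teeth --threshold 25 --min-voxels 1000
```

See `vignettes/tooth-morphology-pipeline.Rmd` for the full account of the
methods, parameter defaults, and what phantom validation does and does not
demonstrate.

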