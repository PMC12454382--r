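# cataractgrader

Automatic cataract diagnosis and grading on the four LOCS III scales from
anterior-segment photographs, for image-analysis researchers and
ophthalmic-imaging engineers who want a fully interpretable, hand-crafted
alternative to CNN graders.

Cataract severity is read from two photographic modalities: slit-beam
images show an optical cross-section of the lens and carry the nuclear
scales — opalescence **NO** (0–6) and colour **NC** (0–6) — while
retro-illumination images show opacities as dark silhouettes against the
red reflex and carry the cortical **C** (0–5) and posterior subcapsular
**P** (0–5) scales. Grade 0 is a normal lens on every scale.

The system is a classical image-processing pipeline feeding shallow
networks:

* **Nuclear branch** — saturated flash reflections (all channels > 250)
  are painted black; the grayscale image is Otsu-binarized; the lens is
  localized as the *maximum inscribed white ellipse*: over all axis-aligned
  rectangles in the coarse lens box, the inscribed ellipse of maximal area
  πab whose interior pixel centres are all white, searched in decreasing
  area with O(1) row whiteness tests and validated against an exhaustive
  oracle. Features are *fuzzy-interval colour proportions*: the fraction
  of lens pixels with all channels within ±Offset of standard cyan
  (0,255,255) for NO and standard yellow (255,255,0) for NC.
* **Retro branch** — the pupil is segmented by the minimum enclosing
  circle of the Otsu foreground; flash highlights are filled by three-way
  agglomerative colour clustering (yellow / white / black, fill = rounded
  yellow-cluster mean); a circular Hough transform refines the pupil;
  adaptive (local-mean) binarization preserves lesions; cortical spokes
  become Hough line-segment statistics, posterior plaques become contour
  area / perimeter / centroid statistics.
* **Grading** — per scale, a two-layer sigmoid network (one hidden layer,
  one output unit) trained by full-batch gradient descent on MSE against
  targets scaled to (grade − min)/(max − min); the raw output is rescaled,
  rounded and clipped to the grade range. Evaluation reports the confusion
  matrix, per-class precision/recall/F1, accuracy, and one-vs-rest
  ROC/AUC.

Because the clinical photograph archive is not public, the package
includes a grade-controlled synthetic generator (`gen_dataset()`) that
renders both modalities with known ground truth; all end-to-end results
below are computed on it.

## Worked example

```r
library(cataractgrader)

## render a slit-beam photograph with nuclear opalescence grade 3
o <- gen_slit_beam(slit_beam_spec(no_grade = 3, nc_grade = 0, seed = 42))
nf <- extract_nuclear_features(o$image)
nf$ellipse
#> <ellipse_region centre=(64.50, 48.00) semi-axes=(34.10, 22.55)>
round(nf$features, 4)
#>   cyan_40   cyan_80 yellow_40 yellow_80
#>    0.2276    0.2301    0.0588    0.0592
```

The located lens (centre ≈ (64.5, 48), semi-axes ≈ (34, 23)) matches the
generated ellipse to within a pixel, and about 23% of lens pixels fall in
the cyan fuzzy interval — the monotone signature of NO grade 3 (the
generator tints `0.04 + 0.065 × grade` ≈ 23.5% of the lens cyan).

A small end-to-end run (10 images per grade cell, ~1 min):

```r
res <- run_pipeline(pipeline_config(n_per_grade = 10, seed = 1))
print(res)
#> Cataract grading pipeline result
#>   dataset: 260 images (10 per type-grade cell), seed 1
#>   feature extraction success: NO 100%, NC 100%, C 100%, P 100%
#>   NO: test accuracy 95.2%, macro AUC 100.0% (n = 21)
#>   NC: test accuracy 95.2%, macro AUC 99.2% (n = 21)
#>   C: test accuracy 100.0%, macro AUC 100.0% (n = 18)
#>   P: test accuracy 83.3%, macro AUC 98.5% (n = 18)
```

Each report holds the full confusion matrix and per-grade metrics
(`print(res$reports$NO)`), and with `out_dir` set the run writes feature
CSVs, model JSONs, evaluation reports and the resolved configuration,
reproducibly byte-for-byte for a fixed seed.

A command-line front end with the same operations (`synth`,
`locate-lens`, `segment-retro`, `extract-features`, `train`, `evaluate`,
`grade-nuclear`, `grade-retro`, `pipeline`) lives at
`inst/cli/cataract.R`.

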