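# segvar

Interobserver variability analysis for 2D binary lesion segmentations,
built around intraoperative B-mode ultrasound of brain tumours.

Tumour margins on intraoperative ultrasound are often genuinely
ambiguous — fuzzy borders, peritumoural oedema, speckle — so experienced
clinicians segmenting the same frame disagree, and the disagreement
concentrates on a minority of hard images. `segvar` is for researchers
quantifying that disagreement: it implements the standard agreement
metrics on mask pairs, the relaxation of segmentations to bounding
boxes (a cheaper annotation that washes out boundary disagreement while
preserving localisation), an image-side classifier of margin clarity,
and a synthetic annotation-study generator, together with the
aggregation conventions needed to reproduce a published 30-image,
3-annotator agreement study whose per-image results ship with the
package as a CSV fixture.

## The metrics

For masks $A, B$ on a shared pixel grid:

- $\mathrm{IoU} = \dfrac{|A \cap B|}{|A \cup B|}$
- $\mathrm{DSC} = \dfrac{2|A \cap B|}{|A| + |B|} = \dfrac{2\,\mathrm{IoU}}{1 + \mathrm{IoU}}$
- $\mathrm{HD} = \max\left\{\max_{a \in A_c}\min_{b \in B_c}\lVert a-b\rVert,\;
  \max_{b \in B_c}\min_{a \in A_c}\lVert a-b\rVert\right\}$

with $A_c, B_c$ the boundary-pixel contours (8-connectivity) and all
distances in Euclidean pixel units. HD is the classical max–min form:
it reports the single worst boundary disagreement.

Beyond the mask-level metrics: `mask_to_bbox()` / `bbox_agreement()`
evaluate the bounding-box relaxation with the same three metrics,
`containment_fraction()` scores how much of a reference segmentation an
annotator's box captures, and `dispersion_study()` samples image
intensities in a ±10 px band perpendicular to a contour and classifies
the density of the band as unimodal / bimodal / other — a bimodal band
indicates a visibly well-separated margin, a unimodal band an
indistinct one.

## Worked example

Two 2×2 blocks offset by one column:

```r
library(segvar)
a <- matrix(0, 8, 8); a[3:4, 3:4] <- 1
b <- matrix(0, 8, 8); b[3:4, 4:5] <- 1
agreement(a, b)
#>       iou       dsc        hd
#> 0.3333333 0.5000000 1.0000000
```

The intersection is 2 px and the union 6 px, so IoU = 1/3 and DSC =
2·2/8 = 1/2; the contours are one column apart, so HD = 1 px.

The packaged study table aggregates back to every summary value printed
in its source — per-annotator means, interquartile-range reductions
after box conversion, and the cross-annotator headline values:

```r
rep <- reproduce_tables()
rep$cross_annotator
#>  metric printed recomputed   ok
#>     iou   0.723  0.7229111 TRUE
#>     dsc   0.813  0.8133222 TRUE
#>      hd 115.675 115.6759444 TRUE
rep$reductions[1:3, ]
#>  annotator metric printed_percent recomputed_percent   ok
#>        An1    iou              40                 40 TRUE
#>        An1    dsc              44                 44 TRUE
#>        An1     hd              52                 52 TRUE
```

So on average the annotators overlap the reference standard at IoU
0.723, and converting segmentations to boxes shrinks the across-image
IQR of annotator 1's IoU by 40% — boxes agree much more consistently
than outlines.

The margin-clarity classifier, calibrated on a blurred-circle phantom
(radius 100 px, contrast 0/255): a sharp boundary gives a bimodal band,
severe blur collapses it:

```r
sharp <- make_blurred_circle(100, c(290, 290))
dispersion_study(sharp$image, sharp$mask)
#> <boundary_band_profile> 16716 samples in a +/-10 px band
#>   modality: bimodal (2 peaks at 0, 255)
hazy <- make_blurred_circle(100, c(290, 290), blur = blur_config("gaussian", 100/3))
dispersion_study(hazy$image, hazy$mask)
#> <boundary_band_profile> 16716 samples in a +/-10 px band
#>   modality: unimodal (1 peak at 163)
```

A synthetic annotation study end to end — reference lesions, three
simulated annotators with 3 px boundary jitter, summary in the
`Metric[Mean:IQR]` reporting style:

```r
spec <- synthetic_spec(image_size = c(128, 128), radius = 26, seed = 42)
cohort <- generate_cohort(spec, n_images = 5)
records <- do.call(rbind, lapply(cohort, function(img)
  versus_reference(img$reference, img$annotators)))
summarize_agreement(records)
#>  annotator variant metric  mean median   iqr
#>        An1     Seg    iou 0.895  0.901 0.031
#>        An1     Seg    dsc 0.944  0.948 0.017
#>        An1     Seg     hd 2.785  2.828 1.000
#>        ...
```

Masks read and write as NRRD (2D dialect, as segmentation tools export)
or PNG via `read_mask()` / `write_mask()`; a thin command-line wrapper
with `metrics`, `summarize`, `reproduce-tables`, `dispersion` and
`simulate` subcommands is installed at
`system.file("scripts", "segvar.R", package = "segvar")`.

The methods vignette
(`vignettes/segmentation-variability.Rmd`) documents the conventions —
contour definition, quartile type, KDE bandwidth and peak-prominence
rules, the synthetic generator's difficulty model — and why each was
chosen.

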