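# thermoroi

Illumination-adaptive detection of body-surface regions of interest
(ROIs) on dairy-cow images and extraction of their radiometric
temperatures.

## The problem

Rectal temperature (RT) is the reference health indicator in dairy
cattle, but measuring it is invasive and stressful.  Infrared
thermography offers a contact-free surrogate: on lactating cows the
lower udder (**LU**) and the area around the anus (**AA**) are thermal
windows whose surface temperatures track RT, with a stable gradient
RT > AA > LU.  Automating the measurement means detecting LU and AA on
an RGB frame co-registered with a per-pixel temperature map, then
summarizing the temperatures inside each detected box — under barn
illumination that is routinely too dark or blown out, and on coats whose
random black-and-white patches defeat appearance-only detectors.

## What the package provides

* **Illumination gate and dual-path enhancement.**  Frames are routed by
  mean luminance mu (BT.601 weights; low light if mu < 60, overexposed
  if mu >= 150).  Low-light frames are enhanced by Retinex
  decomposition — `I = R * L`, closed-form max-channel initialization,
  penalized alternating refinement with monotonically non-increasing
  energy, gamma brightening `L^0.5` — and overexposed frames by CLAHE on
  the Lab luminance channel (8 x 8 tiles, clip limit 3.0, exact-mass
  clip redistribution, bilinear tile blending, chroma untouched).
* **Text-conditioned miniature detector.**  A five-category anatomical
  text bank (LU, AA, RU, hind legs, hind quarters) whose descriptions
  encode the spatial chain between the ROIs; a deterministic hashing
  text encoder; the EDC text-guided modulation block
  `Y = X + GELU(LN(X' gs cs + gb + cb))` with joint spatial/channel
  attention and identity-at-initialization; fast-normalized
  learnable-weight feature fusion; a small CPU-trainable two-scale head
  whose per-category score is the sigmoid of visual-embedding x
  text-embedding dot products.
* **Training strategy.**  Task-aligned assignment
  `A = p_cls^alpha IoU^beta` combined with Gaussian soft-constrained
  centre sampling `w = exp(-d^2/sigma^2)`, and the hybrid regression
  loss `1 - (lambda CIoU + (1 - lambda) GIoU)`.
* **Evaluation** (precision, recall, all-point-interpolated AP, mAP50,
  per-detection confidence) and **ROI temperature extraction**
  (TMax/TMin/Tavg over box pixels, absolute error statistics, Spearman
  correlation against RT for ROI selection).
* **Seeded synthetic scene generator** producing paired RGB +
  radiometric cow scenes with the five-region layout, the three
  illumination regimes and the RT > AA > LU gradient, so every claim is
  testable offline.

## Worked example

```r
library(thermoroi)

# a dim synthetic scene, gated and enhanced
scene <- generate_scene(scene_params(width = 160, height = 120,
                                     regime = "low", seed = 7))
mean_luminance(rgb_to_gray(scene$image))
#> [1] 40
enh <- enhance_auto(scene$image)
enh$label
#> <illumination: low_light (mean luminance 40.00)>
mean_luminance(rgb_to_gray(enh$image))
#> [1] 96.20637

# ROI temperatures inside the ground-truth AA box of a rear-view scene
rear <- generate_scene(scene_params(width = 160, height = 120,
                                    view = "rear", seed = 21))
b <- rear$annotation$boxes
aa <- as.numeric(b[b$category == "AA", 2:5])
extract_roi_temperatures(rear$thermal, aa)[c("t_max", "t_min", "t_avg")]
#> $t_max
#> [1] 38.05105
#> $t_min
#> [1] 37.52709
#> $t_avg
#> [1] 37.77795

# which surface sites track the rectal reference best?
tab <- read.csv(system.file("extdata", "cow_temperatures_example.csv",
                            package = "thermoroi"))
m <- spearman_matrix(tab)
round(m["RT", c("LU", "AA")], 3)
#>    LU    AA
#> 0.757 0.818
select_rois(m, target = "RT", k = 2)
#> [1] "AA" "LU"
```

The first number after enhancement (40.0 -> 96.2) is the mean luminance
lift of the Retinex path on a dim frame.  The extracted AA maximum
(38.05 degC; the planted region temperature is 37.78 degC plus the upper
extreme of the 0.1 degC pixel noise over the box) sits above the scene's
body surface and below its rectal reference, as the physiology dictates,
and the Spearman ranking selects AA and LU as the two sites most
correlated with RT — the basis for using them as detection targets.

Training the miniature detector end to end on a generated dataset:

```r
dir <- tempfile()
generate_dataset(200, dir, params = scene_params(width = 160, height = 120),
                 seed = 11)
# (load the train split, enhance, then)
w <- train_tiny_detector(train_scenes, load_text_bank(),
                         epochs = 250, lr = 0.05, seed = 7)
report <- pipeline_run(load_config(NULL), dir, w, split = "test")
```

A command-line front end over the same functions is installed as
`exec/thermoroi` (subcommands `enhance`, `simulate`, `train`, `detect`,
`evaluate`, `extract-temp`, `roi-select`, `textbank`).

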