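# tissueseg

Tissue-background segmentation for multiresolution whole-slide
histopathology images.

Whole-slide scanners and image-analysis pipelines both need to know where
the tissue is on a digitized glass slide: scanners to avoid imaging empty
glass, pipelines to skip background tiles. Simple intensity thresholds fail
on fatty tissue (mostly transparent), faint immunohistochemical stains, and
structured non-tissue such as air bubbles, cover-slip edges, pen markings
and stain residue. `tissueseg` implements, behind one interface:

* a **fully convolutional network** — seven convolutions (5×5×16, 5×5×32,
  3×3×64, 3×3×64, 3×3×1024, 1×1×512, 1×1×2 softmax) with max pooling after
  the first three, total downsampling 8× — trained on 128×128 patches drawn
  by class-weighted sampling from six-label masks (edge, artifacts,
  background, external margin, internal margin, tissue; weights
  1, 1, 1, 1, 5, 1) with stain-agnostic augmentation (full-circle hue
  rotation in HSB space, among others). A *multi-level* variant draws each
  patch's source spacing uniformly from {0.5, 1, 2, 4, 8} µm and segments
  any of those resolutions with one set of weights;
* three classical baselines: **fixed grayscale threshold** (tissue =
  mean(R,G,B) < 217), **Otsu's adaptive threshold** (minimum within-class
  variance on the 256-bin histogram), and **FESI** (foreground extraction
  from structure information: blurred Laplacian → mean threshold → median /
  opening → background flood fill → distance-transform seed pruning with
  the 100 px / 100 px rule);
* the **annotation pipeline**: ASAP-XML / GeoJSON polygon reading, cleanup
  rules (remove tissue regions and holes with equivalent diameter < 250 µm,
  merge tissue closer than 50 µm), rasterization, 125-pixel margin bands,
  and the shared morphological post-processing applied to every method's
  output;
* **region-level evaluation**: Dice score `2|P∩R|/(|P|+|R|)`, region
  sensitivity (a reference region counts as detected when ≥ 80 % of its
  area is found), false-positive counts and area fractions, and pairwise
  paired t-tests with Bonferroni correction;
* a **synthetic slide generator** producing pyramidal TIFFs with
  ground-truth polygon annotations — stained textured sections, fatty
  lobule membranes, bubbles, cover-slip edges, residue, out-of-focus
  patches — so everything above is testable without scanned data.

The convolution forward/backward passes are implemented in
Rcpp/RcppArmadillo (im2col + BLAS) and run at useful speed on a single CPU
core.

## Worked example

Generate a synthetic slide, segment it with two methods, and evaluate
against the ground truth:

```r
library(tissueseg)

# a 3072 px pyramid at 0.5 um with 5 levels, one or two stained sections,
# an air bubble, a cover-slip edge and stain residue
slide <- synth_generate(synthetic_spec(seed = 7))
slide$pyramid
#> image_pyramid: 5 level(s)
#>   level 0: 3072 x 3072 px, 0.5000 um/px
#>   level 1: 1536 x 1536 px, 1.0000 um/px
#>   level 2: 768 x 768 px, 2.0000 um/px
#>   level 3: 384 x 384 px, 4.0000 um/px
#>   level 4: 192 x 192 px, 8.0000 um/px

ann <- clean_annotations(slide$annotations, spacing = 0.5)
ref <- reference_mask(ann, slide$pyramid, target_spacing = 2)

lv  <- closest_level(slide$pyramid, 2)     # level 2, 2.0 um/px
img <- read_level(slide$pyramid, lv)

fx <- postprocess(fixed_threshold_segment(img, lv$spacing))
ot <- postprocess(otsu_segment(img, lv$spacing))
fe <- postprocess(fesi_segment(img, lv$spacing))

c(fixed = dice(fx, ref), otsu = dice(ot, ref), fesi = dice(fe, ref))
#>     fixed      otsu      fesi
#> 0.9982187 0.9996233 0.9772095

region_metrics(fe, ref)[c("tp", "fn", "fp")]
#> $tp [1] 2   $fn [1] 0   $fp [1] 0
```

On this artifact-bearing but non-fatty fixture the intensity thresholds do
well (the background is homogeneous white), and FESI finds both tissue
sections but with coarser, blur-and-morphology-shaped boundaries, hence
its lower Dice. With `fatty_fraction = 1` the fixed threshold's Dice drops
markedly — fat interiors are as bright as the background — and that
failure mode is what the learned segmenter is for.

Training the multi-level network on ten synthetic slides and tuning its
confidence threshold on the two validation slides (about ten minutes on one
CPU core):

```r
slides <- lapply(1:10, function(s) synth_generate(synthetic_spec(
  canvas_px = 2048L, n_blobs = 2L, blob_radius_um = c(140, 220), seed = s)))
samplers <- lapply(slides, function(s)
  patch_sampler(s$pyramid, clean_annotations(s$annotations, 0.5),
                spacings = c(0.5, 1, 2, 4, 8)))

cfg <- train_config(batch_size = 8L, train_iterations = 60L,
                    val_iterations = 8L, max_epochs = 8L, seed = 11L)
fit <- train_fcnn(cfg, samplers[1:8], samplers[9:10])
tail(fit$history$val_accuracy, 1)
#> [1] 0.9966  (validation pixel accuracy)

val <- lapply(slides[9:10], function(s)
  list(pyramid = s$pyramid,
       annotations = clean_annotations(s$annotations, 0.5)))
tuned <- tune_threshold(fit$model, val)
tuned$threshold
#> [1] 0.5

mask <- postprocess(infer_fcnn(fit$model, slide$pyramid, 2,
                               threshold = tuned$threshold))
dice(mask, ref)
#> [1] 0.99  (about; held-out slides average 0.97-0.998 across 0.5-8 um)
```

The same trained network segments the 0.5, 2 and 8 µm levels with a mean
Dice spread below 0.05, and rotating the fixtures' stain hue by 140°
changes its Dice by less than 0.05 — the desk-scale analogue of
transferring across resolutions and stains.

## Command line

A thin wrapper over the same functions is installed at
`inst/scripts/tissueseg`:

```sh
tissueseg synth    --out slides/ --seed 1 --n 4
tissueseg segment  --method otsu --input slides/synthetic_001.tif \
                   --output mask.tif --spacing 2
tissueseg train    --data-dir slides/ --checkpoint model.rds
tissueseg segment  --method fcnn --checkpoint model.rds \
                   --input slides/synthetic_001.tif \
                   --output mask_fcnn.tif --spacing 2
tissueseg evaluate --pred-dir masks/ --ref-dir refs/ --report report.csv
```

Every artifact-producing run writes a JSON manifest (subcommand, arguments,
seed, package version) next to its output.

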