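# nucleikit

Nucleus-level analysis of histopathology-style images in R: classification
of nucleus phenotypes, segmentation of nuclear masks, and detection of
nucleus centers, using recurrent convolutional networks built and trained
on a small self-contained CPU engine.  The package bundles everything the
three tasks need around the networks — patch extraction and tiling,
point-annotation ground truth (dilated masks and Gaussian density
surfaces), cell-level evaluation, a seeded synthetic-scene generator, and a
training harness with k-fold cross-validation — so the entire pipeline runs
end to end without external datasets or a GPU.

It is aimed at computational-pathology researchers and methods developers
who want a transparent, fully testable reference implementation of this
model family rather than a production inference engine.

## Models

The shared building block is the *recurrent convolutional layer*: a
feed-forward term refined by additive recurrent steps,

    a   = conv_f(ReLU(BN(x)))
    h_s = a + conv_r[s](ReLU(BN_r(h_{s-1}))),    h_0 = a,  s = 1..t

Four architectures are built from it (`model_spec()` + `build_model()`):

| variant    | task           | structure                                     | parameters |
|------------|----------------|-----------------------------------------------|-----------:|
| `densenet` | classification | 4 dense blocks x 7 layers, growth rate 12     | 1.228 M    |
| `dcrn`     | classification | same, recurrent layers unrolled at t = 2      | 1.228 M    |
| `r2unet`   | segmentation   | encoder-decoder 1-32-64-128-256-...-1, t = 2  | 0.983 M    |
| `udnet`    | detection      | same skeleton, t = 3, density-regression head | 1.038 M    |

Dense blocks concatenate all previous layer outputs (layer `l` receives
`k(l-1) + k0` channels); transition blocks (1x1 conv + 2x2 average pooling)
halve the grid between blocks.  The encoder-decoder variants concatenate
encoder features into the decoder and end in a sigmoid per-pixel head, so
detection reduces to thresholding the predicted density surface at 0.5,
extracting connected-component centroids, and matching them one-to-one to
the annotated centers (optimal assignment within a 6 px radius).
Evaluation uses the Dice coefficient `2|GT∩SR|/(|GT|+|SR|)`, MSE,
precision/recall/F1 from TP/FP/FN counts, and macro one-vs-rest ROC-AUC.
The methods vignette (`vignettes/nucleikit-methods.Rmd`) documents the
calibrated architecture defaults and every numerical choice.

## Worked example

```r
library(nucleikit)

# a reproducible synthetic tile: elliptical nuclei of 4 classes + mask + centers
cfg <- synth_config(image_size = 96, n_nuclei = c(3, 12), seed = 11)
scenes <- lapply(1:32, function(i) generate_scene(cfg, i))

# train the segmenter for a few epochs on grayscale scenes
data <- prepare_segmentation_data(scenes)
tc <- train_config("segment", learning_rate = 1e-3, epochs = 10, batch_size = 4)
run <- run_training(tc, data, verbose = TRUE)
#> epoch   1  loss 0.3400  dice=0.0924 mse=0.0635
#> epoch   2  loss 0.0946  dice=0.7698 mse=0.0204
#> ...
#> epoch  10  loss 0.0170  dice=0.9327 mse=0.0073
run$final$val_dice
#> [1] 0.9326576
```

After ten epochs the validation Dice coefficient is 0.93: the model
reproduces 93% (by the overlap statistic) of the held-out nuclear masks.
The detection ground-truth pipeline is exactly invertible for separated
nuclei:

```r
sc <- generate_scene(synth_config(image_size = 256, n_nuclei = c(15, 15),
                                  seed = 1), 1)
dens <- make_density_target(sc$points, dim(sc$mask), sigma = 2)
det <- detect_peaks(dens, threshold = 0.5)
precision_recall_f1(match_detections(det, sc$points, radius = 6))
#> precision    recall        f1
#>         1         1         1
```

Model specs print their size directly:

```r
build_model(model_spec("r2unet"))
#> <nk_model> variant=r2unet  trainable parameters: 983,171 (0.983 M)
```

A command-line interface over the same functions ships with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/nucleikit.R", package="nucleikit"))')" \
    synth --task seg --n 4 --size 128 --nmin 5 --nmax 12 --seed 7 --out demo/
```

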