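# radwindow

Learnable intensity windowing for high-bit-depth radiograph
classification.

Chest radiographs are acquired at 12-bit depth (4096 gray values), but
the images fed to classifiers are usually compressed to 8 bits, and no
display transform is applied. Radiologists do the opposite: they
*window* the image — clamp it to an intensity range described by a
level (center) and width (extent) and spend the whole gray scale on
that range — precisely because subtle findings live in narrow intensity
bands. `radwindow` implements that idea as a model component: a
trainable multi-window layer whose parameters *are* window settings,
together with everything needed to study it — fixed-window
preprocessing, bit-depth reduction, a grid search over fixed windows,
the training protocol, bootstrap AUC evaluation, and a synthetic
12-bit image generator whose class signals are confined to narrow
intensity bands so that windowing provably matters.

## The core idea

A window with level `WL` and width `WW` clamps pixels to
`[L, U] = [WL - WW/2, WL + WW/2]`:

    window(px) = min(max(px, L), U)

Rescaling `[L, U]` onto the 8-bit display range `[0, 255]` turns this
into a clamped affine map — a 1×1 convolution with output clamping:

    clamp(W·px + b, 0, 255),   W = 255/WW,   b = -(255/WW)·(WL - WW/2)

Because `W` and `b` are ordinary convolution parameters, a bank of K
such channels is a *trainable* front-end: the network learns K windows
in parallel, and after training the settings are read back via

    WW = 255/W,   WL = -b/W + WW/2.

The full model ("WindowNet"-style) is: window layer (K clamped affine
channels) → 1×1 K→3 channel mixer → per-image rescale to `[0, 255]` →
ImageNet normalization → backbone classifier → 14 per-class logits.
Ablations with an unclamped first layer ("no windowing"), with
brightness/contrast augmentations, and a fixed-preprocessing baseline
are built from the same configuration interface.

## Worked example

Windows are tibbles; everything composes with the pipe.

```r
library(radwindow)

# the classic CT lung window: level -600 HU, width 1500 HU
window_limits(window_set(level = -600, width = 1500))
#> # A tibble: 1 × 4
#>   level width lower upper
#>   <dbl> <dbl> <dbl> <dbl>
#> 1  -600  1500 -1350   150
# everything below -1350 HU displays black, above 150 HU white

# its clamped-affine form, and the exact round trip
window_to_affine(window_set(1250, 1000))
#> # A tibble: 1 × 3
#>   weight  bias out_max
#>    <dbl> <dbl>   <dbl>
#> 1  0.255 -191.     255
affine_to_window(window_to_affine(window_set(2500, 3000)))
#> # A tibble: 1 × 3
#>   level width inverted
#>   <dbl> <dbl> <lgl>
#> 1  2500  3000 FALSE

# a synthetic band-signal study, end to end
cfg  <- synthetic_config(n_train = 2000, n_validate = 400, n_test = 400,
                         image_size = 32, seed = 11)
data <- generate_dataset(cfg)

grid <- grid_search_probe(data)          # 75 fixed windows, linear probe
init <- select_init_windows(grid)        # class-wise top 3 + full range

fit <- model_config("windownet", init_windows = init, image_size = 32) |>
  build_model() |>
  train_model(data, train_config(max_epochs = 10, seed = 1))
glance(fit)
#> # A tibble: 1 × 6
#>   mode      n_epochs selected_epoch val_loss val_mean_auc final_lr
#>   <chr>        <int>          <int>    <dbl>        <dbl>    <dbl>
#> 1 windownet       10             10    0.555        0.703   0.0001

extract_learned_windows(fit$model)       # which windows did it keep?
evaluate_model(fit, data, split = "test", n_resamples = 1000, seed = 1)
#> <eval_report> 14 classes, mean AUC 0.698 (400 images, 1000 bootstrap resamples)
#> # A tibble: 14 × 5
#>    class                        auc ci_low ci_high n_defined
#>    <chr>                      <dbl>  <dbl>   <dbl>     <dbl>
#>  1 Atelectasis                0.678  0.614   0.739      1000
#>  2 Cardiomegaly               0.579  0.520   0.646      1000
#>  # ... 12 more rows (mean AUC 0.698; Support Devices highest at 0.891)
```

On this band-signal data the learnable multi-window model reaches a
higher validation mean AUC (0.703 in the run above) than the identical
architecture without clamping (~0.67) and than an 8-bit full-range
baseline (~0.66) — the same ordering the windowing hypothesis predicts,
at desk scale. `autoplot()` methods draw training curves and per-class
AUC forests; `plot_windows()` draws window sets as intensity intervals.

## Package map

| area | functions |
|---|---|
| window math | `window_set()`, `window_limits()`, `apply_window()`, `window_to_affine()`, `affine_to_window()`, `apply_affine_window()` |
| preprocessing | `load_image()`, `reduce_bit_depth()`, `preprocess_fixed()`, `read_image_set()` |
| model | `model_config()`, `build_model()`, `default_window_init()`, `init_window_layer()`, `forward_window_layer()`, `extract_learned_windows()` |
| training | `train_config()`, `train_model()`, `multilabel_loss()`, `lr_schedule_step()`, `early_stop_decision()`, `predict_scores()` |
| evaluation | `auc()`, `bootstrap_auc_ci()`, `evaluate_model()` |
| grid search | `enumerate_grid()`, `grid_search_probe()`, `select_init_windows()` |
| synthetic data | `synthetic_config()`, `generate_dataset()`, `write_image_set()` |

The methods vignette (`vignettes/windowing-methods.Rmd`) documents the
model, the training protocol, the synthetic generator and the numerical
choices in detail.
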