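# mwiseg

Microwave breast sensing with pixel-wise tumor probability maps, end to end
and fully synthetic: randomized 2D dielectric breast phantoms, a
method-of-moments (MoM) forward solver for a 30-antenna multi-view
multi-static acquisition, a U-Net-with-dense-head network that converts the
30×30 complex scattering matrix *directly* into a 108×108 tumor probability
map (no image formation step), and a three-tier evaluation suite. It is
aimed at researchers studying learning-based detection/localization in
microwave imaging who need a controlled, reproducible in-silico laboratory.

## The method

A breast slice occupies a 15×15 cm domain rasterized at 7.2 px/cm (one
pixel = 15/108 ≈ 0.139 cm) with six tissue classes (background, skin,
adipose, transitional, fibro-glandular, tumor) and a complex relative
permittivity map ε(r). Thirty antennas on a 9 cm ring take turns
transmitting at 1 GHz (TM-z, unit line sources); the scattered fields at
all receivers form the scattering matrix S ∈ C³⁰ˣ³⁰. The forward problem is
solved by the method of moments (pulse basis, point matching, Richmond's
equivalent-circle self term) on the contrast χ = ε/ε_b − 1, and the solver
is validated against the analytic Mie series for a dielectric cylinder to
< 0.5% relative RMS.

S is split into real/imaginary channels, standardized entry-wise with
training-set statistics, zero-padded to 2×32×32, and fed to a three-level
U-Net (3 convs per block, ReLU + batch-norm, max-pool down, transposed-conv
up, skip connections) whose flattened output passes through a single dense
layer with sigmoid to 108² = 11664 per-pixel tumor probabilities. Training
minimizes binary cross-entropy with Adam (lr 0.00123), with early stopping
on validation BCE and lossless dihedral augmentation (ring rotations by
multiples of 12° and reflections act as exact antenna permutations of S).

Evaluation follows three tiers:

1. **classification** — a profile is tumorous if any pixel > 0.15; reports
   confusion counts, accuracy/sensitivity/specificity/precision/F1 and
   ROC-AUC (max-pixel score);
2. **localization** — probability-weighted center of mass vs reference
   center, Euclidean distance in px/cm, on a density-balanced
   single-tumor subset;
3. **pixel-wise similarity** — soft-Dice, normalized cross-correlation, and
   NRMSE restricted to reference-or-detected pixels, on malignant profiles.

## Worked example

```r
library(mwiseg)

# one diseased dense-breast phantom and its scattering matrix
ph <- generate_phantom(7, density_class = 4, with_tumor = TRUE)
ph
#> <breast_phantom> 108x108 (0.139 cm/px), density class 4, glandular fraction 0.640, 83 tumor px

arr <- antenna_array()               # 30 antennas, 9 cm ring, 1 GHz
S <- solve_forward(build_contrast(ph, arr, 54), arr)
S
#> <scattering_matrix> 30x30 complex, f = 1 GHz, |S| rms = 0.181

# small end-to-end study: 200 profiles, train, evaluate
res <- run_pipeline(list(
  seed = 6,
  dataset = list(n_profiles = 200, solver_grid = 36),
  model = list(base_channels = 2),
  train = list(batch_size = 40, max_epochs = 3, patience = 2)))
res$report
```

`generate_phantom` draws a breast whose glandular fraction lands in the
requested density class (class 4 = densest, the hard screening case);
`solve_forward` returns the complex multi-static scattering matrix
(reciprocal to machine precision); the report prints the confusion matrix,
the derived classification metrics, ROC-AUC, tumor-center distances on the
single-tumor subset (in cm, 1 px = 0.139 cm) and the soft-Dice / NCC /
NRMSE summaries over malignant profiles.

The methods vignette (`vignettes/mwiseg-methods.Rmd`) documents the model,
its assumptions, every tunable parameter, and the study design at desk
scale (2,000 profiles) versus the reference scale (160,000 profiles).

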