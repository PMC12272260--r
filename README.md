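# InfoCycle

Unpaired image-to-image translation for biomedical images that preserves
spatial and quantitative information — cell positions, per-cell signal
traces, intensities — not just plausible appearance.

## Who this is for

Labs that image the same biology through two modalities they cannot
acquire as registered pairs: cytosolic vs. nuclear-localised calcium
indicators, label-free vs. stained tissue, two MRI contrasts, low- vs.
high-SNR fluorescence. Ordinary cycle-consistency GANs only require that
a translation be *invertible*, which tolerates spatially misplaced or
intensity-inverted outputs; downstream quantitative analysis (ROI
matching, activity traces) does not.

## The model

Generators are encoder–decoder pairs sharing a full-resolution feature
domain. Encoders G_A, G_B produce feature maps Z = G(X) with C_Z channels
and the *same spatial size* as the input; translation is
X_{A→B} = F_B(G_A(X_A)). Training minimises

    L_tot = λ_adv · L_adv + λ_cyc · L_cyc + λ_info · L_info

with least-squares adversarial terms on PatchGAN-style score maps,
L1 cycle consistency

    L_cyc = |X_A − T_{B→A}(T_{A→B}(X_A))|₁ + |X_B − T_{A→B}(T_{B→A}(X_B))|₁,

and the information-consistency constraint

    L_info = |Z_A − G_B(X_{A→B})|₁ + |Z_B − G_A(X_{B→A})|₁,

which forces the features encoded from a translated image to match those
of its source. Every upsampling step inside the U-shaped networks is a
*learnable dynamic operator*: a 1×1 convolution predicts a 2s²-channel
offset field from the feature map, pixel shuffle rearranges it to a
2 × sH × sW offset grid O, and the map is resampled by differentiable
bilinear interpolation at S = G + O. With zero offsets this is exactly
bilinear upsampling (also its initialisation); training moves the
sampling positions to wherever preserves structure best.

The whole stack — convolutions, pooling, batch norm, weight
modulation/demodulation, dynamic upsampling, reverse-mode gradients,
AdamW — is implemented in this package (R + Rcpp/BLAS, CPU), validated
against finite differences and independent oracles in the test suite.

## Worked example: the synthetic rings-to-disks task

The package ships a seeded generator for a two-domain microscopy testbed:
latent cell fields with shared per-cell activity traces render either as
cytosolic rings (domain A) or nuclear disks (domain B). The domains are
anti-monotonic pixel-wise inside cells and perfectly correlated at the
cell level — the structure that makes naive unpaired translation fail.

```r
library(InfoCycle)

ds  <- makeSyntheticDataset(seed = 101)      # 40 + 40 unpaired images, 6 paired test fields
cfg <- taskConfig("synthetic")               # 64x64, lambda (adv, cyc, info) = (1, 10, 1)
fit <- trainModel(cfg, ds@trainA, ds@trainB, iterations = 500, seed = 101)

ev <- evaluateTranslation(fit$model, ds@testPaired, cfg)
ev$medianDist; ev$medianIoU; ev$tracePcc
```

On one CPU core this trains in a few minutes and prints (seed 101):

```
median centroid distance : 1.87 px     (cell radius: 8 px)
median ROI IoU           : 0.19
median trace PCC         : 0.47
generator loss           : 4.68 -> 2.16   (median, first vs last 10% of iterations)
```

i.e. nuclei synthesised from rings land ~2 px from their true centres,
and per-cell activity extracted from the translations correlates with
the latent ground-truth traces. An untrained model run through the same
evaluation gives a median centroid distance of ~21 px. Ablations are
one flag away:
`taskConfig("synthetic", info_loss = FALSE)` drops the information term,
`taskConfig("synthetic", upsampler = "bilinear")` freezes the upsampler.

Configurations reproducing the published recipes for the full-scale
tasks (calcium imaging, virtual H&E, DAPI labelling, MRI transfer, SNR
restoration) ship under `inst/configs/` — see the methods vignette
(`vignettes/unpaired-translation-methods.Rmd`) for every hyperparameter
and the reasoning behind the desk-scale choices. Published headline
numbers for those tasks require the deposited real datasets and
GPU-scale training and are not reproduced here.

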