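---
title: "Information-consistent unpaired image translation: models, training and the synthetic testbed"
author: "InfoCycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-consistent unpaired image translation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Many biomedical questions need the same sample seen through two imaging
modalities — a cytosolic and a nuclear-localised calcium indicator, a
label-free image and its stained counterpart, two MRI contrasts. Paired
acquisitions are often impossible, so the mapping between modalities must
be learned from *unpaired* collections. Plain cycle-consistency GANs
guarantee only that a translation can be *undone*; they happily produce
translations that are spatially misplaced or intensity-inverted, because
reconstruction is possible either way. For quantitative biology — cell
positions, per-cell signal traces — that is not good enough.

InfoCycle implements an unpaired translation model built around two ideas:

1. **Information consistency in a full-resolution feature domain.** Each
   generator is an encoder--decoder pair. Encoders $G_A, G_B$ map images
   to feature maps $Z = G(X)$ with $C_Z$ channels and *exactly the
   spatial size of the input*. Translation is $X_{A\to B} = F_B(G_A(X_A))$.
   An L1 penalty
   $$L_{info} = |Z_A - G_B(X_{A\to B})|_1 + |Z_B - G_A(X_{B\to A})|_1$$
   forces the feature map recovered from a translated image to carry the
   same spatial and quantitative information as the feature map of its
   source.
2. **Learnable dynamic upsampling.** Every upsampling step inside the
   U-shaped networks resamples the low-resolution feature map at positions
   $S = G + O$, where $G$ is the uniform bilinear grid and the offset grid
   $O$ is predicted from the feature map itself by a $1\times1$
   convolution followed by pixel shuffle. Fixed bilinear upsampling
   accumulates sub-pixel misplacements through repeated application; a
   learned, content-dependent grid can correct them.

The total objective is
$$L_{tot} = \lambda_{adv} L_{adv} + \lambda_{cyc} L_{cyc} + \lambda_{info} L_{info},$$
with least-squares adversarial terms (score maps from PatchGAN-style
discriminators, no sigmoid), L1 cycle consistency, and the information
term above. All L1 terms are **means** over elements rather than sums, so
the $\lambda$ values keep their meaning across patch sizes and channel
counts. The classical log (cross-entropy) adversarial form is available
behind `adversarialLoss(form = "log")` for reference, but the
least-squares form is what the discriminator architecture is built for
and what training uses.

## Architecture

Encoders and decoders share one U-shaped template (`unetInit`): per level
two $3\times3$ convolutions each followed by ReLU (batch norm between
convolution and ReLU when enabled), $2\times2$ max pooling on the way
down, dynamic upsampling + skip concatenation + two more conv/ReLU units
on the way up, and a final $1\times1$ convolution to the output channel
count. The encoder output is linear; decoders are linear by default
(unbounded intensities) with an optional sigmoid for [0,1] tasks.
Discriminators stack stride-2 $4\times4$ convolutions with
LeakyReLU(0.2) (widths 64/128/256/512 by default) and end in a
$3\times3$ convolution to a single-channel score map.

Decisions taken where the design was genuinely open:

* **Coordinates.** 0-based pixel centres, x = column, y = row; offsets in
  input-pixel units. Under this convention the uniform grid at $s=1$ is
  exactly the identity and integer-position sampling returns exact pixel
  values, which makes the operator testable to machine precision.
* **Offset initialisation.** The $1\times1$ offset convolutions start at
  zero, so the dynamic upsampler begins as *exact* bilinear upsampling
  and can only improve on it. An `offsetScale` multiplier exists
  (default 1).
* **Border handling.** Sampling positions are clamped to the image border
  before interpolation; clamped positions get zero position-gradient.
  Clamping avoids injecting zeros at feature-map edges.
* **Modulation.** Weight modulation/demodulation (per-input-channel
  scaling followed by per-filter unit-L2 renormalisation, `modulateDemodulate`)
  is implemented as self-modulation with learned per-layer scale vectors,
  off by default; the droplet-artifact mechanism it suppresses needs a
  conditioning signal the translation setting does not naturally provide.
* **Decoder shape.** Decoders mirror the encoder U; their input is the
  $C_Z$-channel feature map.
* **Batch-norm placement.** After each $3\times3$ convolution, before
  ReLU. With batch size 1 the batch statistics are spatial statistics;
  running moments serve inference.

## Training engine

Per iteration (batch size 1 throughout): draw one random patch per
domain (random frame + random crop), apply a random dihedral augmentation
(90-degree rotations, horizontal/vertical flips), update the
discriminators on real vs. detached fakes, then update the generators
through the adversarial + cycle + information terms with the freshly
updated discriminators. Optimiser: AdamW, learning rate $3\times10^{-4}$,
no weight decay. The cycle weight can follow a sigmoid growth schedule
$\lambda_{cyc}\,\sigma(k(i/I - m))$ (defaults $k=10$, $m=0.5$), used by
the calcium recipe. Images are percentile-normalised per full frame
before patching — either affine $(x-P_{lo})/(P_{hi}-P_{lo})$ or
scale-only $x/P_{hi}$ for calcium-like data whose baseline is
meaningful; degenerate (constant) images map to zeros.

The master seed is split into independent data and augmentation streams,
so toggling augmentation does not shift initialisation, and two runs with
one seed produce identical loss logs. Checkpoints keep the last three
periodic snapshots plus the best-by-generator-loss model; a non-finite
loss aborts with a diagnostic rather than training on.

**Numerical precision.** Convolution arithmetic inside the training loop
runs in single precision (sgemm), the precision this model family is
ordinarily trained in on GPUs; every exposed operator, inference pass and
the gradient-check path use double precision. The two paths share all
code except the GEMM precision; 20-iteration loss logs agree to about
$3\times10^{-4}$ relative.

**Subgradients.** ReLU clipping produces exact zeros, so max-pool windows
can be exactly tied; at such points the loss is non-differentiable and
the backward pass returns one valid subgradient (route to the first
maximum), as reverse-mode frameworks do. Gradient-check tests therefore
evaluate at generic random points, where analytic gradients match central
finite differences to ~1e-7.

## Task recipes

One YAML per task under `inst/configs/`, loaded by `taskConfig()`:

| task | patch | $\lambda_{adv},\lambda_{cyc},\lambda_{info}$ | widths | $C_Z$ | BN | normalisation |
|------|------|------|------|----|----|------|
| calcium | 256 | 1, 5, 10 (cyc scheduled) | 8/16/32 | 8 | no | scale / P99 |
| he | 512 | 5, 10, 10 | 32/64/128/256 | 3 | yes | [0,1] |
| dapi | 256 | 1, 10, 5 | 32/64/128/256 | 8 | yes | P0.1--P99.0 |
| mri, penicillium | 256 | 1, 10, 1 | 32/64/128/256 | 3 | yes | P0.1--P99.9 |
| planaria | 64 | 1, 10, 1 | 32/64/128/256 | 3 | yes | P0.1--P99.9 |
| synthetic | 64 | 1, 10, 1 | 8/16/32 | 8 | no | scale / P99 |

Iteration budgets for the full-scale tasks are user-set; the desk-scale
synthetic task defaults to 500 iterations, which one CPU core completes
in a few minutes. Ablation toggles: `info_loss = FALSE` removes the
information term; `upsampler = "bilinear"` replaces dynamic upsampling
with the fixed grid. Together they span the four classic configurations
(cycle-only baseline, + dynamic upsampling, + information consistency,
full model).

**Why the synthetic task uses (1, 10, 1) rather than the calcium weights.**
With $\lambda_{info}$ large, a 500-iteration budget collapses both
encoders to constant feature maps within about 100 iterations: the
cheapest way to make $Z_A$ and $G_B(X_{A\to B})$ agree is to make both
input-independent, after which translations are constant images and no
adversarial signal can recover input dependence (a constant $Z$ admits
only a constant decode). Following the standard recipe-selection
procedure for this model family (a sweep over weights in the 1/2/5/10
range, judged on training stability across three seeds),
$\lambda_{info} \ge 5$ collapses always, $\lambda_{info} = 2$ collapses
at one seed in three, and $\lambda_{info} = 1$ — with (adv, cyc) =
(1, 10), the weights this model family prescribes for its 64x64-patch
restoration task — trains stably at every seed. Cycle consistency, the
term that directly punishes input-independent translation, carries the
largest weight. The architecture stays the calcium one (8/16/32,
$C_Z=8$, no batch norm) with a 32/64-width discriminator sized for 64x64
frames. Discriminators are He-initialised rather than the common
N(0, 0.02): with tiny initial weights the discriminator needs over a
hundred iterations before its scores carry information, and the
unopposed early generator drift occasionally ruined a desk run.

## The synthetic testbed

`makeSyntheticDataset()` builds the study data: latent cell fields (cell
centres with a minimum separation, cytosolic radius 8 px and nuclear
radius 4 px at 64x64 — half the ~16-pixel neuron diameter typical of the
real recordings, matching the halved image size), per-cell activity
traces (Poisson spike trains convolved with a causal exponential kernel,
default rate 0.05/frame, decay 5 frames, baseline 0.3), and two
renderings: domain A paints each cell as a smooth ring (difference of
Gaussians with $\sigma = r/2$ per compartment, centre dip 0.9), domain B
as a Gaussian nuclear disk. Both scale linearly with the same per-cell
activity, so

* inside a cell, A and B run in **opposite** radial directions
  (anti-monotonic pixel relationship: the A centre is dim where B is
  bright, the A rim bright where B is dim);
* across cells, mean A and B intensities are **perfectly positively
  correlated** (the monotone cell-level relationship).

Profiles are truncated at $r_{cyto}$ (tails there are below $2\times
10^{-3}$ of peak), and the default minimum separation of $2 r_{cyto}$
makes cell footprints disjoint; together these keep the cell-level
relationship exactly linear rather than approximately so. The centre dip
of 0.9 (rather than a shallower one) keeps the ring's rim strictly
brighter than its centre at every rasterised rim pixel, so the
anti-monotonic structure survives pixel rounding.

Training sets for the two domains come from disjoint latent fields —
the dataset is unpaired *by construction*, and the object's validity
check enforces disjoint field seeds. The paired test set shares one
field per item across both domains and carries ground-truth instance
masks (domain A: the filled cell-body disk, domain B: the nuclear disk;
a ring-shaped cell segments as its filled body, and this makes the
nuclear ROI a strict subset of its cytosolic ROI with analytic IoU
$(r_{nuc}/r_{cyto})^2 = 0.25$) and the latent traces. Overlapping mask
pixels (possible only with a user-lowered separation) go to the nearer
centre. Infeasible packing requests fail loudly: $n$ cells with minimum
separation $s$ must satisfy $n\pi(s/2)^2 \le 0.9069\,HW$ (the hexagonal
packing density bound), and rejection sampling gives up after a bounded
number of attempts.

Noise is additive Gaussian with $\sigma = 0.05$ of dynamic range by
default, with optional Poisson shot noise. The generator emulates the
*statistical structure* the model cares about — shared latent geometry,
anti-monotonic pixel mapping, monotone cell-level intensities, temporal
traces — and deliberately not realistic optics (no PSF beyond Gaussian
smoothness, no motion, no 3D). Passing desk-scale tests therefore
demonstrates that the machinery optimises and preserves structure under
the model's assumptions, not that it reaches published real-data
performance, which requires the deposited datasets and GPU-scale
training.

## Evaluation

`imageMetrics` computes RMSE, MAE, PSNR ($10\log_{10} \max(x)^2 /
\mathrm{RMSE}^2$ — note the reference to $\max(x)$ of the estimate,
kept exactly as the metric is defined in this literature rather than the
fixed-dynamic-range convention), PCC, and SSIM from **global** image
statistics with $C_1=(0.01L)^2$, $C_2=(0.03L)^2$; a sliding-window SSIM
variant is available behind a flag for cross-tool comparison but the
global form is the tested default. Identical images give PSNR $+\infty$;
zero-variance inputs give an NA correlation rather than an error.

ROI correspondence (`matchAndScore`) matches each reference ROI to the
translated ROI with the nearest centroid (one-directional, reuse
allowed — no bipartite assignment), reporting centroid distance, the IoU
of the two single-ROI binary masks, and ROI counts. `extractTraces`
takes per-ROI mean intensities per frame, and `dff` computes
$\Delta F/F$ against a trailing moving-average baseline (window $k$,
shrinking over the first $k-1$ samples; the window length tracks the
recording rate and is a parameter). The sign convention is the standard
$(p - MA)/MA$; the opposite reading exists behind `invert = TRUE`.
Baselines $\le 0$ are masked NA. `segmentLabels` (Otsu threshold +
connected components) supplies instance masks for translated images
where no trained segmentation model is in play; trained segmentation of
real data is out of scope — evaluation consumes label masks.

## Known limitations

* Desk-scale training shows the optimisation works and the synthetic
  structure is preserved; it says nothing quantitative about real
  microscopy, histology or MRI performance.
* The GAN equilibrium at 500 iterations is rough: translated images
  over-segment noise specks (`minArea` prunes the smallest), and run-to-run
  variability across seeds is substantial.
* At desk scale the information-consistency term does **not** measurably
  improve ROI placement over the cycle-only ablation, for a structural
  reason: the default generator keeps cell footprints disjoint (required
  for the exact cell-level correlation property), which removes the dense
  packing that makes cycle-only translation misplace nuclei on real
  recordings, and weights that would give the info term real force
  collapse the encoders at this budget. The corresponding desk-scale
  ablation check in the test suite is expected to fail and is kept as an
  honest record; the info term's benefit is a full-scale, densely-packed
  phenomenon that this testbed cannot reproduce.
* Batch norm uses spatial statistics (batch size 1); its running-moment
  inference path is exercised by tests but not stress-tested at scale.
* The deformable-convolution alternative to grid-offset upsampling is
  deliberately not implemented.
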