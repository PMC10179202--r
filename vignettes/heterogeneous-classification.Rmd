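---
title: "Unsupervised classification of heterogeneous cryo-EM projection images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised classification of heterogeneous cryo-EM projection images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cryohetero)
```

## The problem

A single-particle cryo-EM dataset is a stack of extremely noisy 2D
projection images. When the sample mixes several molecules (compositional
heterogeneity) or several conformations of one flexible molecule
(conformational heterogeneity), the stack mixes projections of several
distinct 3D structures, and standard single-particle reconstruction -- which
assumes one structure -- breaks down. One practical remedy is to first
classify the images into homogeneous subsets and then reconstruct each
subset separately. `cryohetero` implements an unsupervised classifier for
this step that needs to know only the number of structures K: no templates,
no common lines, no orientation estimates.

The pipeline has four steps:

1. **Preprocess.** Projections are Fourier-cropped to 64x64 (an exact
   band limit that also removes most of the high-frequency noise) and each
   image is min-max normalised to [-1, 1]. For the convolutional model the
   single channel is replicated to three.
2. **Feature extraction.** An autoencoder is trained to reproduce the
   images through a latent space; the encoder output is the feature vector.
   Two models are provided: `AE-MLP`, a symmetric dense autoencoder
   (4096-512-8-512-4096, ReLU hidden activations, Tanh output) trained
   iteratively, and `AE-RES`, an asymmetric residual convolutional
   autoencoder with a 4096-D latent trained in a single pass.
3. **Unsupervised classification.** The latent vectors are reduced to 2D
   with UMAP; a shared-nearest-neighbour (SNN) graph is built on the
   embedding with an adaptive neighbourhood size `k = floor(sqrt(N)) + NS`
   (`NS = 5`); the binary adjacency (connect i and j when they share
   strictly more than NS of their k nearest neighbours) is clustered with
   the symmetric normalized spectral algorithm into K groups.
4. **Reconstruction.** Each predicted group is reconstructed by
   direct-Fourier central-slice insertion using the recorded orientations,
   and compared with references by Fourier shell correlation (FSC).

```{r}
vols <- lapply(0:2, function(c) make_phantom_volume(c, 128, seed = 1))
cfg <- simulation_config(num_classes = 3, images_per_class = 100,
                         snr = 0.1, seed = 1)
stack <- build_heterogeneous_stack(vols, cfg)
res <- classify_particle_stack(stack, k_classes = 3, model = "mlp",
                               seed = 1, epochs = 200)
res$accuracy
```

## The SNR model

Noise is added per image as i.i.d. zero-mean Gaussian noise with variance
`var(clean image) / SNR`; the default `SNR = 0.1` matches the noise level
of real micrographs. The definition is applied per image -- each clean
projection sets its own noise variance -- rather than per stack, because
the signal energy of a projection depends strongly on its viewing
direction. `estimate_snr()` inverts the definition and is used by the test
suite to confirm the generator's calibration.

## The autoencoders

**AE-MLP.** Encoder `4096 -> ReLU(512) -> linear(8)`, decoder
`8 -> ReLU(512) -> linear(4096) -> Tanh`. The 8-D bottleneck forces the
model to keep only the dominant structured variance of the stack, which at
SNR 0.1 is mostly signal; that is where its denoising power comes from.

**AE-RES.** Encoder: input conv (3->16), five ResDown blocks halving the
spatial size 64->32->16->8->4->2, and a kernel-2 valid convolution to a
1x1x4096 latent. Decoder: six ResUp blocks doubling 1->...->64 and an
output conv to 3 channels with Tanh. Each residual block combines a
pool/upsample+conv path with a conv-BN-RReLU-pool/upsample-conv-BN path by
elementwise addition, followed by RReLU. Channel widths (16, 32, 64, 64,
128 down; 64, 64, 32, 32, 16, 16 up) were chosen as the narrowest ladder
that satisfies the module counts, the spatial ladders and the 4096-D
latent; the architecture contract is those constraints, not a particular
width, and narrower widths keep one-pass training fast on a single CPU.

Training uses plain minibatch SGD (batch 32, learning rate 0.001), 500
epochs by default for AE-MLP and exactly one epoch for AE-RES.

### Numerical choices that matter

* **Gradient normalisation.** The reconstruction loss is reported as the
  per-pixel mean squared error, but the *training gradient* of AE-MLP uses
  the batch mean of per-image summed squared errors. With the per-pixel
  mean the gradient is 4096 times smaller and SGD at learning rate 0.001
  cannot move the network measurably within the configured epochs; with
  the image-sum convention the same learning rate trains effectively. The
  convolutional model is the opposite case: its gradients accumulate over
  every spatial position, so the image-sum convention would saturate the
  output Tanh in one step; AE-RES therefore uses the per-element mean.
* **Gradient clipping.** Occasional minibatch gradients spike an order of
  magnitude above the typical norm and a single such SGD step drives the
  output Tanh into saturation, after which all gradients vanish and
  training is dead. Gradients are clipped to a global L2 norm of 500
  (`grad_clip` in `training_config()`); typical healthy norms are 200-400
  for AE-MLP, so ordinary steps are unaffected.
* **Batch normalisation.** Running statistics use a cumulative moving
  average rather than a fixed momentum, so they equal the average batch
  statistics even after a single one-pass epoch; with a conventional 0.1
  momentum the statistics would still be dominated by their initialisation
  after ten minibatches, and evaluation-mode encoding would normalise with
  badly calibrated constants.
* **RReLU.** The negative-branch slope is drawn per element from
  U(1/8, 1/3) during training and fixed at the midpoint 11/48 during
  evaluation, so `extract_latents()` is a pure function of weights and
  input.
* **Residual combination.** The two paths of a residual block are combined
  by elementwise addition. (Addition is the standard residual operation
  and keeps channel counts consistent; a concatenation reading would
  double the channels at every block.)
* **Initialisation.** Uniform fan-in scaling, `U(-1/sqrt(fan_in),
  1/sqrt(fan_in))`, seeded; training is bit-reproducible given the seed.

## UMAP

No UMAP implementation ships with the R environment this package targets,
so a compact one is included: exact Euclidean k-nearest neighbours, the
standard smooth-kNN bandwidth calibration (binary search so that the local
membership sum equals log2(k)), fuzzy union symmetrisation, spectral
initialisation from the graph Laplacian, and negative-sampling SGD on the
standard rational output kernel (a, b fitted to the min_dist = 0.1
plateau). Defaults are n_neighbors = 15, min_dist = 0.1 and 300 layout
epochs. Exact neighbour search and a dense eigendecomposition are entirely
adequate at the stack sizes this workflow targets (N up to a few
thousand). The layout is deterministic given the seed.

## SNN graph and spectral clustering

The adjacency rule is strict (`> NS`): the formula wins over the looser
"at least NS" phrasing sometimes used to describe it. `k` uses floor
rounding of `sqrt(N)`. A point is not a member of its own neighbour set --
including it would shift every pair's shared count by up to 2 and
effectively change NS. Ties in neighbour distance break towards the
smaller index, which makes the graph reproducible.

Spectral clustering uses the symmetric normalised Laplacian: the K leading
eigenvectors of `D^-1/2 A D^-1/2`, row-normalised, then seeded k-means
with 10 restarts. Two degenerate situations are handled explicitly rather
than silently:

* **Isolated vertices** are connected to their nearest neighbour in the
  embedding before clustering (logged in the diagnostics).
* **More connected components than K.** UMAP occasionally tears one class
  into two islands; the SNN graph then has more components than clusters,
  the leading eigenspace is an arbitrary span of component indicators, and
  k-means merges components at random. In that case components are merged
  by single-linkage agglomeration over component *centroids* in the
  embedding, which is deterministic and robust to stray boundary points
  (the few impure points that sit between clusters would otherwise make a
  minimum-distance linkage chain across classes). The merge is flagged in
  the diagnostics.

## Evaluation

Unsupervised cluster ids carry no class names, so accuracy is computed
after optimally assigning clusters to classes on the contingency table
(Hungarian algorithm; the test suite checks it against exhaustive
permutation for K <= 4). Reported quantities: overall accuracy (correctly
classified images / total), per-class accuracy, and matched group counts.

## Reconstruction and FSC

The built-in reconstructor inserts each image's centred 2D DFT as a
central slice oriented by its rotation, with trilinear gridding and
overlap weighting, then inverts the averaged 3D transform. It is intended
for comparing subsets (its FSC ordering is what matters), not for
competing with iterative refinement packages; it uses the recorded
ground-truth orientations, which isolates classification quality from
orientation estimation. FSC uses shells of one Fourier voxel, assigned by
rounding the radial frequency; `resolution_at_threshold()` interpolates
the first crossing linearly and reports Nyquist when the curve never
drops below the threshold.

The projector integrates the rotated volume along +z with trilinear
interpolation; the viewing direction is the third row of the rotation
matrix, and the ZYZ Euler convention (`R = Rz(rot) Ry(tilt) Rz(psi)`,
degrees) is used in CSV sidecars. Volume centre and FFT origin share the
index-D/2 convention so the projector and the Fourier-slice reconstructor
agree without phase corrections.

## The synthetic generator

`make_phantom_volume()` builds density maps as sums of Gaussian blobs.
Classes differ along two rotation-stable axes, spread over class indices
by golden-ratio sequences and scaled by `separation`: overall object scale
(shell radius and blob width together) and granularity (how many blobs
carry the mass). These are the kinds of gross size/compactness differences
that also distinguish real macromolecular complexes in projection, and
they remain visible after orientation averaging -- which matters, because
at SNR 0.1 a class signature that depends on the viewing direction is
unrecoverable. A floor of six blobs keeps each class quasi-isotropic, so
its projection manifold is unimodal and the UMAP embedding does not
legitimately split it.

What the generator deliberately does **not** emulate: CTF, structural
noise and ice gradients, particle-picking errors, and the near-identical
conformer pairs of hard conformational datasets. Passing the synthetic
acceptance checks therefore demonstrates that the machinery is correct and
that the method separates structures whose projections differ at the
configured SNR; it does not certify accuracy on subtle real-world
conformational mixtures, where published results show substantially lower
accuracy than on compositional mixtures.

## Problem sizes

The shipped checks run the full pipeline on three 128^3 phantoms with 100
projections per class at SNR 0.1 (AE-MLP trained 200 epochs, AE-RES one
pass), verify the noise model on 100 replicate images, cross-check the
SNN graph against brute force on point sets up to N = 100, and score a
1000-image clean reconstruction of a spherical phantom. These sizes were
chosen so a complete run finishes comfortably on one CPU core while still
exercising every stage at realistic ratios (images per class, SNR, k).

## Known limitations

* K must be known; there is no model selection.
* No CTF model anywhere in the pipeline.
* Reconstruction requires known orientations (it is a scoring tool, not a
  refinement engine).
* The one-pass residual model's features depend on a well-conditioned
  random initialisation; its accuracy has higher seed-to-seed variance
  than the iteratively trained dense model.
* Stacks are held in memory; N in the tens of thousands would need a
  chunked redesign.
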