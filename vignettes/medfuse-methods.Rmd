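---
title: "Two-branch multimodal image fusion: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-branch multimodal image fusion: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medfuse)
```

## The problem and the model

Clinical imaging routinely produces co-registered pairs in which each
modality carries part of the picture: a structural scan (CT, T1/T2 MRI)
resolves anatomy — boundaries, texture, fine ridges — while a functional
scan (PET, perfusion imaging) carries smooth region intensities at low
spatial resolution. Image fusion composes one image that retains both
information sets. `medfuse` implements a two-branch strategy:

1. **Two-scale decomposition.** Each source $I_k$ ($k = 1, 2$) is split
   into a smooth *base part* $I^b_k$ and a residual *detail part*
   $I^d_k = I_k - I^b_k$. The default base is the minimiser of

   $$\lVert I - I^b\rVert_F^2 +
     \lambda\left(\lVert g_x * I^b\rVert_F^2 +
                  \lVert g_y * I^b\rVert_F^2\right),$$

   with first-difference kernels $g_x = [-1\; 1]$, $g_y = [-1\; 1]^T$.
   Under periodic boundary conditions the normal equations are
   diagonalised by the 2-D DFT, so the solver is exact and $O(n \log n)$:
   $I^b = \mathcal{F}^{-1}\!\left[\mathcal{F}(I) \,/\,
   (1 + \lambda(|\mathcal{F}(g_x)|^2 + |\mathcal{F}(g_y)|^2))\right]$.
   A dual-tree complex wavelet (DTCWT) backend is selectable: there the
   base is the inverse transform of the final-level lowpass with all
   highpass subbands zeroed, and the detail is the residual, so
   additivity $I = I^b + I^d$ holds by construction for both backends.

2. **Base fusion.** $F_b = \alpha_1 I^b_1 + \alpha_2 I^b_2$ with
   $\alpha_1 = \alpha_2 = 0.5$ by default (preserving features common to
   both sources), or per-pixel weights $W \in [0,1]$ from the Siamese
   saliency network, $F_b = W \odot I^b_1 + (1 - W) \odot I^b_2$.

3. **Detail fusion.** Each detail part is pushed through a four-level
   feature extractor (channel counts $64 \cdot 2^{i-1}$ at $1/2^{i-1}$
   resolution, $i = 1..4$). Per level, the activity map is the L1 norm
   across channels, $C^i_k(x,y) = \sum_n |\phi^{i,n}_k(x,y)|$, block
   averaged over a $(2r+1)^2$ window ($r = 1$) for robustness to slight
   misregistration; softmax across sources gives weights
   $w^i_k = \hat c^i_k / \sum_n \hat c^i_n$; block replication upsamples
   them to full resolution; the per-level fused details
   $F^i_d = \sum_k \hat w^i_k I^d_k$ are combined by the pointwise
   maximum $F_d(x,y) = \max_i F^i_d(x,y)$.

4. **Reconstruction.** $F = F_b + F_d$, clipped to $[0,1]$. Clipping
   (rather than renormalisation) preserves absolute intensity semantics;
   the sum can exceed the range only where a bright base meets a strong
   positive detail.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `lam` | 5 | Gradient penalty of the optimization split; more pushes content into the detail branch. As $\lambda \to 0$ the base tends to the image, as $\lambda \to \infty$ to its mean. The default matches the two-scale literature this formulation derives from and gives visually smooth bases on the synthetic fixtures. |
| `levels` | 2 | DTCWT backend depth. |
| `alpha` | (0.5, 0.5) | Scalar base weights; must sum to 1. |
| `r` | 1 | Block-average radius (pixels at level resolution). Larger is more tolerant to misregistration but blurs the weight boundaries. |
| `stride` | 2 | Siamese dense-inference stride; 1 is exact, 2 is four times faster with near-identical maps (overlap averaging). |
| `extractor_seed` | 1 | Seed of the fixture extractor's kernel draw. |

Two conventions deserve explicit record because they change numbers,
not just style. The cross-level maximum is taken on *signed* detail
values, not absolute values; detail coefficients can be negative, so
the choice is observable (negative-going edges are slightly attenuated
relative to an absolute-value rule). And the maximum runs over all four
feature levels, matching the four-level extractor contract.

## Feature extractors

The detail branch is defined against a *contract*: four rectified
levels, channel counts (64, 128, 256, 512), spatial sizes
$\lceil H/2^{i-1}\rceil \times \lceil W/2^{i-1}\rceil$ (ceiling division
covers odd sizes; the block-replication upsampler crops to the target).
Two extractors satisfy it:

* the **fixture extractor** — four stages of bias-free seeded random
  3×3 convolutions with ReLU and stride-2 average pooling. Random
  rectified projections preserve local energy, which is what the L1
  activity measure consumes, so the fusion behaves sensibly without any
  trained weights, and every test is deterministic and download-free;
* the **VGG-19 adapter** — relu1_1/relu2_1/relu3_1/relu4_1 activations
  of a pretrained VGG-19, given a user-supplied weights file (RDS; the
  package never downloads anything). Grayscale input is replicated to
  three channels and normalised with the natural-image mean/std
  convention, the standard practice for pretrained-backbone feature
  extraction.

## The Siamese saliency network

The base-weight network scores which of two co-located 16×16 patches is
more salient. Branch: conv 11×11 (pad 5, which keeps the 16×16 patch
size) → conv 5×5 (pad 2) → max pool 3×3 stride 2 →
conv 3×3 (pad 1), ReLU throughout, then a fully-connected layer to a
256-dimensional branch vector; the concatenated 512-vector feeds a
2-way softmax head. The kernel schedule, the 16×16 patch size and the
256-dimensional branch vector are fixed design points; the conv channel
counts (8, 16, 32) are sized so that desk-scale training runs in
minutes on one CPU. The network uses neither dropout nor local
response normalisation.

The network is trained on a synthetic saliency-discrimination task
(`make_patch_pairs()`): textured grating patches where one copy is
degraded by Gaussian blur ($\sigma \in [1,3]$) and/or contrast scaling
($\in [0.2, 0.6]$), the non-degraded patch labelled salient, labels
exactly balanced. Cross-entropy, mini-batch SGD with momentum 0.9,
learning rate 0.02, 20 epochs over 2000 pairs: held-out accuracy
reaches 1.0 in 2–4 minutes on one CPU (blur discrimination is an easy
task; the point of the stated scale is a reproducible, fast training
check, not a hard benchmark).

Two structural guarantees are worth noting. Scores are always evaluated
in both branch orders and averaged, $s(a,b) = (p_1(a,b) + p_2(b,a))/2$,
which makes $s(a,b) = 1 - s(b,a)$ exact despite the concatenating
(asymmetric) head. Dense inference anchors the final window row/column
to the far edge so every pixel is covered at any stride $\le 16$, and
overlap counts normalise the accumulated scores, keeping the map in
$[0,1]$. The map carries source 1's probability; the swap test pins
the convention.

## The dual-tree complex wavelet transform

No DTCWT implementation exists in the R package ecosystem, so the
package carries its own. The structure is the standard dual tree: an
odd-length symmetric biorthogonal first stage (CDF 9/7) in which tree B
is the one-sample-delayed copy of tree A, and even-length orthonormal
*Q-shift* filters for levels ≥ 2 in which tree B is the time reverse of
tree A. The 14-tap Q-shift lowpass was designed by constrained
optimisation (exact orthonormality and two vanishing moments as
equality constraints; objective = passband mismatch from the
half-sample-delay condition plus stopband energy); the resulting
iterated complex wavelet has a negative/positive frequency energy ratio
of 0.018, i.e. it is genuinely near-analytic, and level-3 subband
magnitudes change by ~9% under a one-pixel shift (versus ~40% for a
decimated real DWT). Boundaries are periodic, which keeps each per-tree
branch an exact filter-bank identity; the four per-tree lowpass
reconstructions are averaged. The six oriented complex subbands per
level feed the multi-scale edge-preservation metric.

No inverse transform is applied after the additive reconstruction
$F = F_b + F_d$: that image is already spatial, and under the DTCWT
backend the only inverse lives inside the decomposition itself.

## Metrics

All metrics work on the 0–255 scale so magnitudes are commensurate with
the image-fusion literature.

* **MSE / PSNR** — $\mathrm{PSNR} = 10\log_{10}(255^2/\mathrm{MSE})$,
  with an infinity sentinel at zero error; the report's conventions
  block records the exact form used. Because a fused image has two
  legitimate references, the report carries per-source values and
  their mean.
* **SSIM** — the canonical 11×11 Gaussian ($\sigma = 1.5$) windowed
  form with $C_1 = (0.01 \cdot 255)^2$, $C_2 = (0.03 \cdot 255)^2$.
* **Q_MI** — mutual information of each source with the fused image
  from 256-bin joint histograms (entropies in bits). The default
  normalised variant $2[\mathrm{MI}(A,F)/(H_A + H_F) +
  \mathrm{MI}(B,F)/(H_B + H_F)]$ equals 2 at $F = A = B$; the plain sum
  is available. Note the histogram estimator's positive bias of order
  (occupied cells)/$2N\ln 2$: independence tests need large images.
* **Q_M** — a package-defined multi-scale scheme, flagged as not
  comparable to other implementations' scores of the same name:
  decompose $A$, $B$, $F$ with the DTCWT;
  per level and oriented subband compute per-coefficient preservation
  $\min(|F|,|A_k|)/\max(|F|,|A_k|)$ (1 where both vanish), weight by
  source magnitude $|A_k|$, pool over both sources, average levels. It
  is 1 when $F$ equals both sources, near 0 when edges are destroyed,
  and decreases monotonically as $F$ is blurred.

## The synthetic pair generator

`make_pair()` builds a phantom composite — an outer boundary ellipse
with 3–5 internal ellipses at distinct intensities (drawn from bands
clearly above or below the background so region contrast never
degenerates), five thin bright ridges, fine oriented texture — and two
modality renditions. The *structural* rendition keeps all sharp
structure but re-renders the smooth region levels with
modality-specific contrast: attenuated towards the mean (×0.8) plus a
per-region offset (0.04–0.07) directed *away* from the composite's
level, so the structural contrast is correlated with but never an
accidental copy of the functional signal; acquisition noise sd 0.03.
The *functional* rendition is the composite under a Gaussian of
$\sigma = 2.5$ px plus noise sd 0.01. The design intent is that the two
renditions are genuinely complementary in the information-theoretic
sense: each shares more histogram MI with the composite than they share
with each other, and fusing them lands closer (MSE) to the composite
than either input — both properties hold across generator seeds and are
asserted in the test suite. An early design that merely *scaled* the
structural low band failed the MI property, instructively: attenuation
is invertible and destroys no information; decoupling requires
modality-private randomness.

What the generator does **not** emulate: scanner physics (partial
volume, attenuation maps, Rician noise), deformable misalignment,
pathology. Passing the synthetic suite shows the pipeline's mechanics
and its information-combining behaviour are right, not that clinical
fusion quality matches any published table — reproducing those tables
would need the external datasets and the trained networks behind them.

## Numerical choices and degenerate inputs

* Softmax weights at all-zero activity pixels are uniform $1/K$; for
  $K = 2$ the larger-activity source takes the exact complement
  $1 - w$ of the smaller's quotient, so per-pixel sums are exactly 1 in
  floating point while swap symmetry is preserved.
* Block averaging zero-pads without border renormalisation: a corner
  of a constant map keeps $4c/9$ at $r = 1$.
* Registration searches integer translations exhaustively (±5 px
  default, optional coarse angle grid), then refines by coordinate
  descent with 1-D `optimize()` line searches — a direction-set scheme
  chosen over a full Powell implementation for robustness in 2–3
  dimensions. MI cost uses a 64-bin joint histogram with +1 smoothing;
  a constant fixed image is rejected (MI undefined up to ties).
* Histogram equalisation maps level $v$ to its plain CDF value; a
  constant image is returned unchanged.
* Resampling is bilinear with zero fill outside the frame, so borders
  are predictable in tests.
* Problem sizes in the tests: oracle equivalence at 8×8 (dense
  65×… systems stay tiny), pipeline properties at 48–64 px, generator
  invariants at the 256 px default, Siamese training at 2000 pairs ×
  20 epochs. These are the package's study conditions; the synthetic
  properties above hold at these sizes with wide margins.

## Known limitations

* JPEG input is not supported (no decoder in the dependency set); PNG
  and TIFF are. PNG output is always 8-bit; 16-bit output uses TIFF.
* The VGG-19 path is exercised against its contract with synthetic
  weights; results with real pretrained weights will differ from the
  fixture extractor's (the fusion arithmetic downstream is identical).
* Q_M is package-defined (see above) and not comparable across
  implementations.
* Registration covers rigid translation + rotation only; scaling is
  excluded (the fusion stages assume pre-registered inputs anyway).
* K = 2 sources per fusion call; the formulas generalise but every
  stated instantiation is pairwise.
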