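---
title: "Inside the lightweight tea-bud detector: blocks, budgets, and what the tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inside the lightweight tea-bud detector}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lmtb)
```

## The problem

Tea buds that meet the premium "one leaf, one bud" picking standard are small
(tightly wrapped tips of 3–5 mm against young leaves up to ~2 cm, a 4–6×
linear scale spread), densely clustered, frequently occluding one another,
and nearly the same colour as the canopy behind them. A detector that should
eventually run on a picking robot additionally has to be small. YOLO-LMTB is
a nano-scale one-stage detector addressing both constraints by replacing
three stages of the standard nano layout:

* the backbone's CSP bottleneck stages become **MERCA** blocks (multi-scale
  edge-refinement context aggregation),
* the similarity-attention stage at the end of the backbone becomes a
  **DHTST** block (dynamic-tanh + token-statistics attention),
* the path-aggregation neck becomes a single-sweep **weighted bidirectional
  feature pyramid** with stride-4 (P2) detail injection.

This package builds both the baseline and the improved graph, audits their
parameter and FLOP budgets exactly, exercises gradient flow end to end on a
hand-built autodiff core, and evaluates detections with IoU-matched
precision/recall and mAP. Everything runs on one CPU.

## MERCA

An input map $X \in \mathbb{R}^{H\times W\times C_{in}}$ enters four scale
branches and one local branch. Branch $k$ pools $X$ to a $g_k \times g_k$
grid by adaptive average pooling with the pyramid $g_k = 3k$, $k = 1..4$
(so $\{3, 6, 9, 12\}$), then applies a $1\times1$ reduction conv to
$C_{out}/4$ channels and a grouped $3\times3$ conv — the *scale adapter*.
Each adapted map passes the *edge refiner*

$$ER(X) = X + \mathrm{Conv}(X - P_{avg}(X)),$$

where $P_{avg}$ is a $3\times3$, stride-1 box blur whose zero padding is
counted in the divisor, and the conv is linear ($3\times3$, grouped). The
difference $X - P_{avg}(X)$ isolates the high-frequency component — bud
contours, tips, leaf junctions — which the conv re-weights before the
residual restores the low-frequency content. Refined branches are rescaled
to $H\times W$ by bilinear interpolation (half-pixel centres, no corner
alignment) and concatenated with a local $1\times1$ branch; since the four
branches carry $C_{out}/4$ channels each, the concatenation holds exactly
$2C_{out}$ channels, the CSP-style budget, and a final $1\times1$
aggregation conv returns $C_{out}$.

Choices the block's definition leaves open, and what this package does:

* **Branch widths and groups.** The reduction width is $C_{out}/4$; the
  scale conv is depthwise (group width 1) and the edge conv uses group
  width 2. These widths were fixed once, by closed-form parameter
  arithmetic, so that the four backbone blocks together land the assembled
  model on its published parameter budget; they are constructor arguments
  (`group_width`, `er_group_width`) if you want to explore the trade-off.
* **Linear edge conv.** The residual form is exact on constants only if the
  conv path is linear, and the block's defining identity
  $ER(X) - X = \mathrm{Conv}(X - P_{avg}(X))$ is asserted in the tests to
  $10^{-10}$; the nonlinearity lives in the adapter convs instead.
* **Small inputs.** Pooled sizes are clamped to $\min(H, W)$. Clamped
  branches are *kept*, not dropped: each owns distinct parameters, and the
  aggregation conv's input width is part of the block contract. (Dropping
  duplicate-sized branches would make the graph input-shape-dependent.)
* **Per-branch refinement.** The edge refiner sits inside each scale branch
  (operating at the branch's own scale), not once after aggregation.

## DHTST

A $1\times1$ conv splits the 256-channel P5 features 1:1 into a main and an
auxiliary half. The auxiliary half passes a **DyT** layer,

$$F_{dyn}(X) = \beta \odot \tanh(\alpha \odot X + \gamma),$$

with learnable per-channel scaling $\alpha$ (init 0.5), weight $\beta$
(init 1) and bias compensation $\gamma$ (init 0). The tanh compresses
activations into $[-1, 1]$ (scaled by $\beta$), suppressing outlier
responses from specular highlights before any statistics are taken.

The dynamised half is flattened to $n = H \cdot W$ tokens of dimension 128
and passes **token-statistics attention**: one linear projection, a split
into $h = 4$ heads, and per-head weights

$$\Pi_h = \mathrm{softmax}_n\!\left(\tau_h \, \lVert p_{h,n} \rVert_2^2\right),$$

a softmax over the temperature-scaled squared norms of the projected
tokens. No $n \times n$ similarity matrix is formed — the weights derive
from second-order token statistics, which is both the mechanism's
linear-in-$n$ efficiency argument and its robustness argument in scenes
where foreground and background are similar (similarity scores collapse,
norm statistics do not). The projected tokens are rescaled by
$\Pi$ and by $1/\sqrt{M_h + \varepsilon}$, where $M_h$ is the
$\Pi$-weighted second moment per head dimension and $\varepsilon = 10^{-6}$
is the numerical floor; a learnable per-head gate multiplies each head
(this package reads the sign ambiguity in the mechanism's published
formula as a learnable-gate convention), and a second linear projection
merges the heads. Temperatures initialise to 1; dropout is 0 and the whole
block is deterministic at inference.

The attention output rejoins its input residually, is concatenated with the
main half, and the 256-channel result passes a second DyT and a two-layer
$1\times1$ FFN (expansion 1×) with a final residual. The published
formulation applies the first DyT twice in its fusion expression; it is
computed once and reused here.

## The neck

All levels are first compressed to a common width of 64 channels by
$1\times1$ convs. The width is the neck's main dial; 64 was fixed at design
time by the same closed-form budget arithmetic as the MERCA widths and is
exposed as a constructor argument. One bidirectional sweep follows:

* top-down: P5 is upsampled (nearest ×2) and fused with P4; the fusion
  output is refined by a three-conv stack ($3\times3$, $1\times1$,
  $3\times3$). The result is upsampled and fused with P3 **and** with a
  stride-2 full $3\times3$ conv of the backbone's P2 map — the detail
  injection that carries stride-4 edge information of the smallest bud tips
  into the finest detection level (a full conv here, where the fine detail
  enters; the later bottom-up downsample of the already-refined P3 output
  uses a cheap separable conv).
* bottom-up: the refined P3 is downsampled and fused with P4 (three-input
  node), then P4 with P5 (two-input node; the figure of the published
  design is not legible enough to decide two versus three inputs for P5,
  and two is the variant consistent with the parameter budget).

Every fusion node uses fast normalised fusion

$$\mathrm{out} = \frac{\sum_i \mathrm{relu}(w_i)\, F_i}{\sum_j \mathrm{relu}(w_j) + \varepsilon}, \qquad \varepsilon = 10^{-4},$$

whose effective coefficients are nonnegative and sum to just under one, so
each output element stays inside the (slightly shrunk) elementwise envelope
of its inputs — a property the test suite checks against a brute-force
bound. Weights initialise to 1.

## Assembly and audit

`build_baseline()` reconstructs the publicly documented nano layout (stem,
four CSP stages at widths 64/128/128/256 after a 0.25 width gain, SPPF,
attention stage, path-aggregation neck, three decoupled heads with a
16-bin distribution-focal box branch; single class). `build_lmtb()` swaps
in the three modules above; further variants mirror the ablation and
placement studies (`merca-backbone`, `merca-neck`, `merca-all`, `dhtst`,
`bifpn`, and pairwise combinations).

Two conventions matter when comparing budgets:

* **Parameters** are counted on the deploy-style fused graph: each
  conv+normalisation pair is a conv with a per-channel bias, which is also
  exactly how the layers are parameterised here. The distribution-focal
  expectation is fixed arithmetic, not a parameter. On this convention the
  reconstructed baseline counts 2,582,331 trainable scalars and the
  improved model 1,851,573 — a 28.3% reduction, with the per-stage
  breakdown summing exactly to the totals.
* **FLOPs** are $2\times$ multiply–accumulates over all conv and linear
  operations (including attention projections and, for the baseline
  similarity attention, the $n^2$ matmuls) at a stated input size, batch 1;
  pooling, resizing and activations are not counted. The audit propagates
  shapes analytically, so `count_flops()` at any legal input size is
  instant and exact with respect to this convention.

`scripts/acceptance.R` rebuilds both graphs and reports these three
numbers; `audit_variant()` gives the same per-variant.

## Training smoke

Full training (the published schedule: 640², 300 epochs, batch 32, SGD,
lr 0.01, momentum 0.973, weight decay $10^{-5}$) is out of scope for a CPU
build and is not attempted. What *is* verified is end-to-end
trainability: `train_smoke()` renders 8 synthetic scenes at 320² and runs
200 SGD-with-momentum steps (lr 0.2, momentum 0.9, weight decay $10^{-5}$
— chosen for the simplified loss below, not the published schedule) of a
dense objective: per level, an MSE between the sigmoid class map and a
box-centre objectness target, plus an MSE on the distribution-focal
distance expectations at positive cells. The loss touches both branches of
every head and therefore every parameter group upstream. The suite asserts
that the mean loss over the scenes at least halves and that every
parameter tensor received a nonzero gradient. Problem sizes (8 scenes,
320², 200 steps, batch 1) are the smallest at which both assertions are
meaningful rather than noisy.

The autodiff core behind this is a tape-based reverse-mode engine over
(H, W, C) arrays with im2col convolutions (C++ inner loops, BLAS gemms);
every primitive's gradient is checked against central finite differences
in the test suite.

## The synthetic scenes

`generate_scene()` emulates the *structure* of the field data regime —
what makes the detection problem hard — without pretending to be a plant
renderer: elongated soft-edged ellipses (aspect 2.2–3.6) on a green
value-noise background with a smooth illumination gradient; a 5× spread
between the smallest and largest minor axis with the two extremes pinned
in every scene; cluster-based placement that produces overlap and
occlusion; and a small controlled luminance offset (default 0.10) between
targets and background. Boxes are exact tight extents of the rendered
ellipses, written as normalised YOLO TXT lines. Everything is
deterministic given the seed.

What passing tests on these scenes do **not** show: robustness to real
foliage texture, specular highlights, motion blur, or annotation noise —
none of which the generator models. The scenes make architecture,
metric and trainability claims testable offline; they are not a substitute
for the field dataset's accuracy benchmarks, and no accuracy number
measured on them should be compared to published detection accuracy.

`mosaic_augment()` implements the 2×2 collage used during training-set
augmentation (native-scale placement around a random centre, label
clipping, minimum-side dropping), and `split_dataset()` the 7:2:1 split.
The split floors the train and validation shares and gives the remainder
to test — the one rounding rule that reproduces the published
2143/613/306 partition of 3062 images (flooring the first two shares in
order would give 612 test images).

## Numerical notes and limitations

* Adaptive pooling uses floor/ceil window bounds (the reference
  convention); its output is tested against a per-window-mean loop oracle
  for every grid size up to 12.
* Bilinear rescaling uses half-pixel centres without corner alignment.
* The box blur divides by 9 everywhere, counting zero padding in the
  divisor; the edge refiner's constant-identity property is therefore
  asserted with the conv path zeroed.
* Greedy confidence-ordered matching (the community default) stands in for
  optimal assignment in the metrics; the suite cross-checks it against an
  exhaustive assignment oracle on a crafted case. AP uses all-points
  interpolation by default, 101-point as an option.
* Weight initialisation is He-style with zero biases; a single seed fixes
  builds bit-for-bit, and inference is fully deterministic.
* The graph runs batch-1 only — sufficient for auditing, property tests
  and the smoke run; a batched engine was deliberately out of scope.
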