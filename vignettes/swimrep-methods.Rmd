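---
title: "Methods: attention blocks, fusion gates, and the ECG beat pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attention blocks, fusion gates, and the ECG beat pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of what it computes and why the
defaults are what they are. Everything numeric quoted here is produced by the
test suite or by `scripts/acceptance.R`; nothing is asserted that the code
does not itself compute.

## The tensor substrate

No deep-learning framework is assumed. All blocks run on a small in-package
reverse-mode automatic-differentiation engine over dense R arrays
(`R/autograd.R`). Feature maps are stored channel-first, `(C, H, W, B)`, so
per-channel broadcasts are plain vector recycling and convolutions reduce to
one BLAS matrix product per kernel tap. The tape records nodes in forward
order; reverse traversal of the creation order is a valid topological order
because the graph is built during the forward pass. Every analytic backward
pass is validated against central-difference gradients in
`test-autograd.R` (tolerance `1e-6` on problems small enough for finite
differences to be trustworthy).

## Criss-cross attention and its sparse variant

Criss-cross attention restricts self-attention, per query pixel $u=(i,j)$, to
the $H + W - 1$ pixels sharing $u$'s row or column. Queries and keys are
projected to $C' = \max(1, C/8)$ channels (the convention of the criss-cross
literature; configurable via `qk_channels`), values keep $C$ channels, and
the output adds the attention-aggregated values back to the input. Two
design points deserve note:

* **The pixel itself is counted once.** It enters through the column branch
  and is masked out of the row branch before the joint softmax, giving
  exactly $H + W - 1$ attention weights that sum to one.
* **The affinity is a plain scaled-free dot product.** The cross-attention
  literature applies a softmax over the cross positions of $Q_u^\top
  \Omega_u$; we treat the attention as acting over the $H \times W$ plane
  rather than introducing a scalar temperature of $H\cdot W$, which would
  contradict the cited construction.

Recurrence (`rounds = 2` by default) re-applies the same weights so that
information propagates from the cross to the full plane. The sparse variant
(FRCA) bilinearly rescales the input to half resolution (corner alignment
disabled, both directions), applies the recurrent attention there, rescales
back, and adds the input. The half-resolution plane realizes the "every
second pixel" sparsification: the quadratic cross-energy term shrinks by a
factor of four, which `sr_count()` makes measurable. The algorithm's
published step 3 asks for a *downsampling* of the half-resolution attention
result while simultaneously requiring it to match the input size; size
consistency is mandatory, so the implementation upsamples by 2.

1x1 inputs are rejected by FRCA as degenerate (the half-resolution plane
would be empty); the fused block propagates that error.

## Polarized self-attention and the fused block

The polarized block is sequential (channel gate, then spatial gate), because
the composition applies the spatial operator to the channel-attended map; the
parallel layout is deliberately not implemented. The channel branch pools a
$C/2$ bottleneck descriptor with a spatial softmax, re-expands it to $C$, and
squashes with a sigmoid; the spatial branch scores each pixel against a
channel-softmaxed descriptor of the gated map. Both gates are sigmoid
outputs, hence in $[0,1]$, and are retained in `$last_gates` for inspection.
Odd channel counts use $\lfloor C/2 \rfloor$ (minimum 1) for the bottleneck.

The fused block (FRCPA) concatenates the polarized and sparse criss-cross
outputs along channels ($2C$) and compresses back to $C$ with a 1x1
convolution initialized with fan-in scaling; no residual is added around the
projection, since the composition itself contains residual paths inside both
branches.

## Strip pooling and the fusion gates

Both fusion modules combine two same-shaped maps as $M x + (1-M) y$ with a
sigmoid gate $M$ computed from $x + y$. The two-branch baseline (AFF-style)
uses a global average-pooled channel bottleneck plus a point-wise local
bottleneck (reduction ratio $r = 4$, the usual convention). The five-branch
MPF adds a horizontal strip branch (average over width, length-3
one-dimensional convolution along height, broadcast back), the analogous
vertical strip branch, and a 3x3 local convolution. The exact branch
inventory is not fully pinned down by the published description, which asks
for "multi-branched, multi-axis orthogonal pooling" on top of the
global/local channel context; the five branches above are the minimal set
realizing that description, and the branch count is exposed for
introspection. Branch outputs are summed, not concatenated, so the gate
keeps shape `(B, C, H, W)`.

With all branch parameters zeroed the pre-sigmoid sum is exactly 0, the gate
is exactly 0.5, and fusion returns $(x+y)/2$ — a useful exact identity that
the tests assert bitwise. Self-fusion (`x == y`) returns `x` for any gate,
because the mix is convex.

Cross-stage alignment downsamples with an integer-stride average pool
followed by a 1x1 channel projection (bilinear resampling for non-integer
ratios), or projects then upsamples bilinearly. With matching channel counts
the projection can be identity-initialized, making same-shape alignment the
identity — the hook the tests use.

## Rep blocks and structural reparameterization

A Rep block is the parallel sum 3x3 conv + BN, 1x1 conv + BN, and identity
BN (present iff channels match and stride is 1), under a ReLU. After
training, each branch's batch norm is folded into its kernel
($w' = w\,\gamma/\sqrt{\sigma^2+\varepsilon}$,
$b' = \beta - \gamma\mu/\sqrt{\sigma^2+\varepsilon}$), the 1x1 kernel is
zero-padded to the center tap, the identity becomes a per-channel delta
kernel, and the three fold into a single 3x3 convolution. Folding requires
finalized statistics, so `reparameterize()` refuses to run on a block in
training mode. Equivalence between the multi-branch and fused forms is
checked on 100 random inputs across branch/stride configurations at `1e-4`,
a tolerance reflecting accumulated floating-point reassociation, not model
error.

## Window attention and complexity accounting

Swin-style blocks are pre-norm: layer norm, windowed multi-head attention
with a learned relative-position bias table of size $(2M-1)^2$ per head, a
residual, then a two-layer GELU MLP with hidden width $4D$ and a second
residual. Shifted blocks roll the map by $\lfloor M/2 \rfloor$, partition,
and mask attention across wrap boundaries using the standard nine-region
labeling; the mask construction is validated against an explicit
roll-and-partition per-window loop oracle on an 8x8, $M=4$ toy. Windows
larger than the feature map are clamped to it, in which case shifting is a
no-op and the shifted block provably reduces to the unshifted one. When the
grid is not divisible by the (clamped) window the constructor raises an
error rather than silently padding; all built-in configurations satisfy
divisibility.

The closed forms

$$\Omega(\mathrm{MSA}) = 4hwC^2 + 2(hw)^2C, \qquad
  \Omega(\mathrm{W\!-\!MSA}) = 4hwC^2 + 2M^2hwC$$

are implemented exactly and cross-checked against the operator-level counter,
which also verifies that measured window-attention cost is linear in the
token count at fixed $M$ and $C$.

`count_params()` sums trainable parameter lengths; `count_flops()` walks the
module tree counting multiply-accumulates for convolutions, linear layers
and attention matrix products (one MAC = one FLOP unit; normalizations and
activations are excluded — the convention under which the cited backbone
numbers were published). For the RepVGG-B0 reference with a 7-class head the
fused form counts 13.07M parameters and 3.056G MACs and the multi-branch
form 14.55M and 3.396G; the quoted accounting for this architecture (13.1M,
3.325G) matches the fused parameter count to three significant figures while
its FLOP figure falls between the two forms, whose identity (train vs deploy)
its source does not state. Both forms are therefore reported. The Swin-base
reference counts 86.75M parameters and 15.43G MACs at 224x224 with 7
classes, within 0.1% of the quoted 86.78M / 15.437G.

## The four-stage hybrid assembly

A `swimrep_config` fixes per-stage widths, Rep and Swin depths, window,
heads, fusion (`none`/`aff`/`mpf`) and attention (`none`/`frcpa`). The
input must be divisible by patch size times $2^3$ so all four stages have
integer resolutions (1/4, 1/8, 1/16, 1/32 of the input). Each stage runs its
Rep blocks on the feature map and then its Swin blocks on the same grid
(the map/token conversion is a flatten/reshape); stages are joined by patch
merging (2x2 neighborhood concatenation, layer norm, linear reduction to the
next width). From stage 2 on, the previous stage's output is aligned and
fused into the current stage, then refined by FRCPA. Stage 1 has no
predecessor and receives neither. Only the serial wiring is implemented;
the parallel and overlapping hooks raise "not implemented" by design. The
exact per-stage depths of the published fused models are never printed, so
the package defines an explicit `"even"` variant
(`rep_depths = (2,2,2,2)`, `swin_depths = (2,2,2,2)`) and a `"tiny"`
desk-scale variant (widths 8/16/32/64, one block of each kind per stage,
32x32 input, window 4); the published ~185M-parameter counts are treated as
non-reproducible context, not targets.

## The ECG pipeline

Records are read from WFDB triplets (header, format-16 or -212 signal, MIT
annotation stream); the reader and writer are implemented in-package since
the environment provides no WFDB codec. Beat symbols map to the five AAMI
classes (N, SVEB, VEB, F, Q) with the EC57 grouping; rhythm and artifact
codes are excluded. Beats are the half-open windows $[r - 0.5s, r + 0.4s)$
around annotated R peaks — 324 samples at 360 Hz — with boundary-crossing
beats dropped and counted, and annotation indices trusted as given (no
re-detection). Indices are 0-based throughout the WFDB layer.

**Baseline wander.** The wander estimate is the coarse approximation of an
*undecimated* (à trous) Daubechies-6 cascade, depth 8 (approximation band
below about 0.7 Hz at 360 Hz), subtracted from the signal; the subtraction is
applied twice. Three choices matter here and were made on measurement:

* *Undecimated, not decimated.* The decimated transform is
  periodically-time-varying; zeroing its approximation leaves an aliased
  residual of a pure 0.2 Hz drift tone of over 20% that no reasonable depth
  removes. The stationary cascade is LTI and zero-phase: the same tone is
  attenuated to below 2% interior residual, and R-peak locations are
  untouched by construction.
* *Depth 8, not 9.* Depth 9 (band edge ~0.35 Hz) leaves most of a
  0.2-0.25 Hz drift in the transition band; depth 7 (band edge ~1.4 Hz)
  swallows the beat-rate fundamental near 1 Hz and demonstrably *worsens*
  beat SNR. Depth 8 is the only depth that both removes slow drift and
  leaves cardiac content intact, and the tests pin both properties.
* *Slope-continuous extension.* Signals are extended by the line through
  their endpoints plus an odd reflection of the residual, which is value-
  and slope-continuous; plain even reflection leaves an edge kink that
  dominates the drift residual.

Two passes square the residual drift gain of the linear operator while
leaving the pass band essentially unchanged.

**Powerline.** A second-order IIR notch at 60 Hz with quality factor 30,
applied forward-backward (zero phase), followed by a centered 5-point moving
average with reflected edges. Measured: better than 80 dB attenuation of a
60 Hz tone, less than 0.1 dB change of a 5 Hz tone. The moving average does
attenuate the upper cardiac band (about 1.5 dB at 40 Hz); it is configurable
(`smooth_width = 1` disables it) and the guarantees the tests assert are the
60 Hz and 5 Hz figures.

**Network input.** How 0.9 s beats become 224x224 inputs is not stated by
the source; the package uses a deterministic representation — resample to
the target side, min-max normalize to $[0,1]$ (constant beats map to 0.5),
tile as identical rows, replicate to 3 channels — rather than rendering
plots, which would drag in font/DPI dependence. Desk-scale training uses
side 32; the default of `beat_to_input()` remains 224, the published input
size.

**Splits.** Stratified by class (the source is silent on stratification, but
beat-wise splitting is implied), deterministic under the recorded seed:
80/20 for supervised runs, 50/40/10
(labeled/unlabeled/validation) for semi-supervised runs, with
largest-remainder allocation so the stated ratios hold within rounding.

## Training and the pseudo-label loop

The objective is mean cross-entropy; the optimizer is Adam (the source
states the learning rate, `1e-4`, but not the optimizer; Adam is the common
pairing at that rate, and the rate plus the optional step schedule —
milestones 80/160/240, factor 0.1 — are configuration fields). Divergence
(non-finite loss) aborts with a diagnostic rather than continuing. Zero
epochs are an explicit no-op.

The semi-supervised protocol trains on the labeled half, then repeatedly:
scores the residual unlabeled pool, accepts items whose maximum softmax
probability *strictly* exceeds 0.95 (raw softmax, no calibration; hard
labels, unit weight), merges them with everything previously accepted plus
the labeled set, retrains, and evaluates on validation. The loop stops when
validation accuracy fails to improve over the previous round (patience of
one round) or a round accepts nothing, and the best-validation checkpoint is
returned — so the returned model is never worse on validation than the
round-1 model. The published folder mechanics (confident items moved between
directories) are realized as index manifests; nothing is moved on disk.

## Synthetic data: what it emulates and what it does not

The beat generator emulates 360 Hz sampling, R-peak-centred 324-sample
windows, class-dependent morphology (sums of 3-5 Gaussian components per
class), additive baseline drift (0.15 mV sinusoid at 0.25 Hz, random phase),
60 Hz interference (0.05 mV) and white noise (0.03 mV), with a 5% per-beat
amplitude jitter. The class distinctions encode clinically *suggestive*
differences only — a widened, high-amplitude R without a P wave for the
VEB-like class, an absent P wave for the SVEB-like class, a pacing spike
plus wide complex for the paced/unknown class — as parameter choices, with
no claim of physiological realism. Classes are balanced by default; the
pathological class imbalance of real ambulatory databases is deliberately
not replicated. Fixture records place beats at a regular 1 s spacing
(windows never overlap) and stay short so tests are fast.

Consequently, a model reaching high accuracy on these beats demonstrates
that the architecture, gradients, pipeline and protocol work end to end —
it says nothing about accuracy on real arrhythmia data, which differs in
noise structure, morphology variability, inter-patient variation and class
imbalance, and which the published headline accuracies refer to.

Denoising efficacy is measured at the record level (denoise the fixture
record, then compare beat windows against the clean reference), which is how
the pipeline operates; on an isolated 0.9 s beat a 0.25 Hz drift term is
spectrally inseparable from beat morphology and no causal-free filter can
be expected to improve every such window.

The image generator writes class-per-directory PNG folders of oriented
sinusoidal gratings with class-specific frequency, angle and blob density —
enough structure that a linear classifier on Fourier features separates
distinct classes, which is what the generic image path needs to be testable.

## Problem sizes and determinism

Desk-scale runs use the `"tiny"` variant (about 252k parameters) at input
side 32: the supervised surrogate trains on 200 synthetic beats per class
(80/20 split, 10 epochs, batch 32, learning rate `1e-3`) and the
semi-supervised run on 80 beats per class (50/40/10, 16 epochs per round,
threshold 0.95). These sizes are the package's documented defaults for its
own verification runs. All generators, splits and training loops are pure
functions of their seeds; the test suite asserts bitwise reproducibility for
generation, preprocessing and checkpoint round-trips.

## Known limitations

* The published headline accuracies on MIT-BIH and the RSSCN7 scene
  benchmark are out of scope: they require the real datasets and long
  training of models whose exact depths are not printed.
* The tensor engine is single-threaded R on BLAS; it is meant for
  correctness and desk-scale experiments, not throughput.
* Shifted windows require grid divisibility after clamping (satisfied by
  all built-in configurations); arbitrary resolutions would need padding
  plus key masking, which is not implemented.
* WFDB support covers the PhysioNet dialect actually needed here: format 16
  and 212 signals, single-segment records, the standard annotation codes.
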