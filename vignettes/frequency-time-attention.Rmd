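---
title: "Self-supervised frequency-time attention for EEG: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-supervised frequency-time attention for EEG: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aftanet)
```

## The model

`aftanet` implements a self-supervised masked-reconstruction Transformer for
multichannel EEG whose blocks combine adaptive spectral filtering with
frequency-gated self-attention.

**Pretext task.** An epoch $X \in \mathbb{R}^{C \times T}$ (microvolts) is cut
into patches $p_{i,j} = X[i,\, jd:(j+1)d]$ of length $d$ samples. A dual-ratio
mask selects `round(0.5 * n_time)` time columns and `round(0.8 * C)` channel
rows; a patch is masked when its row *or* column is selected (union rule), so
the visible context is sparse and the model must infer global spatiotemporal
structure. Unmasked patches are embedded as
$W_p^\top p_{i,j} + b_p + \zeta_i + \pi_j$ (channel embedding $\zeta$,
temporal position $\pi$, both learnable); masked slots carry only
$\zeta_i + \pi_j$ plus a learnable mask token — the signal values are withheld.
Learnable summary tokens are appended to carry sequence-level context.

The encoder sees only unmasked patch tokens plus summary tokens. A predictor
(one cross-attention read over the encoder output followed by a two-layer MLP,
both with residual paths) produces a feature vector per masked slot; an
exponential-moving-average **momentum encoder** run on the fully visible
sequence provides gradient-stopped targets for those slots. The
**reconstructor** (two plain blocks plus a skip connection from its input and
a linear projection to patch length) rebuilds the masked patches from encoder
features and predictor outputs, each re-tagged with its positional identity.

Two losses are summed, $L = L_A + L_R$:

* reconstruction $L_R = \frac{1}{|M|} \sum_{(i,j) \in M} \lVert
  \mathrm{rec}_{i,j} - p_{i,j} \rVert^2$ (squared norm over the $d$ samples,
  averaged over patches), and
* alignment $L_A = \frac{1}{N} \sum_j \lVert \mathrm{pred}_j -
  \mathrm{LN}(\mathrm{menc}_j) \rVert^2$ with parameter-free layer
  normalization of the momentum features. The alignment term is implemented
  with positive sign: a negated norm has no minimizer, so the minimizable
  reading is the only self-consistent one.

**Adaptive frequency filtering (AFFM).** Inside every encoder block the token
sequence $H$ is Fourier-transformed along the token axis, independently per
embedding dimension. Three learnable mechanisms act on the spectrum:

1. *Gains.* $G_{\mathrm{global}}[k] = \sigma(W_{\mathrm{global}}[k])$ over all
   bins and $G_{\mathrm{local}}[k] = \sigma(W_{\mathrm{local}}[k])$ over bins
   above a cutoff fraction of Nyquist (identity below), combined as
   $G = G_{\mathrm{global}} \cdot G_{\mathrm{local}} \in (0,1)$. Gains are
   real and phase-preserving: the sigmoid's output is real, so the natural
   action on a complex spectrum is a magnitude scaling.
2. *Adaptive mask.* Per-bin power $P[k] = |F[k]|^2$ is normalized by the
   median power (plus $\epsilon = 10^{-12}$) and compared against a learnable
   threshold $\theta$. The hard comparison is non-differentiable in $\theta$,
   so training uses the sigmoid relaxation
   $\sigma((P/\mathrm{med} - \theta)/\tau)$ with temperature $\tau = 0.1$,
   and evaluation uses the hard 0/1 mask. The task loss carries a
   $\lambda \theta^2$ regularizer ($\lambda = 10^{-4}$), active whenever the
   soft mask is.
3. *Fusion.* The filtered spectrum is inverse-transformed and blended with the
   block input: $\tilde{x} = \alpha x + (1-\alpha)\hat{x}$, with $\alpha$
   sigmoid-reparameterized (initial 0.5) so it stays in $(0,1)$. At
   $\alpha = 1$ the module is the identity.

Gain weights live on a fixed reference grid of bins spanning normalized
frequency $[0, 0.5]$ and are linearly interpolated to the actual bin count, so
one filter bank serves sequences of different lengths (the online encoder sees
fewer tokens than the momentum encoder).

**Frequency-gated attention.** The filtered sequence enters multi-head
attention where the value rows are scaled by a per-token gate before
aggregation: $A_f = A\,\mathrm{diag}(g)\,V$. A frequency-bin-indexed diagonal
cannot multiply a token-indexed attention matrix directly, so the gate is
derived per token: $g$ is the time-domain energy profile of the filtered
(masked, gain-weighted) signal, normalized to mean 1. Tokens whose content
survives the learned filtering contribute more to the attention output. With
$g \equiv 1$ the block is standard attention. The block output follows the
enhanced-residual wiring
$\mathrm{LayerNorm}(H_{\mathrm{attn}} + \tilde{H} + \mathrm{FC}(H_{\mathrm{attn}}))$
followed by a LayerNorm-wrapped MLP residual stage — a post-norm structure; the
reduction test compares against an independently written plain-attention
reference with the same wiring.

## Numerical choices

* **Stop-gradients.** Two data-dependent quantities are treated as constants
  during backpropagation: the normalized-energy ratio inside the adaptive mask
  (gradients flow to $\theta$ through the soft relaxation and to the input
  through the multiplicative filter path, but not through the power spectrum
  into the mask), and the per-token attention gate. Both choices avoid
  circular second-order paths; every learnable tensor — $W_{\mathrm{global}}$,
  $W_{\mathrm{local}}$, $\theta$, $\alpha$, and all Transformer weights —
  still receives an exact gradient, verified against finite differences in the
  test suite.
* **Gradients by hand.** The package computes all gradients with hand-derived
  reverse-mode formulas in base R matrix code (no autodiff dependency). The
  FFT paths use the adjoint identities of the DFT; correctness is
  finite-difference-tested per layer and for the full block.
* **Optimizer.** Decoupled-weight-decay Adam (betas 0.9/0.999); weight decay
  0.05 applies to matrices only, as is standard. Learning rate: linear warm-up
  to the 5e-4 peak over 15 epochs, cosine decay to zero afterwards, and a
  layer-wise multiplier of 0.65 per level below the output during
  fine-tuning.
* **Masked-count rounding** is round-half-up, giving the exact
  `round(ratio * n)` contract.
* **Degenerate inputs.** All-zero epochs embed and reconstruct without special
  casing; an empty mask gives $L_R = L_A = 0$ with a warning; sequences
  shorter than 2 tokens pass through the AFFM with a warning (their spectrum
  is degenerate); a NaN/Inf loss aborts pretraining with a diagnostic error.

## Preprocessing

The standard recipe — channel selection/reordering by label, zero-phase
band-pass (0.1–75 Hz default; 1–40 Hz variant for pediatric seizure data),
50 Hz notch, polyphase resampling to 200 Hz, non-overlapping fixed-length
epochs (4 s default, longer windows exposed as a parameter), reflection and
scaling augmentation, and majority-class subsampling to a 1:1 balance. The
band-pass is a cascade of 4th-order Butterworth high-pass and low-pass
filters applied forward-backward: a single 8th-order band-pass polynomial
with a 0.1 Hz edge at 200 Hz is numerically marginal, while the cascade is
stable and keeps the zero-phase property that reconstruction targets need.
The notch is an RBJ biquad with Q = 30. Signals are demeaned before the
high-pass so finite-window filtfilt edge transients cannot leak DC. Patches
are non-overlapping by default; patch length is a config key (200 samples at
200 Hz in the full-scale preset).

## Synthetic data: what it emulates, and what it does not

`generate_recording()` mixes a $1/f$ Gaussian background (exponent 1 by
default, the classic EEG-like spectrum) with band-limited components:
sinusoids, band-limited noise, and a spike-wave train (a sharp transient plus
a slow half-wave per cycle at ~3 Hz, the standard absence-seizure surrogate).
`inject_artifacts()` adds 50 Hz line interference and Hann-windowed 20–60 Hz
bursts at a Poisson event rate. All randomness comes from one seeded generator
per call; the global RNG state is restored.

The defaults represent the regimes the pipeline targets: 4 s windows,
background RMS 5 µV, component amplitudes 10–40 µV, and a "separable" preset
whose two classes carry disjoint dominant bands (3 Hz spike-wave vs 10 Hz
alpha) so that a bandpower threshold alone reaches ≥ 95% accuracy — making
end-to-end classification results interpretable. The tests therefore
demonstrate that the implementation learns what is learnable by construction;
they do not show clinical-grade seizure detection. The generator has no head
model, no electrode geometry, no inter-channel propagation, and no
non-stationarity beyond burst events, so transfer to real EEG corpora is
explicitly out of scope.

## Problem sizes in the tests and acceptance script

The shipped runs use the tiny preset: d_model 64, 2 encoder blocks, 4 heads,
32-sample patches on 4-channel, 4 s, 64 Hz epochs (a 4 × 8 patch grid),
batch 8, 150–300 optimizer steps, datasets of 48–256 epochs. These sizes were
chosen so a full pretraining run completes in about two minutes on one CPU
while still exhibiting the qualitative behavior of interest (decreasing
reconstruction loss, better-than-mean reconstruction on predictable signals,
perfect separation of the separable preset). The full-scale preset
(d_model 256, 8 blocks, 200-sample patches, batch 120, 100 epochs) is a
configuration, not an exercised test path.

## Open design points resolved here

* **Mask-slot filling:** the masked positions are represented by a single
  learnable mask token added to $\zeta_i + \pi_j$.
* **Positional encodings** are learnable per-index embeddings (matching the
  learnable channel embeddings and summary tokens); summary tokens receive no
  positional encoding. Four summary tokens by default.
* **Patch overlap:** patches are non-overlapping; the patch length default
  follows the 200-sample convention.
* **Threshold $\theta$** is a scalar per block; each block owns a distinct
  filter bank.
* **Alignment targets** use all masked patch slots of the momentum encoder's
  full-sequence features.
* **Vector-quantization codebook:** some descriptions of this family of
  models mention a 1024-entry codebook, but no dataflow ties it to the
  losses implemented here; it is omitted.

## Known limitations

* Pure-R training loops are practical at the tiny-preset scale only; the
  full-scale preset would need hours, not minutes.
* Multi-class AUROC is deliberately out of interface (AUROC is reported for
  binary tasks; Cohen's kappa monitors multi-class tasks).
* The EDF reader/writer covers the single-record, 16-bit subset this package
  emits, not the full EDF+ standard.
* Artifact rejection (ICA, regression) is not implemented; the filtering
  stack is band-pass + notch only.
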