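---
title: "Group-wise sparse adaptive tensor decoding with prewnpls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-wise sparse adaptive tensor decoding with prewnpls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prewnpls)
```

## The decoding problem

Motor brain-computer interfaces translate multichannel neural recordings
into continuous effector commands at a high decision rate (about 10 Hz).
The features are naturally tensor-structured: each 1-s epoch of a 64-channel
signal sampled at 586 Hz is mapped by a complex Morlet wavelet transform
(10-150 Hz in 10-Hz bands) and temporal averaging into a
temporal-frequency-spatial tensor $X_t \in \mathbb{R}^{10\times 15\times 64}$.
The target is the 3D Cartesian vector from the current effector position to
the active target, and the model is multilinear-affine,

$$ y_t = \langle X_t, \mathrm{Beta} \rangle + \mathrm{bias} + \varepsilon_t. $$

Two constraints shape the estimator. First, training happens *online*
during closed-loop use: data arrive in update blocks of $\Delta L$ samples
and the decoder must be refreshed from sufficient statistics only. Second,
the feature space (9,600 coordinates) is large, noisy and redundant, so a
*group-wise sparse* solution — entire channel slices of `Beta` set exactly
to zero — reduces computation, data transfer and overfitting.

## The adaptive estimator

`rewnpls_init()` / `fit_update()` implement recursive exponentially
weighted N-way PLS. The state consists of the covariance matrices of the
unfolded features,
$XX \leftarrow \mu_1 XX + X^\top X$, $XY \leftarrow \mu_1 XY + X^\top Y$,
exponentially weighted normalization statistics (per-coordinate mean and
standard deviation of the features, mean of the targets, same forgetting
factor $\mu_1$), and the current model family. $\mu_1 = 1$ means no
forgetting, in which case the state is exactly invariant to how the stream
was partitioned into blocks.

At every update the family $\{\mathrm{Beta}^f, \mathrm{bias}^f\}_{f=1}^F$
is re-extracted from $(XX, XY)$ by a kernel-PLS factor loop. For factor
$f$:

1. The deflated cross-covariance (a $D \times J$ matrix) is collapsed to an
   order-3 tensor $V$. With $J > 1$ outputs the leading eigenvector of
   $XY_w^\top XY_w$ picks the output direction first.
2. $V$ is scaled to unit Frobenius norm and decomposed by one rank-1
   PARAFAC step (`parafac1_als()`), giving unit-norm mode projectors
   $w^1, w^2, w^3$.
3. The Kronecker-consistent flattening $w = w^1 \otimes w^2 \otimes w^3$ is
   orthogonalized against previous loadings,
   $r_f = w - \sum_{k<f}(p_k^\top w)\, r_k$. The vector $r_f$ — not $w$ —
   maps the *original* features to the factor score, so the explained
   covariance $c_f = r_f^\top XX\, r_f$, the loadings $p_f = XX r_f / c_f$,
   $q_f = XY_w^\top r_f / c_f$, the deflation
   $XY_w \leftarrow XY_w - c_f\, p_f q_f^\top$ and the coefficient
   accumulation $\mathrm{Beta}^f = \sum_{k \le f} r_k q_k^\top$ all use
   $r_f$. (With $w$ in place of $r_f$ the recursion is subtly wrong: a
   noiseless stream whose features live on $K$ coordinates is then *not*
   fit exactly by $K$ factors, while with $r_f$ it is, to machine
   precision; the test suite pins this property.)
4. Extraction truncates when a factor degenerates (all-penalized projector,
   or explained covariance below $10^{-12}\,\mathrm{tr}(XX)$); later family
   slots repeat the last valid model so the family stays F-indexed.

The working dimension $f^*$ is chosen by recursive validation: each
incoming block is scored against the *previous* family before being
absorbed, $\mathrm{val}_f \leftarrow \mu_1 \mathrm{val}_f + \mathrm{MSE}_f$,
and $f^* = \arg\min_f \mathrm{val}_f$ with ties to the smallest $f$
(parsimony). Validation data is therefore always unseen at scoring time.

## Lp penalization and selective sets

Sparsity enters inside the rank-1 PARAFAC step. Each ALS mode update
separates into scalar problems

$$ \min_w\; a\,(w - u)^2 + \lambda\, g_p(w), \qquad
   a = \|K\|^2,\; u = \text{LS value}, $$

with $g_0(w) = \mathbb{1}\{w \ne 0\}$, $g_1(w) = |w|$,
$g_{1/2}(w) = \sqrt{|w|}$. `scalar_penalized_ls()` returns the *exact*
global minimizer:

* $p = 1$: soft thresholding at $\lambda / (2a)$;
* $p = 0$: hard thresholding — keep $u$ iff $a u^2 > \lambda$ (ties go to
  zero, favouring sparsity);
* $p = 1/2$: zero whenever $|u| \le \tfrac34 (\lambda/a)^{2/3}$; otherwise
  the candidate $\mathrm{sign}(u)\, B |u|$, where $B$ is the largest root in
  $[0,1]$ of $x(1-x)^2 = C$ with $C = \lambda^2/(16 a^2 |u|^3)$, kept only
  if it beats the zero candidate's cost.

Two conventions deserve a note. The thresholds above are the exact
minimizers of the stated costs; published renderings of the hard/soft
thresholds are typographically inconsistent with the costs they accompany,
and the cost function is what defines the method (the $L_{1/2}$ boundary
$\tfrac34(\lambda/a)^{2/3}$ comes out identically under this convention,
which corroborates it). The boundary for $p = 1/2$ is where the cubic root
*exists*; the minimizer's jump to a nonzero value happens at the cost tie
slightly above it. The cubic is solved by bisection on $[1/3, 1]$ to
$10^{-12}$ — unconditionally stable, no complex arithmetic. An independent
grid-search oracle (`scalar_penalized_ls_oracle()`) verifies all three maps
in the tests.

Penalization is *selective*: at each update the sets of penalizable
coordinates start full, and coordinates that received nonzero weight at
factor $f$ are exempt from penalization at factors $> f$
(`update_penalization_sets()`). The sets reset at the next update, so a
channel dropped at one update may re-enter later. A channel absent from
every factor's spatial projector has its entire `Beta` slice exactly zero —
an invariant asserted after every fit in the tests.

### The scale of V and the meaning of lambda

The covariance sums grow with the amount of absorbed data, so the tensor
$V$ fed to the penalized PARAFAC has data-dependent scale, while useful
$\lambda$ values should be $O(1)$. The package therefore scales $V$ to unit
Frobenius norm before each rank-1 extraction. Only the unit-norm projectors
are used downstream, so at $\lambda = 0$ this is a no-op (the unpenalized
path is bitwise unchanged), while under penalization it gives $\lambda$ a
stable meaning across updates and factors: the default grids (0-0.5 in 0.02
steps for $L_{1/2}$ and $L_1$; 0-0.05 in 0.002 steps for $L_0$, whose
threshold scales as $\sqrt{\lambda}$ rather than $\lambda$) then produce
the full range from dense to maximally sparse solutions.

## Defaults and tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `dims` | 10 x 15 x 64 | time-lag x frequency x channel features |
| `J` | 3 | Cartesian outputs |
| `F` | 100 | cap on latent dimensions (family size) |
| `mu1` | 1.0 | forgetting factor; 1 = no forgetting |
| `normalize` | TRUE | running z-scoring of features, centering of targets |
| `als_tol`, `als_max_iter` | 1e-6, 100 | ALS stop rules (projector change) |
| `lambda` | 0 | penalization; 0 = generic unpenalized decoder |
| `fs`, `window`, `step` | 586 Hz, 1 s, 0.1 s | epoching |
| `freqs` | 10-150 Hz, step 10 | Morlet analysis bands |
| `omega0` | 5 | Morlet cycles parameter |

Neither $\mu_1$ nor $\Delta L$ has a canonical published value; the
defaults (no forgetting; blocks as supplied by the caller) are declared,
not inferred. Penalized-cost monotonicity across ALS sweeps is *not*
asserted anywhere: the per-mode renormalization required once penalties fix
the projector scales can break monotone descent, so convergence is judged
on the projector change only. ALS initialization is deterministic (leading
left singular vector of each unfolding), which removes run-to-run
variability; the sign of each projector is fixed so its largest-magnitude
entry is positive.

Numerical edge cases: zero-variance feature coordinates get their scale
clamped to 1; an all-zero mode update flags the factor as degenerate and
truncates the family; predictions before any update are exactly zero (the
decoder is initialized with the zero model).

## The synthetic session generator

`make_ground_truth()` builds a rank-$R$ channel-sparse coefficient tensor:
$\mathrm{Beta} = \sum_r a_r \circ b_r \circ c_r \circ d_r$ with every
channel factor $c_r$ supported on one common random channel subset.
Support loadings have magnitudes in (0.5, 1.5), so every "informative"
channel carries a non-negligible share — a channel with vanishing loading
would be informative in name only. `simulate_session()` draws features as
AR(1)-smoothed Gaussian noise (coefficient 0.9, mimicking the
autocorrelation of overlapping wavelet features) plus a component locked to
piecewise-constant target directions, then computes
$y_t = \langle X_t, \mathrm{Beta}\rangle + \mathrm{bias} + \varepsilon_t$
with the noise variance set from the requested signal-to-noise ratio.
Everything is bit-reproducible given the mandatory seed.
`pursuit_rollout()` closes the loop: a decoder callback moves the effector
with gain 0.05 per 10-Hz step toward targets on cube vertices, and the
position is never reset.

What the generator does *not* emulate: raw ECoG voltages and electrode
geometry, non-stationary drift, user learning, or feedback-dependent neural
adaptation. Passing tests on synthetic sessions therefore demonstrate
algorithmic correctness (recursions, penalization, protocol), not clinical
decoding performance; absolute cosine-similarity levels on real recordings
are far lower than on these idealized streams.

## Evaluation protocol

`pseudo_online_experiment()` replays training blocks strictly in order
through `fit_update()` (no shuffling, no lookahead — the training stream is
consumed before the test stream is opened), freezes the model, and scores
held-out blocks sample by sample. Performance is the per-sample cosine
similarity between predicted and optimal directions, summarized as median
(Q1-Q3) with linear-interpolation quantiles (the quantile convention is a
package choice); zero-norm samples are masked and counted rather than
scored. Compactness is the sparsity index: the percentage of mode slices of
`Beta` that are entirely zero. `lambda_sweep()` runs one experiment per
grid value on shared data; `paired_signed_rank_compare()` wraps the paired
two-sided Wilcoxon signed-rank test (exact null for 25 or fewer non-tied
pairs, normal approximation otherwise) with and without Bonferroni
correction. The unit of pairing is the caller's choice — the function
accepts any paired vectors (per-sample or per-session summaries).

## Problem sizes used in the checks

The packaged tests and the acceptance script run, as the package's own
choice of desk-scale study conditions: full-size (10 x 15 x 64, J = 3)
streams of 600 samples in 6 blocks for the reduction and
partition-invariance checks; 4 x 5 x 64 features with 16 informative
channels, SNR 10, 2,000 training and 1,000 held-out samples for the
sparsity sweeps (26-point grids per penalty, family cap F = 5); and a
4 x 5 x 16, SNR 100 stream of 2,000 training samples for the end-to-end
pipeline. F defaults to 100 in production use but the checks use small
caps, which the recursive validation would also select.

## Known limitations

* Storing $XX$ costs $O(D^2)$ memory (737 MB at $D = 9600$ in doubles);
  this is inherent to the covariance-only formulation.
* The comparison of penalties is protocol-level only; nothing here settles
  which $p$ is preferable on real recordings.
* Penalization interacts with the running normalization: recursive
  z-scoring is order-dependent by construction, so exact block-partition
  invariance holds with normalization disabled.
* Only order-3 feature tensors (plus order-4 observation/coefficient
  arrays) are supported; this is not a general N-way toolkit.

## A worked example

```{r example, eval = FALSE}
dims <- c(4, 5, 64)
gt <- make_ground_truth(dims, J = 3, support_size = 16, rank_true = 3,
                        snr = 10, seed = 1)
ses <- simulate_session(gt, session_spec(3000, 200, dims, J = 3, seed = 2))
sw <- lambda_sweep(ses$blocks[1:10], ses$blocks[11:15], p = 1,
                   dims = dims, J = 3, F = 5)
subset(sw$table, sparsity_percent >= 50)
```
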