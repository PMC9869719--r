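---
title: "Methods: co-completion of drug side-effect and target matrices"
author: "gtmcc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-completion of drug side-effect and target matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtmcc)
```

## The problem

A drug's side effects arise from its interactions with protein targets, but
both records are incomplete: target catalogues miss off-target bindings, and
side effects discovered post-market are absent from label data. Treating
the zeros of the drug × side-effect matrix $Y \in \{0,1\}^{n\times c}$ and
the drug × target matrix $X \in \{0,1\}^{n\times d}$ as negatives is
therefore wrong — they are *unlabelled*. `gtmcc` frames side-effect
prediction as transductive multi-label learning with missing labels *and*
missing features, and solves both imputation problems jointly.

## Model

Assuming $Y$ and $X$ are jointly low rank, the concatenation
$Z = [Y, X]$ is factorized as $Z \approx W^\top H$ with
$W \in \mathbb{R}^{t\times n}$, $H \in \mathbb{R}^{t\times (c+d)}$ and
$t \ll \min(n, c+d)$. The fitted objective is

$$\sum_{(i,j)\in\Omega}
  \bigl[\beta\,\mathbf{1}\{Z_{ij}=1\} + (1-\beta)\,\mathbf{1}\{Z_{ij}=0\}\bigr]
  \,(Z_{ij} - w_i^\top h_j)^2
  \;+\; \gamma\,\mathrm{Tr}(W L W^\top)
  \;+\; \lambda_1\|W\|_F^2 + \lambda_2\|H\|_F^2 .$$

Three modelling devices:

* **Positive-unlabelled weighting.** Only positive associations are ever
  observed, so the squared error on an observed 1 carries weight $\beta$
  and that on an unobserved 0 carries $1-\beta$. With $\beta > 1/2$ the
  model is penalized more for missing a known positive than for scoring an
  unlabelled entry high — the biased matrix-completion treatment of
  one-sided binary data.
* **Graph regularization.** Chemically similar drugs tend to share side
  effects. From the Tanimoto similarity matrix $S$ we keep
  $A_{ij} = S_{ij}$ when $j$ is among the $k$ nearest neighbours of $i$
  *or vice versa* (union symmetrization), zero otherwise, and penalize
  $\gamma\,\mathrm{Tr}(WLW^\top)$ with the **normalized** Laplacian
  $L = D^{-1/2}(D-A)D^{-1/2}$, $D = \mathrm{Diag}(A\mathbf{1})$. The
  familiar identity $\sum_{ij} S_{ij}\|w_i - w_j\|^2 = 2\,\mathrm{Tr}(WLW^\top)$
  holds exactly only for the *unnormalized* Laplacian; we treat it as
  motivation and implement the normalized form, whose spectrum lies in
  $[0,2]$ and which equalizes the influence of high-degree drugs.
* **Transduction.** The mask $\Omega$ contains every entry of $X$ and the
  $Y$-rows of training drugs only. Held-out ("test") drugs keep their
  target columns in the loss but contribute no label; their $Y$ entries are
  zeroed and excluded, not down-weighted. Consequently predictions exist
  only for drugs present at fit time — scoring a genuinely new drug
  requires refitting, which we keep as an explicit contract (no `newdata`
  in `predict()`).

### Tunable parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `t` | latent dimension | 400 | the full-corpus selection; desk-scale synthetic fits here use `t = 20` (about twice the generator's true rank 10) |
| `beta` | weight on observed positives | 0.8 | must lie strictly in (0, 1) |
| `gamma` | graph penalty | 10 | 0 disables the graph |
| `lambda1`, `lambda2` | ridge penalties on W, H | 2, 1 | also guarantee the W-prox system is well posed |
| `k_nn` | neighbours in the similarity graph | 5 | a dataset-shape choice, independent of `t`; exposed because no canonical value exists |
| `max_iters`, `rel_tol` | stopping rule | 500, 1e-6 | relative objective change |

## Optimization

The smooth loss $f(W,H)$ is minimized by proximal alternating linearized
minimization. Per outer iteration:

1. $t_w = 2\max(\beta, 1-\beta)\,\sigma_{\max}(H)^2$, the Lipschitz
   constant of $\nabla_W f$ (every entry weight is bounded by
   $\max(\beta,1-\beta)$, and the per-drug Hessian by
   $2\max(\beta,1-\beta)\,HH^\top$);
   $G = W - \nabla_W f / t_w$; then the closed-form proximal map
   $W \leftarrow t_w\,G\,(2\gamma L + (2\lambda_1 + t_w)I)^{-1}$, computed
   as a linear solve. Inside the fit loop the symmetric matrix
   $2\gamma L + 2\lambda_1 I$ is eigendecomposed once and only its spectrum
   is rescaled as $t_w$ changes, so each iteration costs a dense
   multiply rather than a factorization.
2. $t_h = 2\max(\beta,1-\beta)\,\sigma_{\max}(W)^2$ recomputed from the
   *updated* $W$; $V = H - \nabla_H f / t_h$; then the elementwise
   shrinkage $H \leftarrow t_h V / (2\lambda_2 + t_h)$. (Dimensional
   analysis fixes the gradient step to act on $H$, not $W$.)

With these step sizes the objective is non-increasing; the test suite
asserts monotonicity to a $10^{-8}$ slack at every iteration of twenty
seeded runs. Step sizes are floored at $10^{-8}$ so an all-zero factor
block cannot produce a division by zero, and they are recomputed every
outer iteration because the factors' spectral norms change as the fit
progresses. An optional `backtrack` flag re-does a block update with a
doubled $t$ whenever an update would increase the objective — a pure
robustness guard that never fires under the exact Lipschitz constants.
Initialization is i.i.d. Gaussian with standard deviation $1/\sqrt{t}$
(initial scores $O(1)$), drawn from a mandatory seed: two fits with the
same seed are bit-identical.

Degenerate inputs: isolated drugs in the kNN graph get zero Laplacian
rows/columns ($0^{-1/2}\equiv 0$) and are simply unregularized; two
all-zero fingerprints get Tanimoto similarity 0 rather than NaN; ties at
the kNN boundary are broken by ascending drug index so graphs are
platform-independent.

## Evaluation protocols and metrics

* **Local CV** (cold start): drugs are partitioned into folds; a fold's
  drugs become transductive test rows with *all* labels masked. All five
  metrics are computed on the held-out block.
* **Global CV**: the known (drug, side-effect) *pairs* are partitioned;
  a fold's pairs are zeroed during fitting — the model has no third state,
  so masked positives are simply unobserved zeros with weight $1-\beta$ —
  and then scored against an equal number of unobserved entries sampled
  uniformly (negative:positive ratio 1). Only AUC and AP apply.
* **Target CV**: the same pair protocol on the $X$ block, training with
  the full $Y$.

Metric conventions, fixed explicitly because tie handling varies between
libraries: AUC is the Mann–Whitney statistic with half credit for ties;
AP is $\sum_k (R_k - R_{k-1}) P_k$ over distinct decreasing score
thresholds; a label's rank is the number of labels scored at or above it
(ranks start at 1, so coverage error lies in $[1, c]$ and equals the mean
per-drug positive count under a perfect ranking); ranking loss counts
(true, false) pairs ordered incorrectly with ties again worth one half,
which makes a row's ranking loss exactly $1 - \mathrm{AUC}$ of that row.
Rows without any true label are skipped for LRAP/coverage (undefined
there) and counted; rows without any false label are likewise skipped for
ranking loss. Every metric implementation is tested against literal
pairwise/rank enumeration on hundreds of random instances, and AUC
additionally against an independent ROC package.

Repeat $r$ of a CV experiment derives its seed as `seed + r - 1`, so any
single repeat is reproducible in isolation.

## The synthetic-data generator

`synthetic_scenario()` draws Gaussian factors $W^\*, H^\*$ of a chosen true
rank, thresholds $W^{*\top}H^*$ at the quantile giving an exact requested
positive density (quantile thresholding was chosen over logistic sampling
precisely for that exact density control), and derives the similarity
matrix from the cosine similarity of the $W^*$ columns mapped to $[0,1]$ —
so "chemically similar drugs share latent structure" holds *by
construction*, with a `similarity_noise` knob to degrade it. The
positive-unlabelled mask then reveals each true positive independently
with probability `observe_frac`, never flipping zeros; hidden positives
are recorded as evaluation ground truth. All randomness flows from the
scenario seed through fixed offsets (seed for factors, seed + 1 for
similarity noise, seed + 2 for masking).

`paper_shape_scenario()` is the desk-scale default used throughout the
tests and the acceptance script: $n = 120$ drugs, $c = 200$ side effects,
$d = 100$ targets, true rank 10, positive density 0.06 (so ~94 % of the
side-effect block is zero, the sparsity order of real side-effect data),
`observe_frac = 0.5`, noise-free similarity. These sizes keep a full fit
under a second while leaving ~1100 hidden positives for evaluation; the
fits on this scenario use $t = 20$.

What the generator does *not* emulate: real substructure fingerprints and
their correlated bit patterns, side-effect ontology structure, the
heavy-tailed degree distributions of real association data, and
non-low-rank signal. Passing recovery tests on this generator therefore
demonstrates that the estimator recovers planted jointly-low-rank PU
structure and that the graph term helps when its assumption holds — not
that any particular performance level transfers to a real corpus.

```{r recovery}
sim <- simulate_dataset(paper_shape_scenario(seed = 1))
fit <- gtmcc(sim$Y, sim$X, sim$S, hyper = gtmcc_hyper(t = 20), seed = 1)
heldout_positive_auc(fit, sim, "side_effects")
heldout_positive_auc(fit, sim, "targets")
```

## Design choices made where the design was open

* **kNN symmetrization by union**, not mutual kNN: mutual kNN can
  disconnect outlier drugs, silencing the regularizer exactly where side
  information is most needed.
* **`k_nn` default 5**: no canonical neighbour count exists for this graph
  (it is unrelated to the latent dimension); 5 is the conventional small
  default and is exposed as configuration.
* **Masked positives in global CV are trained as weight-$(1-\beta)$
  zeros** rather than removed from $\Omega$: the model has only two entry
  states, and this is the natural consequence of the PU loss.
* **Coverage error uses 1-based ranks** (affects values by a constant 1
  versus a 0-based convention).
* **Dense computation throughout**: at both the real corpus scale
  (~10³ × 10⁴) and desk scale the weighted residual fits comfortably in
  memory, so no sparse-residual machinery is used.
* **Model archive as a single JSON document** (full-precision doubles):
  portable, diffable, loadable for prediction without refitting.

## Known limitations

* Transductive only: new drugs require refitting the whole model.
* The target space is the known target universe; associations through
  proteins absent from $X$ cannot be recovered.
* The factorization is non-convex; different seeds reach different local
  minima (the monotone objective and seeded initialization make each run
  reproducible, not globally optimal).
* Latent factors are not directly interpretable as target–side-effect
  mechanisms.
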