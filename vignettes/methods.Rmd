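---
title: "Methods: gated mixtures of GP experts for microbiome-metabolome prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gated mixtures of GP experts for microbiome-metabolome prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moegpr)
```

This vignette is the package's own account of the statistics it implements:
the model and its assumptions, the defaults and why they were chosen, what
the synthetic data generator does and does not emulate, and the numerical
decisions a maintainer would want written down.

## Model

Let $x \in \mathbb{R}^d$ be a sample's CLR-transformed microbial profile and
$y \in \mathbb{R}^m$ its (CLR-transformed) metabolite profile. The model is
a finite mixture over $L$ experts,

$$ y \mid x \;\sim\; \sum_{l=1}^{L} w_l(x;\psi)\,
   \mathcal{N}\!\bigl(y \mid f_l(x), \sigma_l^2(x)\,I\bigr), $$

where each expert $f_l$ is an exact Gaussian-process regression and the
weights $w_l$ come from a small feed-forward network with a softmax output.

**Experts.** Each expert uses a zero mean function and the
squared-exponential ARD kernel
$k(x,x') = \sigma^2 \exp\{-\tfrac12 \sum_i (x_i-x'_i)^2 / l_i^2\}$, plus
observation noise $\sigma_s^2$. Outputs (metabolites) are modelled as
conditionally independent given a *shared* kernel: hyperparameters minimise
the negative log marginal likelihood summed over output columns. This is a
deliberate choice — it yields exactly one length-scale vector per expert,
which is what the ARD interpretability layer ranks; cross-output covariance
modelling (LMC/ICM-style) is out of scope. Posterior means are per-output,
the posterior variance is shared across outputs and broadcast.

**Assumptions worth stating.** (i) Smooth, stationary taxa→metabolite maps
within a phenotype group; (ii) homoscedastic Gaussian noise on the CLR
scale; (iii) the phenotype structure is recoverable from the microbial
profile — the gating network can only route what is, in principle,
classifiable.

**Gating.** The network is $d \to 128 \to 64 \to L$ with ReLU activations,
dropout after the last hidden layer, and a max-subtracted softmax.
Evaluation-mode forward passes are pure functions; dropout only acts during
training. With all-zero weights the output is uniform $1/L$, and $L = 1$
degenerates to a single GP.

**Prediction.** Experts' Gaussian predictions are combined by moment
matching, $\mu = \sum_l w_l f_l$ and
$\sigma^2 = \sum_l w_l(\sigma_l^2 + (f_l - \mu)^2)$. The second term means
expert disagreement widens the interval — the mixture can be *less*
confident than any single expert, which is exactly the behaviour wanted
near a phenotype boundary. $\mu \pm 2\sigma$ is reported as the 95%
credible band, and the expert predictive variance entering the formula
includes observation noise, since the band is compared against observed
values.

## Training procedure

Training is two-phase by default:

1. **Experts** are fitted on their allocation blocks (one block per
   phenotype label by default) by L-BFGS on the summed NLML in
   log-parameter space, with analytic gradients. L-BFGS was preferred over
   Adam as the default for the experts because at the block sizes this
   package targets (tens to a few hundred samples) it reaches a minimum in
   far fewer NLML evaluations and is deterministic; Adam (learning rate
   0.01, decay 0.95 every 500 steps — the same schedule as the gating) is
   available via `gp_optimizer = "adam"`.
2. **Gating** is trained on all training samples by Adam (initial learning
   rate 0.01, exponential decay by 0.95 every 500 steps, full batch up to
   512 samples, else minibatches of 64) minimising the mixture negative
   log-likelihood with the experts frozen. A supervised variant
   (cross-entropy against the allocation labels) exists for comparison.

Two refinements matter in practice and deserve their rationale:

* **Leave-one-out gating targets.** The per-expert densities
  $\log \mathcal{N}(y_i \mid f_l(x_i), \sigma_l^2(x_i))$ that define the
  gating loss are, for samples inside expert $l$'s own training block,
  computed from the expert's *leave-one-out* predictive distribution
  ($\mu_i = y_i - \alpha_i / [A^{-1}]_{ii}$,
  $v_i = 1/[A^{-1}]_{ii}$, closed form from the cached factorisation).
  In-sample posteriors interpolate their own training points, so without
  this the gating targets collapse to overconfident hard labels that carry
  no information about how soft the phenotype boundary actually is.
* **Validation-based early stopping.** The gating optimiser monitors an
  evaluation-mode loss on a held-out 20% split of the training samples
  (`val_frac`; set 0 to monitor the training loss) and restores the best
  parameters seen. A 128/64-unit network on a few dozen samples will
  otherwise memorise its routing targets.

An optional end-to-end refinement (`joint_rounds > 0`) alternates
hard re-assignment of training samples to their highest-responsibility
expert, expert refits, and gating retraining; it is off by default because
the two-phase path is deterministic, testable, and already realises the
allocation structure.

Numerical-failure policy: a non-finite gating loss halves the learning rate
and retries the step (three attempts, then error); GP factorisations
escalate diagonal jitter from $10^{-6}\sigma^2$ by factors of 10 up to
$10^{-2}\sigma^2$ before failing.

## Tunable parameters

| parameter | default | notes |
|---|---|---|
| `max_zero_fraction` | 0.5 | features with *more* than 50% zeros are removed (exactly 50% is kept) |
| zero replacement | half-min | half the feature's smallest positive value; scale-aware; fixed ε available |
| CLR | natural log, both tables | log base only shifts units; rank metrics are unaffected; `which = "microbial"` restricts |
| `hidden` | (128, 64) | gating architecture |
| `dropout_rate` | 0.2 | unspecified upstream; mild regularisation for 64–128-unit layers on small-n data; applied after the last hidden layer only |
| `lr`, decay | 0.01, ×0.95 / 500 steps | gating (and optional expert-Adam) schedule |
| `gating_steps`, `patience` | 2000, 200 | with validation-split early stopping |
| `gp_maxit` | 100 | L-BFGS iterations per expert |
| jitter | 1e-6·σ² → 1e-2·σ² | escalate ×10 on factorisation failure |
| `sparse` | off; auto over 2000 samples/block | collapsed variational bound, k-means inducing points (128), validated against exact inference on small data |
| folds | 5, label-stratified | filter/zero-replacement statistics are fitted on the training fold only; CLR is per-sample and leaks nothing |

Expert hyperparameter initialisation: $\sigma^2 = 1$, $\sigma_s^2 = 0.1$,
$l_i$ = median pairwise distance in dimension $i$ (subsampled above 200
points; falls back to the dimension's SD, then 1, if degenerate).

Deterministic tie-breaks: ARD rankings sort by descending inverse length
scale with ties broken lexicographically by feature name; undefined Spearman
correlations (constant vectors) are returned as `NA`, excluded from means,
and counted in a diagnostics field.

## The synthetic generator

`generate_paired()` emulates the structure of curated paired cohorts:

* taxa: Gaussian log-abundances around group-specific means, exponentiated,
  Bernoulli zero-masked, and closed to relative abundances. A fifth of the
  non-causal taxa get an elevated zero probability so the ≥50% filter has
  genuine work to do; the overall zero fraction matches `zero_inflation`.
* metabolites: a group-specific map (linear, sinusoidal, or a draw from an
  SE-ARD GP with short length scales on the causal dimensions) applied to
  the CLR of a small causal taxon set, plus Gaussian noise. With
  `metabolite_scale = "latent"` the latent values are used directly, which
  makes the GP expert *exactly* well-specified — that preset backs the
  credible-interval coverage checks.

**The heterogeneous preset** (two groups of 60, d = 20, disjoint causal
sets of 3, sinusoidal maps with opposite sign, group-mean shift 0.6,
noise SD 0.2) was designed so that both defining features of the problem
are actually present: the phenotype must be *learnable* from the microbial
profile (at much smaller shifts even logistic regression routes at chance —
closure and CLR dilute per-taxon mean shifts substantially), and the
taxa→metabolite map must be *heterogeneous enough that one stationary GP
cannot absorb it* (with linear opposing maps a pooled GP largely can, by
exploiting the group separation that the kernel sees). A sign-flipped
smooth nonlinear response on disjoint causal sets is the cleanest
embodiment of "same niche, opposite metabolic consequence".

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: phylogenetic correlation between taxa,
sequencing-depth artefacts, batch effects, non-Gaussian metabolite noise,
and label noise. Results on the fixtures demonstrate correctness of the
machinery and the qualitative value of phenotype-allocated experts under
heterogeneity, not field performance on any particular cohort.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` run entirely on generated data:
ARD recovery uses 150 samples × 30 taxa with 3 causal taxa (20 seeds in the
suite, 10 in the script); the allocation comparison uses the heterogeneous
preset with a single stratified 80/20 split per seed (10 seeds in the
suite, 6 in the script) and 500 gating steps; calibration uses 160 samples
with a 4-fold split; oracle-equivalence checks use 50 random problems up to
n = 50, d = 10. These sizes were chosen to make each statistical claim
testable with comfortable margins while keeping any single check in the
tens of seconds.

## Known limitations

* Independent outputs per expert: correlations between metabolites are not
  modelled, only shared relevance structure.
* Exact inference is cubic in block size; the variational path trades
  accuracy for scalability and optimises its bound with numerical
  gradients, so it is slower per iteration and intended as an option, not
  the default.
* The gating network needs enough samples to learn a boundary; with tiny
  phenotype groups (the allocation warns below 5 samples) the mixture
  degrades toward whichever expert generalises best.
* "Double" allocation halves already-small blocks and is included as an
  ablation, not a recommendation.
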