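---
title: "PSSM texture descriptors and the Discriminative Vector Machine: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PSSM texture descriptors and the Discriminative Vector Machine: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppidvm)
```

## The problem

Experimental maps of protein–protein interactions are incomplete and
noisy, and many computational predictors require structural models or
curated annotations that are unavailable for most proteins. A purely
sequence-based route is to encode each protein by its PSI-BLAST
position-specific scoring matrix (PSSM) — an L × 20 table of per-position
log-odds substitution scores that summarises the protein's evolutionary
conservation — and to learn interaction labels from features of the two
partners' PSSMs. `ppidvm` implements one such pipeline: a local texture
descriptor of the PSSM (the improved Weber Local Descriptor, IWLD), PCA
reduction of concatenated pair features, and a robust per-query
classifier (the Discriminative Vector Machine, DVM), evaluated under
stratified cross-validation.

## The IWLD descriptor

The PSSM is read as a grey-level image whose rows are sequence
positions. Two fields are computed per cell.

**Differential excitation.** Weber's law motivates measuring local
change *relative to* the local intensity. For cell $x_i$ with the eight
neighbours $x_j$ of its 3×3 ring,

$$\xi(x_i) = \arctan\!\Big(\sum_{j=0}^{7}\frac{x_j - x_i}{x_i}\Big)
\in [-\pi/2, \pi/2].$$

**Orientation.** The gradient direction from horizontal and vertical
3×3 Sobel responses $v^{10}, v^{11}$,

$$\gamma(x_i) = \operatorname{atan2}(v^{11}, v^{10}) + \pi \in [0, 2\pi),$$

using all eight neighbours, which both preserves orientation detail and
damps single-cell noise relative to a 4-neighbour gradient.

$\xi$ is quantised into $M$ equal bins of $[-\pi/2,\pi/2]$ (bin $m$
spans $[(m/M - 1/2)\pi,\ ((m+1)/M - 1/2)\pi)$), $\gamma$ to the nearest
of $T$ dominant orientations $2\pi t/T$ with wraparound. The matrix is
split into $V\times H$ contiguous blocks, a joint $M\times T$ count
histogram is accumulated per block, and the flattened block histograms
are concatenated. At the defaults $M = T = 8$, $V = H = 2$ the
descriptor has $8\cdot 8\cdot 2\cdot 2 = 256$ entries, a pair feature
$512$; PCA then keeps `n_comp = 200` components. These defaults follow
the operating point established for this method family by grid search on
real interaction datasets; they are exposed through `iwld_params()` but
there is rarely a reason to move them.

### Numerical choices

- **Intensity scaling.** PSSM scores are integers in roughly
  $[-16, 13]$ and can be zero or negative, while the excitation
  denominator needs positive intensities. Scores are therefore passed
  through the logistic map $1/(1+e^{-s})$ into $(0,1)$, which preserves
  order and keeps the ratio well defined; `epsilon = 1e-8` remains as a
  residual guard, and `iwld_params(scale = FALSE)` runs raw scores with
  the guard only, for users who want the undistorted ratio semantics.
- **Borders.** Replicate padding gives every cell, including the edges
  of the 20-wide matrix, a full 3×3 neighbourhood, so the histogram mass
  is exactly $L \cdot 20$ — a conservation law the tests exploit. This
  also sets the minimum protein length to $L \ge 2$.
- **Flat regions.** Both Sobel responses vanish on constant
  neighbourhoods; `atan2(0, 0)` is taken as 0, so flat texture maps
  deterministically to $\gamma = \pi$ (and $\xi = 0$, excitation bin
  $m = M/2$).
- **Binning edges.** The top excitation bin is closed at $\pi/2$; the
  orientation assignment wraps ($\gamma \to 2\pi$ maps to $t = 0$).
  Block row/column bands have size $\lfloor \dim/\text{bands}\rfloor$
  with remainder cells joining the last band; blocks are concatenated
  row-band-major. These conventions are arbitrary but fixed, for
  bit-reproducibility.
- **Counts, not frequencies.** Descriptors default to raw counts, which
  keep the conservation invariant testable; per-block L1 normalisation
  is available (`normalize = TRUE`) when proteins of very different
  lengths are mixed and length itself should not act as a feature.

## The DVM classifier

For a query $\mathbf{y}$, the $k$ nearest training samples (Euclidean
distance, ties by training index) form the dictionary
$X_k \in \mathbb{R}^{d\times k}$, columns = neighbours. The coefficient
vector $\beta$ minimises

$$\delta\|\beta\|_2^2 + \sum_{i=1}^{d}\phi\big((\mathbf{y}-X_k\beta)_i\big)
 + \gamma\sum_{p,q} w_{pq}(\beta_p-\beta_q)^2,$$

with the Welsch M-estimator $\phi(x) = \tfrac12(1-e^{-x^2})$, whose
influence function decays for gross residuals, and neighbour
similarities $w_{pq}$ forming the graph Laplacian $L = D - W$. Setting
$P = \mathrm{diag}(p_i)$, $p_i = e^{-r_i^2/\sigma^2}$,
$\sigma^2 = \theta\, \mathbf{r}^\top\mathbf{r}/d$ for the current
residual $\mathbf{r} = \mathbf{y}-X_k\beta$, the inner problem is the
weighted, doubly regularised least squares with closed-form solution

$$\beta = (X_k^\top P X_k + \delta I + \gamma L)^{-1} X_k^\top P\,\mathbf{y}.$$

Prediction computes one residual per class from that class's neighbour
columns only, $R_i = \|\mathbf{y} - X_{k,i}\beta_{k,i}\|_2$, and takes
the argmin. Defaults $\delta = 10^{-3}$, $\gamma = 10^{-4}$,
$\theta = 1$; the classifier is insensitive to these within sensible
ranges, which is part of its appeal.

### Design decisions

- **Dimensions.** The weight matrix $P$ is $d\times d$ (one Welsch
  weight per *feature* dimension) and $\beta$ has one entry per
  neighbour; this is the only orientation under which the weight
  formula (indexed $i = 1..d$) and the kernel size (divided by $d$) are
  consistent.
- **Iteration.** $P$ depends on $\beta$, so the closed form is embedded
  in half-quadratic refinement: initialise $P = I$, alternate solve and
  weight update until $\|\Delta\beta\|_\infty < 10^{-6}$ or 50
  iterations. Each solve exactly minimises its fixed-$P$ objective, so
  that objective cannot increase within an iteration — the property the
  test suite asserts. (The kernel size $\sigma$ is re-estimated from
  the current residual each iteration, so a single global Lyapunov
  function for the whole alternation is not available; in practice the
  loop converges in a handful of iterations.)
  `dvm_params(single_step = TRUE)` gives the literal one-shot solve.
- **Neighbourhood size.** $k$ is not dictated by the method; the
  default `k = min(n_train, 40)` keeps both classes represented with
  high probability at the dataset scales this package targets while
  keeping the $k\times k$ solve cheap. It is exposed in `dvm_params()`.
- **Similarities.** $w_{pq}$ is the cosine *similarity* of neighbours
  clipped to $[0,1]$ (diagonal 1; zero-norm rows get 0). A Laplacian
  smoothness penalty needs nonnegative weights with "large = similar":
  using a literal cosine *distance* would pull apart the coefficients
  of similar neighbours, inverting the regulariser's meaning.
- **Degenerate cases.** A class absent from the neighbourhood receives
  the empty-dictionary residual $R_i = \|\mathbf{y}\|_2$; zero residual
  sets all Welsch weights to 1; argmin ties break toward the smaller
  class id. All three keep prediction total and deterministic.

## Pipeline and evaluation

`cross_validate()` runs stratified 5-fold CV (within each class,
shuffled indices are dealt round-robin). Per fold: PCA is fitted on the
training rows only — fitting it on all rows is a transductive leakage,
available explicitly as `pca_global = TRUE` for comparison — then the
DVM (or the SVM baseline) is trained and evaluated. `n_comp` is capped
at $\min(n_{\text{train}}-1, d)$ with a message, since 200 components
need at least 201 training rows. Metrics are accuracy, sensitivity,
precision and MCC from the confusion matrix (interacting = positive),
with undefined ratios reported as 0 with a warning, plus trapezoidal
ROC-AUC, which equals the rank statistic with ties counted one half.
The DVM's ROC score is the scale-free residual margin
$(R_{\text{neg}}-R_{\text{pos}})/(R_{\text{neg}}+R_{\text{pos}})$,
positive when the interacting class reconstructs the query better.
Fold dispersion is reported as the sample (n−1) standard deviation.
"Five-fold" is read as one stratified partition evaluated on all five
folds; `repeats` re-partitions independently and pools.

The SVM baseline is `e1071::svm` (LIBSVM) with a Gaussian kernel at
$C = 0.6$, kernel width $\gamma = 0.01$, on the same folds and PCA
features, with LIBSVM's standard per-feature standardisation — at these
tuned values the RBF kernel degenerates on unstandardised raw-count
features. `cross_species_eval()` implements the transfer protocol: fit
PCA and DVM on one full dataset, evaluate on an independent one.

## The synthetic data generator

Real PSSMs require a PSI-BLAST search against a large sequence
database; the generator instead emulates their *shape and texture*:
integer scores, clipped to $[-16, 13]$, with i.i.d. Gaussian background
noise of sd 4 — the typical spread of log-odds columns. Three regimes
differ in local-gradient statistics, the quantity IWLD measures:
`smooth` (moving-average-correlated field), `rough` (i.i.d. noise) and
`motif` (a square-wave row stripe of period 4). In
`synth_pair_dataset()`, signal-regime proteins carry a stripe of
amplitude $2\cdot\text{effect}$ score units on top of the background;
interacting pairs join two signal proteins, non-interacting pairs one
signal and one background protein in random order. At `effect = 0` the
regimes coincide and labels are independent of all features, giving an
exact chance-level null; the planted contrast grows monotonically with
`effect`, and at `effect = 3` (stripe ±6 against noise sd 4) the
classes are cleanly separable — the regime used as the "strong signal"
study condition.

What the generator does **not** emulate: amino-acid compositional
structure, the column correlations of real substitution profiles,
protein-family clustering, hub proteins appearing in many pairs, or
negative sampling by subcellular localisation. Passing tests on
synthetic data therefore demonstrate that the descriptor measures
local PSSM texture and that the classifier recovers a texture-coded
pair signal at the stated operating point — not that any particular
accuracy will transfer to real interaction data.

## Problem sizes

The test suite and the acceptance script run the full pipeline on
400-pair datasets (800 proteins of 30–80 residues) for the signal and
null conditions, 210 pairs for the PCA-width check, and small randomly
generated instances ($k \le 6$, $d \le 8$, 20 repetitions) for the
solver-versus-numerical-minimiser comparisons; these sizes give stable
statistics while keeping a full run in tens of seconds on one core.
Every stochastic step — generation, fold assignment, random instances —
is driven by an explicit seed, and identical seeds give bit-identical
results.

## Known limitations

- PSSM production itself (PSI-BLAST database, iterations, E-value) is
  out of scope; the parser accepts any standard ASCII PSSM and the
  choice of search settings is the user's.
- The logistic intensity scaling is this package's choice for making
  the Weber ratio well defined on signed scores; other monotone
  positive maps would give quantitatively different (not obviously
  worse) descriptors.
- DVM prediction is $O(n_{\text{train}})$ per query for the neighbour
  search plus an iterated $k\times k$ solve; no indexing structure is
  provided, so very large training sets are slow.
- Redundancy filtering of near-identical sequences (e.g. CD-HIT at 40%
  identity) is a dataset-curation step left to the user; the CLI's
  `--min-length` filter covers only the short-fragment rule.
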