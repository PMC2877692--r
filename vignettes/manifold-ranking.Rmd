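---
title: "Ranking candidate blood-secretory proteins by manifold ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking candidate blood-secretory proteins by manifold ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secrank)
library(ggplot2)
```

## The problem

Serum biomarker discovery needs to know which tissue-expressed proteins can
end up in blood. Experimentally validated blood-secretory proteins are few
(hundreds), while the candidate pool is the whole proteome (tens of
thousands), and there is no clean negative set: a protein not known to be
secreted may simply be unstudied. This is a *positive-unlabeled* (PU)
problem, and secrank treats it as **ranking**, not classification: given a
small set of known positives (the *queries*) and a large unlabeled
background, score every protein by its relevance to the queries and return
the top of the list for experimental follow-up.

Each protein is a fixed-length numeric feature vector (physicochemical and
sequence-derived descriptors; 85 dimensions in the motivating screen). The
features themselves are taken as given — computing them is out of scope.

## The model

All samples (queries and background together) become nodes of a weighted
graph. With Euclidean feature distances $d_{ij}$ and a bandwidth $\sigma$,

$$W_{ij} = \exp\!\left(-\frac{d_{ij}^2}{2\sigma^2}\right), \qquad W_{ii}=0 ,$$

and the symmetrically normalised operator is
$L = D^{-1/2} W D^{-1/2}$ with $D_{ii} = \sum_j W_{ij}$. Evidence
propagates from the queries by

$$f^{(t+1)} = \alpha\, L f^{(t)} + (1-\alpha)\, y ,$$

where $y_i = 1$ for queries and 0 otherwise, and $\alpha \in [0,1)$ sets
how much the graph structure (versus the raw query indicator) shapes the
result. Because the spectral radius of $L$ is at most 1, the iteration
contracts geometrically with ratio $\alpha$ and converges to

$$f^\ast = (1-\alpha)\,(I-\alpha L)^{-1} y ,$$

which `rank_closed_form()` computes with a single linear solve (the
default path; `rank_iterative()` exists for verification and very large
problems). The $(1-\alpha)$ factor is a positive scale that cannot change
the ordering; it is kept so the two solvers agree numerically. Samples are
ranked by decreasing $f^\ast$; queries float to the top and are excluded
from evaluation.

When trusted negatives exist, the *universal* variant propagates a second
vector $y^-$ ($-1$ at known negatives) through the same operator and
returns $f^\ast = A(y^+ + \gamma y^-)$ with $A = (1-\alpha)(I-\alpha L)^{-1}$
and $\gamma \in (0,1]$ damping the negatives: being far from positives is
evidence against secretion, but being far from negatives means little, so
negative evidence must weigh less. $\gamma = 0$ is accepted as the
degenerate input that reproduces the positive-only ranking bitwise.

## Parameters that matter

* **$\alpha$** (propagation strength, default 0.5). Selected by
  query-level cross-validation (`tune_alpha()`): the positives are split
  into folds, each fold plays the queries while the remaining positives
  are the held-out truth, and the grid value (0.1–0.9, step 0.1) with the
  highest mean recall-precision AUC wins, ties to the smaller value.
  Values at or above 1 are clamped to $1-10^{-6}$ with a warning, since
  the closed form needs $\alpha<1$.
* **$\sigma$** (kernel bandwidth, feature-space distance units). Default:
  the mean of all $n(n-1)/2$ pairwise distances of the dataset being
  ranked. Duplicated points shrink it (their zero distances enter the
  mean) — a documented consequence of the definition, not a bug. It is
  sometimes claimed that normalisation makes the ranking insensitive to
  $\sigma$; this is not true in general (the kernel is nonlinear in
  $\sigma$), so $\sigma$ is exposed as an override and treated as a real
  tuning knob. After prefiltering, $\sigma$ is recomputed on the retained
  subset, because the heuristic is defined on the dataset actually being
  ranked.
* **$\gamma$** (negative damping, universal mode, default 0.5). Only the
  admissible interval (0,1] is dictated by the model; the midpoint is the
  package default and it is exposed everywhere.
* **$b$** (sparsifier degree budget, default `max(5, ceil(log2 n))`). See
  below.
* **$k$** (prefilter budget, default 0). See below.
* Convergence controls: `tol = 1e-9`, `max_iter = 10000` for the
  iterative solver; hitting the cap flags the result and warns, never
  silently.

## Graph sparsification by b-matching

Most edges of the dense Gaussian graph carry no ranking information and
some carry noise. secrank can replace the dense graph with a
maximum-weight **b-matching**: a binary symmetric pattern $P$ ($P_{ii}=0$)
with *exactly* $b$ edges per node maximising $\sum_{ij} W_{ij}P_{ij}$,
after which $W' = W \odot P$ (retained edges keep their kernel weight).
Feasibility requires $b \le n-1$ and $nb$ even. Exact degree (rather than
an upper bound) was chosen because it is the canonical problem solved by
the max-product solver below and it guarantees no node is orphaned by
sparsification.

The solver iterates damped synchronous max-product messages
($m_{i\to j} = -\,b\text{-th largest of } \{W_{ik}+m_{k\to i}\}_{k\ne i,j}$,
damping 0.5, tolerance $10^{-6}$, cap 1000 iterations; the inner loop is
compiled code), then selects edges where both endpoints place each other
in their top-$b$ beliefs. Two safety nets make the result a valid
b-matching in all cases: a deterministic greedy/repair completion on the
beliefs when mutual selection is not exactly b-regular, and a
degree-preserving local polish — best-gain 4-cycle exchanges at any size,
plus an alternating-closed-walk search (depth 8, first improvement) on
instances up to 16 nodes. Max-product is only guaranteed to reach the
optimum when the linear relaxation is tight; on small instances where it
stalls (fractional optima do occur), the walk search closes the gap: in
testing against the exhaustive oracle (`bmatching_oracle()`, itself
limited to $n \le 10$ with lexicographic tie-breaking) the solver attained
the exact optimum on every seeded instance tried.

Sparsification is optional and the pipeline runs dense by default, but on
high-dimensional data it is often the difference between a mediocre and a
near-perfect ranking — see "What the synthetic experiments show" below.

## Prefiltering

Propagation costs $O(n^3)$, so for large candidate pools
`filter_bottom_k()` removes the $k$ unlabeled samples farthest from the
query set (by nearest-query Euclidean distance) before the graph is
built. Positives are never dropped; known negatives are protected by
default. Ties break by input row order, making the filter deterministic.
On separable data this barely moves the ranking of what remains: the
dropped samples are precisely those that would have received (and
contributed) the least evidence.

## Evaluation

`pr_curve()` sweeps the descending-score order of the evaluated
(non-query) samples and reports precision $TP/(TP+FP)$ against recall
$TP/(TP+FN)$ at every prefix; the area is computed as **average
precision** — the mean of the precision at each true positive's rank —
i.e. step integration with no interpolation, matching the pointwise
definition of the curve. Queries are always excluded: the protocol
measures retrieval of *held-out* positives.

One calibration subtlety: the average precision of a uniformly random
ranking is not exactly the prevalence $P/n$ at finite $n$. Conditioning
on a random positive at rank $r$ (uniform on $1..n$), the expected count
of positives at or above it is $1 + (P-1)(r-1)/(n-1)$, giving

$$\mathbb{E}[\mathrm{AP}] \;=\; \frac{1}{n}\left[H_n + \frac{P-1}{n-1}\,(n-H_n)\right]
 \;\xrightarrow{\;n\to\infty\;}\; \frac{P}{n},$$

with $H_n$ the harmonic number. At $n=80$, $P=16$ this is 0.240, not
0.200. The test suite checks the Monte-Carlo mean against this exact
expectation, not against the asymptotic prevalence.

`run_benchmark()` implements the query-subsampling protocol: for each
query-set size (default 10/20/30) and repeat (default 5), a random subset
of the known positives becomes the queries, every registered method ranks
the data from those same queries, PR-AUC is scored on the non-query
samples with the remaining positives as truth, and repeats are averaged.
Baselines: the nearest-query-distance ranker, a binary SVM trained on the
queries versus sampled negatives (default 100 per query, the
N-times-negatives heuristic; unlabeled samples stand in when no negatives
are known, which is announced), and a one-class SVM on the queries alone.
Both SVMs use a radial kernel with bandwidth tied to the graph $\sigma$
so all methods see the same feature geometry.

## What the synthetic generator emulates — and what it does not

`simulate_pu_data()` produces seeded PU datasets with the geometry the
method assumes, at desk scale: defaults are 85 features, 10 queries, 40
hidden positives, 200 negatives (roughly the 1:20 class imbalance of the
motivating 305-versus-14,770 screen), isotropic unit noise, and class
separation 6 in noise-sd units.

* `gaussian_clusters`: two isotropic Gaussian clouds with centres
  `separation * noise_sd` apart along a random direction — the benign
  geometry where ranking should be nearly perfect.
* `curved_manifold`: positives along a half-circle arc (radius fixed at
  4× the class gap) in the first two coordinates, negatives along a
  concentric arc one gap further out, noise in all coordinates. The arc
  is long relative to the gap, so a query's Euclidean neighbourhood
  crosses to the negative arc long before it reaches the far end of the
  positive arc — the regime in which propagation along the densely
  sampled manifold beats point-to-query distance, which is the reason
  this layout exists.

What passing these tests shows is that the implementation exploits
cluster and manifold structure exactly as the model predicts. What it
does **not** show is performance on real protein feature vectors, whose
features are correlated, heterogeneous in scale and partly discrete;
none of that is emulated. Results on the synthetic defaults are not
comparable to published AUCs on the real screen.

Two empirical notes from these conditions, both reproduced by the test
suite and the acceptance script:

* On the 85-dimensional gaussian clusters, the *dense* graph at
  $\alpha=0.5$ ranks at mean PR-AUC ≈ 0.82: pairwise kernel contrast
  between classes is weak in high dimension and diffusion spreads
  evidence almost uniformly. Adding the pipeline's sparsification step
  (default budget $b=\max(5,\lceil\log_2 n\rceil)$) lifts it to ≈
  0.95–1.00 across 10–30 queries, because b-matching keeps only each
  node's strongest partners, which are overwhelmingly same-class. The
  full pipeline — prefilter, graph, sparsify, rank — is therefore what
  the end-to-end checks measure.
* The planted-structure sanity margin (hidden positives closer to the
  queries than negatives are, on average) is wide at low dimension but
  shrinks like $\mathrm{sep}/\sqrt{2m}$ relative to the noise floor;
  at $m=20$, separation 3 it can invert for unlucky seeds. The margin
  checks therefore run at low dimension and at the default
  (85-dimension, separation 6) conditions, where it is comfortably
  positive.

## Numerical choices and degenerate inputs

* Ties in every ordering (output ranking, prefilter drops, PR curve)
  break by input row order — stable and deterministic.
* Isolated nodes (possible after sparsification) get zero rows in $L$
  with a warning; they simply take no part in propagation.
* An all-identical dataset makes $\sigma = 0$ and is rejected as
  degenerate; missing or non-numeric feature cells are hard errors with
  row/column coordinates.
* $(I-\alpha L)$ is provably non-singular for $\alpha<1$; if the solve
  fails anyway the numerical error is surfaced, never masked.
* The b-matching oracle breaks objective ties toward the
  lexicographically smallest edge set, so reference results are unique.
* Problem sizes in the tests and acceptance script (30-node solver
  cross-checks, 8-node exhaustive oracle sweeps, 250-sample synthetic
  screens, 5–10 seeds per condition) were chosen so the full suite
  completes in a few minutes on a single core while keeping every
  Monte-Carlo margin far from its threshold.

## Known limitations

* Transductive only: adding a new protein means re-ranking; there is no
  out-of-sample extension.
* The dense solve is $O(n^3)$ and the dense graph $O(n^2)$ memory; the
  prefilter is the intended mitigation, not sparse linear algebra.
* $\sigma$ is a single global bandwidth; strongly non-uniform data
  densities would need locally adaptive kernels, which are out of scope.
* The belief-propagation solver's optimality is guaranteed only under
  relaxation tightness; beyond 16 nodes the polish is limited to 4-cycle
  exchanges, so the returned pattern is a high-quality feasible
  b-matching rather than a certified optimum.
* Feature computation, GO-enrichment analysis and reproduction of the
  published whole-proteome ranking are out of scope.

## A five-minute tour

```{r tour, fig.width = 5, fig.height = 3.2}
sim <- simulate_pu_data(n_query = 8, n_hidden_pos = 16, n_neg = 80,
                        m = 20, separation = 5, seed = 42)
ranking <- manifold_rank(sim$data, sim$labels)
glance(ranking)
autoplot(ranking)

queries <- which(sim$labels$status == "positive")
truth <- as.integer(sim$truth$is_positive)
truth[queries] <- 0L
curve <- pr_curve(tidy(ranking)$score, truth, exclude = queries)
curve$auc
autoplot(curve)
```

```{r benchmark, fig.width = 5, fig.height = 3.2}
pool <- sim$labels
pool$status[sim$truth$is_positive] <- "positive"
bench <- run_benchmark(sim$data, pool, query_sizes = c(4, 8), repeats = 3,
                       methods = c("manifold", "nearest"), seed = 1)
bench$summary
```
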