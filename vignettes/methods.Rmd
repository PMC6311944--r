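---
title: "Models and methods behind n2vko"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind n2vko}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(n2vko)
```

This vignette is the package's own account of what it computes, which
choices were genuinely open, and what the synthetic benchmarks do and do
not demonstrate.

## The prediction problem

Given an undirected PPI network, per-gene binary annotations, and a short
list of known disease genes, we want a score per gene for membership in
the disease class. Two structural facts dominate the design. First, known
disease genes for a single disease number in the tens while the
interactome has 10⁴ genes, so the classification problem is severely
imbalanced. Second, the only labels available are positives: every
unlabeled gene is treated as a negative, which is an approximation
(Positive–Unlabeled learning caveat) — some "negatives" are simply
undiscovered positives, and measured AUCs are accordingly slightly
pessimistic.

## Biased random walks and the transition model

The walk engine is second-order: the distribution of the next node depends
on the current node *v* and the previous node *t*. For each neighbor *x*
of *v*, mass is proportional to `search_bias(d_tx, p, q) * w_vx` where
`d_tx ∈ {0, 1, 2}` classifies *x* as the previous node itself (bias `1/p`),
a shared neighbor of *t* and *v* (bias `1`), or a node that moves the walk
away from *t* (bias `1/q`). No other value of `d_tx` can occur, because
*x* is adjacent to *v*. Small `p` keeps walks local; small `q` drives them
outward. Both default to 1 (unbiased) and are tuned by `tune_pq()` over
the standard grid `{0.25, 0.5, 1, 2, 4}²` on cross-validated AUC.

Two numerical points. The per-edge transition distributions are
precomputed and stored exactly (normalized within 1e-9; tested against a
brute-force BFS recomputation on exhaustively enumerated small graphs), so
sampling is a categorical draw and the memory cost is
O(Σ_v deg(v)²) — fine for sparse interactomes. Walks that reach a node
with no neighbors truncate; isolated nodes start no walks, are reported,
and receive the zero embedding vector so that keyword features can still
carry them in the downstream table.

## Skip-gram embeddings

Walk corpora are treated as sentences and genes as tokens; embeddings come
from a skip-gram model with negative sampling (5 negatives, unigram^(3/4)
proposal), symmetric context window, and linearly decaying learning rate
from 0.025. Training is single-threaded C++ with a self-contained
xorshift64* RNG, so a seed pins the embedding bit-for-bit; `epochs = 0` is
defined to return the seeded random initialization, which gives tests a
fixed point. The defaults — dimension 128, 10 walks of length 80 per node,
window 10, 5 epochs — are the established choices for this family of
embedding methods; nothing in our experiments suggested the pipeline is
sensitive to them within sane ranges, and the benchmark suite runs a
scaled-down d = 32, 10 × 40 configuration (see below).

## The N2VK representation and labels

`build_n2vk()` concatenates the embedding block (`emb_1..emb_d`) with one
binary column per annotation keyword (`kw_*`). Keyword columns are plain
presence/absence — no TF-IDF or frequency weighting — matching how such
annotation vectors are normally used. Rows align by gene identifier, and a
mismatch between the embedding's and the annotation matrix's gene universe
is an error rather than a silent intersection: in practice a mismatch
means an upstream identifier-mapping bug.

## Feature selection

Three selectors, all deterministic, all fitted on training data only:

* **MRMR** (greedy, mutual-information difference): continuous features
  are discretized into 3 bins at mean ± one standard deviation — the
  classic discretization for this scheme — binary features used as-is;
  relevance is I(f; y), redundancy the mean MI with already-selected
  features. Ties break lexicographically so results are reproducible
  across platforms.
* **t-statistic importance**: one OLS fit of the 0/1 label on all
  features; importance is |t| per coefficient. We deliberately use the
  linear-model t (the behavior of the variable-importance convention this
  mirrors) rather than the logistic Wald z; the two can diverge on
  strongly separable data, which is documented here as a known property,
  not a bug. A ridge of 1e-8 on the normal equations keeps near-collinear
  embedding columns finite.
* **Backward stepwise AIC** on the logistic model, k counting all
  coefficients including the intercept; elimination stops when no drop
  improves AIC. Non-convergent candidate fits (typical under perfect
  separation) are skipped with a warning.

The subset size `m` defaults to 100: large enough to keep most of the
informative embedding directions, small enough that the later OLS/logistic
fits are well-posed at interactome-scale n. It is exposed as
configuration because no single value suits every disease.

## Imbalance correction

* **SMOTE**: each minority sample contributes N/100 synthetic points,
  interpolated toward one of its k = 5 nearest minority neighbors with
  u ~ U(0, 1). Distances are Euclidean on raw features and binary keyword
  columns interpolate to fractional values — the original formulation of
  the method, kept for fidelity rather than switching to a mixed-type
  variant. `N = "auto"` picks the multiple of 100 closest to balancing
  the classes from below.
* **ROSE**: a smoothed bootstrap; class drawn Bernoulli(p = 0.5), source
  row drawn uniformly within class, Gaussian noise per feature with the
  multivariate Silverman-type bandwidth
  `(4 / ((d + 2) n_j))^(1/(d+4)) σ_jd` scaled by `bandwidth_shrink`
  (default 1; 0 degenerates to a plain bootstrap, a property the tests
  exploit). Output size defaults to the input size.

Oversampling always runs *after* feature selection and *inside* the
training folds. The second point deserves emphasis: oversampling before
splitting leaks synthetic near-copies of test points into training and
inflates AUC. The test suite enforces this with a permutation-style null —
on label-independent features the full pipeline must stay at AUC ≈ 0.5.

## Classifier and evaluation

The required classifier is a logistic model fitted by IRLS with an
unpenalized intercept and a small ridge (1e-6) on the slopes; the ridge
keeps the optimum defined when embeddings separate the classes perfectly,
which happens routinely on cohesive disease communities. Convergence is a
max coefficient change below 1e-8 within 100 iterations. kNN (score =
positive fraction among k nearest training rows, distance ties broken by
training row order) is included as the optional alternative; other
classifiers can be plugged in by implementing the `classifier_model`
scoring contract.

AUC uses the Mann–Whitney formulation with ties counted half. Evaluation
is stratified five-fold cross-validation: per-class counts differ by at
most one across folds, the assignment is a function of labels and seed
only, and each fold's AUC is computed on a test set untouched by feature
selection and oversampling. With 13–47 positives per disease,
unstratified folds would regularly produce positive-free test folds, so
stratification is not optional.

Two protocol caveats are inherited from the workflow this package
implements and are flagged rather than silently changed: `tune_pq()` and
`select_best_combination()` choose hyperparameters by the same CV AUC that
is then reported (an optimistic selection bias), and the final
`rank_candidates()` model is refitted on all labeled data, the standard
choice once evaluation is done.

## Sub-network diagnostics

`one_hop_subnetwork()` induces the subgraph on a disease's genes plus
their direct neighbors, including *all* edges among that node set.
"Clustering coefficient" is read as the average local clustering
coefficient, with nodes of degree < 2 contributing 0 rather than being
excluded — on sparse disease neighborhoods the two conventions differ
materially, and counting low-degree nodes as 0 is the honest choice when
sparsity itself is the signal; global transitivity is reported alongside.
Component counts come from standard traversal. `normalize_range()` maps a
batch of statistics linearly onto [0.5, 1] (constant input → 0.75, the
midpoint) so clustering and component counts for several diseases can
share an axis. Low clustering and many components predict poor
embedding-based performance, which is the practical use of this module:
deciding whether to trust the ranking for a given disease.

## The synthetic benchmark: what it shows and what it does not

`make_planted_disease_network()` is a planted-partition generator: disease
pairs connect with probability `p_in = 0.2`, all other pairs with
`p_out = 0.01`, at n = 500 genes and a 30-gene community.
`make_keyword_annotations()` adds 200 keywords of which 10 fire at
`rho1 = 0.6` in disease genes versus `rho0 = 0.05` elsewhere. These
defaults make the community detectable but not trivial (expected
within-community degree ≈ 5.8 against background ≈ 5), and keyword signal
genuinely complementary to topology — the regime where combining the two
blocks should help, mirroring the qualitative finding the pipeline is
built on. A planted partition is used instead of a scale-free or LFR
generator because community cohesion is precisely the property the
embedding must detect; no attempt is made to emulate interactome degree
distributions, annotation sparsity patterns, or OMIM phenotype structure.
Passing the benchmark therefore shows the machinery is correct and
leakage-free, not that any particular real-data AUC will be reached.

The test suite runs this benchmark at d = 32 with 10 walks of length 40
(seeds 1–5, five-fold CV) — sizes chosen so the whole suite stays in the
minutes range on one core — and checks the two scenario orderings that are
stable under the generator: the integrated pipeline reaches mean AUC ≥
0.85, and keyword-augmented features do at least as well as embeddings
alone. The candidate-recovery check hides 10 of the 30 community genes and
requires a majority of seeds to place ≥ 6 of them in the top 10.

## Degenerate inputs and tie-breaking, collected

* Duplicate edges collapse to the maximum weight (order-independent);
  self-loops are dropped and counted; isolated nodes require an explicit
  node-list sidecar at load time.
* All selector ties break lexicographically by feature name; ranking ties
  break lexicographically by gene identifier; kNN distance ties break by
  training row order; `tune_pq` ties prefer smaller p, then smaller q.
* SMOTE with k ≥ minority count clamps k with a warning; fewer than two
  minority samples is an error, as is a ROSE class with a single sample
  (its bandwidth is undefined).
* One global seed expands into independent per-stage seeds
  (`derive_seed`), so walks, fold assignment and oversampling draw from
  disjoint reproducible streams.

## Known limitations

Unlabeled genes are treated as negatives (PU caveat above). The embedding
stage cannot help genes that are isolated or near-isolated in the PPI
network; they survive on keyword features alone. MRMR's 3-bin
discretization loses information for strongly multimodal features. The
stepwise selector refits one logistic model per candidate drop and is the
slowest selector at interactome scale. And hyperparameter selection by
the reported CV metric, noted above, means published-style mean AUCs from
`tune_pq`/`select_best_combination` should be treated as upper bounds.
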