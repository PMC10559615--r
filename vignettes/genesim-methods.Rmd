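---
title: "Ontology-based gene similarity and stacked ensemble classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology-based gene similarity and stacked ensemble classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genesim)
```

# The problem

Disease-gene classification asks, given a set of genes known to be
associated with a disease (here the motivating case is autism spectrum
disorder) and a much larger set of genes believed unrelated, which other
genes resemble the disease set. `genesim` implements one complete route to
that answer: genes are described by their Gene Ontology biological-process
annotations, pairwise functional similarity between genes is computed from
the ontology graph, the resulting similarity matrix doubles as a feature
table, the heavy class imbalance typical of disease cohorts is corrected by
resampling, and a stacked ensemble whose strongest member is a gradient
boosting classifier over small random forests produces the final
probabilities.

Everything below is computable offline: the package ships generators for
random ontologies, annotation cohorts with a planted disease signal, and
Gaussian blob datasets, so every claim in the test suite is reproduced from
code alone.

# Hybrid semantic similarity (HGS)

## Semantic values

For a term $x$, let $DAG_x$ be the subgraph containing $x$, all its
ancestors $T_x$ (following child $\to$ parent `is_a` and `part_of` edges),
and the edges $E_x$ among them. Each ancestor $t$ receives a *semantic
value* — the share of $x$'s meaning it carries:

$$S_x(x) = 1, \qquad
  S_x(t) = \max_{t' \in \mathrm{children}(t) \cap T_x} \; w(t' \to t)\, S_x(t').$$

Because every weight is below one, values decay monotonically toward the
root; the maximum over children means the *strongest* path determines an
ancestor's contribution. `semantic_values()` evaluates the recursion in a
topological order of $DAG_x$ so each value is final when read.

Where the classic Wang similarity fixes one constant weight per relation
kind, the hybrid method derives the weight from how informative a term is.
A term with many children is a broad category and should transmit less
meaning, so

$$w = \min\!\Big(w_{\max},\; \frac{1}{\mathrm{childrenCount}(t) + c} + d_{\mathrm{rel}}\Big).$$

Children are counted on the **full ontology**, not inside $DAG_x$: the
weight is a property of the term itself, and a per-subgraph count would
make term–term similarity depend on which gene asked.

Three numerical choices deserve note:

* **Defaults** are $c = 2$, $d_{is\_a} = 0.3$, $d_{part\_of} = 0.2$,
  $w_{\max} = 0.9$. They keep every weight strictly below 1 (so semantic
  values decay and all similarities stay in $[0,1]$) and order the two
  relation kinds the way Wang's constants traditionally do (`is_a`
  stronger than `part_of`). All four are exposed through `hgs_config()`;
  none is canonical.
* **Whose children count feeds the weight.** The recursion leaves open
  whether the edge $t' \to t$ uses the child's or the parent's count. We
  default to the child $t'$ — the term whose contribution is being passed
  up, matching the rationale that an unspecific term carries less
  information — and expose `weight_on = "child" | "parent"`.
* **Both `is_a` and `part_of` edges** are retained and both count as
  children; all other ontology relations are dropped, as in Wang's method.

## From terms to genes

Term-level similarity aggregates over shared ancestors,

$$\mathrm{sim}(a, b) =
  \frac{\sum_{t \in T_a \cap T_b} \big(S_a(t) + S_b(t)\big)}
       {\sum_{t \in T_a} S_a(t) + \sum_{t \in T_b} S_b(t)},$$

and gene-level similarity is the best-match average over the two genes'
annotation sets $A$ (size $m$) and $B$ (size $n$):

$$\mathrm{BMA}(A, B) = \frac{\sum_{i} \max_j \mathrm{sim}(a_i, b_j)
  + \sum_{j} \max_i \mathrm{sim}(a_i, b_j)}{m + n}.$$

`build_gfs_matrix()` assembles the gene functional similarity (GFS) matrix
— symmetric, unit diagonal, entries in $[0,1]$ — computing each unordered
term pair once. Self-similarity is returned as exactly 1 (short-circuited
rather than recomputed, so floating-point summation order cannot perturb
the diagonal). Genes whose terms are all absent from the ontology are an
error by default; `drop_unannotated = TRUE` downgrades this to a warning,
because silently dropping samples changes the cohort.

```{r hgs-example}
dag <- synth_dag(120, 5, max_parents = 1, seed = 1)
coh <- synth_cohort(dag, n_positive = 4, n_negative = 6, seed = 1)
gfs <- build_gfs_matrix(dag, coh$annotations)
round(gfs[1:5, 1:5], 3)
```

# Resampling the imbalanced cohort

Disease cohorts are dominated by the negative class. Three from-scratch
resamplers operate on a `labeled_dataset`:

* **SMOTE** (`smote()`): synthetic minority rows
  $x_s = x_i + u\,(x'_i - x_i)$, $u \sim U(0,1)$, where $x'_i$ is drawn
  uniformly from the $k$ nearest *minority* neighbours of $x_i$ under
  Euclidean distance. Defaults: $k = 5$, target minority/majority ratio 1.
  Base points cycle through the minority rows in input order, the
  remainder is drawn uniformly; distance ties break to the lower original
  index, so a fixed seed gives bit-identical output. Originals are never
  touched; new rows carry `synthetic = TRUE`.
* **RUS** (`rus()`): uniform subsampling of the majority without
  replacement.
* **SMOTE-RUS** (`smote_rus()`): SMOTE to an intermediate ratio $r_1$,
  then RUS to the target. No canonical split for $r_1$ exists, so the
  default is the geometric midpoint $\sqrt{r_0\,r}$ between the starting
  ratio $r_0$ and the target $r$ — both classes move by the same factor —
  and $r_1$ is a parameter.

# GBBRF: gradient boosting over small random forests

The classifier minimises binary log loss
$L = -\tfrac1N \sum_i \big[y_i \log p_i + (1-y_i)\log(1-p_i)\big]$
with an additive score. Training starts from the empirical log-odds
$f_0 = \log(n_{pos}/n_{neg})$; round $m$ fits a *forest* of
`trees_per_round` regression trees to the pseudo-residuals $y - p$ and
adds the learning-rate-shrunken mean of their outputs.

The weak learner is deliberately a small random forest rather than a
single stump or tree: each tree sees a bootstrap sample of rows and
examines a random `feature_fraction` of features per split (default
$\sqrt{p}/p$), and the forest output is the plain mean. Defaults follow
the regularisation set used throughout the package's evaluation:
`n_rounds = 500`, `learning_rate = 0.1`, `lambda = 5`, `max_depth = 3`,
`trees_per_round = 10`.

Numerical decisions:

* **Leaf values** are the one-step Newton update
  $\gamma = \sum_{i \in \mathrm{leaf}} r_i \big/ \big(\sum_{i \in
  \mathrm{leaf}} p_i(1-p_i) + \lambda\big)$, computed over the tree's own
  (in-bag) rows. Placing $\lambda$ in the Newton denominator is a design
  choice: it damps leaves supported by few or low-curvature samples,
  which is the usual reading of a leaf regulariser.
* **Splits** maximise the sum-of-squares gain (variance reduction) with a
  minimum of 2 samples per leaf and a minimal accepted gain of $10^{-10}$
  (guards pure nodes); ties resolve to the lowest feature index, then the
  lowest threshold. The split search is compiled code (`src/tree.cpp`)
  but draws bootstrap rows and feature subsets through R's RNG, so
  `seed` makes the whole model reproducible.
* With `trees_per_round = 1`, `bootstrap = FALSE`,
  `feature_fraction = 1` the model reduces exactly to classic gradient
  tree boosting — the test suite holds it against an independently coded
  single-tree booster.
* The decision threshold is fixed at 0.5 and no class weighting is
  applied: imbalance is handled upstream by resampling.

# Two-level stacking

`fit_stacked()` implements stacked generalization: each level-0 learner is
evaluated out-of-fold (stratified, default 5 folds) so that no sample's
own label ever reaches the model that scores it; the level-1 learner is
trained on those out-of-fold columns; level-0 learners are then refit on
the full training data for deployment (the standard arrangement — without
the refit, deployment models would each see only a fold complement).

Meta-features are positive-class *probabilities* by default (they preserve
ranking information); `meta_features = "label"` switches to hard 0/1
predictions. The level-1 learner sees only the meta-features, no
passthrough of the original columns.

Base learners sit behind one interface (`fit_base_learner()`): random
forest (`randomForest`), SVM with an RBF kernel whose decision values are
mapped to probabilities by a fitted logistic link (`e1071`), naive Bayes
(`e1071`), $k$-nearest neighbours as vote fractions (`class`), logistic
regression (`stats::glm`), and GBBRF. Their hyperparameters keep the
conventional defaults and are exposed through `learner_opts`. Five named
presets ship as `stacking1` … `stacking5`; `stacking3`
(level 0 GBBRF, NB, SVM, KNN, RF; level 1 RF) is the recommended
combination.

# Evaluation

`cross_validate()` runs stratified $k$-fold cross-validation (default
$k = 5$) and reports accuracy, positive-class precision, recall,
F-measure, and AUC-ROC computed as the Mann–Whitney rank statistic (ties
counted one half). Per-fold values and their unweighted mean are reported;
pooled-confusion aggregation is available via `aggregate = "pooled"`.
Metrics with zero denominators are reported as 0 with a warning rather
than NaN.

Two pipeline orders are provided because they answer different questions:

* **safe (default)** — split first, resample only the training folds,
  evaluate on untouched originals. Synthetic rows can never reach a test
  fold (the report counts them per fold so the property is checkable).
* **paper** — resample the whole dataset, shuffle, then split. This is
  the order many published pipelines use. It leaks information: synthetic
  copies interpolated near test points enter training, so scores read
  optimistic. The mode is recorded in every report so the two are never
  silently confused.

# Synthetic data: what it does and does not show

The generators define the package's study conditions:

* `synth_dag()` builds a single-rooted layered DAG; each non-root term
  takes 1–`max_parents` parents from the layer above (acyclic by
  construction, generation is linear in the number of terms), and edges
  are `part_of` with a configurable probability (default 0.2).
* `synth_cohort()` plants the class signal: the exclusive leaf
  descendants of one root child form a "disease" subtree; positive genes
  draw `ceiling(signal * terms_per_gene)` of their terms there, negatives
  draw from the remaining leaves. At `signal = 0` the classes are
  exchangeable; at `signal = 1` positives annotate entirely inside the
  disease subtree.
* `synth_blobs()` gives imbalanced Gaussian clusters for the resampling
  and boosting tests.

The test suite and the acceptance script use, as the package's own
choices: 300-term, 6-layer tree-shaped ontologies; cohorts of 40 positive
and 160 negative genes with 5 terms per gene at signal 0.8; blob datasets
of 200–1000 samples; and a reduced GBBRF (40 rounds × 5 trees) inside
stacking so the full pipeline stays comfortably within a desktop run.
Tree-shaped ontologies (`max_parents = 1`) are used for cohorts because
heavy multi-parenthood blurs subtree membership and with it the planted
pools; multi-parent DAGs are exercised throughout the similarity tests.

What passing these tests does **not** show: real GO has skewed depth and
fan-out distributions, annotation counts per gene vary by orders of
magnitude, and real disease cohorts carry label noise and shared pathway
structure far subtler than a planted subtree. Results on synthetic cohorts
validate the *machinery* — correctness of the similarity algebra, the
resampling contracts, the boosting behaviour, leakage discipline — not any
clinical performance level.

# Known limitations

* Information-content similarities (Resnik, Lin, Relevance) are out of
  scope; HGS is the only gene similarity implemented.
* The similarity stage is quadratic in genes and in annotated terms; it is
  comfortable at hundreds of genes but not tuned for genome-scale runs.
* Boosting is binary-only, with a fixed round count (no early stopping)
  and no monotonic constraints.
* `part_of` weights are a modelling default, not a fitted quantity; if
  your ontology encodes other relation kinds they are ignored.
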