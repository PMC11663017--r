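---
title: "Quantifying visual subjective effects from narrative reports: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying visual subjective effects from narrative reports: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psyvis)
```

# The scientific problem

Visual perceptual changes are hallmark effects of psychedelic compounds, but
whether different substances produce *consistently different* visual effects
is hard to study experimentally: effects vary widely across and within
individuals, so enormous samples are needed. Archives of unconstrained,
first-person "experience reports" provide that scale, at the cost of
unstructured narrative text. psyvis implements a pipeline that turns such
text into quantitative, comparable visual-effect profiles per substance:

1. **Corpus assembly** — reports are stripped of markup, segmented into
   sentences, and filtered (single-substance reports only; substances with at
   least a minimum number of reports).
2. **Sentence embedding** — each sentence is mapped to a fixed-dimension
   vector by a pluggable backend, such that semantic similarity corresponds
   to small Euclidean distance.
3. **Visual-effect classification** — a ridge-penalised logistic model over
   embedding vectors flags sentences that explicitly describe visual
   effects; sentences at or above a probability threshold (default 0.75)
   form the visual-effect subset.
4. **Seed-sentence categorisation** — each visual-effect sentence is
   compared against a catalogue of prototypical "seed sentences"
   (`seedCatalogue()`, 41 seeds in 8 categories); a sentence belongs to a
   seed's region when its vector lies within a distance threshold (default
   0.55) of the seed's vector. The per-substance membership proportions form
   the matrix $V(s, d)$.
5. **Inference** — substance-vs-classification association is tested by
   Pearson chi-square with Cramér's $V$ effect size; psychedelic vs other
   substances by a Welch $t$-test on substance-level proportions; and
   consistency of profile differences by a dispersion statistic $T$ with a
   label-permutation null.

# The dispersion statistic and its null

For seed set $S$ and substance set $D$,

$$T \;=\; \frac{1}{|S|} \sum_{s \in S} \frac{2}{|D|\,(|D|-1)}
  \sum_{\{d_1, d_2\} \subset D} \bigl|V(s, d_1) - V(s, d_2)\bigr|,$$

the mean over seeds of the mean absolute pairwise difference of membership
proportions across substances. The inner sum runs over *unordered* pairs, so
with the $2/(|D|(|D|-1))$ normalisation the bracket is exactly the mean
absolute pairwise difference; the implementation uses the sorted-sum
identity $\sum_{i<j}|x_i-x_j| = \sum_k x_{(k)}(2k-n-1)$, and the test suite
checks it against a brute-force double loop to $10^{-12}$.

The null distribution of $T$ is obtained by uniformly shuffling substance
labels across the visual-effect sentences (sentence-level shuffling — the
dataset being permuted is the visual-effect sentence set; group sizes are
preserved by construction), rebuilding $V$, and recomputing $T$. The
p-value is the plain proportion of permuted values greater than or equal to
the observed one; the $(b+1)/(n+1)$ estimator is available behind
`smoothed = TRUE` but off by default, matching the plain-proportion
definition of the reference procedure. Report-level shuffling could be added
as a sensitivity analysis; sentence-level shuffling is the default because
the permuted dataset is the visual-effect sentence set itself.

# Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `minReports` | 100 reports | substance inclusion threshold for a corpus |
| probability threshold | 0.75 | inclusive cut on classifier probability for the visual-effect subset (training diagnostics use 0.5) |
| distance threshold | 0.55 | inclusive Euclidean radius around a seed vector, on unit-normalised embeddings |
| `split` | 0.8 | training fraction; the held-out 20% keeps its natural class balance |
| ridge penalty | $\lambda = 1/n$ | L2 strength 1 on the summed-loss scale; recorded in the training report |
| `nPermutations` | 10,000 | label shuffles for the permutation null |
| linkage | average | clustermap agglomeration (configurable: single, complete, average, ward) |

Both thresholds are inclusive ($\ge$ 0.75, $\le$ 0.55): the reference
procedure's wording ("at least", "within") reads inclusively, and the
boundary has measure zero for continuous embeddings. `runPipeline()` warns
when either threshold is moved off its reference value.

Embedding vectors are L2-normalised on ingestion regardless of backend.
On the unit sphere a Euclidean radius $r$ is equivalent to a cosine
similarity cut of $1 - r^2/2$ (0.84875 for $r = 0.55$), which makes the
distance threshold meaningful across backends of different dimensions. A
reference commercial embedding model returns 1,536-dimensional vectors; the
pipeline only ever uses distances, so any dimension works behind the
`EmbeddingBackend` contract, and whether a live service's vectors arrive
pre-normalised or not becomes irrelevant.

# Corpus segmentation rules

Sentences are split at period characters with two exceptions: a period
flanked by numerals on *both* sides is a decimal point ("2.5 grams"; "5.
grams" still splits), and any run of two or more periods is an ellipsis,
retained inside the current segment. Only `.` terminates sentences by
default; `?` and `!` can be opted in via `extraTerminators` but are off by
default, keeping segment counts comparable with the reference procedure.
The terminating period is stripped from each segment (sentence counts are
unaffected either way); segments are trimmed and empty segments dropped. No
abbreviation handling ("e.g.", "Dr.") is implemented — such tokens split,
as the plain rule dictates. A property test fuzzes 1,000 random strings and
checks that splitting then rejoining preserves every non-period,
non-whitespace character in order.

# The synthetic corpus generator

The real report archive is access-restricted and the reference embedding
model is a commercial service, so the package ships a generator
(`generateCorpus()`) that emulates the *statistical structure* the analysis
assumes, with full ground truth:

* per-substance report counts and right-skewed sentences-per-report counts
  (discretised log-normal, median ≈ 40 and mean ≈ 50, matching the skew of
  the published corpus summary; the exact family is a modelling choice —
  the reference only reports summary statistics);
* a per-substance probability $p_d$ that a sentence is a visual-effect
  sentence (defaults 0.15 for psychedelics, 0.04 for comparison substances,
  consistent with a corpus-wide visual fraction of a few percent and a
  marked psychedelic excess);
* per-substance category mixtures $\theta_d$ over visual-effect categories
  (flat-Dirichlet by default, or user-specified);
* embedding geometry: unit anchor vectors per category with pairwise
  separation above twice the distance threshold (so ground-truth membership
  is exclusive), plus background anchors placed further than
  `threshold + 3 * noiseSd` from every category anchor (so non-visual
  sentences never intrude on seed regions).

Sentence text is templated ("I saw … shapes …") with per-category tokens,
so the offline rule labeller and the synthetic backend agree with ground
truth by construction; every sentence carries a unique digit-free nonce so
texts are distinct. The synthetic backend embeds a tagged sentence as
`normalize(anchor + eps)` with noise keyed to the backend seed and a hash
of the text — the same string always embeds identically, which is the
determinism contract every backend must satisfy. `noiseSd` is defined as
the RMS *norm* of the perturbation (per-coordinate sd `noiseSd/sqrt(dim)`),
so thresholds keep their meaning whatever the embedding dimension (default
64; the analysis depends only on distances).

**What passing tests show, and what they do not.** The generator emulates
cluster geometry, label noise and count structure — not language. Passing
recovery tests demonstrates that the pipeline's machinery is correct
(splitting, embedding plumbing, training, thresholding, $V$, $T$,
permutation calibration), not that any particular real embedding model
separates visual from non-visual prose, nor that the 0.55 radius is
semantically right for a given backend. Those are properties of the data
and backend, fixed here as inputs.

# Numerical and design choices

* **Classifier.** Undersampling applies to the training split only: the
  majority class is randomly reduced to the minority count, and held-out
  accuracy is computed on the untouched 20% split at a 0.5 decision
  threshold (the natural, not the rebalanced, distribution). The fit is a
  deterministic penalised maximum-likelihood logistic regression; with the
  penalty fixed the decision boundary is stable under dataset duplication.
  A class missing from a training split is an error advising a different
  seed or larger sample.
* **Degenerate inputs.** A substance with zero visual-effect sentences has
  undefined $V(\cdot, d)$ (0/0) and is dropped from the matrix with a
  warning rather than silently assigned 0. A single-substance corpus is a
  hard error for $T$ and the permutation test. A single-report substance
  reports a sentences-per-report standard deviation of 0. A constant $V$
  yields a valid but arbitrary clustermap order.
* **Categorisation is per seed sentence, not per category.** All 41 seeds
  enter $V$ individually; categories are row metadata for labelling and
  colouring. Substance names are verbatim opaque keys, never normalised.
* **p-value lattice.** With $n$ permutations the plain estimator takes
  values on $\{0, 1/n, \dots, 1\}$; under an exchangeable null the observed
  statistic's rank among the $n + 1$ values is uniform, so rejection at
  $p \le \alpha$ occurs at essentially the nominal rate. The test suite
  verifies calibration empirically: 400 null corpora at 199 permutations
  give a rejection rate within [0.03, 0.07] at $\alpha = 0.05$ and
  p-values that pass a Kolmogorov–Smirnov uniformity check.
* **Cache.** Embeddings are cached by (backend name, exact sentence text);
  warmed caches make re-runs free and the backend is provably not invoked
  for cached sentences.
* **UMAP.** No R implementation of UMAP is part of the package's
  dependency set; `projectUMAP()` delegates to the established
  `umap-learn` implementation through a `python` subprocess behind a thin
  contract. The projection is inspection-only: all quantitative analysis
  runs in the full-dimensional space.
* **Chi-square degrees of freedom** are always recomputed from the
  analysed table's shape, never forced to an external value; published
  analyses may use a slightly different substance universe than a given
  corpus summary, and the implementation makes no attempt to reconcile
  such bookkeeping.
* **Welch $t$-test, unweighted.** Substance-level proportions enter the
  group comparison unweighted (each substance is one observation) with
  unequal-variance pooling; weighting by sentence count is a defensible
  alternative the reference leaves unspecified.

# Problem sizes used in validation

The shipped validation studies are sized for a single CPU: the permutation
calibration uses 400 null corpora of 6 substances (about 100 visual
sentences each) at 199 permutations; parameter recovery uses 8 substances
with 2,000 sentences each in 64 dimensions; oracle-equivalence checks for
$T$ and the clustermap use random matrices up to 10 × 10. The demo
pipeline (`demoPipelineConfig()`) runs 6 substances × 12 reports × 12
sentences with 200 permutations end to end. Scaling any of these up is a
matter of configuration, not code.

# Known limitations

* The offline rule labeller is a transparent keyword system intended for
  synthetic corpora and auditing, not a substitute for careful labelling of
  real narrative text; with real data, labels should come from human review
  or a language-model labeller plugged in behind the same function
  contract, with corrections recorded in the ledger format.
* Seed sentences are a fixed, manually curated input; the package does not
  attempt data-driven category discovery.
* Membership proportions for rare substances are noisy; $V$ entries carry
  no interval estimates, and no multiple-testing control is applied across
  seeds (the global $T$ test is a single test by design).
* Contextual confounders of real self-report data (set, setting, reporting
  populations) are outside the generator's scope and cannot be controlled
  by this analysis.
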