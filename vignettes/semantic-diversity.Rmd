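---
title: "Semantic diversity from LSA context vectors: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic diversity from LSA context vectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semdiv)
```

## The measure

Semantic diversity (SemD) quantifies how variable the contexts are in which
a word occurs. A corpus is cut into fixed-length windows of content words
("contexts"), a context-by-word count matrix is weighted and reduced to a
k-dimensional space by truncated SVD, and each context becomes a vector.
For a word occurring in $n$ contexts with vectors $v_1, \dots, v_n$,

$$\mathrm{SemD}(w) \;=\; -\log \Bigl(\tbinom{n}{2}^{-1}
  \sum_{i<j} \cos(v_i, v_j)\Bigr).$$

Identical contexts give SemD $= 0$; mutually dissimilar contexts push the
mean cosine toward 0 and SemD up. Each context counts once, no matter how
often the word occurs inside it. A word needs at least two usable contexts
to be scored.

The package computes the mean pairwise cosine in closed form from the sum
of the unit-normalised vectors, $\bigl(\lVert\sum_i u_i\rVert^2 - n\bigr) /
\bigl(n(n-1)\bigr)$, which is exact and linear in $n$; tests verify it
against an explicit double loop to $10^{-12}$.

## Pipeline and its parameters

| stage | function | parameter | default | why |
|---|---|---|---|---|
| chunking | `chunk_documents()` | `window` | 1000 tokens | the classical context length for this measure; 100 is the usual robustness setting |
| cleaning | `clean_config()` | `min_word_len` | 2 | one-letter words carry no topical signal |
| cleaning | `clean_config()` | `stoplist` | shipped function words | function words dominate counts without topical content; the list is replaceable |
| vocabulary | `build_vocabulary()` | `min_count`, `min_contexts` | 50, 40 | the standard thresholds removing words too rare or too narrow for stable vectors |
| weighting | `log_entropy_weight()` | `base` | $e$ | provably inert downstream (see below) |
| reduction | `truncated_svd()` | `k` | 300 | the dimensionality at which this family of spaces is conventionally used |
| space | `make_space()` | `scaled` | `TRUE` | the classical LSA output weights singular vectors by singular values |

Three places where the procedure is genuinely underdetermined are exposed
as flags rather than silently fixed:

* **Cleaning before or after windowing.** By default windows are counted
  over content words (cleaning first), so every retained context carries
  exactly `window` informative tokens. The alternative — window the raw
  token stream, then clean within each window — is available via
  `clean_first = FALSE` for sensitivity checks; it yields contexts of
  varying effective length.
* **The exactly-full final window.** Final windows shorter than `window`
  are always dropped: they would represent less context than the rest. An
  exactly full final window is kept by default, because the reason for
  dropping finals is only that they *may* be short; `drop_final_always =
  TRUE` selects the stricter reading.
* **Threshold logic.** The default excludes a word if *either* frequency
  criterion fails (keep only count $\ge$ `min_count` **and** contexts
  $\ge$ `min_contexts`), which matches the intent of removing rare and
  narrow words. The literal Boolean alternative (exclude only words
  failing both) is `rule = "either"`.

Non-alphabetic characters are stripped inside tokens by default
(`cat's` → `cats`); `nonalpha = "split"` treats them as separators instead.
Lowercasing is on by default. Lemmatisation is a plain surface-to-lemma
lookup supplied by the user; the package deliberately does not bundle a
lemmatiser.

## Log-entropy weighting

The count matrix (contexts in rows, words in columns) is weighted cell-wise
as $g_j \cdot \log(1 + f_{ij})$ with the global word weight

$$g_j = 1 + \frac{\sum_i p_{ij} \log p_{ij}}{\log n},
  \qquad p_{ij} = \frac{f_{ij}}{\sum_i f_{ij}},$$

the standard convention for LSA spaces. $g_j = 1$ for a word confined to
one context, $g_j \to 0$ for a word spread uniformly over all $n$
contexts, and $g_j \in [0, 1]$ always; entropy is computed per *word* over
its distribution across contexts, the orientation fixed by that
convention. Changing the logarithm base multiplies the whole matrix by a
constant and leaves $g_j$ (a ratio of logarithms) untouched, so cosines —
and SemD — are invariant to it; the test suite asserts this rather than
trusting the algebra.

## Scaled and unscaled spaces

Context vectors are rows of $U_k \Sigma_k$ (`scaled = TRUE`, the classical
LSA coordinates) or of $U_k$ alone. The two variants produce correlated
but measurably different SemD values on structured corpora, and published
norm sets appear to disagree on exactly this choice, so both are
first-class: a `semantic_space` stores $U_k$ and $\Sigma_k$ separately and
`set_scaling()` flips the variant without recomputation.
`compare_variants()` reports Pearson and Spearman correlations between any
two SemD tables over their shared words.

## Numerical choices

* **SVD backend.** `truncated_svd()` uses the dense LAPACK decomposition
  and truncates: at the corpus sizes this package targets (hundreds to a
  few tens of thousands of contexts) this is exact, deterministic and fast,
  and avoids convergence tuning entirely. A `seed` argument is accepted so
  run configs stay complete descriptions of a run. Requested `k` beyond
  the numerical rank (relative tolerance $10^{-10}$) is capped with a
  warning, not an error. Tests check the result against an independent
  eigen-decomposition of the Gram matrix to $10^{-8}$.
* **Vocabulary order.** Columns are ordered by descending corpus count
  with alphabetical tie-breaks, making matrices reproducible across runs
  and platforms.
* **Degenerate inputs.** Contexts containing no vocabulary word stay in
  the matrix as zero rows (indexing stays aligned with the manifest) but
  can never enter any word's context set. Context vectors that are
  numerically zero are excluded from a word's pair set and counted. A word
  with fewer than two usable contexts, or a nonpositive mean cosine (where
  $-\log$ is undefined), yields `NA` with an explanatory status — clamping
  would fabricate a diversity score.
* **Permutation baseline.** The Calinski–Harabasz baseline permutes the
  observed label multiset (category sizes preserved), the stricter null,
  rather than resampling labels independently. Its mean tends to 1 for any
  vector configuration as $n$ grows, which the suite asserts at
  $n = 5000$.
* **Context sampling for word diagnostics.** Where a labelled subsample of
  a word's contexts is scored, the sample is drawn without replacement
  under a recorded seed, making an otherwise irreproducible manual
  sampling step reproducible.
* **t-SNE.** `embed_2d()` implements exact t-SNE (perplexity-calibrated
  Gaussian affinities; Student-t output kernel; momentum gradient descent
  with early exaggeration), quadratic in $n$. It is a visual aid: no
  quantitative result in the package depends on the embedding's geometry,
  and tests cover only shape, determinism and a planted-cluster sanity
  check.

## What the synthetic generator emulates — and what it does not

`generate_corpus()` produces a corpus with one topic per document:
background tokens are drawn i.i.d. from a Zipf-weighted mixture of the
document topic's private word inventory (70%) and a shared pool (30%),
and planted words are inserted Poisson-per-document at uniform positions,
replacing background tokens so documents keep their exact length. The
design mirrors the structure that corpus metadata imposes on real
collections — documents cluster by domain and register — which is exactly
the structure the diagnostics are meant to detect. One-topic-per-document
is deliberate; admixture would blur the planted ground truth that the
recovery tests depend on.

The committed reference spec (`reference_spec()`, stored as YAML under
`inst/extdata/`) uses 5 topics × 12 documents × 240 tokens, a 100-token
window, thresholds (10, 5) and $k = 50$ — a deliberately desk-scale
configuration (120 contexts, ~250 words) chosen so the full pipeline runs
in seconds while every planted word comfortably survives thresholding.
Planted words sit at topic spreads 1–5 with equal expected total frequency
(24 insertions each), so spread is decoupled from frequency. Two ambiguous
words probe what the metric can and cannot see:

* `twokeyed` — two meanings keyed to two different topics. Its contexts
  form two separable clusters, and the Calinski–Harabasz score of the true
  meaning labels exceeds the permutation baseline by a wide margin.
* `evenblend` — two meanings assigned per document at random, with
  *identical* topic-spread profiles. Nothing in the context distribution
  distinguishes the meanings, and its CH score stays inside the baseline
  band. This is the constructed analogue of the central interpretive
  point: the pipeline measures spread across kinds of text, not meaning
  structure, so two "meanings" that inhabit the same kinds of text are
  invisible to it.

What synthetic corpora do **not** emulate: natural syntax and collocation,
Zipfian document-length variation, topic admixture within documents, and
genuine sense-dependent context vocabulary for the random-meaning case.
Passing recovery tests therefore shows the pipeline recovers planted
*topic* structure under clean conditions; it does not certify behaviour on
natural corpora, where topic boundaries are soft and metadata is noisy.

## Problem sizes used by the tests and the reproduction script

The suite and `scripts/acceptance.R` run the reference corpus (120
contexts, $k = 50$), 100-replicate oracle comparisons for the SVD, SemD
and CH kernels, a 5000-point × 300-dimension × 1000-permutation baseline
check, and a 20-replicate Monte-Carlo in which a five-topic planted word
must out-score a one-topic word of equal frequency. These sizes are the
package's canonical desk-scale study conditions; they complete in well
under two minutes on one CPU.

## Known limitations

* Corpus-scale statistics published for licensed corpora (context and
  vocabulary counts, correlations with published norm sets) cannot be
  recomputed here; the package reproduces the *procedure*, and its
  external-corpus claims are limited to what the machinery supports
  (e.g. lemmatised and inflected runs of the same corpus correlating
  strongly).
* The dense SVD backend is the right tool up to roughly $10^4 \times 10^5$
  matrices; corpora far beyond that would need a sparse iterative backend
  behind the same interface.
* SemD values depend on the log base and on the scaling variant; comparing
  against published norms requires matching both dialect options, which is
  why they are explicit flags rather than constants.
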