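---
title: "Linking preprints to their published versions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking preprints to their published versions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`preplink` treats preprint-to-publication linkage as retrieval followed by
binary classification. For a preprint $p$ and a corpus of published papers,
three similarity features are computed per candidate paper $c$:

* $s_T(p, c)$ — cosine similarity of title sentence vectors,
* $s_A(p, c)$ — cosine similarity of abstract sentence vectors,
* $s_U(p, c)$ — author similarity: the maximum of the Jaccard overlap of
  the case-folded last-name sets and of the overlap between the preprint's
  fore names and the paper's last names (the *flip check*, because name
  fields are occasionally swapped in preprint metadata).

Retrieval takes the union of the 100 papers with the most similar titles
and the 100 with the most similar abstracts (so up to 200 candidates — the
union is implemented literally). An RBF-kernel support vector machine over
$(s_T, s_A, s_U)$ classifies each candidate, and a small rule layer
corrects two known failure modes:

* a **negative** classification is rescued when the first 7
  whitespace-delimited abstract tokens match exactly (introductions often
  survive heavy revision), when the pre-colon title text matches exactly
  and both titles contain a colon (tool-name titles), or when the preprint
  has more than 10 authors and $s_U = 1$ (large author lists almost never
  coincide by chance, and Jaccard is size-blind);
* a **positive** classification is vetoed when neither title nor abstract
  similarity exceeds 0.999 and $s_U < 0.33$.

Among accepted candidates the one with the highest product $s_T \cdot s_A$
is returned (ties broken by ascending PMID); the product mirrors the
criterion used for hard-negative mining. The working assumption throughout
is that the highest-similarity paper *is* the published version; the
classifier's job is to decide whether that similarity is high enough.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| embedding dimension | 300 | sentence-vector size; 50 is plenty for the synthetic corpora and much faster |
| training sample fraction | 0.10 | share of titles/abstracts used to train each embedding model |
| `min_count` | 5 | tokens rarer than this are embedded purely from character n-grams |
| n-gram lengths | 3–6 | subword units backing out-of-vocabulary composition |
| `sample_t` | 1e-4 | frequent-word subsampling threshold during training |
| `top_k` | 100 | per-field retrieval depth |
| `very_high_sim` | 0.999 | similarity above which the author veto is bypassed |
| `author_veto_min` | 0.33 | minimum author Jaccard for a non-bypassed positive |
| `abstract_prefix_words` | 7 | abstract-prefix rescue length, in whitespace tokens |
| `large_authorset_min` | 10 | author count that must be *exceeded* for the author-set rescue |
| SVM | C = 1, RBF, gamma = 1/(3·Var x) | the common library default ("scale") |

All thresholds live in `rule_config()`; the embedding hyperparameters in
`train_embeddings()`.

## Embedding choices

The embedding trainer is a single-threaded skip-gram with negative
sampling (window 5, 5 epochs, 5 negatives, initial learning rate 0.05,
linear decay) with fastText-style hashed character n-gram buckets, so any
token — including unseen ones — has a vector. Determinism was preferred
over raw speed: with a fixed seed, training is bit-reproducible, which the
test suite relies on.

Two numerical choices deserve explanation:

* **Sentence composition.** A sentence vector is the *normalized average*:
  each token vector is scaled to unit norm before averaging, and the
  average is scaled to unit norm afterwards. Normalizing per token stops
  high-frequency, high-norm tokens from dominating the mean.
* **Common-component removal.** Word vectors trained on small, homogeneous
  corpora share one large direction (the well-known anisotropy of
  skip-gram spaces, extreme at this scale: without correction all
  abstract-to-abstract cosines exceed 0.999 and carry no signal). Token
  embeddings are therefore mean-centered — the unit-normalized vocabulary
  mean is subtracted from each unit token vector — before sentences are
  composed. This is the mean-only variant of standard embedding
  post-processing, applied identically to in-vocabulary and
  out-of-vocabulary tokens, and is recomputed from the stored vectors when
  a model is loaded.

Frequent-word subsampling (`sample_t = 1e-4`, the usual default) further
reduces the common component at the source.

## The synthetic world

`generate_corpus()` builds a labeled corpus: `n_pairs` true
preprint-paper pairs, `n_decoys` unrelated papers, `n_unpublished`
preprints with no published version. Texts are generated from topic
templates — each topic draws subject, method, organism and adjective words
from shared pools (a wide consonant-vowel syllable grammar, so synthetic
terms share few character n-grams, as real domain terms mostly do) plus a
unique tool name. Decoys draw from the same pools, which makes some of
them hard negatives. Defaults state the world the acceptance tests run in:

* 200 pairs / 300 decoys / 100 unpublished — desk scale, large enough for
  stable percentages;
* publication gap log-normal with median 199 days (a typical
  preprint-to-paper gap) and log-sd 0.6;
* 57% of true pairs carry a server-announced publication id (announced
  matches are roughly that share of published preprints in the wild);
* revision noise: per-token substitution at `text_sub_rate` (optionally
  growing linearly with the simulated gap via `gap_noise_slope`, which
  reproduces the inverse gap-similarity relationship); author edits at
  add/remove/flip rates (0.1 / 0.1 / 0.05 in the noisy acceptance
  scenarios — modest team churn plus occasional swapped name fields).

What the generator does **not** emulate: natural English (texts are slot
grammars over pseudo-words), realistic journal/DOI metadata, multiple
preprint versions, retractions, or collective authors. A green end-to-end
test therefore establishes that the pipeline's machinery — retrieval,
features, classifier, rules, evaluation — is correct and robust to the
modeled noise, not that the headline numbers on real corpora would be
reproduced. Conversely the printed-arithmetic acceptance targets (578/404)
are exact properties of the test-set construction flow and transfer as-is.

Hard negatives are mined exactly as the protocol dictates — for each
unannounced preprint, the corpus paper with the highest product of title
and abstract similarity — with the fixture ground truth standing in for
the manual curation that removed true matches.

## Numerical and degenerate-input conventions

* Dates: a missing day in a publication date becomes the 1st, a missing
  month January; season strings map to the season's first month (Spring =
  March, Summer = June, Fall/Autumn = September, Winter = December).
* Empty-vs-empty Jaccard is 0, not 1, so authorless records cannot match.
* Papers with absent abstracts get zero abstract vectors: they can enter
  the candidate set only through title rank, and their abstract similarity
  is 0 (flagged).
* Retrieval ties are broken by ascending PMID; zero-norm rows can never
  outrank a positive-similarity row.
* Metric denominators of zero yield `NA` ("undefined"), never 0.
* A wrong-PMID prediction on a true positive counts as a false positive
  only (the missed positive is reported separately as `wrong_pmid`), which
  keeps `tp + fp + fn + tn` additive over the evaluated preprints.
* McNemar: the chi-square statistic $(a-b)^2/(a+b)$ *and* the exact
  two-sided binomial p are both reported, because the exact test is named
  while the chi-square formula is printed; with $a + b = 0$ the statistic
  is reported as 0 with p = 1 and a no-evidence flag.
* SMO stops at a duality gap of 1e-6; the dual optimum is unique for the
  RBF kernel, so training is row-order invariant (asserted by test).

## Open design points, and the choices made

* *Multi-language records*: a paper tagged `{eng, fre}` passes the
  language filter — the rule is "contains eng", not "is only eng".
* *10% of papers or 10% of texts per field*: sampled per field (titles and
  abstracts pooled and sampled independently).
* *Union cap*: the candidate union is a true union (≤ 200), not capped at
  100; the narrower phrasing elsewhere is treated as a prose slip.
* *Veto scope*: the 0.33 author veto applies per candidate, removing it
  from contention before best-candidate selection.
* *Very-high bypass*: either title *or* abstract similarity above 0.999
  bypasses the veto.
* *Name splitting* for preprint author strings: final whitespace token is
  the last name; particles stay in the fore name. This is a stand-in for
  server-segmented names.
* *Group authors* (no last name) are dropped with a warning; the
  author-string format presumes a last name.
* *Ablations* re-train the decision layer on the restricted feature subset
  and disable rules whose features are absent; retrieval is unchanged.
* *Config format*: the run config is JSON rather than YAML — no YAML
  parser is available in the target environment, and JSON round-trips
  through the same library used everywhere else in the package.

## Known limitations

* The embedding trainer is deliberately small: single-threaded, dense
  updates, no hierarchical softmax; it is sized for desk-scale corpora
  (hundreds to tens of thousands of short texts), not full PubMed.
* Exhaustive scan retrieval is O(corpus) per query — correct and exact at
  the scales the package targets; no approximate nearest-neighbor index.
* One preprint maps to at most one paper; multi-paper outcomes
  (e.g. split publications) are out of scope.
* Author matching is exact on case-folded last names: no diacritic
  stripping, transliteration or initial expansion.
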