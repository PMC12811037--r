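---
title: "Measuring and simulating text-quality effects in clinical NLP pipelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and simulating text-quality effects in clinical NLP pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noteqc)
```

## The problem

Free-text progress notes — the running record nurses and carers keep about a
patient or resident — are written quickly, on shared keyboards, often by
staff for whom documentation is a secondary task. Two error classes dominate
in practice: misspellings (`overnite`, `bfast`) and missing whitespace
between words, typically at sentence boundaries (`unwell.Resident`). When
these notes feed a machine-learning pipeline (mortality or adverse-event
prediction from bag-of-words or embedding features), nobody usually measures
how much the noise costs. noteqc provides the instruments to measure it:

1. a **token-level error metric**: for one note,
   `error rate = erroneous whitespace tokens / total whitespace tokens`,
   with the corpus value the mean of per-note rates;
2. a **controlled corruption engine** that injects misspellings and
   whitespace merges at an exact target rate, with ground-truth annotations;
3. **detection/correction backends** (a dictionary reference implementation
   and a mockable adapter for external language-model services) plus their
   evaluation against ground truth;
4. the two standard **feature families** — unigram TF-IDF and mean-pooled
   token embeddings — and a **benchmark harness** that produces
   ROC-AUC-vs-error-rate degradation curves for a five-model suite.

Everything runs on a bundled synthetic note generator, so the full pipeline
is testable without access to restricted clinical corpora.

## The error metric and its scope

A note is split into whitespace tokens (maximal runs of non-whitespace);
each token is either erroneous or not. The metric deliberately ignores
grammatical errors and punctuation-only deviations: automated and manual
assessments disagree too much on grammar, while misspellings and merges can
be counted reliably. One fused token (`unwell.Resident`) counts as **one**
erroneous token. Notes with fewer than 5 tokens are excluded from corpus
aggregates (configurable `min_tokens`); very short notes are
near-telegraphic and rarely contain the error classes of interest. The
corpus summary uses the **population** standard deviation so replications
are bit-stable regardless of language or library.

## The corruption model

For a note with `n` whitespace tokens and target rate `r`, the error budget
is `k = round(r * n)` (round-half-to-even; no rounding rule is canonical, so
we pick one and state it). The budget splits between the two error types
either randomly — the misspelling count drawn uniformly from `{0, ..., k}` —
or by a fixed fraction (e.g. 0.4 gives a 4%/6% split at a 10% rate).

* **Whitespace merges** delete the space between tokens *i* and *i + 1*
  (rightward fusion). Merge sites are sampled without replacement, with
  weight 1.5 when either adjacent token carries punctuation and 1.0
  otherwise — matching the empirical observation that merges cluster at
  sentence boundaries. The target count is computed on the *original* token
  total; the post-hoc rate measured on the corrupted text therefore differs
  by at most `k_merge / n`, since each merge also shortens the note by one
  token.
* **Misspellings** are one seeded character edit (substitute / delete /
  insert / transpose at a random position) applied to an alphabetic token of
  length ≥ 3, retried until the variant is outside the forbidden set
  (normally the corpus dictionary). A rule engine rather than a generative
  model is used deliberately: the error *rate* is independent of who
  generates the misspelling, only the *style* differs, and a seeded rule
  engine is reproducible. An adapter contract exists for plugging in an
  external generative service.
* The two index sets are disjoint, and tokens adjacent to a merge site are
  ineligible for misspelling, so every annotation is unambiguous.

Every injected error yields one annotation carrying both the token's index
in the clean note and its index in the corrupted note's own tokenization
(merges shift subsequent indices; detectors operate on the corrupted text,
so evaluation needs the corrupted basis). Per-note RNG streams are derived
by hashing `(base_seed, rate, note_id)`, making every corpus version
reproducible note-by-note.

## Detection and correction

The dictionary detector flags tokens whose punctuation-stripped, lowercased
form is missing from a dictionary. The paired corrector tries, in order: a
two-way split into two in-dictionary words (preferring a cut right after
internal punctuation — undoing merges), then the unique dictionary word at
edit distance 1, then at distance 2; with no unique candidate the token is
left alone. Comparison strips boundary punctuation and case, consistent
with the metric's scope.

Correction is scored against the clean reference by re-tokenizing and
aligning token sequences with a minimal-edit dynamic program (corrections
can change token counts); the residual error rate is the fraction of
reference tokens not matched exactly, and
`pct_errors_corrected = 1 - residual / baseline`. The alignment-based
definition is our convention; no canonical recipe exists for re-scoring
corrected text.

The `llm_backend()` adapter is transport-agnostic: any
`function(prompt) -> completion` works, and tests use scripted mocks.
Detection completions must be a JSON array of flagged tokens; a token absent
from the note is treated as a backend error (real services hallucinate
errors that are not there — a failure mode the adapter surfaces instead of
silently absorbing).

## Feature representations

`fit_tfidf()`/`transform_tfidf()` implement unigram TF-IDF with the smoothed
idf dialect `idf(t) = ln((1 + N) / (1 + df_t)) + 1` and L2-normalized rows —
stated explicitly so any implementation reproduces the matrix bit-for-bit
(our test suite checks it against a brute-force oracle to 1e-12). The
feature tokenizer is the regular expression `\b[a-zA-Z]+\b`, lowercased:
purely alphabetic runs, digits and punctuation never yield features, and an
alphabetic run glued to a digit (`0400hrs`) yields nothing because no word
boundary exists there. Vocabulary variants: keep the 5,000 most frequent
tokens (total-count ordering, ties lexicographic), keep tokens with total
count strictly greater than 5, or keep everything. Whether "frequency"
means document frequency or total count is ambiguous in common usage; we
use total count and expose the threshold.

`embed_document()` mean-pools per-token vectors, skipping tokens the backend
cannot embed — the standard recipe for documents far longer than any
transformer context. `hash_embedding_backend()` supplies deterministic
pseudo-random unit vectors (hash-seeded, dimension 300 by default): distinct
tokens map to near-orthogonal directions, so a corrupted variant shares no
mass with its original — exactly the property that makes corruption hurt
static-vocabulary embeddings. Closed-vocabulary mode reproduces
word2vec-style OOV skipping; open mode embeds anything, emulating subword
coverage. Pretrained vector tables plug in through
`table_embedding_backend()`.

One consequence worth noting: merges at punctuation (`unwell.Resident`) are
*invisible* to the alphabetic feature tokenizer, which splits them back
apart; only letter-to-letter fusions and misspellings reach the feature
space. The whitespace-token error metric and the feature space react to
corruption differently by design.

## The benchmark harness

`run_degradation_experiment()` corrupts the corpus at each rate (0 = clean
baseline), assembles per-subject documents (notes concatenated in order with
single spaces), and for each seed draws a stratified 2/3–1/3 split.
Stratification is a deliberate choice: at ~12% prevalence, unstratified
splits of desk-scale corpora are unstable. Representations are fit on the
training split only — no test-set vocabulary leaks into the features. The
model suite is ridge logistic regression (glmnet), an RBF SVM (e1071), a
probability random forest (ranger), gradient boosting (xgboost) and a
single-hidden-layer MLP (nnet), all behind one seeded interface reporting
ROC-AUC (rank-sum formulation, ties counted half) plus precision/recall/F1
at threshold 0.5. By default the whole corpus is corrupted before splitting;
`corrupt_scope = "test_only"` covers the deployment regime where a clean-
trained model meets noisy input. `grid_search()` selects hyperparameters by
inner-split ROC-AUC, ties broken by grid order, and logs every grid point.

## The synthetic generator

`generate_corpus()` draws bag-of-words notes: subject labels are
Bernoulli(prevalence 0.118 by default — an ICU-mortality-like prevalence);
each of 20 signal words enters a note with probability 0.6 for cases and 0.2
for controls; background pseudo-words (600 by default) fill the note to a
length drawn from N(60, 20²), floored at 5 tokens; 15% of tokens get a
trailing `.` or `,`. There is deliberately no grammar: TF-IDF and mean
pooling are order-insensitive, so bag-level structure is sufficient for
what the benchmark measures. The default of one note per subject keeps the
note the unit of corruption and the document; multi-note concatenation is
exercised separately through `assemble_documents()`.

The vocabulary generator enforces pairwise Levenshtein distance **≥ 3** and
rejects words that concatenate two existing words. Distance ≥ 2 would
already guarantee single-edit misspellings are out-of-dictionary, but not
unique correction: with `d(a, b) = 2`, one edit of `a` can sit at distance 1
from both `a` and `b`, and the corrector would have to abstain. Distance 3
makes the original the *unique* distance-1 candidate, which is what makes
the misspelling-only round-trip exact. This separation is stronger than any
real lexicon (real data has `there/three`); the collision-free corpus
bounds what a dictionary method can achieve at its best, it does not
predict real-world accuracy.

## What the tests show — and don't

The acceptance suite checks, at desk scale on one CPU: exact injection
fidelity (every note's annotation count equals `round(r × n)` for rates
5–20% on 1,000 notes); the unbiased type split and the 1.5× punctuation
preference (10,000 simulated plans, 3-σ binomial bands); exact detector
recovery on collision-free pairs and smooth, monotone degradation under
nested dictionary dropout; the exact misspelling-only correction
round-trip; oracle equivalence of TF-IDF and ROC-AUC to 1e-12; strict
vocabulary inflation with the corruption rate; a degradation curve on the
reference corpus (n = 1,000, 5 seeds) in which TF-IDF + logistic loses
≥ 0.02 ROC-AUC between clean and 20% corruption with a non-increasing
five-point curve and the hash-embedding pipeline degrades at least as fast;
and chance-level calibration (each model × representation cell's mean
ROC-AUC over 10 seeds within [0.4, 0.6]) on a null corpus (n = 400) whose
signal probabilities are equal. "Within [0.4, 0.6] across seeds" is
interpreted as a condition on the per-cell mean: individual-seed AUCs on a
~130-document test set have a standard error near 0.09, so a per-seed
band would mostly measure test-set size.

Passing these says the *machinery* is correct and the qualitative
degradation story holds under controlled conditions. It does not certify
real-data effect sizes: synthetic notes have no grammar, no informal
abbreviations, no valid-word typos, and a cleanly separable signal
vocabulary. On real corpora the clean-performance ceiling, the error mix
and the dictionary quality all differ.

## Numerical choices and degenerate inputs

* Round-half-to-even for error budgets; budgets computed on original token
  counts.
* Population SD everywhere a spread is reported.
* All-OOV or stop-word-only documents map to zero rows (TF-IDF) or zero
  vectors (embeddings) rather than errors; downstream models see them as
  empty evidence.
* Empty token lists make the error rate undefined (an error, not NaN);
  zero-baseline correction evaluation is likewise refused.
* Ties in ROC-AUC scores count one half; `roc_auc(s) + roc_auc(-s) = 1`
  holds exactly for tie-free scores.
* Capacity errors (too few eligible tokens for the requested budget) report
  the achievable budget instead of silently under-injecting.

## Limitations

Only two error classes are modeled; informal abbreviations, OCR noise and
grammatical errors are out of scope. The dictionary corrector abstains on
ambiguity rather than ranking candidates by frequency or context. The hash
backend reproduces embedding geometry, not semantics: tasks where synonymy
matters will behave differently with pretrained vectors. Chain merges
(adjacent merge sites fusing three tokens) are corrected only partially by
the two-way split rule.
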