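---
title: "Scoring generated diagnoses and meta-evaluating automated metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring generated diagnoses and meta-evaluating automated metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dxeval)
```

## The problem

When a language model writes a differential diagnosis from a progress note,
string-overlap metrics see only how much the output resembles a reference
list. Clinicians care about different things: whether each proposed
diagnosis is a real diagnosis, whether it is plausible for this patient or
a hallucination, how specific it is, what was omitted, and whether the
model's stated reasoning holds up. `dxeval` implements a branched human
annotation instrument for these judgments, collapses them into two
record-level composites — Diagnostic Accuracy (D) and Diagnostic Reasoning
(R) — and provides the statistics needed to ask how well any automated
metric tracks them.

## The scoring model

Each generated output (one per progress note) is annotated at three levels:

* **per diagnosis**: Accuracy (1–5), then — only if the diagnosis is judged
  accurate — Plausibility (1–5), then — only if plausible — Specificity
  (0–5);
* **per output**: Omission (0–5, the maximum meaning nothing was omitted)
  and, only when an omission occurred, Uncertainty (0–5), which separates
  omissions the model should have avoided (it had the information) from
  those it could not;
* **per reasoning sentence**: Comprehension, Rationale and Recall (1–5),
  each phrased as *evidence of a problem*, so 1 is best; plus a binary
  output-level reasoning Omission (the output lacks any explanation).

Scoring is a fixed pipeline: **validate → impute → invert → average**.
Validation enforces ranges and the branching rules. Imputation replaces
every absent value that branching explains with 0 — an inaccurate diagnosis
contributes zeros to the plausibility and specificity means rather than
being dropped. Inversion maps the three reasoning components to `6 - x` so
that higher is uniformly better. Then, with \(\bar p_i, \bar s_i\) the means
over all diagnoses of record \(i\), \(\bar o_i\) the mean of the omission
and (imputed) uncertainty ratings, and \(\bar c_i, \bar e_i, \bar a_i\) the
post-inversion means of comprehension, recall and rationale:

\[
D_i = \frac{\bar p_i + \bar s_i + \bar o_i}{15}, \qquad
R_i = \frac{\bar c_i + \bar e_i + \bar a_i}{15}.
\]

Both composites live in \([0, 1]\).

```{r score-example}
rec <- record_annotation(
  "R001",
  diagnoses = list(
    diagnosis_item("sepsis from pneumonia", accuracy = 5,
                   plausibility = 5, specificity = 4),
    diagnosis_item("generalized fatigue", accuracy = 2)   # gated out
  ),
  omission = 3, uncertainty = 2,
  reasoning_sentences = list(
    reasoning_sentence_item("the note shows fevers and hypotension",
                            comprehension = 1, rationale = 2, recall = 1)
  )
)
score_record(rec)
```

### Design choices the instrument description leaves open

The instrument's published description leaves several details open; the
package fixes them as follows (all configurable in `framework_config()`):

* **Gates.** "Classified as accurate" means an Accuracy rating of 4 or 5 —
  the agreement region of a 5-point Likert scale; the plausibility gate is
  the same. There is no other natural reading of a Likert agreement item.
* **Zero-based scales.** Specificity, Omission and Uncertainty run 0–5
  (their zero doubles as the imputation value); Accuracy, Plausibility and
  the reasoning components run 1–5; the output-level reasoning Omission is
  binary and kept as {0, 1}.
* **Accuracy is a gate, not a summand.** The D formula contains only
  \(\bar p, \bar s, \bar o\); Accuracy influences D solely by deciding which
  diagnoses contribute imputed zeros.
* **\(\bar o_i\) is the mean of exactly two values**, omission and
  uncertainty-after-imputation.
* **A consequence worth knowing:** when nothing was omitted
  (Omission = 5), Uncertainty is branched out and imputed to 0, so
  \(\bar o_i = 2.5\) and the largest D a branch-consistent record can reach
  is \(12.5/15 \approx 0.833\). This ceiling is a property of
  imputation-to-zero combined with conditional items, not a bug; D = 1 is
  reachable only by value combinations that violate the branching rules.
* **Records without reasoning sentences** get `R = NA` and are excluded
  (with a message) from cohort R summaries.
* **The output-level reasoning Omission** is reported in the component
  frequency table but does not enter R, whose formula lists only the three
  sentence-level means.

## The automated metrics

All metrics compare a candidate text with a reference text at the output
level (multi-diagnosis lists are joined with a configurable separator;
`" ; "` by default so the join never collides with the `#` list syntax).

* `rouge_l()` — longest-common-subsequence F-score, single-sequence LCS,
  \(\beta = 1\); tokenization is lowercase, punctuation stripped,
  whitespace split. Outputs here are short diagnosis strings, so no
  summary-level union-LCS is needed.
* `greedy_match_fscore()` — BERTScore-style greedy matching: each token's
  maximum cosine similarity to the other side, averaged into precision and
  recall. No IDF weighting and no baseline rescaling are applied — both
  are deliberate simplifications, and the embedding backend is pluggable
  (`embedding_provider()`): SapBERT-, clinicalBERT- or PubMedBERT-style
  encoders slot in through the same contract the bundled hashed and
  one-hot toy providers use.
* `concept_fscore()` — set precision/recall/F over concept identifiers
  (CUI-style) extracted by a pluggable `concept_extractor()`; the bundled
  extractor is a longest-match dictionary over a packaged lexicon, while
  real terminology services are external adapters.
* `graph_embedding_fscore()` — the same greedy matching applied to
  *concept* embeddings rather than token embeddings. A knowledge-graph
  "scorer that computes an F-score" admits several readings; greedy
  maximum-cosine matching over concept embeddings is the one implemented,
  and it is documented as an interpretation.
* `logprob_score()` — BARTScore-style sum of candidate token
  log-probabilities given the reference, through a `conditional_scorer()`;
  a reference-trained bigram model and a uniform model are bundled.
* Learned-regression metrics (COMET- or BLEURT-style) are **never
  reimplemented**: `adapter_metric()` wraps whatever external call returns
  a float per pair, and unbound adapters are skipped with a warning rather
  than silently zeroed.

## The meta-evaluation statistics

`correlation_table()` produces one row per metric and human-score
component (D, plausibility, specificity, omission) with Spearman, Pearson
and Kendall \(\tau_b\) coefficients, intervals, p-values, and a paired
Wilcoxon signed-rank test. Choices that matter:

* **Unit of analysis** is the record: one D and one metric value per note
  output. Diagnosis-level analysis is possible by scoring per-diagnosis
  pairs and passing them as records.
* **Confidence intervals.** Pearson uses the Fisher z transform. For the
  rank correlations no standard method is simultaneously exact and tidy,
  and published rank-correlation intervals in this literature are often
  implausibly narrow for their sample size, so the package reports either
  a seeded percentile bootstrap (default, 2,000 resamples) or an adjusted
  Fisher z (Bonett–Wright for Spearman, Fieller–Hartley–Pearson for
  Kendall), always tagged with the method used.
* **Kendall \(\tau_b\)** is computed from the cumulative contingency table
  with the full tie correction, and its p-value from the tie-corrected
  normal approximation of \(C - D\).
* **Wilcoxon signed-rank** discards zero differences, uses midranks, and
  is exact (a subset-sum recursion over the signed-rank null) for 12 or
  fewer non-zero differences, switching to a tie- and
  continuity-corrected normal approximation beyond that. Because
  log-probability metrics are unbounded, `correlation_table()` min-max
  rescales each metric to \([0, 1]\) (and divides 0–5 component means
  by 5) before pairing; rank correlations are unaffected by either
  rescaling.
* **Comparing metrics.** `compare_dependent_correlations()` tests
  \(\rho(\mathrm{human}, A) = \rho(\mathrm{human}, B)\) with Steiger's z
  for overlapping dependent correlations (pooled Williams-type estimate),
  with a seeded percentile bootstrap as the cross-check.
* **Multiple testing** is off by default (raw p-values are reported);
  Holm adjustment is a flag.
* **Interrater agreement** uses `cohen_kappa()` with optional linear or
  quadratic weights and a 0.70 pass threshold, the usual adjudication bar
  for this kind of annotation effort.

## The synthetic cohort generator

Real cohorts of this kind require credentialed clinical notes and
clinician raters, so the package ships a generator that emulates the
*shape* of such a study and plants a known ground truth:

* 186 note-level records; 3–5 diagnoses and 3–6 reasoning sentences per
  record (about 750 diagnoses and 840 sentences in expectation);
* a toy concept lexicon (unique CUI-like IDs, 1–3 surface variants,
  specificity tiers) from which reference and candidate lists are drawn;
* a latent quality \(q_i \sim \mathrm{Beta}(2, 2)\) per record that drives
  the Likert responses through affine mean maps discretized from a normal
  with `noise_sd` (default 0.7, under one Likert step);
* a mixing parameter \(\rho^*\): the candidate/reference concept-overlap
  target is \(|\rho^*| \cdot q_i + (1 - |\rho^*|) \cdot u_i\) (direction
  flipped for negative \(\rho^*\)), so \(\rho^* = 0\) makes text overlap
  independent of the human scores and larger \(\rho^*\) couples them
  monotonically. Response means depend on \(q\) only — overlap enters the
  judgments solely through this mixing — which is what makes the planted
  null exactly null.

The affine maps (accuracy and plausibility `3.4 + 1.6q`, specificity
`2 + 3q`, omission and uncertainty `5q`, raw reasoning `3 - 2q`) were
calibrated once so that a mid-quality cohort shows marginals of the order
seen when clinicians rate LLM-generated diagnoses — roughly 80% of
diagnoses accurate, two thirds plausible, 40% specific, high reasoning
scores — while the noiseless extremes remain exact: at \(q = 1\) every
component sits at its maximum (D reaches its branch-consistent ceiling of
\(12.5/15\)) and at \(q = 0\) every gate fails and D is 0.

What the generator does **not** emulate: real clinical language (sentences
are templated around lexicon surfaces), rater idiosyncrasies and
disagreement, non-monotone response styles, or any clinical validity of
the notes. Passing tests therefore demonstrate that the machinery is
correct and that planted structure is recovered — not that any particular
metric aligns with real clinician judgment.

```{r generator, eval = FALSE}
cohort <- generate_cohort(generator_config(seed = 7, rho_star = 0.5))
scored <- score_cohort(cohort$records)
pairs  <- generation_pairs(cohort$generations)
mt     <- run_metric_suite(pairs, metric_registry(lexicon = cohort$lexicon))
correlation_table(scored$scores, mt, components = "D")
```

## Numerical and degenerate-input conventions

* Undefined precision or recall (division by zero: empty token or concept
  sets) is reported as 0 with a warning, and F as 0.
* Cosine similarity against a zero vector is 0; concepts without an
  embedding back off to the zero vector with a warning.
* Constant series make Pearson/Spearman/Kendall undefined: reported as
  `NA` with a warning, never as 0.
* All-zero paired differences give Wilcoxon p = 1 with a degenerate flag;
  two constant raters on the same label give kappa = 1 with a degenerate
  flag.
* Scores are kept at full double precision; oracle-equivalence tests hold
  to 1e-12.
* Every stochastic component (generator, bootstrap, hashed embeddings)
  is seeded, and seeded draws restore the caller's RNG state, so whole
  report bundles reproduce byte-identically.

## Validation scale

The test suite validates the scoring engine against an independent flat
recomputation on 500 random records plus 1,000 monotonicity
perturbations; LCS against exhaustive subsequence enumeration on 1,000
random pairs; greedy matching against set-overlap on 1,000 duplicate-free
pairs; \(\tau_b\) against explicit pair counting on 200 tied series up to
n = 200; exact Wilcoxon p against full \(2^n\) sign enumeration; the
type-I error of all four tests under 1,000 null simulations at n = 186;
and \(\rho^*\) recovery over 20 seeds at each of
\(\rho^* \in \{0, 0.2, 0.5, 0.8\}\). These sizes were chosen to give tight
property checks at interactive runtimes.

## Limitations

* The branching gates and scale zero-points are best readings of an
  instrument whose full anchor texts are not machine-readable; both are
  configurable rather than hard-coded.
* The greedy-matching reading of the knowledge-graph F-score is one
  interpretation among several defensible ones.
* The bundled backends are toys by design; conclusions about real
  clinical encoders require plugging real models into the provider
  contracts.
* Rank-correlation intervals are method-dependent; the report always
  carries a `ci_method` tag and offers both families.
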