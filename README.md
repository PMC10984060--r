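# dxeval

Human-evaluation scoring and automated-metric meta-evaluation for
language-model generated medical diagnoses.

When an LLM writes a differential diagnosis from a clinical progress note,
the field's default metrics (ROUGE and friends) measure string resemblance
to a reference list — not whether the diagnoses are real, plausible,
specific, complete, or well reasoned. `dxeval` is for researchers
evaluating clinical NLG systems: it implements a branched human annotation
instrument and its composite scores, the standard reference-based
automated metrics over pluggable clinical backends, and the statistics
needed to quantify how well any automated metric tracks human judgment.

## The model

Each generated output is annotated per diagnosis (Accuracy 1–5, then —
only for accurate diagnoses — Plausibility 1–5, then — only for plausible
ones — Specificity 0–5), per output (Omission 0–5 and, only when an
omission occurred, Uncertainty 0–5), and per reasoning sentence
(Comprehension, Rationale, Recall, each 1–5 with 1 = no evidence of a
problem). Branched-out values are imputed to 0; the reasoning components
are inverted (6 − x); then for record *i*:

    D_i = (p̄_i + s̄_i + ō_i) / 15        Diagnostic Accuracy
    R_i = (c̄_i + ē_i + ā_i) / 15        Diagnostic Reasoning

where p̄, s̄ are the plausibility and specificity means over **all**
diagnoses (imputed zeros included), ō is the mean of omission and
uncertainty, and c̄, ē, ā are the inverted means of comprehension, recall
and rationale. Both scores lie in [0, 1].

The metric suite provides `rouge_l()` (LCS F-score),
`greedy_match_fscore()` (BERTScore-style greedy cosine matching over any
`embedding_provider()`), `concept_fscore()` (set F over extracted
CUI-style concept IDs), `graph_embedding_fscore()` (greedy matching over
concept embeddings), `logprob_score()` (BARTScore-style conditional
log-probability), and `adapter_metric()` for external learned-regression
scorers (COMET/BLEURT-style), which are integrated but never
reimplemented.

The meta-evaluation layer (`correlation_table()`, `pearson_r()`,
`spearman_rho()`, `kendall_tau_b()`, `wilcoxon_signed_rank()`,
`compare_dependent_correlations()`, `cohen_kappa()`) reports coefficients
with confidence intervals (seeded bootstrap or adjusted Fisher z), exact
small-sample Wilcoxon p-values, Steiger's z for comparing dependent
correlations, and weighted kappa against a 0.70 agreement bar.

A seeded synthetic cohort generator (`generate_cohort()`) emulates the
shape of a clinician-annotated study — 186 records, 3–5 diagnoses and 3–6
reasoning sentences each — with a latent quality per record and a tunable
correlation `rho_star` between quality and candidate/reference concept
overlap, so the whole pipeline is testable with known ground truth and no
clinical data.

## Worked example

```r
library(dxeval)

rec <- record_annotation(
  "R001",
  diagnoses = list(
    diagnosis_item("sepsis from pneumonia", accuracy = 5,
                   plausibility = 5, specificity = 4),
    diagnosis_item("generalized fatigue", accuracy = 2)   # fails the gate
  ),
  omission = 3, uncertainty = 2,
  reasoning_sentences = list(
    reasoning_sentence_item("the note shows fevers and hypotension",
                            comprehension = 1, rationale = 2, recall = 1)
  )
)
score_record(rec)
#>   record_id n_diagnoses n_sentences p_bar s_bar o_bar c_bar e_bar a_bar     D     R
#> 1 R001                2           1   2.5     2   2.5     5     5     4 0.467 0.933
```

The second diagnosis failed the accuracy gate, so its plausibility and
specificity enter the means as imputed zeros: p̄ = (5 + 0)/2 = 2.5,
s̄ = (4 + 0)/2 = 2, ō = (3 + 2)/2 = 2.5, giving D = 7/15 ≈ 0.467. The
single reasoning sentence had almost no evidence of problems (raw 1, 2, 1
→ inverted 5, 4, 5), giving R = 14/15 ≈ 0.933.

End to end on a synthetic cohort with planted quality–overlap correlation
0.5:

```r
cohort <- generate_cohort(generator_config(seed = 7, rho_star = 0.5))
scored <- score_cohort(cohort$records)
scored$summary
#>   score                    n median   q25   q75
#> 1 diagnostic_accuracy    186  0.553 0.379 0.717
#> 2 diagnostic_reasoning   186  0.8   0.733 0.855

pairs <- generation_pairs(cohort$generations)
mt    <- run_metric_suite(pairs, metric_registry(lexicon = cohort$lexicon))
correlation_table(scored$scores, mt, components = "D", seed = 1)
#>     metric_name spearman spearman_lo spearman_hi pearson kendall wilcoxon_p
#> 1       rouge_l   0.3193      0.1785       0.447  0.3016  0.2222   1.04e-07
#> 2  embed_greedy   0.3819      0.2474       0.498  0.3948  0.2641   1.30e-07
#> 3       logprob   0.0746     -0.0673       0.221  0.0653  0.0474   1.29e-06
#> 4     concept_f   0.4192      0.2984       0.539  0.4350  0.3044   8.51e-02
#> 5 graph_embed_f   0.3970      0.2830       0.506  0.4186  0.2668   8.27e-01
```

Concept-aware metrics track the planted quality signal more strongly than
surface overlap, and the log-probability metric barely at all — the
pattern this kind of meta-evaluation is designed to expose. The
`wilcoxon_p` column asks a different question (whether the paired central
tendencies differ after rescaling), so a metric can correlate well yet
still sit on a different scale.

A thin command-line front end over the same functions lives in
`inst/cli/dxeval.R` with subcommands `simulate`, `score`, `metrics`,
`correlate`, `agreement` and `run`.

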