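# littriage

Semi-automatic triage of biomedical literature for living systematic
reviews. Publications arrive faster than human curators can screen them;
`littriage` provides the machinery to classify each record (title,
abstract, source) into a nested study-design taxonomy, to combine several
imperfect classifiers into an ensemble that is more accurate than any
member, and to trade coverage for confidence by letting the ensemble
abstain on documents it is unsure about.

## The model

The label space is a three-level hierarchy: 22 mutually exclusive
**sub-subclasses** (case report, cohort study, modelling study, ...)
nested into 3 **subclasses** (EPI — epidemiologic study designs, BASIC —
laboratory research, OTHER) nested into 2 **classes** (ORIGINAL research
vs NON-ORIGINAL material). A classifier outputs, per document, a
probability distribution *p* over the 22 leaves; predictions at coarser
levels roll up by summation,

  P(label L) = Σ_{leaf ℓ below L} p_ℓ,

and the predicted category at any level is the argmax of the rolled-up
distribution.

Given M member classifiers, two ensembles are provided:

- **probability sum** — score(L) = Σ_m P_m(L); always yields a unique
  prediction;
- **voting with abstention** — model m votes for its argmax label only if
  that label's probability reaches a per-vote threshold t_v; the ensemble
  decides a label when its tally is the unique maximum and reaches the
  vote threshold — a static t, or a dynamic majority (⌊v/2⌋+1) or
  unanimity (v) threshold recomputed from the v non-abstaining voters —
  and otherwise returns the distinguished UNKNOWN outcome. The fraction
  of decided documents is the **coverage**.

The evaluation battery covers one-vs-rest precision/recall/F1 (micro and
macro averaged), confusion matrices per level, macro one-vs-rest AUC-ROC
with percentile-bootstrap confidence intervals (n = 2000 resamples),
McNemar paired significance tests, ranking metrics P@k, R@k and MAP@k
(single relevant label, so AP@k = 1/rank when the truth is in the top k),
precision/recall curves, and a k-vote grid scanning (rule, t, t_v)
configurations with decided-only metrics and coverage.

For interpretability, integrated gradients attribute a scorer's output to
input features along a straight-line path from an empty-document
baseline; sub-word attributions merge into word scores (mean over
pieces), words lemmatize and pool across documents (mean over
occurrences), and the top-20 positive-impact lemmas with ≥ 5 occurrences
summarize what drives each subclass prediction.

Because the original annotated collection and its five fine-tuned
transformer classifiers are not required at desk scale, the package ships
a reference multinomial ridge classifier on token counts (any
leaf-probability model can stand behind the same contract) and synthetic
generators: a corpus generator with class-conditional signature
vocabulary and realistic label imbalance, and a committee simulator with
configurable per-model accuracy, inter-model error correlation, and
intra-subclass confusion preference.

## Worked example

```r
library(littriage)

tax <- default_taxonomy()
tax
#> <taxonomy> COAP study-design taxonomy: 2 classes, 3 subclasses, 22 sub-subclasses [3c507bc0]

# synthetic corpus with the collection's label imbalance, and a simulated
# 5-member committee of ~0.8-accurate classifiers over its true labels
corpus    <- generate_corpus(corpus_config(n_docs = 2000, seed = 42))
committee <- simulate_predictions(corpus$label, tax,
                prediction_config(per_model_accuracy = c(0.78, 0.80, 0.82, 0.80, 0.79),
                                  agreement = 0.3, seed = 42))

# probability-sum ensemble at the subclass level
psum      <- probability_sum_ensemble(committee, tax, "subclass")
truth_sub <- ancestor(tax, corpus$label, "subclass")
rep <- metrics_by_label(truth_sub, psum$label, level_labels(tax, "subclass"))
rep$per_label[, c("label", "precision", "recall", "f1")]
#>   label precision recall    f1
#> 1 epi       0.836  1     0.910
#> 2 basic     0.982  0.857 0.915
#> 3 other     1      0.693 0.819
round(rep$micro, 3)
#> precision    recall        f1
#>     0.887     0.887     0.887
```

Micro F1 0.887 is the committee's pooled accuracy when every document
must be decided. Static unanimity voting abstains on contentious
documents and buys precision on the decided subset:

```r
dec <- voting_ensemble(committee, tax, "class", voting_config(t = 5, t_v = 0.5))
coverage(dec)
#> [1] 0.688
decided <- dec$label != "UNKNOWN"
cts <- contingency(ancestor(tax, corpus$label, "class")[decided],
                   dec$label[decided], "original")
round(c(precision = precision_score(cts), recall = recall_score(cts),
        f1 = f1_score(cts)), 3)
#> precision    recall        f1
#>     0.986     1.000     0.993
```

On the 68.8% of documents all five members agree about, detection of
original research reaches F1 0.993. Ranking view of a single member:

```r
ranking_metrics(corpus$label, committee$matrices[[1]], tax, ks = c(1, 3))
#>       k p_at_k r_at_k map_at_k
#> 1     1  0.784  0.784    0.784
#> 2     3  0.268  0.806    0.793
```

P@1 = R@1 = MAP@1 by construction; R@3 says the correct sub-subclass is
among the top three suggestions for 80.6% of documents.

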