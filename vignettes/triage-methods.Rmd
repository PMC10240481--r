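---
title: "Hierarchical triage of biomedical literature: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical triage of biomedical literature: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(littriage)
```

## The problem

Living systematic reviews keep a curated knowledge base of published
evidence continuously up to date. The bottleneck is screening: every new
record (title, abstract, source database) must be assigned to a study
design category before reviewers can prioritize it. `littriage`
implements the computational side of a semi-automatic triage workflow: a
nested label taxonomy, probabilistic classifiers behind a uniform
contract, two ensembling strategies, an evaluation battery, and
attribution tools that surface which words drive a prediction.

## Taxonomy and roll-ups

The default taxonomy is the COAP living-evidence scheme: 22 sub-subclass
leaves nested into the EPI, BASIC and OTHER subclasses, themselves nested
into the ORIGINAL and NON-ORIGINAL classes. Taxonomies are declarative
JSON documents (`load_taxonomy()` / `write_taxonomy()`), so other review
projects can substitute their own scheme; every derived artifact carries
a structural fingerprint and probability-matrix files repeat the leaf
order in their header, because silent column misalignment is the main
corruption risk in a file-based pipeline.

The collection the default scheme was built for uses both the
"modeling" and "modelling" spellings for the within-host modelling
leaf; the packaged document standardizes on "modelling" and records the
other spelling in an `alias` field.

Leaf probabilities roll up to a coarser level by summing over each
ancestor's descendant leaves; counts roll up the same way. Both
operations conserve their totals, and `roll_up_distribution()` enforces
its contract (nonnegative entries, unit sum within 1e-9) rather than
silently renormalizing, so an ill-formed matrix fails at the boundary.

Predictions at any level take the argmax of the rolled-up distribution.
Exact ties are broken toward the earlier label in declaration order — an
arbitrary but fixed rule chosen for bit-reproducibility; ties have
measure zero for real-valued probabilities and only arise with
hand-constructed inputs.

## The reference classifier

The five fine-tuned transformer models the triage workflow was designed
around are deliberately out of scope here: every downstream computation
is classifier-agnostic, needing only a documents × leaves probability
matrix. The package therefore ships a reference classifier that is cheap,
deterministic and learns exactly the class-conditional lexical signal the
attribution module later inspects: multinomial logistic regression with a
ridge penalty on lowercased word-count features (`glmnet`). The penalty
is selected on the dev set by micro F1 (equal to accuracy for
single-label data) along glmnet's warm-started path; the path's length
(`nlambda`, default 15) and depth (`lambda_min_ratio`, default 1e-3) are
the tunable knobs. Class probabilities are computed from the linear
predictors with an overflow-safe softmax, since naive exponentiation
overflows on long documents.

Leaves absent (or singleton) in a training fold are excluded from the fit
with a warning — the model can never predict them and reports exactly
zero probability; a degenerate single-class training set yields a
point-mass model. Persistence (`save_baseline()`) writes plain-text JSON
(vocabulary, coefficients, taxonomy fingerprint) and prediction under a
mismatched taxonomy is refused.

Input text is the title, abstract and source concatenated in that order
with single spaces. Records lacking a title or abstract are excluded
(`filter_incomplete()`), with the exclusion reported per document; a
missing source merely contributes nothing. Upstream metadata imputation
is an acquisition concern and out of scope.

## Cross-validation protocol

`kfold_split()` produces k folds whose test sets are disjoint and tile
the corpus (k = 5 by 20% test in the default protocol; train and dev take
70% and 10%). Splits are stratified by leaf label by default — the
protocol itself does not require stratification and a label-blind mode is
exposed, but with leaves as rare as 0.5% of the collection an
unstratified split can lose a leaf from a fold entirely. Per-stratum
remainders are assigned to the currently smallest folds so global fold
sizes stay exact; leaves with fewer labeled documents than k relax
stratification with a warning. `run_crossval()` wires the whole loop and
averages fold metrics with equal weight (the test folds are equal-sized
by construction), recording config, seed and taxonomy fingerprint in a
manifest for bit-identical reruns.

## Ensembles and abstention

- **Probability sum**: per level label, the unnormalized sum of the
  members' rolled-up probabilities (range [0, M]); an option divides by
  M for plotting. Always decides.
- **Voting**: a member votes for its rolled-up argmax iff that label's
  probability is ≥ t_v (inclusive, so the binary-level guarantee at
  t_v = 0.5 holds together with the tie-break); otherwise it abstains. A
  label is decided iff its tally is the *unique* maximum and reaches the
  effective threshold: static t, or — under dynamic rules — majority
  ⌊v/2⌋+1 or unanimity v of the v non-abstaining voters. Anything else
  is UNKNOWN. Static t is an absolute tally threshold regardless of
  abstentions; that makes static and dynamic rules coincide when nobody
  abstains and keeps the two notions separable in the k-vote grid.

Coverage (decided fraction) is monotone non-increasing in t for fixed
votes. It is also non-increasing in t_v whenever t ≥ ⌈(M+1)/2⌉, where a
winning tally is automatically unique; at lower t, raising t_v can break
a tie and *create* a decision, which is why the package tests
monotonicity only in the guaranteed regime.

## Evaluation battery

One-vs-rest contingency counts define precision, recall, F1 and
false-positive rate; zero denominators yield 0 (and F1 = 0 when tp = 0),
keeping macro averages defined for never-predicted rare leaves. Micro
averages pool counts (equal to accuracy for single-label data); macro
averages are unweighted label means. AUC-ROC is computed per label by an
explicit threshold sweep with trapezoidal integration and macro-averaged
one-vs-rest across labels present in the truth (the averaging scheme for
a single per-level AUC is otherwise underdetermined; macro is the
recorded choice). Confidence intervals use the percentile bootstrap
(n = 2000 resamples, 2.5/97.5 percentiles) with undefined resamples
redrawn and counted. McNemar's paired test uses the exact two-sided
binomial on the discordant counts when b + c < 25 and the
continuity-corrected chi-square ((|b−c|−1)²/(b+c)) otherwise; the switch
point is configurable since both variants are standard.

Ranking metrics exploit the single-label structure: with the truth at
rank r, a document contributes 1/k to P@k and 1 to R@k when r ≤ k, and
AP@k = 1/r (relevant-set size 1). Hence P@1 = R@1 = MAP@1, R@(number of
leaves) = 1, and P@k ≤ 1/k.

Metrics over ensemble decisions with abstention are computed on the
decided subset only, with coverage reported alongside (`kvote_grid()`);
a strict mode counting UNKNOWN as wrong is available for sensitivity
analysis. Attribution toward word lists uses the *predicted* subclass
(the quantity the model actually produced); a flag could equally target
the annotated one.

## Integrated gradients and word impact

`integrated_gradients()` implements the path-integral attribution with a
midpoint Riemann discretization: attribution_i = (x_i − baseline_i) ·
mean over path points of ∂score/∂x_i. For linear scorers this is exact at
any step count; in general the attributions sum to score(x) −
score(baseline) up to O(steps⁻²) error (the completeness axiom), which
the tests verify at steps ∈ {10, 50, 200}. The baseline input is the
all-zero count vector — an empty document — chosen as the natural
"absence of evidence" reference.

For the reference classifier the scorer is the rolled-up probability of
a target label with an analytic softmax gradient, and each vocabulary
feature is already a whole word; the sub-word → word merge
(`word_scores_from_subwords()`, mean over flagged continuation pieces)
exists for ingesting precomputed transformer token attributions from
file. Word scores lowercase, lemmatize (a small deterministic suffix
stripper by default; any string map can be plugged in) and pool across
documents by arithmetic mean; the reported list keeps the top 20
positive-impact lemmas with at least 5 occurrences, filtering
one-off high scores that do not generalize.

## Synthetic data: what it emulates, and what it does not

`generate_corpus()` emulates the *structure* of an annotated living
evidence snapshot: heavily imbalanced leaf proportions (default: the
packaged collection's, 0.5%–27.6%), three text fields, four source
databases, and class-conditional lexical signal — each leaf owns
`signature_tokens_per_leaf` private tokens and each content token is a
signature draw with probability `signal_strength` (default 0.7, enough
for the reference classifier to reach high but not saturated accuracy),
else a shared background token. Titles draw 5–15 tokens and abstracts
40–120, matching typical field lengths. It does not emulate grammar,
topical correlation between leaves, or annotation noise — so passing
tests show the pipeline's correctness and the classifier's capacity to
exploit lexical signal, not performance on real abstracts.

`simulate_predictions()` emulates a committee of M = 5 imperfect
classifiers: each member's modal label equals the truth with its
configured accuracy; error events correlate across members through a
shared latent draw mixed in with weight `agreement` (default 0.3 —
real co-trained models err on overlapping hard documents); erring
members choose a confusable leaf preferring the same subclass 3:1,
reproducing the intra-subclass confusion block structure observed in
study-design classifiers; and rows are Dirichlet with weight
`concentration` (default 20) on the modal leaf and 1 elsewhere, the
single knob governing how often per-vote thresholds trigger abstention.
With independent errors at accuracy 0.8, 3-of-5 majority voting has
closed-form accuracy Σ_{j≥3} C(5,j) 0.8^j 0.2^{5−j} ≈ 0.942, which the
simulation reproduces within ±0.02 — the quantitative testbed for the
ensemble module.

## Numerical choices and degenerate inputs

- Probability rows must sum to 1 within 1e-6 (matrix contract) and 1e-9
  (roll-up contract); violations are errors, not silent fixes.
- Argmax and top-tally ties break toward the earlier label; ranking ties
  break by leaf order (stable sort).
- Empty corpora predict empty matrices; empty decision sets make
  `coverage()` an error rather than NaN; zero-decided k-vote rows carry
  coverage 0 and NA metrics.
- Bootstrap resamples on which a metric is undefined are redrawn with a
  hard cap, and the redraw count is reported.
- All randomness flows through explicit integer seeds; generators and
  bootstrap results are bit-reproducible.

## Problem sizes in the tests

The suite exercises the oracle equivalences exhaustively where feasible
(all 3^5 vote patterns; all 243 abstention patterns for dynamic rules)
and uses simulation sizes chosen for stable assertions at desk scale:
n = 5000 documents for simulator parameter recovery and ensemble lift
(±0.02 assertions), n = 2000–3000 for random-baseline identities,
corpora of 200–1200 documents for classifier fits. The acceptance script
mirrors these sizes.

## Known limitations

- The reference classifier is a bag-of-words linear model; it cannot
  represent word order or context, and its attribution scores are
  correspondingly word-level.
- Polyhierarchies and multi-label leaves are out of scope; the taxonomy
  is a strict tree and every document carries exactly one leaf.
- Weighted voting, stacking and probability calibration of members are
  out of scope; member probabilities enter the sum ensemble as-is.
- The synthetic corpus cannot certify real-world performance; it
  certifies the machinery around whatever classifiers are plugged in.
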