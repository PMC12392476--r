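---
title: "Mining symptom associations with an outcome-targeted Apriori"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining symptom associations with an outcome-targeted Apriori}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symrules)
```

## The problem and the model

`symrules` analyses case-control style cohorts in which each patient is a
vector of binary symptom indicators plus a binary outcome (the motivating
setting is early-stage diabetes screening from 16 self-reportable
symptoms, without laboratory values). Per-symptom screening — a 2×2 table
and a chi-square test per symptom — answers whether each symptom is
marginally associated with the outcome. Association rule mining answers a
different question: which *combinations* of present symptoms make the
outcome likely, including combinations whose members are individually
unremarkable.

Each patient is encoded as a transaction: the set of `"<Variable>=1"`
tokens for their present indicators. Only presence tokens are emitted by
default, because outcome-directed rules are built from positive symptoms;
absence tokens are available behind `include_absence = TRUE` for users
who want to mine protective patterns. A rule $A \to B$ with antecedent
itemset $A$ and consequent item $B$ (here always the outcome-positive
item) is scored by

$$\mathrm{supp}(A \to B) = \frac{|\{t : A \cup B \subseteq t\}|}{N},
\qquad
\mathrm{conf}(A \to B) = \frac{\mathrm{supp}(A \cup B)}{\mathrm{supp}(A)},
\qquad
\mathrm{lift}(A \to B) = \frac{\mathrm{conf}(A \to B)}{\mathrm{supp}(B)}.$$

Rule support is the support of the *union* $A \cup B$ — the fraction of
patients showing the whole combination — not the antecedent-only support.
Lift compares the rule's confidence with the consequent's base rate:
lift 1 means independence, and a confidence-1 rule attains the ceiling
$1/\mathrm{supp}(B)$. With outcome prevalence $320/520$ the ceiling is
$1.625$, displayed as $1.63$.

## The miner

`frequent_itemsets()` is a from-scratch level-wise Apriori. Size-1 items
are filtered by minimum support; size-$k$ candidates are formed by
joining size-$(k{-}1)$ frequent sets that share a $(k{-}2)$-prefix under
a canonical (radix, locale-independent) item order, pruned when any
$(k{-}1)$-subset is infrequent, then support-counted against an
incidence matrix and filtered. The prune is exact because support is
anti-monotone: adding an item can only shrink the set of containing
transactions — the property-based tests sample random itemset pairs to
assert this, and it is also why higher-order rule tables show
monotonically lower supports.

`generate_rules()` emits one candidate per frequent itemset containing
the target item, with the remainder as antecedent. Both thresholds must
hold (defaults: support ≥ 0.03, confidence ≥ 0.60, the analysis settings
of the motivating study); lift is reported but never filtered on, so
negative associations such as a lift-0.99 rule survive if they pass the
thresholds. The consequent is constrained to the single configured
target item; rules with an empty antecedent are not emitted.

`brute_force_rules()` enumerates every antecedent subset directly and
recomputes the metrics by counting; it shares no candidate-generation or
pruning logic with the Apriori path and refuses universes above 15 items.
The suite asserts exact rule-for-rule agreement between the two routes on
hundreds of random transaction sets — the strongest correctness evidence
the package has, since the two computations only coincide when both are
right.

### Numerical conventions

* **Raw vs displayed metrics.** All comparisons, threshold checks and
  sorting use raw double-precision values; rounding happens only at
  render time. Display rounding is half-up to 2 decimals
  (`round_half_up()`), the convention that maps a raw lift of 1.125 to
  1.13 and 1.625 to 1.63; base R's half-to-even `round()` would print
  1.12 and 1.62. A published table computed with spreadsheet-style
  rounding occasionally shows a double-rounded cell (e.g. a confidence of
  0.7148 printed as 0.72); `symrules` always reports single-rounded
  values.
* **Closed forms match counting bit-for-bit.** `rule_metrics_from_counts()`
  evaluates the metrics as ratios of support fractions rather than count
  ratios, so its doubles are identical — not merely close — to the
  transaction-counting path. The fixture test asserts raw equality for
  all 16 order-2 rules.
* **Sorting.** Rule tables sort by descending raw support, then raw
  confidence, then raw lift, then lexicographic antecedent; the sort is
  stable, so rows whose raw keys all tie keep their canonical order.
  Display rounding never feeds back into ordering.

## Screening

* `chi_square()` is the uncorrected Pearson $X^2$ on the 2×2 table. The
  choice is pinned empirically by regression tests: the uncorrected
  statistic reproduces the published screening p-values (0.012 for
  genital thrush, 0.1 for obesity) from the published counts, while the
  Yates-corrected one (0.016, 0.12) does not. Tables with a zero margin
  are rejected rather than silently returning `NaN`.
* `roc_cutoff()` computes the AUC by the rank (Mann–Whitney)
  construction with ties counted one half, its p-value by the normal
  approximation to the rank-sum statistic with tie correction (no
  continuity correction — no method is prescribed in the source
  analysis, and the uncorrected form is the simplest defensible choice),
  and the cutoff as the midpoint between adjacent distinct values
  maximizing Youden's $J$, taking the smallest midpoint on ties so output
  is deterministic. Classification is positive strictly above the
  cutoff.
* `dichotomize()` follows the same strictly-above convention: with the
  canonical age boundary 46.5, integer ages of 47 and older code 1. The
  motivating analysis reports a ROC cutoff of 47.5 while labelling its
  positive age stratum "47+" with a 260/260 split; these two statements
  put 47-year-olds on opposite sides. The package follows the printed
  group sizes (47 is positive) and records the discrepancy here rather
  than resolving it.
* `compare_group_means()` is the pooled-variance two-sample t-test; the
  motivating cohort reports equal group standard deviations, and no
  variant is named, so the equal-variance form is used. A pooled SD of
  zero is an error, not an infinite statistic.
* No multiple-testing adjustment is applied across the 16 screens,
  matching the source analysis; users screening many more variables
  should adjust downstream.

## Synthetic cohorts and the fixture

`generate_cohort()` draws the outcome Bernoulli(prevalence) and each
symptom independently given the outcome with its conditional probability.
Conditional independence is the maximum-entropy completion when only the
pairwise symptom–outcome margins are specified — which is exactly what a
published set of 2×2 tables constrains. Higher-order structure can be
injected only explicitly, via implications: itemsets whose joint presence
forces the outcome to 1 after generation, creating confidence-1 rules by
construction. Generation is bit-reproducible under the spec's integer
seed (Mersenne–Twister), and the caller's RNG state is untouched. The
default spec *is* the study condition set: $n = 520$, prevalence
$320/520$, and the published conditional frequencies.

`table2_fixture()` is deterministic rather than sampled: 320
outcome-positive rows then 200 negative, with each symptom's published
positive-stratum and negative-stratum counts placed as runs at the top of
each block. Every symptom × outcome crosstab therefore reproduces its
published counts *exactly*, making every order-2 quantity (frequencies,
chi-squares, rule metrics) an exact offline reproduction. The
block-placement is also why the fixture needs no seed and diffs cleanly.

**Limitation, by construction:** the fixture's joint distributions of
order ≥ 3 are artifacts of the run placement (within each outcome block
the symptoms are perfectly nested), so only order-2 quantities are
faithful to the study. Higher-order published tables are not desk-scale
reproducible — no higher-order joint counts are published — and are
covered instead by the miner's structural guarantees (anti-monotone
support; confidence-1 ⇒ lift $= 1/\mathrm{supp}(B)$), which hold on any
dataset. For the same reason, passing tests on synthetic cohorts show
that the machinery is correct under the conditional-independence model,
not that real symptom data lacks higher-order dependence — real cohorts
certainly have it, and the miner makes no assumption either way.

## Problem sizes and test design

The suite mines the 520 × 17 fixture (order capped at 2–3, where the
published values live and where the fixture is faithful), checks
oracle equivalence on 200 random transaction sets of up to 12 items and
200 transactions, and checks parameter recovery at $n = 10{,}000$ with a
3-standard-error bound per conditional frequency — wide enough that a
correctly seeded generator passes deterministically, tight enough that a
miscoded probability fails immediately. Unbounded-order mining of the
fixture is deliberately avoided in examples: its nested blocks keep
*every* itemset above 3% support, so the frequent-set lattice is the full
$2^{17}$ — a useful reminder that Apriori's cost is driven by the data's
dependence structure, not only by $n$.

## Interfaces

`run_pipeline(run_config(...))` wires read → screen → transactions →
mine → sort/render, computes everything before writing anything (a
failing stage leaves no partial outputs), and emits TSV tables, a
combined JSON rule document and a manifest (inputs, thresholds, seed,
versions). Identical configurations give byte-identical outputs. The
`exec/symrules` script exposes `screen`, `mine`, `simulate`, `fixture`
and `run` subcommands for shell use; it is a thin wrapper, and every
capability is available programmatically.
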