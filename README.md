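# symrules

Outcome-targeted association rule mining for binary clinical symptom
cohorts.

Early-detection studies often score each symptom against a disease one at
a time, ignoring that symptoms which are unremarkable in isolation can be
strongly predictive in combination. `symrules` implements the
complementary co-occurrence view for case-control style cohorts of 0/1
symptom indicators (the motivating application is a 520-patient,
16-symptom early-stage diabetes cohort): it screens each symptom against
the outcome with 2×2 contingency tables and uncorrected Pearson chi-square
tests, selects cutoffs for continuous covariates by ROC/Youden analysis,
and then mines association rules of the form
*{symptom₁ = 1, …, symptomₖ = 1} → {outcome = 1}* with a from-scratch
level-wise Apriori algorithm.

Rules are scored by the three standard market-basket metrics. For a rule
A → B over N patient transactions:

- **support** `supp(A → B) = |A ∪ B| / N` — how common the full symptom
  combination is;
- **confidence** `conf(A → B) = supp(A ∪ B) / supp(A)` — the probability
  of the outcome given the antecedent symptoms;
- **lift** `lift(A → B) = conf(A → B) / supp(B)` — the strength of the
  association relative to chance (`> 1` positive, `= 1` independent,
  `< 1` negative).

Because the consequent is pinned to the outcome item, a confidence-1 rule
attains the analytic lift ceiling `1 / supp(B)`; with outcome prevalence
320/520 that ceiling is 1.625, displayed as **1.63** under the half-up
2-decimal convention.

The package also ships a synthetic cohort generator
(conditional-independence model given the outcome, with optional planted
implications) and `table2_fixture()`, a deterministic 520-row cohort that
embeds the published 2×2 margin of every symptom, so all order-2 results
are exactly reproducible without access to the original dataset.

## Worked example

```r
library(symrules)

coh   <- table2_fixture()                      # 520 patients, 16 symptoms
ts    <- to_transactions(coh)                  # presence tokens "<Var>=1"
rules <- mine_rules(ts, mining_config(min_support = 0.03,
                                      min_confidence = 0.60,
                                      target = "Diabetes=1",
                                      max_order = 2))
tab <- sort_rules(stratify_rules(rules)[["2"]])
cat(render_rules_table(tab, "tsv"))
```

prints

```
LHS	RHS	supp	conf	lift
{Polyuria=1}	{Diabetes=1}	0.47	0.94	1.53
{Polydipsia=1}	{Diabetes=1}	0.43	0.97	1.57
{weakness=1}	{Diabetes=1}	0.42	0.71	1.16
{partial.paresis=1}	{Diabetes=1}	0.37	0.86	1.39
{Polyphagia=1}	{Diabetes=1}	0.36	0.80	1.30
{sudden.weight.loss=1}	{Diabetes=1}	0.36	0.87	1.41
{Age=1}	{Diabetes=1}	0.35	0.70	1.13
{visual.blurring=1}	{Diabetes=1}	0.34	0.75	1.22
{Gender=1}	{Diabetes=1}	0.33	0.90	1.46
{Itching=1}	{Diabetes=1}	0.30	0.61	0.99
{delayed.healing=1}	{Diabetes=1}	0.29	0.64	1.04
{muscle.stiffness=1}	{Diabetes=1}	0.26	0.69	1.13
{Irritability=1}	{Diabetes=1}	0.21	0.87	1.42
{Genital.thrush=1}	{Diabetes=1}	0.16	0.72	1.16
{Obesity=1}	{Diabetes=1}	0.12	0.69	1.13
```

Reading the top row: polyuria and diabetes are jointly positive in 47% of
patients; 94% of polyuria-positive patients are diabetes-positive; and a
polyuria-positive patient is 1.53 times as likely to be diabetes-positive
as a randomly chosen one. Itching illustrates why lift matters: its
confidence clears the 60% floor but its lift of 0.99 marks the
association as indistinguishable from chance. Alopecia produces no rule
at all — its confidence (78/179 ≈ 0.44) falls below the floor.

`run_pipeline(run_config("cohort.csv", out_dir = "out"))` wires the whole
flow — read/validate, screen, mine, report — and writes TSV/JSON
artifacts plus a run manifest. The same stages are available from a shell
via the thin wrapper `exec/symrules` (subcommands `screen`, `mine`,
`simulate`, `fixture`, `run`).

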