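---
title: "Disproportionality screening of adverse-event reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality screening of adverse-event reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rorscreen)
```

## The screen

Spontaneous pharmacovigilance databases such as FAERS collect reports in
which patients or clinicians name the drugs a patient took and the
adverse reactions they experienced. When a drug and a reaction appear in
the same report, they *co-occur*. Disproportionality analysis asks
whether a drug co-occurs with an event of interest more often than the
rest of the database would predict, and the idea behind side-effect-based
drug repositioning is that the excess itself can be a therapeutic
signal: drugs over-reported for *hypotension* are candidates for
*anti-hypertensive* activity, because the adverse event is the
therapeutic effect observed in the wrong context.

`rorscreen` implements that screen as a pipeline of small, separately
testable stages:

1. **report_model** — read report corpora (canonical JSONL, or an import
   of openFDA-style nested JSON records);
2. **normalization** — map raw drug strings to canonical
   single-ingredient identities and decide event-term matches;
3. **counting** — one pass over the corpus produces, per study drug, the
   2×2 table of drug co-occurrence × event occurrence;
4. **stats** — reporting odds ratio, log-space Fisher exact test,
   conditional-MLE odds ratio, significance ranking;
5. **evaluation** — ROC AUC, partial AUC, DCG/NDCG, and enrichment of a
   binary known-indication label set;
6. **synthetic_data** — seeded corpora with known ground-truth
   association strength, and exact reconstruction of corpora from
   printed 2×2 tables;
7. thin pipeline drivers (`run_simulate()`, `run_screen()`,
   `run_evaluate()`, and the `inst/cli/rorscreen` wrapper script).

## The model

For a drug $d$ and an event definition $E$ (a set of reaction terms),
every report falls into exactly one cell of

|            | event           | no event  |
|------------|-----------------|-----------|
| drug       | $n_{11}$        | $n_{10}$  |
| no drug    | $n_{01}$        | $n_{00}$  |

and the **reporting odds ratio** is

$$\mathrm{ROR} = \frac{n_{11}\,n_{00}}{n_{10}\,n_{01}}.$$

A report counts once per drug (set semantics) and contributes its
integer *weight*, so a corpus whose margins total millions of reports
can be represented by a handful of weighted pseudo-reports
(`corpus_from_table()`) and screened exactly.

Significance is attached by the **Fisher exact test** on the table. At
corpus scale the P values of strong signals are routinely smaller than
the smallest positive double (`1e-308`) — a top-ranked drug over a few
million reports can reach $P \sim 10^{-600}$ — so the entire tail
computation is carried out in natural-log space: hypergeometric point
masses via log-gamma, accumulation via log-sum-exp, and ranking on
$\log_{10} P$. The display-scale value `p_display` underflows to an
honest 0 below $10^{-308}$, but the ranking never consumes it;
`rank_signals()` orders by `log10_p`, breaking ties by descending ROR
and then drug name. This is what keeps two drugs printing as
"0" and "3.95E−315" distinguishable and correctly ordered.

The two-sided P value follows the point-probability convention: it sums
the probabilities of all tables (margins fixed) whose point probability
is at most the observed one times $(1 + 10^{-7})$, the standard
relative-tolerance guard against floating-point ties. Sidedness is
configurable (`alternative = "greater"` / `"less"`); the default is
two-sided, the dominant convention in disproportionality work. With
corpus-scale cell counts the choice does not alter the ranking of
strong signals, though it does move absolute P values.

The **conditional maximum-likelihood odds ratio**
(`conditional_mle_or()`) is the estimate conventionally reported
alongside a Fisher exact test: the $\psi$ maximizing the noncentral
hypergeometric likelihood of $n_{11}$ given the margins, found by
monotone root-finding on the expected-count equation
$E_\psi[n_{11}] = n_{11}$. The root is solved to relative tolerance
$10^{-8}$, tighter than `fisher.test()`'s default
(`.Machine$double.eps^0.25`); on the worked enrichment table
(48, 8, 247, 380) the accurate root is 9.2035 where coarser solvers
print 9.21. Both the conditional MLE and the cross-product ratio
(9.2308 on that table) are exposed, because published enrichment odds
ratios may use either.

## Normalization choices

Raw generic names mix case, whitespace and salt/ester suffixes.
`normalize_drug_name()` lowercases, collapses whitespace, and strips
trailing salt/ester/counter-ion tokens right-to-left until none
remains, never emptying a name (the drug "potassium" survives even
though "potassium" is also a counter-ion token). The suffix list
(~30 tokens) is configuration, not a dictionary: real-world merging of
the most-reported generic names involves vendor-specific rules that no
fixed list reproduces, so the list is editable, logged into output
metadata, and deliberately conservative.

Combination products ("oxycodone and acetaminophen",
"amlodipine/benazepril") are detected by marker patterns — the token
`" and "`, or `/` and `+` between alphabetic tokens — rather than an
ingredient dictionary. Flagged names are excluded from study-drug
lists; their *reports* are kept and still contribute to the corpus
margins through any single-ingredient entries they carry.

Event matching is **exact set membership** on lowercased,
whitespace-collapsed terms, never substring: with
"orthostatic hypotension" in the term set, the reaction
"orthostatic hypotension aggravated" does not match. Substring
matching would silently widen the event definition. The default term
set is the hypotension definition: *hypotension*, *blood pressure
decreased*, *orthostatic hypotension*.

## Ranking evaluation

Given binary labels (1 = approved for the target indication),
`ranking_metrics()` computes:

* **ROC AUC** in its Mann–Whitney form — the fraction of
  (positive, negative) pairs where the positive ranks better, ties
  credited 0.5. The ranking key is (`log10_p` ascending, ROR
  descending), identical to `rank_signals()`; `signal_scores()` encodes
  it as a numeric score with exact tie groups.
* **Partial AUC** — the unnormalized area of the empirical ROC over
  FPR $\in [0, f_{\max}]$ (default 0.1), trapezoidal on the step curve
  with linear interpolation at the boundary. A perfect classifier
  scores $f_{\max}$; chance scores $f_{\max}^2/2$.
* **DCG/NDCG** — the default DCG convention is the classic
  $\mathrm{DCG}_k = rel_1 + \sum_{i=2}^{k} rel_i/\log_2 i$, chosen
  because published formulations that name $rel_1$ as a separate term
  use this form; the $\sum rel_i/\log_2(i+1)$ convention is available
  via `convention = "log2i1"`. The ideal ordering sorts the full
  relevance multiset descending *before* truncating at $k$, so with
  $\ge k$ relevant drugs IDCG@k is the all-relevant discount sum.
  Published per-class NDCG@20 values computed from figure-only
  equations are not reproducible from either standard convention, which
  is why the convention is a flag rather than a claim.
* **Enrichment** — the 2×2 table of label × (unadjusted $P$ below a
  cut-off, default $10^{-10}$), scored by the conditional-MLE odds
  ratio and log-space Fisher P. A cut-off below every P value empties a
  margin and errors rather than returning a degenerate estimate.

No multiple-testing adjustment enters the ranking (the screen ranks by
unadjusted P); Bonferroni and Benjamini–Hochberg columns are emitted
for context only.

## The synthetic generator

`generate_corpus()` emulates the structure the screen consumes: each
report draws drugs independently by per-drug `usage_prob` (empty draws
are rejected and redrawn), then the event occurs with odds

$$o = o_0 \prod_{d \in \text{report}} \theta_d,$$

a multiplicative odds model — the simplest structure whose single-drug
marginal ROR converges to $\theta_d$ when usage is rare. Every report
carries one decoy reaction drawn from a pool disjoint from the event
terms (so negative event matches are always exercised); event reports
additionally carry one event term. Generation is a single seeded
stream: the same spec and seed give byte-identical corpora, and the
seed and spec hash are recorded in the corpus metadata and the JSONL
header.

Two consequences of these choices deserve flagging:

* Because odds satisfy $o/(1+o) < 1$ for any finite $o$, the model
  cannot produce an event probability of 1; the spec validator instead
  rejects parameter sets whose worst-case odds product overflows,
  naming the offending high-$\theta$ combination.
* The **resample-if-empty rule conditions every report on carrying at
  least one drug**. This raises each drug's effective prevalence (by
  the factor $1/P(\text{any drug})$) and induces a mild *negative*
  association between drugs: reports lacking drug $d$ are enriched for
  the other panel drugs, so when one of those others is a true signal,
  null drugs acquire a small protective bias in their marginal ROR. The
  bias shrinks as the panel grows. The calibration studies below size
  the panel so the bias stays far from any significance threshold; on a
  panel where *all* drugs are null the bias vanishes identically, since
  the event odds are then $o_0$ for every report.

What the generator does **not** emulate: duplicate and stimulated
reporting, missing or free-text drug fields, indication-driven
channeling, reporting-rate drift over time, or any MedDRA hierarchy.
Tests passing on synthetic corpora therefore demonstrate the
*statistical machinery* — counting, exact tests, ranking, recovery of a
known odds multiplier — not robustness to the biases of real
spontaneous-report data.

## Study sizes used by the test suite

The package's calibration and recovery checks run at sizes chosen to
make their statistical targets sharp:

* *Exact-test oracle*: every 2×2 table with total $\le 60$
  (635,376 tables) against direct enumeration with binomial
  coefficients, relative error $< 10^{-10}$.
* *Type-I error*: 2,000 multinomial null tables ($N = 500$, independent
  0.1 × 0.1 margins); the two-sided rejection rate at $\alpha = 0.05$
  must sit at or below the exact binomial 99% envelope — exact tests
  are conservative.
* *Recovery*: 20 seeded corpora of 200,000 reports over a 15-drug panel
  (one $\theta = 3$ signal, fourteen nulls, `usage_prob` 0.01,
  $o_0 = 0.02$). The panel size follows a power analysis: 15 drugs give
  the signal drug roughly 14,000 carrying reports per corpus — enough
  that ±10% around $\theta$ is ≈ 2.4 standard errors of the log-ROR —
  while keeping the conditioning bias on null drugs near
  $|\log \mathrm{ROR}| \approx 0.12$, z ≈ 1.9, orders of magnitude away
  from the $P < 10^{-10}$ significance cut-off the nulls must not
  cross. A markedly smaller panel would push null drugs toward that
  threshold; a markedly larger one starves the signal drug of reports.
* *Qualitative ranking recovery*: a 50,000-report corpus with six
  labelled $\theta = 4$ drugs among thirty; AUC and NDCG both exceed
  0.9. Full-scale published ranking metrics require the original
  multi-million-report screen and are deliberately not correctness
  targets.

## Worked example

Screening the bundled top-20 excerpt (printed contingency rows fed in
directly, no corpus needed):

```{r}
t20 <- hypotension_top20()
signals <- signal_screen(t20)
signals[1:5, c("drug", "n11", "n10", "ror", "log10_p", "p_display", "rank")]
all(round(signals$ror, 2) == signals$printed_ror)
```

Evaluating the excerpt's ranking against its approved-antihypertensive
flags (9 of the 20 drugs). Every drug in the excerpt clears
$P < 10^{-10}$, so the enrichment table would be degenerate (and
`enrichment()` says so); the rank-quality metrics still apply:

```{r}
labels <- setNames(t20$antihypertensive, t20$drug)
rel <- labels[signals$drug]
c(auc = roc_auc(signal_scores(signals), rel),
  ndcg = ndcg(rel), ndcg_at_10 = ndcg(rel, k = 10))
```

These top-20 metrics characterize only the excerpt — every drug in it
is a strong hypotension signal, so the discrimination task is much
harder than over a full drug list, and the values are correspondingly
modest.

## Known limitations

* Co-occurrence is not causation: the screen detects reporting
  disproportionality, which confounds with indication, co-medication
  and reporting fashions. The package ranks; it does not adjudicate.
* The salt-suffix list will not reproduce any specific vendor's
  generic-name merging; drug lists normalized elsewhere should be
  passed in already canonical.
* Event definitions are literal term sets; no MedDRA hierarchy
  traversal or synonym expansion.
* The conditional-MLE boundary conventions (0 and $\infty$ for tables
  with $n_{11}$ on its support boundary) are returned as such, not
  continuity-corrected; use `ror(..., haldane = TRUE)` if a finite
  cross-product estimate is required.
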