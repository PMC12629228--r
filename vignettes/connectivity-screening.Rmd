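---
title: "Connectivity screening: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity screening: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigconnect)
```

## The problem

A transcriptomic *signature* encodes the genome-wide response to a
perturbation as a vector of gene-level z-scores (perturbation vs control).
Connectivity analysis scores the concordance between a query signature (for
example, a disease expression profile or a TWAS-imputed genetically regulated
expression profile) and each member of a large repository of compound-induced
reference signatures. Strongly positive connectivity suggests a shared
mechanism of action; strongly negative connectivity suggests the reference
compound *reverses* the query state and is therefore a drug-repurposing
candidate.

Published connectivity methods disagree often enough that no single one is
reliable across contexts. `sigconnect` therefore runs six of them side by
side and summarizes their agreement in a consensus meta-score.

## The six methods

Three methods use the whole shared gene list:

* **Pearson correlation** of the two z vectors,
* **Spearman correlation** (average ranks on ties),
* **cosine similarity**.

Three use only the query's *extreme genes* — its `K` most up-regulated and
`K` most down-regulated genes (`select_extreme_genes()`):

* **WTCS**, the weighted connectivity score: two GSEA-style weighted
  Kolmogorov–Smirnov enrichment scores, one for the up set and one for the
  down set, walked along the reference ranking (z descending). A hit at gene
  $g$ advances the running sum by $|z_{\mathrm{ref}}(g)|^w / \sum_{s \in
  \mathrm{set}} |z_{\mathrm{ref}}(s)|^w$, a miss retreats it by $1/(N-m)$;
  the enrichment score is the signed maximum-magnitude deviation.
  $\mathrm{WTCS} = (ES_{up} - ES_{down})/2$ when the two components have
  strictly opposite signs and 0 otherwise.
* **CSS**, the signed-rank connection strength score: reference genes get
  signed ranks $R_{\mathrm{ref}}(g) = \mathrm{rank}(|z_{\mathrm{ref}}|)
  \cdot \mathrm{sign}(z_{\mathrm{ref}})$ over all $N$ universe genes, the
  $2K$ query extremes get signed ranks $1..2K$ by $|z_q|$; the inner product
  $\sum_g R_{\mathrm{ref}}(g) R_q(g)$ is normalized by its rearrangement
  bound $c_{\max}$, giving a value in $[-1, 1]$.
* **XSum**, the eXtreme Sum: reference z-scores are truncated to the
  reference's own top/bottom `ref_extreme_n` genes (all others zeroed), then
  summed over the query's up genes minus its down genes.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `K` | 50 | extreme genes per side; 100/150/200 are common alternatives |
| `ref_extreme_n` | `K` | reference-side truncation for XSum |
| `n_perm` | 10000 | permutation count for the CSS/XSum nulls |
| `vote_quantile` | 0.05 | top fraction of a screen that earns a method's vote |
| `min_overlap_frac` | 0.8 | minimum fraction of query genes found in the repository universe |

`K = 50` is the conventional default for extreme-gene connectivity methods;
the WTCS hit-weight exponent is fixed at 1 (weights $= |z_{\mathrm{ref}}|$),
a choice we make explicitly since rank-based and higher-exponent variants
exist. The `min_overlap_frac` guard exists because a low overlap almost
always means the query uses a different gene-identifier namespace, which
this package deliberately does not translate.

## Permutation nulls and empirical p-values

CSS and XSum have no convenient analytic null, so each reference signature
carries a precomputed permutation background (`build_background()`): every
iteration draws 2K distinct genes uniformly from the universe, splits them
randomly into an up and a down list of K, assigns the query importance ranks
$1..2K$ as a uniform random permutation, and records the statistic against
the fixed reference. Because the null randomizes the *query* side, the
backgrounds are query-independent and can be computed once per repository —
the trick that turns a ~100-hour screen into seconds per signature pair.
One-sided empirical p-values use the add-one rule
$p = (1 + \#\{b \ge x\})/(n_{\mathrm{perm}}+1)$ (lower tail in reversal
screens), so $p \in [1/(n_{\mathrm{perm}}+1), 1]$ and never 0.

Two numerical choices deserve a note:

* **Antithetic pairing.** Null draws are generated in mirror pairs (each
  sampled extreme set is followed by its up/down-swapped twin, whose
  statistic is exactly the negated value). The mirror is equally likely
  under the null, so the marginal distribution is untouched, but the stored
  sample becomes sign-symmetric. This makes lower- and upper-tail p-values
  exactly dual, which in turn makes a screen of the negated query in the
  flipped direction reproduce the original ranking bit for bit — a property
  we consider part of the method's contract and test for.
* **Substream seeding.** The RNG stream for each background is derived
  deterministically from `(master seed, sig_id, method, K)` via a string
  hash, so backgrounds are reproducible regardless of build order, worker
  count, or which subset of a repository is rebuilt.

## The meta-score, gating and ranking

For each method, the references whose directional effective score lands in
the top `ceiling(vote_quantile * S)` of the screen receive that method's
vote (for CSS/XSum the ranking is by the one-sided empirical p-value, score
breaking ties; negative screens negate scores first). The **meta-score** is
the vote count, 0–6: 0 means no method places the pair in its top 5%, 6
means all six do.

WTCS costs far more than the other five methods, so it is computed only for
references already significant by at least one of them (`wtcs_gate()`); an
ungated reference carries no WTCS value and a WTCS vote of 0, while the
top-5% cutoff keeps the full screen size as its denominator so the 5%
semantics stay comparable across methods. By default "significant" means
"received that method's top-5% vote" — one consistent criterion with no
extra thresholds; `sig_rule = "pvalue"` switches the gate to p ≤ 0.05
(empirical for CSS/XSum, t-approximation for the correlations, vote rule
for cosine, which has no p-value).

The final ordering is (meta-score desc, consensus percentile desc, sig_id
asc), where the **consensus percentile** is the mean of the six directional
percentile ranks (ungated WTCS contributing 0). The within-meta-score
ordering is our choice — some scalar is needed and the six raw scores live
on incomparable scales; percentile ranks are the only common currency, and
their mean is also what the radar plot displays. Ties beyond that break
lexicographically by signature id, making reports reproducible to the byte.

## What the simulator does and does not emulate

`simulate_repository()` generates null reference signatures with i.i.d.
standard-normal z over a shared universe, and plants signals as
$\pm\alpha \cdot \mathrm{standardized}(q) + \varepsilon$ with
$\varepsilon \sim N(0, \sigma^2)$ i.i.d. Defaults (1000 genes, 500
signatures, reversal at $\alpha = 1$, $\sigma = 0.3$) are chosen so that a
planted reversal is clearly but not trivially detectable — the planted
signature correlates about $-0.95$ with the query, comparable to a strong
true connectivity hit, while the 500-signature screen keeps the top-5% vote
cutoffs meaningful at desk scale.

The simulator deliberately does **not** emulate gene–gene correlation,
dose–response structure, cell-line batch effects, or the heavy-tailed
z distributions of real moderated signatures. A green planted-signal test
therefore establishes that the scoring, null, voting and ranking machinery
is correct and deterministic — not that any method will rank real compounds
correctly in a real repository.

## Degenerate inputs and edge rules

* Ties in query z during extreme selection, and in reference z during
  ranking, break by lexicographic gene id (C-locale radix sort) — stable
  across platforms.
* `|z|` ties in CSS ranks are averaged, matching the Spearman convention.
* An exact tie in the running-sum maximum magnitude takes the deviation
  occurring earliest in the ranking.
* Zero-variance or zero-norm vectors raise rather than return NA; a gene
  set spanning the whole universe is rejected (the KS miss penalty would
  divide by zero).
* Screens with fewer than `1/vote_quantile` references warn: the ceiling
  rule still votes at least one reference per method, which is degenerate.

## Scope limits

Gene-identifier translation, probe collapsing, replicate aggregation into
level-5 signatures, normalized connectivity scores / tau scaling, and
compound-level aggregation across signatures are out of scope. The
remote-repository backend is specified as a fetcher contract
(`repository_from_fetcher()`) and exercised against a local stub; no HTTP
transport ships with the package.
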