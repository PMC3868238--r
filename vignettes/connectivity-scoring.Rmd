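---
title: "Rank-based connectivity scoring of kinase inhibitor panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based connectivity scoring of kinase inhibitor panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinconn)
```

## The problem and the model

Kinase inhibitors are promiscuous, and large selectivity panels — a drug
× kinase matrix of percent inhibition at a fixed dose, or of dissociation
constants Kd in micromolar — record that promiscuity quantitatively.
`kinconn` treats each drug's panel as a *signature*: the kinases sorted
from most to least potently hit. A user's query (a set of kinases implicated
in some biology) is then matched against every drug's signature with a
rank-based, nonparametric enrichment statistic, the same family of
statistic used by connectivity-map approaches on gene-expression
signatures. Because only ranks enter the score, percent-inhibition and Kd
databases are handled identically once ranked, and any strictly monotone
transformation of the raw values (unit changes, log scales) leaves every
result untouched — a property the test suite checks directly.

For a drug whose profile contains N kinases, of which the query matches M
at ranks $R_1 \le \dots \le R_M$:

$$a = \max_{j=1}^{M}\left(\frac{j}{M} - \frac{R_j}{N}\right), \qquad
  b = \max_{j=1}^{M}\left(\frac{R_j}{N} - \frac{j-1}{M}\right)$$

with $KS = a$ if $a > b$ and $KS = -b$ if $b > a$. Both `a` and `b` are
non-negative (the $j = M$ and $j = 1$ terms respectively are), and
$KS \in [-1, 1]$. Across all drugs of the selected database, with
$P = \max_i KS^i$ and $Q = \min_i KS^i$, the connectivity score is
$S = KS/P$ for positive and $S = -KS/Q$ for negative statistics, so the
extremes are exactly ±1. The running-sum curve
$D(r) = \mathrm{hits}(r)/M - r/N$ visualizes where in a drug's ranked list
the query concentrates; its maximum equals `a` exactly (this is why the
uniform $r/N$ step is used rather than a hit/miss-weighted GSEA-style
penalty, under which that identity would fail).

Three cases the formulas leave open are fixed here as package policy:

* **a == b** resolves to the positive branch ($KS = a$). A symmetric
  choice is impossible, the tie set has measure zero on real-valued
  panels, and the positive branch matches the enrichment-favoring
  precedent of connectivity-map scoring.
* **KS = 0** maps to $S = 0$ (neither branch of the $S$ definition covers
  it); if every KS is zero, every $S$ is zero and nothing is divided.
* **0–1 normalization** uses the affine map $(S+1)/2$. Only the range
  0–1 is conventionally stated, not the map; the affine map is chosen
  because it is strictly increasing (ranking unchanged) and preserves the
  sign of $S$ (normalized score above/below 0.5). This is an
  implementation choice and both columns are always reported.

## Ranking policy

Rank 1 is the *most potent* kinase — lowest Kd, highest percent
inhibition — so a positive score means "this drug specifically hits the
query". Ties in the raw values break by ascending kinase symbol
(bytewise, after uppercasing): downstream formulas require each profile's
ranks to be an integer permutation of $1..N_i$, which average ranks would
violate, and the bytewise rule makes output fully reproducible.

Panels rarely assay every kinase for every drug. A drug's profile ranks
only its assayed kinases, so N is per-drug ($N_i$); query kinases a drug
never assayed are dropped *for that drug only*, with the per-drug match
count M reported as `n_matched` so users can filter. Padding unassayed
kinases with worst ranks would fabricate negative evidence, and drugs
matching none of the query are listed in a separate unscored section
rather than being scored at all. How panels with disjoint kinase coverage
should be pooled is genuinely open; the per-drug-$N_i$ policy is this
package's resolution of it.

## Permutation p-values

The p-value for a drug asks: how often would a random same-size set of
its ranks score at least as extremely? `permutation_pvalue()` draws `T`
uniform size-M subsets of $1..N$ *without replacement* (a query cannot
contain the same kinase twice), recomputes KS for each, and reports
$f/T$ where $f$ counts exceedances. Defaults that matter:

* **T = 500** trials, the conventional choice for this family of tools.
  The discreteness of $f/T$ (resolution 0.002) is the price of speed.
* **Sidedness.** The default counts $|KS_t| \ge |KS_0|$, making the
  p-value genuinely two-sided; the literal rule $KS_t \ge KS_0$ is
  available as `mode = "literal-one-sided"` but yields $p \approx 1$ for
  every strongly negative observed score, which is rarely what is meant.
* **No pseudocount** by default ($p = 0$ is representable from a finite
  trial count); `pseudocount = TRUE` gives the $(f+1)/(T+1)$ estimator
  for users who prefer p-values bounded away from zero.
* **Reproducibility.** Each drug's subset draws come from a substream
  seeded deterministically from (master seed, drug id), so p-values do
  not depend on the order drugs are iterated, and rerunning with the same
  seed reproduces every number bit-for-bit. The caller's RNG state is
  never disturbed.

When $\binom{N}{M}$ is small, `exhaustive_pvalue()` enumerates all
subsets and returns the exact exceedance fraction (default cap $10^5$
subsets); the Monte-Carlo estimate converges to it, and the test suite
verifies both the convergence band and the exact calibration
$P(p \le p_0) = p_0$ on the discrete null support.

## The synthetic-panel generator

`fixture_spec()`/`generate_fixture()` exist so every pipeline stage is
testable without any external dataset. Defaults emulate the *shape* of a
published comprehensive Kd panel — 72 inhibitors × 442 kinases — with
background Kd drawn log-normal (location $\log 1$ μM, scale 2, i.e.
roughly 0.02–50 μM central range spanning several orders of magnitude, as
real Kd panels do) and percent inhibition drawn from a Beta(1.2, 3)
scaled to 0–100. "Spiked" drugs are engineered specific binders: their
target values beat the drug's own background by at least a potency-gap
factor (default 100×) — divided Kd for `kd` panels, divided *residual
activity* $100 - v$ for `ic50` panels, since the gap cannot be applied
multiplicatively on a scale capped at 100.

What the generator does **not** emulate: correlated off-target structure
across chemically similar drugs, kinase-family block structure, assay
noise floors, or the exact marginal distributions of any published
dataset. Passing the recovery tests therefore shows the scoring machinery
is correct and well-calibrated, not that any particular biological
conclusion transfers; with real panels the ranking is only as meaningful
as the underlying assay.

## Numerical and design notes

* Scores are exact rational arithmetic in doubles (no iteration, no
  tolerance); equality assertions like $\max_r D(r) = a$ hold to the last
  bit and are tested that way.
* Final tables sort by normalized score descending with ties broken by
  ascending drug id; TSV output prints scores to 4 decimals and p-values
  to 3 so identical runs are byte-identical, while JSON output keeps full
  precision plus the running-sum curves.
* Outputs are written to a temporary sibling file and renamed, so a
  failing run never leaves a partial result behind.
* Annotation-driven queries (`expand_family()`, `expand_go()`) read plain
  user-supplied TSV maps; a GO term's kinase set is exactly its listed
  kinases (no ontology-graph propagation), family and term matching is
  case-insensitive, and a name substring must resolve to exactly one term.
  No live ontology or alias resolution is attempted — symbols are matched
  verbatim after uppercasing, which keeps the tool self-contained but
  means HGNC aliases are the user's responsibility.

## Problem sizes used in the checks

The shipped verification uses panel sizes chosen to exercise every code
path at interactive speed: exhaustive oracle comparison over all 502
query subsets of panels up to N = 8; Monte-Carlo concentration at T = 500
over 200 seeds on the 6-subset exact case; spiked recovery over 100
simulated 15 × 60 panels at gap 100×; and one full-shape 72 × 442 Kd
panel with four engineered MET binders queried on MET, mirroring how a
single-kinase repurposing query behaves at realistic scale. With a
one-kinase query the score reduces to $1 - R/N$ versus $R/N$, so every
drug placing that kinase first in its own profile ties at score 1 — a
genuine property of rank-based scoring worth knowing when querying single
kinases on large panels.

## Known limitations

* Raw per-drug p-values only; no multiple-testing correction across the
  drugs of a database is applied or reported.
* Mutant or fusion kinase entries are treated as verbatim symbol strings,
  not linked to their parent gene.
* The two published selectivity datasets this design targets are not
  redistributed; users supply them (or any panel) as wide or long TSV/CSV.
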