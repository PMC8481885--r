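---
title: "Methods: ceRNA network inference from methylation and expression screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ceRNA network inference from methylation and expression screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernet)
```

## The model

`cernet` operationalises the competing-endogenous-RNA hypothesis: lncRNAs
and mRNAs that share miRNA response elements compete for a common miRNA
pool, so a lncRNA sharing unexpectedly many miRNA partners with an mRNA,
and positively co-expressed with it, is a candidate sponge regulating that
mRNA. The pipeline looks for such regulation specifically among genes whose
expression change is plausibly methylation-driven — hypermethylated genes
with reduced expression and hypomethylated genes with elevated expression —
on the premise that this double evidence enriches for genuinely
disease-relevant regulation.

### Differential screens

Each feature of a two-group matrix gets a signed t-statistic (positive =
higher in cases) and a two-sided p-value, and is called differential when
*P* < 0.05 **and** |t| > 2, both strict. Three statistic flavours are
offered:

* `student` (default): pooled-variance two-sample t. Fully
  self-contained, exact under Gaussian noise with equal group variances.
* `welch`: unequal variances, Satterthwaite degrees of freedom. Preferable
  when group variances differ (common for beta values near the boundary).
* `moderated`: limma's empirical-Bayes moderated t, the statistic GEO2R
  reports for microarray series. With only a handful of samples per group,
  variance shrinkage across features stabilises the denominator; use this
  flavour when chasing parity with GEO2R-derived gene lists.

Which flavour a published |t| > 2 cutoff referred to is often
undeterminable; `student` is the default because its behaviour depends on
nothing but the data at hand, and the screens' type-I calibration is
checked against it (the null positive rate at *P* < 0.05 must sit inside
the 99% binomial band around 5% on 2,000 null genes — recomputed by
`scripts/acceptance.R` at every run).

Probe-to-gene collapsing keeps the smallest-p record per feature ID, the
common GEO practice. Features with fewer than 3 observed values in a group
are skipped with a warning; a feature with zero variance in both groups
and equal means is reported as t = 0, *P* = 1 rather than `NaN`.

### Aberrant gene classes

`hyper_low` is the intersection of hypermethylated and down-regulated
genes, `hypo_high` of hypomethylated and up-regulated genes. Matching is
exact gene-symbol equality after uppercasing and whitespace stripping — no
alias resolution, since alias maps would drag in an external database
dependency and silently change results as that database evolves.

### The shared-miRNA test

For one gene class, the mRNA–miRNA table restricted to the class defines
the miRNA universe of size *N*. For an mRNA with *n* partners and a lncRNA
with *m* partners sharing *x*, the null distribution of the shared count is
hypergeometric, and the reported p-value is an upper tail. Two conventions
are implemented:

* `tail = "ge"` (default): *P*(X ≥ x), the standard enrichment tail.
* `tail = "gt"`: *P*(X > x) = 1 − Σ<sub>k=0..x</sub> pmf(k).

The `gt` form is occasionally printed in the literature; summing the pmf
to *x* inclusive makes the observed overlap itself part of the "expected"
mass, which is atypical (it returns 0 whenever x = min(n, m), however
improbable the overlap). Both are provided so either convention can be
reproduced; `ge` is the default as the conservative standard. Pairs with
*P* < 0.05 (raw — multiplicity adjustment is deliberately applied only at
the co-expression stage, matching how these two filters are conventionally
combined) survive.

Two numerical choices matter. First, *m* is counted **after** restricting
the lncRNA's partners to the universe; otherwise m > N is possible and the
formula is undefined. Second, the tail is summed directly in log space
(`lchoose` terms combined by log-sum-exp) rather than as 1 − (lower sum),
which avoids catastrophic cancellation for small upper tails; the
acceptance script verifies agreement with exhaustive pmf enumeration to
better than 10⁻¹² over the full grid N ≤ 30.

The two gene classes run completely separately, each with its own universe
*N* and its own network — pooling them would let one class's interaction
density distort the other's null.

### Co-expression filter

Each surviving pair gains the Pearson correlation of its mRNA and lncRNA
profiles across all samples, a p-value from the exact-under-normality
t-transform t = r√((s−2)/(1−r²)), and a Benjamini–Hochberg FDR computed
over all pairs in the run. Retention requires PCC > 0.5 and FDR < 0.05,
strict — a pair at exactly 0.5 is rejected. Positive correlation is the
ceRNA-consistent direction (sponging de-represses), which is why the
filter is one-sided in effect.

### Network topology and biomarkers

Surviving pairs expand into one triple per shared miRNA; triples assemble
into a tripartite network (edges mRNA–miRNA and miRNA–lncRNA only; an ID
appearing in two roles is a hard error rather than a silent merge). Degree
and betweenness are reported raw (betweenness unnormalised, as pair-count
fractions): normalisation rescales by a constant per graph and cannot
change within-network rankings, while raw values are directly comparable
to hand counts. PPI hubs are genes with degree strictly > 10 in a
user-supplied edge list, network-wide. Hub genes present as mRNA nodes are
the "critical genes"; their partner lncRNAs are ranked by degree, then
betweenness, then lexicographically — the last tie-break is arbitrary but
deterministic, and ties at the top are flagged (`tied_top`).

### Over-representation

The enrichment stage reuses the same hypergeometric core (single source of
truth; a dedicated test asserts the ORA p-value equals
`hypergeom_cerna_p()` on the same counts) with N = |background|,
n = |query|, m the set's size within the background. Plain hypergeometric,
not DAVID's EASE variant (which deflates the overlap by one); EASE-derived
published p-values will therefore not be reproduced exactly.

## Tunable parameters

| parameter | default | units / scale | rationale |
|---|---|---|---|
| `p_threshold`, `t_threshold` | 0.05, 2 | probability, t | conventional screen cutoffs, strict |
| `hyper_p` | 0.05 | probability | raw shared-miRNA cutoff |
| `tail` | `"ge"` | — | conservative enrichment convention |
| `pcc_threshold`, `fdr_threshold` | 0.5, 0.05 | correlation, probability | co-expression cutoffs, strict |
| `hub_degree` | 10 | edges | strict PPI hub rule |
| `t_method` | `"student"` | — | self-contained default |

## What the generator emulates — and what it does not

`simulate_cerna_study()` draws expression as Gaussian noise (sd
`noise_sd`, default 1) around gene baselines ~ N(8, 1.5) on a log2-like
scale, matching the magnitude conventions of normalised two-colour/oligo
microarrays; differential genes shift by `de_effect` (default 2) in cases.
Methylation beta values are clamped Gaussians (sd 0.05, typical of
gene-averaged 450K betas) around baselines ~ U(0.2, 0.8), shifted by
`dm_effect` (default 0.2); a Beta distribution would respect the boundary
without clamping but complicates the planted effect size, and at sd 0.05
with baselines away from the boundary, clamping is almost never active.
The defaults (25+25 samples, 2,000 genes, 10% differential in each data
type with half-overlapping direction-consistent intersections, 20 planted
ceRNA units at ρ = 0.8 sharing 4 miRNAs each, 2% background edge density)
are the package's fixed study conditions for calibration and recovery
checks.

Planted co-expression mixes the lncRNA profile from the standardised mRNA
profile (lnc = ρ·z(mRNA) + √(1−ρ²)·ε), so the target correlation holds
across **all** samples even though planted mRNAs also carry a group shift;
a naive bivariate-noise construction would attenuate the realised
correlation by the between-group variance and silently miss the target.
Planted units alternate between the two aberrant classes so both networks
carry recoverable structure.

Deliberately not emulated: probe-level 450K structure, batch effects,
missing-value mechanisms, heavy-tailed expression noise, correlated
background genes, and scale-free interaction-table topology (background
edges are uniform). Passing recovery tests therefore shows the pipeline's
logic and statistics are correct under a clean generative model — it does
not certify performance on real arrays, where unmodelled correlation
structure inflates both tails of every screen.

## Degenerate inputs and edge behaviour

Empty gene classes propagate as empty (warned, not fatal) through
`match_dmg_mirna()` and onward; pairs sharing zero miRNAs are never
enumerated; a pair's absent or zero-variance expression profile drops the
pair with a warning; an empty curated list is an error (it would silently
erase all triples); an empty PPI table yields zero hubs and an empty —
warned — biomarker report.

## Problem sizes used in the checks

The package's own test suite runs the full grid N ≤ 30 for the
hypergeometric core (≈86,000 tail evaluations), 1,000 random vectors for
BH-FDR, 200 random ≤12-node networks for betweenness, and the default
2,000-gene/25+25 study for calibration and recovery; the complete suite
executes in well under a minute, and `scripts/acceptance.R` recomputes the
same quantities in a few seconds.

## Known limitations

* Gene-level inputs only: mapping 450K probes to genes (promoter vs gene
  body) is upstream and materially affects which genes appear
  hypermethylated.
* Interaction tables are consumed as given; no database retrieval, no
  confidence weighting of edges.
* The curated-miRNA restriction matches IDs after lowercasing and
  stripping the `hsa-` prefix, keeping arm suffixes distinct; curated
  lists mixing arm-annotated and legacy names can under-match.
* Raw (unadjusted) shared-miRNA p-values mean the pair stage does not
  control FDR; the co-expression FDR gate downstream is what keeps the
  false-discovery proportion of reported triples low under the study
  conditions.
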