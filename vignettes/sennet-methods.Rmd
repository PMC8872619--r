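---
title: "Methods: ncRNA regulatory-network analysis of senescent cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ncRNA regulatory-network analysis of senescent cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sennet)
```

## Scope and model

`sennet` analyses how miRNAs and lncRNAs jointly regulate the genes that
change expression when cells senesce. It deliberately starts *after*
primary differential-expression analysis: DE tables (feature, log2FC, p,
BH-adjusted p) and regulator→target interaction tables are inputs, because
the statistics that produce them (limma/DESeq2 moderation, multiMiR
database queries, LongHorn inference) are established tools we do not
re-implement. What the package owns is everything downstream: threshold
selection, bipartite network construction, hub ranking, partition
accounting, overrepresentation, and topology-based impact analysis — plus
a synthetic-data generator that makes the whole chain testable offline.

## DE selection

A feature is differentially expressed when its modular linear fold change
is at least `fc_linear_min` **and** its BH-adjusted p-value is at most
`q_max`; both comparisons are inclusive and both default to the source
study's thresholds (1.5 and 0.01). The study's figure legends state the
stricter `|log2FC| ≥ 1` (linear 2.0); we follow the Methods text for the
default and leave the alternative one parameter away, since a
reproduction should be able to do either. The fold-change comparison runs
on the log2 scale (`|log2fc| ≥ log2(fc_linear_min) − 1e-12`) so a row
sitting exactly on the boundary is never lost to a `2^x` round-trip.

`bh_adjust()` implements the step-up rule directly
(`q_(i) = min_{j≥i} p_(j)·m/j`, capped at 1). `NA`/`NaN` p-values are
excluded from `m` and returned as `NA` with a count attribute: silently
including them would shrink every adjusted value. The implementation is
cross-checked in the tests against a literal double-loop of the
definition on 1,000 random vectors at 1e-12.

A per-feature Welch t-test (`two_group_test()`) exists solely so synthetic
end-to-end runs can start from expression matrices; it is documented as
*not* a moderated-statistics replacement and should not be applied to real
count data (the study itself had n = 2 per group, exactly the regime where
moderation matters).

## Network construction

Interaction rows are kept when the regulator is a DE miRNA/lncRNA *and*
the target is a DE gene; duplicate (regulator, target) pairs across source
databases collapse into one edge carrying the merged evidence list. Edges
are unsigned: at this level the analysis counts regulatory contacts, and
activation/repression direction only exists in pathway topologies.

Identifier matching is where real data bites, and the package normalises
the three patterns the field actually mixes: gene symbols are matched
case-insensitively; miRNA names are compared after stripping the
three-letter species prefix (`hsa-miR-335-3p` ≡ `miR-335-3p`); and
slash-joined aliases (`LINC00086/SMIM10L2A`, `SERHL/SRHL`) are split into
synonyms, any of which matches. Display spellings always come from the DE
tables, so outputs are stable regardless of the interaction table's
conventions. Self-loops and gene-class regulator tables are rejected with
errors rather than dropped — silent filtering is how mismatched inputs go
unnoticed.

Merging the miRNA and lncRNA networks is an edge-set union (commutative,
associative, identity on the empty network — all asserted as properties);
a regulator claiming two classes across the inputs is an error.

## Centrality, hubs and the co-regulation partition

In a bipartite regulator→gene network, the only centrality in play is the
out-degree over *distinct* DE targets; alternative centralities
(betweenness, eigenvector) are out of scope by design. `top_k()` defaults
to k = 10 with lexicographic tie-breaking — the source analysis states no
tie rule, and determinism matters more than any particular choice; a
`keep-all-ties` rule is available when the boundary tie itself is of
interest. Regulators with more than 100 distinct DE targets are labelled
hubs and those below 20 minor, the empirical split observed for lncRNAs
in the motivating study.

`partition_stats()` computes `|M|` (top-miRNA targets), `|L|` (top-lncRNA
targets), `|M∩L|` and `|M∪L|` (by inclusion–exclusion, asserted on every
input) and seven percentages against both the network and the full DE-gene
denominator. Percentages are rounded to one decimal, half away from zero;
an integer display mode truncates to whole percents because that is how
the motivating study prints the co-regulated share (217/828 = 26.2 →
"26%"). Regulator similarity is the Jaccard index over target sets, with
zero-target regulators defined as similarity 0 and flagged.

## Overrepresentation analysis

`ora()` is the classical hypergeometric upper tail. Two conventions are
fixed deliberately:

* **Background**: the default universe is all genes present in the DE
  input, configurable. Web tools ship their own (undisclosed) backgrounds,
  so adjusted p-values from such tools are not reproduction targets here —
  only the `%Affected = 100·k/K` arithmetic is, and the package reproduces
  the published values of that ratio exactly.
* **Set size after intersection**: `go_size` is computed after
  intersecting each set with the background, standard ORA practice.

`hypergeom_tail()` accumulates the tail in log-space from `lchoose` terms
(max-factored), so p-values far below double underflow of individual
factorials remain accurate; the tests compare it with exhaustive
`choose()` enumeration for every configuration with N ≤ 20 at 1e-12. BH
runs across the whole collection in one pass, not per GO branch.

## Pathway impact analysis

The impact model propagates observed log2 fold changes through a signed
pathway graph: `PF(i) = ΔE(i) + Σ_j β_ij/N_ds(j)·PF(j)`, solved as
`(I − B)·PF = ΔE`. Only the edge sign (+1 activation, −1 inhibition)
affects scores; richer relation labels are carried as annotation. A
feedback loop can make `I − B` exactly singular (two mutually activating
genes with no other downstream edges being the minimal case); the error
names the nodes of the offending cycle (strongly connected components),
because "singular matrix" alone is useless to a user staring at a 100-edge
topology.

Significance combines two independent views: `pNDE`, the hypergeometric
probability of the pathway's DE count; and `pPERT`, the probability of a
total accumulation at least as extreme as observed when the observed DE
log2FC multiset is re-assigned to uniformly random pathway positions.
Because `tA` is linear in `ΔE`, each bootstrap replicate reduces to a dot
product with the precomputed column sums of `(I−B)⁻¹ − I`, making 10⁵
replicates cheap — the tests exploit the same identity independently to
build a high-replicate oracle. `pPERT` uses add-one smoothing
(`(1+x)/(n_boot+1)`) so it is never exactly zero, and
`pG = c − c·ln c` combines the two (the product of two uniforms has CDF
`c − c·ln c`). Under the null, `pPERT` is uniform up to the discreteness
of the bootstrap, which the suite checks with a Kolmogorov–Smirnov test
over 200 seeded trials.

`regulator_overlay()` is the bridge back to the network: for each pathway
gene it counts incident DE miRNAs and lncRNAs and flags the
most-regulated gene(s). On a fixture encoding the motivating study's
published edges it returns ZEB1 = 4 miRNAs + 6 lncRNAs (most regulated in
the prostate-cancer pathway) and NFATC1 = 4 ncRNAs (most targeted in the
senescence pathway).

## The synthetic world

The generator emulates the *statistical structure* the analysis assumes,
not any particular dataset:

* **DE tables** — log2FC from a two-component mixture: null `N(0,
  null_sd)` and, with probability `de_fraction`, an effect at
  `±(effect_mean ± effect_sd)`. P-values come from the location-shift
  statistic `z = log2FC/null_sd` folded two-sided, so p is a deterministic
  function of the effect: null features get uniform p, shifted features
  small p, and the downstream threshold filter behaves as it does on real
  tables. Defaults (5,000 genes, 400 miRNAs, 60 lncRNAs, `de_fraction`
  0.1, `effect_mean` 2, `effect_sd` 0.5, `null_sd` 0.35) give DE counts of
  the same order as the motivating study (hundreds of genes, tens of
  miRNAs, a dozen lncRNAs). The study reports no distributional
  description of its DE statistics (n = 2 per group), so this mixture is a
  stand-in and is not claimed to match the deposited data.
* **Interaction tables** — regulator out-degrees from a truncated discrete
  power law (`P(d) ∝ d^-2`, d ≤ min(#targets, 150)): a few very-high-degree
  regulators over a mass of low-degree ones, the shape that makes hub
  ranking meaningful. Planted hubs are assigned *after* background
  sampling and receive exactly their stated target count, giving tests a
  known truth. `overlap_fraction` (default 0.45, the observed co-regulation
  scale: 217 of 478 top-lncRNA targets were also miRNA targets) is the
  probability each lncRNA target is drawn from the miRNA-target union
  rather than its complement, making the realised M∩L controllable; at
  exactly 0 the pools are disjoint by construction.
* **Pathways** — random DAGs over DE-table gene ids with ±1 weights
  (75% activating, the activation-heavy mix of curated signalling maps).

Determinism is a contract: one master seed, with fixed per-table
sub-streams, so identical parameters give byte-identical outputs and
adding one table never perturbs another.

What a green test on this world does **not** establish: robustness to
library-size artefacts, batch effects, annotation-version drift, or the
correlated evidence structure of real interaction databases — none of
which the generator simulates (deliberately; they are properties of
upstream tools and inputs, not of this pipeline).

## Numerical and design choices

* Rounding: percentages use round-half-away-from-zero at one decimal (with
  a 1e-9 guard against binary representation error); integer display
  truncates.
* Boundary comparisons are inclusive and performed on the log scale.
* The pipeline's provenance hash (FNV-1a over the canonical JSON of the
  config) excludes the output directory, so the same analysis hashes
  identically wherever it is written — required for the byte-determinism
  guarantee to be checkable across two output directories.
* Pipeline configs are JSON; YAML is not supported because no YAML parser
  is available in the supported dependency set.
* Top-k with `k` larger than the population returns everything with a
  warning rather than erroring: in small synthetic worlds (or the study's
  own 13 lncRNAs vs k = 10) this is routine, not exceptional.
* Hub ranking is computed before any GO-term restriction of the target
  space; the motivating study's figure order implies the same, and the
  alternative is expressible by filtering the DE gene table first.

## Known limitations

* DE statistics are taken at face value; no moderation, batch correction
  or multi-factorial design handling (the study mentions a batch
  correction whose design matrix is unpublished — not reproducible, so
  excluded).
* Interaction tables are trusted as given: no prediction-score filtering,
  no validated-vs-predicted distinction beyond the evidence strings.
* The impact module consumes pre-parsed signed edge TSVs; KGML parsing and
  any proprietary pathway-tool scoring are out of scope.
* Published adjusted p-values from web enrichment tools are not
  reproducible without their backgrounds; only the count arithmetic is.
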