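---
title: "Identifying a core microbiome from presence/absence enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying a core microbiome from presence/absence enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coremic)
```

## The question and the model

A *core microbiome* is the set of taxa consistently associated with a
habitat — a plant's root zone, a body site, a soil type — across samples
and, ideally, across independent studies. Most descriptive approaches
(Venn-style overlap of observed taxa) attach no statistical statement to
membership. This package makes membership an explicit hypothesis test on
**presence/absence** data.

For each taxon, samples are split into an interest in-group and an
out-group and cross-classified by detection:

|            | present | absent |
|------------|---------|--------|
| in-group   | $a$     | $b$    |
| out-group  | $c$     | $d$    |

Under the null hypothesis that presence is independent of group, $a$
follows the hypergeometric distribution with population $N = a+b+c+d$,
$K = a+c$ "present" successes and $n = a+b$ in-group draws. The
one-tailed Fisher's exact p-value is the upper tail

$$p = P(X \ge a) = \sum_{x = a}^{\min(n, K)}
  \frac{\binom{K}{x}\binom{N-K}{n-x}}{\binom{N}{n}},$$

testing enrichment of presence in the in-group. We sum this tail directly
in log space (`lchoose` plus a log-sum-exp reduction), which is exact to
floating precision and overflow-free for any table size; when $a$ sits at
the lower bound of the support the function returns exactly 1. The
direction is fixed — to ask the opposite question, swap the groups —
which avoids sign-convention ambiguity.

P-values across **all merged taxa** are adjusted by the
Benjamini–Hochberg step-up ($q_{(i)} = \min_{j \ge i} p_{(j)} m / j$,
clipped at 1; ties share a q-value). A taxon is reported as core when

1. $q < \alpha$ (default $\alpha = 0.05$),
2. in-group presence $\ge$ `min_in_pct` (default 90%),
3. out-group presence $\le$ `max_out_pct` (default 100%, i.e. no
   ceiling — the classical criteria are (1) and (2); the ceiling exists
   because out-group presence is a legitimate user criterion), and
4. the lineage is informative (below).

The ordering matters: BH is applied **before** the presence filters, so
the FDR family is the full set of merged taxa. Filtering first would
shrink the family and change every q-value. The informativeness filter is
applied last, as a reporting filter, for the same reason.

Working on presence/absence deliberately discards abundance. That is the
method's point: it treats rare and dominant taxa symmetrically and makes
no assumption that read counts track true relative abundance. It is a
complement to — not a replacement for — abundance-based differential
tests; taxa can be core without ever being abundant, and vice versa.

## From heterogeneous tables to one test family

Meta-analysis across studies proceeds in a fixed order
(`identify_core()` wires it together):

1. **Collapse** (`collapse_by_taxonomy`): within each study, rows with
   identical canonical taxonomy are summed per sample. Canonical form
   normalizes Greengenes-style prefixes (`p_X` and `p__X` both become
   `p__X`) and strips whitespace, so "identical taxonomy" is well
   defined. Collapse conserves per-sample totals exactly.
2. **Merge** (`merge_tables`): the row set is the *intersection* of the
   studies' taxonomies — a taxon absent from any study is dropped rather
   than imputed absent, since different primer/platform choices make
   non-detection across studies uninterpretable. Sample ids must be
   disjoint; collisions are an error, never silently renamed, because a
   renamed sample would detach from its group mapping.
3. **Depth filter** (optional): samples below a minimum total count are
   removed and logged.
4. **Normalization**: `none` (default), `total_sum`, or seeded `rarefy`
   (subsampling without replacement via `vegan::rrarefy`; retained
   columns sum exactly to the target depth). Because the test consumes
   only presence/absence, normalization mostly does not change the
   result — see the threshold note below — and `none` is the default.
5. **Binarize**: the default `detection_threshold = 1` applies the
   zero/nonzero rule — any nonzero value is "present". We interpret the
   threshold this way (rather than literally `count >= 1`) so that
   presence is invariant to sample-wise rescaling: total-sum proportions
   are below 1, and a literal reading would declare everything absent.
   For integer counts the two readings coincide. A threshold above 1
   requires `count >= threshold` and is meant for raw counts, as a guard
   against index bleed-through or singleton noise.

The presence criterion itself is compared on exact unrounded fractions
(`100*a >= min_in_pct * n_in` in integer arithmetic); the percentages in
reports are display-rounded half-up to one decimal, matching the
convention of published presence tables (e.g. 28 of 31 samples prints as
90.3).

### Uninformative lineages

Open-reference OTU picking produces rows classified no deeper than
kingdom (`k__Bacteria;p__;c__;o__;f__;g__;s__`). Such a row can pass the
statistics while carrying no reportable identity, so lineages with fewer
than `min_named_ranks` (default 2) named ranks are flagged uninformative
and excluded from the core set (their test results are still reported).
The default keeps taxa resolved only to, say, order level — real core
members are often unnamed below order in reference databases — while
dropping kingdom-only rows.

### The taxonomy tree

`build_tree()` arranges the core taxa as a trie over rank paths: shared
prefixes share nodes, and each lineage's leaf carries its q-value and a
group tag. This is a *taxonomy* tree — relationships reflect
classification labels, not inferred phylogeny — and is exported as Newick
(`export_newick`; labels quoted per the grammar, full lineages in
sanitized comments, parseable by `ape::read.tree`) or indented text
(`render_ascii`, with numeric q-value annotation standing in for the
color scales of graphical viewers).

## The synthetic validation data

Real two-study datasets for this design come from public archives and
need read-level processing far upstream of this package, so correctness
is demonstrated on a generator (`synth_spec()` / `generate_dataset()`)
that reproduces the *statistical* structure the method consumes:

- two studies with disjoint samples, partially overlapping taxon sets
  (default `overlap_fraction = 0.8` of background taxa shared — in the
  kind of two-study merge this emulates, most taxa of the smaller study
  are shared) and different sequencing depths
  (`depth_mean = c(2000, 10000)`, emulating pyrosequencing-vs-MiSeq
  scale differences without modelling platforms);
- 30 + 30 samples split across studies; 10 planted core taxa occurring
  with probability 0.95 per in-group sample and 0.15 per out-group
  sample; 300 background taxa at 0.5 in both groups;
- counts conditional on presence drawn as
  `1 + NegBinom(size = 1, mu = depth/n_taxa)` — a documented free
  choice: the test consumes only the presence pattern, so the count law
  only needs to be positive and depth-scaled.

Everything is reproducible from a single seed, and `evaluate_recovery()`
scores results against the planted truth (sensitivity; false discovery
proportion, defined 0 when nothing is flagged). At the default
conditions, mean sensitivity over 100 replicates is about 0.94 — the
ceiling is the presence criterion itself, since a 0.95-occurrence taxon
shows up in at least 90% of 30 samples with probability
`1 - pbinom(26, 30, 0.95)` ≈ 0.94 — and the false discovery proportion
is near 0.

What the generator does **not** emulate: ecological correlation between
taxa, phylogenetic signal, compositional coupling, chimeras, or
platform-specific taxonomy bias. Passing tests therefore demonstrate the
statistical machinery (merging, family-wise q-values, criteria,
determinism), not robustness to every artifact of real amplicon data.

## Numerical and design choices

- **Fisher tail**: log-space summation, exact 1 at the degenerate lower
  bound; validated against exhaustive fixed-margin enumeration for all
  tables with $N \le 30$ (agreement within 1e-10) and against
  `stats::fisher.test(alternative = "greater")`.
- **BH**: implemented as the textbook step-up and validated against an
  independent re-implementation (exact) and `stats::p.adjust` (1e-12).
- **Rounding**: report percentages round half-up (via
  `floor(10x + 0.5)/10`), not banker's rounding; decision thresholds
  never use rounded values.
- **Determinism**: the only randomness in the pipeline is rarefaction,
  which takes an explicit seed and restores the global RNG state. Result
  files are sorted by (q, p, taxonomy) and contain no timestamps, so a
  fixed configuration yields byte-identical outputs and input row/sample
  order cannot affect reports.
- **Degenerate inputs**: a taxon absent everywhere gets p = q = 1 and is
  never core; an all-zero sample is an error under total-sum
  normalization; merging tables with no shared taxonomy is an error, as
  is an interest label matching zero samples (matching is
  case-sensitive by design).
- **Problem sizes in the test suite** were chosen to exercise the
  stochastic guarantees at the generator's default conditions (100
  replicates for recovery and null control), which keeps the full suite
  under a minute on a laptop-class machine.

## Limitations

Intersection merging discards taxa not observed in every study, which is
conservative and can remove genuine core members detected by only one
primer set. Presence/absence is sensitive to sequencing depth for rare
taxa (a taxon can be "absent" because it was unsampled); the ≥90%
presence requirement plus significance testing mitigates but does not
eliminate this. Taxonomy-label merging caps resolution at the label —
distinct organisms sharing a lineage string are one row. Group selection
(especially the out-group) is a scientific choice the package cannot
make for the user; datasets in which each study contributes only one
group confound study with group and should be avoided.
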