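---
title: "Prioritizing comorbidity candidate genes by multi-criteria rank aggregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing comorbidity candidate genes by multi-criteria rank aggregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorank)
```

## The model

`comorank` operationalizes a simple idea: genes driving the comorbidity
of two diseases should be associated with both of them, and should look
"important" under several independent lines of evidence at once. The
pipeline therefore has three layers:

1. **Candidate definition.** Each disease's gene set is the union of
   its curated network-database associations and its GeneCards-style
   list; the candidate list *X* is the set of gene entities associated
   with both diseases, and the *complete comorbidity network* is the
   subgraph of the global typed network induced on them. A "gene
   entity" merges the gene node and the protein node sharing a symbol
   (matched case-insensitively): priority tables rank symbols, not node
   classes. The *regulatory network* keeps only regulatory edge types —
   activity, expression, transport and degradation regulation, and
   downregulation. We include degradation regulation by default because
   it is a regulation category, although regulatory networks are often
   described without it; the type set is an argument.

2. **Ten criteria.** Three come from external prioritizer score tables;
   seven are computed here (enrichment participation, centralities in
   two networks, process specificity, three SNP criteria). Each
   criterion *c* maps every candidate to a rank in [1, *N*].

3. **Aggregation.** The final score is the unweighted arithmetic mean
   of the ten ranks, ascending. Binary SNP criteria take values only in
   {1, *N*}, which deliberately gives polymorphism evidence more weight
   than the graded criteria.

The assumptions worth stating: the two disease gene sets are taken at
face value (no reliability weighting of sources); the global network's
edges are treated as undirected and equally credible regardless of
type when computing centralities; and the ten criteria are treated as
exchangeable in the average, which is a choice, not an estimate.

## Statistical components

**Enrichment (criterion 4).** Over-representation of a GO biological
process in a query of *n* genes uses the upper hypergeometric tail
P(X ≥ k) with universe *N* = all genes in the annotation file and *K* =
genes annotated to the process; Benjamini–Hochberg adjustment is
applied across processes and a process is "enriched" when the adjusted
value is below `enrichment_alpha` (default 0.01). Using the annotation
file as the universe keeps the test self-contained; a whole-genome
universe would make every process look more enriched and is not what
the per-gene counts need. An EASE-style offset (`ease_offset`) is
available for users who want the more conservative k−1 tail; the
default is the plain hypergeometric. Per gene, criterion 4 counts the
enriched processes of the complete network (*N1*) and regulatory
network (*N2*) containing it and ranks by *N1 + N2* descending.

**Centralities (criteria 5–6).** On the entity-level simple graph:
degree centrality *k/(N−1)*; betweenness as the sum over source–target
pairs of the fraction of shortest paths through the node, divided by
(N−1)(N−2)/2 so it lies in [0, 1] (pairs in different components
contribute 0); and *CC = 2eₙ/(kₙ(kₙ−1))*, the fraction of connected
pairs among a node's neighbors. The CC formula is the local clustering
coefficient, whatever name a workflow gives it; we implement the
formula as printed because the formula, not the label, is what is
operational. Nodes of degree < 2 get CC = 0 (the denominator
vanishes). Criteria 5 and 6 rank by the unweighted mean of the three
normalized values — the three are on a common [0, 1] scale and no
principled weighting presents itself. Candidates absent from the
regulatory network score 0 there rather than being excluded, so every
gene keeps a complete rank vector. Hub detection uses BC ≥ 0.005,
CC ≥ 0.2 and degree > 40 (the degree cutoff strict, the others
inclusive, mirroring the conventional notation of those cutoffs).

**Process specificity (criterion 7).** The test set is the processes
linked to *both* diseases (restricted to annotated processes); the
control set is every other annotated process. For each gene we form the
0/1 membership vector over the test set and over the control set and
compare them with Welch's unequal-variance *t*-test, BH-adjusted across
genes. The per-gene "sample" is not uniquely determined by the verbal
description of this criterion; the 0/1 indicator construction is the
most direct reading of "interactions between genes and biological
processes" and is what we adopt — graded annotation weights are out of
scope. Three numerical edge cases: a gene annotated to nothing (or to
everything) has zero variance on both sides and equal means — it is
flagged degenerate with p = 1; a gene annotated to *every* test process
and *no* control process (or vice versa) also has zero variances but
perfect separation — its statistic diverges, so it receives p = 0 and a
±Inf statistic rather than a degenerate flag, which keeps "maximal
evidence" ordered first; everything else goes through the ordinary
Welch formula. For ranking, genes with positive statistics come first
by ascending adjusted p (positive = specifically associated with the
shared processes), and non-positive/degenerate genes follow in
alphabetical order.

**SNP criteria (8–10).** A qualifying SNP is a brain eQTL with minor
allele frequency ≥ 5% (inclusive boundary: "at least 5%"); the floor
reflects what genotyping arrays detect reliably. Criterion 8 asks for
any qualifying SNP; 9 for one associated with either studied disease;
10 for one associated with a disease on the user-supplied comorbid
list (matched case-insensitively; synonym resolution is out of scope).
Criteria 9 and 10 require their SNPs to pass the criterion-8 filters —
the qualifying list is the natural reading of what those criteria
search. The fallback rank for a gene without a hit is *N*, the size of
the current candidate list, generalizing the published constant (231)
which was simply that study's list length. SNP density (qualifying
SNPs per 1000 nt of gene length) is reported as a companion statistic;
values above ~7/kb marked the densest genes in the motivating study.

**Ranking and ties.** All graded criteria use fractional (average)
ranks for ties, which conserves the rank sum: each fully scored
criterion's mean rank is exactly (N+1)/2, a property the tests exploit.
Candidates missing from an external score table receive rank *N* rather
than being dropped, keeping the ten columns commensurate. The final
table breaks average-rank ties alphabetically so output is
deterministic.

## The synthetic study generator

Real studies of this design depend on dated snapshots of curated
databases (association networks, GeneCards, GTEx, external
prioritizers) that cannot be redistributed or re-queried
reproducibly. `generate_study()` therefore emulates the *shape* of
those inputs with planted ground truth:

* two disease gene sets whose overlap is `overlap_fraction` of
  `n_genes` (default 0.25 of 200, giving a 50-gene candidate list —
  comparable in order of magnitude to real comorbidity intersections
  while keeping a pipeline run well under a second);
* a typed global network at `edge_density` 0.05 whose edge-type
  proportions follow the breakdown typical of literature-mined disease
  networks (generic associations dominate, ~88%);
* GO annotations over `n_processes` (default 120) with background
  membership probability 0.06; the disease-shared processes are
  moderately over-annotated among all shared genes (+0.3·signal) so
  they genuinely enrich in the candidate query, and strongly among
  drivers (background + signal·(1 − background));
* an SNP catalog with ~Poisson(2) SNPs per gene, 40% brain eQTLs,
  MAF uniform on [0.01, 0.5], rare disease associations (4% studied,
  4% comorbid) — and, with probability `driver_signal`, two planted
  qualifying SNPs per driver, one associated with a studied disease
  and one with a comorbid disease;
* three external score tables in which drivers are better in
  expectation, with the boost proportional to `driver_signal`.

Every planted effect scales with `driver_signal`, so at signal 0 the
drivers are exchangeable with the other shared genes — this is what the
null-calibration test checks (their mean final rank sits at (N+1)/2
within sampling error over 50 seeded studies), and recovery of drivers
in the top 20 rises with the signal. One integer seed drives a separate
pseudo-random stream per artifact, so adding an artifact never perturbs
the others and the whole bundle is byte-reproducible.

What the generator does **not** emulate — and therefore what passing
tests do not demonstrate about real data: linkage disequilibrium and
genomic coordinates; the GO DAG (annotations are flat, no is_a/part_of
propagation); correlated evidence between criteria (real prioritizers
partly share inputs, so real criteria are far from independent);
annotation bias toward well-studied genes; and any particular disease
biology. Driver recovery on this generator validates the plumbing and
the statistics, not the biological validity of the criteria.

## Problem sizes and numerical choices

The shipped tests run the full pipeline at n_genes = 200 (50
candidates) across 20 seeds per signal level and 50 seeds for the null,
sizes chosen so the entire stochastic suite completes in about a
minute while leaving the stochastic assertions comfortable margins.
Exactness is tested where exactness is claimed: hypergeometric tails
against exhaustive enumeration for every configuration with a universe
up to 12; betweenness/cohesion against brute-force shortest-path
enumeration on 50 random graphs of up to 30 nodes at 1e-9; Welch
statistics against R's `t.test` at 1e-9.

Other numerical conventions: BH is applied to raw p-values (when a
published workflow says "FDR correction" without naming the variant,
step-up BH on p is the standard reading); enrichment excludes
processes with no query overlap (their tail probability is 1 by
construction and they would only dilute the FDR); duplicated edges
collapse at parse time so repeated database exports are harmless;
readers reject out-of-range MAFs, malformed GO identifiers, negative
relevance scores and unknown interaction types at the offending line.

## Limitations

The average of ranks is a deliberately simple aggregate: it ignores
criterion correlation and gives the binary SNP criteria implicit extra
weight (a design feature here, but one to be aware of). Disease-name
matching is exact (case-insensitive); synonymy must be resolved
upstream. The centrality layer treats the network as a simple
undirected graph, discarding edge types and directions that a richer
model could exploit. And because the ten criteria are recomputed from
user-supplied snapshots, two users with different database exports
will — correctly — get different priority tables; the run manifest
records input digests so such differences are attributable.
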