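---
title: "Methods: upstream TF over-representation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: upstream TF over-representation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uptf)
```

## The model

`uptf` treats a list of genes of interest (GOIs) as a draw of *n* genes from
a reference universe of *N* genes. A transcription factor with *X* target
genes in that universe partitions the universe into targets and
non-targets; under the null hypothesis that the GOI list is unrelated to the
TF, the number of targets *x* observed among the GOIs follows the
hypergeometric distribution with population *N*, *X* successes and *n*
draws. The enrichment p-value is the upper tail

$$P(K \ge x) \;=\; \sum_{k=x}^{\min(n,X)}
  \frac{\binom{X}{k}\binom{N-X}{n-k}}{\binom{N}{n}} .$$

The binomial alternative (`test = "binomial"`) replaces sampling without
replacement by independent draws at rate $X/N$. The hypergeometric test is
the default: a gene list is a subset of a finite genome, drawn without
replacement, and reconstructing published cistrome-enrichment tables from
their printed counts confirms that the hypergeometric — not the binomial —
tail matches the reported p-values. Both tests are one-sided upper tails;
depletion is out of scope.

Assumptions worth stating explicitly:

* **The universe is an explicit input.** Results are only meaningful
  relative to the reference population the GOI list was drawn from (e.g.
  all genes tested for differential expression), and published target
  counts depend on which annotation release backed the database. `uptf`
  never infers a universe; GOI genes outside it are dropped with a warning
  before `n` is counted, and each TF's target set is intersected with the
  universe before `X` is counted.
* **Target sets are binary.** Peak strength, binding affinity and distance
  to the TSS are not weighted; a gene either is or is not a target.
* **Tests are independent across TFs only in the correction's sense.**
  TF target sets overlap heavily in real cistromes; BH remains valid under
  the positive-dependence conditions typical of such data, Bonferroni
  unconditionally.

## Multiple testing

With hundreds of TFs tested simultaneously, raw p-values are corrected by
either

* **Bonferroni** (`correction = "bonferroni"`): adjusted $p = \min(1, p\,m)$,
  controlling the family-wise error rate; or
* **Benjamini–Hochberg** (`correction = "fdr_bh"`, default): sorted
  ascending with rank $k$, the step-up value is $p_{(k)}\,m/k$, made
  monotone by a running minimum from the largest rank downward and capped
  at 1. Monotonicity enforcement matters only when $p_{(k)} m / k$ is not
  itself increasing; on already well-separated cistrome tables the raw and
  enforced values coincide.

$m$ defaults to the number of TFs actually tested, which is the database TF
count minus any TF whose target set is disjoint from the universe. It can
be overridden (`m` in `enrichment_config()`, `--m` on the command line) when
untested hypotheses should still count toward the family — reconstructing
published corrected values requires the full database TF count (349 for the
Arabidopsis DAP-seq collection) regardless of how many TFs the run retains.
TFs with zero GOI overlap stay in the output with $p = 1$ so the record
count equals $m$ by default. Both corrections are computed by
`stats::p.adjust(..., n = m)`, which implements exactly these formulas;
the package's tests verify them against hand-applied step-up examples and
published corrected tables rather than against `p.adjust` itself.

## Parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `test` | hypergeometric | — | finite-genome sampling without replacement; confirmed against published tables |
| `correction` | fdr_bh | — | FDR is the conventional ranking criterion; Bonferroni available for FWER control |
| `alpha` | 0.05 | — | conventional significance level; also the network's edge-inclusion threshold |
| `m` | TFs tested | count | see above |
| `upstream_window` | 1000 | bp | conventional promoter span for compact plant genomes |
| `include_gene_body` | TRUE | — | DAP/ChIP peaks within gene bodies are common regulatory evidence in plants |

## Peak-to-gene assignment

Databases are built from per-TF BED peak files and a GFF3 annotation. A
gene's regulatory interval is its gene body (optional) plus
`upstream_window` bp 5' of the TSS — the start of a `+` gene, the end of a
`-` gene. BED is 0-based half-open, GFF3 1-based inclusive; all arithmetic
is performed in 0-based half-open space after converting GFF3 coordinates,
which makes boundary behaviour exact and testable: moving a peak end by one
base across the interval boundary flips the assignment on either strand.
A single overlapping base assigns the gene (no minimum-overlap fraction in
this version); downstream windows are not included. Published cistrome
target lists were produced with unknown assignment parameters, so
reproducing them exactly from raw peaks is not attempted — the rule here is
a documented, configurable convention.

Genes on strand `.` are skipped with a warning (no TSS can be oriented);
duplicate gene IDs are an error (ambiguous annotation); peaks on
chromosomes absent from the annotation are counted and ignored.

## The synthetic-data generator

`make_universe()`, `make_database()`, `make_goi()` and `generate_scenario()`
produce data with the same structure the test statistic sees in real
studies: a universe of AGI-syntax locus IDs (so ID-normalization paths are
exercised), TFs with target fractions $X/N$ drawn from a configurable range,
and GOI lists in which a chosen fraction of the list is drawn from one TF's
target set and the remainder from the rest of the universe. The planted
overlap is therefore hit *exactly* ($x = \mathrm{round}(f\,n)$), which makes
generator and analyzer mutually checkable; with `targets = NULL` the GOI
list is a uniform null draw. The default scenario scales mirror the
published Arabidopsis analyses: $N = 27{,}206$, $n = 722$, an enriched TF
with $X = 11{,}896$ and overlap fraction 0.716 (hence $x = 517$), against
decoy TFs with target fractions 0.05–0.5, which brackets the $X$ range of
the published tables.

What the generator does **not** emulate: correlated target sets between TFs
(real cistromes of related TFs overlap strongly), non-uniform gene sampling
(GC/length biases of expression studies), peak-strength distributions, or
annotation errors. Passing tests therefore demonstrate correctness of the
counting, the tail probabilities, the corrections and the ranking — not
robustness to the dependence structure of real cistrome data.

All generators take an explicit integer seed and restore the RNG state on
exit (`withr::with_seed`); identical seeds give byte-identical files through
the `simulate` subcommand.

## Numerical choices

* Tail probabilities come from `stats::phyper`/`stats::pbinom` survival
  functions, accurate to the smallest normal doubles (~1e-300); the test
  suite checks them against exhaustive combinatorial enumeration over every
  feasible configuration with $N \le 60$ (relative error < 1e-9, ~1.2
  million tail values).
* P-values are stored at full double precision; output files round
  percentages to one decimal and p-values to three significant figures,
  matching conventional reporting.
* Equal raw p-values (common at $x = 0$) are ranked lexicographically by TF
  ID, so output is deterministic.
* An empty GOI list, an empty database, or a GOI list disjoint from the
  universe is an error, not an empty result.

## Null calibration and power, as tested

The test suite (sizes chosen to keep the default run under a minute for the
statistical blocks) verifies:

* **Conservativeness under the null**: 2,000 uniform GOI draws of $n = 200$
  from $N = 5{,}000$ against a TF with $X = 750$; the empirical frequency
  of $p \le \alpha$ stays within $\alpha + 3\,\mathrm{SE}$ for
  $\alpha \in \{0.01, 0.05, 0.1\}$ (the discrete test is conservative).
* **Planted-signal recovery**: in 100 seeded replicates of the
  published-scale scenario above (48 decoys), the planted TF ranks first in
  all 100.

## Network export

Edges connect each significant TF ($p_{adj} \le \alpha$) to the GOI genes in
its target set — deliberately restricted to the input list rather than the
TF's full cistrome, since the network is meant to display the regulatory
structure *of the GOI set*. Attributes are computed on the undirected
projection: `degree` is the incident-edge count (a self-regulating TF's
loop counts once) and `neighborhood_connectivity` the mean degree of a
node's neighbors; isolated nodes get connectivity 0 (Cytoscape leaves it
undefined; a total table imports more cleanly). SIF was chosen over
XGMML/JSON because it is the simplest Cytoscape-ingestible text format and
diffable in tests. Both files are written in sorted order, so identical
inputs give byte-identical output.

## Known limitations

* Binary target membership ignores binding strength and distance.
* The assignment rule cannot recover a published database built with a
  different (unstated) rule.
* BH's FDR guarantee degrades under arbitrary negative dependence between
  TF target sets (Benjamini–Yekutieli is not offered).
* Species knowledge is limited to ID normalization; any locus-ID scheme
  works, but no annotation-aware validation is performed.
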