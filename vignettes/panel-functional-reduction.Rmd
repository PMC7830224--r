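---
title: "Functional characterization and variant QC of targeted gene panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional characterization and variant QC of targeted gene panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelora)
```

## The problem

A targeted sequencing panel — for example an amplicon panel of a few dozen
disease-relevant genes — raises two recurring analysis questions. First, the
functional one: which biological processes does the chosen gene set actually
represent? Gene Ontology style over-representation analysis answers this with
one significant term per enriched process, but on a gene set with a coherent
biology it easily produces dozens of overlapping terms spread over a deep
polyhierarchy; a human reader needs that condensed to a handful of
"functional areas". Second, the descriptive one: are the variants that the
panel calls trustworthy and distributed as expected — in Hardy-Weinberg
equilibrium, adequately covered, and with per-gene variant counts that track
gene length rather than some artifact?

`panelora` implements both arms as a reusable, tested pipeline, plus a
synthetic-data module that generates every input with known ground truth so
the whole chain can be validated without access to any cohort data.

## Over-representation analysis

For a study set of $n$ genes drawn from a background of $N$ genes, a term $T$
annotated (after true-path propagation) to $K$ background genes and $k$ study
genes is scored with the one-sided Fisher exact tail

$$p(T) = P(X \ge k), \qquad X \sim \mathrm{Hypergeometric}(N, K, n).$$

True-path propagation means a gene annotated to a term is implicitly
annotated to every ancestor of that term; by default all three edge types
(`is_a`, `part_of`, `regulates`) count as ancestry, with a flag to restrict
to `is_a`. Multiplicity is controlled by Bonferroni as threshold division:
a term is significant when $p < t_p / m$, where $m$ counts the tested terms
(those with at least `min_annotated` study genes; terms never annotated are
not tested and do not inflate $m$). The default threshold $t_p = 5\times
10^{-15}$ is deliberately conservative: it is chosen so that the number of
significant terms stays on the order of the study-set size rather than in
the hundreds, which is the regime the downstream reduction is designed for.

## Knowledge reduction

The significant terms are condensed in four steps.

**Remarkableness.** Each significant term gets
$\mathrm{Rem}(T) = \mathrm{Cert}(T)\cdot\mathrm{Info}(T)$ with

$$\mathrm{Cert}(T_i) = \frac{|\{T_k : p(T_k) < p(T_i)\}|}{n_T}, \qquad
\mathrm{Info}(T_i) = -e\, p_i \ln p_i,\quad p_i = k_i/n,$$

where $n_T$ is the number of significant terms. The information value is a
Shannon-style term: it vanishes for terms annotated to none or all study
genes and peaks (at exactly 1) for terms covering a $1/e \approx 37\%$ share
— terms that are neither trivial nor all-encompassing. The certainty formula
as written ranks a term by how many *better* p-values exist, so the single
most significant term receives $\mathrm{Cert}=0$ and the most marginal
significant terms score highest. We implement this literal form as the
default because it is the published definition, and it has a defensible
reading — the deepest, most specific significant statements sit near the
threshold and are the ones worth headlining — but since the accompanying
prose ("how safe it is to assume the term describes the set") suggests the
opposite orientation, a `complement = TRUE` variant
($1 - |\{p(T_k)<p(T_i)\}|/n_T$) is available in `certainty()` and
`term_scores()`.

**Details and headlines.** A *detail* is a significant term with no
significant descendant — the tip of a significant branch. For every detail
and every distinct path from it to a root, the significant on-path term with
maximal remarkableness is the path's *headline*; ties go to the term nearest
the detail (the more specific statement). The headline set is the union over
all details and paths. Internally this is computed by champion propagation
over the detail's ancestor sub-DAG in topological order, which is equivalent
to exhaustive path enumeration (the test suite checks this equivalence
against a path-enumerating oracle) without materializing an exponential path
set.

**Computed ABC analysis.** Headlines are reduced to the "important few" by
partitioning their remarkableness values: items are sorted descending, the
curve of cumulative item fraction versus cumulative value fraction is
formed, the A/B boundary is the curve point closest to the ideal point
$(0,1)$, and the B/C boundary is the first subsequent point where the
segment slope reaches the break-even $dy/dx \le 1$ (equivalently, where the
next item's value drops to the mean). Tie blocks are never split — the whole
block joins the more important set — except in the fully degenerate
all-equal case, which is partitioned by the curve alone (first half into A)
with a warning. With fewer than three headlines the curve is undefined and
all are kept.

**Subsumption.** Set A is finally abstracted toward Miller's 5–9 range:
while more than 9 terms remain, an abstraction pass collects every ontology
term that is a strict ancestor of at least two current members, ranks the
candidates by depth (longest path from a root), then by member coverage,
then by term id, and executes them in order, each absorbing its still-present
covered members. Deepest-first ordering guarantees that the most specific
common ancestor wins its members. A pass with several disjoint high-coverage
ancestors can legitimately land below 5 — twelve headlines that are children
of exactly three disjoint parents collapse to three areas — which we accept:
singletons are never collapsed, so overshoot only happens when no finer
merge exists. If nothing covers two members while the set is still above 9,
the irreducible set is returned with a warning. The final set, merged
ancestors plus untouched headlines, are the *functional areas*; node classes
for rendering (structural / significant / detail / headline / functional
area) follow the precedence functional area > headline > detail >
significant, and `export_dot()` writes the classified DAG with the
conventional coloring (red / green / yellow / violet).

## Variant arm

**Location classes.** Gene models are BED-like interval tables (0-based,
half-open) with one `span` row per gene plus `cds`, `utr5`, `utr3`
intervals. A variant (1-based VCF position) is classified by containment
priority: CDS → `exonic`, UTR intervals → `utr5`/`utr3`, elsewhere in the
span → `intronic`, only within the 25-base padded target (or nowhere) →
`intergenic`. Strand is ignored — UTR identity comes from the interval
labels. Overlapping genes resolve to the gene whose CDS contains the
position, else the first in genomic order. Multiallelic VCF records are
decomposed into one record per alternate allele.

**Hardy-Weinberg filtering.** From observed genotype counts
$(n_{AA}, n_{Aa}, n_{aa})$ the allele frequency $p$ gives the expectation
$(np^2, 2npq, nq^2)$. Three tests are offered. The default,
`fisher_expected`, is Fisher's exact test on the 2×3 table of observed
versus rounded expected counts; because it treats the deterministic
expectation as if it were a second noisy sample, it is a deliberately
conservative screen — under exact equilibrium it retains essentially all
variants, and it still rejects gross disequilibrium such as a
heterozygote-free 50/0/50 split. The `exact` method is the standard exact
test conditioning on allele counts; like all discrete exact tests it is
somewhat conservative (rejection below the nominal level). The `midp`
variant subtracts half the probability of the observed configuration, the
standard correction when rejection at the nominal level is wanted; it is the
method to use when the filter should behave like a calibrated 5% test, and
it is the one the calibration checks in the test suite are written against
(retention of 95% ± 2% under equilibrium at $n = 61$, MAF 0.2). Monomorphic
variants are retained with $p = 1$ by convention.

**Coverage.** A padded target region counts as successfully analyzed only if
*every* base exceeds the depth bound (default 20, strictly — a base at
exactly 20 fails).

**Length correlation.** The per-gene variant count is related to gene length
with the percentage-bend correlation (bend fraction $\beta = 0.2$, the
conventional default): each vector is standardized by its bend scale
$\omega$ (the $\lfloor(1-\beta)n + 0.5\rfloor$-th smallest absolute
deviation from the median) around a bend-adjusted location, residuals are
clipped to $[-1,1]$, and the clipped residuals are correlated; the p-value
uses the $t_{n-2}$ approximation. Constant vectors, or vectors constant
after bending ($\omega = 0$), are a hard error.

## The synthetic-data module

The generators produce every input the pipeline consumes, with ground truth:

* `gen_ontology()` builds a single-root layered DAG (default 500 terms, 6
  layers, up to 3 parents drawn preferentially from the adjacent shallower
  layer), acyclic by construction, with ~80% `is_a` edges.
* `gen_annotations_with_planting()` annotates a background (default 2000
  genes) to leaf terms with power-law term sizes and draws a study set
  (default 72 genes, mirroring a realistic panel size).
* `gen_genotypes()` draws genotype trios from the inbreeding model
  $(p^2 + Fpq,\; 2pq(1-F),\; q^2 + Fpq)$; $F=0$ is exact equilibrium.
* `gen_variant_table()` draws gene lengths uniformly and counts from a
  Poisson law with rate affine in length, the slope solved from
  $\rho^2 = \beta_\ell^2 V / (\mu + \beta_\ell^2 V)$ so the population
  correlation equals the requested `target_rho` at the requested mean count.

**The planted theme.** The recoverable truth for the functional arm is a
*theme*: an intermediate-layer term that is the primary parent of
`n_planted_leaves` bottom-layer leaves (default 40), about half of which
carry one additional cross-link to a shallower term, as multi-parentage does
in real ontologies. A pool of `n_theme_genes` background genes (default 80)
is annotated to `leaf_membership` planted leaves each (default 18), and the
study set oversamples pool genes by `enrichment_factor` (default 100).

These defaults are a deliberate emulation of the regime the method is meant
for, and the power reasoning is worth recording. A real panel's study set is
a fraction of a percent of the genome-wide background, so a functionally
coherent term can be enriched twenty-fold and reach $p \ll 10^{-15}$ at
modest $k$. At the desk-scale background of 2000 genes the study set is
3.6% of the background, hypergeometric expectations are an order of
magnitude larger, and the same significance requires the study set to cover
most of a planted term's annotation pool — hence a strong oversampling
weight and a high leaf membership, which together put $k \approx 20$ of
$K \approx 35$ study genes on each planted leaf. The cross-links matter for
a subtler reason: under the as-printed certainty formula the most remarkable
term on a path is typically the most *marginal* significant one, and on the
path through the theme's ancestors a barely-significant shallow ancestor can
claim every headline; the cross-link gives each leaf a second root path on
which the leaf itself headlines. Cross-links go only to layers shallower
than the theme, so no ancestor deeper than the theme can intercept the
subsumption merge that should reunite the leaves under it. With this
construction the pipeline recovers the theme among the functional areas
essentially always, and with `enrichment_factor = 1` (a uniform study draw)
the conservative threshold yields zero significant terms, hence zero
functional areas — both properties are computed by the test suite (50 seeds
each) and the acceptance script.

What the generator does *not* emulate: real GO term-size distributions and
evidence codes, annotation biases, linkage between variants, genotyping
error, or read-level artifacts. Passing the planted-recovery checks shows
the reduction machinery is sound, not that any particular biological claim
holds on real data.

## Numerical and interface choices

* Gene symbols are uppercased on entry; duplicate symbols collapse with a
  warning. Ties in ORA p-values order by term id; ties in ABC values stay in
  input order and never straddle a boundary.
* VCF positions are 1-based and converted internally to the 0-based
  half-open convention of the BED-like gene models.
* Every generator derives an independent seed stream from the master seed,
  so adding a generator never perturbs existing draws, and `run_full()`
  reruns bit-identically for a fixed configuration.
* The problem sizes used throughout the tests and the acceptance script —
  500-term ontologies, 2000-gene backgrounds, 50-seed recovery loops,
  1000-variant calibration draws, 100-seed correlation loops — were chosen
  as the smallest sizes at which the stochastic properties are stable.
* The command-line surface of the pipeline is the R API itself
  (`run_full()` and the per-stage functions); artifacts (TSV tables, a DOT
  rendering, a JSON report) are written when `out_dir` is given.

## A worked run

```{r example}
cfg <- sim_config(seed = 7)
report <- run_full(cfg)
report
```

The functional summary shows the condensation chain: tested terms →
significant terms → details → headlines → ABC set A → functional areas, and
`report$functional$theme_recovered` confirms the planted theme ended among
the areas. The full intermediate objects are under `report$objects`.

## Known limitations

* The subsumption lower bound is a soft aim: one abstraction pass can
  overshoot below 5 when a single ancestor covers most of set A.
* `fisher_expected` should be read as a screen, not a calibrated test; use
  `midp` when the nominal level matters.
* The headline definition is per path; a detail reachable from a root along
  many paths can contribute several headlines, which is intended but can
  surprise on very dense DAGs.
* Location classification trusts the gene models; it does not check
  consistency between overlapping genes' annotations beyond the CDS-priority
  rule.
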