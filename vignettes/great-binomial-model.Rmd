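---
title: "The GREAT binomial model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The GREAT binomial model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grenrich)
```

## Why region-centric enrichment

Genomic studies produce lists of regions — ChIP-seq peaks, differentially
methylated regions, variant positions — whose biology is usually read off by
mapping each region to nearby genes and running gene-centric
over-representation analysis (ORA). ORA's null model assumes genes are picked
independently and with equal probability. Regions violate that null: genes
sit unevenly on the genome, their regulatory territories differ enormously in
size, and a cluster of regions near one long gene inflates its pick
probability. The GREAT approach inverts the question. Instead of asking
"which genes did my regions pick?", it asks "how much of the genome belongs
to this biological function, and did my regions land there more often than
uniform placement predicts?"

## The model

For each gene, a **regulatory domain** is built from its transcription start
site (TSS):

* a **basal domain** of `basal_upstream` bases upstream and
  `basal_downstream` bases downstream of the TSS (defaults 5000 and 1000;
  strand-aware, clipped at chromosome ends), always owned by the gene;
* an **extension** of the basal domain in both directions, up to
  `max_extension` bases (default 1 Mb) or until it meets the nearest other
  gene's basal-domain boundary, whichever comes first. The basal domain
  itself is never shrunk, even when a neighbour's basal domain overlaps it.

For a gene set (a "term"), the extended domains of its member genes are
unioned and merged; the fraction of the genome the merged set covers is
`p`. With `N` input regions placed uniformly at random, the number `X`
landing in the term's domain is `X ~ Binomial(N, p)`, and the enrichment
P-value is the exact upper tail `Pr(X >= n)` at the observed count `n`. A
region "lands in" a domain when its midpoint base lies inside it (see
*Conventions* below). Fold enrichment is `n / (N * p)`.

### Background restriction

When a background is supplied — either directly (`background`) or as its
complement (`exclude`) — the same model is applied inside the universe `U`:
domains are intersected with `U`, giving `p2 = |domain ∩ U| / |U|`; only the
`N2` input regions falling in `U` count as trials; `n2` of them fall in the
restricted domain; the P-value is the `Binomial(N2, p2)` upper tail. Input
regions are never fragmented by the restriction — each remains one whole
Bernoulli trial — only domains are clipped when computing `p2`.

The classic GREAT background test is also provided
(`great_hypergeometric()`): foreground regions must be an exact coordinate
subset of the background regions, and the foreground hit count is tested
against `Hypergeometric(N_bg, N_fg, n_bg)`. When background regions are
disjoint and each lies fully inside or outside a domain,
`p2` reduces to the width ratio of in-domain background to all background;
with equal widths that is exactly `n_bg / N_bg`, which is why the two tests
agree closely in that regime (the package's acceptance checks measure the
maximal `|Δlog10 P|` across terms on such a fixture). The agreement degrades
as background widths become heterogeneous and as P-values move into deep
tails, where the with/without-replacement distinction matters; the binomial
form is the more general of the two since it does not require the subset
relation.

Choosing the background matters: an oversized universe (e.g. the whole
genome when regions could only ever occur in a subset of it) underestimates
every `p` and can only deflate P-values. With the term domain contained in
the true universe this is a theorem, not a tendency — the tail is monotone
increasing in `p` at fixed `n` and `N` — and the package asserts it
replicate by replicate.

## Conventions and numerical choices

* **Coordinates.** All files and user-entered coordinates are 0-based
  half-open (BED-native); GTF input (1-based closed) is converted on read.
  Internally intervals ride on `GenomicRanges`.
* **Hit rule.** Default `hit_mode = "midpoint"`: a region hits iff
  `floor((start + end) / 2)` lies in the domain, making each region one
  unambiguous trial; `"any_overlap"` is available. This is a documented
  convention choice (original GREAT lineage), not a published rule.
* **Merging.** Book-ended intervals are coalesced; `p` depends only on
  covered bases, so the merged form is canonical. Input regions are *not*
  merged with each other: trials are regions, not bases.
* **Neighbour rule.** Extension stops at the nearest basal boundary among
  all other genes on the chromosome, either strand. With mixed strands the
  nearest-reaching boundary need not belong to the adjacent TSS, so running
  extrema of basal boundaries are used. Genes at an identical TSS are
  ordered by `gene_id` and block each other at the shared basal boundary
  while still extending outward.
* **One TSS per gene.** Annotation sources often carry several transcripts;
  the GTF reader reduces to the 5'-most TSS on the gene's strand. This is a
  package decision — sources differ and the reduction must be explicit.
* **Exact tails.** `Pr(X >= n)` is computed by exact tail routines for every
  `N`; with region counts in the 10^2–10^6 range exact evaluation is cheap
  and avoids approximation error in deep tails. `n = 0` returns exactly 1.
* **Degenerate inputs.** A term with no annotated member gets an empty
  domain, `p = 0`, `P = 1`, and a flag; a hit count in a zero-measure domain
  is an internal-consistency error; an empty universe, or a background that
  contains no input region, is rejected with an actionable message.
* **Multiple testing.** Benjamini–Hochberg across all terms of one run,
  reported next to the raw P-values. The choice is labelled, not hidden: it
  is the field default, and nothing in the model prescribes another.
* **Chromosome naming.** Matching is exact; `chr1` and `1` are different
  chromosomes. Records on unknown chromosomes are skipped with a counted
  warning (or rejected, by option).

## The synthetic-fixture generator

Every statistical property is testable without downloads via seeded
synthetic data (`fixture_config()`, `simulate_*()`, or `grenrich simulate`
on the command line). The default configuration is a toy diploid-scale
genome of 2 × 10 Mb with 200 uniformly placed genes, 20 gene sets of 10
genes, and 500 input regions of width 100. At that gene density a 10-gene
term's merged domain covers roughly 10% of the genome under default domain
parameters — comparable to a mid-sized GO term against a mammalian
annotation — which makes the planted-enrichment and calibration experiments
representative. Region midpoints are uniform over the genome under the null;
planted enrichment draws a configured fraction of midpoints uniformly from a
target term's domain.

The generator emulates uniform placement only. Real data violate the
binomial null in known ways — GC and mappability bias, gene clustering,
assembly gaps, chromatin-driven peak co-location — so passing calibration
here demonstrates correctness of the statistic under its own null, not
robustness to those violations; the `background`/`exclude` machinery is the
tool for addressing them on real data.

R has no pass-by-value random-generator object, so each `simulate_*()`
function takes an integer seed and saves/restores `.Random.seed` around its
draws: runs are byte-reproducible and the caller's RNG state is never
touched.

## Verification experiment sizes

The test suite validates the interval engine against base-by-base boolean
oracles (1000 randomized cases on a 10 kb toy chromosome) and the tail
routines against direct log-space pmf summation (all `N <= 50` exhaustively,
randomized sweeps to `N = 5000`, agreement within 1e-12 relative error).
Statistical experiments use 1000 null simulations for type-I calibration at
`alpha = 0.05` (each scoring one designated term, so the 1000 indicators are
independent and an exact binomial acceptance interval applies — pooling all
terms of a run would correlate them) and 100 replicates for
planted-enrichment recovery (fraction 0.5 into a `p ~ 0.1` term, 500
regions, top rank required in at least 95). These sizes give the binomial
acceptance bands quoted in the tests while keeping the whole suite fast on
one CPU. One caveat worth knowing: the binomial test is discrete, so its
attained size at `alpha = 0.05` sits slightly below 0.05 (typically
0.03–0.05 at `N = 500` trials, depending on where the term's `p` places the
rejection threshold); the calibration band accounts for that.

## Known limitations

* Only the basal-plus-extension association rule is implemented; GREAT's
  "two nearest genes" and "single nearest gene" variants are not.
* Curated per-gene regulatory-domain overrides are not honoured.
* Gene sets arrive flattened (GMT); no GO-graph structure, term
  decorrelation, or gene-centric ORA mode.
* No network retrieval of annotations or gene sets; the GTF/gene-table
  readers make user-supplied files usable.
* `background` and `exclude` are mutually exclusive; combining them has no
  defined semantics here.

## A worked run

```{r worked}
cfg <- fixture_config(seed = 42, enrichment_fraction = 0.4)
genome <- simulate_genome(cfg)
genes <- simulate_genes(genome, cfg)
sets <- simulate_gene_sets(genes, cfg)
doms <- regulatory_domains(genes, genome)
target <- term_domain(sets[[1]], doms, genome)$domain
regions <- simulate_regions(genome, cfg, target_domain = target)

res <- great(regions, genes, sets, genome)
head(res$enrichment, 3)
res$distance_summary
```

The planted term tops the table with a hit count far above `N * p`, while
unplanted terms scatter around fold enrichment 1.
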