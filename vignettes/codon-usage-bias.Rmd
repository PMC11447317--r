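---
title: "Codon usage bias analysis of plastid coding sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage bias analysis of plastid coding sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastocub)
```

## The problem

Synonymous codons are not used equally. In plastomes (chloroplast genomes)
the protein-coding genes are strongly AT-biased at third codon positions, and
the balance of forces behind that bias — neutral mutation pressure versus
selection (typically for translational efficiency) — is a classic question in
molecular evolution. plastocub implements the standard analysis battery for
one or more plastomes: extract and quality-filter the coding sequences (CDS),
compute per-gene codon-usage indices, apply three mutation-versus-selection
diagnostics, identify optimal codons, and cluster species by their codon
usage profiles.

## The statistics

**RSCU.** For codon $j$ in a synonymous family $i$ with degeneracy $n_i$ and
counts $x_{ij}$,
$\mathrm{RSCU}_{ij} = x_{ij}\, n_i / \sum_j x_{ij}$ — observed over expected
under uniform use; 1 means no bias. Family sums conserve the degeneracy, and
single-codon families (Met, Trp) are 1 whenever observed. The stop group is
carried in RSCU tables (64-codon summaries) but excluded from statistics
defined on sense codons.

**ENC.** Wright's effective number of codons summarises how far a gene sits
from uniform synonymous usage (61 = all sense codons equal, 20 = one codon
per amino acid). We use the bias-corrected family homozygosity
$\hat F_i = (n_i \sum p^2 - 1)/(n_i - 1)$, class means $\bar F_k$ over
degeneracy classes $k \in \{2,3,4,6\}$, and
$\mathrm{ENC} = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$,
with the classic repairs: a missing or non-positive $\bar F_3$ (Ile is the
only three-fold family) is replaced by $(\bar F_2 + \bar F_4)/2$, any other
missing class mean by the mean of the available ones, and the result is
capped at 61 (the estimator overshoots on uniform tables). Six-fold families
(Leu, Ser, Arg) are kept whole rather than split 2+4.

**Positional GC and third-base composition.** GC1/GC2/GC3 are computed over
all codons of a gene, including the stop codon (so full-gene bookkeeping
like total length = 3 × codon count holds exactly), and
GCall = (GC1+GC2+GC3)/3. A3s/T3s/G3s/C3s restrict to codons of families with
degeneracy ≥ 2 (stop, Met, Trp excluded); by default they are fractions of a
single denominator and sum to 1. A base-specific-denominator variant
(`codonw_compat = TRUE`) is available; note the two definitions differ — the
base-specific denominators are not the same for A/T and G/C, so even the PR2
ratios shift slightly between them.

**Diagnostics.**

* *Neutrality plot*: OLS regression of GC12 on GC3 across genes; slope near 1
  means all positions drift together (mutation), near 0 means the first two
  positions are constrained (selection). We report the slope, Pearson's r
  and r² (both, because published reports are often ambiguous about which
  they print), and slope × 100 as the percent mutation contribution.
* *ENC-plot*: observed ENC against GC3s with the mutation-only expectation
  $\mathrm{ENC}_{exp} = 2 + s + 29/(s^2 + (1-s)^2)$, plus the frequency
  ratio $(\mathrm{ENC}_{exp} - \mathrm{ENC}_{obs})/\mathrm{ENC}_{exp}$,
  binned at width 0.05 centred on zero; genes with |ratio| ≤ 0.05 are read
  as mutation-dominated. GC3s (the curve's natural argument) is the default
  abscissa.
* *PR2 plot*: A3s/(A3s+T3s) against G3s/(G3s+C3s). Quadrants are numbered
  counter-clockwise from the upper right; a point on a dividing line takes
  the lowest quadrant index whose closed quadrant contains it. Note the
  genetic code itself is asymmetric here: A/G-ending two-fold families offer
  no T third base and T/C-ending ones no A, so perfectly symmetric base
  usage does *not* sit exactly at (0.5, 0.5) — which is why the synthetic
  generator records each gene's true model coordinates rather than assuming
  the naive centre.

**Optimal codons.** Genes are ranked by ENC; the extreme 10% at each end
(floor rounding, minimum one gene, name tie-break) form the weakest- and
strongest-bias groups. Following the usual reading of ENC as an inverse
expression proxy, the low-ENC group is treated as high-expression (a
`literal_direction` flag swaps this). ΔRSCU = pooled RSCU(high) − pooled
RSCU(low); codons with ΔRSCU ≥ 0.08 are high-expression codons, codons with
species-level pooled RSCU > 1 are high-frequency codons, and the optimal set
is their intersection minus stop codons. Pooling counts (rather than
averaging per-gene RSCU) is the default because it weights genes by codon
content. Group-size rounding, threshold strictness and the ΔRSCU threshold
itself are exposed as flags.

**Clustering.** Species-level RSCU vectors over the 59 informative codons
(64 minus 3 stops minus Met and Trp, whose RSCU is constant) are clustered
by average linkage (UPGMA) on Euclidean distances; correlation distance
(1 − Pearson) is a flag since published work rarely states the metric. Rows
are sorted by label before clustering so the tree is invariant to input
order; output is an `hclust`, an `ape` phylo and Newick.

## CDS filtering

Before any statistic, CDS sets pass a fixed-order screen; each rejected
record is reported under its first failing rule:

1. `DUPLICATE` — later copies of a gene name (case-insensitive, e.g. the
   inverted-repeat duplicates rps7/ndhB/ycf2), plus an exact-sequence second
   pass catching identical copies under different names;
2. `NOT_TRIPLET`, 3. `TOO_SHORT` (default ≥ 300 nt; the boundary is
   exposed because "greater than 300 bp" is ambiguous at the 300-divisible
   boundary), 4. `BAD_BASE` (strict ACGT), 5. `BAD_START` (ATG),
   6. `BAD_STOP` (TAA/TAG/TGA), 7. `INTERNAL_STOP`.

Partial or trans-spliced annotation fragments normally fail the start/stop
rules and drop out without special-casing. Filtering is idempotent and
order-preserving.

GenBank flat files are parsed directly (LOCUS/FEATURES/ORIGIN; `join()`,
`order()` and `complement()` locations, `<`/`>` partial markers stripped;
`/gene` falling back to `/locus_tag`); minus-strand features are
reverse-complemented via Biostrings. A CDS whose location cannot be
extracted becomes a recorded rejection, not an error.

## The synthetic generator

`generate_cds_set()` emits plastome-like CDS collections with known ground
truth so every stage is testable without downloads. Defaults: 51 genes
(a typical filtered plastome CDS count), codon-aligned lengths uniform on
300–7,002 nt, a fixed hydrophobic-rich amino-acid profile resembling plastid
proteins, ATG start, TAA-weighted stop (0.6/0.2/0.2), no internal stops by
construction, and a single seed controlling everything (generation is gene
by gene, codon by codon, and platform-stable; the caller's RNG stream is
restored afterwards).

Regimes and their encoded truth:

* **mutation** — whole codons are drawn from an independent-base model at a
  gene-specific GC pressure $g \sim U(0.22, 0.37)$ (stop codons excluded and
  renormalised). All three positions respond to $g$, so GC12 and GC3 are
  coupled: expected neutrality slope ≈ 1. We draw whole codons rather than
  fixing the amino-acid profile because a fixed profile pins GC12 and would
  make the slope-1 ground truth unreachable.
* **selection** — the amino-acid profile is Dirichlet-perturbed per gene
  (concentration 500, giving a GC12 spread of a few percentage points; the
  value was chosen by a power analysis so that the n = 200 OLS slope
  estimator has sd ≈ 0.04 and the decoupling is actually testable — a
  literally constant GC3 makes the slope estimator ill-conditioned), while
  the third-position GC preference is drawn from the same range
  independently. Every family carries the same conditional third-base GC
  share, and Met/Trp stay at fixed profile share, so amino-acid composition
  cannot leak into GC3: expected slope ≈ 0.
* **uniform** — equal synonymous usage: pooled RSCU → 1, ENC → 61.
* **biased** — one AT-ending codon per multi-codon family (18 codons,
  configurable) is up-weighted by a per-gene intensity uniform on
  (0, strength); with strength ≥ 2 and ≥ 50 genes the optimal-codon
  procedure recovers the planted set.

What the generator does **not** emulate: genome structure (inverted repeats,
introns, intergenic DNA), among-site dependence, real gene-length
distributions (real plastome CDS are shorter on average, which only makes
per-gene indices noisier), or evolution along a tree. Passing recovery tests
therefore demonstrates correctness of the estimators under the stated
sampling models, not performance guarantees on real annotation errors.

A note on attainable coupling: with $g$ uniform on 0.22–0.37 and independent
codon draws at realistic gene lengths, the *population* Pearson correlation
between per-gene GC12 and GC3 is capped at about 0.89–0.90 by regression
dilution (var(g) ≈ 0.0019 against per-gene multinomial noise ≈ 0.0003).
Slope recovery (0.8–1.2) is unaffected, but correlation expectations above
0.9 are not reachable under these study conditions; the test suite records
this openly rather than quietly widening the GC3 range.

## Worked example

```{r example}
inputs <- list(
  spA = generate_cds_set(synthetic_spec(
    n_genes = 51, regime = "mutation", seed = 11
  ))$records,
  spB = generate_cds_set(synthetic_spec(
    n_genes = 51, regime = "biased", seed = 12
  ))$records
)
out <- file.path(tempdir(), "cub-demo")
res <- run_pipeline(inputs, out, make_figures = FALSE)
res$summary[, c("species_id", "n_cds_retained", "enc_min", "enc_max",
                "n_optimal_codons")]
res$neutrality[, c("species_id", "slope", "pearson_r", "p_value")]
```

The report bundle written to `out` contains every table as TSV
(`gene_indices.tsv`, `rscu_species.tsv`, `neutrality.tsv`, `enc_plot.tsv`,
`enc_ratio_hist.tsv`, `pr2.tsv`, `correlation.tsv`, `delta_rscu.tsv`,
`optimal_codons.tsv`, `filter_report.tsv`, `summary.tsv`), the cluster tree
as Newick, a `run_log.tsv` recording every decision flag in effect, and —
with `make_figures = TRUE` — SVG figures regenerable from the tables alone.

## Numerical and degenerate-input choices

* ENC is `NA` for genes with no usable synonymous family (e.g. Met/Trp/stop
  only); per-gene `NA`s propagate as missing fields, never errors.
* Empty input gives empty tables; GC of an empty gene is `NA`.
* Spearman p-values use the t approximation (adequate at ~50 genes); ties
  get average ranks; constant variables give `NA` correlations. No
  multiple-testing correction is applied — stars annotate single pairs.
* Histogram bins are half-open, width 0.05 centred on 0, and conserve the
  gene count.
* All percentages are kept at full precision internally; output tables are
  written unrounded so reruns are byte-identical.
* Test-suite problem sizes (200-gene recovery runs, 1,000 random ENC
  tables, ≤ 6-leaf clustering oracles) were chosen to keep the whole suite
  in the low minutes on one CPU while leaving estimator noise well below
  the asserted bounds.

## Known limitations

* GenBank parsing covers the flat-file constructs seen in organelle
  records; exotic location operators beyond `join`/`order`/`complement`
  are rejected explicitly.
* The optimal-codon direction convention (low ENC = high expression) is an
  assumption, not an inference; the literal alternative is a flag.
* CAI/tAI/Fop-style indices that need external reference sets, and true
  correspondence analysis of codon counts, are out of scope.
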