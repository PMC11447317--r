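# plastocub

Codon usage bias (CUB) analysis for plastid protein-coding genes, built for
studies of the kind routinely run on newly sequenced chloroplast genomes:
which synonymous codons a plastome prefers, whether mutation pressure or
natural selection shaped that preference, which codons are "optimal" for
transgene design, and how species group by their codon usage profiles.

The package covers the whole workflow as tested, reusable functions:

* **CDS extraction and filtering** — GenBank flat files (feature locations
  including `join()` and `complement()`) or multi-FASTA, then the standard
  quality screen: drop duplicate gene copies (inverted-repeat twins), keep
  codon-aligned CDS ≥ 300 nt, strict ACGT, ATG start, proper stop, no
  internal stop, each rejection reported under its rule.
* **Codon usage indices** — per gene and pooled: codon count L_aa, RSCU
  (RSCU_ij = x_ij·n_i / Σ_j x_ij), Wright's effective number of codons
  ENC = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆ from corrected family
  homozygosities F̂ = (nΣp²−1)/(n−1), positional GC1/GC2/GC3/GCall, and
  synonymous third-base composition A3s/T3s/G3s/C3s with GC3s.
* **Mutation-vs-selection diagnostics** — the neutrality plot (OLS of GC12
  on GC3; slope ×100 = percent mutation contribution), the ENC-plot against
  the mutation-only curve ENCexp = 2 + s + 29/(s²+(1−s)²) with the ENC
  frequency ratio (ENCexp−ENCobs)/ENCexp and its 0.05-wide histogram, and
  the PR2 bias plot A3s/(A3s+T3s) vs G3s/(G3s+C3s).
* **Correlation analysis** — Spearman's rho with t-approximation p-values
  and star annotation across GC1, GC2, GC3, GCall, ENC, L_aa.
* **Optimal codons** — high-frequency codons (species RSCU > 1) intersected
  with high-expression codons (ΔRSCU ≥ 0.08 between the lowest- and
  highest-ENC 10% gene groups), stop codons excluded.
* **RSCU clustering** — UPGMA on Euclidean distances over the 59
  informative codons, with Newick output.
* **A seeded synthetic-CDS generator** with known ground truth (mutation /
  selection / uniform / biased regimes), so the entire pipeline is testable
  offline.

See `vignettes/codon-usage-bias.Rmd` for the full model description,
parameter choices and limitations.

## Worked example

Two synthetic "species" — one mutation-driven, one with an engineered codon
preference — through the full pipeline:

```r
library(plastocub)

inputs <- list(
  spA = generate_cds_set(synthetic_spec(
    n_genes = 51, regime = "mutation", seed = 11
  ))$records,
  spB = generate_cds_set(synthetic_spec(
    n_genes = 51, regime = "biased", seed = 12
  ))$records
)
res <- run_pipeline(inputs, "cub-demo", make_figures = FALSE)

res$summary[, c("species_id", "n_cds_retained", "enc_min", "enc_max",
                "n_optimal_codons")]
#>   species_id n_cds_retained  enc_min enc_max n_optimal_codons
#> 1        spA             51 44.60842      61               26
#> 2        spB             51 45.16219      61               18

res$neutrality[, c("species_id", "slope", "pearson_r", "p_value")]
#>   species_id      slope pearson_r      p_value
#> 1        spA 0.80648882 0.8812831 1.434753e-17
#> 2        spB 0.03594995 0.1329985 3.521667e-01
```

Read: in `spA`, GC12 tracks GC3 with slope 0.81 (r = 0.88, p ≈ 1e-17) — the
signature of mutation pressure driving all codon positions, contributing
about 81% here. In `spB`, the slope is ~0 (p = 0.35): its codon bias is not
compositional, and the optimal-codon report recovers the up-weighted codons
(e.g. `res$optimal$spB$optimal_set` contains the planted AT-ending set).
The output directory holds every table as TSV (`gene_indices.tsv`,
`neutrality.tsv`, `pr2.tsv`, `optimal_codons.tsv`, `summary.tsv`, ...), the
cluster tree as Newick, and a `run_log.tsv` with every decision flag.

Real plastomes go through the same entry point:

```r
res <- run_pipeline(
  list(P_kingianum = list(paths = "PP315902.gb", format = "genbank")),
  "kingianum-out"
)
```

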