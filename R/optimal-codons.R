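# Optimal-codon determination: high-frequency codons (species-level RSCU > 1)
# intersected with high-expression codons (delta-RSCU between the extreme-ENC
# gene groups).

#' Split genes into putative high- and low-expression groups by ENC
#'
#' Genes are sorted by ENC from largest to smallest (ties broken by gene name
#' for determinism) and the extreme `fraction` from each end is taken,
#' `max(1, floor(fraction * n))` genes per group (`rounding = "ceiling"`
#' switches to `ceiling`). By default the low-ENC (strongest-bias) group is
#' treated as the high-expression group — the usual reading of ENC as an
#' inverse expression proxy; `literal_direction = TRUE` swaps the roles.
#'
#' @param index_rows A per-gene index tibble with `enc`.
#' @param fraction Fraction of genes per group (default 0.10).
#' @param rounding `"floor"` (default) or `"ceiling"` group sizing.
#' @param literal_direction Treat the high-ENC group as high-expression.
#' @return A list: `high_expression` and `low_expression` (character vectors
#'   of gene names), `group_size`, and `enc_ties` (TRUE when a tie at a group
#'   boundary made the name tie-break decisive).
#' @export
expression_groups <- function(index_rows, fraction = 0.10,
                              rounding = c("floor", "ceiling"),
                              literal_direction = FALSE) {
  rounding <- match.arg(rounding)
  d <- index_rows[is.finite(index_rows$enc), , drop = FALSE]
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 genes with defined ENC", call. = FALSE)
  k <- max(1L, if (rounding == "floor") floor(fraction * n) else {
    ceiling(fraction * n)
  })
  ord <- order(-d$enc, d$gene_name)
  sorted <- d[ord, , drop = FALSE]
  top <- sorted$gene_name[seq_len(k)] # highest ENC = weakest bias
  bottom <- sorted$gene_name[seq(n - k + 1L, n)] # lowest ENC = strongest bias
  enc_sorted <- sorted$enc
  ties <- (k < n && enc_sorted[k] == enc_sorted[k + 1L]) ||
    (n - k >= 1L && enc_sorted[n - k + 1L] == enc_sorted[n - k])
  list(
    high_expression = if (literal_direction) top else bottom,
    low_expression = if (literal_direction) bottom else top,
    highest_enc = top,
    lowest_enc = bottom,
    group_size = k,
    enc_ties = ties
  )
}

#' Per-codon RSCU difference between two pooled gene groups
#'
#' delta-RSCU = RSCU(high-expression pool) - RSCU(low-expression pool),
#' computed codon-wise on the pooled count tables of each group. A family
#' absent from one group contributes that side's RSCU as 0 and is flagged.
#'
#' @param high_counts,low_counts `codon_counts` tables pooled over the
#'   high- and low-expression gene groups.
#' @return A tibble: `codon` (RNA), `codon_dna`, `aa`, `rscu_high`,
#'   `rscu_low`, `delta_rscu`, `family_absent` (absent from either side).
#' @export
delta_rscu <- function(high_counts, low_counts) {
  hi <- rscu(high_counts)
  lo <- rscu(low_counts)
  tibble::tibble(
    codon = hi$codon,
    codon_dna = hi$codon_dna,
    aa = hi$aa,
    rscu_high = hi$rscu,
    rscu_low = lo$rscu,
    delta_rscu = hi$rscu - lo$rscu,
    family_absent = hi$family_absent | lo$family_absent
  )
}

#' Optimal codons of a species
#'
#' Runs the full optimal-codon procedure on one species' filtered CDS set:
#' high-frequency codons are those with pooled species-level RSCU > 1;
#' high-expression codons are those with delta-RSCU at least `threshold`
#' between the strongest-bias (lowest-ENC) and weakest-bias (highest-ENC)
#' `fraction` gene groups; the optimal set is their intersection, with stop
#' codons excluded.
#'
#' @param records A filtered CDS tibble for one species.
#' @param index_rows Optional precomputed [gene_index_table()] for `records`.
#' @param fraction,rounding,literal_direction Passed to
#'   [expression_groups()].
#' @param threshold delta-RSCU cut-off (default 0.08), compared with `>=`;
#'   `strict_greater = TRUE` uses `>`.
#' @param strict_greater Use a strict comparison for the threshold.
#' @return A list: `species_id`, `high_enc_group`, `low_enc_group` (gene
#'   names), `rscu_species`, `delta` (tibbles), `high_frequency_set`,
#'   `high_expression_set`, `optimal_set` (RNA codon vectors, sorted), and
#'   `enc_ties`.
#' @export
optimal_codon_set <- function(records, index_rows = NULL, fraction = 0.10,
                              rounding = "floor", literal_direction = FALSE,
                              threshold = 0.08, strict_greater = FALSE) {
  stopifnot(is.data.frame(records), nrow(records) >= 2L)
  sp <- unique(records$species_id)
  if (length(sp) != 1L) {
    stop("records must belong to a single species", call. = FALSE)
  }
  if (is.null(index_rows)) index_rows <- gene_index_table(records)
  counts <- .count_records(records)
  pooled <- merge_counts(counts)
  species_rscu <- rscu(pooled)

  grp <- expression_groups(index_rows,
    fraction = fraction, rounding = rounding,
    literal_direction = literal_direction
  )
  pool_of <- function(genes) {
    merge_counts(counts[match(genes, records$gene_name)])
  }
  dl <- delta_rscu(pool_of(grp$high_expression), pool_of(grp$low_expression))

  hf <- species_rscu$codon[species_rscu$rscu > 1]
  he <- if (strict_greater) {
    dl$codon[dl$delta_rscu > threshold]
  } else {
    dl$codon[dl$delta_rscu >= threshold]
  }
  stops_rna <- codon_to_rna(STOP_CODONS)
  optimal <- sort(setdiff(intersect(hf, he), stops_rna))
  list(
    species_id = sp,
    high_enc_group = grp$highest_enc,
    low_enc_group = grp$lowest_enc,
    rscu_species = species_rscu,
    delta = dl,
    high_frequency_set = sort(hf),
    high_expression_set = sort(he),
    optimal_set = optimal,
    enc_ties = grp$enc_ties
  )
}
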