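# Per-gene and pooled codon-usage indices: RSCU, Wright's effective number of
# codons, positional GC content and synonymous third-base composition.

#' Relative synonymous codon usage
#'
#' For codon j of a synonymous family i with degeneracy n_i and counts x_ij,
#' RSCU_ij = x_ij * n_i / sum_j(x_ij): the observed count divided by the count
#' expected were all synonyms of the family used equally. Values above 1 mark
#' over-used codons. The stop group (degeneracy 3) is included so that full
#' 64-codon summaries can be drawn; families with zero total count get RSCU 0
#' for every member and are flagged absent.
#'
#' @param counts A `codon_counts` table (one gene or a pooled group).
#' @return A tibble with one row per codon: `codon` (RNA spelling),
#'   `codon_dna`, `aa`, `degeneracy`, `count`, `rscu`, `family_absent`.
#'   Within each family present in the data the `rscu` values sum to the
#'   family's degeneracy; single-codon families (Met, Trp) have RSCU 1 when
#'   observed.
#' @examples
#' rscu(count_codons("GCTGCTGCCGCA")) # Ala: 2,1,1,0 -> RSCU 2,1,1,0
#' @export
rscu <- function(counts) {
  stopifnot(inherits(counts, "codon_counts"))
  gc <- genetic_code()
  aa <- gc$codon_to_aa[CODONS]
  deg <- gc$degeneracy[aa]
  x <- as.numeric(unclass(counts))
  fam_tot <- as.numeric(tapply(x, aa, sum)[aa])
  val <- ifelse(fam_tot > 0, x * deg / fam_tot, 0)
  tibble::tibble(
    codon = codon_to_rna(CODONS),
    codon_dna = CODONS,
    aa = unname(aa),
    degeneracy = unname(as.integer(deg)),
    count = as.integer(x),
    rscu = unname(val),
    family_absent = unname(fam_tot == 0)
  )
}

#' Effective number of codons (ENC)
#'
#' Wright's summary of how far a gene departs from uniform synonymous codon
#' usage: 20 would mean one codon per amino acid, 61 equal use of all sense
#' codons. Computed from the bias-corrected family homozygosity
#' F_i = (n_i * sum(p^2) - 1) / (n_i - 1), averaged within each degeneracy
#' class k to give F_k, then
#' ENC = 2 + 9/F_2 + 1/F_3 + 5/F_4 + 3/F_6.
#'
#' Stop codons and the single-codon families (Met, Trp) are excluded.
#' Families observed fewer than twice contribute nothing to their class mean;
#' a missing or non-positive F_3 (Ile is the only three-fold family) is
#' replaced by (F_2 + F_4)/2, and any other missing class mean by the mean of
#' the available class means. The result is capped at 61.
#'
#' @param counts A `codon_counts` table.
#' @return ENC in (1, 61], or `NA` when no multi-codon family is usable.
#' @export
enc <- function(counts) {
  stopifnot(inherits(counts, "codon_counts"))
  gc <- genetic_code()
  deg <- .multi_codon_families()
  f_hat <- lapply(setNames(nm = names(deg)), function(a) {
    x <- as.numeric(counts[gc$family_of[[a]]])
    n <- sum(x)
    if (n < 2) {
      return(NA_real_)
    }
    p <- x / n
    (n * sum(p^2) - 1) / (n - 1)
  })
  f_hat <- unlist(f_hat)
  f_bar <- tapply(f_hat, deg[names(f_hat)], mean, na.rm = TRUE)
  f_bar[is.nan(f_bar)] <- NA_real_
  f_bar[!is.na(f_bar) & f_bar <= 0] <- NA_real_
  fb <- setNames(rep(NA_real_, 4), c("2", "3", "4", "6"))
  fb[names(f_bar)] <- f_bar
  if (is.na(fb["3"]) && !is.na(fb["2"]) && !is.na(fb["4"])) {
    fb["3"] <- (fb["2"] + fb["4"]) / 2
  }
  if (all(is.na(fb))) {
    return(NA_real_)
  }
  fb[is.na(fb)] <- mean(fb, na.rm = TRUE)
  out <- 2 + 9 / fb["2"] + 1 / fb["3"] + 5 / fb["4"] + 3 / fb["6"]
  unname(min(out, 61))
}

#' GC content by codon position
#'
#' Percent of codons whose first, second and third base is G or C, over all
#' codons of the input including stop codons, plus the overall value
#' GCall = (GC1 + GC2 + GC3)/3.
#'
#' @param x A `codon_counts` table or a codon-aligned nucleotide string.
#' @return Named numeric vector `c(gc1, gc2, gc3, gc_all)` in percent, or all
#'   `NA` for empty input.
#' @export
gc_by_position <- function(x) {
  counts <- if (inherits(x, "codon_counts")) x else count_codons(x)
  n <- sum(counts)
  if (n == 0L) {
    return(c(gc1 = NA_real_, gc2 = NA_real_, gc3 = NA_real_,
             gc_all = NA_real_))
  }
  gc_at <- function(k) {
    base_k <- substr(CODONS, k, k)
    100 * sum(counts[base_k %in% c("G", "C")]) / n
  }
  v <- c(gc1 = gc_at(1), gc2 = gc_at(2), gc3 = gc_at(3))
  c(v, gc_all = mean(v))
}

#' Synonymous third-base composition
#'
#' Restricts to codons of amino-acid families with degeneracy >= 2 (stop,
#' Met and Trp excluded) and reports the composition of their third bases.
#' Under the default definition A3s, T3s, G3s and C3s are the fractions of
#' those third positions occupied by each base, so they sum to 1, and
#' GC3s = G3s + C3s (as percent).
#'
#' `codonw_compat = TRUE` switches to base-specific denominators: each base's
#' fraction is taken over only those family codon counts whose family offers
#' that base at the third position (so the four values need not sum to 1).
#' Because the denominators differ between bases — A/G-ending two-fold
#' families offer no T, T/C-ending ones no A — downstream PR2 ratios also
#' shift slightly between the two definitions.
#'
#' @param counts A `codon_counts` table.
#' @param codonw_compat Use base-specific denominators.
#' @return Named numeric vector `c(a3s, t3s, g3s, c3s, gc3s)`; the first four
#'   are fractions, `gc3s` is percent. All `NA` when no synonymous codon is
#'   observed.
#' @export
synonymous_third_base_composition <- function(counts, codonw_compat = FALSE) {
  stopifnot(inherits(counts, "codon_counts"))
  gc <- genetic_code()
  deg <- .multi_codon_families()
  fam_codons <- gc$family_of[names(deg)]
  syn_codons <- unlist(fam_codons, use.names = FALSE)
  x <- as.numeric(counts[syn_codons])
  tot <- sum(x)
  naout <- c(a3s = NA_real_, t3s = NA_real_, g3s = NA_real_,
             c3s = NA_real_, gc3s = NA_real_)
  if (tot == 0) {
    return(naout)
  }
  third <- substr(syn_codons, 3, 3)
  if (!codonw_compat) {
    frac <- vapply(c(A = "A", T = "T", G = "G", C = "C"), function(b) {
      sum(x[third == b]) / tot
    }, numeric(1))
  } else {
    fam_of_codon <- rep(names(fam_codons), lengths(fam_codons))
    frac <- vapply(c(A = "A", T = "T", G = "G", C = "C"), function(b) {
      fams_with_b <- unique(fam_of_codon[third == b])
      denom <- sum(x[fam_of_codon %in% fams_with_b])
      if (denom == 0) NA_real_ else sum(x[third == b]) / denom
    }, numeric(1))
  }
  c(
    a3s = unname(frac["A"]), t3s = unname(frac["T"]),
    g3s = unname(frac["G"]), c3s = unname(frac["C"]),
    gc3s = 100 * unname(frac["G"] + frac["C"])
  )
}

#' Per-gene codon usage index table
#'
#' One row per CDS with every index downstream analyses use: codon count
#' (`l_aa`, including the stop codon), ENC, positional GC percentages, GC3s
#' and the synonymous third-base fractions.
#'
#' @param records A filtered CDS tibble (see [filter_cds()]).
#' @param codonw_compat Passed to [synonymous_third_base_composition()].
#' @return A tibble with columns `gene_name`, `species_id`, `l_aa`, `enc`,
#'   `gc1`, `gc2`, `gc3`, `gc_all`, `gc3s`, `a3s`, `t3s`, `g3s`, `c3s`, in
#'   input record order.
#' @export
gene_index_table <- function(records, codonw_compat = FALSE) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    return(tibble::tibble(
      gene_name = character(), species_id = character(),
      l_aa = integer(), enc = numeric(),
      gc1 = numeric(), gc2 = numeric(), gc3 = numeric(), gc_all = numeric(),
      gc3s = numeric(), a3s = numeric(), t3s = numeric(), g3s = numeric(),
      c3s = numeric()
    ))
  }
  rows <- lapply(seq_len(nrow(records)), function(i) {
    ct <- count_codons(records$sequence[i])
    g <- gc_by_position(ct)
    s <- synonymous_third_base_composition(ct, codonw_compat = codonw_compat)
    tibble::tibble(
      gene_name = records$gene_name[i],
      species_id = records$species_id[i],
      l_aa = sum(ct),
      enc = enc(ct),
      gc1 = g[["gc1"]], gc2 = g[["gc2"]], gc3 = g[["gc3"]],
      gc_all = g[["gc_all"]],
      gc3s = s[["gc3s"]],
      a3s = s[["a3s"]], t3s = s[["t3s"]], g3s = s[["g3s"]], c3s = s[["c3s"]]
    )
  })
  dplyr::bind_rows(rows)
}
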