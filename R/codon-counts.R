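# Codon count tables: a named integer vector over the fixed 64-codon order,
# with class "codon_counts". The total codon count is always sum(x).

new_codon_counts <- function(counts) {
  stopifnot(identical(names(counts), CODONS))
  structure(as.integer(counts), names = CODONS, class = "codon_counts")
}

#' Count codons in a coding sequence
#'
#' Splits a codon-aligned nucleotide sequence into non-overlapping triplets
#' read 5' to 3' from position 1 and tallies all 64 codons.
#'
#' @param sequence A single nucleotide string (alphabet ACGT or ACGU; case
#'   insensitive). Length must be divisible by 3; the empty string is allowed
#'   and yields an all-zero table.
#' @return A `codon_counts` object: a named integer vector over the 64 codons
#'   (DNA alphabet, fixed order). `sum()` of the table is the codon count
#'   (L_aa when the input is one complete gene including its stop codon).
#' @examples
#' count_codons("ATGTAA")
#' @export
count_codons <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  s <- toupper(sequence)
  s <- gsub("U", "T", s, fixed = TRUE)
  n <- nchar(s)
  if (n %% 3L != 0L) {
    stop("sequence length (", n, ") is not divisible by 3", call. = FALSE)
  }
  bad <- regexpr("[^ACGT]", s)
  if (bad > 0L) {
    stop(
      "ambiguous or invalid base '", substr(s, bad, bad),
      "' at position ", bad, call. = FALSE
    )
  }
  if (n == 0L) {
    return(new_codon_counts(setNames(integer(64), CODONS)))
  }
  codons <- substring(s, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
  new_codon_counts(table(factor(codons, levels = CODONS)))
}

#' Merge codon count tables
#'
#' Element-wise sum of count tables, e.g. to pool per-gene counts into a
#' species-level table for pooled RSCU.
#'
#' @param tables A list of `codon_counts` objects (possibly empty).
#' @return A single `codon_counts` object; the empty list gives an all-zero
#'   table.
#' @export
merge_counts <- function(tables) {
  stopifnot(is.list(tables))
  out <- setNames(integer(64), CODONS)
  for (tb in tables) {
    stopifnot(inherits(tb, "codon_counts"))
    out <- out + unclass(tb)
  }
  new_codon_counts(out)
}

#' @export
print.codon_counts <- function(x, ...) {
  cat("<codon_counts> total =", sum(x), "codons\n")
  nz <- x[x > 0]
  if (length(nz)) {
    print(setNames(as.integer(nz), codon_to_rna(names(nz))))
  }
  invisible(x)
}

# Counts for many genes at once; returns a list of codon_counts named by gene.
.count_records <- function(records) {
  stopifnot(is.data.frame(records))
  out <- lapply(records$sequence, count_codons)
  names(out) <- records$gene_name
  out
}
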