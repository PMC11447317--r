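#' @keywords internal
"_PACKAGE"

#' @import tibble
#' @importFrom dplyr %>% arrange bind_rows distinct filter group_by left_join
#'   mutate n pull row_number select summarise ungroup desc across all_of
#' @importFrom rlang .data
#' @importFrom stats cor cor.test dist hclust lm coef pt runif rgamma setNames
#'   sd complete.cases as.dist
#' @importFrom graphics hist plot
#' @importFrom utils head write.table
NULL

# Fixed 64-codon order (DNA alphabet, alphabetical) used by every count table.
.codon_levels <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(t(outer(
    as.vector(t(outer(b, b, paste0))), b, paste0
  )))
}

CODONS <- .codon_levels()

# Standard genetic code (identical to the bacterial/plastid table for all 64
# codons); stop rendered "*".
GENCODE <- {
  gc <- Biostrings::GENETIC_CODE
  setNames(unname(gc[CODONS]), CODONS)
}

STOP_CODONS <- names(GENCODE)[GENCODE == "*"]

#' The genetic code as used throughout the package
#'
#' Returns the standard genetic code together with the synonymous-family
#' structure needed for codon-usage statistics: the codon-to-amino-acid map,
#' the synonymous codon set of each of the 21 coding groups (20 amino acids
#' plus the stop group), and each group's degeneracy class.
#'
#' Six-fold families (Leu, Ser, Arg) are kept as single six-member families,
#' matching the classic treatment in effective-number-of-codons work. The
#' three stop codons (TAA, TAG, TGA) form their own three-member group so
#' that full 64-codon summaries (e.g. RSCU bar charts) can include them;
#' statistics defined on synonymous sense codons exclude the group explicitly.
#'
#' @return A list with elements `codon_to_aa` (named character vector over the
#'   64 DNA codons; stop is `"*"`), `family_of` (named list: amino-acid symbol
#'   to its codon set), and `degeneracy` (named integer vector: amino-acid
#'   symbol to family size).
#' @examples
#' gc <- genetic_code()
#' gc$degeneracy[["L"]] # Leu is six-fold
#' @export
genetic_code <- function() {
  fam <- split(names(GENCODE), GENCODE)
  list(
    codon_to_aa = GENCODE,
    family_of   = fam,
    degeneracy  = vapply(fam, length, integer(1))
  )
}

#' Render DNA codons in the RNA alphabet
#'
#' Codons are stored internally with T; reports use the RNA spelling (U) that
#' codon-usage tables conventionally print (UUA, GCU, ...).
#'
#' @param codons Character vector of DNA codons.
#' @return Character vector with T replaced by U.
#' @export
codon_to_rna <- function(codons) gsub("T", "U", codons, fixed = TRUE)

#' Render RNA codons in the DNA alphabet
#' @param codons Character vector of RNA codons.
#' @return Character vector with U replaced by T.
#' @export
codon_to_dna <- function(codons) gsub("U", "T", toupper(codons), fixed = TRUE)

# Amino-acid degeneracy class lookup, excluding single-codon families.
.multi_codon_families <- function() {
  gc <- genetic_code()
  deg <- gc$degeneracy
  deg[deg >= 2 & names(deg) != "*"]
}
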