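# RSCU-based hierarchical clustering of species.

#' Species-by-codon RSCU matrix
#'
#' Stacks species-level RSCU tables into a matrix with one row per species
#' and one column per synonymous sense codon. By default the 59-codon set is
#' used: the three stop codons and the two single-codon families (Met AUG,
#' Trp UGG, whose RSCU is 1 by definition) are dropped; `all_codons = TRUE`
#' keeps all 64 columns.
#'
#' @param species_rscu A named list (names = species) of RSCU tibbles from
#'   [rscu()], or of `codon_counts` tables (converted internally).
#' @param all_codons Keep all 64 codons instead of the 59 informative ones.
#' @return A numeric matrix, species in rows, codons (RNA spelling) in a
#'   fixed column order.
#' @export
rscu_matrix <- function(species_rscu, all_codons = FALSE) {
  stopifnot(is.list(species_rscu), length(species_rscu) >= 2L)
  if (is.null(names(species_rscu)) || any(names(species_rscu) == "")) {
    stop("species_rscu must be a fully named list", call. = FALSE)
  }
  tabs <- lapply(species_rscu, function(x) {
    if (inherits(x, "codon_counts")) rscu(x) else x
  })
  gc <- genetic_code()
  keep <- if (all_codons) {
    CODONS
  } else {
    deg <- gc$degeneracy[gc$codon_to_aa[CODONS]]
    CODONS[deg >= 2 & gc$codon_to_aa[CODONS] != "*"]
  }
  mat <- t(vapply(tabs, function(tb) {
    stopifnot(is.data.frame(tb), all(c("codon_dna", "rscu") %in% names(tb)))
    tb$rscu[match(keep, tb$codon_dna)]
  }, numeric(length(keep))))
  colnames(mat) <- codon_to_rna(keep)
  rownames(mat) <- names(tabs)
  mat
}

#' Hierarchical clustering of species by codon usage
#'
#' Agglomerative clustering of the RSCU matrix rows, average linkage (UPGMA)
#' on Euclidean distances by default; `metric = "correlation"` uses
#' 1 - Pearson correlation between RSCU profiles instead.
#'
#' @param mat A species-by-codon matrix from [rscu_matrix()].
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @param metric `"euclidean"` or `"correlation"`.
#' @return A list: `hclust` (the [stats::hclust] object), `phylo` (an
#'   [ape::as.phylo] tree), `newick` (Newick string with branch lengths),
#'   `merge_heights` (sorted merge heights).
#' @export
hierarchical_cluster <- function(mat, linkage = "average",
                                 metric = c("euclidean", "correlation")) {
  metric <- match.arg(metric)
  stopifnot(is.matrix(mat), nrow(mat) >= 2L)
  if (any(!is.finite(mat))) {
    stop("RSCU matrix contains non-finite entries", call. = FALSE)
  }
  mat <- mat[order(rownames(mat)), , drop = FALSE] # label-order determinism
  d <- if (metric == "euclidean") {
    dist(mat, method = "euclidean")
  } else {
    stats::as.dist(1 - cor(t(mat), method = "pearson"))
  }
  hc <- hclust(d, method = linkage)
  phy <- ape::as.phylo(hc)
  list(
    hclust = hc,
    phylo = phy,
    newick = ape::write.tree(phy),
    merge_heights = sort(hc$height)
  )
}

#' Write a cluster tree as a Newick file
#'
#' @param tree The list returned by [hierarchical_cluster()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cluster_newick <- function(tree, path) {
  ape::write.tree(tree$phylo, file = path)
  invisible(path)
}
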