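# Independent oracle implementations used to cross-check the package. Each is
# written as a direct, naive transcription of the definition and shares no
# code path with the implementation it checks.

# Sliding-window codon tally: walk the string position by position.
oracle_count_codons <- function(sequence) {
  out <- new.env()
  i <- 1L
  while (i + 2L <= nchar(sequence)) {
    cd <- substr(sequence, i, i + 2L)
    out[[cd]] <- (if (is.null(out[[cd]])) 0L else out[[cd]]) + 1L
    i <- i + 3L
  }
  unlist(as.list(out))
}

# Naive Wright homozygosity ENC: explicit loops over amino acids.
oracle_enc <- function(counts) {
  code <- Biostrings::GENETIC_CODE
  names(code) <- gsub("U", "T", names(code))
  aas <- setdiff(unique(code), "*")
  f_by_class <- list()
  for (aa in aas) {
    codons <- names(code)[code == aa]
    k <- length(codons)
    if (k < 2) next
    x <- as.numeric(counts[codons])
    x[is.na(x)] <- 0
    n <- sum(x)
    if (n < 2) next
    f <- (n * sum((x / n)^2) - 1) / (n - 1)
    f_by_class[[as.character(k)]] <- c(f_by_class[[as.character(k)]], f)
  }
  fbar <- vapply(f_by_class, mean, numeric(1))
  fbar <- fbar[fbar > 0]
  fb <- c("2" = NA, "3" = NA, "4" = NA, "6" = NA)
  fb[names(fbar)] <- fbar
  if (is.na(fb["3"]) && !is.na(fb["2"]) && !is.na(fb["4"])) {
    fb["3"] <- (fb["2"] + fb["4"]) / 2
  }
  if (all(is.na(fb))) return(NA_real_)
  fb[is.na(fb)] <- mean(fb, na.rm = TRUE)
  min(unname(2 + 9 / fb["2"] + 1 / fb["3"] + 5 / fb["4"] + 3 / fb["6"]), 61)
}

# Spearman rho as Pearson correlation of average ranks.
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Brute-force agglomerative average linkage: merge the closest pair of
# clusters, recomputing the average pairwise inter-cluster distance from the
# raw point matrix at every step. Returns the sorted merge heights.
oracle_average_linkage_heights <- function(mat) {
  clusters <- as.list(seq_len(nrow(mat)))
  d <- as.matrix(dist(mat))
  heights <- numeric(0)
  cluster_dist <- function(a, b) {
    mean(d[a, b, drop = FALSE])
  }
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        h <- cluster_dist(clusters[[i]], clusters[[j]])
        if (h < best_h) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_h)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1L]] <- merged
  }
  sort(heights)
}

# Straight-line optimal-codon procedure: sort by ENC, slice the extreme 10%,
# pool counts, compute RSCU from first principles, subtract, threshold,
# intersect. Independent of the package's rscu()/enc() helpers except for
# the ENC values passed in.
oracle_optimal_codons <- function(records, enc_values, fraction = 0.10,
                                  threshold = 0.08) {
  code <- Biostrings::GENETIC_CODE
  names(code) <- gsub("U", "T", names(code))
  tally <- function(seqs) {
    all_cod <- unlist(lapply(seqs, function(s) {
      substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    }))
    table(factor(all_cod, levels = names(code)))
  }
  naive_rscu <- function(tab) {
    out <- setNames(numeric(length(tab)), names(tab))
    for (aa in unique(code)) {
      codons <- names(code)[code == aa]
      tot <- sum(tab[codons])
      out[codons] <- if (tot > 0) {
        as.numeric(tab[codons]) * length(codons) / tot
      } else {
        0
      }
    }
    out
  }
  ord <- order(-enc_values, records$gene_name)
  k <- max(1, floor(fraction * nrow(records)))
  lo_enc <- records$sequence[ord][seq(nrow(records) - k + 1, nrow(records))]
  hi_enc <- records$sequence[ord][seq_len(k)]
  delta <- naive_rscu(tally(lo_enc)) - naive_rscu(tally(hi_enc))
  species_rscu <- naive_rscu(tally(records$sequence))
  hf <- names(species_rscu)[species_rscu > 1]
  he <- names(delta)[delta >= threshold]
  stops <- names(code)[code == "*"]
  sort(gsub("T", "U", setdiff(intersect(hf, he), stops)))
}

# Random codon count table (named over the package's 64-codon order).
random_counts <- function(max_count = 50) {
  x <- setNames(
    sample(0:max_count, 64, replace = TRUE),
    plastocub::codon_to_dna(plastocub::codon_to_rna(
      names(Biostrings::GENETIC_CODE)
    ))
  )
  # reorder into the package's fixed order via count_codons of a dummy:
  template <- count_codons("")
  template[names(x)] <- x
  template
}

# A short synthetic CDS tibble without going through the generator.
toy_records <- function(seqs, genes = NULL, species = "sp1") {
  tibble::tibble(
    gene_name = genes %||% paste0("g", seq_along(seqs)),
    species_id = species,
    sequence = seqs,
    source_location = paste0("toy:", seq_along(seqs))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
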