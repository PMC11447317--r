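test_that("rscu matches the hand-computed Ala example", {
  # Ala counts GCT:2 GCC:1 GCA:1 GCG:0 -> RSCU 2, 1, 1, 0
  tab <- rscu(count_codons("GCTGCTGCCGCA"))
  ala <- tab[tab$aa == "A", ]
  expect_equal(
    setNames(ala$rscu, ala$codon_dna)[c("GCT", "GCC", "GCA", "GCG")],
    c(GCT = 2, GCC = 1, GCA = 1, GCG = 0)
  )
  expect_false(any(ala$family_absent))
  expect_true(all(tab$family_absent[tab$aa == "K"]))
})

test_that("uniform usage gives RSCU 1 everywhere and family sums conserve", {
  every_codon_once <- paste(codon_to_dna(rscu(count_codons(""))$codon),
    collapse = ""
  )
  tab <- rscu(count_codons(every_codon_once))
  expect_true(all(abs(tab$rscu - 1) < 1e-12))
  # family-sum conservation on generated genes
  g <- generate_cds_set(synthetic_spec(n_genes = 10, seed = 13,
    regime = "biased"
  ))
  for (s in g$records$sequence[1:5]) {
    tb <- rscu(count_codons(s))
    sums <- tapply(tb$rscu, tb$aa, sum)
    degs <- tapply(tb$degeneracy, tb$aa, max)
    present <- !tapply(tb$family_absent, tb$aa, any)
    expect_equal(as.numeric(sums[present]), as.numeric(degs[present]))
  }
})

test_that("single-codon families have RSCU 1 when present", {
  tab <- rscu(count_codons("ATGTGG"))
  expect_equal(tab$rscu[tab$codon_dna == "ATG"], 1)
  expect_equal(tab$rscu[tab$codon_dna == "TGG"], 1)
})

test_that("ENC reaches 61 in the uniform-usage limit", {
  counts <- count_codons("")
  sense <- names(counts)[!(names(counts) %in% c("TAA", "TAG", "TGA"))]
  counts[sense] <- 10000L
  expect_lt(abs(enc(counts) - 61), 0.05)
})

test_that("ENC equals the brute-force homozygosity oracle", {
  g <- generate_cds_set(synthetic_spec(
    n_genes = 1, length_range = c(600, 600), seed = 7, regime = "biased"
  ))
  ct <- count_codons(g$records$sequence[1])
  expect_equal(enc(ct), oracle_enc(ct), tolerance = 1e-9)
  set.seed(99)
  for (i in 1:50) {
    ct <- random_counts()
    e1 <- enc(ct)
    e2 <- oracle_enc(ct)
    if (is.na(e1)) expect_true(is.na(e2)) else {
      expect_equal(e1, e2, tolerance = 1e-9)
    }
  }
})

test_that("ENC is undefined for genes with no usable synonymous family", {
  expect_true(is.na(enc(count_codons("ATGTGGTAA")))) # Met + Trp + stop only
})

test_that("ENC stays within (1, 61] on random count tables", {
  set.seed(61)
  for (i in 1:25) {
    e <- enc(random_counts())
    if (!is.na(e)) {
      expect_gt(e, 1)
      expect_lte(e, 61)
    }
  }
  uniform <- count_codons("")
  uniform[setdiff(names(uniform), c("TAA", "TAG", "TGA"))] <- 10L
  expect_equal(enc(uniform), 61) # estimator overshoot is capped
})

test_that("positional GC content matches direct inspection", {
  expect_equal(
    gc_by_position("GCGGCG"),
    c(gc1 = 100, gc2 = 100, gc3 = 100, gc_all = 100)
  )
  expect_equal(unname(gc_by_position("ATATAT")), c(0, 0, 0, 0))
  mixed <- gc_by_position("GAATTC") # G.. at 1 of 2 codons; C at third of 2nd
  expect_equal(unname(mixed[1:3]), c(50, 0, 50))
  expect_equal(unname(mixed["gc_all"]), mean(c(50, 0, 50)))
  expect_true(all(is.na(gc_by_position(""))))
})

test_that("GCall equals the positional mean on every generated gene", {
  g <- generate_cds_set(synthetic_spec(n_genes = 25, seed = 21))
  idx <- gene_index_table(g$records)
  expect_equal(idx$gc_all, (idx$gc1 + idx$gc2 + idx$gc3) / 3)
})

test_that("synonymous third-base fractions cover the Leu-only example", {
  v <- synonymous_third_base_composition(count_codons("TTATTG"))
  expect_equal(
    v,
    c(a3s = 0.5, t3s = 0, g3s = 0.5, c3s = 0, gc3s = 50)
  )
  expect_true(all(is.na(
    synonymous_third_base_composition(count_codons("ATGTGG"))
  )))
})

test_that("third-base fractions sum to one and match a direct tally", {
  g <- generate_cds_set(synthetic_spec(n_genes = 40, seed = 11))
  idx <- gene_index_table(g$records)
  expect_equal(idx$a3s + idx$t3s + idx$g3s + idx$c3s,
    rep(1, nrow(idx)),
    tolerance = 1e-12
  )
  # direct tally oracle on one gene: walk codons, keep multi-codon families
  s <- g$records$sequence[1]
  code <- Biostrings::GENETIC_CODE
  names(code) <- gsub("U", "T", names(code))
  fam_size <- table(code)
  cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  keep <- cods[code[cods] != "*" & fam_size[code[cods]] >= 2]
  expect_equal(
    unname(synonymous_third_base_composition(count_codons(s))["a3s"]),
    mean(substr(keep, 3, 3) == "A")
  )
})

test_that("the base-specific third-base definition stays within bounds", {
  g <- generate_cds_set(synthetic_spec(n_genes = 12, seed = 17))
  default_idx <- gene_index_table(g$records)
  compat_idx <- gene_index_table(g$records, codonw_compat = TRUE)
  for (col in c("a3s", "t3s", "g3s", "c3s")) {
    expect_true(all(compat_idx[[col]] >= 0 & compat_idx[[col]] <= 1))
  }
  # compat fractions use larger (base-specific) denominators than the
  # shared-denominator default, so they are never smaller
  expect_true(all(compat_idx$a3s >= default_idx$a3s - 1e-12))
  expect_true(all(compat_idx$g3s >= default_idx$g3s - 1e-12))
  # and they do not sum to 1
  tot <- compat_idx$a3s + compat_idx$t3s + compat_idx$g3s + compat_idx$c3s
  expect_false(isTRUE(all.equal(tot, rep(1, length(tot)))))
})

test_that("gene_index_table is the row-wise composition of single-gene calls", {
  g <- generate_cds_set(synthetic_spec(n_genes = 6, seed = 2))
  idx <- gene_index_table(g$records)
  expect_equal(nrow(idx), 6)
  i <- 4
  ct <- count_codons(g$records$sequence[i])
  expect_equal(idx$l_aa[i], sum(ct))
  expect_equal(idx$enc[i], enc(ct))
  expect_equal(idx$gc3[i], unname(gc_by_position(ct)["gc3"]))
  expect_equal(
    idx$gc3s[i],
    unname(synonymous_third_base_composition(ct)["gc3s"])
  )
  expect_equal(nrow(gene_index_table(g$records[0, ])), 0)
})
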