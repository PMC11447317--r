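# A miniature GenBank flat file exercising forward, complement and join
# locations, written programmatically. Sequence (30 nt):
#   positions 1..6   ATGTAA (forward CDS)
#   positions 7..12  TTACAT = revcomp(ATGTAA) (complement CDS)
#   join(13..15,19..21) -> ATG + TAG (split CDS with an intervening gap)
write_toy_genbank <- function(path) {
  seq30 <- "atgtaattacatatgxxxtagccccccccc"
  seq30 <- gsub("x", "g", seq30)
  writeLines(c(
    "LOCUS       TOY00001                30 bp    DNA     circular PLN",
    "DEFINITION  toy record for parser tests.",
    "FEATURES             Location/Qualifiers",
    "     source          1..30",
    "     CDS             1..6",
    "                     /gene=\"fwd\"",
    "     CDS             complement(7..12)",
    "                     /gene=\"rev\"",
    "     CDS             join(13..15,19..21)",
    "                     /locus_tag=\"split\"",
    "ORIGIN",
    paste0("        1 ", paste(substring(seq30, seq(1, 30, 10),
      seq(10, 30, 10)
    ), collapse = " ")),
    "//"
  ), path)
  path
}

test_that("GenBank CDS features are extracted with strand and splicing", {
  gb <- write_toy_genbank(withr::local_tempfile(fileext = ".gb"))
  recs <- read_cds_collection(gb, format = "genbank")
  expect_equal(nrow(recs), 3)
  expect_equal(recs$gene_name, c("fwd", "rev", "split"))
  expect_equal(recs$sequence[recs$gene_name == "fwd"], "ATGTAA")
  expect_equal(recs$sequence[recs$gene_name == "rev"], "ATGTAA")
  expect_equal(recs$sequence[recs$gene_name == "split"], "ATGTAG")
  expect_equal(unique(recs$species_id), "TOY00001")
})

test_that("a CDS with an out-of-range span is a rejection, not a crash", {
  gb <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       BADTOY                12 bp    DNA     linear PLN",
    "FEATURES             Location/Qualifiers",
    "     CDS             1..6",
    "                     /gene=\"ok\"",
    "     CDS             10..99",
    "                     /gene=\"broken\"",
    "ORIGIN",
    "        1 atgtaaatgtaa",
    "//"
  ), gb)
  recs <- read_cds_collection(gb, format = "genbank")
  expect_equal(recs$gene_name, "ok")
  fails <- attr(recs, "extraction_failures")
  expect_equal(fails$gene_name, "broken")
})

test_that("non-GenBank input is rejected with the file named", {
  bad <- withr::local_tempfile(fileext = ".gb")
  writeLines("this is not a flat file", bad)
  expect_error(read_cds_collection(bad, format = "genbank"), "LOCUS")
  expect_error(read_cds_collection("no/such/file.gb", format = "genbank"),
    "not found"
  )
})

test_that("FASTA round trip preserves a CDS collection", {
  g <- generate_cds_set(synthetic_spec(n_genes = 8, seed = 11,
    species_id = "spA"
  ))
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_cds_fasta(g$records, fa)
  back <- read_cds_collection(fa, format = "fasta")
  expect_equal(back$gene_name, g$records$gene_name)
  expect_equal(back$species_id, g$records$species_id)
  expect_equal(back$sequence, g$records$sequence)
})

test_that("an empty collection writes an empty FASTA", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_cds_fasta(toy_records(character(0)), fa)
  expect_true(file.exists(fa))
  expect_equal(file.size(fa), 0)
})

test_that("filter rules fire in order and are reported per gene", {
  clean <- paste0("ATG", strrep("GAA", 99), "TAA") # 303 nt, valid
  short <- paste0("ATG", strrep("GAA", 48), "TAA") # 150 nt
  internal <- paste0("ATG", "TAA", strrep("GAA", 98), "TAA") # internal stop
  res <- filter_cds(toy_records(c(clean, short, internal)))
  expect_equal(res$report$n_retained, 1)
  expect_equal(res$records$gene_name, "g1")
  expect_setequal(res$report$rejections$rule, c("TOO_SHORT", "INTERNAL_STOP"))
  expect_equal(
    res$report$n_input,
    res$report$n_retained + nrow(res$report$rejections)
  )
})

test_that("every rejection rule is reachable and the first failure wins", {
  base <- paste0("ATG", strrep("GAA", 99), "TAA")
  recs <- toy_records(
    c(
      base,
      base, # DUPLICATE by name (same gene name below)
      paste0(base, "A"), # NOT_TRIPLET
      paste0("ATG", strrep("GAN", 99), "TAA"), # BAD_BASE
      paste0("TTG", strrep("GAA", 99), "TAA"), # BAD_START
      paste0("ATG", strrep("GAA", 99), "CAA"), # BAD_STOP
      # too short AND bad start: TOO_SHORT is tested first
      paste0("TTG", strrep("GAA", 10), "TAA")
    ),
    genes = c("a", "A", "b", "c", "d", "e", "f")
  )
  res <- filter_cds(recs)
  expect_equal(
    res$report$rejections$rule,
    c("DUPLICATE", "NOT_TRIPLET", "BAD_BASE", "BAD_START", "BAD_STOP",
      "TOO_SHORT")
  )
  # exact-sequence dedup catches identical copies under a different name
  res2 <- filter_cds(toy_records(c(base, base), genes = c("x", "y")))
  expect_equal(res2$report$rejections$rule, "DUPLICATE")
  res3 <- filter_cds(toy_records(c(base, base), genes = c("x", "y")),
    dedup_sequence = FALSE
  )
  expect_equal(res3$report$n_retained, 2)
})

test_that("the length threshold boundary is >= by default, > behind a flag", {
  exactly300 <- paste0("ATG", strrep("GAA", 98), "TAA")
  expect_equal(nchar(exactly300), 300)
  expect_equal(filter_cds(toy_records(exactly300))$report$n_retained, 1)
  strict <- filter_cds(toy_records(exactly300), strict_greater = TRUE)
  expect_equal(strict$report$rejections$rule, "TOO_SHORT")
})

test_that("filtering is idempotent and preserves input order", {
  g <- generate_cds_set(synthetic_spec(n_genes = 30, seed = 5))
  once <- filter_cds(g$records)
  twice <- filter_cds(once$records)
  expect_equal(twice$records, once$records)
  expect_equal(nrow(twice$report$rejections), 0)
  expect_equal(once$records$gene_name, g$records$gene_name)
  # empty input
  empty <- filter_cds(toy_records(character(0)))
  expect_equal(empty$report$n_input, 0)
  expect_equal(nrow(empty$report$rejections), 0)
})

test_that("retained total length is three times the retained codon count", {
  g <- generate_cds_set(synthetic_spec(n_genes = 20, seed = 8))
  kept <- filter_cds(g$records)$records
  idx <- gene_index_table(kept)
  expect_equal(sum(nchar(kept$sequence)), 3 * sum(idx$l_aa))
})
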