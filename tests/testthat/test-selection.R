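make_idx <- function(gc12, gc3) {
  # index rows with GC1 = GC2 = GC12 so that (gc1 + gc2)/2 = gc12
  tibble::tibble(
    gene_name = paste0("g", seq_along(gc3)),
    species_id = "s",
    gc1 = gc12, gc2 = gc12, gc3 = gc3
  )
}

test_that("points on the identity line give slope 1 and r 1", {
  res <- neutrality_analysis(make_idx(gc12 = c(20, 30, 40, 50),
                                      gc3 = c(20, 30, 40, 50)))
  expect_equal(res$slope, 1)
  expect_equal(res$pearson_r, 1)
  expect_equal(res$mutation_contribution, 100)
  expect_equal(res$n_genes, 4)
})

test_that("degenerate GC3 variance yields missing regression fields", {
  res <- neutrality_analysis(make_idx(gc12 = c(20, 30, 40),
                                      gc3 = c(25, 25, 25)))
  expect_true(is.na(res$slope))
  expect_true(is.na(res$pearson_r))
  expect_equal(res$n_genes, 3)
})

test_that("neutrality regression recovers the generator regimes", {
  mut <- generate_cds_set(synthetic_spec(
    n_genes = 200, regime = "mutation", seed = 1
  ))
  res_m <- neutrality_analysis(gene_index_table(mut$records))
  expect_gte(res_m$slope, 0.8)
  expect_lte(res_m$slope, 1.2)
  expect_gt(res_m$pearson_r, 0.8)
  expect_lt(res_m$p_value, 1e-6)

  sel <- generate_cds_set(synthetic_spec(
    n_genes = 200, regime = "selection", seed = 1
  ))
  res_s <- neutrality_analysis(gene_index_table(sel$records))
  expect_gte(res_s$slope, -0.1)
  expect_lte(res_s$slope, 0.1)
})

test_that("the ENC expectation curve matches its closed form", {
  expect_equal(enc_expected(0.5), 60.5)
  expect_equal(enc_expected(0), 31)
  expect_equal(enc_expected(0.3), 2.3 + 29 / 0.58)
  expect_equal(enc_expected(0.3), 52.3, tolerance = 1e-3)
  expect_error(enc_expected(1.2), "0, 1")
  expect_error(enc_expected(-0.1), "0, 1")
})

test_that("ENC ratios, bins and the neutral band behave as defined", {
  idx <- tibble::tibble(
    gene_name = c("a", "b", "c"),
    enc = c(60.5, 30, 52.3),
    gc3s = c(50, 50, 30)
  )
  d <- enc_diagnostics(idx)
  expect_equal(d$rows$enc_ratio[1], 0) # observed on the curve
  expect_equal(d$rows$enc_ratio[2], (60.5 - 30) / 60.5, tolerance = 1e-9)
  expect_equal(d$rows$enc_ratio[2], 0.5041, tolerance = 1e-3)
  expect_lt(abs(d$rows$enc_ratio[3]), 0.01)
  # genes below the curve (smaller observed ENC) have positive ratio
  expect_gt(d$rows$enc_ratio[2], 0)
  # binning conserves the gene count
  expect_equal(sum(d$histogram$n), 3)
  expect_equal(d$n_neutral_band, 2)
  # bins are width 0.05 centred on 0
  expect_true(any(abs(d$histogram$bin_low + 0.025) < 1e-9))
  expect_equal(unique(round(diff(d$histogram$bin_low), 9)), 0.05)
})

test_that("PR2 places symmetric usage at the centre", {
  idx <- tibble::tibble(
    gene_name = "g",
    a3s = 0.3, t3s = 0.3, g3s = 0.2, c3s = 0.2
  )
  p <- pr2_analysis(idx)
  expect_equal(p$points$x, 0.5)
  expect_equal(p$points$y, 0.5)
})

test_that("PR2 quadrants are numbered counter-clockwise with low-index ties", {
  idx <- tibble::tibble(
    gene_name = c("q1", "q2", "q3", "q4", "tie_x", "center"),
    a3s = c(0.6, 0.2, 0.2, 0.6, 0.25, 0.25),
    t3s = c(0.2, 0.6, 0.6, 0.2, 0.25, 0.25),
    g3s = c(0.15, 0.15, 0.05, 0.05, 0.3, 0.25),
    c3s = c(0.05, 0.05, 0.15, 0.15, 0.2, 0.25)
  )
  p <- pr2_analysis(idx)
  expect_equal(p$points$quadrant, c(1L, 2L, 3L, 4L, 1L, 1L))
  expect_equal(sum(p$quadrant_counts), 6)
})

test_that("PR2 flags genes with a degenerate denominator", {
  idx <- tibble::tibble(
    gene_name = c("noAT", "ok"),
    a3s = c(0, 0.5), t3s = c(0, 0.25),
    g3s = c(0.6, 0.15), c3s = c(0.4, 0.10)
  )
  p <- pr2_analysis(idx)
  expect_true(is.na(p$points$x[1]))
  expect_true(is.na(p$points$quadrant[1]))
  expect_false(is.na(p$points$x[2]))
})

test_that("PR2 means recover the generator's true codon-model coordinates", {
  g <- generate_cds_set(synthetic_spec(
    n_genes = 500, regime = "uniform", seed = 1
  ))
  p <- pr2_analysis(gene_index_table(g$records))
  expect_lt(abs(p$mean_x - g$truth$expected_pr2_center[["x"]]), 0.02)
  expect_lt(abs(p$mean_y - g$truth$expected_pr2_center[["y"]]), 0.02)
})

test_that("selection diagnostics are invariant to gene order", {
  g <- generate_cds_set(synthetic_spec(n_genes = 40, seed = 23))
  idx <- gene_index_table(g$records)
  perm <- idx[sample(nrow(idx)), ]
  expect_equal(neutrality_analysis(idx), neutrality_analysis(perm))
  expect_equal(
    enc_diagnostics(idx)$histogram,
    enc_diagnostics(perm)$histogram
  )
  expect_equal(
    pr2_analysis(idx)$quadrant_counts,
    pr2_analysis(perm)$quadrant_counts
  )
})
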