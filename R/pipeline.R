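# End-to-end orchestration: extract -> filter -> indices -> selection
# diagnostics -> correlation -> optimal codons -> clustering, with a tidy
# report bundle written to disk.

#' Run the full codon-usage-bias pipeline
#'
#' Executes every stage for one or more species and writes the complete
#' report bundle: per-gene index table, species RSCU table, neutrality
#' regression, ENC-plot table and ENC-ratio histogram, PR2 table, Spearman
#' correlations, delta-RSCU and optimal codons, a per-species summary, the
#' filtering report, a run log of every decision flag in effect, and (when
#' at least two species are present) the RSCU cluster tree as Newick. All
#' tables are tab-separated; figures are SVG regenerable from the tables.
#'
#' @param inputs A named list (names = species labels). Each element is
#'   either a CDS tibble (e.g. from [generate_cds_set()]) or a list
#'   `list(paths =, format =)` understood by [read_cds_collection()].
#' @param out_dir Output directory, created if needed.
#' @param min_length,strict_greater,dedup_sequence Passed to [filter_cds()].
#' @param codonw_compat Passed to [gene_index_table()].
#' @param fraction,delta_threshold,strict_delta,literal_direction Optimal
#'   codon settings (see [optimal_codon_set()]).
#' @param cluster_metric,cluster_linkage Clustering settings (see
#'   [hierarchical_cluster()]).
#' @param make_figures Write SVG figures (default TRUE).
#' @return Invisibly, a list with all in-memory results: `records`,
#'   `filter_reports`, `indices`, `rscu_species`, `neutrality`,
#'   `enc_diagnostics`, `pr2`, `correlation`, `optimal`, `cluster` (NULL for
#'   a single species), `summary`.
#' @export
run_pipeline <- function(inputs, out_dir,
                         min_length = 300, strict_greater = FALSE,
                         dedup_sequence = TRUE, codonw_compat = FALSE,
                         fraction = 0.10, delta_threshold = 0.08,
                         strict_delta = FALSE, literal_direction = FALSE,
                         cluster_metric = "euclidean",
                         cluster_linkage = "average",
                         make_figures = TRUE) {
  stopifnot(is.list(inputs), length(inputs) >= 1L)
  if (is.null(names(inputs)) || any(names(inputs) == "")) {
    stop("inputs must be a fully named list (names = species labels)",
      call. = FALSE
    )
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(d, f) {
    write.table(d, file.path(out_dir, f),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }

  species <- names(inputs)
  raw <- lapply(species, function(sp) {
    x <- inputs[[sp]]
    if (is.data.frame(x)) {
      x$species_id <- sp
      x
    } else {
      read_cds_collection(x$paths, format = x$format, species_id = sp)
    }
  })
  names(raw) <- species

  filtered <- lapply(raw, filter_cds,
    min_length = min_length, strict_greater = strict_greater,
    dedup_sequence = dedup_sequence
  )
  records <- lapply(filtered, `[[`, "records")
  reports <- lapply(filtered, `[[`, "report")

  idx <- dplyr::bind_rows(lapply(records, gene_index_table,
    codonw_compat = codonw_compat
  ))
  rscu_sp <- lapply(records, function(r) rscu(merge_counts(.count_records(r))))

  by_sp <- split(idx, idx$species_id)[species]
  neut <- dplyr::bind_rows(lapply(by_sp, neutrality_analysis), .id = "species_id")
  encd <- lapply(by_sp, enc_diagnostics)
  pr2 <- lapply(by_sp, pr2_analysis)
  corr <- lapply(by_sp, spearman_matrix)
  optim <- lapply(species, function(sp) {
    optimal_codon_set(records[[sp]],
      index_rows = by_sp[[sp]],
      fraction = fraction, threshold = delta_threshold,
      strict_greater = strict_delta, literal_direction = literal_direction
    )
  })
  names(optim) <- species

  cluster <- NULL
  if (length(species) >= 2L) {
    cluster <- hierarchical_cluster(
      rscu_matrix(rscu_sp),
      linkage = cluster_linkage, metric = cluster_metric
    )
    write_cluster_newick(cluster, file.path(out_dir, "cluster.nwk"))
  }

  summary_tab <- dplyr::bind_rows(lapply(species, function(sp) {
    r <- records[[sp]]
    i <- by_sp[[sp]]
    tibble::tibble(
      species_id = sp,
      n_cds_input = reports[[sp]]$n_input,
      n_cds_retained = reports[[sp]]$n_retained,
      total_nt = sum(nchar(r$sequence)),
      total_codons = sum(i$l_aa),
      enc_min = min(i$enc, na.rm = TRUE),
      enc_max = max(i$enc, na.rm = TRUE),
      gc3_min = min(i$gc3, na.rm = TRUE),
      gc3_max = max(i$gc3, na.rm = TRUE),
      n_optimal_codons = length(optim[[sp]]$optimal_set),
      optimal_codons = paste(optim[[sp]]$optimal_set, collapse = ",")
    )
  }))

  # --- write the bundle ---
  tsv(idx, "gene_indices.tsv")
  rscu_wide <- dplyr::bind_rows(rscu_sp, .id = "species_id") %>%
    dplyr::select("species_id", "codon", "aa", "rscu") %>%
    tidyr::pivot_wider(names_from = "species_id", values_from = "rscu")
  tsv(rscu_wide, "rscu_species.tsv")
  tsv(neut, "neutrality.tsv")
  tsv(
    dplyr::bind_rows(lapply(encd, `[[`, "rows"), .id = "species_id"),
    "enc_plot.tsv"
  )
  tsv(
    dplyr::bind_rows(lapply(encd, `[[`, "histogram"), .id = "species_id"),
    "enc_ratio_hist.tsv"
  )
  tsv(
    dplyr::bind_rows(lapply(pr2, `[[`, "points"), .id = "species_id"),
    "pr2.tsv"
  )
  tsv(
    dplyr::bind_rows(lapply(corr, `[[`, "long"), .id = "species_id"),
    "correlation.tsv"
  )
  tsv(
    dplyr::bind_rows(lapply(optim, `[[`, "delta"), .id = "species_id"),
    "delta_rscu.tsv"
  )
  tsv(
    dplyr::bind_rows(lapply(optim, function(o) {
      tibble::tibble(
        species_id = o$species_id,
        codon = o$optimal_set
      )
    })),
    "optimal_codons.tsv"
  )
  tsv(
    dplyr::bind_rows(lapply(reports, function(rp) rp$rejections)),
    "filter_report.tsv"
  )
  tsv(summary_tab, "summary.tsv")
  flags <- tibble::tibble(
    flag = c(
      "min_length", "strict_greater", "dedup_sequence", "codonw_compat",
      "fraction", "delta_threshold", "strict_delta", "literal_direction",
      "cluster_metric", "cluster_linkage"
    ),
    value = as.character(c(
      min_length, strict_greater, dedup_sequence, codonw_compat,
      fraction, delta_threshold, strict_delta, literal_direction,
      cluster_metric, cluster_linkage
    ))
  )
  tsv(flags, "run_log.tsv")

  if (make_figures && nrow(idx) > 0) {
    .save_svg(plot_neutrality(idx), file.path(out_dir, "neutrality.svg"))
    .save_svg(plot_enc(idx), file.path(out_dir, "enc_plot.svg"))
    .save_svg(
      plot_enc_ratio_hist(
        dplyr::bind_rows(lapply(encd, `[[`, "histogram"),
          .id = "species_id"
        )
      ),
      file.path(out_dir, "enc_ratio_hist.svg")
    )
    .save_svg(
      plot_pr2(
        dplyr::bind_rows(lapply(pr2, `[[`, "points"), .id = "species_id")
      ),
      file.path(out_dir, "pr2.svg")
    )
    .save_svg(plot_rscu_bars(rscu_sp), file.path(out_dir, "rscu_bars.svg"))
    .save_svg(plot_gc_heatmap(idx), file.path(out_dir, "gc_heatmap.svg"),
      height = 8
    )
    if (!is.null(cluster)) {
      grDevices::svg(file.path(out_dir, "dendrogram.svg"), width = 6,
                     height = 5)
      plot(cluster$phylo, main = "RSCU-based clustering")
      grDevices::dev.off()
    }
  }

  invisible(list(
    records = records, filter_reports = reports, indices = idx,
    rscu_species = rscu_sp, neutrality = neut, enc_diagnostics = encd,
    pr2 = pr2, correlation = corr, optimal = optim, cluster = cluster,
    summary = summary_tab
  ))
}
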