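# Seeded generator of plastome-like CDS collections with known ground truth.
# Every gene it emits starts with ATG, ends with a stop codon, contains no
# internal stop and is codon-aligned, so generated sets pass filter_cds()
# untouched.

# Fixed amino-acid frequency profile loosely resembling plastid proteins
# (hydrophobic-rich, Leu/Ile/Ser-heavy); normalised at use.
AA_PROFILE <- c(
  L = 10.5, I = 8.5, S = 7.8, G = 6.8, F = 6.5, A = 6.0, V = 6.0,
  T = 5.5, E = 5.0, K = 5.0, R = 5.0, N = 4.5, P = 4.5, D = 4.0,
  Q = 3.5, Y = 3.5, H = 2.5, M = 2.5, W = 2.0, C = 1.5
)

# Synonymous third-position weights giving every multi-codon family the same
# conditional third-base GC share h: within a family the GC-ending codons
# split weight h equally and the AT-ending codons split 1 - h. Because the
# share is identical across families, a gene's realised GC3 is decoupled
# from its amino-acid composition (the GC12 channel).
.third_position_weights <- function(sense, aa_of_sense, h) {
  third_gc <- substr(sense, 3, 3) %in% c("G", "C")
  n_gc <- tapply(third_gc, aa_of_sense, sum)[aa_of_sense]
  n_at <- tapply(!third_gc, aa_of_sense, sum)[aa_of_sense]
  unname(ifelse(third_gc, h / pmax(n_gc, 1), (1 - h) / pmax(n_at, 1)))
}

# Default up-weighted codon set for the "biased" regime: one codon per
# multi-codon family, the alphabetically first ending in A, else in T
# (mimicking the A/T-ending preference of plastomes).
.default_preferred <- function() {
  gc <- genetic_code()
  fams <- gc$family_of[names(.multi_codon_families())]
  vapply(fams, function(cs) {
    third <- substr(cs, 3, 3)
    if (any(third == "A")) sort(cs[third == "A"])[1] else {
      sort(cs[third == "T"])[1]
    }
  }, character(1), USE.NAMES = FALSE)
}

#' Specification of a synthetic plastome-like CDS collection
#'
#' Bundles and validates the generator parameters. Defaults emulate the CDS
#' complement of one plastome after quality filtering: about 50 genes of
#' 300-7,000 nt with AT-rich third positions (GC3 roughly 22-37%).
#'
#' Regimes (the ground truth each one encodes):
#' * `"mutation"` — a gene-specific GC-pressure parameter g drawn uniformly
#'   from `gc3_target_range` drives base choice at all three codon positions
#'   (whole codons are drawn from an independent-base model tilted to GC
#'   content g, stop codons excluded), coupling GC12 to GC3: expected
#'   neutrality slope about 1.
#' * `"selection"` — the two channels are decoupled: a per-gene Dirichlet
#'   perturbation of the amino-acid profile makes GC12 vary, while the
#'   third-position GC preference is drawn from `gc3_target_range`
#'   independently of it (every synonymous family carries the same
#'   conditional third-base GC share, so the amino-acid mix cannot leak
#'   into GC3): expected slope about 0.
#' * `"uniform"` — equal use within every synonymous family: per-codon RSCU
#'   tends to 1 and ENC to 61.
#' * `"biased"` — a designated codon subset (default [.default_preferred]
#'   style: one AT-ending codon per family) is up-weighted by a per-gene
#'   intensity uniform on (0, `codon_preference_strength`), for
#'   optimal-codon recovery tests.
#'
#' @param n_genes Number of genes (default 51, a typical filtered plastome
#'   CDS count).
#' @param length_range Min/max gene length in nt (default 300-7,002, the
#'   span of filtered plastome CDS lengths); lengths are codon-aligned.
#' @param regime One of `"mutation"`, `"selection"`, `"uniform"`, `"biased"`.
#' @param gc3_target_range GC-pressure range for the mutation regime.
#' @param codon_preference_strength Up-weighting strength for `"biased"`.
#' @param preferred_codons Optional DNA codon vector for `"biased"`.
#' @param species_id Species label stamped on every record.
#' @param seed Integer seed; the single source of randomness.
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genes = 51, length_range = c(300, 7002),
                           regime = c(
                             "mutation", "selection", "uniform", "biased"
                           ),
                           gc3_target_range = c(0.22, 0.37),
                           codon_preference_strength = 2,
                           preferred_codons = NULL,
                           species_id = "synthetic", seed = 1) {
  regime <- match.arg(regime)
  stopifnot(
    n_genes >= 1, length(length_range) == 2, length_range[1] >= 9,
    length_range[2] >= length_range[1],
    length(gc3_target_range) == 2,
    gc3_target_range[1] >= 0, gc3_target_range[2] <= 1,
    gc3_target_range[1] <= gc3_target_range[2],
    codon_preference_strength >= 0
  )
  if (is.null(preferred_codons)) preferred_codons <- .default_preferred()
  preferred_codons <- codon_to_dna(preferred_codons)
  stopifnot(all(preferred_codons %in% setdiff(CODONS, STOP_CODONS)))
  structure(
    list(
      n_genes = as.integer(n_genes),
      length_range = as.integer(length_range),
      regime = regime,
      gc3_target_range = gc3_target_range,
      codon_preference_strength = codon_preference_strength,
      preferred_codons = preferred_codons,
      species_id = species_id,
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic CDS collection with known ground truth
#'
#' Draws `spec$n_genes` coding sequences gene by gene, codon by codon, from
#' the regime-specific codon model (see [synthetic_spec()]). Output is fully
#' reproducible from the seed and always passes [filter_cds()] unchanged.
#'
#' @param spec A [synthetic_spec()].
#' @return A list: `records` (CDS tibble) and `truth`, a list carrying the
#'   regime, its parameters, the expected neutrality slope and PR2 centre,
#'   the up-weighted codon set (biased regime), and `per_gene` — a tibble of
#'   each gene's true parameters and third-position base probabilities.
#' @export
generate_cds_set <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(spec$seed, kind = "Mersenne-Twister")

  gc <- genetic_code()
  sense <- setdiff(CODONS, STOP_CODONS)
  aa_of_sense <- gc$codon_to_aa[sense]
  prof <- AA_PROFILE / sum(AA_PROFILE)
  syn <- aa_of_sense %in% names(.multi_codon_families())
  third <- substr(sense, 3, 3)

  # codon-length grid honouring the nt length range
  lo <- ceiling(spec$length_range[1] / 3)
  hi <- floor(spec$length_range[2] / 3)
  if (hi < lo) stop("length_range admits no codon-aligned length",
    call. = FALSE
  )

  codon_probs_for_gene <- function() {
    # returns list(prob over `sense`, params recorded for the truth table)
    switch(spec$regime,
      mutation = {
        g <- runif(1, spec$gc3_target_range[1], spec$gc3_target_range[2])
        pb <- c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
        p <- pb[substr(sense, 1, 1)] * pb[substr(sense, 2, 2)] *
          pb[substr(sense, 3, 3)]
        list(prob = p / sum(p), g = g, bias = NA_real_)
      },
      selection = {
        # GC12 channel: per-gene Dirichlet perturbation of the amino-acid
        # profile, restricted to the multi-codon families (Met and Trp,
        # whose third base is always G, stay at their profile share so the
        # amino-acid mix cannot leak into GC3). GC3 channel: a per-gene
        # third-position GC preference drawn independently of it.
        vary <- setdiff(names(prof), c("M", "W"))
        w <- rgamma(length(vary), shape = prof[vary] * 500)
        aa_w <- prof
        aa_w[vary] <- (1 - prof[["M"]] - prof[["W"]]) * w / sum(w)
        h <- runif(1, spec$gc3_target_range[1], spec$gc3_target_range[2])
        syn_w <- .third_position_weights(sense, aa_of_sense, h)
        p <- unname(aa_w[aa_of_sense]) * syn_w /
          tapply(syn_w, aa_of_sense, sum)[aa_of_sense]
        list(prob = unname(p / sum(p)), g = h, bias = NA_real_)
      },
      uniform = {
        p <- unname(prof[aa_of_sense]) /
          unname(table(aa_of_sense)[aa_of_sense])
        list(prob = as.numeric(p / sum(p)), g = NA_real_, bias = NA_real_)
      },
      biased = {
        b <- runif(1, 0, spec$codon_preference_strength)
        syn_w <- ifelse(sense %in% spec$preferred_codons, 1 + b, 1)
        p <- unname(prof[aa_of_sense]) * syn_w /
          tapply(syn_w, aa_of_sense, sum)[aa_of_sense]
        list(prob = unname(p / sum(p)), g = NA_real_, bias = b)
      }
    )
  }

  len_grid <- seq.int(lo, hi)
  n_codons <- if (length(len_grid) == 1L) {
    rep(len_grid, spec$n_genes)
  } else {
    sample(len_grid, spec$n_genes, replace = TRUE)
  }
  gene_names <- sprintf("sgene%03d", seq_len(spec$n_genes))
  seqs <- character(spec$n_genes)
  per_gene <- vector("list", spec$n_genes)
  for (i in seq_len(spec$n_genes)) {
    model <- codon_probs_for_gene()
    m <- n_codons[i] - 2L # interior codons between ATG and the stop
    interior <- sample(sense, m, replace = TRUE, prob = model$prob)
    stop_codon <- sample(STOP_CODONS, 1, prob = c("TAA" = 0.6, "TAG" = 0.2,
                                                  "TGA" = 0.2)[STOP_CODONS])
    seqs[i] <- paste0("ATG", paste(interior, collapse = ""), stop_codon)
    p3 <- tapply(model$prob, third, sum)
    # true PR2 coordinates of the gene's codon model (synonymous families)
    syn_p <- function(b) sum(model$prob[syn & third == b])
    per_gene[[i]] <- tibble::tibble(
      gene_name = gene_names[i],
      n_codons = n_codons[i],
      g = model$g,
      bias_intensity = model$bias,
      p3_a = p3[["A"]], p3_c = p3[["C"]], p3_g = p3[["G"]], p3_t = p3[["T"]],
      pr2_x_true = syn_p("A") / (syn_p("A") + syn_p("T")),
      pr2_y_true = syn_p("G") / (syn_p("G") + syn_p("C"))
    )
  }

  records <- cds_tibble(
    gene_name = gene_names,
    species_id = spec$species_id,
    sequence = seqs,
    source_location = paste0("synthetic:", gene_names)
  )
  truth <- list(
    regime = spec$regime,
    seed = spec$seed,
    gc3_target_range = spec$gc3_target_range,
    codon_preference_strength = spec$codon_preference_strength,
    preferred_codons = if (spec$regime == "biased") {
      spec$preferred_codons
    } else {
      character()
    },
    expected_slope = switch(spec$regime,
      mutation = 1, selection = 0, NA_real_
    ),
    expected_pr2_center = {
      pg <- dplyr::bind_rows(per_gene)
      c(x = mean(pg$pr2_x_true), y = mean(pg$pr2_y_true))
    },
    per_gene = dplyr::bind_rows(per_gene)
  )
  list(records = records, truth = truth)
}

#' Serialise generator ground truth as a flat table
#'
#' @param truth The `truth` element of [generate_cds_set()].
#' @return A tibble with one row per gene plus the regime-level parameters
#'   repeated on each row (regime, expected slope, up-weighted codons).
#' @export
truth_report <- function(truth) {
  pg <- truth$per_gene
  pg$regime <- truth$regime
  pg$seed <- truth$seed
  pg$expected_slope <- truth$expected_slope
  pg$preferred_codons <- paste(codon_to_rna(truth$preferred_codons),
    collapse = ","
  )
  pg
}
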