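# Mutation-versus-selection diagnostics: neutrality plot regression, the
# ENC-plot expectation curve with its frequency-ratio distribution, and the
# PR2 bias plot.

#' Neutrality plot analysis
#'
#' Regresses GC12 (the mean GC content of the first two codon positions) on
#' GC3 across genes. Under pure mutation pressure all three positions drift
#' together and the slope approaches 1; selective constraint on the first two
#' positions pushes the slope towards 0. The slope times 100 is read as the
#' percent contribution of mutation pressure.
#'
#' @param index_rows A per-gene index tibble from [gene_index_table()].
#' @return A one-row tibble: `slope`, `intercept`, `pearson_r`, `r_squared`,
#'   `p_value`, `n_genes`, `mutation_contribution` (= slope * 100). With
#'   degenerate GC3 variance the regression fields are `NA`.
#' @export
neutrality_analysis <- function(index_rows) {
  d <- index_rows[is.finite(index_rows$gc1) & is.finite(index_rows$gc2) &
    is.finite(index_rows$gc3), , drop = FALSE]
  gc12 <- (d$gc1 + d$gc2) / 2
  gc3 <- d$gc3
  n <- length(gc3)
  if (n < 3L || stats::sd(gc3) == 0) {
    return(tibble::tibble(
      slope = NA_real_, intercept = NA_real_, pearson_r = NA_real_,
      r_squared = NA_real_, p_value = NA_real_, n_genes = n,
      mutation_contribution = NA_real_
    ))
  }
  fit <- lm(gc12 ~ gc3)
  ct <- cor.test(gc3, gc12, method = "pearson")
  tibble::tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    pearson_r = unname(ct$estimate),
    r_squared = unname(ct$estimate)^2,
    p_value = ct$p.value,
    n_genes = n,
    mutation_contribution = unname(coef(fit)[2]) * 100
  )
}

#' Expected ENC under mutation pressure alone
#'
#' The mutation-only expectation curve of the ENC-plot:
#' ENCexp = 2 + s + 29 / (s^2 + (1 - s)^2), with s the GC3s fraction.
#'
#' @param gc3s GC3s as a fraction in \[0, 1\] (vectorised).
#' @return Expected ENC values.
#' @examples
#' enc_expected(0.5) # 60.5
#' @export
enc_expected <- function(gc3s) {
  if (any(!is.finite(gc3s)) || any(gc3s < 0 | gc3s > 1)) {
    stop("gc3s must lie in [0, 1]", call. = FALSE)
  }
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' ENC-plot diagnostics and ENC frequency ratio distribution
#'
#' For each gene computes the expected ENC at its GC3s, the frequency ratio
#' (ENCexp - ENCobs)/ENCexp (positive when the observed ENC falls below the
#' mutation-only curve), and bins the ratios into a histogram of width
#' `bin_width` centred on 0. Genes with a ratio inside
#' \[-`neutral_band`, `neutral_band`\] sit close enough to the curve to be
#' read as mutation-dominated.
#'
#' @param index_rows A per-gene index tibble (needs `enc` and `gc3s`).
#' @param bin_width Histogram bin width (default 0.05).
#' @param neutral_band Half-width of the near-curve band (default 0.05).
#' @return A list: `rows` (tibble gene_name, enc_obs, gc3s, enc_exp,
#'   enc_ratio), `histogram` (tibble bin_low, bin_high, bin_mid, n),
#'   `n_neutral_band` (genes with |ratio| <= `neutral_band`).
#' @export
enc_diagnostics <- function(index_rows, bin_width = 0.05,
                            neutral_band = 0.05) {
  s <- index_rows$gc3s / 100
  rows <- tibble::tibble(
    gene_name = index_rows$gene_name,
    enc_obs = index_rows$enc,
    gc3s = index_rows$gc3s,
    enc_exp = enc_expected(s),
    enc_ratio = (enc_expected(s) - index_rows$enc) / enc_expected(s)
  )
  r <- rows$enc_ratio[is.finite(rows$enc_ratio)]
  half <- bin_width / 2
  k_lo <- floor((min(r) + half) / bin_width)
  k_hi <- ceiling((max(r) - half) / bin_width)
  breaks <- seq(k_lo * bin_width - half, k_hi * bin_width + half,
                by = bin_width)
  h <- hist(r, breaks = breaks, plot = FALSE, right = FALSE,
            include.lowest = TRUE)
  list(
    rows = rows,
    histogram = tibble::tibble(
      bin_low = h$breaks[-length(h$breaks)],
      bin_high = h$breaks[-1],
      bin_mid = h$mids,
      n = h$counts
    ),
    n_neutral_band = sum(abs(r) <= neutral_band)
  )
}

#' PR2 (parity rule 2) bias plot
#'
#' Plots each gene at x = A3s/(A3s + T3s), y = G3s/(G3s + C3s), computed on
#' synonymous-family third positions. Under strand-symmetric mutation alone
#' both coordinates sit at 0.5; displacement marks base-specific bias.
#' Quadrants are numbered counter-clockwise from the upper right around the
#' centre (0.5, 0.5); a point lying exactly on a dividing line is assigned
#' the lowest quadrant index whose closed quadrant contains it.
#'
#' @param index_rows A per-gene index tibble (needs a3s, t3s, g3s, c3s).
#' @return A list: `points` (tibble gene_name, x, y, quadrant; undefined
#'   coordinates are `NA` with quadrant `NA`), `quadrant_counts` (named
#'   vector over quadrants 1-4), `fraction_below_center` (genes with
#'   y < 0.5), `mean_x`, `mean_y`.
#' @export
pr2_analysis <- function(index_rows) {
  at <- index_rows$a3s + index_rows$t3s
  gcd <- index_rows$g3s + index_rows$c3s
  x <- ifelse(at > 0, index_rows$a3s / at, NA_real_)
  y <- ifelse(gcd > 0, index_rows$g3s / gcd, NA_real_)
  quadrant <- mapply(function(xi, yi) {
    if (!is.finite(xi) || !is.finite(yi)) {
      return(NA_integer_)
    }
    cand <- c(
      xi >= 0.5 && yi >= 0.5, # 1: upper right
      xi <= 0.5 && yi >= 0.5, # 2: upper left
      xi <= 0.5 && yi <= 0.5, # 3: lower left
      xi >= 0.5 && yi <= 0.5  # 4: lower right
    )
    which(cand)[1]
  }, x, y)
  pts <- tibble::tibble(
    gene_name = index_rows$gene_name,
    x = x, y = y, quadrant = as.integer(quadrant)
  )
  qc <- table(factor(pts$quadrant, levels = 1:4))
  list(
    points = pts,
    quadrant_counts = setNames(as.integer(qc), paste0("Q", 1:4)),
    fraction_below_center = mean(y < 0.5, na.rm = TRUE),
    mean_x = mean(x, na.rm = TRUE),
    mean_y = mean(y, na.rm = TRUE)
  )
}
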