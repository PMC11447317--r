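# Spearman rank correlation among per-gene codon usage indices.

#' Spearman correlation matrix of codon usage indices
#'
#' Computes Spearman's rho (average-rank tie handling) between all pairs of
#' the requested indices across genes, with two-sided p-values from the
#' t approximation t = rho * sqrt((n - 2) / (1 - rho^2)), and the usual
#' significance stars (`*` p < 0.05, `**` p < 0.01). No multiple-testing
#' correction is applied; stars annotate each pair on its own.
#'
#' @param index_rows A per-gene index tibble from [gene_index_table()].
#' @param variables Character vector of column names to correlate; defaults
#'   to `c("gc1", "gc2", "gc3", "gc_all", "enc", "l_aa")`.
#' @return A list: `rho`, `p`, `stars` (square matrices over `variables`;
#'   `rho` has unit diagonal; a constant variable gives `NA` off-diagonals),
#'   `n` (rows used), and `long` (tidy tibble var1, var2, rho, p, stars over
#'   the lower triangle).
#' @export
spearman_matrix <- function(index_rows,
                            variables = c(
                              "gc1", "gc2", "gc3", "gc_all", "enc", "l_aa"
                            )) {
  stopifnot(all(variables %in% names(index_rows)))
  d <- index_rows[, variables, drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 complete rows", call. = FALSE)
  k <- length(variables)
  rho <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  p <- rho
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      xi <- d[[i]]
      xj <- d[[j]]
      if (i == j) {
        rho[i, j] <- 1
        p[i, j] <- 0
        next
      }
      if (stats::sd(xi) == 0 || stats::sd(xj) == 0) next
      r <- cor(xi, xj, method = "spearman")
      rho[i, j] <- r
      tval <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
      p[i, j] <- 2 * pt(-abs(tval), df = n - 2)
    }
  }
  stars <- matrix("", k, k, dimnames = dimnames(rho))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  diag(stars) <- ""
  idx <- which(lower.tri(rho), arr.ind = TRUE)
  long <- tibble::tibble(
    var1 = variables[idx[, "row"]],
    var2 = variables[idx[, "col"]],
    rho = rho[idx],
    p = p[idx],
    stars = stars[idx]
  )
  list(rho = rho, p = p, stars = stars, n = n, long = long)
}
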