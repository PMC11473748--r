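#' One-sided hypergeometric enrichment test
#'
#' Upper-tail probability of drawing at least `k` annotated genes in a set of
#' size `n` from a universe of `N` genes of which `K` are annotated, i.e.
#' P(X >= k) for X ~ Hypergeom(N, K, n). Computed via the log-space
#' hypergeometric tail (stats::phyper), accurate far into the tail.
#'
#' @param k observed overlap.
#' @param n set size.
#' @param K annotated genes in the universe.
#' @param N universe size.
#' @return the one-sided upper-tail p-value.
#' @export
hypergeom_test <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || k > min(n, K) || n > N || K > N)
    stop("inconsistent margins: need 0 <= k <= min(n, K) <= N")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Association statistics for a 2x2 contingency table
#'
#' Computes, for the table (a, b; c, d): the chi-square statistic without
#' continuity correction and its p-value; the G (log-likelihood ratio)
#' statistic 2 * sum O log(O/E) with 0 log 0 = 0; Cramer's V = sqrt(chi2/N);
#' the odds ratio ad/bc with a Haldane-Anscombe +0.5 applied to every cell
#' iff any cell is zero (flagged); and Fisher's exact p-value.
#'
#' @param a,b,c,d non-negative integer cell counts (row 1: a, b; row 2: c, d).
#' @return list of class `ContingencyResult` with elements `table`,
#'   `chi_square`, `chi_p`, `g_stat`, `g_p`, `cramers_v`, `odds_ratio`,
#'   `or_corrected` (logical), `fisher_p`, `n`.
#' @export
contingency_stats <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  N <- sum(cells)
  if (N == 0) stop("empty table")
  tab <- matrix(cells, 2, 2, byrow = TRUE,
                dimnames = list(c("row1", "row2"), c("col1", "col2")))
  rs <- rowSums(tab); cs <- colSums(tab)
  E <- outer(rs, cs) / N
  chi2 <- if (any(rs == 0) || any(cs == 0)) 0 else
    N * (a * d - b * c)^2 / (prod(rs) * prod(cs))
  chi_p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  O <- as.vector(tab); Ev <- as.vector(E)
  nz <- O > 0
  g <- 2 * sum(O[nz] * log(O[nz] / Ev[nz]))
  g_p <- pchisq(g, df = 1, lower.tail = FALSE)
  v <- sqrt(chi2 / N)
  corrected <- any(cells == 0)
  oc <- if (corrected) cells + 0.5 else cells
  or <- (oc[1] * oc[4]) / (oc[2] * oc[3])
  fisher_p <- fisher.test(tab)$p.value
  structure(list(table = tab, chi_square = chi2, chi_p = chi_p,
                 g_stat = g, g_p = g_p, cramers_v = v, odds_ratio = or,
                 or_corrected = corrected, fisher_p = fisher_p, n = N),
            class = "ContingencyResult")
}

#' @export
print.ContingencyResult <- function(x, ...) {
  print(x$table)
  cat(sprintf("chi2 = %.4g (p = %.3g), G = %.4g (p = %.3g)\n",
              x$chi_square, x$chi_p, x$g_stat, x$g_p))
  cat(sprintf("Cramer's V = %.4g, odds ratio = %.4g%s, Fisher p = %.3g\n",
              x$cramers_v, x$odds_ratio,
              if (x$or_corrected) " (Haldane-Anscombe corrected)" else "",
              x$fisher_p))
  invisible(x)
}

#' Gene-set enrichment among differentially expressed genes
#'
#' Builds the 2x2 table of set membership against differential expression in
#' the requested direction and reports the full contingency statistics plus
#' the one-sided hypergeometric enrichment p-value.
#'
#' @param de a `DEResult`.
#' @param gene_set character vector of gene IDs (must be within the
#'   universe).
#' @param universe character vector of gene IDs; defaults to all genes in
#'   `de`.
#' @param direction which DE genes count: `up`, `down`, or `any`.
#' @param fdr significance threshold.
#' @return a `ContingencyResult` with extra elements `hyper_p`, `k`,
#'   `set_size`, `K_universe`, `direction`.
#' @export
gene_set_enrichment <- function(de, gene_set, universe = de$gene_id,
                                direction = c("any", "up", "down"),
                                fdr = 0.05) {
  direction <- match.arg(direction)
  gene_set <- unique(gene_set)
  if (length(gene_set) == 0) stop("empty gene set")
  if (!all(gene_set %in% universe)) stop("gene_set must be within the universe")
  d <- .direction(de, fdr)
  hit <- switch(direction, any = d != "ns", up = d == "up", down = d == "down")
  de_genes <- de$gene_id[hit]
  de_genes <- intersect(de_genes, universe)
  N <- length(unique(universe))
  K <- length(de_genes)
  n <- length(gene_set)
  k <- length(intersect(gene_set, de_genes))
  cs <- contingency_stats(k, n - k, K - k, N - n - K + k)
  cs$hyper_p <- hypergeom_test(k, n, K, N)
  cs$k <- k; cs$set_size <- n; cs$K_universe <- K; cs$direction <- direction
  cs
}

#' Project pathways onto the B. napus differential-expression results
#'
#' Maps each pathway's A. thaliana members to B. napus genes through the
#' ortholog map, tabulates member direction calls, and tests for enrichment
#' of up-regulated genes. Hypergeometric p-values are BH-adjusted across
#' pathways.
#'
#' @param pathways named list of character vectors of A. thaliana gene IDs.
#' @param de a `DEResult`.
#' @param orthomap an `OrthologMap`.
#' @param fdr significance threshold for direction calls.
#' @param direction direction tested for enrichment.
#' @return list with `summary` (one row per pathway: member counts by
#'   direction, hypergeometric p, Cramer's V, BH-adjusted p; NA rows for
#'   pathways with no mapped members) and `members` (per-gene direction
#'   calls).
#' @export
pathway_projection <- function(pathways, de, orthomap, fdr = 0.05,
                               direction = "up") {
  om <- as.data.frame(orthomap)
  rows <- list(); members <- list()
  for (pw in names(pathways)) {
    at <- unique(pathways[[pw]])
    bn <- unique(om$bnapus_id[om$athaliana_id %in% at])
    bn <- intersect(bn, de$gene_id)
    if (length(bn) == 0) {
      rows[[pw]] <- data.frame(pathway = pw, n_members = 0L, n_up = NA_integer_,
                               n_down = NA_integer_, n_ns = NA_integer_,
                               hyper_p = NA_real_, cramers_v = NA_real_,
                               stringsAsFactors = FALSE)
      next
    }
    idx <- match(bn, de$gene_id)
    d <- .direction(de[idx, ], fdr)
    en <- gene_set_enrichment(de, bn, direction = direction, fdr = fdr)
    rows[[pw]] <- data.frame(pathway = pw, n_members = length(bn),
                             n_up = sum(d == "up"), n_down = sum(d == "down"),
                             n_ns = sum(d == "ns"), hyper_p = en$hyper_p,
                             cramers_v = en$cramers_v, stringsAsFactors = FALSE)
    members[[pw]] <- data.frame(pathway = pw, gene_id = bn, direction = d,
                                stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, rows)
  summary$padj <- NA_real_
  ok <- !is.na(summary$hyper_p)
  summary$padj[ok] <- p.adjust(summary$hyper_p[ok], method = "BH")
  rownames(summary) <- NULL
  list(summary = summary,
       members = if (length(members)) do.call(rbind, members) else NULL)
}
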