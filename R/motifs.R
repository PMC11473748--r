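.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

.revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

.scan_one_strand <- function(chars, consensus) {
  L <- nchar(consensus)
  n <- length(chars)
  if (n < L) return(0L)
  pat <- strsplit(consensus, "")[[1]]
  ok <- rep(TRUE, n - L + 1)
  for (l in seq_len(L)) {
    allowed <- .IUPAC_SETS[[pat[l]]]
    ok <- ok & chars[l:(n - L + l)] %in% allowed
  }
  sum(ok)
}

#' Count IUPAC consensus matches in a DNA sequence
#'
#' A position matches when every consensus letter's IUPAC class contains the
#' sequence base at that offset. Overlapping matches are counted. An `N` in
#' the sequence matches nothing (the base is unknown, so no claim of a
#' binding site is made). With `both_strands`, the reverse complement of the
#' sequence is scanned as well and the counts summed.
#'
#' @param sequence DNA string over A/C/G/T/N (character or
#'   [Biostrings::DNAString]).
#' @param consensus IUPAC consensus string.
#' @param both_strands scan the reverse complement too.
#' @return integer occurrence count.
#' @export
scan_motif <- function(sequence, consensus, both_strands = TRUE) {
  if (!nzchar(consensus)) stop("empty consensus")
  consensus <- toupper(consensus)
  if (!all(strsplit(consensus, "")[[1]] %in% names(.IUPAC_SETS)))
    stop("consensus contains non-IUPAC characters")
  s <- toupper(as.character(sequence))
  chars <- strsplit(s, "")[[1]]
  cnt <- .scan_one_strand(chars, consensus)
  if (both_strands) {
    rc <- strsplit(.revcomp(s), "")[[1]]
    cnt <- cnt + .scan_one_strand(rc, consensus)
  }
  as.integer(cnt)
}

#' Scan a promoter set for every motif in a motif table
#'
#' @param promoters named character vector or [Biostrings::DNAStringSet] of
#'   promoter sequences, keyed by gene ID.
#' @param motif_set a `MotifSet` (columns `motif_id`, `tf`, `consensus`).
#' @param both_strands scan both strands.
#' @return a `MotifHitTable`: integer matrix of occurrence counts, genes in
#'   rows, motifs in columns; attribute `promoter_length` records per-gene
#'   scanned lengths.
#' @export
scan_motifs <- function(promoters, motif_set, both_strands = TRUE) {
  seqs <- vapply(as.character(promoters), identity, character(1))
  genes <- names(promoters)
  if (is.null(genes)) stop("promoters must be named by gene ID")
  hits <- matrix(0L, length(seqs), nrow(motif_set),
                 dimnames = list(genes, motif_set$motif_id))
  char_list <- strsplit(toupper(seqs), "")
  rc_list <- if (both_strands) lapply(seqs, function(s)
    strsplit(.revcomp(toupper(s)), "")[[1]]) else NULL
  for (j in seq_len(nrow(motif_set))) {
    cons <- motif_set$consensus[j]
    for (i in seq_along(seqs)) {
      cnt <- .scan_one_strand(char_list[[i]], cons)
      if (both_strands) cnt <- cnt + .scan_one_strand(rc_list[[i]], cons)
      hits[i, j] <- cnt
    }
  }
  attr(hits, "promoter_length") <- setNames(nchar(seqs), genes)
  class(hits) <- c("MotifHitTable", class(hits))
  hits
}

#' Motif enrichment among regulated genes
#'
#' For each motif, a gene "contains" the motif when its promoter has at least
#' one occurrence; the 2x2 table of containment against regulation (regulated
#' versus unchanged genes) is tested with the one-sided hypergeometric test
#' and summarized with the full contingency statistics. P-values are
#' BH-adjusted across motifs.
#'
#' @param hits a `MotifHitTable` from [scan_motifs()].
#' @param regulated,unchanged disjoint character vectors of gene IDs.
#' @return data.frame: one row per motif with the 2x2 cells, `hyper_p`,
#'   `cramers_v`, `odds_ratio`, `padj`, ordered as in `hits`.
#' @export
motif_enrichment <- function(hits, regulated, unchanged) {
  if (length(unchanged) == 0) stop("empty unchanged set")
  if (length(intersect(regulated, unchanged)) > 0)
    stop("regulated and unchanged sets must be disjoint")
  genes <- intersect(rownames(hits), c(regulated, unchanged))
  reg <- genes %in% regulated
  out <- lapply(colnames(hits), function(mid) {
    contains <- hits[genes, mid] >= 1
    a <- sum(contains & reg); b <- sum(!contains & reg)
    c <- sum(contains & !reg); d <- sum(!contains & !reg)
    cs <- contingency_stats(a, b, c, d)
    hp <- hypergeom_test(a, sum(reg), sum(contains), length(genes))
    data.frame(motif_id = mid, n_contain_regulated = a,
               n_lack_regulated = b, n_contain_unchanged = c,
               n_lack_unchanged = d, hyper_p = hp,
               cramers_v = cs$cramers_v, odds_ratio = cs$odds_ratio,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$padj <- p.adjust(res$hyper_p, method = "BH")
  rownames(res) <- NULL
  res
}

#' Family-fixed-effects regression of fold change on binding-site counts
#'
#' Fits log2 fold change = beta_bss * n_bss + family effect + error, where
#' the family effects are fixed per-family intercepts absorbing the shared
#' ancestry of paralogs. Estimated by within-family demeaning of response
#' and covariate (Frisch-Waugh) followed by least squares; genes without a
#' family form singleton families (their demeaned contribution is zero).
#' The F test (1 numerator df, N - M - 1 denominator df, M the number of
#' families) tests beta_bss = 0 and is identical to the explicit
#' dummy-variable regression.
#'
#' @param lfc per-gene log2 fold change (response).
#' @param n_bss per-gene binding-site occurrence count for one motif.
#' @param families per-gene family labels (NA = singleton family).
#' @return list of class `BssModel`: `beta_bss`, `se`, `f_stat`, `p_value`,
#'   `df_den`, `n_genes`, `n_families`, `family_effects` (named per-family
#'   intercepts).
#' @export
fit_bss_glm <- function(lfc, n_bss, families) {
  stopifnot(length(lfc) == length(n_bss), length(lfc) == length(families))
  keep <- is.finite(lfc) & is.finite(n_bss)
  y <- lfc[keep]; x <- n_bss[keep]
  fam <- as.character(families[keep])
  fam[is.na(fam)] <- paste0(".singleton", seq_len(sum(is.na(fam))))
  fam <- factor(fam)
  M <- nlevels(fam)
  N <- length(y)
  xbar <- ave(x, fam); ybar <- ave(y, fam)
  xd <- x - xbar; yd <- y - ybar
  sxx <- sum(xd^2)
  if (sxx == 0)
    stop("binding-site counts are constant within every family: ",
         "beta_bss is collinear with the family effects and cannot be estimated")
  beta <- sum(xd * yd) / sxx
  df_den <- N - M - 1L
  if (df_den < 1) stop("not enough residual degrees of freedom")
  rss <- sum((yd - beta * xd)^2)
  sigma2 <- rss / df_den
  se <- sqrt(sigma2 / sxx)
  f <- (beta / se)^2
  p <- pf(f, 1, df_den, lower.tail = FALSE)
  fe <- tapply(y - beta * x, fam, mean)
  fam_eff <- setNames(as.numeric(fe), names(fe))
  structure(list(beta_bss = beta, se = se, f_stat = f, p_value = p,
                 df_den = df_den, n_genes = N, n_families = M,
                 family_effects = fam_eff),
            class = "BssModel")
}

#' @export
print.BssModel <- function(x, ...) {
  cat(sprintf(
    "BssModel: beta_bss = %.4g (SE %.4g), F(1, %d) = %.4g, p = %.3g\n",
    x$beta_bss, x$se, x$df_den, x$f_stat, x$p_value))
  cat(sprintf("  %d genes in %d families\n", x$n_genes, x$n_families))
  invisible(x)
}

#' Trim promoter records to a fixed upstream length
#'
#' Keeps the 3'-most `length` bases of each record (the end closest to the
#' gene start). Shorter records are kept as-is and flagged.
#'
#' @param promoters a named [Biostrings::DNAStringSet] or character vector.
#' @param length promoter length in bases.
#' @return a [Biostrings::DNAStringSet] with attribute `short` (logical per
#'   gene, TRUE when the record was shorter than `length`).
#' @export
extract_promoters <- function(promoters, length = 1000) {
  seqs <- Biostrings::DNAStringSet(promoters)
  if (length(seqs) == 0) {
    attr(seqs, "short") <- logical(0)
    return(seqs)
  }
  if (is.null(names(seqs))) stop("promoter records must be keyed by gene ID")
  if (anyDuplicated(names(seqs))) stop("duplicated gene IDs in promoter set")
  w <- Biostrings::width(seqs)
  short <- w < length
  start <- pmax(1L, w - as.integer(length) + 1L)
  out <- Biostrings::subseq(seqs, start = start, end = w)
  attr(out, "short") <- setNames(short, names(seqs))
  out
}
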