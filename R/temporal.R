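.TEMPORAL_MAP <- c(
  "down.down" = "sustained_down", "down.ns" = "transient_down",
  "down.up" = "opposite",
  "ns.down" = "delayed_down", "ns.ns" = "unchanged", "ns.up" = "delayed_up",
  "up.down" = "opposite", "up.ns" = "transient_up", "up.up" = "sustained_up")

.direction <- function(res, fdr) {
  sig <- !is.na(res$padj) & res$padj < fdr & !is.na(res$lfc)
  ifelse(sig & res$lfc > 0, "up", ifelse(sig & res$lfc < 0, "down", "ns"))
}

#' Classify genes by temporal response pattern
#'
#' A gene's direction at each time point is the sign of its LFC if its
#' adjusted p-value is below the FDR threshold, otherwise `ns` (genes with NA
#' adjusted p, i.e. filtered, are `ns`). The (direction15, direction60) pair
#' maps deterministically onto eight categories; "transient" means
#' significant at 15 min only, "delayed" significant at 60 min only,
#' "sustained" significant at both in the same direction, "opposite"
#' significant in discordant directions.
#'
#' @param de15,de60 `DEResult`s for the 15- and 60-minute contrasts over the
#'   same gene universe.
#' @param fdr significance threshold on the adjusted p-value.
#' @return data.frame of class `TemporalCall`: `gene_id`, `direction15`,
#'   `direction60`, `category`.
#' @export
classify_temporal <- function(de15, de60, fdr = 0.05) {
  if (!identical(sort(de15$gene_id), sort(de60$gene_id)))
    stop("the two results must cover the same gene universe")
  de60 <- de60[match(de15$gene_id, de60$gene_id), ]
  d15 <- .direction(de15, fdr)
  d60 <- .direction(de60, fdr)
  out <- data.frame(gene_id = de15$gene_id, direction15 = d15,
                    direction60 = d60,
                    category = unname(.TEMPORAL_MAP[paste(d15, d60, sep = ".")]),
                    stringsAsFactors = FALSE)
  class(out) <- c("TemporalCall", "data.frame")
  out
}

#' 3x3 contingency table of 15- versus 60-minute directions
#'
#' @param calls a `TemporalCall` data.frame.
#' @return 3x3 integer table (rows: direction at 15 min; columns: at 60 min),
#'   cells summing to the size of the gene universe.
#' @export
contingency_15_60 <- function(calls) {
  lev <- c("down", "ns", "up")
  table(factor(calls$direction15, lev), factor(calls$direction60, lev),
        dnn = c("direction15", "direction60"))
}

#' Regression of 60-minute on 15-minute log fold changes
#'
#' Ordinary least squares of `lfc60` on `lfc15`, optionally restricted to a
#' subset of genes (e.g. those significant at either time).
#'
#' @param lfc15,lfc60 numeric vectors of log2 fold changes.
#' @param restrict optional logical mask selecting genes.
#' @return list with `r_squared` (unadjusted), `slope`, `p_value` (F test),
#'   `n`.
#' @export
lfc_correlation <- function(lfc15, lfc60, restrict = NULL) {
  stopifnot(length(lfc15) == length(lfc60))
  keep <- is.finite(lfc15) & is.finite(lfc60)
  if (!is.null(restrict)) keep <- keep & restrict
  x <- lfc15[keep]; y <- lfc60[keep]
  if (length(x) < 3) stop("need >= 3 genes after masking")
  if (sd(x) == 0) stop("lfc15 is constant: slope inference undefined")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  f <- sm$fstatistic
  list(r_squared = unname(sm$r.squared), slope = unname(coef(fit)[2]),
       p_value = unname(pf(f[1], f[2], f[3], lower.tail = FALSE)),
       n = length(x))
}
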