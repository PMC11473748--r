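#' Wald test for a design coefficient
#'
#' Fits the per-gene NB GLM (log link, size-factor offsets, final shrunk
#' dispersions) by iteratively reweighted least squares and tests the named
#' coefficient with the Wald statistic z = beta / SE(beta), two-sided against
#' the standard normal. Fold changes are reported in log2 units.
#'
#' @param counts a [CountMatrix()] or integer matrix.
#' @param design design matrix from [build_design()].
#' @param dispersions a `DispersionFit` (or numeric vector of per-gene
#'   dispersions).
#' @param contrast name of the design coefficient to test, e.g. `"time60"`.
#' @param size_factors per-sample size factors.
#' @return data.frame of class `DEResult`: `gene_id`, `base_mean`, `lfc`
#'   (log2), `se` (log2), `stat`, `pvalue`, plus `padj`/`significant` columns
#'   filled by [adjust_pvalues()].
#' @export
wald_test <- function(counts, design, dispersions, contrast, size_factors) {
  m <- if (inherits(counts, "CountMatrix")) counts$counts else as.matrix(counts)
  if (!contrast %in% colnames(design))
    stop("contrast '", contrast, "' is not a design coefficient (have: ",
         paste(colnames(design), collapse = ", "), ")")
  alpha <- if (inherits(dispersions, "DispersionFit")) dispersions$final
           else dispersions
  offset <- log(size_factors)
  base_mean <- rowMeans(sweep(m, 2, size_factors, "/"))
  ci <- match(contrast, colnames(design))
  n_gene <- nrow(m)
  lfc <- se <- stat <- pval <- rep(NA_real_, n_gene)
  repcols <- grep("^rep", colnames(design))
  rep_eff <- matrix(NA_real_, n_gene, length(repcols))
  for (i in seq_len(n_gene)) {
    if (is.na(alpha[i]) || all(m[i, ] == 0)) next
    fit <- .fit_nb_glm(m[i, ], design, offset, max(alpha[i], 1e-8))
    if (!fit$converged || any(!is.finite(fit$se))) next
    lfc[i] <- fit$beta[ci] / log(2)
    se[i] <- fit$se[ci] / log(2)
    stat[i] <- fit$beta[ci] / fit$se[ci]
    pval[i] <- 2 * pnorm(-abs(stat[i]))
    if (length(repcols) > 0) rep_eff[i, ] <- fit$beta[repcols]
  }
  res <- data.frame(gene_id = rownames(m), base_mean = base_mean,
                    lfc = lfc, se = se, stat = stat, pvalue = pval,
                    padj = NA_real_, significant = FALSE,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "contrast") <- contrast
  if (length(repcols) > 0) {
    colnames(rep_eff) <- colnames(design)[repcols]
    attr(res, "replicate_effects") <- rep_eff
  }
  class(res) <- c("DEResult", "data.frame")
  res
}

#' Benjamini-Hochberg adjustment with independent filtering
#'
#' Scans mean-expression quantile thresholds (0 to 95% in 1% steps by
#' default); for each, genes below the threshold are set aside and BH is
#' applied to the rest. The threshold maximizing the number of rejections at
#' the given FDR is selected (ties broken toward the smaller threshold, which
#' keeps more genes). Filtered genes receive an NA adjusted p-value.
#'
#' @param p raw p-values (NA allowed).
#' @param filter_stat per-gene filter statistic (mean of normalized counts).
#' @param fdr target FDR for the rejection count used to pick the threshold.
#' @param quantiles candidate filter quantiles.
#' @return numeric vector of adjusted p-values with NA for filtered genes;
#'   attribute `filter_threshold` records the chosen filter-statistic cutoff.
#' @export
adjust_pvalues <- function(p, filter_stat = NULL, fdr = 0.05,
                           quantiles = seq(0, 0.95, by = 0.01)) {
  if (all(is.na(p))) stop("all p-values are NA")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (is.null(filter_stat)) {
    out <- p.adjust(p, method = "BH")
    attr(out, "filter_threshold") <- -Inf
    return(out)
  }
  stopifnot(length(p) == length(filter_stat))
  best <- NULL; best_rej <- -1L; best_cut <- -Inf
  for (q in quantiles) {
    cut <- quantile(filter_stat, q, na.rm = TRUE, names = FALSE)
    keep <- !is.na(filter_stat) & filter_stat >= cut
    adj <- rep(NA_real_, length(p))
    adj[keep] <- p.adjust(p[keep], method = "BH")
    rej <- sum(adj < fdr, na.rm = TRUE)
    if (rej > best_rej) {  # strict >: ties keep the earlier, smaller threshold
      best_rej <- rej; best <- adj; best_cut <- cut
    }
  }
  attr(best, "filter_threshold") <- best_cut
  best
}

#' Run the full differential-expression stage
#'
#' Size factors, design, dispersion fitting, Wald tests for the 15- and
#' 60-minute contrasts, and BH adjustment with independent filtering.
#'
#' @param counts a [CountMatrix()].
#' @param fdr FDR threshold for significance calls.
#' @param contrasts design coefficients to test.
#' @return list with `size_factors`, `design`, `dispersions`, and one
#'   `DEResult` per contrast (named `de15`, `de60` for the default design).
#' @export
run_de <- function(counts, fdr = 0.05, contrasts = c("time15", "time60")) {
  stopifnot(inherits(counts, "CountMatrix"))
  sf <- estimate_size_factors(counts)
  X <- build_design(counts$samples)
  contrasts <- intersect(contrasts, colnames(X))
  disp <- fit_dispersions(counts, X, sf)
  out <- list(size_factors = sf, design = X, dispersions = disp, fdr = fdr)
  for (ct in contrasts) {
    res <- wald_test(counts, X, disp, ct, sf)
    res$padj <- as.numeric(adjust_pvalues(res$pvalue, res$base_mean, fdr))
    res$significant <- !is.na(res$padj) & res$padj < fdr
    out[[sub("^time", "de", ct)]] <- res
  }
  out
}

#' Batch-corrected normalized counts for visualization
#'
#' Divides size-factor-normalized counts by each sample's fitted replicate
#' batch effect (equivalently, subtracts the replicate coefficient on the log
#' scale), leaving condition effects untouched.
#'
#' @param counts a [CountMatrix()].
#' @param de_result a `DEResult` from [wald_test()] carrying per-gene
#'   replicate-effect estimates, or a matrix of natural-log replicate
#'   effects (genes x non-reference replicates).
#' @param size_factors per-sample size factors.
#' @return matrix of corrected normalized counts.
#' @export
batch_correct_counts <- function(counts, de_result, size_factors) {
  stopifnot(inherits(counts, "CountMatrix"))
  rep_eff <- if (is.matrix(de_result)) de_result
             else attr(de_result, "replicate_effects")
  if (is.null(rep_eff))
    stop("model was fitted without replicate terms; nothing to correct")
  norm <- sweep(counts$counts, 2, size_factors, "/")
  reps <- counts$samples$replicate
  lev <- sort(unique(reps))
  for (j in seq_len(ncol(norm))) {
    cn <- paste0("rep", reps[j])
    if (cn %in% colnames(rep_eff)) {
      eff <- rep_eff[, cn]
      eff[is.na(eff)] <- 0
      norm[, j] <- norm[, j] / exp(eff)
    }
  }
  norm
}

#' Compare negative-binomial and Poisson fits per gene
#'
#' For each gene, the log-likelihood of the within-condition replicate counts
#' is maximized under Poisson (per-condition means only) and under NB
#' (per-condition means plus one gene-level dispersion). Reports the AIC
#' difference (positive favours NB) and the fraction of genes with
#' delta-AIC > 2.
#'
#' @param counts a [CountMatrix()].
#' @param size_factors optional size factors (normalization offsets).
#' @return list with per-gene data.frame `table` (`gene_id`, `ll_pois`,
#'   `ll_nb`, `alpha_hat`, `delta_aic`, `favors_nb`) and scalar
#'   `frac_favor_nb`.
#' @export
compare_nb_poisson <- function(counts, size_factors = NULL) {
  stopifnot(inherits(counts, "CountMatrix"))
  m <- counts$counts
  cond <- factor(counts$samples$time_min)
  if (min(table(cond)) < 2) stop("need >= 2 replicates per condition")
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  off <- log(size_factors)
  ncond <- nlevels(cond)
  n <- nrow(m)
  ll_p <- ll_n <- a_hat <- rep(NA_real_, n)
  cidx <- split(seq_len(ncol(m)), cond)
  for (i in seq_len(n)) {
    y <- m[i, ]
    # per-condition mean on the normalized scale, then back to each sample
    mu <- numeric(length(y))
    for (ix in cidx) mu[ix] <- exp(off[ix]) * sum(y[ix]) / sum(exp(off[ix]))
    if (all(mu == 0)) next
    mu <- pmax(mu, 1e-10)
    ll_p[i] <- sum(dpois(y, mu, log = TRUE))
    opt <- optimize(function(la) sum(dnbinom(y, mu = mu, size = exp(-la),
                                             log = TRUE)),
                    c(log(1e-10), log(30)), maximum = TRUE)
    ll_n[i] <- max(opt$objective, ll_p[i])  # Poisson is the alpha -> 0 limit
    a_hat[i] <- exp(opt$maximum)
  }
  aic_p <- -2 * ll_p + 2 * ncond
  aic_n <- -2 * ll_n + 2 * (ncond + 1)
  delta <- aic_p - aic_n
  tab <- data.frame(gene_id = rownames(m), ll_pois = ll_p, ll_nb = ll_n,
                    alpha_hat = a_hat, delta_aic = delta,
                    favors_nb = !is.na(delta) & delta > 2,
                    stringsAsFactors = FALSE)
  list(table = tab, frac_favor_nb = mean(tab$favors_nb[!is.na(delta)]))
}

#' MA table (mean expression versus log fold change)
#'
#' @param result a `DEResult`.
#' @return data.frame with columns `gene_id`, `A` (mean normalized count),
#'   `M` (log2 fold change), `significant`.
#' @export
ma_table <- function(result) {
  stopifnot(inherits(result, "DEResult"))
  data.frame(gene_id = result$gene_id, A = result$base_mean, M = result$lfc,
             significant = result$significant, stringsAsFactors = FALSE)
}
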