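#' Median-of-ratios size factors
#'
#' Per-sample normalization scalars: the median across genes of the ratio of
#' a sample's counts to the per-gene geometric-mean reference, rescaled so
#' the factors have geometric mean 1. Only genes with a positive count in
#' every sample enter the reference.
#'
#' @param counts a [CountMatrix()] or an integer matrix.
#' @return named positive numeric vector, one per sample, geometric mean 1.
#' @export
estimate_size_factors <- function(counts) {
  m <- if (inherits(counts, "CountMatrix")) counts$counts else as.matrix(counts)
  if (any(colSums(m) == 0)) stop("sample with all-zero counts: ",
                                 paste(colnames(m)[colSums(m) == 0], collapse = ", "))
  usable <- rowSums(m > 0) == ncol(m)
  if (!any(usable))
    stop("no gene has a nonzero count in every sample; cannot form the reference")
  lg <- log(m[usable, , drop = FALSE])
  ref <- rowMeans(lg)
  sf <- exp(apply(lg - ref, 2, median))
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(m))
}

#' Negative-binomial probability mass function
#'
#' The NB pmf in its mean/dispersion parameterization:
#' Pr(K = k) = Gamma(k + 1/alpha) / (k! Gamma(1/alpha)) *
#' (mu / (mu + 1/alpha))^k * (1 / (1 + mu alpha))^(1/alpha),
#' so that Var(K) = mu + alpha mu^2. Evaluated in log space.
#'
#' @param k non-negative integer count (vectorized).
#' @param mu mean, > 0.
#' @param alpha dispersion, > 0.
#' @param log return the log pmf.
#' @return probability (or log probability).
#' @export
nb_pmf <- function(k, mu, alpha, log = FALSE) {
  if (any(mu <= 0)) stop("mu must be > 0")
  if (any(alpha <= 0)) stop("alpha must be > 0")
  if (any(k < 0) || any(k != round(k))) stop("k must be a non-negative integer")
  r <- 1 / alpha
  ll <- lgamma(k + r) - lfactorial(k) - lgamma(r) +
    k * (base::log(mu) - base::log(mu + r)) - r * log1p(mu * alpha)
  if (log) ll else exp(ll)
}

#' Build the full-rank design matrix for the time-course model
#'
#' The study design crosses treatment time with replicate batch. The natural
#' six-indicator encoding (one per time, one per replicate) is rank-deficient
#' because each block of indicators sums to one; this reparameterizes to an
#' intercept, per-time effects relative to t = 0, and per-replicate effects
#' relative to replicate 1. The linear map back to the redundant six-effect
#' encoding is attached as attribute `effect_map`.
#'
#' @param samples data.frame with `time_min` and `replicate` columns (or a
#'   [CountMatrix()]).
#' @param times allowed time labels.
#' @return numeric design matrix (samples x coefficients) with attribute
#'   `effect_map`; coefficients are named `Intercept`, `time<t>`, `rep<r>`.
#' @export
build_design <- function(samples, times = c(0, 15, 60)) {
  if (inherits(samples, "CountMatrix")) samples <- samples$samples
  if (!all(samples$time_min %in% times))
    stop("unknown time label(s): ",
         paste(setdiff(samples$time_min, times), collapse = ", "))
  tf <- factor(samples$time_min, levels = sort(unique(samples$time_min)))
  rf <- factor(samples$replicate, levels = sort(unique(samples$replicate)))
  drop_rep <- nlevels(rf) < 2
  if (drop_rep)
    warning("single replicate level: replicate columns dropped from the design")
  X <- if (drop_rep) model.matrix(~tf) else model.matrix(~ tf + rf)
  colnames(X) <- sub("^\\(Intercept\\)$", "Intercept", colnames(X))
  colnames(X) <- sub("^tf", "time", colnames(X))
  colnames(X) <- sub("^rf", "rep", colnames(X))
  rownames(X) <- samples$sample_id
  # redundant effect r for level l equals Intercept + (level effect), so the
  # map from fitted coefficients to the six printed effects is affine
  attr(X, "effect_map") <-
    "time effect t = Intercept + time<t>; replicate effect r = rep<r> (0 for reference levels)"
  X
}

# one-gene NB GLM with log link and offset, by iteratively reweighted least
# squares; weights W = mu / (1 + alpha mu). Returns natural-log coefficients.
.fit_nb_glm <- function(y, X, offset, alpha, max_iter = 50, tol = 1e-8) {
  beta <- qr.solve(X, log(pmax(y, 0.5)) - offset)
  eta <- drop(X %*% beta) + offset
  mu <- pmin(exp(eta), 1e12)
  dev_old <- Inf
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    W <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    XtW <- t(X * W)
    beta_new <- tryCatch(solve(XtW %*% X, XtW %*% z),
                         error = function(e) NULL)
    if (is.null(beta_new)) break
    beta <- drop(beta_new)
    eta <- drop(X %*% beta) + offset
    mu <- pmin(pmax(exp(eta), 1e-10), 1e12)
    dev <- -2 * sum(dnbinom(y, mu = mu, size = 1 / alpha, log = TRUE))
    if (is.finite(dev) && abs(dev - dev_old) < tol * (abs(dev) + 0.1)) {
      conv <- TRUE
      break
    }
    dev_old <- dev
  }
  W <- mu / (1 + alpha * mu)
  cov <- tryCatch(solve(t(X * W) %*% X), error = function(e)
    matrix(NA_real_, ncol(X), ncol(X)))
  list(beta = beta, se = sqrt(pmax(diag(cov), 0)), mu = mu, converged = conv)
}

# Cox-Reid adjusted profile log-likelihood of alpha for one gene, mu fixed
.cr_apl <- function(alpha, y, mu, X) {
  W <- mu / (1 + alpha * mu)
  ld <- determinant(t(X * W) %*% X, logarithm = TRUE)$modulus
  sum(dnbinom(y, mu = mu, size = 1 / alpha, log = TRUE)) - 0.5 * as.numeric(ld)
}

# maximize a function of log alpha over [lo, hi]: coarse grid to bracket the
# global maximum (the profile can have flat shoulders golden-section search
# alone mislocates), then local refinement
.max_log_alpha <- function(f, lo = log(1e-8), hi = log(30), n_grid = 20) {
  grid <- seq(lo, hi, length.out = n_grid)
  vals <- vapply(grid, f, numeric(1))
  i <- which.max(vals)
  opt <- optimize(f, c(grid[max(1, i - 1)], grid[min(n_grid, i + 1)]),
                  maximum = TRUE)
  if (opt$objective >= vals[i]) opt$maximum else grid[i]
}

#' Estimate gene-wise dispersions with trend and shrinkage
#'
#' Three stages, in the style of standard NB differential-expression tools:
#' (1) a gene-wise maximum (Cox-Reid adjusted profile) likelihood estimate of
#' alpha given fitted means; (2) a parametric trend alpha(mu) = a1/mu + a0
#' fitted across genes by iterative gamma-family regression; (3) an
#' empirical-Bayes shrinkage of log dispersion toward the trend, with the
#' likelihood variance approximated by trigamma((m - p)/2) and the prior
#' variance estimated from the residual spread. Genes more than 2 residual
#' standard deviations above the trend are flagged as outliers and keep
#' their gene-wise estimate.
#'
#' @param counts a [CountMatrix()] or integer matrix.
#' @param design design matrix from [build_design()].
#' @param size_factors from [estimate_size_factors()].
#' @param min_mu genes with mean normalized count below this are skipped (NA).
#' @return a `DispersionFit` list: `base_mean`, `mle`, `trend`, `final`,
#'   `outlier`, `trend_coef` (a0, a1), and the per-gene fitted means.
#' @export
fit_dispersions <- function(counts, design, size_factors, min_mu = 0.5) {
  m <- if (inherits(counts, "CountMatrix")) counts$counts else as.matrix(counts)
  n_gene <- nrow(m)
  p <- ncol(design)
  if (nrow(m) < 10) stop("need >= 10 genes to fit a dispersion trend")
  if (nrow(design) <= p)
    stop("no residual degrees of freedom: the design needs replication ",
         "(more samples than coefficients)")
  offset <- log(size_factors)
  norm <- sweep(m, 2, size_factors, "/")
  base_mean <- rowMeans(norm)
  use <- base_mean >= min_mu
  if (!any(use)) stop("all genes below the minimum mean; nothing to fit")

  mle <- rep(NA_real_, n_gene)
  mu_mat <- matrix(NA_real_, n_gene, ncol(m), dimnames = dimnames(m))
  # initial moment estimate of alpha for the mean fit
  v <- apply(norm, 1, var)
  alpha0 <- pmax((v - base_mean) / base_mean^2, 0.01)
  for (i in which(use)) {
    y <- m[i, ]
    # alternate fitting the means and profiling the dispersion until the
    # adjusted profile maximum stabilizes
    a <- alpha0[i]
    for (round in 1:10) {
      fit <- .fit_nb_glm(y, design, offset, a)
      a_new <- exp(.max_log_alpha(function(la)
        .cr_apl(exp(la), y, fit$mu, design)))
      done <- abs(log(a_new) - log(max(a, 1e-8))) < 1e-3
      a <- a_new
      if (done) break
    }
    mle[i] <- a
    mu_mat[i, ] <- fit$mu
  }

  trend_coef <- .fit_disp_trend(base_mean[use], mle[use])
  trend <- rep(NA_real_, n_gene)
  trend[use] <- pmax(trend_coef[["a1"]] / base_mean[use] + trend_coef[["a0"]],
                     1e-8)

  # robust spread of log residuals about the trend; genes whose MLE
  # collapsed toward zero are uninformative about the prior width
  lres <- log(mle) - log(trend)
  reliable <- !is.na(lres) & mle > trend * 1e-3
  s2_lik <- trigamma((nrow(design) - p) / 2)
  prior_var <- max(mad(lres[reliable])^2 - s2_lik, 0.25)
  sd_res <- sqrt(s2_lik + prior_var)
  outlier <- !is.na(mle) & (log(mle) - log(trend) > 2 * sd_res)
  # posterior mode: per-gene Cox-Reid likelihood plus log-normal prior
  # centred on the trend; uses the actual likelihood curvature, so genes
  # whose dispersion is poorly determined are pulled to the trend
  final <- rep(NA_real_, n_gene)
  for (i in which(use)) {
    if (outlier[i]) { final[i] <- mle[i]; next }
    lt <- log(trend[i])
    y <- m[i, ]; mu <- mu_mat[i, ]
    final[i] <- exp(.max_log_alpha(function(la)
      .cr_apl(exp(la), y, mu, design) - (la - lt)^2 / (2 * prior_var)))
  }
  structure(list(base_mean = base_mean, mle = mle, trend = trend,
                 final = final, outlier = outlier, trend_coef = trend_coef,
                 fitted_mu = mu_mat, prior_var = prior_var, s2_lik = s2_lik),
            class = "DispersionFit")
}

# iterative gamma-family regression of gene-wise dispersions on 1/mean,
# excluding extreme ratio outliers until the fit stabilizes
.fit_disp_trend <- function(base_mean, mle, max_iter = 10) {
  ok <- is.finite(mle) & mle > 1e-7
  x <- 1 / base_mean[ok]
  y <- mle[ok]
  keep <- rep(TRUE, length(y))
  coefs <- c(a0 = 0.1, a1 = 1)
  for (it in seq_len(max_iter)) {
    fit <- tryCatch(
      stats::glm(y[keep] ~ x[keep], family = stats::Gamma(link = "identity"),
                 start = pmax(coefs, 1e-6)),
      error = function(e) NULL)
    if (is.null(fit)) break
    new <- pmax(coef(fit), c(1e-6, 0))
    names(new) <- c("a0", "a1")
    pred <- new[["a1"]] * x + new[["a0"]]
    ratio <- y / pred
    keep_new <- ratio > 1e-4 & ratio < 15
    done <- sum(abs(new - coefs)) < 1e-6 * sum(abs(coefs))
    coefs <- new
    if (done || all(keep_new == keep)) break
    keep <- keep_new
  }
  coefs
}

#' @export
print.DispersionFit <- function(x, ...) {
  cat(sprintf(
    "DispersionFit: %d genes, trend alpha(mu) = %.4g/mu + %.4g, %d outlier(s)\n",
    length(x$final), x$trend_coef[["a1"]], x$trend_coef[["a0"]],
    sum(x$outlier, na.rm = TRUE)))
  invisible(x)
}
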