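test_that("median-of-ratios size factors match hand computations", {
  m <- matrix(c(4L, 9L), 1, 2, dimnames = list("g1", c("a", "b")))
  expect_equal(unname(estimate_size_factors(m)), c(4, 9) / 6, tolerance = 1e-12)

  set.seed(1)
  base <- matrix(rpois(40, 60) + 1L, 20, 2,
                 dimnames = list(sprintf("g%d", 1:20), c("a", "b")))
  base[, 2] <- base[, 1]
  expect_equal(unname(estimate_size_factors(base)), c(1, 1), tolerance = 1e-12)

  dbl <- base; dbl[, 2] <- 2L * dbl[, 1]
  expect_equal(unname(estimate_size_factors(dbl)),
               c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  # invariant to gene order
  perm <- dbl[sample(nrow(dbl)), ]
  expect_equal(estimate_size_factors(perm), estimate_size_factors(dbl))

  zero <- base; zero[, 2] <- 0L
  expect_error(estimate_size_factors(zero), "all-zero")
})

test_that("NB pmf matches closed forms, normalizes, and has the Poisson limit", {
  expect_equal(nb_pmf(0, mu = 1, alpha = 1), 0.5, tolerance = 1e-12)
  expect_gte(sum(nb_pmf(0:500, mu = 5, alpha = 0.3)), 1 - 1e-10)
  expect_equal(nb_pmf(0:50, mu = 7, alpha = 1e-8), dpois(0:50, 7),
               tolerance = 1e-6)
  expect_equal(nb_pmf(3, 5, 0.4), dnbinom(3, mu = 5, size = 2.5),
               tolerance = 1e-12)
  expect_error(nb_pmf(2, mu = -1, alpha = 1), "mu")
  expect_error(nb_pmf(2, mu = 1, alpha = 0), "alpha")
  expect_error(nb_pmf(-1, mu = 1, alpha = 1), "k")
})

test_that("the design reparameterizes the redundant 6-effect encoding to full rank", {
  cm <- toy_counts()
  X <- build_design(cm$samples)
  expect_identical(dim(X), c(9L, 5L))
  expect_identical(colnames(X), c("Intercept", "time15", "time60", "rep2", "rep3"))
  expect_identical(qr(X)$rank, 5L)
  # the paper-style redundant encoding (3 time + 3 replicate indicators)
  # spans the same column space
  tf <- factor(cm$samples$time_min); rf <- factor(cm$samples$replicate)
  X6 <- cbind(model.matrix(~ 0 + tf), model.matrix(~ 0 + rf))
  expect_identical(qr(X6)$rank, 5L)
  expect_identical(qr(cbind(X, X6))$rank, 5L)

  s6 <- cm$samples[cm$samples$time_min != 60, ]
  X2 <- build_design(s6)
  expect_identical(dim(X2), c(6L, 4L))
  expect_identical(qr(X2)$rank, 4L)

  s1 <- cm$samples; s1$replicate <- 1
  expect_warning(X1 <- build_design(s1), "single replicate")
  expect_false(any(grepl("^rep", colnames(X1))))

  bad <- cm$samples; bad$time_min[1] <- 30
  expect_error(build_design(bad), "unknown time")
})

test_that("LFC estimates are equivariant to rescaling one sample", {
  # noiseless data following the model exactly: ten flat genes (so the size
  # factors stay at 1) plus two genes with LFC15 = 1, LFC60 = 2
  samples <- toy_counts(1)$samples
  mu0 <- c(rep(c(16L, 32L, 64L, 40L, 24L), 2), 20L, 8L)
  fold <- c(1L, 1L, 1L, 2L, 2L, 2L, 4L, 4L, 4L)
  m <- outer(mu0, rep(1L, 9))
  m[11:12, ] <- outer(mu0[11:12], fold)
  dimnames(m) <- list(sprintf("g%d", seq_along(mu0)), samples$sample_id)
  m2 <- m; m2[, 1] <- m2[, 1] * 2L
  X <- build_design(samples)
  run <- function(mm) {
    cmx <- CountMatrix(mm, samples)
    sf <- estimate_size_factors(cmx)
    wald_test(cmx, X, rep(0.05, nrow(mm)), "time60", sf)
  }
  r1 <- run(m); r2 <- run(m2)
  expect_equal(r1$lfc[11:12], rep(2, 2), tolerance = 1e-6)
  expect_equal(r1$lfc[1:10], rep(0, 10), tolerance = 1e-6)
  expect_equal(r2$lfc, r1$lfc, tolerance = 1e-6)
  expect_equal(run(m * 2L)$lfc, r1$lfc, tolerance = 1e-6)
})

test_that("Wald test recovers planted fold changes and flags a bad contrast", {
  cfg <- sim_config(n_genes = 300, frac_de60 = 0.5, frac_de15_of_de = 0,
                    frac_transient = 0, lfc_mean = 2, lfc_sd = 0,
                    basemean_meanlog = log(100), basemean_sdlog = 0,
                    disp_a0 = 0.05, disp_a1 = 0, disp_sdlog = 0, batch_sd = 0)
  out <- simulate_counts(cfg, seed = 31)
  de <- run_de(out$counts)
  tr <- out$truth$genes
  est <- de$de60$lfc[tr$de60] * sign(tr$lfc60[tr$de60])
  expect_lt(abs(mean(est) - 2), 0.2)
  expect_gt(cor(de$de60$lfc, tr$lfc60), 0.95)
  expect_error(wald_test(out$counts, de$design, de$dispersions, "time90",
                         de$size_factors), "time90")
})

test_that("differential-expression calls agree with an independent NB GLM engine", {
  skip_if_not_installed("DESeq2")
  cfg <- sim_config(n_genes = 300, frac_de60 = 0.3, basemean_meanlog = log(80),
                    basemean_sdlog = 1, batch_sd = 0.1)
  out <- simulate_study(cfg, seed = 13)
  de <- run_de(out$counts)
  suppressMessages({
    cd <- out$counts$samples
    cd$time <- factor(cd$time_min); cd$rep <- factor(cd$replicate)
    dds <- DESeq2::DESeqDataSetFromMatrix(out$counts$counts, cd, ~ rep + time)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    rr <- DESeq2::results(dds, contrast = c("time", "60", "0"))
  })
  expect_gt(cor(de$de60$lfc, rr$log2FoldChange, use = "complete.obs"), 0.98)
  ok <- de$de60$base_mean > 20
  expect_lt(median(abs(de$de60$lfc - rr$log2FoldChange)[ok], na.rm = TRUE), 0.1)
  expect_gt(cor(estimate_size_factors(out$counts), DESeq2::sizeFactors(dds)),
            0.999)
})

test_that("dispersion estimation recovers the truth and shrinks toward the trend", {
  cfg <- sim_config(n_genes = 800, frac_de60 = 0, frac_de15_of_de = 0,
                    frac_transient = 0, disp_a0 = 0.2, disp_a1 = 0,
                    disp_sdlog = 0, batch_sd = 0,
                    basemean_meanlog = log(100), basemean_sdlog = 1)
  out <- simulate_counts(cfg, seed = 17)
  sf <- estimate_size_factors(out$counts)
  X <- build_design(out$counts$samples)
  disp <- fit_dispersions(out$counts, X, sf)
  expect_gt(median(disp$final, na.rm = TRUE), 0.15)
  expect_lt(median(disp$final, na.rm = TRUE), 0.25)
  # trend decreases in mu whenever a1 > 0
  tc <- disp$trend_coef
  expect_gt(tc[["a1"]] / 10 + tc[["a0"]], tc[["a1"]] / 1000 + tc[["a0"]])
  # shrinkage pulls every non-outlier gene-wise estimate toward the trend
  ok <- !is.na(disp$mle) & !disp$outlier
  expect_true(all(abs(log(disp$final[ok]) - log(disp$trend[ok])) <=
                    abs(log(disp$mle[ok]) - log(disp$trend[ok])) + 1e-10))
  # no replication: refuse to fit
  one <- CountMatrix(out$counts$counts[, c(1, 4, 7)],
                     out$counts$samples[c(1, 4, 7), ])
  X1 <- suppressWarnings(build_design(one$samples))
  expect_error(fit_dispersions(one, X1, rep(1, 3)), "replication|degrees")
})

test_that("BH with independent filtering matches hand computation and contracts", {
  expect_equal(as.numeric(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04))),
               rep(0.04, 4), tolerance = 1e-12)
  expect_equal(as.numeric(adjust_pvalues(0.03)), 0.03)
  expect_error(adjust_pvalues(c(NA_real_, NA_real_)), "all p-values")
  expect_error(adjust_pvalues(c(0.5, 1.5)), "0, 1")

  set.seed(8)
  p <- runif(200); fs <- rlnorm(200, 3, 1)
  adj <- adjust_pvalues(p, fs)
  both <- !is.na(adj)
  expect_true(all(adj[both] >= p[both]))
  # invariant to input order
  o <- sample(200)
  expect_equal(as.numeric(adjust_pvalues(p[o], fs[o])), as.numeric(adj)[o])
  # monotone in p among kept genes with identical filter stat
  adj2 <- adjust_pvalues(sort(p), rep(1, 200))
  expect_true(!is.unsorted(as.numeric(adj2)))
})

test_that("batch correction removes a planted replicate effect and only that", {
  set.seed(23)
  n <- 300
  times <- rep(c(0, 15, 60), each = 3); reps <- rep(1:3, 3)
  mu0 <- rep(200, n)
  batch <- ifelse(reps == 2, 2, 1)   # replicate 2 at a 2x batch factor
  m <- sapply(seq_len(9), function(j)
    rnbinom(n, mu = mu0 * batch[j] * ifelse(times[j] == 60, 2, 1), size = 50))
  dimnames(m) <- list(sprintf("g%d", 1:n), sprintf("t%d_r%d", times, reps))
  cm <- CountMatrix(m, data.frame(sample_id = colnames(m), time_min = times,
                                  replicate = reps))
  # one noiseless gene with planted condition ordering t0 < t15 < t60
  m <- rbind(m, gdet = as.integer(100 * ifelse(times == 15, 2,
                                               ifelse(times == 60, 4, 1)) *
                                    batch))
  cm <- CountMatrix(m, cm$samples)
  de <- run_de(cm)
  bc <- batch_correct_counts(cm, de$de60, de$size_factors)
  r1 <- rowMeans(bc[, reps == 1]); r2 <- rowMeans(bc[, reps == 2])
  expect_lt(abs(median(r2 / r1) - 1), 0.05)
  # correction removes the planted 2x batch factor from the noiseless gene
  # and leaves its condition ordering intact
  cmeans <- tapply(bc["gdet", ], times, mean)
  expect_identical(order(cmeans), order(c(1, 2, 4)))
  expect_lt(abs(bc["gdet", reps == 2][1] / bc["gdet", reps == 1][1] - 1), 0.1)
  # a model without replicate terms cannot correct
  expect_error(batch_correct_counts(cm, fake_de("g1", 0, 1), de$size_factors),
               "replicate")
})

test_that("the NB-versus-Poisson comparison detects overdispersion", {
  mk <- function(alpha, mu, n = 500, seed = 9) {
    set.seed(seed)
    times <- rep(c(0, 15, 60), each = 3); reps <- rep(1:3, 3)
    m <- matrix(if (alpha == 0) rpois(n * 9, mu)
                else rnbinom(n * 9, mu = mu, size = 1 / alpha), n, 9)
    dimnames(m) <- list(sprintf("g%d", 1:n), sprintf("t%d_r%d", times, reps))
    CountMatrix(m, data.frame(sample_id = colnames(m), time_min = times,
                              replicate = reps))
  }
  expect_lte(compare_nb_poisson(mk(0, 100))$frac_favor_nb, 0.1)
  expect_gte(compare_nb_poisson(mk(1, 100))$frac_favor_nb, 0.8)

  # a constant gene: equal likelihoods, Poisson wins by the parameter penalty
  cm <- mk(0, 100, n = 2)
  cm$counts[1, ] <- 7L
  out <- compare_nb_poisson(cm, size_factors = rep(1, 9))
  expect_equal(out$table$delta_aic[1], -2, tolerance = 1e-6)

  one <- CountMatrix(mk(0, 100)$counts[, c(1, 4, 7)],
                     mk(0, 100)$samples[c(1, 4, 7), ])
  expect_error(compare_nb_poisson(one), "replicates")
})

test_that("the MA table is centred for null genes and flags exactly the calls", {
  cfg <- sim_config(n_genes = 1000, frac_de60 = 0, frac_de15_of_de = 0,
                    frac_transient = 0, basemean_meanlog = log(200),
                    basemean_sdlog = 0.5, batch_sd = 0)
  out <- simulate_counts(cfg, seed = 41)
  de <- run_de(out$counts, contrasts = "time60")
  ma <- ma_table(de$de60)
  expect_lt(abs(mean(ma$M, na.rm = TRUE)), 0.05)
  expect_identical(ma$significant, de$de60$significant)
  expect_identical(nrow(ma_table(de$de60[0, ])), 0L)
})
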