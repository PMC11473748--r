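test_that("IUPAC scanning counts overlapping matches and honours degeneracy", {
  expect_identical(scan_motif("ACGTACGT", "ACGT", both_strands = FALSE), 2L)
  expect_identical(scan_motif("AGGG", "RG", both_strands = FALSE), 3L)
  expect_identical(scan_motif("ANGT", "ACGT", both_strands = FALSE), 0L)
  expect_identical(scan_motif("AAAA", "AA", both_strands = FALSE), 3L)
  # palindrome counted on both strands
  expect_identical(scan_motif("ACGT", "ACGT", both_strands = TRUE), 2L)
  expect_error(scan_motif("ACGT", ""), "empty")
  expect_error(scan_motif("ACGT", "AXG"), "non-IUPAC")
})

test_that("the scanner equals the brute-force oracle on random cases", {
  set.seed(21)
  iupac <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
             "B", "D", "H", "V", "N")
  for (i in 1:300) {
    s <- random_dna(sample(10:60, 1), c("A", "C", "G", "T", "N"))
    m <- paste(sample(iupac, sample(2:6, 1), replace = TRUE), collapse = "")
    both <- runif(1) < 0.5
    expect_identical(scan_motif(s, m, both), as.integer(naive_scan(s, m, both)))
  }
  # both-strand count decomposes into forward plus reverse-complement scans
  for (i in 1:50) {
    s <- random_dna(40)
    m <- paste(sample(iupac, 5, replace = TRUE), collapse = "")
    rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
    expect_identical(scan_motif(s, m, both_strands = TRUE),
                     scan_motif(s, m, FALSE) + scan_motif(rc, m, FALSE))
  }
})

test_that("promoter trimming keeps the 3'-most bases and flags short records", {
  seqs <- Biostrings::DNAStringSet(c(g1 = paste(rep("ACGT", 500), collapse = ""),
                                     g2 = "ACGTACGT"))
  tr <- extract_promoters(seqs, 1000)
  expect_identical(Biostrings::width(tr), c(1000L, 8L))
  expect_identical(unname(attr(tr, "short")), c(FALSE, TRUE))
  expect_identical(as.character(tr[["g2"]]), "ACGTACGT")
  long <- paste(c(rep("A", 1500), rep("C", 500)), collapse = "")
  tr2 <- extract_promoters(Biostrings::DNAStringSet(c(g = long)), 1000)
  expect_identical(as.character(tr2[["g"]]),
                   paste(c(rep("A", 500), rep("C", 500)), collapse = ""))
  empty <- extract_promoters(Biostrings::DNAStringSet(), 1000)
  expect_identical(length(empty), 0L)
  expect_error(extract_promoters(Biostrings::DNAStringSet(c(g = "A", g = "C"))),
               "duplicated")
})

test_that("motif enrichment finds a planted motif and stays null otherwise", {
  plant_sim <- function(rho, seed) {
    set.seed(seed)
    n_up <- 60; n_ns <- 200
    genes <- sprintf("g%d", seq_len(n_up + n_ns))
    lam <- c(rep(0.4 * rho, n_up), rep(0.4, n_ns))
    hits <- cbind(M_focal = rpois(n_up + n_ns, lam),
                  M_d1 = rpois(n_up + n_ns, 0.4),
                  M_d2 = rpois(n_up + n_ns, 0.4),
                  M_d3 = rpois(n_up + n_ns, 0.4))
    rownames(hits) <- genes
    motif_enrichment(hits, genes[1:n_up], genes[(n_up + 1):(n_up + n_ns)])
  }
  top_focal <- vapply(1:20, function(s) {
    enr <- plant_sim(4, 100 + s)
    enr$motif_id[which.min(enr$hyper_p)] == "M_focal"
  }, logical(1))
  expect_gte(mean(top_focal), 0.9)

  null_frac <- mean(vapply(1:20, function(s)
    mean(plant_sim(1, 200 + s)$padj < 0.05), numeric(1)))
  expect_lte(null_frac, 0.05)

  hits <- matrix(0L, 4, 1, dimnames = list(sprintf("g%d", 1:4), "M_gone"))
  enr <- motif_enrichment(hits, c("g1", "g2"), c("g3", "g4"))
  expect_equal(enr$hyper_p, 1)
  expect_error(motif_enrichment(hits, "g1", character(0)), "empty unchanged")
  expect_error(motif_enrichment(hits, "g1", c("g1", "g2")), "disjoint")
})

test_that("enrichment is invariant to gene order", {
  set.seed(5)
  hits <- matrix(rpois(200, 0.6), 100, 2,
                 dimnames = list(sprintf("g%d", 1:100), c("m1", "m2")))
  reg <- sprintf("g%d", 1:30); ns <- sprintf("g%d", 31:100)
  a <- motif_enrichment(hits, reg, ns)
  b <- motif_enrichment(hits[sample(100), ], sample(reg), sample(ns))
  expect_equal(a$hyper_p, b$hyper_p)
})

test_that("the family-fixed-effects fit interpolates noiseless data exactly", {
  fam <- rep(c("f1", "f2", "f3"), each = 4)
  n_bss <- c(0, 1, 2, 3, 1, 1, 2, 4, 0, 0, 1, 5)
  eff <- c(f1 = -1, f2 = 0.5, f3 = 2)
  lfc <- 1.0 * n_bss + eff[fam]
  fit <- fit_bss_glm(lfc, n_bss, fam)
  expect_equal(fit$beta_bss, 1.0, tolerance = 1e-10)
  expect_equal(unname(fit$family_effects[c("f1", "f2", "f3")]),
               unname(eff), tolerance = 1e-10)
  expect_error(fit_bss_glm(lfc, rep(2, 12), fam), "collinear")
})

test_that("within-family demeaning equals the dummy-variable regression oracle", {
  set.seed(33)
  for (i in 1:20) {
    M <- sample(3:20, 1)
    sizes <- sample(2:6, M, replace = TRUE)
    fam <- rep(sprintf("f%d", seq_len(M)), sizes)
    n <- length(fam)
    x <- rpois(n, 1.5)
    y <- 0.7 * x + rnorm(M, 0, 2)[as.integer(factor(fam))] + rnorm(n)
    if (all(tapply(x, fam, function(v) length(unique(v))) == 1)) next
    fit <- fit_bss_glm(y, x, fam)
    oracle <- lm(y ~ x + factor(fam))
    expect_equal(fit$beta_bss, unname(coef(oracle)["x"]), tolerance = 1e-8)
    expect_equal(fit$se, unname(sqrt(diag(vcov(oracle)))["x"]),
                 tolerance = 1e-8)
    ft <- anova(lm(y ~ factor(fam)), oracle)
    expect_equal(fit$p_value, ft$`Pr(>F)`[2], tolerance = 1e-8)
    expect_identical(fit$df_den, n - M - 1L)
  }
  # genes without a family act as singletons and contribute nothing
  fit_a <- fit_bss_glm(c(1, 2, 3, 9), c(0, 1, 2, 7),
                       c("f1", "f1", "f1", NA))
  fit_b <- fit_bss_glm(c(1, 2, 3), c(0, 1, 2), c("f1", "f1", "f1"))
  expect_equal(fit_a$beta_bss, fit_b$beta_bss, tolerance = 1e-10)
})

test_that("the binding-site effect is recovered with calibrated inference", {
  # CI coverage across replicate regression-scale simulations
  covered <- vapply(1:200, function(s) {
    set.seed(5000 + s)
    fam <- rep(sprintf("f%d", 1:50), each = 4)
    x <- rpois(200, 1.2)
    y <- 0.8 * x + rnorm(50, 0, 1.5)[as.integer(factor(fam))] +
      rnorm(200, 0, 0.5)
    fit <- fit_bss_glm(y, x, fam)
    abs(fit$beta_bss - 0.8) <= 2 * fit$se
  }, logical(1))
  expect_gte(mean(covered), 0.93)

  # F-test p-values are uniform under the null
  ps <- vapply(1:500, function(s) {
    set.seed(7000 + s)
    fam <- rep(sprintf("f%d", 1:20), each = 4)
    x <- rpois(80, 1.2)
    y <- rnorm(20, 0, 1)[as.integer(factor(fam))] + rnorm(80, 0, 0.5)
    if (max(tapply(x, fam, function(v) length(unique(v)))) == 1) return(NA_real_)
    fit_bss_glm(y, x, fam)$p_value
  }, numeric(1))
  expect_gt(ks.test(ps[!is.na(ps)], "punif")$p.value, 0.01)
})

test_that("the full simulated study is self-consistent end to end", {
  cfg <- sim_config(n_genes = 400, promoter_len = 400, beta_bss = 0.4,
                    frac_de60 = 0.25, basemean_meanlog = log(100))
  st <- simulate_study(cfg, seed = 19)
  hits <- scan_motifs(st$promoters, st$motifs)
  # scanning finds at least the planted copies of the focal motif
  expect_true(all(hits[, "M_focal"] >= st$truth$motifs$planted_count))

  de <- truth_de(st$truth)
  up <- st$truth$genes$gene_id[st$truth$genes$de60 & st$truth$genes$lfc60 > 0]
  ns <- st$truth$genes$gene_id[!st$truth$genes$de60]
  enr <- motif_enrichment(hits, up, ns)
  expect_identical(enr$motif_id[which.min(enr$hyper_p)], "M_focal")

  fam_of <- st$truth$families$athaliana_id[
    match(rownames(hits), st$truth$families$gene_id)]
  fit <- fit_bss_glm(st$truth$genes$lfc60, st$truth$motifs$planted_count,
                     fam_of)
  expect_lt(fit$p_value, 1e-6)
  expect_lt(abs(fit$beta_bss - 0.4), 0.15)
})
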