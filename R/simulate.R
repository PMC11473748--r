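#' Configuration for the synthetic guard-cell ABA study generator
#'
#' Defaults emulate the design of the modelled experiment: three treatment
#' times (0, 15, 60 min of ABA), three replicate batches, roughly 12% of genes
#' ABA-responsive at 60 min with only a small fraction already significant at
#' 15 min and a rare transient (15-min-only) class, negative-binomial counts
#' with a mean-dependent dispersion trend, multiplicative replicate batch
#' effects, ortholog families with correlated member fold changes plus rare
#' divergent members, a signed TF-to-target network of configurable direction
#' fidelity, and promoters carrying a focal binding-site motif planted
#' preferentially upstream of up-regulated genes.
#'
#' @param n_genes number of genes (>= 10).
#' @param n_reps replicate batches (>= 2).
#' @param times treatment times in minutes.
#' @param frac_de60 fraction of genes differentially expressed at 60 min.
#' @param frac_de15_of_de fraction of the 60-min DE genes that are already
#'   significant at 15 min.
#' @param frac_transient fraction (relative to the 60-min DE count) of
#'   additional genes regulated only at 15 min.
#' @param lfc_mean,lfc_sd mean and sd of the planted |log2 fold change| at
#'   60 min.
#' @param lfc15_ratio planted LFC at 15 min as a multiple of the 60-min LFC
#'   for genes significant at both times.
#' @param basemean_meanlog,basemean_sdlog log-normal parameters of baseline
#'   expression; the defaults give a mean count of about 1,200 per gene,
#'   matching a study sequencing roughly 100 million reads per sample over
#'   some 78,000 expressed genes.
#' @param disp_a0,disp_a1 dispersion trend alpha(mu) = a1/mu + a0.
#' @param disp_sdlog log-normal scatter of gene dispersions about the trend.
#' @param batch_sd sd of gene-wise replicate batch effects on the natural-log
#'   scale.
#' @param libsize_sdlog log-normal sd of library size factors; ignored when
#'   `size_factors` is given.
#' @param size_factors optional explicit per-sample size factors.
#' @param family_size_probs named numeric vector: probability of each family
#'   size (names are the sizes).
#' @param family_cor within-family correlation of member LFCs, between 0 and 1
#'   (1 means members share the family LFC exactly).
#' @param frac_orphan fraction of genes left out of the ortholog map.
#' @param divergent_prob probability that a family of size >= 2 carries one
#'   divergent member with an independent large LFC.
#' @param divergent_lfc_mean,divergent_lfc_sd |LFC| distribution of divergent
#'   members.
#' @param n_edges,n_tfs regulatory network size.
#' @param sign_probs named probabilities for edge signs
#'   (activation/repression/unknown).
#' @param fidelity probability phi that a target's true direction matches the
#'   prediction from its TF and edge sign (low-throughput studies).
#' @param fidelity_high same for high-throughput studies (defaults to
#'   `fidelity`).
#' @param frac_low_throughput fraction of edges drawn from low-throughput
#'   (< 50 interactions) studies.
#' @param promoter_len promoter length in bases.
#' @param focal_consensus IUPAC consensus of the planted focal motif.
#' @param n_decoy_motifs number of unplanted decoy motifs.
#' @param motif_rho planting rate ratio (>= 1) for up-regulated genes, used
#'   when `beta_bss == 0`.
#' @param beta_bss planted per-site effect on the log2 fold change; when > 0
#'   each planted copy adds `beta_bss` to the gene's true 60-min LFC and the
#'   rho mechanism is disabled (see [simulate_promoters()]).
#' @param motif_lambda Poisson rate of planted copies.
#' @param bg_probs background base composition (A, C, G, T).
#' @return a `SimulationConfig` list.
#' @export
sim_config <- function(n_genes = 2000, n_reps = 3, times = c(0, 15, 60),
                       frac_de60 = 0.12, frac_de15_of_de = 0.04,
                       frac_transient = 0.001,
                       lfc_mean = 2, lfc_sd = 0.8, lfc15_ratio = 0.5,
                       basemean_meanlog = log(400), basemean_sdlog = 1.5,
                       disp_a0 = 0.05, disp_a1 = 5, disp_sdlog = 0.3,
                       batch_sd = 0.1, libsize_sdlog = 0.15,
                       size_factors = NULL,
                       family_size_probs = c("1" = 0.15, "2" = 0.20,
                                             "3" = 0.25, "4" = 0.20,
                                             "5" = 0.12, "6" = 0.08),
                       family_cor = 0.9, frac_orphan = 0.05,
                       divergent_prob = 0.05, divergent_lfc_mean = 4,
                       divergent_lfc_sd = 0.5,
                       n_edges = 300, n_tfs = 25,
                       sign_probs = c(activation = 0.5, repression = 0.35,
                                      unknown = 0.15),
                       fidelity = 0.9, fidelity_high = NULL,
                       frac_low_throughput = 0.5,
                       promoter_len = 1000, focal_consensus = "ACGTGGC",
                       n_decoy_motifs = 4, motif_rho = 2, beta_bss = 0,
                       motif_lambda = 0.5,
                       bg_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  cfg <- as.list(environment())
  if (is.null(cfg$fidelity_high)) cfg$fidelity_high <- cfg$fidelity
  fr <- c(frac_de60, frac_de15_of_de, frac_transient, frac_orphan,
          family_cor, fidelity, cfg$fidelity_high, frac_low_throughput,
          divergent_prob)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (disp_a0 < 0 || disp_a1 < 0) stop("dispersion trend parameters must be >= 0")
  if (motif_rho < 1) stop("motif_rho must be >= 1")
  if (beta_bss < 0) stop("beta_bss must be >= 0")
  if (n_genes < 10) stop("n_genes must be >= 10 (downstream estimators undefined)")
  if (n_reps < 2) stop("n_reps must be >= 2 (dispersion estimation needs replication)")
  structure(cfg, class = "SimulationConfig")
}

# deterministic substream seed per stage, keeps R's 32-bit seed range
.substream <- function(seed, stage) {
  (as.double(seed) * 7919 + stage * 104729) %% 2147483629 + 1
}

.new_truth <- function() {
  structure(list(genes = NULL, families = NULL, network = NULL,
                 motifs = NULL, beta_bss = NA_real_, counts_drawn = FALSE),
            class = "GroundTruth")
}

.gene_ids <- function(n) sprintf("BnaSim%05dD", seq_len(n))

# independent (family-free) assignment of true LFCs and DE labels
.init_genes <- function(config) {
  n <- config$n_genes
  n_de60 <- round(config$frac_de60 * n)
  n_shared <- round(config$frac_de15_of_de * n_de60)
  n_transient <- round(config$frac_transient * n_de60)
  if (n_de60 + n_transient > n) stop("DE fractions exceed the gene universe")
  idx <- sample.int(n, n_de60 + n_transient)
  de60_idx <- idx[seq_len(n_de60)]
  tr_idx <- if (n_transient > 0) idx[n_de60 + seq_len(n_transient)] else integer(0)
  sh_idx <- if (n_shared > 0) de60_idx[seq_len(n_shared)] else integer(0)
  lfc60 <- numeric(n)
  lfc60[de60_idx] <- sample(c(-1, 1), n_de60, TRUE) *
    abs(rnorm(n_de60, config$lfc_mean, config$lfc_sd))
  lfc15 <- numeric(n)
  lfc15[sh_idx] <- config$lfc15_ratio * lfc60[sh_idx]
  lfc15[tr_idx] <- sample(c(-1, 1), length(tr_idx), TRUE) *
    abs(rnorm(length(tr_idx), config$lfc_mean, config$lfc_sd))
  data.frame(gene_id = .gene_ids(n), lfc15 = lfc15, lfc60 = lfc60,
             de15 = lfc15 != 0, de60 = lfc60 != 0,
             stringsAsFactors = FALSE)
}

.draw_mu_alpha <- function(config, n) {
  mu0 <- rlnorm(n, config$basemean_meanlog, config$basemean_sdlog)
  alpha <- (config$disp_a1 / mu0 + config$disp_a0) *
    rlnorm(n, 0, config$disp_sdlog)
  list(mu0 = mu0, alpha = alpha)
}

#' Simulate negative-binomial read counts with known truth
#'
#' Counts for gene i in sample j are drawn from NB(mean = s_j * mu0_i *
#' 2^(x_j' lfc_i) * exp(b_{i,rep(j)}), dispersion alpha_i), i.e. the
#' log-link NB model the differential-expression stage fits, with gene-wise
#' dispersions from the trend alpha(mu) = a1/mu + a0 (log-normal scatter) and
#' gene-wise multiplicative replicate batch effects. When `truth` already
#' carries family-structured LFCs (from [simulate_families()]), those are
#' used; otherwise independent per-gene LFCs are drawn.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; identical (config, seed) give identical output.
#' @param truth optional `GroundTruth` carrying pre-drawn true LFCs.
#' @return list with elements `counts` (a [CountMatrix()]) and `truth`.
#' @export
simulate_counts <- function(config, seed = 1, truth = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(.substream(seed, 1))
  if (is.null(truth)) truth <- .new_truth()
  if (is.null(truth$genes)) truth$genes <- .init_genes(config)
  g <- truth$genes
  n <- nrow(g)
  ma <- .draw_mu_alpha(config, n)
  g$mu0 <- ma$mu0
  g$alpha <- ma$alpha
  times <- rep(config$times, each = config$n_reps)
  reps <- rep(seq_len(config$n_reps), times = length(config$times))
  sample_id <- sprintf("t%d_r%d", times, reps)
  sf <- config$size_factors
  if (is.null(sf)) {
    sf <- rlnorm(length(times), 0, config$libsize_sdlog)
    sf <- sf / exp(mean(log(sf)))
  }
  if (length(sf) != length(times)) stop("size_factors length must match samples")
  # gene x replicate batch effects, replicate 1 is the reference batch
  B <- matrix(0, n, config$n_reps)
  if (config$n_reps > 1 && config$batch_sd > 0)
    B[, -1] <- rnorm(n * (config$n_reps - 1), 0, config$batch_sd)
  lfc_at <- function(t) if (t == 15) g$lfc15 else if (t == 60) g$lfc60 else 0
  mu <- vapply(seq_along(times), function(j) {
    sf[j] * g$mu0 * 2^lfc_at(times[j]) * exp(B[, reps[j]])
  }, numeric(n))
  counts <- matrix(0L, n, length(times),
                   dimnames = list(g$gene_id, sample_id))
  for (j in seq_along(times)) {
    counts[, j] <- ifelse(g$alpha < 1e-12,
                          rpois(n, mu[, j]),
                          rnbinom(n, mu = mu[, j], size = 1 / pmax(g$alpha, 1e-12)))
  }
  samples <- data.frame(sample_id = sample_id, time_min = times,
                        replicate = reps, stringsAsFactors = FALSE)
  truth$genes <- g
  truth$size_factors <- sf
  truth$counts_drawn <- TRUE
  list(counts = CountMatrix(counts, samples), truth = truth)
}

#' Simulate ortholog gene families with correlated member fold changes
#'
#' Partitions the gene universe into families sharing an A. thaliana ortholog.
#' Family-level DE status and a family LFC are drawn first; members of a DE
#' family scatter around the family LFC with within-family sd
#' `lfc_sd * sqrt(1 - family_cor)`, so `family_cor = 1` makes members share
#' the family value exactly. With probability `divergent_prob` a family of
#' size >= 2 carries one member with an independent large LFC. Call this
#' before [simulate_counts()] so that the counts are drawn from the
#' family-structured LFCs; if counts were already drawn, the partition is
#' still generated but member LFCs are left as-is (with a warning), since the
#' observed counts could no longer reflect a re-draw.
#'
#' @inheritParams simulate_counts
#' @return list with elements `orthologs` (an `OrthologMap`) and `truth`.
#' @export
simulate_families <- function(config, seed = 1, truth = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(.substream(seed, 2))
  if (is.null(truth)) truth <- .new_truth()
  redraw <- !isTRUE(truth$counts_drawn)
  if (!redraw)
    warning("counts already drawn: assigning families without re-drawing LFCs, ",
            "so within-family correlation is not enforced")
  n <- config$n_genes
  sizes <- as.integer(names(config$family_size_probs))
  if (any(sizes > n)) stop("family sizes exceed n_genes")
  fam_sizes <- integer(0)
  while (sum(fam_sizes) < n) {
    draw <- sizes[sample.int(length(sizes), 50, TRUE,
                             prob = config$family_size_probs)]
    fam_sizes <- c(fam_sizes, draw)
  }
  fam_sizes <- fam_sizes[cumsum(fam_sizes) <= n]
  if (sum(fam_sizes) < n) fam_sizes <- c(fam_sizes, n - sum(fam_sizes))
  n_fam <- length(fam_sizes)
  at_ids <- sprintf("AT%dG%05d", sample(1:5, n_fam, TRUE),
                    sample.int(89999, n_fam) + 10000)
  gene_id <- .gene_ids(n)
  fam_of_gene <- rep(seq_len(n_fam), fam_sizes)

  # family-level truth
  de60_f <- runif(n_fam) < config$frac_de60
  de15_f <- de60_f & runif(n_fam) < config$frac_de15_of_de
  tr_f <- !de60_f & runif(n_fam) < config$frac_de60 * config$frac_transient
  c60 <- ifelse(de60_f, sample(c(-1, 1), n_fam, TRUE) *
                  abs(rnorm(n_fam, config$lfc_mean, config$lfc_sd)), 0)
  c15 <- ifelse(de15_f, config$lfc15_ratio * c60, 0)
  c15[tr_f] <- sample(c(-1, 1), sum(tr_f), TRUE) *
    abs(rnorm(sum(tr_f), config$lfc_mean, config$lfc_sd))
  sig_w <- config$lfc_sd * sqrt(1 - config$family_cor)

  member <- function(centers, active) {
    x <- numeric(n)
    act <- active[fam_of_gene]
    x[act] <- centers[fam_of_gene][act] + rnorm(sum(act), 0, sig_w)
    x
  }
  lfc60 <- member(c60, de60_f)
  lfc15 <- member(c15, de15_f | tr_f)

  # divergent members: one gene with an independent large LFC at 60 min
  div_fam <- which(fam_sizes >= 2 & runif(n_fam) < config$divergent_prob)
  div_gene <- integer(0)
  for (f in div_fam) {
    gidx <- which(fam_of_gene == f)
    pick <- gidx[sample.int(length(gidx), 1)]
    lfc60[pick] <- sample(c(-1, 1), 1) *
      abs(rnorm(1, config$divergent_lfc_mean, config$divergent_lfc_sd))
    div_gene <- c(div_gene, pick)
  }

  genes <- data.frame(gene_id = gene_id, lfc15 = lfc15, lfc60 = lfc60,
                      de15 = lfc15 != 0, de60 = lfc60 != 0,
                      stringsAsFactors = FALSE)
  genes$de60[div_gene] <- TRUE
  if (redraw) {
    keep <- truth$genes  # may carry mu0/alpha if counts stage ran first on NULL
    truth$genes <- genes
    if (!is.null(keep$mu0)) { truth$genes$mu0 <- keep$mu0; truth$genes$alpha <- keep$alpha }
  } else if (is.null(truth$genes)) {
    truth$genes <- genes
  }
  fam_tab <- data.frame(gene_id = gene_id,
                        athaliana_id = at_ids[fam_of_gene],
                        family_center60 = c60[fam_of_gene],
                        divergent_member = seq_len(n) %in% div_gene,
                        family_divergent = fam_of_gene %in% div_fam,
                        stringsAsFactors = FALSE)
  orphan <- runif(n) < config$frac_orphan
  truth$families <- fam_tab
  truth$families$orphan <- orphan
  om <- fam_tab[!orphan, c("gene_id", "athaliana_id")]
  names(om) <- c("bnapus_id", "athaliana_id")
  om$common_name <- NA_character_
  rownames(om) <- NULL
  class(om) <- c("OrthologMap", "data.frame")
  list(orthologs = om, truth = truth)
}

#' Simulate a signed TF-to-target network with configurable fidelity
#'
#' Draws edges from differentially expressed TFs to differentially expressed
#' targets. For a signed edge the predicted target direction is
#' sign(TF LFC) * sign(edge); with probability `fidelity` the target is
#' sampled from genes whose true direction matches the prediction, otherwise
#' from the opposite direction. Edges are attributed to low-throughput
#' (< 50 interactions) or high-throughput source studies; the two strata can
#' have different fidelities.
#'
#' @inheritParams simulate_counts
#' @return list with elements `interactions` (an `InteractionSet`) and
#'   `truth` (gains a `network` table with the per-edge consistency label).
#' @export
simulate_network <- function(config, seed = 1, truth) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (is.null(truth$genes)) stop("truth must carry per-gene directions")
  set.seed(.substream(seed, 3))
  g <- truth$genes
  # emit edges in the A. thaliana namespace (as an AGRIS-like table) when an
  # ortholog map exists; restrict to mapped genes so every edge is mappable
  at_of <- NULL
  if (!is.null(truth$families)) {
    fam <- truth$families[!truth$families$orphan, ]
    at_of <- setNames(fam$athaliana_id, fam$gene_id)
    g <- g[g$gene_id %in% fam$gene_id, ]
  }
  de <- g[g$de60 & g$lfc60 != 0, ]
  if (config$n_tfs > nrow(de) || config$n_edges > config$n_genes^2)
    stop("network larger than the available gene universe")
  up <- de$gene_id[de$lfc60 > 0]
  down <- de$gene_id[de$lfc60 < 0]
  if (length(up) == 0 || length(down) == 0)
    stop("need DE genes in both directions to simulate the network")
  tfs <- de$gene_id[sample.int(nrow(de), config$n_tfs)]
  tf_dir <- sign(g$lfc60[match(tfs, g$gene_id)])
  n_e <- config$n_edges
  e_tf_idx <- sample.int(config$n_tfs, n_e, TRUE)
  sign_lab <- sample(names(config$sign_probs), n_e, TRUE,
                     prob = config$sign_probs)
  low <- runif(n_e) < config$frac_low_throughput
  # studies: ids with interaction counts strictly below / at-or-above 50
  n_lo <- max(2, ceiling(sum(low) / 40))
  n_hi <- max(2, ceiling(sum(!low) / 100))
  lo_sizes <- sample(5:49, n_lo, TRUE)
  hi_sizes <- sample(60:500, n_hi, TRUE)
  study_id <- character(n_e); study_n <- integer(n_e)
  si <- sample.int(n_lo, sum(low), TRUE)
  study_id[low] <- sprintf("S_low%02d", si); study_n[low] <- lo_sizes[si]
  si <- sample.int(n_hi, sum(!low), TRUE)
  study_id[!low] <- sprintf("S_high%02d", si); study_n[!low] <- hi_sizes[si]

  phi <- ifelse(low, config$fidelity, config$fidelity_high)
  pred <- ifelse(sign_lab == "activation", 1,
                 ifelse(sign_lab == "repression", -1, 0)) * tf_dir[e_tf_idx]
  consistent <- runif(n_e) < phi
  want <- ifelse(consistent, pred, -pred)
  target <- character(n_e)
  pool_any <- de$gene_id
  for (w in c(-1, 0, 1)) {
    idx <- which(want == w)
    if (length(idx) == 0) next
    pool <- if (w > 0) up else if (w < 0) down else pool_any
    target[idx] <- pool[sample.int(length(pool), length(idx), replace = TRUE)]
  }
  # no self-regulation edges: redraw the rare TF-equals-target picks
  for (i in which(target == tfs[e_tf_idx])) {
    pool <- if (want[i] > 0) up else if (want[i] < 0) down else pool_any
    pool <- setdiff(pool, tfs[e_tf_idx[i]])
    target[i] <- pool[sample.int(length(pool), 1)]
  }
  tf_gene <- tfs[e_tf_idx]
  tf_id <- if (is.null(at_of)) tf_gene else unname(at_of[tf_gene])
  target_id <- if (is.null(at_of)) target else unname(at_of[target])
  edges <- data.frame(tf = tf_id, target = target_id, sign = sign_lab,
                      study_id = study_id, study_interaction_count = study_n,
                      stringsAsFactors = FALSE)
  class(edges) <- c("InteractionSet", "data.frame")
  truth$network <- data.frame(edges, tf_gene = tf_gene, target_gene = target,
                              predicted = pred,
                              consistent = ifelse(pred == 0, NA, consistent),
                              low_throughput = low, stringsAsFactors = FALSE)
  list(interactions = edges, truth = truth)
}

.instantiate_iupac <- function(consensus) {
  amb <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
              Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
              K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
              D = c("A", "G", "T"), H = c("A", "C", "T"),
              V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  paste(vapply(strsplit(consensus, "")[[1]], function(ch) {
    opts <- amb[[ch]]
    opts[sample.int(length(opts), 1)]
  }, character(1)), collapse = "")
}

#' Simulate promoter sequences with planted binding sites
#'
#' Generates an i.i.d. background promoter per gene and plants copies of a
#' focal motif. Two planting models are available. With `beta_bss == 0` (the
#' default study conditions), copies are Poisson with rate `motif_lambda`,
#' multiplied by `motif_rho` for up-regulated genes, emulating enrichment of
#' the site upstream of ABA-induced genes without feeding back into the
#' expression truth. With `beta_bss > 0`, copies are Poisson with rate
#' `motif_lambda` and each copy adds `beta_bss` to the gene's true 60-min
#' LFC, so the truth satisfies exactly the model [fit_bss_glm()] estimates
#' (LFC = beta_bss * n + family effect); in that mode this generator must
#' run before [simulate_counts()], as [simulate_study()] does, so the counts
#' reflect the updated LFCs. Planted copies are placed non-overlapping,
#' separated by at least one background base. Decoy motifs are never
#' planted.
#'
#' @inheritParams simulate_counts
#' @return list with `promoters` (a named [Biostrings::DNAStringSet]),
#'   `motifs` (a `MotifSet`), and `truth` (gains a `motifs` table of planted
#'   counts and `beta_bss`).
#' @export
simulate_promoters <- function(config, seed = 1, truth) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (is.null(truth$genes)) stop("truth must carry true LFCs")
  set.seed(.substream(seed, 4))
  L <- nchar(config$focal_consensus)
  len <- config$promoter_len
  if (L > len) stop("motif longer than the promoter")
  g <- truth$genes
  n <- nrow(g)
  max_copies <- floor(len / (L + 1))
  if (config$beta_bss > 0) {
    if (isTRUE(truth$counts_drawn))
      warning("counts already drawn: the binding-site LFC contribution will ",
              "not be reflected in the simulated counts")
    n_plant <- pmin(rpois(n, config$motif_lambda), max_copies)
    g$lfc60 <- g$lfc60 + config$beta_bss * n_plant
    g$de60 <- g$lfc60 != 0
    truth$genes <- g
  } else {
    rate <- config$motif_lambda *
      ifelse(g$de60 & g$lfc60 > 0, config$motif_rho, 1)
    n_plant <- pmin(rpois(n, rate), max_copies)
  }
  bases <- names(config$bg_probs)
  seqs <- character(n)
  for (i in seq_len(n)) {
    s <- sample(bases, len, TRUE, prob = config$bg_probs)
    if (n_plant[i] > 0) {
      slots <- sample.int(max_copies, n_plant[i])
      for (sl in slots) {
        copy <- strsplit(.instantiate_iupac(config$focal_consensus), "")[[1]]
        at <- (sl - 1) * (L + 1) + 1
        s[at:(at + L - 1)] <- copy
      }
    }
    seqs[i] <- paste(s, collapse = "")
  }
  promoters <- Biostrings::DNAStringSet(setNames(seqs, g$gene_id))
  decoys <- vapply(seq_len(config$n_decoy_motifs), function(k)
    paste(sample(c("A", "C", "G", "T"), 7, TRUE), collapse = ""), character(1))
  motifs <- data.frame(
    motif_id = c("M_focal", sprintf("M_decoy%02d", seq_along(decoys))),
    tf = c("ATSIMTF001", sprintf("ATSIMTF%03d", seq_along(decoys) + 1)),
    consensus = c(config$focal_consensus, decoys),
    stringsAsFactors = FALSE)
  class(motifs) <- c("MotifSet", "data.frame")
  truth$motifs <- data.frame(gene_id = g$gene_id, planted_count = n_plant,
                             stringsAsFactors = FALSE)
  truth$beta_bss <- config$beta_bss
  list(promoters = promoters, motifs = motifs, truth = truth)
}

#' Simulate a complete synthetic study
#'
#' Runs the four generators in dependency order (families, then promoters,
#' then counts, then the network), so that counts are drawn from the
#' family-structured LFCs including any binding-site contribution, each
#' stage on its own deterministic substream of the master seed.
#'
#' @inheritParams simulate_counts
#' @return list with `counts`, `orthologs`, `interactions`, `promoters`,
#'   `motifs`, `truth`.
#' @export
simulate_study <- function(config = sim_config(), seed = 1) {
  fam <- simulate_families(config, seed)
  prm <- simulate_promoters(config, seed, fam$truth)
  cnt <- simulate_counts(config, seed, prm$truth)
  net <- simulate_network(config, seed, cnt$truth)
  list(counts = cnt$counts, orthologs = fam$orthologs,
       interactions = net$interactions, promoters = prm$promoters,
       motifs = prm$motifs, truth = net$truth)
}

#' Write a simulated study to disk
#'
#' Writes counts.tsv, samples.tsv, orthologs.tsv, interactions.tsv,
#' motifs.tsv, promoters.fasta and the ground-truth tables under truth/.
#'
#' @param study result of [simulate_study()].
#' @param outdir output directory (created if needed).
#' @export
write_study <- function(study, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_counts(study$counts, p("counts.tsv"), p("samples.tsv"))
  write_result_table(study$orthologs, p("orthologs.tsv"))
  write_result_table(study$interactions, p("interactions.tsv"))
  write_result_table(study$motifs, p("motifs.tsv"))
  Biostrings::writeXStringSet(study$promoters, p("promoters.fasta"))
  dir.create(p("truth"), showWarnings = FALSE)
  tr <- study$truth
  write_result_table(tr$genes, p("truth/genes.tsv"))
  if (!is.null(tr$families)) write_result_table(tr$families, p("truth/families.tsv"))
  if (!is.null(tr$network)) write_result_table(tr$network, p("truth/network.tsv"))
  if (!is.null(tr$motifs)) write_result_table(tr$motifs, p("truth/motifs.tsv"))
  invisible(outdir)
}
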