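# shared fixtures built in code

# tiny deterministic count matrix with full 3x3 design
toy_counts <- function(n_genes = 6, seed = 42) {
  set.seed(seed)
  times <- rep(c(0, 15, 60), each = 3)
  reps <- rep(1:3, times = 3)
  m <- matrix(rpois(n_genes * 9, 50), n_genes, 9,
              dimnames = list(sprintf("G%02d", seq_len(n_genes)),
                              sprintf("t%d_r%d", times, reps)))
  CountMatrix(m, data.frame(sample_id = colnames(m), time_min = times,
                            replicate = reps))
}

# a minimal DEResult-like data.frame from known calls
fake_de <- function(gene_id, lfc, padj) {
  d <- data.frame(gene_id = gene_id, base_mean = 100, lfc = lfc,
                  se = 0.1, stat = lfc / 0.1, pvalue = padj, padj = padj,
                  significant = !is.na(padj) & padj < 0.05,
                  stringsAsFactors = FALSE)
  class(d) <- c("DEResult", "data.frame")
  d
}

# DEResult carrying the simulator's ground truth as perfect calls
truth_de <- function(truth, time = 60) {
  lfc <- if (time == 60) truth$genes$lfc60 else truth$genes$lfc15
  de <- if (time == 60) truth$genes$de60 else truth$genes$de15
  fake_de(truth$genes$gene_id, lfc, ifelse(de, 1e-6, 0.9))
}

# ortholog map reconstructed from the simulator's ground truth
truth_orthomap <- function(truth) {
  fam <- truth$families[!truth$families$orphan, ]
  om <- data.frame(bnapus_id = fam$gene_id, athaliana_id = fam$athaliana_id,
                   common_name = rep(NA_character_, nrow(fam)),
                   stringsAsFactors = FALSE)
  class(om) <- c("OrthologMap", "data.frame")
  om
}

# identity B. napus -> A. thaliana map (each gene its own family)
identity_orthomap <- function(gene_ids) {
  om <- data.frame(bnapus_id = gene_ids, athaliana_id = gene_ids,
                   common_name = rep(NA_character_, length(gene_ids)),
                   stringsAsFactors = FALSE)
  class(om) <- c("OrthologMap", "data.frame")
  om
}

# brute-force IUPAC scanner used as the independent oracle for scan_motif
naive_scan <- function(sequence, consensus, both_strands = TRUE) {
  sets <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
               Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
               K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
               D = c("A", "G", "T"), H = c("A", "C", "T"),
               V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  count_fwd <- function(s) {
    sc <- strsplit(s, "")[[1]]
    pc <- strsplit(consensus, "")[[1]]
    L <- length(pc); n <- length(sc)
    if (n < L) return(0L)
    hits <- 0L
    for (i in seq_len(n - L + 1)) {
      ok <- TRUE
      for (l in seq_len(L)) {
        if (!(sc[i + l - 1] %in% sets[[pc[l]]])) { ok <- FALSE; break }
      }
      if (ok) hits <- hits + 1L
    }
    hits
  }
  rc <- function(s) paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]),
                          collapse = "")
  cnt <- count_fwd(sequence)
  if (both_strands) cnt <- cnt + count_fwd(rc(sequence))
  cnt
}

random_dna <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

extdata <- function(f) system.file("extdata", f, package = "guardABA")
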