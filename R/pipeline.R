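#' Configuration for an end-to-end pipeline run
#'
#' Validates paths and thresholds up front so a run fails before any stage
#' executes, not midway.
#'
#' @param counts,samples paths to the count matrix and sample sheet TSVs
#'   (required).
#' @param orthologs,interactions,motifs,promoters optional paths; stages
#'   needing a missing input are skipped.
#' @param gene_sets optional named list of A. thaliana gene-ID vectors, or a
#'   path to a TSV with columns `set_id`, `athaliana_id`.
#' @param outdir output directory.
#' @param fdr FDR threshold for significance calls.
#' @param sd_threshold family-divergence threshold on the LFC SD.
#' @param low_throughput_max strict upper bound on source-study interaction
#'   counts for the low-throughput network stratum.
#' @param promoter_length bases of promoter scanned.
#' @return a validated `RunConfig` list.
#' @export
pipeline_config <- function(counts, samples, orthologs = NULL,
                            interactions = NULL, motifs = NULL,
                            promoters = NULL, gene_sets = NULL,
                            outdir = "guardaba_out", fdr = 0.05,
                            sd_threshold = 1.6, low_throughput_max = 50,
                            promoter_length = 1000) {
  cfg <- as.list(environment())
  for (f in c("counts", "samples")) {
    if (is.null(cfg[[f]])) stop("config is missing the required '", f, "' path")
    if (!file.exists(cfg[[f]])) stop(f, " file not found: ", cfg[[f]])
  }
  for (f in c("orthologs", "interactions", "motifs", "promoters")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop(f, " file not found: ", cfg[[f]])
  }
  if (fdr <= 0 || fdr >= 1) stop("fdr must lie in (0, 1)")
  if (sd_threshold < 0) stop("sd_threshold must be >= 0")
  if (low_throughput_max < 1) stop("low_throughput_max must be >= 1")
  if (promoter_length < 1) stop("promoter_length must be >= 1")
  structure(cfg, class = "RunConfig")
}

.read_gene_sets <- function(x) {
  if (is.list(x)) return(x)
  df <- .read_tsv(x, "gene sets")
  .require_cols(df, c("set_id", "athaliana_id"), x)
  split(as.character(df$athaliana_id), df$set_id)
}

#' Run every pipeline stage in dependency order
#'
#' Differential expression first, then the downstream stages that have their
#' inputs available: temporal classification, family statistics, gene-set
#' enrichment, regulatory-network consistency, and promoter motif analysis.
#' Stage outputs are written as TSVs under `config$outdir`; a machine-readable
#' summary of every stage's headline numbers is written as `report.json` and
#' returned.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return the report, a nested list (invisibly identical to `report.json`).
#' @export
run_all <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  say <- function(stage, ...) if (!quiet) message("[", stage, "] ", ...)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  report <- list(fdr = config$fdr)

  say("io", "reading counts")
  cm <- read_counts(config$counts, config$samples)
  say("de", "fitting NB GLM differential expression")
  de <- run_de(cm, fdr = config$fdr)
  for (nm in intersect(c("de15", "de60"), names(de))) {
    write_result_table(de[[nm]], p(paste0(nm, ".tsv")))
    write_result_table(ma_table(de[[nm]]), p(paste0("ma_", nm, ".tsv")))
    report$de[[nm]] <- list(
      n_significant = sum(de[[nm]]$significant),
      n_up = sum(de[[nm]]$significant & de[[nm]]$lfc > 0),
      n_down = sum(de[[nm]]$significant & de[[nm]]$lfc < 0))
  }
  disp <- de$dispersions
  write_result_table(
    data.frame(gene_id = rownames(cm$counts), base_mean = disp$base_mean,
               mle = disp$mle, trend = disp$trend, final = disp$final,
               outlier = disp$outlier),
    p("dispersions.tsv"))
  report$dispersion_trend <- as.list(disp$trend_coef)

  if (all(c("de15", "de60") %in% names(de))) {
    say("temporal", "classifying temporal patterns")
    calls <- classify_temporal(de$de15, de$de60, config$fdr)
    write_result_table(calls, p("temporal_calls.tsv"))
    tab <- contingency_15_60(calls)
    write_result_table(as.data.frame.matrix(tab), p("temporal_contingency.tsv"))
    report$temporal <- list(
      categories = as.list(table(calls$category)),
      contingency = unclass(tab))
    corr <- tryCatch(
      lfc_correlation(de$de15$lfc, de$de60$lfc,
                      restrict = de$de15$significant | de$de60$significant),
      error = function(e) NULL)
    if (!is.null(corr)) report$lfc_correlation <- corr
    if (any(grepl("^rep", colnames(de$design)))) {
      bc <- batch_correct_counts(cm, de$de60, de$size_factors)
      write_result_table(data.frame(gene_id = rownames(bc), bc,
                                    check.names = FALSE),
                         p("batch_corrected.tsv"))
    }
  }

  orthomap <- NULL
  if (!is.null(config$orthologs)) {
    orthomap <- read_ortholog_map(config$orthologs)
    say("families", "family fold-change statistics")
    fams <- build_families(orthomap, de$de60$gene_id)
    fs <- family_lfc_stats(fams, de$de60, config$sd_threshold)
    write_result_table(fs, p("families.tsv"))
    report$families <- list(
      n_families = nrow(fs),
      n_divergent = sum(fs$divergent),
      divergent = fs$athaliana_id[fs$divergent])
  }

  if (!is.null(config$gene_sets) && !is.null(orthomap)) {
    say("enrich", "gene-set enrichment")
    sets <- .read_gene_sets(config$gene_sets)
    proj <- pathway_projection(sets, de$de60, orthomap, fdr = config$fdr)
    write_result_table(proj$summary, p("enrichment.tsv"))
    report$enrichment <- proj$summary
  }

  if (!is.null(config$interactions) && !is.null(orthomap)) {
    say("regnet", "regulatory-network consistency")
    ints <- read_interactions(config$interactions)
    ev <- evaluate_edges(ints, de$de60, orthomap, config$fdr)
    write_result_table(ev, p("edge_evaluations.tsv"))
    ct_all <- tryCatch(consistency_table(ev), error = function(e) NULL)
    ev_low <- evaluate_edges(filter_by_study_size(ints, config$low_throughput_max),
                             de$de60, orthomap, config$fdr)
    ct_low <- tryCatch(consistency_table(ev_low), error = function(e) NULL)
    report$regnet <- list(
      n_edges_mapped = nrow(ev), n_evaluable = sum(ev$evaluable),
      odds_ratio_all = if (!is.null(ct_all)) ct_all$odds_ratio else NA,
      odds_ratio_low_throughput = if (!is.null(ct_low)) ct_low$odds_ratio else NA)
    keep <- ev_low[ev_low$tf_direction != "ns" & ev_low$target_direction != "ns", ]
    if (nrow(keep) > 0)
      export_network(keep, p("network.sif"), p("network.graphml"))
  }

  if (!is.null(config$promoters) && !is.null(config$motifs)) {
    say("motifs", "promoter binding-site analysis")
    proms <- extract_promoters(read_promoters(config$promoters),
                               config$promoter_length)
    mset <- read_motifs(config$motifs)
    hits <- scan_motifs(proms, mset)
    write_result_table(data.frame(gene_id = rownames(hits), unclass(hits),
                                  check.names = FALSE), p("motif_hits.tsv"))
    d60 <- .direction(de$de60, config$fdr)
    up <- de$de60$gene_id[d60 == "up"]
    down <- de$de60$gene_id[d60 == "down"]
    ns <- de$de60$gene_id[d60 == "ns"]
    for (dn in c("up", "down")) {
      regset <- if (dn == "up") up else down
      if (length(regset) == 0 || length(ns) == 0) next
      enr <- motif_enrichment(hits, regset, ns)
      write_result_table(enr, p(paste0("motif_enrichment_", dn, ".tsv")))
      report$motifs[[paste0("top_", dn)]] <-
        head(enr[order(enr$hyper_p), c("motif_id", "hyper_p", "padj")], 5)
    }
    if (!is.null(orthomap)) {
      fam_of <- orthomap$athaliana_id[match(rownames(hits), orthomap$bnapus_id)]
      lfc <- de$de60$lfc[match(rownames(hits), de$de60$gene_id)]
      bss <- lapply(colnames(hits), function(mid)
        tryCatch({
          fit <- fit_bss_glm(lfc, hits[, mid], fam_of)
          data.frame(motif_id = mid, beta_bss = fit$beta_bss, se = fit$se,
                     f_stat = fit$f_stat, p_value = fit$p_value,
                     stringsAsFactors = FALSE)
        }, error = function(e) NULL))
      bss <- do.call(rbind, bss)
      if (!is.null(bss)) {
        write_result_table(bss, p("bss_glm.tsv"))
        report$motifs$bss_glm <- bss
      }
    }
  }

  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  say("done", "report written to ", p("report.json"))
  invisible(report)
}
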