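#' Group B. napus genes into ortholog-defined families
#'
#' One family per A. thaliana ortholog present in the map; B. napus genes in
#' the universe but absent from the map become singleton "orphan" entries,
#' excluded from family SD statistics.
#'
#' @param orthomap an `OrthologMap` from [read_ortholog_map()].
#' @param universe character vector of B. napus gene IDs under study.
#' @return data.frame with `gene_id`, `athaliana_id` (NA for orphans),
#'   `orphan`.
#' @export
build_families <- function(orthomap, universe) {
  om <- as.data.frame(orthomap)
  dup <- duplicated(om[, c("bnapus_id", "athaliana_id")])
  if (any(dup)) {
    warning("collapsing ", sum(dup), " duplicated ortholog row(s)")
    om <- om[!dup, ]
  }
  absent <- setdiff(om$bnapus_id, universe)
  if (length(absent) > 0) {
    warning(length(absent), " mapped gene(s) absent from the universe; dropped")
    om <- om[om$bnapus_id %in% universe, ]
  }
  fam <- data.frame(gene_id = universe,
                    athaliana_id = om$athaliana_id[match(universe, om$bnapus_id)],
                    stringsAsFactors = FALSE)
  fam$orphan <- is.na(fam$athaliana_id)
  fam
}

#' Within-family fold-change conservation statistics
#'
#' For each family, the mean and the sample standard deviation (denominator
#' n - 1) of the members' 60-minute log2 fold changes, over members with a
#' finite LFC. Families with fewer than two such members get SD = NA. A
#' family is flagged divergent when its SD strictly exceeds the threshold.
#'
#' @param families output of [build_families()].
#' @param de60 a `DEResult` for the 60-minute contrast (or a data.frame with
#'   `gene_id` and `lfc` columns).
#' @param sd_threshold divergence threshold on the LFC standard deviation.
#' @return data.frame of class `FamilyStats`: `athaliana_id`, `n_members`,
#'   `n_lfc` (members with finite LFC), `mean_lfc`, `sd_lfc`, `divergent`.
#' @export
family_lfc_stats <- function(families, de60, sd_threshold = 1.6) {
  lfc <- de60$lfc[match(families$gene_id, de60$gene_id)]
  fam <- families[!families$orphan, ]
  lfc <- lfc[!families$orphan]
  sp <- split(lfc, fam$athaliana_id)
  stats <- lapply(sp, function(v) {
    v <- v[is.finite(v)]
    c(n_lfc = length(v),
      mean_lfc = if (length(v) > 0) mean(v) else NA_real_,
      sd_lfc = if (length(v) >= 2) sd(v) else NA_real_)
  })
  st <- do.call(rbind, stats)
  out <- data.frame(athaliana_id = names(sp),
                    n_members = as.integer(lengths(sp)),
                    n_lfc = as.integer(st[, "n_lfc"]),
                    mean_lfc = st[, "mean_lfc"], sd_lfc = st[, "sd_lfc"],
                    stringsAsFactors = FALSE)
  out$divergent <- !is.na(out$sd_lfc) & out$sd_lfc > sd_threshold
  rownames(out) <- NULL
  class(out) <- c("FamilyStats", "data.frame")
  out
}

#' Convert a log2 fold change to a linear fold change
#'
#' @param lfc log2 fold change (vectorized).
#' @return 2^lfc.
#' @export
log2fc_to_fold <- function(lfc) 2^lfc
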