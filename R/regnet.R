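#' Evaluate signed regulatory edges against observed expression directions
#'
#' Each A. thaliana TF-to-target edge is expanded to every B. napus
#' TF-ortholog x target-ortholog pair through the ortholog map. The predicted
#' target direction is sign(TF direction) x sign(edge) when the TF is
#' significantly regulated and the edge sign is activation or repression;
#' otherwise it is undetermined. An edge is evaluable when the prediction is
#' determined and the target itself is significantly regulated.
#'
#' @param interactions an `InteractionSet` (A. thaliana namespace).
#' @param de a `DEResult` (B. napus genes; by convention the 60-minute
#'   contrast).
#' @param orthomap an `OrthologMap`.
#' @param fdr significance threshold for direction calls.
#' @return data.frame of class `EdgeEvaluation`: the expanded edges with
#'   `tf_bn`, `target_bn`, TF/target/predicted directions, `consistent`
#'   (NA when not evaluable) and `evaluable`.
#' @export
evaluate_edges <- function(interactions, de, orthomap, fdr = 0.05) {
  om <- as.data.frame(orthomap)
  dirs <- setNames(.direction(de, fdr), de$gene_id)
  ortho_of <- split(om$bnapus_id, om$athaliana_id)
  rows <- vector("list", nrow(interactions))
  for (i in seq_len(nrow(interactions))) {
    e <- interactions[i, ]
    tfs <- ortho_of[[e$tf]]; tgts <- ortho_of[[e$target]]
    if (is.null(tfs) || is.null(tgts)) next
    pairs <- expand.grid(tf_bn = tfs, target_bn = tgts,
                         stringsAsFactors = FALSE)
    pairs$tf <- e$tf; pairs$target <- e$target; pairs$sign <- e$sign
    pairs$study_id <- e$study_id
    pairs$study_interaction_count <- e$study_interaction_count
    rows[[i]] <- pairs
  }
  ev <- do.call(rbind, rows)
  if (is.null(ev) || nrow(ev) == 0)
    return(structure(data.frame(), class = c("EdgeEvaluation", "data.frame")))
  ev$tf_direction <- unname(dirs[ev$tf_bn])
  ev$target_direction <- unname(dirs[ev$target_bn])
  ev$tf_direction[is.na(ev$tf_direction)] <- "ns"
  ev$target_direction[is.na(ev$target_direction)] <- "ns"
  sgn <- ifelse(ev$sign == "activation", 1,
                ifelse(ev$sign == "repression", -1, 0))
  tfd <- ifelse(ev$tf_direction == "up", 1,
                ifelse(ev$tf_direction == "down", -1, 0))
  pred <- sgn * tfd
  ev$predicted_direction <- ifelse(pred > 0, "up",
                                   ifelse(pred < 0, "down", "undetermined"))
  ev$evaluable <- pred != 0 & ev$target_direction != "ns"
  obs <- ifelse(ev$target_direction == "up", 1,
                ifelse(ev$target_direction == "down", -1, 0))
  ev$consistent <- ifelse(ev$evaluable, pred == obs, NA)
  rownames(ev) <- NULL
  class(ev) <- c("EdgeEvaluation", "data.frame")
  ev
}

#' Predicted-versus-observed direction consistency table
#'
#' 2x2 cross-tabulation of predicted against observed target direction over
#' the evaluable edges, with the odds ratio (ad/bc; the ratio of the odds of
#' observed up-regulation among targets predicted up versus predicted down)
#' and the full contingency statistics including Fisher's exact p.
#'
#' @param evaluations an `EdgeEvaluation` from [evaluate_edges()].
#' @return a `ContingencyResult` (see [contingency_stats()]); the table rows
#'   are predicted up/down, columns observed up/down.
#' @export
consistency_table <- function(evaluations) {
  if (is.null(evaluations$evaluable) || !any(evaluations$evaluable))
    stop("zero evaluable edges")
  ev <- evaluations[which(evaluations$evaluable), ]
  a <- sum(ev$predicted_direction == "up" & ev$target_direction == "up")
  b <- sum(ev$predicted_direction == "up" & ev$target_direction == "down")
  c <- sum(ev$predicted_direction == "down" & ev$target_direction == "up")
  d <- sum(ev$predicted_direction == "down" & ev$target_direction == "down")
  cs <- contingency_stats(a, b, c, d)
  dimnames(cs$table) <- list(predicted = c("up", "down"),
                             observed = c("up", "down"))
  cs
}

#' Keep only interactions from low-throughput studies
#'
#' @param interactions an `InteractionSet`.
#' @param max_n keep edges whose source study reports strictly fewer than
#'   this many interactions.
#' @return the filtered `InteractionSet`.
#' @export
filter_by_study_size <- function(interactions, max_n = 50) {
  out <- interactions[interactions$study_interaction_count < max_n, ]
  rownames(out) <- NULL
  class(out) <- c("InteractionSet", "data.frame")
  out
}

#' Export the evaluated network as SIF and GraphML
#'
#' Nodes are annotated with their expression direction, edges with the
#' interaction type. SIF edge types are `activates`, `represses`,
#' `regulates` (unknown sign). Edges are written in sorted order so the
#' files are byte-stable.
#'
#' @param evaluations an `EdgeEvaluation`; typically restricted to edges
#'   among differentially expressed genes beforehand.
#' @param sif_path,graphml_path output paths (either may be NULL to skip).
#' @return (invisibly) the igraph object.
#' @export
export_network <- function(evaluations, sif_path = NULL, graphml_path = NULL) {
  ev <- as.data.frame(evaluations)
  if (nrow(ev) == 0) stop("no edges to export")
  rel <- c(activation = "activates", repression = "represses",
           unknown = "regulates")
  ev <- ev[order(ev$tf_bn, ev$target_bn, ev$sign), ]
  edges <- unique(data.frame(from = ev$tf_bn, to = ev$target_bn,
                             interaction = unname(rel[ev$sign]),
                             stringsAsFactors = FALSE))
  nd <- unique(rbind(data.frame(id = ev$tf_bn, direction = ev$tf_direction,
                                stringsAsFactors = FALSE),
                     data.frame(id = ev$target_bn,
                                direction = ev$target_direction,
                                stringsAsFactors = FALSE)))
  nd <- nd[!duplicated(nd$id), ]
  nd <- nd[order(nd$id), ]
  g <- igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nd)
  if (!is.null(sif_path)) {
    lines <- sprintf("%s\t%s\t%s", edges$from, edges$interaction, edges$to)
    writeLines(lines, sif_path)
  }
  if (!is.null(graphml_path))
    igraph::write_graph(g, graphml_path, format = "graphml")
  invisible(g)
}
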