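#' Construct a validated count matrix with sample metadata
#'
#' The central container of the pipeline: an integer gene-by-sample read-count
#' matrix together with the per-sample design labels (treatment time in
#' minutes and replicate batch).
#'
#' @param counts integer matrix, genes in rows, samples in columns; must carry
#'   row and column names.
#' @param samples data.frame with columns `sample_id`, `time_min` and
#'   `replicate`, one row per column of `counts`, in the same order.
#' @return An object of class `CountMatrix`: a list with elements `counts`
#'   (integer matrix) and `samples` (data.frame).
#' @export
CountMatrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene row names and sample column names")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf(
      "counts must be non-negative integers; offending cell gene '%s', sample '%s'",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  if (anyDuplicated(rownames(counts)))
    stop("duplicated gene IDs: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicated sample IDs in counts")
  req <- c("sample_id", "time_min", "replicate")
  if (!all(req %in% names(samples)))
    stop("sample sheet must have columns: ", paste(req, collapse = ", "))
  samples <- as.data.frame(samples)[, req]
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample IDs in sample sheet")
  missing <- setdiff(colnames(counts), samples$sample_id)
  if (length(missing) > 0)
    stop("samples in counts absent from sample sheet: ",
         paste(missing, collapse = ", "))
  extra <- setdiff(samples$sample_id, colnames(counts))
  if (length(extra) > 0)
    stop("samples in sheet absent from counts: ", paste(extra, collapse = ", "))
  if (any(is.na(samples$time_min)) || any(is.na(samples$replicate)))
    stop("every sample needs a time_min and replicate label")
  # counts columns follow sample-sheet order
  counts <- counts[, samples$sample_id, drop = FALSE]
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, samples = samples), class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("times (min):", paste(sort(unique(x$samples$time_min)), collapse = ", "),
      " replicates:", paste(sort(unique(x$samples$replicate)), collapse = ", "),
      "\n")
  invisible(x)
}

.read_tsv <- function(path, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
             check.names = FALSE, stringsAsFactors = FALSE)
}

.require_cols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0)
    stop("missing required column(s) ", paste(miss, collapse = ", "),
         " in ", path)
}

#' Read a count matrix and its sample sheet from TSV files
#'
#' @param counts_path TSV with a header of sample IDs and a first column of
#'   gene IDs.
#' @param samples_path TSV with columns `sample_id`, `time_min`, `replicate`.
#' @return A [CountMatrix()].
#' @export
read_counts <- function(counts_path, samples_path) {
  raw <- .read_tsv(counts_path, "counts")
  if (ncol(raw) < 2) stop("counts file needs a gene column and >= 1 sample")
  genes <- as.character(raw[[1]])
  mat <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(mat, 2, as.numeric))),
                 arr.ind = TRUE)
    stop(sprintf("non-numeric count at gene '%s', sample '%s'",
                 genes[bad[1, 1]], colnames(mat)[bad[1, 2]]))
  }
  rownames(mat) <- genes
  sheet <- .read_tsv(samples_path, "sample sheet")
  .require_cols(sheet, c("sample_id", "time_min", "replicate"), samples_path)
  sheet$sample_id <- as.character(sheet$sample_id)
  CountMatrix(mat, sheet)
}

#' Read a B. napus to A. thaliana ortholog map
#'
#' @param path TSV with columns `bnapus_id`, `athaliana_id` and optionally
#'   `common_name`.
#' @return data.frame of class `OrthologMap`. Each B. napus gene maps to at
#'   most one A. thaliana gene; many-to-one the other way defines gene
#'   families.
#' @export
read_ortholog_map <- function(path) {
  df <- .read_tsv(path, "ortholog map")
  .require_cols(df, c("bnapus_id", "athaliana_id"), path)
  if (!"common_name" %in% names(df)) df$common_name <- NA_character_
  df <- df[, c("bnapus_id", "athaliana_id", "common_name")]
  df$bnapus_id <- as.character(df$bnapus_id)
  df$athaliana_id <- as.character(df$athaliana_id)
  dup <- duplicated(df[, c("bnapus_id", "athaliana_id")])
  if (any(dup)) {
    warning("collapsing ", sum(dup), " duplicated ortholog row(s)")
    df <- df[!dup, ]
  }
  multi <- unique(df$bnapus_id[duplicated(df$bnapus_id)])
  if (length(multi) > 0)
    stop("B. napus gene(s) mapped to more than one A. thaliana gene: ",
         paste(head(multi, 5), collapse = ", "))
  class(df) <- c("OrthologMap", "data.frame")
  df
}

.EDGE_SIGNS <- c("activation", "repression", "unknown")

#' Read a signed TF-to-target interaction table
#'
#' @param path TSV with columns `tf`, `target`, `sign`, `study_id`,
#'   `study_interaction_count`. `sign` must be one of `activation`,
#'   `repression` or (literally) `unknown`.
#' @return data.frame of class `InteractionSet`.
#' @export
read_interactions <- function(path) {
  df <- .read_tsv(path, "interactions")
  .require_cols(df, c("tf", "target", "sign", "study_id",
                      "study_interaction_count"), path)
  df$sign <- as.character(df$sign)
  bad <- setdiff(unique(df$sign), .EDGE_SIGNS)
  if (length(bad) > 0)
    stop("invalid interaction sign(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(.EDGE_SIGNS, collapse = ", "), ")")
  n <- suppressWarnings(as.integer(df$study_interaction_count))
  if (any(is.na(n)) || any(n < 1))
    stop("study_interaction_count must be a positive integer")
  df$study_interaction_count <- n
  df$tf <- as.character(df$tf); df$target <- as.character(df$target)
  class(df) <- c("InteractionSet", "data.frame")
  df
}

.IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                  "B", "D", "H", "V", "N")

#' Read a table of IUPAC binding-site consensus motifs
#'
#' @param path TSV with columns `motif_id`, `tf`, `consensus`. The consensus
#'   must be a non-empty string over the IUPAC DNA alphabet.
#' @return data.frame of class `MotifSet`.
#' @export
read_motifs <- function(path) {
  df <- .read_tsv(path, "motifs")
  .require_cols(df, c("motif_id", "tf", "consensus"), path)
  df$consensus <- toupper(as.character(df$consensus))
  validate_motif_set(df)
  class(df) <- c("MotifSet", "data.frame")
  df
}

validate_motif_set <- function(df) {
  if (any(!nzchar(df$consensus))) stop("empty motif consensus")
  for (i in seq_len(nrow(df))) {
    letters_i <- strsplit(df$consensus[i], "")[[1]]
    bad <- setdiff(letters_i, .IUPAC_CHARS)
    if (length(bad) > 0)
      stop(sprintf("motif '%s': non-IUPAC character(s) %s in consensus '%s'",
                   df$motif_id[i], paste(bad, collapse = ","), df$consensus[i]))
  }
  invisible(df)
}

#' Write a result table as TSV
#'
#' Writes a tab-separated file with a header row. Numeric columns are written
#' at full double precision (R's default 15-significant-digit decimal
#' rendering, which round-trips through re-reading); missing statistics are
#' written as the literal string `NA`.
#'
#' @param rows data.frame with named columns.
#' @param path output path.
#' @export
write_result_table <- function(rows, path) {
  con <- tryCatch(file(path, open = "wt"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  write.table(as.data.frame(rows), con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Write a count matrix and sample sheet as TSV files
#'
#' @param cm a [CountMatrix()].
#' @param counts_path,samples_path output paths.
#' @export
write_counts <- function(cm, counts_path, samples_path) {
  stopifnot(inherits(cm, "CountMatrix"))
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  write_result_table(df, counts_path)
  write_result_table(cm$samples, samples_path)
  invisible(NULL)
}

#' Read promoter sequences from a FASTA file
#'
#' @param path FASTA file; record IDs are gene IDs (text after the first
#'   whitespace is dropped).
#' @return a [Biostrings::DNAStringSet] named by gene ID.
#' @export
read_promoters <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicated gene IDs in promoter FASTA")
  seqs
}
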