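#' Read labeled DNA sequences from a multi-FASTA file
#'
#' Headers are parsed as `"<id> <label-token> ..."`: the first whitespace
#' token is the sequence id and the family label is extracted from the
#' second token (or from the id when the header has a single token).  By
#' default the label is the text before the first colon, so the HLA-style
#' header `">HLA001 A*02:01:01"` yields label `"A*02"` and a synthetic
#' header `">FAM1_001 FAM1"` yields `"FAM1"`.  Pass `label_pattern` (a
#' regex whose first capture group is the label) to override.
#'
#' @param path Path to a FASTA file.
#' @param label_pattern Optional regex with one capture group.
#' @return Data frame with columns `id`, `label`, `bases` (upper-cased),
#'   in file order.
#' @export
read_fasta <- function(path, label_pattern = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("FASTA file contains no sequences: ", path,
                               call. = FALSE)
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  rest <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), ids)
  token <- sub("\\s.*$", "", rest)
  labels <- parse_label(token, label_pattern)
  records <- data.frame(id = ids, label = labels,
                        bases = toupper(as.character(seqs)))
  validate_records(records)
}

parse_label <- function(token, label_pattern = NULL) {
  if (is.null(label_pattern)) {
    sub(":.*$", "", token)
  } else {
    m <- regmatches(token, regexec(label_pattern, token))
    vapply(m, function(g) {
      if (length(g) < 2L) stop("label_pattern did not match: ", g[1] %||% "",
                               call. = FALSE)
      g[2]
    }, "")
  }
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Write sequence records as multi-FASTA
#'
#' Headers are `"<id> <label>"`, the format [read_fasta()] parses back into
#' identical records.
#'
#' @param records Data frame with columns `id`, `label`, `bases`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  validate_records(records)
  set <- Biostrings::DNAStringSet(records$bases)
  names(set) <- paste(records$id, records$label)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a 2-D embedding as TSV
#'
#' Columns `id`, `label`, `x`, `y`, preceded by `#`-comment provenance
#' lines (configuration hash and seed) so every output names the run that
#' produced it.
#'
#' @param emb An `embedding2d`.
#' @param path Output path.
#' @param provenance Optional named list recorded in the header.
#' @param force Overwrite an existing file (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_embedding_tsv <- function(emb, path, provenance = NULL, force = FALSE) {
  stopifnot(is.data.frame(emb))
  if (file.exists(path) && !force) {
    stop("refusing to overwrite ", path, " (use force = TRUE)", call. = FALSE)
  }
  prov <- c(attr(emb, "provenance"), provenance)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(prov) > 0L) {
    flat <- vapply(prov, function(v) paste(format(v), collapse = " "), "")
    writeLines(sprintf("# %s: %s", names(flat), flat), con)
    writeLines(sprintf("# config_hash: %s", rlang::hash(prov)), con)
  }
  utils::write.table(as.data.frame(emb), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back an embedding TSV written by [write_embedding_tsv()]
#'
#' @param path Path to the TSV.
#' @return An `embedding2d` data frame.
#' @export
read_embedding_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          colClasses = c("character", "character",
                                         "numeric", "numeric"))
  embedding2d(as.matrix(df[, c("x", "y")]), ids = df$id, labels = df$label)
}

#' Save / load a trained stacked model
#'
#' The on-disk container is an RDS serialization of the `stacked_model`
#' list; [load_model()] shape-checks every stage against the stored plan
#' before returning it, so a corrupted or hand-edited container fails
#' loudly rather than projecting garbage.
#'
#' @param model A `stacked_model`.
#' @param path File path (conventionally `.rds`).
#' @return `save_model()` returns `path` invisibly; `load_model()` the
#'   validated model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "stacked_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "stacked_model")) {
    stop("not a stacked_model container: ", path, call. = FALSE)
  }
  plan <- model$plan
  if (length(model$stages) != length(plan) - 1L) {
    stop("corrupt model: ", length(model$stages), " stages for plan of ",
         length(plan), " dims", call. = FALSE)
  }
  for (k in seq_along(model$stages)) {
    p <- model$stages[[k]]
    ok <- identical(dim(p$W_enc), c(plan[k + 1L], plan[k])) &&
      identical(dim(p$W_dec), c(plan[k], plan[k + 1L])) &&
      length(p$b_enc) == plan[k + 1L] && length(p$b_dec) == plan[k] &&
      length(model$centers[[k]]) == plan[k]
    if (!ok) stop("corrupt model: stage ", k, " shapes do not match plan",
                  call. = FALSE)
  }
  model
}
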