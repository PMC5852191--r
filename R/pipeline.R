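#' Run the full embedding pipeline on a FASTA file or record set
#'
#' Reads (or takes) labeled sequences, encodes them under the chosen
#' scheme, trains the stacked autoencoder, projects to 2-D, computes the
#' PCA baseline on the same matrix, scores both embeddings, and writes all
#' artifacts to `out_dir`:
#' \describe{
#'   \item{`embedding.tsv`, `pca_embedding.tsv`}{the two 2-D embeddings
#'     with provenance headers (config hash, seed);}
#'   \item{`training_log.tsv`}{per-stage, per-epoch reconstruction error;}
#'   \item{`stage_errors.tsv`}{final per-stage reconstruction errors;}
#'   \item{`scores.json`}{mean and per-label silhouettes of both methods;}
#'   \item{`model.rds`}{the trained model container;}
#'   \item{`embedding.png`}{scatter plot, one color per family (optional).}
#' }
#' Existing files are never overwritten unless `force = TRUE`.  Re-running
#' with the same configuration reproduces the TSV content exactly.
#'
#' @param input Path to a multi-FASTA file, or a records data frame.
#' @param out_dir Output directory (created if missing).
#' @param scheme `"docvec"` (default) or `"onehot"`.
#' @param l Word length for the document-vector scheme.
#' @param plan Optional [stack_plan()]; defaults to the full-size plan for
#'   the scheme (and a geometric fallback for non-standard dimensions).
#' @param cfg A [train_config()].
#' @param label_pattern Passed to [read_fasta()].
#' @param normalize Passed to [encode_dataset()] for the docvec scheme.
#' @param force Overwrite existing outputs.
#' @param write_plot Write the PNG scatter plot (default `TRUE`).
#' @return Invisibly, a list with `records`, `encoded`, `model`,
#'   `embedding`, `pca`, `scores`, `stage_errors` and the output paths.
#' @export
run_pipeline <- function(input, out_dir, scheme = c("docvec", "onehot"),
                         l = 5, plan = NULL, cfg = train_config(),
                         label_pattern = NULL, normalize = TRUE,
                         force = FALSE, write_plot = TRUE) {
  scheme <- match.arg(scheme)
  records <- if (is.character(input)) read_fasta(input, label_pattern)
             else validate_records(input)
  X <- encode_dataset(records, scheme = scheme, l = l, normalize = normalize)
  if (is.null(plan)) plan <- pick_plan(scheme, ncol(X), l)
  if (!inherits(plan, "stack_plan")) plan <- stack_plan(plan)

  cmp <- compare_methods(X, plan, cfg)
  prov <- list(scheme = scheme, l = if (scheme == "docvec") l else NA,
               plan = paste(plan, collapse = ","),
               learning_rate = cfg$learning_rate, epochs = cfg$epochs,
               batch_size = cfg$batch_size, seed = cfg$seed)
  stage_err <- reconstruction_through_stack(cmp$model, X)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(out_dir,
                     c(embedding = "embedding.tsv",
                       pca = "pca_embedding.tsv",
                       log = "training_log.tsv",
                       stage = "stage_errors.tsv",
                       scores = "scores.json",
                       model = "model.rds",
                       plot = "embedding.png"))
  names(paths) <- c("embedding", "pca", "log", "stage", "scores", "model",
                    "plot")
  existing <- paths[file.exists(paths)]
  if (length(existing) > 0L && !force) {
    stop("output file(s) already exist (use force = TRUE): ",
         paste(basename(existing), collapse = ", "), call. = FALSE)
  }

  write_embedding_tsv(cmp$ae, paths[["embedding"]], provenance = prov,
                      force = force)
  write_embedding_tsv(cmp$pca, paths[["pca"]], provenance = prov,
                      force = force)
  write_provenance_tsv(cmp$model$logs, paths[["log"]], prov)
  write_provenance_tsv(stage_err, paths[["stage"]], prov)
  scores <- list(config_hash = rlang::hash(prov), seed = cfg$seed,
                 mean_silhouette = stats::setNames(
                   as.list(cmp$scores$mean_silhouette), cmp$scores$method),
                 per_label = cmp$per_label)
  jsonlite::write_json(scores, paths[["scores"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  save_model(cmp$model, paths[["model"]])
  if (isTRUE(write_plot)) {
    p <- plot_embedding(cmp$ae, title = sprintf("stacked AE (%s)", scheme))
    ggplot2::ggsave(paths[["plot"]], p, width = 6, height = 5, dpi = 150)
  }
  invisible(list(records = records, encoded = X, model = cmp$model,
                 embedding = cmp$ae, pca = cmp$pca, scores = cmp$scores,
                 per_label = cmp$per_label, stage_errors = stage_err,
                 paths = paths))
}

write_provenance_tsv <- function(df, path, prov) {
  con <- file(path, "w")
  on.exit(close(con))
  flat <- vapply(prov, function(v) paste(format(v), collapse = " "), "")
  writeLines(sprintf("# %s: %s", names(flat), flat), con)
  writeLines(sprintf("# config_hash: %s", rlang::hash(prov)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

pick_plan <- function(scheme, D, l) {
  if (scheme == "onehot" && D == 3288L) return(default_plan("onehot"))
  if (scheme == "docvec" && D == 1024L) return(default_plan("docvec"))
  # non-standard input width: geometric descent by ~1/8 per stage
  dims <- D
  while (dims[length(dims)] > 2L) {
    dims <- c(dims, max(2L, dims[length(dims)] %/% 8L))
  }
  stack_plan(dims)
}

#' Word-length sweep for the document-vector scheme
#'
#' Runs the compact benchmark pipeline for each word length `l`, reporting
#' the mean silhouette of the stacked-AE and PCA embeddings — the harness
#' for choosing `l` (word lengths above 6 blow up the vocabulary, and with
#' it the run time, for little gain).
#'
#' @param records Labeled sequence records.
#' @param l_values Word lengths to evaluate (default `c(4, 5, 6)`).
#' @param cfg A [train_config()].
#' @param n_hidden Width of the single intermediate layer of the compact
#'   per-`l` plan `(4^l, n_hidden, 2)` (default 128).
#' @return Data frame with columns `l`, `dim`, `ae_silhouette`,
#'   `pca_silhouette`.
#' @export
sweep_word_length <- function(records, l_values = c(4, 5, 6),
                              cfg = train_config(), n_hidden = 128) {
  validate_records(records)
  if (any(l_values < 2 | l_values > 8)) {
    stop("word lengths must be in [2, 8]", call. = FALSE)
  }
  rows <- lapply(l_values, function(l) {
    X <- encode_dataset(records, "docvec", l = l)
    D <- ncol(X)
    dims <- if (n_hidden < D) c(D, n_hidden, 2L) else c(D, max(D %/% 8L, 2L), 2L)
    dims <- unique(c(dims[dims > 2L], 2L))
    cmp <- compare_methods(X, stack_plan(dims), cfg)
    data.frame(l = l, dim = D,
               ae_silhouette = cmp$scores$mean_silhouette[1],
               pca_silhouette = cmp$scores$mean_silhouette[2])
  })
  do.call(rbind, rows)
}
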