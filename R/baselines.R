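#' PCA projection of an encoded matrix
#'
#' Centers the rows and projects onto the top-k principal axes (via
#' singular value decomposition, as in [stats::prcomp()]).  Each axis is
#' oriented so that its largest-magnitude loading is positive, making the
#' output deterministic rather than deterministic-up-to-sign.
#'
#' @param X An `encoded_matrix` or plain numeric matrix, `N >= 2` rows.
#' @param k Number of components (default 2; `k = 2` yields an
#'   `embedding2d`).
#' @return For `k = 2`, an `embedding2d` data frame (`id`, `label`, `x`,
#'   `y`); otherwise a plain `N x k` score matrix.
#' @export
pca_project <- function(X, k = 2) {
  labels <- seq_labels(X)
  scheme <- attr(X, "scheme")
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("PCA needs at least 2 rows", call. = FALSE)
  stopifnot_scalar_count(k, "k")
  if (k > min(nrow(X), ncol(X))) {
    stop("k = ", k, " exceeds min(N, D) = ", min(nrow(X), ncol(X)),
         call. = FALSE)
  }
  if (all(apply(X, 2L, stats::var) < 1e-24)) {
    stop("matrix has zero variance (all rows identical); PCA is undefined",
         call. = FALSE)
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = k)
  # orient each axis: largest |loading| positive
  flip <- vapply(seq_len(k), function(j) {
    rot <- pc$rotation[, j]
    sign(rot[which.max(abs(rot))])
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2L, flip, "*")
  if (k == 2L) {
    embedding2d(scores, ids = rownames(X), labels = labels,
                provenance = list(scheme = scheme, method = "pca"))
  } else scores
}

#' Silhouette score of a labeled 2-D embedding
#'
#' Standard silhouette widths (Euclidean distance on the embedding
#' coordinates) against the family labels, averaged overall and per label.
#' Labels with a single point get silhouette 0 by the usual convention.
#' The mean silhouette turns the visual claim "families form their own
#' clusters" into a scalar in [-1, 1].
#'
#' @param emb An `embedding2d` (data frame with `label`, `x`, `y`), or a
#'   coordinate matrix plus `labels`.
#' @param labels Optional label vector when `emb` is a plain matrix.
#' @return A `cluster_score` list: `mean_silhouette`, `per_label` (named
#'   means), `n_labels`, `n_points`.
#' @export
silhouette_score <- function(emb, labels = NULL) {
  if (is.data.frame(emb)) {
    if (is.null(labels)) labels <- emb$label
    coords <- as.matrix(emb[, c("x", "y")])
  } else {
    coords <- as.matrix(emb)
  }
  if (is.null(labels)) stop("labels are required", call. = FALSE)
  if (length(labels) != nrow(coords)) {
    stop("length(labels) != number of points", call. = FALSE)
  }
  fac <- factor(labels)
  if (nlevels(fac) < 2L) {
    stop("silhouette needs at least 2 distinct labels", call. = FALSE)
  }
  if (all(tabulate(fac) == 1L)) {
    # every label a singleton: all widths 0 by the singleton convention
    widths <- numeric(nrow(coords))
  } else {
    sil <- cluster::silhouette(as.integer(fac), stats::dist(coords))
    widths <- sil[, "sil_width"]
  }
  per <- tapply(widths, fac, mean)
  structure(list(mean_silhouette = mean(widths),
                 per_label = per[levels(fac)],
                 n_labels = nlevels(fac),
                 n_points = nrow(coords)),
            class = "cluster_score")
}

#' @export
print.cluster_score <- function(x, ...) {
  cat(sprintf("<cluster_score> mean silhouette %.4f over %d points, %d labels\n",
              x$mean_silhouette, x$n_points, x$n_labels))
  print(round(x$per_label, 4))
  invisible(x)
}

#' Stacked-autoencoder versus PCA on one encoded matrix
#'
#' Trains the stack, projects to 2-D, computes the 2-component PCA of the
#' same matrix, and scores both embeddings by mean silhouette against the
#' family labels.  Both methods see the identical input matrix; only the
#' projection differs.
#'
#' @param X An `encoded_matrix` with labels.
#' @param plan A [stack_plan()] whose first dim matches `ncol(X)`.
#' @param cfg A [train_config()].
#' @param ... Further arguments to [train_stack()].
#' @return A `method_comparison` list: embeddings `ae` and `pca`, the
#'   trained `model`, `scores` (data frame, one row per method) and
#'   `per_label` (per-label silhouette means, methods in columns).
#' @examples
#' \donttest{
#' recs <- generate_families(n_families = 3, members_per_family = 10,
#'                           seq_length = 120, seed = 2)
#' X <- encode_dataset(recs, "docvec", l = 3)
#' cmp <- compare_methods(X, stack_plan(c(64, 8, 2)),
#'                        train_config(epochs = 60, seed = 2))
#' cmp$scores
#' }
#' @export
compare_methods <- function(X, plan, cfg = train_config(), ...) {
  model <- train_stack(X, plan, cfg, ...)
  ae_emb <- project_stack(model, X)
  pca_emb <- pca_project(X, k = 2)
  ae_sc <- silhouette_score(ae_emb)
  pca_sc <- silhouette_score(pca_emb)
  structure(list(
    ae = ae_emb, pca = pca_emb, model = model,
    scores = data.frame(method = c("stacked_ae", "pca"),
                        mean_silhouette = c(ae_sc$mean_silhouette,
                                            pca_sc$mean_silhouette)),
    per_label = data.frame(label = names(ae_sc$per_label),
                           stacked_ae = as.numeric(ae_sc$per_label),
                           pca = as.numeric(pca_sc$per_label))),
    class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("<method_comparison>\n")
  print(x$scores, row.names = FALSE)
  invisible(x)
}
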