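#' Layer plan of a stacked autoencoder
#'
#' An ordered, strictly decreasing list of layer widths ending in 2; each
#' adjacent pair defines one compressing autoencoder of the stack.
#'
#' @param dims Integer vector, strictly decreasing, last element 2.
#' @return A `stack_plan` object.
#' @seealso [default_plan()]
#' @export
stack_plan <- function(dims) {
  dims <- as.integer(dims)
  if (length(dims) < 2L) stop("a plan needs at least two dims", call. = FALSE)
  if (any(diff(dims) >= 0L)) {
    stop("plan dims must be strictly decreasing: ",
         paste(dims, collapse = ", "), call. = FALSE)
  }
  if (dims[length(dims)] != 2L) {
    stop("the plan must end in 2 (the embedding dimension)", call. = FALSE)
  }
  structure(dims, class = "stack_plan")
}

#' Default layer plans for the two encoding schemes
#'
#' The full-size architectures: for 822-bp one-hot input, five autoencoders
#' `3288, 1600, 800, 400, 150, 2`; for `l = 5` document vectors, four
#' autoencoders `1024, 768, 384, 128, 2`.  `"docvec-scaled"` is the compact
#' two-stage plan `1024, 128, 2` used by the package's synthetic benchmark
#' and tests.
#'
#' @param scheme `"onehot"` (alias `"one-hot-822bp"`), `"docvec"` (alias
#'   `"docvec-l5"`), or `"docvec-scaled"`.
#' @return A [stack_plan()].
#' @examples
#' length(default_plan("onehot")) - 1  # 5 stages
#' length(default_plan("docvec")) - 1  # 4 stages
#' @export
default_plan <- function(scheme) {
  switch(scheme,
    "onehot" = , "one-hot" = , "one-hot-822bp" =
      stack_plan(c(3288L, 1600L, 800L, 400L, 150L, 2L)),
    "docvec" = , "docvec-l5" =
      stack_plan(c(1024L, 768L, 384L, 128L, 2L)),
    "docvec-scaled" = stack_plan(c(1024L, 128L, 2L)),
    stop("unknown scheme: ", scheme, call. = FALSE))
}

#' Greedy layer-wise training of a stacked autoencoder
#'
#' Trains the first autoencoder on the encoded matrix, the second on the
#' first stage's hidden codes, and so on, until the final 2-dimensional
#' code layer.  Before each stage its input matrix is centered and scaled
#' to unit root-mean-square (the centering keeps ReLU units from dying
#' en masse on all-positive, nearly collinear inputs such as k-mer
#' histograms; the scaling makes the scale-free learning rate meaningful).
#' Both are stored in the model and re-applied at projection time.
#'
#' Stage k trains with seed `cfg$seed + k` so stages are individually
#' reproducible, and with an epoch budget `cfg$epochs * min(d1/dk, 16)`
#' where `d1/dk` is the ratio of the first stage's input width to stage
#' k's: narrow late stages are orders of magnitude cheaper per epoch, and
#' the longer budget lets their SGD actually reach the optimum instead of
#' stopping at an arbitrary iteration count.
#'
#' All hidden layers use ReLU except the final 2-node code layer, which is
#' linear by default (`code_activation`) so embeddings can occupy all four
#' quadrants of the plane.
#'
#' @param X An `encoded_matrix` (or plain matrix) with `plan[1]` columns
#'   and at least 2 rows.
#' @param plan A [stack_plan()] (or integer vector coerced to one).
#' @param cfg A [train_config()].
#' @param code_activation Activation of the final 2-node layer: `"linear"`
#'   (default) or `"relu"`.
#' @param fine_tune If `TRUE`, follow the greedy phase with joint
#'   end-to-end SGD through the unrolled encoder/decoder network for
#'   `cfg$epochs` further epochs.  Off by default: the greedy scheme alone
#'   defines the method.
#' @return A `stacked_model`: per-stage trained parameters, per-stage
#'   centering/scaling, the plan and per-stage training logs.
#' @export
train_stack <- function(X, plan, cfg = train_config(),
                        code_activation = c("linear", "relu"),
                        fine_tune = FALSE) {
  if (!inherits(plan, "stack_plan")) plan <- stack_plan(plan)
  code_activation <- match.arg(code_activation)
  labels <- seq_labels(X)
  X <- as.matrix(X)
  if (ncol(X) != plan[1]) {
    stop("encoded matrix has ", ncol(X), " columns but the plan starts at ",
         plan[1], call. = FALSE)
  }
  if (nrow(X) < 2L) stop("need at least 2 rows to train a stack", call. = FALSE)

  n_stage <- length(plan) - 1L
  stages <- vector("list", n_stage)
  centers <- vector("list", n_stage)
  scales <- numeric(n_stage)
  logs <- vector("list", n_stage)
  cur <- X
  for (k in seq_len(n_stage)) {
    ctr <- colMeans(cur)
    cur <- sweep(cur, 2L, ctr)
    s <- sqrt(mean(cur^2))
    if (s < 1e-12) s <- 1
    cur <- cur / s
    hidden_act <- if (k == n_stage) code_activation else "relu"
    spec <- layer_spec(plan[k], plan[k + 1L], hidden_activation = hidden_act,
                       output_activation = "linear")
    stage_cfg <- cfg
    stage_cfg$epochs <- as.integer(cfg$epochs *
                                     min(ceiling(plan[1] / plan[k]), 16L))
    stage_cfg$seed <- cfg$seed + k
    fit <- tryCatch(train_ae(cur, spec, stage_cfg), error = function(e) {
      stop("stage ", k, " (", plan[k], " -> ", plan[k + 1L], "): ",
           conditionMessage(e), call. = FALSE)
    })
    stages[[k]] <- fit$params
    centers[[k]] <- ctr
    scales[k] <- s
    logs[[k]] <- cbind(stage = k, fit$log)
    cur <- encode_batch(fit$params, cur)
  }
  model <- structure(list(stages = stages, centers = centers, scales = scales,
                          plan = plan, logs = do.call(rbind, logs),
                          code_activation = code_activation,
                          seed = cfg$seed, labels = labels),
                     class = "stacked_model")
  if (isTRUE(fine_tune)) model <- fine_tune_stack(model, X, cfg)
  model
}

#' Project encoded sequences to 2-D through a trained stack
#'
#' Applies each stage's stored centering/scaling and encoder in order; the
#' composition maps the input dimension down to 2.  Axis units carry no
#' physical meaning.
#'
#' @param model A `stacked_model`.
#' @param X Matrix with `model$plan[1]` columns (typically the training
#'   `encoded_matrix`).
#' @return An `embedding2d`: data frame with columns `id`, `label`, `x`,
#'   `y`, one row per input row, with provenance attributes.
#' @export
project_stack <- function(model, X) {
  stopifnot(inherits(model, "stacked_model"))
  labels <- seq_labels(X)
  scheme <- attr(X, "scheme")
  X <- as.matrix(X)
  if (ncol(X) != model$plan[1]) {
    stop("matrix has ", ncol(X), " columns but the model expects ",
         model$plan[1], call. = FALSE)
  }
  cur <- X
  for (k in seq_along(model$stages)) {
    cur <- sweep(cur, 2L, model$centers[[k]]) / model$scales[k]
    cur <- encode_batch(model$stages[[k]], cur)
  }
  embedding2d(cur,
              ids = rownames(X),
              labels = labels,
              provenance = list(scheme = scheme,
                                plan = as.integer(model$plan),
                                seed = model$seed))
}

embedding2d <- function(coords, ids = NULL, labels = NULL,
                        provenance = list()) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2L)
  if (any(!is.finite(coords))) stop("non-finite embedding coordinates",
                                    call. = FALSE)
  n <- nrow(coords)
  out <- data.frame(
    id = if (is.null(ids)) sprintf("seq%03d", seq_len(n)) else ids,
    label = if (is.null(labels)) rep(NA_character_, n) else labels,
    x = coords[, 1L], y = coords[, 2L])
  structure(out, provenance = provenance,
            class = c("embedding2d", "data.frame"))
}

#' Per-stage reconstruction errors of a trained stack
#'
#' For every stage, the mean squared reconstruction error of that stage's
#' autoencoder on its own (centered, scaled) stage input — the quantity
#' whose training trace is in `model$logs`, recomputed on the data given.
#'
#' @param model A `stacked_model`.
#' @param X Matrix with `model$plan[1]` columns.
#' @return Data frame with columns `stage`, `n_in`, `n_hidden`, `error`.
#' @export
reconstruction_through_stack <- function(model, X) {
  stopifnot(inherits(model, "stacked_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$plan[1]) {
    stop("matrix has ", ncol(X), " columns but the model expects ",
         model$plan[1], call. = FALSE)
  }
  cur <- X
  out <- data.frame(stage = integer(), n_in = integer(),
                    n_hidden = integer(), error = numeric())
  for (k in seq_along(model$stages)) {
    cur <- sweep(cur, 2L, model$centers[[k]]) / model$scales[k]
    fw <- ae_forward(model$stages[[k]], cur)
    out[k, ] <- list(k, model$plan[k], model$plan[k + 1L],
                     reconstruction_error(cur, fw$reconstruction))
    cur <- fw$code
  }
  out
}

# Joint end-to-end refinement: SGD through the unrolled network
# (all encoders, then all decoders in reverse) on the stage-1 input.
fine_tune_stack <- function(model, X, cfg) {
  n_stage <- length(model$stages)
  X1 <- sweep(X, 2L, model$centers[[1L]]) / model$scales[1L]
  N <- nrow(X1)
  base_lr <- cfg$learning_rate / ncol(X1)
  acts <- vapply(seq_len(n_stage), function(k)
    model$stages[[k]]$spec$hidden_activation, "")
  with_seed(cfg$seed + n_stage + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      lr <- if (cfg$lr_decay) base_lr * 0.3^(floor(3 * (ep - 1) / cfg$epochs))
            else base_lr
      ord <- if (cfg$shuffle) sample.int(N) else seq_len(N)
      for (start in seq.int(1L, N, by = cfg$batch_size)) {
        ix <- ord[start:min(start + cfg$batch_size - 1L, N)]
        Xb <- X1[ix, , drop = FALSE]
        B <- nrow(Xb)
        # forward: encoders 1..K then decoders K..1, caching pre-activations
        Hs <- vector("list", n_stage); Zs <- vector("list", n_stage)
        cur <- Xb
        for (k in seq_len(n_stage)) {
          p <- model$stages[[k]]
          Z <- sweep(tcrossprod(cur, p$W_enc), 2L, p$b_enc, "+")
          H <- apply_act(Z, acts[k])
          Zs[[k]] <- Z; Hs[[k]] <- H; cur <- H
        }
        Ds <- vector("list", n_stage)   # decoder outputs, index = stage
        for (k in rev(seq_len(n_stage))) {
          p <- model$stages[[k]]
          cur <- sweep(tcrossprod(cur, p$W_dec), 2L, p$b_dec, "+")
          Ds[[k]] <- cur
        }
        delta <- (2 / B) * (cur - Xb)
        # backprop through decoders 1..K (they were applied K..1)
        for (k in seq_len(n_stage)) {
          p <- model$stages[[k]]
          inp <- if (k == n_stage) Hs[[n_stage]] else Ds[[k + 1L]]
          gW <- crossprod(delta, inp)
          gb <- colSums(delta)
          delta <- delta %*% p$W_dec
          model$stages[[k]]$W_dec <- p$W_dec - lr * gW
          model$stages[[k]]$b_dec <- p$b_dec - lr * gb
        }
        # then through encoders K..1
        for (k in rev(seq_len(n_stage))) {
          p <- model$stages[[k]]
          if (acts[k] == "relu") delta <- delta * (Zs[[k]] > 0)
          inp <- if (k == 1L) Xb else Hs[[k - 1L]]
          gW <- crossprod(delta, inp)
          gb <- colSums(delta)
          delta <- delta %*% p$W_enc
          model$stages[[k]]$W_enc <- p$W_enc - lr * gW
          model$stages[[k]]$b_enc <- p$b_enc - lr * gb
        }
      }
    }
  })
  model
}

#' @export
print.stacked_model <- function(x, ...) {
  cat(sprintf("<stacked_model> plan %s (%d stages, %s code layer), seed %d\n",
              paste(x$plan, collapse = " -> "), length(x$stages),
              x$code_activation, x$seed))
  fin <- stats::aggregate(error ~ stage, x$logs, utils::tail, 1)
  cat("  final per-stage reconstruction error:",
      paste(sprintf("%.4g", fin$error), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.embedding2d <- function(x, ...) {
  cat(sprintf("<embedding2d> %d points, %d labels\n",
              nrow(x), length(unique(x$label))))
  NextMethod()
}
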