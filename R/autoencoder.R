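#' Specification of a single compressing autoencoder
#'
#' One unit of the stack: an `n_in`-dimensional input layer, an
#' `n_hidden`-dimensional intermediate layer (`n_hidden < n_in`) and an
#' `n_in`-dimensional output layer.  The hidden activation is ReLU by
#' default; the per-stage output layer is linear so real-valued inputs
#' (including negative, centered values) can be reconstructed.
#'
#' @param n_in Input (= output) dimension.
#' @param n_hidden Intermediate dimension, strictly smaller than `n_in`.
#' @param hidden_activation `"relu"` or `"linear"`.
#' @param output_activation `"linear"` or `"relu"`.
#' @return A `layer_spec` list.
#' @export
layer_spec <- function(n_in, n_hidden, hidden_activation = c("relu", "linear"),
                       output_activation = c("linear", "relu")) {
  stopifnot_scalar_count(n_in, "n_in")
  stopifnot_scalar_count(n_hidden, "n_hidden")
  if (n_hidden >= n_in) {
    stop("`n_hidden` (", n_hidden, ") must be smaller than `n_in` (", n_in,
         "): the autoencoder must compress", call. = FALSE)
  }
  structure(list(n_in = as.integer(n_in), n_hidden = as.integer(n_hidden),
                 hidden_activation = match.arg(hidden_activation),
                 output_activation = match.arg(output_activation)),
            class = "layer_spec")
}

#' Training configuration for (stacked) autoencoders
#'
#' Plain stochastic gradient descent on the squared reconstruction error,
#' with mini-batches reshuffled every epoch from a seeded generator.
#'
#' `learning_rate` is scale-free: the step size actually applied is
#' `learning_rate / n_in`, which keeps one default stable across input
#' dimensions (the curvature of the reconstruction loss grows with the
#' squared row norm, itself proportional to `n_in` for unit-RMS data).
#' With `lr_decay = TRUE` the step is further multiplied by 0.3 at one and
#' two thirds of the epoch budget, the classic step schedule that lets
#' plain SGD settle instead of bouncing around the optimum.
#'
#' @param learning_rate Positive scale-free step size (default 0.5).
#' @param epochs Number of passes over the data per stage (default 400).
#' @param batch_size Mini-batch size (default 32).
#' @param seed Integer seed controlling initialization and shuffling.
#' @param shuffle Reshuffle rows every epoch (default `TRUE`).
#' @param lr_decay Apply the 0.3-step decay schedule (default `TRUE`).
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.5, epochs = 400, batch_size = 32,
                         seed = 1, shuffle = TRUE, lr_decay = TRUE) {
  if (!is.numeric(learning_rate) || learning_rate <= 0) {
    stop("`learning_rate` must be positive", call. = FALSE)
  }
  stopifnot_scalar_count(epochs, "epochs")
  stopifnot_scalar_count(batch_size, "batch_size")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 shuffle = isTRUE(shuffle), lr_decay = isTRUE(lr_decay)),
            class = "train_config")
}

#' Initialize autoencoder parameters
#'
#' Glorot-uniform weights (`U(-a, a)` with `a = sqrt(6 / (n_in + n_hidden))`
#' for both the encoder and the decoder) and zero biases, fully determined
#' by `seed`.  Glorot scaling keeps the initial reconstruction amplitude
#' comparable to the input amplitude even at extreme compression ratios
#' (e.g. 128 -> 2), which fan-in-only scaling does not.
#'
#' @param spec A [layer_spec()].
#' @param seed Integer seed.
#' @return An `ae_params` list with encoder weights `W_enc`
#'   (`n_hidden x n_in`), bias `b_enc`, decoder weights `W_dec`
#'   (`n_in x n_hidden`), bias `b_dec`, plus `spec` and `seed`.
#' @export
init_ae <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "layer_spec"))
  n <- spec$n_in; h <- spec$n_hidden
  with_seed(seed, {
    a <- sqrt(6 / (n + h))
    structure(list(
      W_enc = matrix(stats::runif(h * n, -a, a), h, n),
      b_enc = numeric(h),
      W_dec = matrix(stats::runif(n * h, -a, a), n, h),
      b_dec = numeric(n),
      spec = spec, seed = as.integer(seed)),
      class = "ae_params")
  })
}

apply_act <- function(Z, act) if (act == "relu") pmax(Z, 0) else Z

#' Forward pass of one autoencoder
#'
#' @param params An `ae_params` object.
#' @param x A single input vector of length `n_in`, or a matrix with
#'   `n_in` columns (one row per observation).
#' @return List with `code` (hidden activations) and `reconstruction`
#'   (output activations), vectors for vector input, matrices for matrix
#'   input.
#' @export
ae_forward <- function(params, x) {
  stopifnot(inherits(params, "ae_params"))
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(X) != params$spec$n_in) {
    stop("input has ", ncol(X), " columns; expected n_in = ",
         params$spec$n_in, call. = FALSE)
  }
  Z <- tcrossprod(X, params$W_enc)
  Z <- sweep(Z, 2L, params$b_enc, "+")
  H <- apply_act(Z, params$spec$hidden_activation)
  R <- tcrossprod(H, params$W_dec)
  R <- sweep(R, 2L, params$b_dec, "+")
  R <- apply_act(R, params$spec$output_activation)
  if (is.matrix(x)) list(code = H, reconstruction = R)
  else list(code = drop(H), reconstruction = drop(R))
}

#' Mean squared reconstruction error
#'
#' Per-element mean of squared differences, the scalar monitored during
#' training: 0 iff the reconstruction is exact, and on the scale of the
#' (unit-RMS-normalized) data regardless of dimension.
#'
#' @param x,reconstruction Vectors or matrices of identical shape.
#' @return A single non-negative number.
#' @export
reconstruction_error <- function(x, reconstruction) {
  if (length(x) != length(reconstruction)) {
    stop("input and reconstruction differ in length (", length(x), " vs ",
         length(reconstruction), ")", call. = FALSE)
  }
  mean((as.numeric(x) - as.numeric(reconstruction))^2)
}

#' Train one autoencoder by backpropagation and SGD
#'
#' Minimizes the squared reconstruction error (summed over features,
#' averaged over the mini-batch) by plain stochastic gradient descent.  The
#' reported per-epoch trace is the per-element mean squared error over the
#' whole dataset.  Fully deterministic given `cfg$seed`.
#'
#' @param X Numeric matrix (rows = observations) with `spec$n_in` columns.
#' @param spec A [layer_spec()].
#' @param cfg A [train_config()].
#' @return An `ae_fit` list: `params` (trained `ae_params`) and `log`, a
#'   data frame with columns `epoch` and `error`.
#' @examples
#' X <- matrix(rep(runif(8), each = 20), 20, 8)  # constant rows
#' fit <- train_ae(X, layer_spec(8, 2), train_config(epochs = 100, seed = 1))
#' tail(fit$log$error, 1)  # ~0: constant data is representable by bias alone
#' @export
train_ae <- function(X, spec, cfg = train_config()) {
  stopifnot(inherits(spec, "layer_spec"), inherits(cfg, "train_config"))
  X <- as.matrix(X)
  if (nrow(X) < 1L) stop("need at least one row to train", call. = FALSE)
  if (ncol(X) != spec$n_in) {
    stop("data has ", ncol(X), " columns; spec expects n_in = ", spec$n_in,
         call. = FALSE)
  }
  params <- init_ae(spec, cfg$seed)
  n <- spec$n_in
  N <- nrow(X)
  act_h <- spec$hidden_activation
  act_o <- spec$output_activation
  base_lr <- cfg$learning_rate / n
  errs <- numeric(cfg$epochs)

  with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      lr <- if (cfg$lr_decay) {
        base_lr * 0.3^(floor(3 * (ep - 1) / cfg$epochs))
      } else base_lr
      ord <- if (cfg$shuffle) sample.int(N) else seq_len(N)
      for (start in seq.int(1L, N, by = cfg$batch_size)) {
        ix <- ord[start:min(start + cfg$batch_size - 1L, N)]
        Xb <- X[ix, , drop = FALSE]
        B <- length(ix)
        Z <- sweep(tcrossprod(Xb, params$W_enc), 2L, params$b_enc, "+")
        H <- apply_act(Z, act_h)
        O <- sweep(tcrossprod(H, params$W_dec), 2L, params$b_dec, "+")
        R <- apply_act(O, act_o)
        E <- R - Xb                          # B x n
        if (act_o == "relu") E <- E * (O > 0)
        # gradients of mean_b sum_i (r - x)^2
        dH <- E %*% params$W_dec             # B x h
        if (act_h == "relu") dH <- dH * (Z > 0)
        params$W_dec <- params$W_dec - lr * (2 / B) * crossprod(E, H)
        params$b_dec <- params$b_dec - lr * (2 / B) * colSums(E)
        params$W_enc <- params$W_enc - lr * (2 / B) * crossprod(dH, Xb)
        params$b_enc <- params$b_enc - lr * (2 / B) * colSums(dH)
      }
      full <- ae_forward(params, X)
      errs[ep] <- reconstruction_error(X, full$reconstruction)
      if (!is.finite(errs[ep])) {
        stop("training diverged at epoch ", ep,
             " (non-finite reconstruction error); try a smaller learning_rate",
             call. = FALSE)
      }
    }
  })
  structure(list(params = params,
                 log = data.frame(epoch = seq_len(cfg$epochs), error = errs)),
            class = "ae_fit")
}

#' Hidden codes of a batch of inputs
#'
#' @param params An `ae_params` object (or an `ae_fit`, whose params are
#'   used).
#' @param X Matrix with `n_in` columns.
#' @return An `N x n_hidden` matrix, row i the code of row i.
#' @export
encode_batch <- function(params, X) {
  if (inherits(params, "ae_fit")) params <- params$params
  ae_forward(params, as.matrix(X))$code
}

#' @export
print.ae_fit <- function(x, ...) {
  s <- x$params$spec
  cat(sprintf("<ae_fit> %d -> %d -> %d (%s hidden, %s output); %d epochs, final error %.4g\n",
              s$n_in, s$n_hidden, s$n_in, s$hidden_activation,
              s$output_activation, nrow(x$log), utils::tail(x$log$error, 1)))
  invisible(x)
}
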