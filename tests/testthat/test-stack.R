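test_that("default plans reproduce the published architectures", {
  oh <- default_plan("onehot")
  expect_equal(as.integer(oh), c(3288L, 1600L, 800L, 400L, 150L, 2L))
  expect_equal(length(oh) - 1, 5)   # five autoencoders
  dv <- default_plan("docvec")
  expect_equal(as.integer(dv), c(1024L, 768L, 384L, 128L, 2L))
  expect_equal(length(dv) - 1, 4)   # four autoencoders
  expect_equal(as.integer(default_plan("docvec-scaled")), c(1024L, 128L, 2L))
  expect_equal(length(stack_plan(c(10, 4, 2))) - 1, 2)
  expect_error(default_plan("protein"), "unknown")
  expect_error(stack_plan(c(10, 12, 2)), "decreasing")
  expect_error(stack_plan(c(10, 5, 3)), "end in 2")
  expect_error(stack_plan(2), "at least two")
})

test_that("stacks train greedily with chained dimensions and full logs", {
  recs <- tiny_records(seed = 19)
  X <- encode_dataset(recs, "docvec", l = 3)  # 24 x 64
  cfg <- train_config(epochs = 60, seed = 5)
  m <- train_stack(X, stack_plan(c(64, 16, 2)), cfg)
  expect_s3_class(m, "stacked_model")
  expect_length(m$stages, 2)
  for (k in 1:2) {
    expect_equal(m$stages[[k]]$spec$n_in, as.integer(m$plan[k]))
    expect_equal(m$stages[[k]]$spec$n_hidden, as.integer(m$plan[k + 1]))
  }
  # per-stage training improves (or at least never worsens) the fit
  for (k in 1:2) {
    tr <- m$logs$error[m$logs$stage == k]
    expect_lte(tail(tr, 1), tr[1])
    expect_true(all(is.finite(tr) & tr >= 0))
  }
  # final code layer is linear by default, ReLU elsewhere
  expect_equal(m$stages[[1]]$spec$hidden_activation, "relu")
  expect_equal(m$stages[[2]]$spec$hidden_activation, "linear")
})

test_that("training and projection are deterministic given the seed", {
  recs <- tiny_records(seed = 23)
  X <- encode_dataset(recs, "docvec", l = 3)
  cfg <- train_config(epochs = 40, seed = 11)
  m1 <- train_stack(X, c(64, 8, 2), cfg)
  m2 <- train_stack(X, c(64, 8, 2), cfg)
  expect_identical(m1$stages, m2$stages)
  e1 <- project_stack(m1, X)
  e2 <- project_stack(m2, X)
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(nrow(X), 4L))  # id, label, x, y
  expect_equal(e1$label, recs$label)
})

test_that("projection composes the stage encoders exactly", {
  recs <- tiny_records(seed = 29)
  X <- encode_dataset(recs, "docvec", l = 3)
  m <- train_stack(X, c(64, 8, 2), train_config(epochs = 40, seed = 2))
  emb <- project_stack(m, X)
  # loop oracle: push each row through stage preprocessing + encoder by hand
  for (i in c(1, 7, 24)) {
    cur <- as.numeric(X[i, ])
    for (k in seq_along(m$stages)) {
      cur <- (cur - m$centers[[k]]) / m$scales[k]
      cur <- ae_forward(m$stages[[k]], cur)$code
    }
    expect_equal(c(emb$x[i], emb$y[i]), cur)
  }
})

test_that("a single-stage plan is just one autoencoder on scaled input", {
  recs <- tiny_records(seed = 31)
  X <- encode_dataset(recs, "docvec", l = 2)  # 16 dims
  cfg <- train_config(epochs = 50, seed = 9)
  m <- train_stack(X, c(16, 2), cfg)
  expect_length(m$stages, 1)
  pre <- sweep(as.matrix(X), 2, m$centers[[1]]) / m$scales[1]
  expect_equal(cbind(project_stack(m, X)$x, project_stack(m, X)$y),
               encode_batch(m$stages[[1]], pre), ignore_attr = TRUE)
})

test_that("per-stage reconstruction errors behave at the boundaries", {
  # trained on effectively constant data: all stage errors collapse
  Xc <- matrix(rep(runif(16), each = 12), 12, 16)
  m <- train_stack(Xc, c(16, 4, 2), train_config(epochs = 60, seed = 3))
  errs <- reconstruction_through_stack(m, Xc)
  expect_equal(nrow(errs), 2)
  expect_true(all(errs$error < 1e-3))

  # untrained all-zero stack on binary data: reconstruction is zero, so the
  # stage-1 error is the mean of squared (preprocessed) inputs
  set.seed(41)
  Xb <- matrix(sample(0:1, 10 * 8, replace = TRUE), 10, 8)
  mz <- m
  mz$plan <- stack_plan(c(8, 3, 2))
  mz$stages <- list(zero_ae_params(8, 3), zero_ae_params(3, 2))
  mz$centers <- list(numeric(8), numeric(3))
  mz$scales <- c(1, 1)
  ez <- reconstruction_through_stack(mz, Xb)
  expect_equal(ez$error[1], mean(Xb^2))
  expect_true(all(ez$error >= 0))
})

test_that("dimension mismatches are rejected with stage context", {
  recs <- tiny_records(seed = 37)
  X <- encode_dataset(recs, "docvec", l = 3)
  expect_error(train_stack(X, c(32, 2), train_config()), "plan starts at 32")
  m <- train_stack(X, c(64, 8, 2), train_config(epochs = 20, seed = 1))
  expect_error(project_stack(m, X[, 1:10]), "expects 64")
  expect_error(
    train_stack(X, c(64, 8, 2),
                train_config(learning_rate = 3000, epochs = 30, seed = 1)),
    "stage")
})

test_that("optional end-to-end fine-tuning improves the joint reconstruction", {
  recs <- tiny_records(seed = 43)
  X <- encode_dataset(recs, "docvec", l = 3)
  cfg <- train_config(epochs = 50, seed = 6)
  greedy <- train_stack(X, c(64, 8, 2), cfg, fine_tune = FALSE)
  tuned <- train_stack(X, c(64, 8, 2), cfg, fine_tune = TRUE)
  # end-to-end reconstruction error of the unrolled network
  e2e <- function(m) {
    cur <- sweep(as.matrix(X), 2, m$centers[[1]]) / m$scales[1]
    inp <- cur
    for (k in seq_along(m$stages)) cur <- ae_forward(m$stages[[k]], cur)$code
    for (k in rev(seq_along(m$stages))) {
      p <- m$stages[[k]]
      cur <- sweep(tcrossprod(cur, p$W_dec), 2, p$b_dec, "+")
    }
    reconstruction_error(inp, cur)
  }
  expect_lte(e2e(tuned), e2e(greedy))
  emb <- project_stack(tuned, X)
  expect_true(all(is.finite(emb$x)) && all(is.finite(emb$y)))
})
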