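test_that("vectors reshape to minimally padded row-major squares", {
  expect_identical(dim(reshape_to_2d(1:100)), c(10L, 10L))
  expect_identical(reshape_to_2d(1:100)[1, ], as.numeric(1:10))

  m10 <- reshape_to_2d(1:10)
  expect_identical(dim(m10), c(4L, 4L))
  expect_identical(sum(m10 == 0), 6L)          # six trailing zeros
  expect_identical(m10[1, ], as.numeric(1:4))  # row-major fill
  expect_identical(m10[3, 1:2], c(9, 10))

  expect_identical(reshape_to_2d(7), matrix(7))
  expect_error(reshape_to_2d(numeric(0)), "empty")
})

test_that("forward probabilities are normalized and finite for any input", {
  model <- init_model(tiny_model_config(), seed = 2L)
  x <- matrix(rnorm(12 * 40, sd = 50), 12, 40)
  p <- model_forward(model, x)
  expect_identical(dim(p), c(12L, 3L))
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))

  # softmax(logits) equals forward, elementwise
  z <- model_forward_logits(model, x)
  soft <- exp(z - apply(z, 1, max)) / rowSums(exp(z - apply(z, 1, max)))
  expect_true(max(abs(soft - p)) < 1e-6)

  # all-zero vector still yields a valid probability row
  p0 <- model_forward(model, rep(0, 40))
  expect_false(anyNA(p0))
  expect_lt(abs(sum(p0) - 1), 1e-6)

  # batch of size 1 accepted
  expect_identical(dim(model_forward_logits(model, x[1, , drop = FALSE])),
                   c(1L, 3L))
})

test_that("one set of weights processes any sample count", {
  model <- init_model(tiny_model_config(), seed = 3L)
  for (n in c(1L, 4L, 16L, 40L, 113L)) {
    z <- model_forward_logits(model, matrix(rnorm(5 * n), 5, n))
    expect_identical(dim(z), c(5L, 3L))
    expect_true(all(is.finite(z)))
  }
  # parameter count is independent of input length by construction: the
  # linear stack consumes exactly conv_channels[8] pooled features
  expect_identical(nrow(model$params$lin_w[[1L]]),
                   model$config$conv_channels[[8L]])
})

test_that("spatial bookkeeping matches the architecture contract", {
  # conv stack preserves the side, one halving, then 1x1: verify through
  # equality of a manual pipeline on a 1-channel identity-like setup is
  # impractical; instead verify the boundary cases the contract implies:
  model <- init_model(tiny_model_config(), seed = 4L)
  # n = 1 -> side 1 -> the kernel-2 pool must be skipped, not crash
  expect_true(all(is.finite(model_forward_logits(model, matrix(1, 2, 1)))))
  # n = 4 -> side 2 -> pooled side 1
  expect_true(all(is.finite(model_forward_logits(model, matrix(1:8, 2, 4)))))
})

test_that("head swap preserves the backbone bit-for-bit", {
  model <- init_model(tiny_model_config(), seed = 5L)
  swapped <- swap_head(model, 2L, seed = 6L)
  expect_identical(head_arity(swapped), 2L)
  expect_identical(ncol(model_forward_logits(swapped, matrix(1:20, 2, 10))), 2L)
  for (i in 1:8) {
    expect_identical(swapped$params$conv_w[[i]], model$params$conv_w[[i]])
    expect_identical(swapped$params$conv_b[[i]], model$params$conv_b[[i]])
  }
  for (i in 1:4) expect_identical(swapped$params$lin_w[[i]], model$params$lin_w[[i]])
  expect_false(identical(dim(swapped$params$lin_w[[5L]]),
                         dim(model$params$lin_w[[5L]])))

  # double swap 3 -> 2 -> 3 keeps the backbone throughout
  back <- swap_head(swapped, 3L, seed = 7L)
  expect_identical(head_arity(back), 3L)
  for (i in 1:8) expect_identical(back$params$conv_w[[i]], model$params$conv_w[[i]])
  for (i in 1:4) expect_identical(back$params$lin_w[[i]], model$params$lin_w[[i]])

  expect_error(swap_head(model, 4L), "2 or 3")
})

test_that("class prediction is argmax with ties toward the lower index", {
  model <- init_model(tiny_model_config(head_arity = 2L), seed = 8L)
  # zero out everything: logits are exactly the (equal) head biases
  model$params$conv_w <- lapply(model$params$conv_w, function(w) w * 0)
  model$params$conv_b <- lapply(model$params$conv_b, function(b) b * 0)
  model$params$lin_w <- lapply(model$params$lin_w, function(w) w * 0)
  model$params$lin_b <- lapply(model$params$lin_b, function(b) b * 0)
  pred <- predict_classes(model, matrix(rnorm(6 * 9), 6, 9))
  expect_true(all(pred == 0L))  # exact tie -> class 0

  # plain argmax on a discriminative head
  model$params$lin_b[[5L]] <- c(0, 1)
  expect_true(all(predict_classes(model, matrix(rnorm(4 * 9), 4, 9)) == 1L))
})

test_that("backpropagation agrees with numerical loss gradients", {
  # one full-batch optimizer step moves each weight opposite its gradient;
  # with Adam the first step is lr * sign(gradient), so compare signs
  # against central finite differences of the loss computed via forward()
  cfg <- model_config(conv_channels = rep(2L, 8L),
                      linear_widths = c(4L, 4L, 4L, 4L, 3L))
  model <- init_model(cfg, seed = 9L)
  set.seed(10)
  x <- matrix(rnorm(6 * 9, sd = 2), 6, 9)
  y <- c(0L, 1L, 2L, 0L, 1L, 2L)
  ce_loss <- function(m) {
    z <- model_forward_logits(m, x)
    zs <- z - apply(z, 1, max)
    mean(log(rowSums(exp(zs))) - zs[cbind(seq_along(y), y + 1L)])
  }
  lr <- 1e-5
  fit <- train_level1(model, x, y,
                      train_config(level1 = list(epochs = 1L, batch = 6L,
                                                 lr = lr)),
                      seed = 1L)
  checked <- 0L
  for (spot in list(c("conv_w", 1L), c("conv_w", 8L), c("lin_w", 1L),
                    c("lin_w", 5L), c("conv_b", 3L), c("lin_b", 5L))) {
    block <- spot[[1L]]; layer <- as.integer(spot[[2L]])
    w0 <- model$params[[block]][[layer]]
    w1 <- fit$model$params[[block]][[layer]]
    set.seed(layer)
    for (j in sample(length(w0), min(3L, length(w0)))) {
      h <- 1e-3
      mp <- model; mp$params[[block]][[layer]][j] <- w0[j] + h
      mm <- model; mm$params[[block]][[layer]][j] <- w0[j] - h
      g <- (ce_loss(mp) - ce_loss(mm)) / (2 * h)
      if (abs(g) > 1e-4) {  # skip numerically ambiguous spots
        expect_equal(sign(w1[j] - w0[j]), -sign(g),
                     info = sprintf("%s[%d] elem %d", block, layer, j))
        checked <- checked + 1L
      }
    }
  }
  expect_gte(checked, 5L)
})

test_that("forward output is deterministic", {
  model <- init_model(tiny_model_config(), seed = 11L)
  x <- matrix(rnorm(10 * 25), 10, 25)
  expect_identical(model_forward_logits(model, x), model_forward_logits(model, x))
})
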