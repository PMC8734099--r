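#' Architecture configuration for the convolutional gene classifier
#'
#' The network maps a per-gene 1D expression vector to class scores: the
#' vector is zero-padded to the next perfect square and filled row-major
#' into a square single-channel matrix, passed through eight 3x3
#' convolutional layers (stride 1, padding 1, ReLU) which preserve the
#' spatial side, one kernel-2 max pool which halves it, and an adaptive max
#' pool collapsing it to 1x1 — so the five-layer linear stack always sees
#' exactly `conv_channels[8]` features, whatever the sample count. This
#' makes one set of weights applicable to datasets of any size, the
#' property the transfer experiment relies on.
#'
#' @param conv_channels Output channels of the eight conv layers. Default
#'   `c(8, 8, 16, 16, 32, 32, 64, 64)`: a modest doubling progression keeps
#'   the stack trainable on a single CPU core while giving it the required
#'   depth.
#' @param linear_widths Output widths of the five linear layers; the last
#'   entry must equal `head_arity`. Default `c(64, 32, 16, 8, head_arity)`.
#' @param head_arity 3 for the general (DR/UR/neutral) head, 2 for the
#'   fine-tuned (DR/UR) head.
#' @return A `model_config` list; kernel 3x3, stride 1, padding 1, mid-pool
#'   kernel 2 and a 1x1 adaptive pool target are fixed and recorded.
#' @export
model_config <- function(conv_channels = c(8L, 8L, 16L, 16L, 32L, 32L, 64L, 64L),
                         linear_widths = NULL, head_arity = 3L) {
  if (!head_arity %in% c(2L, 3L)) stop2("head_arity must be 2 or 3")
  conv_channels <- as.integer(conv_channels)
  if (length(conv_channels) != 8L || any(conv_channels < 1L))
    stop2("conv_channels must be 8 positive integers")
  linear_widths <- as.integer(linear_widths %||%
                              c(64L, 32L, 16L, 8L, head_arity))
  if (length(linear_widths) != 5L || any(linear_widths < 1L))
    stop2("linear_widths must be 5 positive integers")
  if (linear_widths[[5L]] != head_arity)
    stop2("the last linear width must equal head_arity")
  structure(list(conv_channels = conv_channels,
                 linear_widths = linear_widths,
                 head_arity = as.integer(head_arity),
                 kernel = c(3L, 3L), stride = 1L, padding = 1L,
                 midpool_kernel = 2L, adaptive_pool_target = c(1L, 1L)),
            class = "model_config")
}

# uniform fan-in initialization, U(-1/sqrt(fan_in), 1/sqrt(fan_in)) for
# weights and biases (the standard framework default for conv/linear layers)
init_layer <- function(fan_in, n_out, n_w) {
  bound <- 1 / sqrt(fan_in)
  list(w = matrix(runif(n_w, -bound, bound), ncol = n_out),
       b = runif(n_out, -bound, bound))
}

#' Initialize a model with random weights
#'
#' @param config A [model_config()].
#' @param seed Integer seed for the weight draw.
#' @return A `degnet_model`: configuration, parameter list and a provenance
#'   record (seed, initialization scheme, training history).
#' @export
init_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  cc <- config$conv_channels
  lw <- config$linear_widths
  in_ch <- c(1L, cc[-8L])
  params <- list(conv_w = vector("list", 8L), conv_b = vector("list", 8L),
                 lin_w = vector("list", 5L), lin_b = vector("list", 5L))
  with_seed(derive_seed(seed, "init"), {
    for (i in 1:8) {
      fan <- in_ch[[i]] * 9L
      l <- init_layer(fan, cc[[i]], fan * cc[[i]])
      params$conv_w[[i]] <- l$w
      params$conv_b[[i]] <- l$b
    }
    lin_in <- c(cc[[8L]], lw[1:4])
    for (i in 1:5) {
      l <- init_layer(lin_in[[i]], lw[[i]], lin_in[[i]] * lw[[i]])
      params$lin_w[[i]] <- l$w
      params$lin_b[[i]] <- l$b
    }
  })
  new_degnet_model(config, params,
                   provenance = list(init_seed = as.integer(seed),
                                     init_scheme = "uniform-fan-in",
                                     trained_on = character(0L)))
}

new_degnet_model <- function(config, params, provenance = list()) {
  structure(list(config = config, params = params, provenance = provenance),
            class = "degnet_model")
}

#' @export
print.degnet_model <- function(x, ...) {
  n_par <- sum(vapply(unlist(x$params, recursive = FALSE), length, numeric(1L)))
  cat(sprintf("<degnet_model: conv (%s), linear (%s), %d-class head, %d parameters>\n",
              paste(x$config$conv_channels, collapse = ","),
              paste(x$config$linear_widths, collapse = ","),
              x$config$head_arity, n_par))
  if (length(x$provenance$trained_on) > 0L)
    cat("  trained on:", paste(x$provenance$trained_on, collapse = " -> "), "\n")
  invisible(x)
}

#' Head arity of a model or checkpoint
#' @param model A `degnet_model`.
#' @return 2 or 3.
#' @export
head_arity <- function(model) {
  stopifnot(inherits(model, "degnet_model"))
  model$config$head_arity
}

#' Reshape a per-gene vector into the square single-channel input matrix
#'
#' The length-n vector is zero-padded at the tail to the next perfect
#' square m = ceiling(sqrt(n))^2 and filled row-major into a sqrt(m) x
#' sqrt(m) matrix. Minimal padding with a symmetric receptive field; works
#' for any n.
#'
#' @param vector Numeric vector (length >= 1).
#' @return A square numeric matrix.
#' @export
reshape_to_2d <- function(vector) {
  if (length(vector) == 0L) stop2("cannot reshape an empty vector")
  s <- ceiling(sqrt(length(vector)))
  padded <- c(as.numeric(vector), rep(0, s * s - length(vector)))
  matrix(padded, nrow = s, ncol = s, byrow = TRUE)
}

as_feature_matrix <- function(x) {
  if (inherits(x, "labeled_gene_set")) x <- x$features
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (!is.matrix(x) || !is.numeric(x)) stop2("expected a numeric feature matrix")
  if (ncol(x) < 1L) stop2("feature vectors must have length >= 1")
  if (any(!is.finite(x))) stop2("feature matrix contains non-finite values")
  x
}

#' Raw class scores (logits) for a batch of gene vectors
#'
#' @param model A `degnet_model`.
#' @param x Numeric matrix of per-gene vectors (genes in rows), a single
#'   vector, or a `labeled_gene_set` (its `features` are used). All vectors
#'   in a batch share one length.
#' @return Numeric matrix, one row per gene, `head_arity` columns of raw
#'   scores (no output activation).
#' @export
model_forward_logits <- function(model, x) {
  stopifnot(inherits(model, "degnet_model"))
  .cnn_forward_cpp(model$params, as_feature_matrix(x))
}

#' Class probabilities for a batch of gene vectors
#'
#' For the 3-class head the raw scores pass through a softmax, so each row
#' sums to 1; for the 2-class fine-tuned head (trained with a sigmoid
#' cross-entropy on raw scores) each score passes through an elementwise
#' sigmoid.
#'
#' @inheritParams model_forward_logits
#' @return Numeric matrix of per-class probabilities.
#' @export
model_forward <- function(model, x) {
  z <- model_forward_logits(model, x)
  if (head_arity(model) == 3L) {
    zmax <- apply(z, 1L, max)
    ez <- exp(z - zmax)
    ez / rowSums(ez)
  } else {
    1 / (1 + exp(-z))
  }
}

#' Predicted class labels
#'
#' Argmax over the class scores; exact ties break toward the lower class
#' index (deterministic by construction). Classes are 0 = down-regulated,
#' 1 = up-regulated, 2 = neutral.
#'
#' @inheritParams model_forward_logits
#' @return Integer vector of class labels.
#' @export
predict_classes <- function(model, x) {
  z <- model_forward_logits(model, x)
  as.integer(max.col(z, ties.method = "first") - 1L)
}

#' Replace the output head of a trained model
#'
#' Swaps the last linear layer for a fresh one of the new arity (the
#' fine-tuning step: the 3-class softmax head becomes a 2-class raw-score
#' head). All other weights — the conv backbone and the first four linear
#' layers — are preserved bit-identically.
#'
#' How the new head starts matters because the fine-tuning budget is
#' short. `init = "reuse"` (default, shrinking only) keeps the trained
#' down-/up-regulated output units and drops the neutral unit — the
#' closest reading of customizing the existing output layer, it preserves
#' the discrimination already learned and feeds aligned gradients to the
#' backbone from the first fine-tuning step. `init = "zero"` starts all
#' scores at exactly 0 (probability one half); it is also the fallback
#' whenever the arity grows, where there are no units to reuse.
#' `init = "uniform"` draws a random head; note a randomly oriented head
#' starts at a weight scale the short schedule cannot traverse, so an
#' unlucky draw can lock the model into a wrong basin.
#'
#' @param model A `degnet_model`.
#' @param new_arity 2 or 3.
#' @param seed Seed for the head initialization (used by `"uniform"`).
#' @param init `"reuse"` (default), `"zero"` or `"uniform"`.
#' @return The model with the new head.
#' @export
swap_head <- function(model, new_arity = 2L, seed = 1L,
                      init = c("reuse", "zero", "uniform")) {
  stopifnot(inherits(model, "degnet_model"))
  if (!new_arity %in% c(2L, 3L)) stop2("new_arity must be 2 or 3")
  init <- match.arg(init)
  new_arity <- as.integer(new_arity)
  old_arity <- model$config$head_arity
  if (init == "reuse" && new_arity > old_arity) init <- "zero"
  fan_in <- model$config$linear_widths[[4L]]
  l <- switch(init,
    reuse = list(w = model$params$lin_w[[5L]][, seq_len(new_arity), drop = FALSE],
                 b = model$params$lin_b[[5L]][seq_len(new_arity)]),
    zero = list(w = matrix(0, fan_in, new_arity), b = rep(0, new_arity)),
    uniform = with_seed(derive_seed(seed, "swap_head"),
                        init_layer(fan_in, new_arity, fan_in * new_arity)))
  model$params$lin_w[[5L]] <- l$w
  model$params$lin_b[[5L]] <- l$b
  model$config$linear_widths[[5L]] <- new_arity
  model$config$head_arity <- new_arity
  model$provenance$head_swapped <- TRUE
  model
}
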