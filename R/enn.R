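#' Configuration for the evolution neural network
#'
#' The network has five fully connected layers (input, three hidden, output)
#' of sizes `m, h1, h2, h3, m`, sigmoid activation at every layer, and
#' dropout between layers during training.  Hidden sizes default to a
#' mirror-image bottleneck `h1 = h3 = max(16, ceiling(m/2))`,
#' `h2 = max(8, ceiling(m/8))`, chosen when the training adjacency is seen.
#'
#' @param hidden_sizes integer vector `(h1, h2, h3)` or `NULL` for the
#'   size-dependent default.
#' @param dropout_rate dropout probability applied to each hidden activation
#'   during training only; in \[0, 1).
#' @param learning_rate Adam step size.
#' @param max_epochs maximum number of training epochs.
#' @param batch_size rows per gradient step; `NULL` means full batch for
#'   `m <= 1000`, otherwise 256.
#' @param patience number of consecutive epochs with loss improvement below
#'   `loss_tolerance` after which training stops.
#' @param loss_tolerance minimal per-epoch loss improvement counted as
#'   progress.
#' @param seed integer seed controlling weight initialisation, dropout masks
#'   and batch shuffling.
#' @param input_mode `"zeros"` feeds every row the all-zero vector (the
#'   no-prior-knowledge reading, under which the trained network is a
#'   constant predictor and all output rows coincide); `"identity"` feeds
#'   row `i` the one-hot indicator of protein `i`, giving row-distinct
#'   outputs.
#' @return an `enn_config` list.
#' @export
enn_config <- function(hidden_sizes = NULL, dropout_rate = 0.2,
                       learning_rate = 1e-3, max_epochs = 500L,
                       batch_size = NULL, patience = 20L,
                       loss_tolerance = 1e-6, seed = 1L,
                       input_mode = c("zeros", "identity")) {
  input_mode <- match.arg(input_mode)
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (loss_tolerance <= 0) stop("loss_tolerance must be positive")
  if (!is.null(hidden_sizes)) {
    hidden_sizes <- as.integer(hidden_sizes)
    if (length(hidden_sizes) != 3L || any(hidden_sizes < 1L)) {
      stop("hidden_sizes must be three positive integers (h1, h2, h3)")
    }
    if (hidden_sizes[2L] > min(hidden_sizes[c(1L, 3L)])) {
      stop("bottleneck h2 must not exceed min(h1, h3)")
    }
  }
  structure(
    list(hidden_sizes = hidden_sizes, dropout_rate = dropout_rate,
         learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
         batch_size = if (is.null(batch_size)) NULL else as.integer(batch_size),
         patience = as.integer(patience), loss_tolerance = loss_tolerance,
         seed = as.integer(seed), input_mode = input_mode),
    class = "enn_config")
}

default_hidden_sizes <- function(m) {
  c(max(16L, as.integer(ceiling(m / 2))),
    max(8L, as.integer(ceiling(m / 8))),
    max(16L, as.integer(ceiling(m / 2))))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Binary cross-entropy training loss
#'
#' Mean over rows of the summed per-unit cross-entropy
#' \eqn{-[y \log p + (1-y)\log(1-p)]}.  Predictions are clamped to
#' `[eps, 1-eps]` so that saturated sigmoid outputs never produce `log(0)`.
#'
#' @param outputs real matrix of predictions in (0,1).
#' @param labels 0/1 matrix of the same shape.
#' @param eps clamping constant.
#' @return nonnegative scalar.
#' @export
enn_loss <- function(outputs, labels, eps = 1e-7) {
  if (!all(dim(outputs) == dim(labels))) stop("shape mismatch")
  p <- pmin(pmax(outputs, eps), 1 - eps)
  sum(-(labels * log(p) + (1 - labels) * log(1 - p))) / nrow(outputs)
}

# Glorot-uniform initial weights for layer sizes `sizes`
init_layers <- function(sizes) {
  lapply(seq_len(length(sizes) - 1L), function(l) {
    fan_in <- sizes[l]; fan_out <- sizes[l + 1L]
    r <- sqrt(6 / (fan_in + fan_out))
    list(W = matrix(stats::runif(fan_in * fan_out, -r, r), fan_in, fan_out),
         b = rep(0, fan_out))
  })
}

# forward pass; dropout masks applied to hidden activations when training
enn_forward <- function(X, layers, dropout_rate = 0, training = FALSE) {
  acts <- vector("list", length(layers) + 1L)
  acts[[1L]] <- X
  a <- X
  for (l in seq_along(layers)) {
    a <- sigmoid(sweep(a %*% layers[[l]]$W, 2L, layers[[l]]$b, `+`))
    if (training && dropout_rate > 0 && l < length(layers)) {
      mask <- matrix(stats::runif(length(a)) >= dropout_rate,
                     nrow(a), ncol(a)) / (1 - dropout_rate)
      a <- a * mask
    }
    acts[[l + 1L]] <- a
  }
  acts
}

#' Train the evolution neural network and emit the evolved matrix EA
#'
#' Each row of the training adjacency matrix is a training label; the
#' corresponding input is the all-zero vector (`input_mode = "zeros"`) or
#' the one-hot row indicator (`input_mode = "identity"`).  The loss is the
#' mean over rows of the summed per-unit binary cross-entropy, minimised by
#' Adam.  No layer-wise pretraining is used.  After training, row `i` of
#' the evolved matrix EA is the forward pass on input `i` with dropout
#' disabled; under the zeros mode all rows of EA are therefore identical
#' and converge towards the column means of the labels.
#'
#' @param trainingAdj symmetric binary adjacency matrix with zero diagonal
#'   (dimnames carry the node order).
#' @param config an [enn_config()].
#' @return object of class `evolved_matrix`: the `m x m` matrix EA with
#'   entries in (0,1), plus attributes `training_log` (data frame of
#'   epoch/loss), `epochs_run`, `final_loss`, `config`.
#' @export
train_enn <- function(trainingAdj, config = enn_config()) {
  A <- as.matrix(trainingAdj)
  m <- nrow(A)
  if (ncol(A) != m) stop("training adjacency must be square")
  if (max(abs(A - t(A))) > 0) stop("training adjacency must be symmetric")
  if (any(diag(A) != 0)) stop("training adjacency must have zero diagonal")
  if (!all(A %in% c(0, 1))) stop("training adjacency must be binary")

  hs <- config$hidden_sizes
  if (is.null(hs)) hs <- default_hidden_sizes(m)
  if (any(hs[c(1L, 3L)] >= m)) {
    warning("hidden layer at least as wide as the proteome (h >= m)")
  }
  sizes <- c(m, hs, m)
  bs <- config$batch_size
  if (is.null(bs)) bs <- if (m <= 1000L) m else 256L
  bs <- min(bs, m)

  X <- if (config$input_mode == "zeros") matrix(0, m, m) else diag(m)

  with_seed(config$seed, {
    layers <- init_layers(sizes)
    nlay <- length(layers)
    adam_m <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
    adam_v <- adam_m
    beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8; t_step <- 0L
    lr <- config$learning_rate

    log_epoch <- integer(config$max_epochs)
    log_loss <- numeric(config$max_epochs)
    best <- Inf; stalled <- 0L; epochs_run <- 0L

    for (epoch in seq_len(config$max_epochs)) {
      ord <- if (bs < m) sample.int(m) else seq_len(m)
      for (start in seq(1L, m, by = bs)) {
        rows <- ord[start:min(start + bs - 1L, m)]
        acts <- enn_forward(X[rows, , drop = FALSE], layers,
                            config$dropout_rate, training = TRUE)
        out <- acts[[nlay + 1L]]
        # d(loss)/d(logits) of sigmoid + cross-entropy, mean over rows
        delta <- (out - A[rows, , drop = FALSE]) / length(rows)
        for (l in rev(seq_len(nlay))) {
          gW <- crossprod(acts[[l]], delta)
          gb <- colSums(delta)
          if (l > 1L) {
            a_prev <- acts[[l]]
            delta <- (delta %*% t(layers[[l]]$W)) * a_prev * (1 - a_prev)
          }
          t_step <- t_step + 1L
          adam_m[[l]]$W <- beta1 * adam_m[[l]]$W + (1 - beta1) * gW
          adam_v[[l]]$W <- beta2 * adam_v[[l]]$W + (1 - beta2) * gW^2
          adam_m[[l]]$b <- beta1 * adam_m[[l]]$b + (1 - beta1) * gb
          adam_v[[l]]$b <- beta2 * adam_v[[l]]$b + (1 - beta2) * gb^2
          mh <- 1 - beta1^t_step; vh <- 1 - beta2^t_step
          layers[[l]]$W <- layers[[l]]$W -
            lr * (adam_m[[l]]$W / mh) / (sqrt(adam_v[[l]]$W / vh) + adam_eps)
          layers[[l]]$b <- layers[[l]]$b -
            lr * (adam_m[[l]]$b / mh) / (sqrt(adam_v[[l]]$b / vh) + adam_eps)
        }
      }
      ea_now <- enn_forward(X, layers)[[nlay + 1L]]
      loss <- enn_loss(ea_now, A)
      if (!is.finite(loss)) stop("non-finite training loss at epoch ", epoch)
      epochs_run <- epoch
      log_epoch[epoch] <- epoch; log_loss[epoch] <- loss
      if (best - loss < config$loss_tolerance) {
        stalled <- stalled + 1L
        if (stalled >= config$patience) break
      } else {
        stalled <- 0L
      }
      best <- min(best, loss)
    }

    EA <- enn_forward(X, layers)[[nlay + 1L]]
    dimnames(EA) <- dimnames(A)
    structure(EA,
              class = c("evolved_matrix", "matrix"),
              training_log = data.frame(epoch = log_epoch[seq_len(epochs_run)],
                                        loss = log_loss[seq_len(epochs_run)]),
              epochs_run = epochs_run,
              final_loss = log_loss[epochs_run],
              config = config)
  })
}

#' @export
print.evolved_matrix <- function(x, ...) {
  cat(sprintf("evolved matrix EA: %d x %d, %d epochs, final loss %.4f\n",
              nrow(x), ncol(x), attr(x, "epochs_run"), attr(x, "final_loss")))
  invisible(x)
}
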