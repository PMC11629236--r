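#' Imputer network configuration
#'
#' Hyper-parameters of the fully connected reaction imputer.  The
#' defaults are the tuned values used throughout: three hidden layers of
#' 256 rectified units with dropout 0.1, batch size 50, 10 epochs, Adam
#' with learning rate 0.005 (beta1 0.9, beta2 0.999, epsilon 1e-8) and
#' learning-rate decay 0.01 per step, and class-weight `b0 = 0.3` in the
#' masked binary cross-entropy loss (absent class weighted by `b0`,
#' present class by `1 - b0`, reflecting that far fewer reactions are
#' present than absent in a typical genome).
#'
#' @param io_size input/output width = pan-reactome size.
#' @param hidden_layers,hidden_nodes hidden topology.
#' @param dropout dropout fraction after each hidden layer (training only).
#' @param batch_size,epochs,learning_rate,beta1,beta2,epsilon,decay
#'   optimisation settings (Adam; `decay` is the per-step learning-rate
#'   decay `lr / (1 + decay * step)`).
#' @param b0 absent-class scaling factor in (0,1).
#' @return a `network_config` list.
#' @export
network_config <- function(io_size, hidden_layers = 3L, hidden_nodes = 256L,
                           dropout = 0.1, batch_size = 50L, epochs = 10L,
                           learning_rate = 0.005, beta1 = 0.9, beta2 = 0.999,
                           epsilon = 1e-8, decay = 0.01, b0 = 0.3) {
  stopifnot(io_size >= 1, hidden_layers >= 0, hidden_nodes >= 1,
            dropout >= 0, dropout < 1, b0 > 0, b0 < 1)
  structure(list(io_size = as.integer(io_size),
                 hidden_layers = as.integer(hidden_layers),
                 hidden_nodes = as.integer(hidden_nodes),
                 dropout = dropout, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 decay = decay, b0 = b0),
            class = "network_config")
}

#' Initialise an untrained imputer network
#'
#' Builds the dense feed-forward topology `io_size -> hidden_nodes x
#' hidden_layers -> io_size` with rectifier hidden activations and a
#' sigmoid output.  Weights use He initialisation, output layer Xavier.
#'
#' @param config a [network_config()].
#' @param seed integer seed for the initial weights.
#' @return an `imputer_network`: list of weight matrices `W` and bias
#'   vectors `b`, plus the config.
#' @export
build_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  dims <- c(config$io_size,
            rep(config$hidden_nodes, config$hidden_layers),
            config$io_size)
  rs <- local_rng(seed)
  on.exit(rs())
  L <- length(dims) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- dims[l]
    sd <- if (l < L) sqrt(2 / fan_in) else sqrt(1 / fan_in)
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1], sd = sd),
                     dims[l], dims[l + 1])
    b[[l]] <- numeric(dims[l + 1])
  }
  structure(list(W = W, b = b, config = config), class = "imputer_network")
}

#' Number of trainable parameters
#' @param network an `imputer_network` or `trained_imputer`.
#' @return integer parameter count (weights + biases).
#' @export
n_parameters <- function(network) {
  sum(vapply(network$W, length, 1L)) + sum(lengths(network$b))
}

CLIP <- 1e-7

#' Masked, class-weighted binary cross-entropy
#'
#' The training loss of the imputer.  For output scores `O`, truth `T`
#' and network input `I` (all vectors or conformable matrices over the
#' pan-reactome), the per-position loss is
#' \deqn{(1 - I) [ -(1 - b_0) T \log O - b_0 (1 - T) \log(1 - O) ]}
#' averaged over all positions.  The `(1 - I)` mask zeroes every position
#' that was given to the network as input, so the network is rewarded for
#' completing the reaction set, not for echoing its input.  Scores are
#' clipped to `[1e-7, 1 - 1e-7]` before the logarithms.
#'
#' @param O predicted scores in \[0,1\].
#' @param truth binary truth vector `T`.
#' @param input binary input vector `I` (must satisfy `I <= T`).
#' @param b0 absent-class scaling factor.
#' @return mean masked loss (non-negative scalar).
#' @examples
#' masked_loss(0.5, 1, 0, b0 = 0.3)  # 0.7 * -log(0.5)
#' @export
masked_loss <- function(O, truth, input, b0 = 0.3) {
  if (length(O) != length(truth) || length(O) != length(input))
    stop("O, truth and input must have the same length")
  if (any(input > truth)) stop("input must satisfy I <= T element-wise")
  O <- pmin(pmax(O, CLIP), 1 - CLIP)
  mean((1 - input) *
         (-(1 - b0) * truth * log(O) - b0 * (1 - truth) * log(1 - O)))
}

# forward pass; returns activations for backprop when training = TRUE
nn_forward <- function(net, X, training = FALSE, dropout_masks = NULL) {
  cfg <- net$config
  L <- length(net$W)
  A <- list(X)
  for (l in seq_len(L - 1)) {
    Z <- sweep(A[[l]] %*% net$W[[l]], 2, net$b[[l]], `+`)
    H <- pmax(Z, 0)
    if (training && cfg$dropout > 0) {
      H <- H * dropout_masks[[l]]
    }
    A[[l + 1]] <- H
  }
  logits <- sweep(A[[L]] %*% net$W[[L]], 2, net$b[[L]], `+`)
  O <- 1 / (1 + exp(-logits))
  list(A = A, O = O)
}

#' Train the imputer network
#'
#' Mini-batch Adam on the masked loss.  Sample order is reshuffled every
#' epoch from the given seed, dropout masks are redrawn per batch, and
#' the loss on a fixed validation batch is recorded per epoch in
#' `$history`.  With `epochs = 0` the initial network is returned
#' unmodified (wrapped as a `trained_imputer`).
#'
#' @param samples list of `corrupted_sample` objects (see [corrupt()]).
#' @param config a [network_config()]; `io_size` must match the samples.
#' @param seed integer seed governing initialisation, shuffling, dropout.
#' @param pan optional `pan_reactome` to freeze as the coordinate system.
#' @param network optional pre-built [build_network()] result to start from.
#' @param quiet suppress per-epoch progress messages.
#' @return a `trained_imputer`: weights, config, `pan` (reaction ids or
#'   NULL), `history` (validation loss per epoch, index 1 = before any
#'   update), `fingerprint` (seed + data hash).
#' @export
train_imputer <- function(samples, config, seed = 1L, pan = NULL,
                          network = NULL, quiet = TRUE) {
  stopifnot(inherits(config, "network_config"), length(samples) >= 1)
  X <- do.call(rbind, lapply(samples, `[[`, "input"))
  Y <- do.call(rbind, lapply(samples, `[[`, "truth"))
  storage.mode(X) <- "double"; storage.mode(Y) <- "double"
  if (ncol(X) != config$io_size)
    stop("sample width ", ncol(X), " does not match io_size ", config$io_size)
  net <- if (is.null(network)) build_network(config, seed = seed) else network
  cfg <- config
  L <- length(net$W)
  n <- nrow(X)
  val <- seq_len(min(200L, n))  # fixed validation batch
  val_loss <- function() {
    fw <- nn_forward(net, X[val, , drop = FALSE])
    masked_loss(fw$O, Y[val, , drop = FALSE], X[val, , drop = FALSE], cfg$b0)
  }
  history <- val_loss()
  if (cfg$epochs > 0) {
    rs <- local_rng(seed + 1L)
    on.exit(rs())
    mW <- lapply(net$W, function(w) w * 0); vW <- mW
    mb <- lapply(net$b, function(x) x * 0); vb <- mb
    step <- 0
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1, n)]
        Xb <- X[idx, , drop = FALSE]; Yb <- Y[idx, , drop = FALSE]
        masks <- NULL
        if (cfg$dropout > 0 && L > 1) {
          masks <- lapply(seq_len(L - 1), function(l)
            matrix(stats::rbinom(length(idx) * cfg$hidden_nodes, 1,
                                 1 - cfg$dropout) / (1 - cfg$dropout),
                   length(idx), cfg$hidden_nodes))
        }
        fw <- nn_forward(net, Xb, training = TRUE, dropout_masks = masks)
        O <- fw$O
        # d(masked loss)/d(logits); the clip only guards the logs, the
        # gradient uses the standard stable product form
        N <- length(O)
        dZ <- (1 - Xb) * (-(1 - cfg$b0) * Yb * (1 - O) +
                            cfg$b0 * (1 - Yb) * O) / N
        if (any(!is.finite(dZ))) stop("NaN/Inf encountered in training gradient")
        step <- step + 1
        lr <- cfg$learning_rate / (1 + cfg$decay * step)
        gW <- vector("list", L); gb <- vector("list", L)
        delta <- dZ
        for (l in rev(seq_len(L))) {
          gW[[l]] <- crossprod(fw$A[[l]], delta)
          gb[[l]] <- colSums(delta)
          if (l > 1) {
            delta <- delta %*% t(net$W[[l]])
            if (!is.null(masks)) delta <- delta * masks[[l - 1]]
            delta <- delta * (fw$A[[l]] > 0)
          }
        }
        for (l in seq_len(L)) {
          mW[[l]] <- cfg$beta1 * mW[[l]] + (1 - cfg$beta1) * gW[[l]]
          vW[[l]] <- cfg$beta2 * vW[[l]] + (1 - cfg$beta2) * gW[[l]]^2
          mb[[l]] <- cfg$beta1 * mb[[l]] + (1 - cfg$beta1) * gb[[l]]
          vb[[l]] <- cfg$beta2 * vb[[l]] + (1 - cfg$beta2) * gb[[l]]^2
          mhat <- 1 - cfg$beta1^step; vhat <- 1 - cfg$beta2^step
          net$W[[l]] <- net$W[[l]] -
            lr * (mW[[l]] / mhat) / (sqrt(vW[[l]] / vhat) + cfg$epsilon)
          net$b[[l]] <- net$b[[l]] -
            lr * (mb[[l]] / mhat) / (sqrt(vb[[l]] / vhat) + cfg$epsilon)
        }
      }
      history <- c(history, val_loss())
      if (!is.finite(history[length(history)]))
        stop("validation loss became non-finite at epoch ", epoch)
      if (!quiet) message(sprintf("epoch %d/%d  val loss %.5f",
                                  epoch, cfg$epochs, history[length(history)]))
    }
  }
  pan_ids <- if (inherits(pan, "pan_reactome")) pan$reactions else pan
  structure(list(W = net$W, b = net$b, config = cfg, pan = pan_ids,
                 history = history,
                 fingerprint = list(seed = seed, n_samples = n,
                                    data_hash = sum(X) + 2 * sum(Y))),
            class = c("trained_imputer", "imputer_network"))
}

#' Score reaction presence with a trained imputer
#'
#' @param object a `trained_imputer`.
#' @param newdata binary input vector, or matrix with one genome per row.
#' @param ... unused.
#' @return score vector (or matrix) in \[0,1\] over the pan-reactome;
#'   dropout is disabled, so repeated calls are identical.
#' @export
predict.trained_imputer <- function(object, newdata, ...) {
  one <- is.null(dim(newdata))
  X <- if (one) matrix(as.numeric(newdata), 1) else {
    newdata <- as.matrix(newdata); storage.mode(newdata) <- "double"; newdata
  }
  if (ncol(X) != object$config$io_size)
    stop("input width ", ncol(X), " does not match io_size ",
         object$config$io_size)
  O <- nn_forward(object, X)$O
  if (!is.null(object$pan)) colnames(O) <- object$pan
  if (one) O[1, ] else O
}

#' @export
print.trained_imputer <- function(x, ...) {
  cat(sprintf("<trained_imputer> %d-%s-%d, %d parameters, final val loss %.5f\n",
              x$config$io_size,
              paste(rep(x$config$hidden_nodes, x$config$hidden_layers),
                    collapse = "-"),
              x$config$io_size, n_parameters(x),
              x$history[length(x$history)]))
  invisible(x)
}

#' Save / load a trained imputer
#'
#' Serialised as a single JSON archive (config + full-precision weights),
#' so trained networks survive as plain text.
#'
#' @param object a `trained_imputer`.
#' @param path archive path.
#' @return `path` invisibly (save); a `trained_imputer` (load).
#' @export
save_imputer <- function(object, path) {
  stopifnot(inherits(object, "trained_imputer"))
  payload <- list(config = unclass(object$config),
                  W = lapply(object$W, function(w)
                    list(dim = dim(w), data = as.numeric(w))),
                  b = object$b, pan = object$pan, history = object$history,
                  fingerprint = object$fingerprint)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_imputer
#' @export
load_imputer <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(network_config, p$config)
  W <- lapply(p$W$dim, function(d) NULL)
  W <- lapply(seq_along(p$W$dim), function(i)
    matrix(p$W$data[[i]], p$W$dim[[i]][1], p$W$dim[[i]][2]))
  structure(list(W = W, b = lapply(p$b, as.numeric), config = cfg,
                 pan = p$pan, history = as.numeric(p$history),
                 fingerprint = p$fingerprint),
            class = c("trained_imputer", "imputer_network"))
}
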