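#' Define the fixed multilayer perceptron architecture
#'
#' The simulator trains one fixed feed-forward network on every client: binary
#' drug-exposure features in, a single sigmoid mortality probability out, with
#' rectified-linear hidden layers and biases on every layer. The default
#' (2814 input units, hidden layers of 20, 10 and 5) has 56,571 trainable
#' parameters.
#'
#' @param input_dim number of input features.
#' @param hidden integer vector of hidden-layer widths.
#' @return an object of class `network_spec`.
#' @examples
#' count_parameters(network_spec())            # 56571
#' count_parameters(network_spec(1, integer())) # a single logistic unit: 2
#' @export
network_spec <- function(input_dim = 2814L, hidden = c(20L, 10L, 5L)) {
  stop_if_not_count(input_dim, "input_dim")
  hidden <- as.integer(hidden)
  if (any(hidden < 1L)) stop("hidden layer widths must be >= 1", call. = FALSE)
  structure(
    list(
      input_dim = as.integer(input_dim),
      hidden = hidden,
      layer_sizes = c(as.integer(input_dim), hidden, 1L)
    ),
    class = "network_spec"
  )
}

#' Count trainable parameters of a network
#'
#' Closed-form sum over layers of `fan_in * fan_out + fan_out` (weights plus
#' biases).
#'
#' @param spec a [network_spec()].
#' @return integer parameter count.
#' @export
count_parameters <- function(spec) {
  sizes <- spec$layer_sizes
  fan_in <- sizes[-length(sizes)]
  fan_out <- sizes[-1]
  sum(fan_in * fan_out + fan_out)
}

#' Initialize network weights
#'
#' Glorot-style uniform initialization: each weight matrix is drawn from
#' `U(-limit, limit)` with `limit = sqrt(6 / (fan_in + fan_out))`; biases start
#' at zero. With a fixed seed the result is bit-identical across calls, which
#' is what lets every client start a federated run from the same `w_0`.
#'
#' @param spec a [network_spec()].
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return an object of class `fed_weights`: a list of layers, each with a
#'   weight matrix `W` (`fan_in x fan_out`) and bias vector `b`.
#' @export
init_weights <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- spec$layer_sizes
  layers <- vector("list", length(sizes) - 1L)
  for (l in seq_along(layers)) {
    fi <- sizes[l]
    fo <- sizes[l + 1L]
    limit <- sqrt(6 / (fi + fo))
    layers[[l]] <- list(
      W = matrix(stats::runif(fi * fo, -limit, limit), fi, fo),
      b = numeric(fo)
    )
  }
  structure(layers, class = "fed_weights", spec = spec)
}

#' Flatten weights to a single numeric vector
#'
#' Canonical ordering: layers first to last; within a layer the weight matrix
#' in column-major order, then the bias vector. The shape manifest returned by
#' [weight_manifest()] makes the flattening lossless.
#'
#' @param weights a `fed_weights` object.
#' @return numeric vector of length [count_parameters()].
#' @export
flatten_weights <- function(weights) {
  unlist(lapply(weights, function(l) c(as.numeric(l$W), l$b)), use.names = FALSE)
}

#' Shape manifest of a weight object
#'
#' @param weights a `fed_weights` object.
#' @return list of `c(fan_in, fan_out)` pairs, one per layer.
#' @export
weight_manifest <- function(weights) {
  lapply(weights, function(l) dim(l$W))
}

#' Rebuild structured weights from a flat vector and manifest
#'
#' @param flat numeric vector from [flatten_weights()].
#' @param manifest list from [weight_manifest()].
#' @return a `fed_weights` object.
#' @export
unflatten_weights <- function(flat, manifest) {
  layers <- vector("list", length(manifest))
  pos <- 0L
  for (l in seq_along(manifest)) {
    fi <- manifest[[l]][1]
    fo <- manifest[[l]][2]
    W <- matrix(flat[pos + seq_len(fi * fo)], fi, fo)
    pos <- pos + fi * fo
    b <- flat[pos + seq_len(fo)]
    pos <- pos + fo
    layers[[l]] <- list(W = W, b = b)
  }
  if (pos != length(flat)) {
    stop("flat vector length does not match the shape manifest", call. = FALSE)
  }
  structure(layers, class = "fed_weights")
}

#' Elementwise average of client weight vectors
#'
#' The server-side aggregation step: an unweighted arithmetic mean of the
#' participating clients' weights (all configurations here use equal-sized
#' shards, so an example-weighted mean would coincide).
#'
#' @param updates non-empty list of congruent `fed_weights` objects.
#' @return a `fed_weights` object of the same shape.
#' @export
average_weights <- function(updates) {
  if (length(updates) == 0L) stop("cannot average an empty list of weights", call. = FALSE)
  ref <- weight_manifest(updates[[1]])
  for (u in updates[-1]) {
    if (!identical(weight_manifest(u), ref)) {
      stop("weight shapes are not congruent", call. = FALSE)
    }
  }
  out <- updates[[1]]
  n <- length(updates)
  for (l in seq_along(out)) {
    W <- out[[l]]$W
    b <- out[[l]]$b
    if (n > 1L) {
      for (u in updates[-1]) {
        W <- W + u[[l]]$W
        b <- b + u[[l]]$b
      }
    }
    out[[l]]$W <- W / n
    out[[l]]$b <- b / n
  }
  out
}

#' Binary cross-entropy loss
#'
#' Mean over examples of `-[y log f + (1 - y) log(1 - f)]`, with predictions
#' clipped to `[eps, 1 - eps]` so the loss stays finite. `reduction = "sum"`
#' restores the unnormalized sum over examples; the mean is the default so
#' that client losses are comparable across shard sizes (the two orderings
#' coincide when shards are equal-sized).
#'
#' @param predictions probability vector.
#' @param labels binary vector of the same length.
#' @param reduction `"mean"` (default) or `"sum"`.
#' @param eps clipping constant, default `1e-7`.
#' @return nonnegative scalar loss.
#' @export
binary_cross_entropy <- function(predictions, labels,
                                 reduction = c("mean", "sum"), eps = 1e-7) {
  reduction <- match.arg(reduction)
  if (length(predictions) != length(labels)) {
    stop("predictions and labels must have equal length", call. = FALSE)
  }
  p <- pmin(pmax(predictions, eps), 1 - eps)
  ll <- -(labels * log(p) + (1 - labels) * log(1 - p))
  if (reduction == "mean") mean(ll) else sum(ll)
}

#' Local training configuration
#'
#' Adam hyperparameters follow the Keras defaults used throughout: learning
#' rate `eta = 0.001`, decay rates `beta1 = 0.9`, `beta2 = 0.999`; minibatch
#' size `B = 30`.
#'
#' @param E local epochs per round.
#' @param B minibatch size.
#' @param learning_rate Adam step size.
#' @param beta1,beta2 Adam moment decay rates.
#' @param loss_reduction `"mean"` or `"sum"` for the reported loss.
#' @param seed optional seed controlling minibatch shuffling; when `NULL` the
#'   current RNG stream is used.
#' @return an object of class `train_config`.
#' @export
train_config <- function(E = 5L, B = 30L, learning_rate = 0.001,
                         beta1 = 0.9, beta2 = 0.999,
                         loss_reduction = "mean", seed = NULL) {
  stop_if_not_count(E, "E")
  stop_if_not_count(B, "B")
  structure(
    list(
      E = as.integer(E), B = as.integer(B),
      learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
      loss_reduction = loss_reduction, seed = seed
    ),
    class = "train_config"
  )
}

# Forward pass; optionally keep pre-activations/activations for backprop.
mlp_forward <- function(weights, X, keep = FALSE) {
  L <- length(weights)
  A <- X
  Zs <- if (keep) vector("list", L) else NULL
  As <- if (keep) vector("list", L + 1L) else NULL
  if (keep) As[[1]] <- X
  for (l in seq_len(L)) {
    Z <- A %*% weights[[l]]$W
    Z <- sweep(Z, 2, weights[[l]]$b, `+`)
    A <- if (l < L) relu(Z) else sigmoid(Z)
    if (keep) {
      Zs[[l]] <- Z
      As[[l + 1L]] <- A
    }
  }
  if (keep) list(prob = as.numeric(A), Z = Zs, A = As) else as.numeric(A)
}

#' Predict mortality probabilities with a weight vector
#'
#' Forward pass of the fixed MLP: sigmoid outputs strictly inside `(0, 1)`.
#'
#' @param weights a `fed_weights` object.
#' @param features numeric/binary matrix with one row per example; column
#'   count must equal the network's input dimension.
#' @return probability vector of length `nrow(features)`.
#' @export
fed_predict <- function(weights, features) {
  features <- as.matrix(features)
  if (ncol(features) != nrow(weights[[1]]$W)) {
    stop(sprintf(
      "feature width %d does not match network input dimension %d",
      ncol(features), nrow(weights[[1]]$W)
    ), call. = FALSE)
  }
  mlp_forward(weights, features)
}

# Gradients of the mean binary cross-entropy wrt all weights, one minibatch.
mlp_gradients <- function(weights, X, y) {
  L <- length(weights)
  fwd <- mlp_forward(weights, X, keep = TRUE)
  n <- nrow(X)
  # sigmoid + mean BCE: dL/dZ_L = (p - y) / n
  dZ <- matrix(fwd$prob - y, ncol = 1L) / n
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(
      W = crossprod(fwd$A[[l]], dZ),
      b = colSums(dZ)
    )
    if (l > 1L) {
      dA <- dZ %*% t(weights[[l]]$W)
      dZ <- dA * (fwd$Z[[l - 1L]] > 0)
    }
  }
  grads
}

#' Train a client model locally with minibatch Adam
#'
#' Initializes the network from the supplied weights, runs exactly `epochs`
#' full passes over the shard in shuffled minibatches of size `B` (the last
#' batch of an epoch may be smaller), and returns the final weights together
#' with the cross-entropy loss evaluated on the full shard after training.
#' `epochs = 0` performs no updates and just evaluates the loss. The Adam
#' state (first/second moments) is created fresh at each call.
#'
#' @param weights starting `fed_weights`.
#' @param shard a `client_shard` or any list with `features` and `labels`.
#' @param epochs number of passes over the shard (`>= 0`).
#' @param config a [train_config()]; its `seed`, when non-`NULL`, fixes the
#'   minibatch shuffling so two identical calls return identical weights.
#' @return list with `weights` (trained `fed_weights`), `loss` (training-set
#'   cross-entropy after training) and `epochs`.
#' @export
train_local <- function(weights, shard, epochs, config = train_config()) {
  if (is.null(shard$features) || nrow(shard$features) == 0L) {
    stop("cannot train on an empty shard", call. = FALSE)
  }
  if (epochs < 0L) stop("epochs must be >= 0", call. = FALSE)
  X <- as.matrix(shard$features)
  storage.mode(X) <- "double"
  y <- as.numeric(shard$labels)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- nrow(X)
  B <- config$B
  lr <- config$learning_rate
  b1 <- config$beta1
  b2 <- config$beta2
  adam_eps <- 1e-7
  if (epochs > 0L) {
    m <- lapply(weights, function(l) list(W = l$W * 0, b = l$b * 0))
    v <- m
    step <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = B)
      for (s in starts) {
        idx <- ord[s:min(s + B - 1L, n)]
        g <- mlp_gradients(weights, X[idx, , drop = FALSE], y[idx])
        step <- step + 1L
        bc1 <- 1 - b1^step
        bc2 <- 1 - b2^step
        for (l in seq_along(weights)) {
          m[[l]]$W <- b1 * m[[l]]$W + (1 - b1) * g[[l]]$W
          m[[l]]$b <- b1 * m[[l]]$b + (1 - b1) * g[[l]]$b
          v[[l]]$W <- b2 * v[[l]]$W + (1 - b2) * g[[l]]$W^2
          v[[l]]$b <- b2 * v[[l]]$b + (1 - b2) * g[[l]]$b^2
          weights[[l]]$W <- weights[[l]]$W -
            lr * (m[[l]]$W / bc1) / (sqrt(v[[l]]$W / bc2) + adam_eps)
          weights[[l]]$b <- weights[[l]]$b -
            lr * (m[[l]]$b / bc1) / (sqrt(v[[l]]$b / bc2) + adam_eps)
        }
      }
    }
  }
  loss <- binary_cross_entropy(mlp_forward(weights, X), y,
    reduction = config$loss_reduction
  )
  list(weights = weights, loss = loss, epochs = as.integer(epochs))
}
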