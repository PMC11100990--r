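# Minimal dense network machinery shared by the utility-prediction networks.
# Hidden layers use ReLU; the output layer is linear. Training minimizes mean
# squared error with the Adam optimizer, full batch. Written in plain matrix
# algebra so that runs are bit-reproducible given the RNG state at init time.

#' Utility-prediction network specification
#'
#' Architecture and training settings for the network that maps
#' generative-model representations to predicted utilities. Presets mirror
#' the architectures used with the visual tasks (two fully connected layers
#' of 64 units) and the phishing task (input 1536 -> 128 -> 128 -> 1).
#'
#' @param input_dim Number of input features.
#' @param hidden Integer vector of hidden-layer widths.
#' @param epochs Training epochs per (re)fit.
#' @param lr Adam learning rate.
#' @param seed Integer seed for weight initialization.
#' @param refit_every Trials between refits of an online agent's network.
#' @return A `utility_net_spec` list.
#' @export
utility_net_spec <- function(input_dim, hidden = c(64, 64), epochs = 100,
                             lr = 1e-2, seed = 1L, refit_every = 1L) {
  if (input_dim < 1 || any(hidden < 1)) stop("widths must be positive")
  structure(list(input_dim = as.integer(input_dim),
                 hidden = as.integer(hidden), epochs = as.integer(epochs),
                 lr = lr, seed = as.integer(seed),
                 refit_every = as.integer(refit_every)),
            class = "utility_net_spec")
}

#' Initialize a dense network
#'
#' He-style initialization for hidden layers; the output layer starts at zero
#' so an untrained network predicts 0 for every input.
#'
#' @param spec A `utility_net_spec`.
#' @return An `mlp` object (list of weight matrices and biases).
#' @export
mlp_init <- function(spec) {
  set.seed(spec$seed)
  dims <- c(spec$input_dim, spec$hidden, 1L)
  n_layers <- length(dims) - 1L
  W <- vector("list", n_layers)
  b <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    if (l < n_layers) {
      W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1L],
                                    sd = sqrt(2 / dims[l])),
                       dims[l], dims[l + 1L])
    } else {
      W[[l]] <- matrix(0, dims[l], dims[l + 1L])
    }
    b[[l]] <- rep(0, dims[l + 1L])
  }
  structure(list(W = W, b = b, spec = spec, adam = NULL), class = "mlp")
}

#' Predict with a dense network
#'
#' @param net An `mlp`.
#' @param X Numeric matrix (rows = samples) or vector (one sample).
#' @return Numeric vector of predictions.
#' @export
mlp_predict <- function(net, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != net$spec$input_dim) stop("input dimension mismatch")
  h <- X
  n_layers <- length(net$W)
  for (l in seq_len(n_layers)) {
    h <- sweep(h %*% net$W[[l]], 2L, net$b[[l]], `+`)
    if (l < n_layers) h <- pmax(h, 0)
  }
  as.numeric(h)
}

# Forward pass keeping pre/post activations for backprop.
mlp_forward <- function(net, X) {
  n_layers <- length(net$W)
  acts <- vector("list", n_layers + 1L)
  acts[[1L]] <- X
  for (l in seq_len(n_layers)) {
    z <- sweep(acts[[l]] %*% net$W[[l]], 2L, net$b[[l]], `+`)
    acts[[l + 1L]] <- if (l < n_layers) pmax(z, 0) else z
  }
  acts
}

adam_state <- function(net) {
  list(mW = lapply(net$W, function(w) w * 0),
       vW = lapply(net$W, function(w) w * 0),
       mb = lapply(net$b, function(bb) bb * 0),
       vb = lapply(net$b, function(bb) bb * 0),
       t = 0L)
}

adam_update <- function(x, g, m, v, t, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g * g
  mhat <- m / (1 - beta1^t)
  vhat <- v / (1 - beta2^t)
  list(x = x - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

#' Train a dense network on (input, target) pairs
#'
#' Full-batch gradient descent on mean squared error with Adam. Training is
#' warm-started from the network's current weights, so repeated calls continue
#' optimization (the refit behavior online agents rely on). `epochs = 0`
#' returns the network unchanged with its current MSE reported.
#'
#' @param net An `mlp`.
#' @param X Input matrix (rows = samples).
#' @param y Numeric target vector, finite.
#' @param epochs Number of epochs (defaults to the spec's value).
#' @param lr Learning rate (defaults to the spec's value).
#' @param tol Relative MSE improvement below which training stops early
#'   (epoch budget is an upper bound); set 0 to always run `epochs` epochs.
#' @return The trained `mlp`, with a numeric `loss` field holding the MSE
#'   trace (initial MSE first, then one entry per epoch run).
#' @export
mlp_train <- function(net, X, y, epochs = net$spec$epochs, lr = net$spec$lr,
                      tol = 1e-5) {
  if (is.null(dim(X))) X <- matrix(X, nrow = length(y))
  if (ncol(X) != net$spec$input_dim) stop("input dimension mismatch")
  if (nrow(X) != length(y)) stop("X rows must match length(y)")
  if (any(!is.finite(y))) stop("targets must be finite")
  mse <- function() mean((mlp_predict(net, X) - y)^2)
  if (epochs == 0L) {
    net$loss <- mse()
    return(net)
  }
  res <- .mlp_train_core(net$W, net$b,
                         if (is.null(net$adam)) list() else net$adam,
                         X, y, as.integer(epochs), lr, tol)
  net$W <- lapply(res$W, identity)
  net$b <- lapply(res$b, as.numeric)
  net$adam <- res$adam
  # trace entries are pre-update MSEs per epoch (first = initial MSE);
  # append the post-update MSE so the last entry reflects current weights
  net$loss <- c(as.numeric(res$trace), mse())
  net
}
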