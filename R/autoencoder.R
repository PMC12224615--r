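# Stacked autoencoder: layer-wise pretraining, end-to-end fine-tuning, and the
# backpropagation machinery the clustering phase reuses to push assignment-loss
# gradients through the encoder. Dense matrices + BLAS; minibatch SGD with
# optional momentum. Activations follow the architecture used throughout the
# package: ReLU on interior encoder layers, tanh on the bottleneck and on every
# decoder layer (so bottleneck features live in (-1, 1)^d).

apply_act <- function(z, act) {
  switch(act,
         relu = pmax(z, 0),
         tanh = tanh(z),
         linear = z,
         stop("unknown activation: ", act))
}

# derivative wrt pre-activation, expressed through the activation output
act_deriv <- function(a, act) {
  switch(act,
         relu = (a > 0) * 1,
         tanh = 1 - a^2,
         linear = array(1, dim(a)),
         stop("unknown activation: ", act))
}

init_layer <- function(n_in, n_out) {
  # conservative fan-in-scaled uniform (variance 1/(3 fan_in)): keeps the
  # encoder near its linear regime at the start of training
  lim <- sqrt(1 / n_in)
  list(W = matrix(runif(n_in * n_out, -lim, lim), n_in, n_out),
       b = numeric(n_out))
}

zero_like <- function(layers)
  lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))

# forward through a stack; returns activations a[[0..L]] (a[[1]] = input)
stack_forward <- function(layers, acts, x) {
  a <- vector("list", length(layers) + 1)
  a[[1]] <- x
  for (l in seq_along(layers)) {
    z <- a[[l]] %*% layers[[l]]$W
    z <- sweep(z, 2, layers[[l]]$b, "+")
    a[[l + 1]] <- apply_act(z, acts[l])
  }
  a
}

# backprop given d(loss)/d(output activation); returns per-layer grads + dInput
stack_backward <- function(layers, acts, a, d_out) {
  L <- length(layers)
  grads <- vector("list", L)
  delta <- d_out
  for (l in rev(seq_len(L))) {
    delta <- delta * act_deriv(a[[l + 1]], acts[l])
    grads[[l]] <- list(W = crossprod(a[[l]], delta),
                       b = colSums(delta))
    delta <- delta %*% t(layers[[l]]$W)
  }
  list(grads = grads, d_input = delta)
}

sgd_step <- function(layers, grads, vel, lr, momentum) {
  for (l in seq_along(layers)) {
    vel[[l]]$W <- momentum * vel[[l]]$W - lr * grads[[l]]$W
    vel[[l]]$b <- momentum * vel[[l]]$b - lr * grads[[l]]$b
    layers[[l]]$W <- layers[[l]]$W + vel[[l]]$W
    layers[[l]]$b <- layers[[l]]$b + vel[[l]]$b
  }
  list(layers = layers, vel = vel)
}

# minibatch SGD on mean-squared reconstruction for an arbitrary stack
train_reconstruction <- function(layers, acts, x, target, epochs, lr, momentum,
                                 minibatch) {
  n <- nrow(x)
  vel <- zero_like(layers)
  trace <- numeric(epochs)
  if (epochs == 0) return(list(layers = layers, trace = trace))
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = minibatch)
    ep_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + minibatch - 1, n)]
      xb <- x[idx, , drop = FALSE]
      tb <- target[idx, , drop = FALSE]
      a <- stack_forward(layers, acts, xb)
      out <- a[[length(a)]]
      resid <- out - tb
      ep_loss <- ep_loss + sum(resid^2)
      d_out <- 2 * resid / length(resid)
      bw <- stack_backward(layers, acts, a, d_out)
      upd <- sgd_step(layers, bw$grads, vel, lr, momentum)
      layers <- upd$layers
      vel <- upd$vel
    }
    trace[ep] <- ep_loss / (n * ncol(target))
    if (!is.finite(trace[ep]))
      stop("reconstruction loss diverged (NaN/Inf); try a smaller learning_rate")
  }
  list(layers = layers, trace = trace)
}

encoder_acts <- function(n_layers) {
  # interior layers ReLU, bottleneck tanh
  if (n_layers == 1) "tanh" else c(rep("relu", n_layers - 1), "tanh")
}

decoder_acts <- function(n_layers) rep("tanh", n_layers)

#' Greedy layer-wise pretraining of a stacked autoencoder
#'
#' Trains each encoder/decoder layer pair in turn to reconstruct the output of
#' the preceding layer under mean-squared error, then assembles the full stack
#' from the greedily trained weights. The assembled encoder applies ReLU on
#' interior layers and tanh on the bottleneck; the mirrored decoder applies
#' tanh throughout.
#'
#' @param x Cells x features numeric matrix (standardized HVG expression).
#' @param dims Integer vector of layer widths including the input width, e.g.
#'   `c(500, 64, 32)`. Defaults to the input width followed by
#'   `config$encoder_dims` (or the size-based default).
#' @param config A [gdesce_config].
#' @return An object of class `encoder_model` with elements `layer_dims`,
#'   `enc`, `dec` (lists of `W`/`b`), `enc_acts`, `dec_acts`, and
#'   `pretrain_trace` (per-stage, per-epoch mean reconstruction MSE).
#' @export
pretrain_layerwise <- function(x, dims = NULL, config = gdesce_config()) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("input contains non-finite values")
  if (nrow(x) < 2) stop("need at least 2 cells to pretrain")
  if (is.null(dims)) {
    hidden <- config$encoder_dims
    if (is.null(hidden)) hidden <- if (nrow(x) >= 1000) c(64L, 32L) else c(32L, 16L)
    dims <- c(ncol(x), hidden)
  }
  dims <- as.integer(dims)
  stopifnot(length(dims) >= 2, dims[1] == ncol(x))
  L <- length(dims) - 1
  e_acts <- encoder_acts(L)
  d_acts <- decoder_acts(L)

  set.seed(derive_seed(config$seed, "pretrain"))
  enc <- vector("list", L)
  dec <- vector("list", L)  # dec[[l]] maps dims[l+1] -> dims[l]
  traces <- vector("list", L)
  h <- x
  for (l in seq_len(L)) {
    pair <- list(init_layer(dims[l], dims[l + 1]),
                 init_layer(dims[l + 1], dims[l]))
    fit <- train_reconstruction(pair, c(e_acts[l], "tanh"), h, h,
                                epochs = config$pretrain_epochs,
                                lr = config$learning_rate,
                                momentum = config$momentum,
                                minibatch = config$minibatch_size)
    enc[[l]] <- fit$layers[[1]]
    dec[[l]] <- fit$layers[[2]]
    traces[[l]] <- fit$trace
    h <- apply_act(sweep(h %*% enc[[l]]$W, 2, enc[[l]]$b, "+"), e_acts[l])
  }
  structure(list(layer_dims = dims, enc = enc, dec = rev(dec),
                 enc_acts = e_acts, dec_acts = d_acts,
                 pretrain_trace = traces, finetune_trace = numeric(0)),
            class = "encoder_model")
}

#' @export
print.encoder_model <- function(x, ...) {
  cat("<encoder_model> dims:", paste(x$layer_dims, collapse = " -> "), "\n")
  invisible(x)
}

#' End-to-end fine-tuning of a pretrained autoencoder
#'
#' Trains the assembled encoder/decoder stack to minimize mean-squared
#' reconstruction of the input. Zero epochs return the model unchanged.
#'
#' @param model An `encoder_model` from [pretrain_layerwise()].
#' @param x The matrix the model was pretrained on.
#' @param config A [gdesce_config].
#' @return The fine-tuned `encoder_model`, with `finetune_trace` recording the
#'   per-epoch mean reconstruction MSE.
#' @export
finetune <- function(model, x, config = gdesce_config()) {
  stopifnot(inherits(model, "encoder_model"))
  x <- as.matrix(x)
  if (config$finetune_epochs == 0) return(model)
  L <- length(model$enc)
  layers <- c(model$enc, model$dec)
  acts <- c(model$enc_acts, model$dec_acts)
  set.seed(derive_seed(config$seed, "finetune"))
  fit <- train_reconstruction(layers, acts, x, x,
                              epochs = config$finetune_epochs,
                              lr = config$learning_rate,
                              momentum = config$momentum,
                              minibatch = config$minibatch_size)
  model$enc <- fit$layers[seq_len(L)]
  model$dec <- fit$layers[L + seq_len(L)]
  model$finetune_trace <- fit$trace
  model
}

#' Encode cells into the bottleneck feature space
#'
#' Deterministic forward pass through the encoder half of the model.
#'
#' @param model An `encoder_model`.
#' @param x Matrix with as many columns as the model's input width.
#' @return n x d feature matrix (d = bottleneck width); entries lie in
#'   (-1, 1) because the bottleneck activation is tanh.
#' @export
encode <- function(model, x) {
  stopifnot(inherits(model, "encoder_model"))
  x <- as.matrix(x)
  if (ncol(x) != model$layer_dims[1])
    stop("input has ", ncol(x), " columns; model expects ", model$layer_dims[1])
  a <- stack_forward(model$enc, model$enc_acts, x)
  a[[length(a)]]
}

#' Reconstruct input through the full autoencoder
#'
#' @param model An `encoder_model`.
#' @param x Matrix with as many columns as the model's input width.
#' @return Reconstruction of `x` (entries in (-1, 1): tanh output layer).
#' @export
reconstruct <- function(model, x) {
  f <- encode(model, x)
  a <- stack_forward(model$dec, model$dec_acts, f)
  a[[length(a)]]
}

reconstruction_mse <- function(model, x) {
  mean((reconstruct(model, x) - as.matrix(x))^2)
}
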