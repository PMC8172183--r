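# Fully connected autoencoder, written from scratch: Glorot-uniform
# initialization, minibatch stochastic gradient descent on the RMSE loss,
# best-epoch checkpointing with early stopping.

act_fun <- function(name) {
  switch(name,
    relu = list(f = function(z) pmax(z, 0), df = function(z) (z > 0) * 1),
    tanh = list(f = base::tanh, df = function(z) 1 - base::tanh(z)^2),
    identity = list(f = identity, df = function(z) array(1, dim = dim(z))),
    abort(sprintf("unknown activation '%s'", name))
  )
}

#' Autoencoder architecture
#'
#' The encoder maps the input through `encoder_widths` fully connected layers;
#' the last encoder layer is the latent code. The decoder mirrors the encoder
#' and ends in a linear output layer of `input_dim` units. The default is the
#' 50-50-50 stack on both sides with a 50-unit code.
#'
#' @param input_dim Feature dimensionality of the data.
#' @param encoder_widths Hidden-layer widths of the encoder; the last entry is
#'   the latent dimension.
#' @param activation Hidden-layer activation: `"relu"` (default), `"tanh"` or
#'   `"identity"`. The output layer is always linear.
#' @return A list of class `ae_architecture` with the full layer-width vector
#'   and per-layer activations.
#' @export
ae_architecture <- function(input_dim, encoder_widths = c(50, 50, 50),
                            activation = "relu") {
  if (input_dim < 1 || any(encoder_widths < 1)) abort("layer widths must be positive")
  decoder_widths <- rev(encoder_widths)[-1]
  widths <- c(input_dim, encoder_widths, decoder_widths, input_dim)
  n_layers <- length(widths) - 1L
  structure(
    list(
      input_dim = input_dim,
      encoder_widths = encoder_widths,
      latent_dim = encoder_widths[length(encoder_widths)],
      decoder_widths = decoder_widths,
      widths = widths,
      encoder_depth = length(encoder_widths),
      activations = c(rep(activation, n_layers - 1L), "identity")
    ),
    class = "ae_architecture"
  )
}

ae_init <- function(arch) {
  w <- arch$widths
  n_layers <- length(w) - 1L
  W <- vector("list", n_layers)
  b <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    lim <- sqrt(6 / (w[l] + w[l + 1]))
    W[[l]] <- matrix(runif(w[l] * w[l + 1], -lim, lim), nrow = w[l])
    b[[l]] <- numeric(w[l + 1])
  }
  list(W = W, b = b)
}

ae_forward <- function(par, arch, X) {
  n_layers <- length(par$W)
  a <- vector("list", n_layers + 1L)
  z <- vector("list", n_layers)
  a[[1]] <- X
  for (l in seq_len(n_layers)) {
    z[[l]] <- sweep(a[[l]] %*% par$W[[l]], 2, par$b[[l]], `+`)
    a[[l + 1]] <- act_fun(arch$activations[l])$f(z[[l]])
  }
  list(a = a, z = z)
}

#' Root-mean-square reconstruction loss
#'
#' `L = sqrt(mean((x - x')^2))` over every scalar entry of the batch.
#'
#' @param x,x_prime Numeric matrices (or vectors) of identical shape: the
#'   input batch and its reconstruction.
#' @return Non-negative scalar loss.
#' @examples
#' rmse_loss(c(1, 2), c(0, 0)) # sqrt(5/2)
#' @export
rmse_loss <- function(x, x_prime) {
  if (!identical(dim(x) %||% length(x), dim(x_prime) %||% length(x_prime))) {
    abort("`x` and `x_prime` must have identical shapes")
  }
  sqrt(mean((x - x_prime)^2))
}

# gradients of the batch RMSE loss w.r.t. all weights and biases
ae_backprop <- function(par, arch, X) {
  fwd <- ae_forward(par, arch, X)
  n_layers <- length(par$W)
  R <- fwd$a[[n_layers + 1L]] - X
  loss <- sqrt(mean(R^2))
  dW <- vector("list", n_layers)
  db <- vector("list", n_layers)
  if (loss == 0) {
    for (l in seq_len(n_layers)) {
      dW[[l]] <- matrix(0, nrow(par$W[[l]]), ncol(par$W[[l]]))
      db[[l]] <- numeric(length(par$b[[l]]))
    }
    return(list(loss = loss, dW = dW, db = db))
  }
  delta <- R / (length(R) * loss) # dL/d a_out, output layer is linear
  for (l in n_layers:1) {
    if (l < n_layers) {
      delta <- delta * act_fun(arch$activations[l])$df(fwd$z[[l]])
    }
    dW[[l]] <- crossprod(fwd$a[[l]], delta)
    db[[l]] <- colSums(delta)
    if (l > 1) delta <- delta %*% t(par$W[[l]])
  }
  list(loss = loss, dW = dW, db = db)
}

#' Train an autoencoder on a feature table
#'
#' Features are z-scored per column (training statistics are stored in the
#' model and re-applied at encode time), weights are initialized
#' Glorot-uniform from the seed, and minibatch SGD minimizes the batch RMSE
#' reconstruction loss. The full-data RMSE is recorded after every epoch;
#' training stops at `max_epochs` or after `patience` epochs without
#' improvement, and the returned weights are those of the best epoch.
#'
#' @param features A feature tibble (or plain numeric matrix).
#' @param arch An [ae_architecture()]; defaults to the 50-50-50 stack on the
#'   data's dimensionality.
#' @param lr Learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs,patience Epoch budget and early-stopping patience.
#' @param seed Integer seed controlling initialization and batch shuffling.
#' @param standardize Whether to z-score columns before training.
#' @return An object of class `eeg_autoencoder`: architecture, weights,
#'   standardization statistics, per-epoch loss trace and the best epoch.
#' @export
ae_train <- function(features, arch = NULL, lr = 0.01, batch_size = 32,
                     max_epochs = 200, patience = 20, seed = 1L,
                     standardize = TRUE) {
  X <- if (is.matrix(features)) features else feature_matrix(features)
  d <- ncol(X)
  if (is.null(arch)) arch <- ae_architecture(d)
  if (arch$input_dim != d) {
    abort(sprintf("architecture expects %d inputs, data has %d columns", arch$input_dim, d))
  }
  if (standardize) {
    mu <- colMeans(X)
    sigma <- apply(X, 2, sd)
    sigma[sigma < 1e-12] <- 1
  } else {
    mu <- rep(0, d); sigma <- rep(1, d)
  }
  Xs <- sweep(sweep(X, 2, mu), 2, sigma, `/`)
  n <- nrow(Xs)

  with_seed(seed, {
    par <- ae_init(arch)
    trace <- numeric(max_epochs + 1L)
    trace[1] <- rmse_loss(Xs, ae_forward(par, arch, Xs)$a[[length(par$W) + 1L]])
    best <- list(par = par, loss = trace[1], epoch = 0L)
    stall <- 0L
    epochs_run <- 0L
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n)
      for (s in seq(1L, n, by = batch_size)) {
        idx <- ord[s:min(s + batch_size - 1L, n)]
        g <- ae_backprop(par, arch, Xs[idx, , drop = FALSE])
        if (!is.finite(g$loss)) {
          abort(sprintf("training diverged (non-finite loss) at epoch %d with lr = %g", epoch, lr))
        }
        for (l in seq_along(par$W)) {
          par$W[[l]] <- par$W[[l]] - lr * g$dW[[l]]
          par$b[[l]] <- par$b[[l]] - lr * g$db[[l]]
        }
      }
      loss <- rmse_loss(Xs, ae_forward(par, arch, Xs)$a[[length(par$W) + 1L]])
      if (!is.finite(loss)) {
        abort(sprintf("training diverged (non-finite loss) at epoch %d with lr = %g", epoch, lr))
      }
      trace[epoch + 1L] <- loss
      epochs_run <- epoch
      if (loss < best$loss - 1e-12) {
        best <- list(par = par, loss = loss, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    }
    structure(
      list(
        arch = arch, W = best$par$W, b = best$par$b,
        standardization = list(mean = mu, sd = sigma),
        trace = tibble(epoch = 0:epochs_run, loss = trace[seq_len(epochs_run + 1L)]),
        best_epoch = best$epoch, loss = best$loss, seed = as.integer(seed),
        hyper = list(lr = lr, batch_size = batch_size,
                     max_epochs = max_epochs, patience = patience)
      ),
      class = "eeg_autoencoder"
    )
  })
}

#' @export
print.eeg_autoencoder <- function(x, ...) {
  cat(sprintf(
    "<eeg_autoencoder> %s | latent %d | best epoch %d, RMSE %.4f\n",
    paste(x$arch$widths, collapse = "-"), x$arch$latent_dim, x$best_epoch, x$loss
  ))
  invisible(x)
}

#' Encode features into the latent space
#'
#' Applies the model's stored standardization, then the encoder layers. Row
#' order, labels and subject ids are carried through unchanged.
#'
#' @param model An `eeg_autoencoder` from [ae_train()].
#' @param features A feature tibble with the dimensionality the model was
#'   trained on.
#' @return A feature tibble with `latent_dim` columns `Z1`, `Z2`, ... and
#'   feature-set name suffixed `"_latent"`.
#' @export
ae_encode <- function(model, features) {
  X <- if (is.matrix(features)) features else feature_matrix(features)
  if (ncol(X) != model$arch$input_dim) {
    abort(sprintf("model expects %d inputs, got %d", model$arch$input_dim, ncol(X)))
  }
  Xs <- sweep(sweep(X, 2, model$standardization$mean), 2, model$standardization$sd, `/`)
  a <- Xs
  for (l in seq_len(model$arch$encoder_depth)) {
    z <- sweep(a %*% model$W[[l]], 2, model$b[[l]], `+`)
    a <- act_fun(model$arch$activations[l])$f(z)
  }
  colnames(a) <- paste0("Z", seq_len(ncol(a)))
  if (is.matrix(features)) return(a)
  meta <- features[intersect(.meta_cols, names(features))]
  set <- paste0(attr(features, "feature_set") %||% "features", "_latent")
  new_feature_tbl(meta, a, set)
}

#' Check backpropagation against finite differences
#'
#' Builds a tiny network and a random batch, and compares every analytic
#' gradient entry of the RMSE loss with a central finite difference.
#'
#' @param arch A small [ae_architecture()]; defaults to a 3-4-2 encoder on
#'   smooth (`tanh`) activations so the loss is differentiable everywhere.
#' @param seed Integer seed for weights and data.
#' @param n Batch size.
#' @param h Finite-difference step.
#' @return Maximum relative gradient error over all weights and biases.
#' @export
ae_gradient_check <- function(arch = ae_architecture(3, c(4, 2), activation = "tanh"),
                              seed = 1L, n = 10, h = 1e-6) {
  with_seed(seed, {
    par <- ae_init(arch)
    X <- matrix(rnorm(n * arch$input_dim), nrow = n)
    g <- ae_backprop(par, arch, X)
    loss_at <- function(p) {
      fwd <- ae_forward(p, arch, X)
      rmse_loss(X, fwd$a[[length(p$W) + 1L]])
    }
    max_err <- 0
    for (l in seq_along(par$W)) {
      for (slot in c("W", "b")) {
        theta <- par[[slot]][[l]]
        analytic <- g[[paste0("d", slot)]][[l]]
        for (i in seq_along(theta)) {
          p_hi <- par; p_lo <- par
          p_hi[[slot]][[l]][i] <- theta[i] + h
          p_lo[[slot]][[l]][i] <- theta[i] - h
          fd <- (loss_at(p_hi) - loss_at(p_lo)) / (2 * h)
          denom <- max(abs(analytic[i]) + abs(fd), 1e-8)
          max_err <- max(max_err, abs(analytic[i] - fd) / denom)
        }
      }
    }
    max_err
  })
}

#' @rdname ae_train
#' @param x An `eeg_autoencoder`.
#' @param ... Unused.
#' @export
tidy.eeg_autoencoder <- function(x, ...) x$trace

#' @rdname ae_train
#' @export
glance.eeg_autoencoder <- function(x, ...) {
  tibble(
    input_dim = x$arch$input_dim, latent_dim = x$arch$latent_dim,
    epochs_run = max(x$trace$epoch), best_epoch = x$best_epoch,
    initial_loss = x$trace$loss[1], final_loss = x$loss, seed = x$seed
  )
}
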