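# Hourglass autoencoder / variational autoencoder over MinMax-scaled
# trajectory features, written as a classical R fitting function.
#
# The network is a fully connected mirror-symmetric MLP: the encoder
# compresses input_dim -> encoder_sizes -> latent_dim (for the VAE through
# two linear heads, posterior mean mu and log-variance), the decoder expands
# through the reversed sizes back to input_dim with a sigmoid output so that
# decodes stay in the scaled coordinate range.  Training maximizes the ELBO:
# a Gaussian reconstruction term (sum of squared errors on the scaled
# features) plus kl_weight times the closed-form KL divergence of the
# diagonal-Gaussian posterior from the standard-normal prior, with the
# reparameterization trick (z = mu + sigma * eps) carrying gradients through
# the sampling step.  Optimization is plain Adam on minibatches.

relu <- function(x) (x > 0) * x
sigmoid <- function(x) 1 / (1 + exp(-x))

## per-sample KL( N(mu, diag exp(logvar)) || N(0, I) ), summed over latent dims
kl_gaussian <- function(mu, logvar) {
  rowSums(0.5 * (mu^2 + exp(logvar) - 1 - logvar))
}

init_layer <- function(nin, nout, sd = sqrt(2 / nin)) {
  list(W = matrix(stats::rnorm(nin * nout, sd = sd), nin, nout),
       b = rep(0, nout))
}

init_params <- function(input_dim, sizes, latent_dim, vae) {
  pr <- list()
  prev <- input_dim
  for (i in seq_along(sizes)) {
    pr[[paste0("e", i)]] <- init_layer(prev, sizes[i])
    prev <- sizes[i]
  }
  pr$mu <- init_layer(prev, latent_dim, sd = sqrt(1 / prev))
  if (vae) pr$lv <- init_layer(prev, latent_dim, sd = 1e-3)
  rs <- rev(sizes)
  prev <- latent_dim
  for (i in seq_along(rs)) {
    pr[[paste0("d", i)]] <- init_layer(prev, rs[i])
    prev <- rs[i]
  }
  pr$out <- init_layer(prev, input_dim, sd = sqrt(1 / prev))
  pr
}

## encoder trunk activations; A[[1]] = X, A[[i+1]] = relu(A[[i]] W + b)
enc_trunk <- function(pr, X, n_hidden) {
  A <- vector("list", n_hidden + 1L)
  A[[1L]] <- X
  for (i in seq_len(n_hidden)) {
    l <- pr[[paste0("e", i)]]
    A[[i + 1L]] <- relu(sweep(A[[i]] %*% l$W, 2L, l$b, `+`))
  }
  A
}

encode_mu <- function(pr, X, n_hidden) {
  A <- enc_trunk(pr, X, n_hidden)
  sweep(A[[n_hidden + 1L]] %*% pr$mu$W, 2L, pr$mu$b, `+`)
}

decode_mean <- function(pr, Z, n_hidden) {
  A <- Z
  for (i in seq_len(n_hidden)) {
    l <- pr[[paste0("d", i)]]
    A <- relu(sweep(A %*% l$W, 2L, l$b, `+`))
  }
  sigmoid(sweep(A %*% pr$out$W, 2L, pr$out$b, `+`))
}

## one forward + backward pass on a minibatch; returns per-sample loss sums
## and the gradient list (same shape as pr).  eps is the reparameterization
## draw for the VAE, NULL for the plain AE.
vae_backprop <- function(pr, X, n_hidden, vae, kl_weight, eps) {
  B <- nrow(X)
  A <- enc_trunk(pr, X, n_hidden)
  H <- A[[n_hidden + 1L]]
  mu <- sweep(H %*% pr$mu$W, 2L, pr$mu$b, `+`)
  if (vae) {
    lv <- sweep(H %*% pr$lv$W, 2L, pr$lv$b, `+`)
    lv <- pmin(pmax(lv, -10), 10)   # numeric guard on the posterior variance
    Z <- mu + exp(0.5 * lv) * eps
  } else {
    Z <- mu
  }
  D <- vector("list", n_hidden + 1L)
  D[[1L]] <- Z
  for (i in seq_len(n_hidden)) {
    l <- pr[[paste0("d", i)]]
    D[[i + 1L]] <- relu(sweep(D[[i]] %*% l$W, 2L, l$b, `+`))
  }
  Y <- sigmoid(sweep(D[[n_hidden + 1L]] %*% pr$out$W, 2L, pr$out$b, `+`))

  recon_sum <- sum((Y - X)^2)
  kl_sum <- if (vae) sum(kl_gaussian(mu, lv)) else 0

  gr <- list()
  dY <- 2 * (Y - X) / B
  dLin <- dY * Y * (1 - Y)
  gr$out <- list(W = crossprod(D[[n_hidden + 1L]], dLin), b = colSums(dLin))
  dA <- dLin %*% t(pr$out$W)
  for (i in rev(seq_len(n_hidden))) {
    dH <- dA * (D[[i + 1L]] > 0)
    l <- pr[[paste0("d", i)]]
    gr[[paste0("d", i)]] <- list(W = crossprod(D[[i]], dH), b = colSums(dH))
    dA <- dH %*% t(l$W)
  }
  dZ <- dA
  if (vae) {
    dmu <- dZ + kl_weight * mu / B
    dlv <- dZ * eps * 0.5 * exp(0.5 * lv) +
      kl_weight * 0.5 * (exp(lv) - 1) / B
    gr$mu <- list(W = crossprod(H, dmu), b = colSums(dmu))
    gr$lv <- list(W = crossprod(H, dlv), b = colSums(dlv))
    dA <- dmu %*% t(pr$mu$W) + dlv %*% t(pr$lv$W)
  } else {
    gr$mu <- list(W = crossprod(H, dZ), b = colSums(dZ))
    dA <- dZ %*% t(pr$mu$W)
  }
  for (i in rev(seq_len(n_hidden))) {
    dH <- dA * (A[[i + 1L]] > 0)
    l <- pr[[paste0("e", i)]]
    gr[[paste0("e", i)]] <- list(W = crossprod(A[[i]], dH), b = colSums(dH))
    dA <- dH %*% t(l$W)
  }
  list(recon_sum = recon_sum, kl_sum = kl_sum, grads = gr)
}

#' Hourglass layer sizes for a given input width
#'
#' Geometric interpolation between the input width and the latent dimension,
#' keeping an approximately constant compression factor between adjacent
#' layers — the same construction rule as the reference architectures, scaled
#' to arbitrary input widths.
#'
#' @param input_dim Feature width.
#' @param n_hidden Number of hidden layers in the encoder (default 4).
#' @param latent_dim Latent dimension (default 2).
#' @return Decreasing integer vector of `n_hidden` encoder layer sizes.
#' @examples
#' hourglass_sizes(150, 4)
#' @export
hourglass_sizes <- function(input_dim, n_hidden = 4, latent_dim = 2) {
  r <- (input_dim / latent_dim)^(1 / (n_hidden + 1))
  sizes <- round(input_dim / r^seq_len(n_hidden))
  sizes <- pmax(sizes, latent_dim + seq(n_hidden, 1))
  as.integer(rev(sort(unique(sizes)))[seq_len(n_hidden)])
}

#' Fit an autoencoder or variational autoencoder to trajectory features
#'
#' Trains a mirror-symmetric dense network on MinMax-scaled coordinates.
#' For `kind = "vae"` the objective is the negative ELBO: the sum-of-squared
#' -errors reconstruction term plus `kl_weight` times the KL divergence of
#' the Gaussian posterior `q(z|x) = N(mu(x), diag sigma^2(x))` from the
#' standard-normal prior, estimated with one reparameterized sample per
#' datum per step.  For `kind = "ae"` only the reconstruction term is
#' minimized and the latent code is deterministic.
#'
#' All randomness (weight initialization, minibatch shuffling, posterior
#' sampling) is driven by a single RNG stream seeded with `seed`, so a fixed
#' seed reproduces the training trajectory exactly.
#'
#' @param x A `feature_matrix` from [featurize()] (preferred: the scaler and
#'   atom metadata are kept for decoding back to Angstrom), or a plain
#'   numeric matrix of frames by features in `[0, 1]`.
#' @param kind `"vae"` (default) or `"ae"`.
#' @param encoder_sizes Decreasing integer vector of hidden-layer widths;
#'   defaults to `hourglass_sizes(ncol(x), 4, latent_dim)`.  The decoder is
#'   always the exact mirror.
#' @param latent_dim Latent-space dimension (default 2).
#' @param epochs Training epochs (default 200); `epochs = 0` returns the
#'   model at its random initialization.
#' @param batch_size Minibatch size (default 32).
#' @param learning_rate Adam step size (default 1e-3).
#' @param kl_weight Non-negative weight on the KL term (default 1, the plain
#'   ELBO); `kl_weight = 0` makes the VAE a stochastic autoencoder.
#' @param split Optional [stride_split()] result; only `split$train` rows are
#'   used for fitting.
#' @param seed Integer RNG seed (default 1).
#' @param verbose Print the loss every 20 epochs?
#' @return Object of class `traj_vae` with components `params` (weights),
#'   `history` (per-epoch `recon`, `kl`, `total`), `scaler`, `atoms`, the
#'   architecture fields, and the training data reference `x`.
#' @seealso [encode()], [decode()], [predict.traj_vae()],
#'   [residuals.traj_vae()], [simulate.traj_vae()], [save_vae()]
#' @export
traj_vae <- function(x, kind = c("vae", "ae"), encoder_sizes = NULL,
                     latent_dim = 2, epochs = 200, batch_size = 32,
                     learning_rate = 1e-3, kl_weight = 1, split = NULL,
                     seed = 1, verbose = FALSE) {
  kind <- match.arg(kind)
  scaler <- NULL; atoms <- NULL
  if (inherits(x, "feature_matrix")) {
    scaler <- x$scaler; atoms <- x$atoms; X <- x$values
  } else X <- as.matrix(x)
  if (!all(is.finite(X))) stop("features contain non-finite values")
  input_dim <- ncol(X)
  if (latent_dim < 1) stop("'latent_dim' must be at least 1")
  if (is.null(encoder_sizes))
    encoder_sizes <- hourglass_sizes(input_dim, 4, latent_dim)
  encoder_sizes <- as.integer(encoder_sizes)
  if (any(diff(encoder_sizes) >= 0))
    stop("'encoder_sizes' must be strictly decreasing")
  if (any(encoder_sizes >= input_dim))
    stop("hidden layers must be narrower than the input (", input_dim, ")")
  if (encoder_sizes[length(encoder_sizes)] < latent_dim)
    stop("the last hidden layer must be at least as wide as 'latent_dim'")
  if (kl_weight < 0) stop("'kl_weight' must be non-negative")
  if (epochs < 0) stop("'epochs' must be non-negative")

  rows <- if (is.null(split)) seq_len(nrow(X)) else split$train
  if (!length(rows)) stop("training set is empty")
  Xtr <- X[rows, , drop = FALSE]
  n <- nrow(Xtr)
  vae <- kind == "vae"
  n_hidden <- length(encoder_sizes)

  set.seed(seed)
  pr <- init_params(input_dim, encoder_sizes, latent_dim, vae)

  ## Adam state mirrors the parameter list
  m <- rapply(pr, function(p) p * 0, how = "replace")
  v <- m
  b1 <- 0.9; b2 <- 0.999; eps_adam <- 1e-8
  step <- 0L
  history <- data.frame(epoch = integer(0), recon = numeric(0),
                        kl = numeric(0), total = numeric(0))
  for (ep in seq_len(epochs)) {
    perm <- sample(n)
    recon_tot <- 0; kl_tot <- 0
    for (start in seq(1L, n, by = batch_size)) {
      idx <- perm[start:min(start + batch_size - 1L, n)]
      Xb <- Xtr[idx, , drop = FALSE]
      eps <- if (vae) matrix(stats::rnorm(length(idx) * latent_dim),
                             length(idx), latent_dim) else NULL
      bp <- vae_backprop(pr, Xb, n_hidden, vae, kl_weight, eps)
      if (!is.finite(bp$recon_sum) || !is.finite(bp$kl_sum))
        stop("non-finite training loss at epoch ", ep,
             "; try a smaller learning rate or check the feature scale")
      recon_tot <- recon_tot + bp$recon_sum
      kl_tot <- kl_tot + bp$kl_sum
      step <- step + 1L
      for (nm in names(pr)) for (pc in c("W", "b")) {
        g <- bp$grads[[nm]][[pc]]
        m[[nm]][[pc]] <- b1 * m[[nm]][[pc]] + (1 - b1) * g
        v[[nm]][[pc]] <- b2 * v[[nm]][[pc]] + (1 - b2) * g^2
        mhat <- m[[nm]][[pc]] / (1 - b1^step)
        vhat <- v[[nm]][[pc]] / (1 - b2^step)
        pr[[nm]][[pc]] <- pr[[nm]][[pc]] -
          learning_rate * mhat / (sqrt(vhat) + eps_adam)
      }
    }
    recon <- recon_tot / n
    kl <- kl_tot / n
    history[ep, ] <- list(ep, recon, kl, recon + kl_weight * kl)
    if (verbose && (ep %% 20 == 0 || ep == 1))
      message(sprintf("epoch %4d  recon %.5f  kl %.5f", ep, recon, kl))
  }

  structure(list(kind = kind, input_dim = input_dim,
                 encoder_sizes = encoder_sizes,
                 decoder_sizes = rev(encoder_sizes),
                 latent_dim = as.integer(latent_dim),
                 kl_weight = kl_weight, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 params = pr, history = history, scaler = scaler,
                 atoms = atoms, x = X, split = split,
                 call = match.call()),
            class = "traj_vae")
}

#' Encode frames into the latent space
#'
#' Deterministic: returns the posterior mean `mu(x)` (for the AE, the latent
#' code), one row per frame.
#'
#' @param object A fitted [traj_vae()].
#' @param x Features to encode (`feature_matrix` or matrix); defaults to the
#'   training data.
#' @return `n x latent_dim` matrix with columns `z1, z2, ...`.
#' @export
encode <- function(object, x = NULL) {
  stopifnot(inherits(object, "traj_vae"))
  X <- if (is.null(x)) object$x else
    if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
  if (is.null(X)) stop("no data to encode: supply 'x'")
  if (ncol(X) != object$input_dim)
    stop("feature width (", ncol(X), ") does not match the model input (",
         object$input_dim, ")")
  Z <- encode_mu(object$params, X, length(object$encoder_sizes))
  colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  Z
}

#' Decode latent points into feature space
#'
#' Deterministic mean decode.  The result lies in the scaled feature space;
#' use [defeaturize()] with the model's scaler to obtain Angstrom
#' coordinates.
#'
#' @param object A fitted [traj_vae()].
#' @param z Latent points: `m x latent_dim` matrix or a single vector.
#' @return `m x input_dim` matrix of scaled feature values.
#' @export
decode <- function(object, z) {
  stopifnot(inherits(object, "traj_vae"))
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  z <- as.matrix(z)
  if (ncol(z) != object$latent_dim)
    stop("latent point dimension (", ncol(z), ") does not match latent_dim (",
         object$latent_dim, ")")
  decode_mean(object$params, z, length(object$encoder_sizes))
}

#' @export
print.traj_vae <- function(x, ...) {
  cat(sprintf("%s: %d -> [%s] -> %d -> [%s] -> %d\n",
              toupper(x$kind), x$input_dim,
              paste(x$encoder_sizes, collapse = ", "), x$latent_dim,
              paste(x$decoder_sizes, collapse = ", "), x$input_dim))
  cat("  parameters:", format(count_params(x), big.mark = ","),
      " epochs trained:", x$epochs, "\n")
  if (nrow(x$history)) {
    h <- x$history[nrow(x$history), ]
    cat(sprintf("  final loss: recon %.5f + %.2g * kl %.5f = %.5f\n",
                h$recon, x$kl_weight, h$kl, h$total))
  }
  invisible(x)
}

count_params <- function(object) {
  sum(vapply(object$params,
             function(l) length(l$W) + length(l$b), numeric(1)))
}

#' @export
summary.traj_vae <- function(object, ...) {
  out <- list(kind = object$kind, input_dim = object$input_dim,
              encoder_sizes = object$encoder_sizes,
              latent_dim = object$latent_dim,
              n_params = count_params(object), epochs = object$epochs,
              kl_weight = object$kl_weight,
              history_tail = utils::tail(object$history, 5),
              has_scaler = !is.null(object$scaler))
  class(out) <- "summary.traj_vae"
  out
}

#' @export
print.summary.traj_vae <- function(x, ...) {
  cat(toupper(x$kind), "with", length(x$encoder_sizes),
      "hidden layers, latent dimension", x$latent_dim, "\n")
  cat("  input width:", x$input_dim, " parameters:",
      format(x$n_params, big.mark = ","), "\n")
  cat("  kl_weight:", x$kl_weight, " epochs:", x$epochs, "\n")
  if (nrow(x$history_tail)) {
    cat("  last epochs:\n")
    print(x$history_tail, row.names = FALSE)
  }
  if (!x$has_scaler)
    cat("  (no scaler attached: decodes stay in scaled feature space)\n")
  invisible(x)
}

#' Predict method for traj_vae models
#'
#' @param object A fitted [traj_vae()].
#' @param newdata Features (`feature_matrix` or matrix); defaults to the
#'   training data.
#' @param type `"latent"` for posterior-mean codes, `"response"` for the
#'   reconstruction `decode(encode(x))` in scaled feature space.
#' @param ... Unused.
#' @export
predict.traj_vae <- function(object, newdata = NULL,
                             type = c("latent", "response"), ...) {
  type <- match.arg(type)
  Z <- encode(object, newdata)
  if (type == "latent") Z else decode(object, Z)
}

#' Reconstruction residuals
#'
#' Per-frame deviation between each frame and its reconstruction
#' `decode(encode(x))`.  With a scaler attached (the model was fitted on a
#' `feature_matrix`) the deviation is the superposition RMSD in Angstrom;
#' otherwise it is the root-mean-square feature-space error.
#'
#' @param object A fitted [traj_vae()].
#' @param newdata Optional features; defaults to the training data.
#' @param ... Unused.
#' @return Numeric vector, one value per frame.
#' @export
residuals.traj_vae <- function(object, newdata = NULL, ...) {
  X <- if (is.null(newdata)) object$x else
    if (inherits(newdata, "feature_matrix")) newdata$values else
      as.matrix(newdata)
  if (is.null(X)) stop("no data: supply 'newdata'")
  Y <- predict(object, X, type = "response")
  if (is.null(object$scaler))
    return(sqrt(rowMeans((Y - X)^2)))
  orig <- defeaturize(X, object$scaler, as_ensemble = FALSE)
  reco <- defeaturize(Y, object$scaler, as_ensemble = FALSE)
  vapply(seq_len(nrow(X)), function(i)
    superposition_rmsd(unflatten_frames(reco[i, , drop = FALSE])[1, , ],
                       unflatten_frames(orig[i, , drop = FALSE])[1, , ]),
    numeric(1))
}

#' Generate conformations from the latent prior
#'
#' Draws `nsim` latent points from the standard-normal prior and decodes
#' them; the generative use of the model.
#'
#' @param object A fitted [traj_vae()].
#' @param nsim Number of conformations.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A [traj_ensemble()] when a scaler is attached, otherwise the
#'   decoded feature matrix.
#' @export
simulate.traj_vae <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  Z <- matrix(stats::rnorm(nsim * object$latent_dim), nsim)
  Y <- decode(object, Z)
  if (is.null(object$scaler)) return(Y)
  defeaturize(Y, object$scaler, object$atoms)
}

#' @export
coef.traj_vae <- function(object, ...) object$params

#' Plot training history or latent embedding
#'
#' @param x A fitted [traj_vae()].
#' @param which `"history"` (loss components per epoch) or `"latent"`
#'   (2-D embedding scatter of the training frames).
#' @param labels Optional per-frame grouping for latent colouring.
#' @param ... Passed to the underlying plot call.
#' @export
plot.traj_vae <- function(x, which = c("history", "latent"), labels = NULL,
                          ...) {
  which <- match.arg(which)
  if (which == "history") {
    if (!nrow(x$history)) stop("no training history to plot")
    graphics::plot(x$history$epoch, x$history$total, type = "l",
                   xlab = "epoch", ylab = "loss", ...)
    graphics::lines(x$history$epoch, x$history$recon, lty = 2)
    graphics::legend("topright", c("total", "reconstruction"), lty = 1:2,
                     bty = "n")
  } else {
    Z <- encode(x)
    col <- if (is.null(labels)) 1 else as.integer(factor(labels))
    graphics::plot(Z[, 1L], Z[, 2L], col = col, pch = 16,
                   xlab = "z1", ylab = "z2", ...)
  }
  invisible(x)
}

#' Save / load a fitted model
#'
#' The model is persisted as a self-describing JSON archive: architecture,
#' weights (as flat arrays with dimensions), training history, and the
#' feature scaler plus atom metadata needed to decode to structures.  The
#' training data matrix is not stored.
#'
#' @param object A fitted [traj_vae()].
#' @param path File path.
#' @return `save_vae()` returns `path` invisibly; `load_vae()` the restored
#'   `traj_vae` object.
#' @export
save_vae <- function(object, path) {
  stopifnot(inherits(object, "traj_vae"))
  ser <- list(
    format = "latentmd-vae", version = "1.0",
    kind = object$kind, input_dim = object$input_dim,
    encoder_sizes = object$encoder_sizes, latent_dim = object$latent_dim,
    kl_weight = object$kl_weight, epochs = object$epochs,
    batch_size = object$batch_size, learning_rate = object$learning_rate,
    seed = object$seed,
    params = lapply(object$params, function(l)
      list(dim = dim(l$W), W = as.vector(l$W), b = l$b)),
    history = object$history,
    scaler = object$scaler,
    atoms = object$atoms)
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname save_vae
#' @export
load_vae <- function(path) {
  ser <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) stop("cannot read model file '", path,
                                           "': ", conditionMessage(e)))
  if (!identical(ser$format, "latentmd-vae") || is.null(ser$params))
    stop("'", path, "' is not a latentmd model archive (corrupt or wrong file)")
  pr <- lapply(ser$params, function(l)
    list(W = matrix(l$W, l$dim[1L], l$dim[2L]), b = as.numeric(l$b)))
  history <- as.data.frame(ser$history)
  if (!nrow(history))
    history <- data.frame(epoch = integer(0), recon = numeric(0),
                          kl = numeric(0), total = numeric(0))
  structure(list(kind = ser$kind, input_dim = ser$input_dim,
                 encoder_sizes = as.integer(ser$encoder_sizes),
                 decoder_sizes = rev(as.integer(ser$encoder_sizes)),
                 latent_dim = as.integer(ser$latent_dim),
                 kl_weight = ser$kl_weight, epochs = as.integer(ser$epochs),
                 batch_size = as.integer(ser$batch_size),
                 learning_rate = ser$learning_rate,
                 seed = as.integer(ser$seed), params = pr,
                 history = history,
                 scaler = if (!is.null(ser$scaler)) as_scaler(ser$scaler),
                 atoms = if (!is.null(ser$atoms)) as.data.frame(ser$atoms),
                 x = NULL, split = NULL, call = NULL),
            class = "traj_vae")
}
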