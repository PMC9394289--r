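#' Model configuration
#'
#' Hyperparameters of the graph-convolutional classifier. Defaults follow
#' the reference setting: Chebyshev order K = 2, dropout 0.2, batch size
#' 128, learning rate 5e-4, at most 1000 epochs with stop threshold 1e-4 on
#' the training loss. The optimizer is Adam; the regularizer is the squared
#' L2 norm of the weights (Chebyshev coefficients and dense-head weights,
#' biases excluded) with coefficient `alpha`.
#'
#' @param K Chebyshev polynomial order (number of terms, >= 1)
#' @param hidden_width feature maps per node after graph convolution
#' @param n_classes number of output classes
#' @param dropout dropout probability on the hidden layer, in `[0, 1)`
#' @param alpha regularization coefficient
#' @param learning_rate Adam step size
#' @param batch_size minibatch size
#' @param max_epochs epoch budget MAX
#' @param stop_threshold stop when the epoch training loss drops to or below
#'   this value
#' @param scaling Laplacian scaling passed to [laplacian()]
#' @param seed RNG seed for initialization, shuffling and dropout
#' @return a `crgcn_model_config`
#' @export
model_config <- function(K = 2L, hidden_width = 32L, n_classes = 2L,
                         dropout = 0.2, alpha = 1e-3,
                         learning_rate = 5e-4, batch_size = 128L,
                         max_epochs = 1000L, stop_threshold = 1e-4,
                         scaling = "shifted", seed = 1L) {
  stopifnot(K >= 1, dropout >= 0, dropout < 1, learning_rate > 0,
            stop_threshold > 0, alpha >= 0, hidden_width >= 1,
            batch_size >= 1, max_epochs >= 1)
  structure(list(K = as.integer(K), hidden_width = as.integer(hidden_width),
                 n_classes = as.integer(n_classes), dropout = dropout,
                 alpha = alpha, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 stop_threshold = stop_threshold, scaling = scaling,
                 seed = as.integer(seed)),
            class = "crgcn_model_config")
}

#' Initialize model parameters
#'
#' Chebyshev coefficients `theta[[k]]` (`bands x hidden_width` per order)
#' and the dense softmax head (`W`: `channels*hidden_width x n_classes`,
#' `b`: length `n_classes`), drawn from small uniform (Glorot-style) bounds.
#'
#' @param config a `crgcn_model_config`
#' @param n_channels graph nodes N
#' @param n_bands input features per node
#' @return a `crgcn_params` list (`theta`, `W`, `b`)
#' @export
init_params <- function(config, n_channels, n_bands) {
  h <- config$hidden_width
  lim1 <- sqrt(6 / (n_bands + h))
  theta <- lapply(seq_len(config$K), function(k)
    matrix(stats::runif(n_bands * h, -lim1, lim1), n_bands, h))
  nin <- n_channels * h
  lim2 <- sqrt(6 / (nin + config$n_classes))
  w <- matrix(stats::runif(nin * config$n_classes, -lim2, lim2),
              nin, config$n_classes)
  structure(list(theta = theta, W = w, b = rep(0, config$n_classes)),
            class = "crgcn_params")
}

# ---- internal forward/backward ---------------------------------------------

# Chebyshev terms for every segment at once: list of K matrices
# (n_segments * N) x F, rows ordered channel-fastest within segment.
precompute_cheb <- function(graph, values, K) {
  if (is.null(graph$scaled_laplacian)) graph <- laplacian(graph)
  lt <- graph$scaled_laplacian
  d <- dim(values)                       # n x N x F
  n <- d[1L]; nn <- d[2L]; f <- d[3L]
  xbig <- matrix(aperm(values, c(2L, 3L, 1L)), nn, f * n)
  mats <- vector("list", K)
  mats[[1L]] <- xbig
  if (K >= 2L) mats[[2L]] <- lt %*% xbig
  if (K >= 3L) for (k in 3:K)
    mats[[k]] <- 2 * (lt %*% mats[[k - 1L]]) - mats[[k - 2L]]
  lapply(mats, function(m) {
    a <- array(m, dim = c(nn, f, n))
    matrix(aperm(a, c(1L, 3L, 2L)), nn * n, f)
  })
}

rows_for <- function(idx, n_ch) rep((idx - 1L) * n_ch, each = n_ch) +
  seq_len(n_ch)

# forward pass over the segments in `idx`; returns caches for backward
model_forward <- function(terms, idx, params, config, n_ch,
                          training = FALSE) {
  m <- length(idx)
  rows <- rows_for(idx, n_ch)
  h <- config$hidden_width
  conv <- matrix(0, m * n_ch, h)
  for (k in seq_along(params$theta))
    conv <- conv + terms[[k]][rows, , drop = FALSE] %*% params$theta[[k]]
  act <- pmax(conv, 0)                              # ReLU
  a3 <- array(act, dim = c(n_ch, m, h))
  flat <- t(matrix(aperm(a3, c(3L, 1L, 2L)), h * n_ch, m))
  mask <- NULL
  if (training && config$dropout > 0) {
    mask <- matrix(stats::runif(length(flat)) >= config$dropout,
                   nrow(flat), ncol(flat)) / (1 - config$dropout)
    flat <- flat * mask
  }
  logits <- flat %*% params$W + rep(params$b, each = m)
  lmax <- apply(logits, 1L, max)
  el <- exp(logits - lmax)
  probs <- el / rowSums(el)
  list(probs = probs, flat = flat, conv = conv, mask = mask, rows = rows,
       m = m)
}

# mean cross-entropy + alpha * squared L2 norm of weights
penalty <- function(params, alpha)
  alpha * (sum(unlist(lapply(params$theta, function(t) sum(t^2)))) +
             sum(params$W^2))

cross_entropy <- function(probs, labels) {
  p <- pmax(probs[cbind(seq_len(nrow(probs)), labels + 1L)], 1e-12)
  -mean(log(p))
}

model_backward <- function(fwd, terms, labels, params, config) {
  m <- fwd$m
  onehot <- matrix(0, m, config$n_classes)
  onehot[cbind(seq_len(m), labels + 1L)] <- 1
  dlogits <- (fwd$probs - onehot) / m
  dW <- crossprod(fwd$flat, dlogits) + 2 * config$alpha * params$W
  db <- colSums(dlogits)
  dflat <- dlogits %*% t(params$W)
  if (!is.null(fwd$mask)) dflat <- dflat * fwd$mask
  h <- config$hidden_width
  n_ch <- length(fwd$rows) / m
  a3d <- array(t(dflat), dim = c(h, n_ch, m))
  dconv <- matrix(aperm(a3d, c(2L, 3L, 1L)), n_ch * m, h)
  dconv <- dconv * (fwd$conv > 0)
  dtheta <- lapply(seq_along(params$theta), function(k)
    crossprod(terms[[k]][fwd$rows, , drop = FALSE], dconv) +
      2 * config$alpha * params$theta[[k]])
  list(theta = dtheta, W = dW, b = db)
}

# ---- public forward / loss --------------------------------------------------

#' Forward pass: class probabilities per segment
#'
#' Graph convolution `sum_k theta_k T_k(Lt) x` to `hidden_width` features
#' per node, ReLU, flatten, dense layer, softmax. Dropout is active only
#' when `training = TRUE`.
#'
#' @param values normalized feature array `segments x channels x bands`
#' @param graph a `crgcn_graph` (run through [laplacian()]; done on the fly
#'   otherwise)
#' @param params a `crgcn_params`
#' @param config a `crgcn_model_config`
#' @param training apply dropout
#' @return matrix `segments x n_classes` of probabilities (rows sum to 1)
#' @export
crgcn_forward <- function(values, graph, params, config,
                          training = FALSE) {
  values <- feature_values(values)
  n_ch <- dim(values)[2L]
  if (!is.null(graph$adjacency) && nrow(graph$adjacency) != n_ch)
    stop("crgcn_forward: graph has ", nrow(graph$adjacency),
         " nodes but features have ", n_ch, " channels")
  terms <- precompute_cheb(graph, values, config$K)
  model_forward(terms, seq_len(dim(values)[1L]), params, config, n_ch,
                training = training)$probs
}

#' Training loss
#'
#' Mean cross-entropy between predicted probabilities and labels plus
#' `alpha` times the squared L2 norm of the model weights. Probabilities
#' are clamped at 1e-12 before the logarithm.
#'
#' @param probs matrix `segments x n_classes`
#' @param labels 0/1 vector
#' @param params a `crgcn_params` (weights entering the penalty)
#' @param alpha regularization coefficient
#' @return scalar loss
#' @export
crgcn_loss <- function(probs, labels, params, alpha) {
  cross_entropy(probs, labels) + penalty(params, alpha)
}

#' Train the graph-convolutional classifier
#'
#' Precomputes the Chebyshev terms of every segment once, then runs
#' minibatch gradient descent with Adam: continue while the epoch training
#' loss exceeds `stop_threshold` and the epoch budget is not exhausted.
#' Fully reproducible from `config$seed`.
#'
#' @param values normalized feature array `segments x channels x bands`
#' @param labels 0/1 vector, one per segment (both classes must be present)
#' @param graph a `crgcn_graph`
#' @param config a `crgcn_model_config`
#' @param verbose print the loss every 50 epochs
#' @return a `crgcn_model`: list with `params`, `config`, `graph` and
#'   `history` (data.frame epoch / loss / train_accuracy)
#' @export
train_crgcn <- function(values, labels, graph, config = model_config(),
                        verbose = FALSE) {
  values <- feature_values(values)
  n <- dim(values)[1L]; n_ch <- dim(values)[2L]; n_bd <- dim(values)[3L]
  if (length(labels) != n)
    stop("train_crgcn: ", n, " segments but ", length(labels), " labels")
  if (length(unique(labels)) < 2L)
    stop("train_crgcn: training data contains a single class")
  if (is.null(graph$scaled_laplacian)) graph <- laplacian(graph,
                                                          config$scaling)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  terms <- precompute_cheb(graph, values, config$K)
  params <- init_params(config, n_ch, n_bd)
  opt <- adam_init(params)
  hist_epoch <- integer(0); hist_loss <- numeric(0); hist_acc <- numeric(0)

  epoch <- 0L
  repeat {
    epoch <- epoch + 1L
    ord <- sample.int(n)
    for (b0 in seq(1L, n, by = config$batch_size)) {
      idx <- ord[b0:min(b0 + config$batch_size - 1L, n)]
      fwd <- model_forward(terms, idx, params, config, n_ch,
                           training = TRUE)
      grad <- model_backward(fwd, terms, labels[idx], params, config)
      upd <- adam_step(opt, params, grad, config$learning_rate)
      params <- upd$params; opt <- upd$opt
    }
    fwd <- model_forward(terms, seq_len(n), params, config, n_ch,
                         training = FALSE)
    loss <- crgcn_loss(fwd$probs, labels, params, config$alpha)
    if (!is.finite(loss))
      stop("train_crgcn: loss diverged (non-finite) at epoch ", epoch)
    acc <- mean(max.col(fwd$probs) - 1L == labels)
    hist_epoch <- c(hist_epoch, epoch)
    hist_loss <- c(hist_loss, loss)
    hist_acc <- c(hist_acc, acc)
    if (verbose && epoch %% 50L == 0L)
      message(sprintf("epoch %d  loss %.5f  acc %.3f", epoch, loss, acc))
    if (!(loss > config$stop_threshold && epoch < config$max_epochs)) break
  }
  structure(list(params = params, config = config, graph = graph,
                 history = data.frame(epoch = hist_epoch, loss = hist_loss,
                                      train_accuracy = hist_acc)),
            class = "crgcn_model")
}

#' @export
print.crgcn_model <- function(x, ...) {
  h <- x$history
  cat("<crgcn_model> K = ", x$config$K, ", hidden = ",
      x$config$hidden_width, "; trained ", nrow(h), " epochs, final loss ",
      signif(utils::tail(h$loss, 1L), 5L), ", train accuracy ",
      signif(utils::tail(h$train_accuracy, 1L), 4L), "\n", sep = "")
  invisible(x)
}

#' Predict classes for new segments
#'
#' @param object a `crgcn_model`
#' @param values normalized feature array `segments x channels x bands`
#' @param type `"class"` (0/1) or `"prob"`
#' @param ... unused
#' @return integer vector or probability matrix
#' @export
predict.crgcn_model <- function(object, values, type = c("class", "prob"),
                                ...) {
  type <- match.arg(type)
  probs <- crgcn_forward(values, object$graph, object$params,
                         object$config, training = FALSE)
  if (type == "prob") probs else max.col(probs) - 1L
}

#' Save / load a model checkpoint
#'
#' Serializes the configuration echo and all parameter arrays.
#'
#' @param model a `crgcn_model`
#' @param path file path
#' @export
write_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "crgcn_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "crgcn_model"))
    stop("read_checkpoint: not a crgcn model checkpoint: ", path)
  m
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  zero_like <- function(p) if (is.list(p)) lapply(p, zero_like) else p * 0
  list(m = zero_like(unclass(params)[c("theta", "W", "b")]),
       v = zero_like(unclass(params)[c("theta", "W", "b")]),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(opt, params, grad, lr) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  upd1 <- function(m, g) b1 * m + (1 - b1) * g
  upd2 <- function(v, g) b2 * v + (1 - b2) * g^2
  corr1 <- 1 - b1^opt$t; corr2 <- 1 - b2^opt$t
  apply_one <- function(p, m, v) p - lr * (m / corr1) /
    (sqrt(v / corr2) + opt$eps)
  for (k in seq_along(params$theta)) {
    opt$m$theta[[k]] <- upd1(opt$m$theta[[k]], grad$theta[[k]])
    opt$v$theta[[k]] <- upd2(opt$v$theta[[k]], grad$theta[[k]])
    params$theta[[k]] <- apply_one(params$theta[[k]], opt$m$theta[[k]],
                                   opt$v$theta[[k]])
  }
  opt$m$W <- upd1(opt$m$W, grad$W); opt$v$W <- upd2(opt$v$W, grad$W)
  params$W <- apply_one(params$W, opt$m$W, opt$v$W)
  opt$m$b <- upd1(opt$m$b, grad$b); opt$v$b <- upd2(opt$v$b, grad$b)
  params$b <- apply_one(params$b, opt$m$b, opt$v$b)
  list(params = params, opt = opt)
}
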