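#' Graph Fourier transform and its inverse
#'
#' Projects a node signal onto the eigenbasis of the symmetric normalized
#' Laplacian: `X_hat = U^T X`; the inverse returns `U X_hat`.
#'
#' @param x N x d signal matrix (or length-N vector).
#' @param u orthonormal eigenvector matrix from [graph_spectra()].
#' @return transformed matrix of the same shape.
#' @export
graph_fourier <- function(x, u) {
  x <- as.matrix(x)
  if (nrow(x) != nrow(u)) stop("signal rows must match eigenvector rows")
  crossprod(u, x)
}

#' @rdname graph_fourier
#' @export
inverse_graph_fourier <- function(x, u) {
  x <- as.matrix(x)
  if (nrow(x) != ncol(u)) stop("signal rows must match eigenvector columns")
  u %*% x
}

#' Apply a spectral filter in the graph Fourier domain
#'
#' Computes `U diag(g(lambda)) U^T X`: the signal is transformed to the
#' spectral domain, each frequency component is scaled by the filter response
#' at its eigenvalue, and the result is transformed back.
#'
#' @param spectra a [graph_spectra()] object.
#' @param g filter response: a function of the eigenvalue, or a numeric
#'   vector of responses (one per eigenvalue, ascending order).
#' @param x N x d signal matrix.
#' @return filtered N x d matrix.
#' @export
spectral_filter_apply <- function(spectra, g, x) {
  x <- as.matrix(x)
  u <- spectra$eigenvectors
  if (nrow(x) != nrow(u)) stop("signal rows must match the graph size")
  resp <- if (is.function(g)) vapply(spectra$eigenvalues, g, numeric(1)) else as.numeric(g)
  if (length(resp) != length(spectra$eigenvalues)) {
    stop("filter response length must equal the number of eigenvalues")
  }
  u %*% (resp * crossprod(u, x))
}

#' Chebyshev polynomial spectral filter
#'
#' Evaluates `sum_k theta_k T_k(L_tilde) X` with
#' `L_tilde = 2 L_sym / lambda_max - I` through the three-term recursion
#' `T_k(x) = 2 x T_{k-1}(x) - T_{k-2}(x)`, using only matrix-vector products
#' — the eigendecomposition is never formed.
#'
#' @param lsym symmetric normalized Laplacian (or a [graph_spectra()], whose
#'   `normalized_laplacian` is used).
#' @param theta coefficients `theta_0..theta_K`.
#' @param lambda_max largest eigenvalue bound used to rescale the spectrum
#'   into `[-1, 1]` (> 0).
#' @param x N x d signal matrix.
#' @return filtered N x d matrix.
#' @export
chebyshev_filter <- function(lsym, theta, lambda_max, x) {
  if (inherits(lsym, "graph_spectra")) lsym <- lsym$normalized_laplacian
  if (lambda_max <= 0) stop("lambda_max must be positive")
  x <- as.matrix(x)
  n <- nrow(lsym)
  if (nrow(x) != n) stop("signal rows must match the graph size")
  lt <- (2 / lambda_max) * lsym - diag(n)
  t_prev <- x          # T_0(L~) X
  out <- theta[1] * t_prev
  if (length(theta) >= 2) {
    t_cur <- lt %*% x  # T_1(L~) X
    out <- out + theta[2] * t_cur
    if (length(theta) >= 3) {
      for (k in 3:length(theta)) {
        t_next <- 2 * (lt %*% t_cur) - t_prev
        out <- out + theta[k] * t_next
        t_prev <- t_cur
        t_cur <- t_next
      }
    }
  }
  out
}

#' Renormalized propagation matrix of the simplified GCN layer
#'
#' `P = D~^(-1/2) A~ D~^(-1/2)` with self-loops `A~ = I + A` and
#' `D~_ii = sum_j A~_ij`. The self-loop guarantees every degree is >= 1, and
#' `P` is symmetric with spectrum in `[-1, 1]`.
#'
#' @param a symmetric, hollow, non-negative adjacency matrix (or a
#'   [brain_graph()]).
#' @return N x N propagation matrix.
#' @export
propagation_matrix <- function(a) {
  a <- graph_adjacency(a)
  if (any(a < 0)) stop("adjacency must be non-negative")
  at <- a + diag(nrow(a))
  dis <- 1 / sqrt(rowSums(at))
  (dis * at) %*% diag(dis, nrow(a))
}

#' One simplified spectral graph-convolution layer
#'
#' `H = f(D~^(-1/2) A~ D~^(-1/2) X Theta)`: node features are averaged over
#' renormalized neighborhoods (including the node itself), linearly mixed by
#' `Theta`, and passed through the activation.
#'
#' @param a adjacency matrix or [brain_graph()].
#' @param x N x d input feature matrix.
#' @param theta d x h weight matrix.
#' @param activation activation function `f` (default ReLU).
#' @return N x h output feature matrix.
#' @export
gcn_layer_forward <- function(a, x, theta, activation = function(z) pmax(z, 0)) {
  x <- as.matrix(x)
  p <- propagation_matrix(a)
  if (nrow(x) != nrow(p)) stop("feature rows must match the graph size")
  activation(p %*% x %*% theta)
}

#' Training configuration of the GCN classifier
#'
#' Defaults follow the reference training protocol: three convolutional
#' layers of 92 units, ReLU with batch normalization between layers, dropout
#' 0.65 after each layer, global mean pooling, Adam with learning rate 0.001
#' and weight decay 0, cross-entropy loss, 100 epochs, and learning-rate
#' reduction on a validation-loss plateau with patience 10.
#'
#' @param hidden hidden width of every convolutional layer.
#' @param n_layers number of convolutional layers.
#' @param dropout dropout rate in `[0, 1)`.
#' @param learning_rate initial Adam learning rate.
#' @param weight_decay L2 penalty added to the gradients.
#' @param epochs training epochs.
#' @param batch_size mini-batch size (the reference grid is 16/32/48/64).
#' @param plateau_patience epochs without validation improvement before the
#'   learning rate is reduced.
#' @param plateau_factor multiplicative learning-rate decay on plateau.
#' @param min_lr learning-rate floor.
#' @param bn_momentum running-statistics momentum of batch normalization.
#' @param seed RNG seed controlling initialization, shuffling and dropout.
#' @return an object of class `gcn_config`.
#' @export
gcn_config <- function(hidden = 92L, n_layers = 3L, dropout = 0.65,
                       learning_rate = 0.001, weight_decay = 0,
                       epochs = 100L, batch_size = 16L,
                       plateau_patience = 10L, plateau_factor = 0.5,
                       min_lr = 1e-5, bn_momentum = 0.1, seed = 1L) {
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  if (batch_size < 1) stop("batch_size must be positive")
  if (n_layers < 1) stop("need at least one layer")
  structure(list(
    hidden = as.integer(hidden), n_layers = as.integer(n_layers),
    dropout = dropout, learning_rate = learning_rate,
    weight_decay = weight_decay, epochs = as.integer(epochs),
    batch_size = as.integer(batch_size),
    plateau_patience = as.integer(plateau_patience),
    plateau_factor = plateau_factor, min_lr = min_lr,
    bn_momentum = bn_momentum, seed = as.integer(seed)
  ), class = "gcn_config")
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

init_gcn_params <- function(d_in, hidden, n_layers, n_classes) {
  w <- vector("list", n_layers)
  gamma <- vector("list", n_layers)
  beta <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    w[[l]] <- glorot(if (l == 1) d_in else hidden, hidden)
    gamma[[l]] <- rep(1, hidden)
    beta[[l]] <- rep(0, hidden)
  }
  list(w = w, gamma = gamma, beta = beta,
       w_head = glorot(hidden, n_classes), b_head = rep(0, n_classes))
}

init_bn_state <- function(hidden, n_layers) {
  list(mean = replicate(n_layers, rep(0, hidden), simplify = FALSE),
       var = replicate(n_layers, rep(1, hidden), simplify = FALSE))
}

BN_EPS <- 1e-5

# Forward pass over a list of samples (each list(p = propagation matrix,
# x = node features)). mode "train" uses batch statistics and dropout and
# returns caches for backprop; "eval" uses running statistics, no dropout.
gcn_forward <- function(samples, params, bn_state, config, mode = "eval") {
  n_layers <- config$n_layers
  ns <- vapply(samples, function(s) nrow(s$x), integer(1))
  ends <- cumsum(ns)
  starts <- ends - ns + 1L
  b <- length(samples)
  h <- do.call(rbind, lapply(samples, function(s) as.matrix(s$x)))
  cache <- if (mode == "train") list(layers = vector("list", n_layers)) else NULL

  for (l in seq_len(n_layers)) {
    h_in <- h
    ph <- matrix(0, nrow(h), ncol(h))
    for (g in seq_len(b)) {
      idx <- starts[g]:ends[g]
      ph[idx, ] <- samples[[g]]$p %*% h_in[idx, , drop = FALSE]
    }
    z <- ph %*% params$w[[l]]
    if (mode == "train") {
      mu <- colMeans(z)
      vr <- colMeans(z^2) - mu^2
      vr[vr < 0] <- 0
      bn_state$mean[[l]] <- (1 - config$bn_momentum) * bn_state$mean[[l]] +
        config$bn_momentum * mu
      bn_state$var[[l]] <- (1 - config$bn_momentum) * bn_state$var[[l]] +
        config$bn_momentum * vr
    } else {
      mu <- bn_state$mean[[l]]
      vr <- bn_state$var[[l]]
    }
    istd <- 1 / sqrt(vr + BN_EPS)
    xhat <- sweep(z, 2, mu, "-") %*% diag(istd, ncol(z))
    y <- sweep(xhat %*% diag(params$gamma[[l]], ncol(z)), 2,
               params$beta[[l]], "+")
    act <- pmax(y, 0)
    if (mode == "train" && config$dropout > 0) {
      mask <- matrix(stats::runif(length(act)) >= config$dropout,
                     nrow(act), ncol(act)) / (1 - config$dropout)
      h <- act * mask
    } else {
      mask <- NULL
      h <- act
    }
    if (anyNA(h) || !all(is.finite(h))) {
      stop(sprintf("non-finite activations in layer %d", l))
    }
    if (mode == "train") {
      cache$layers[[l]] <- list(ph = ph, xhat = xhat, istd = istd, y = y,
                                mask = mask)
    }
  }

  pooled <- do.call(rbind, lapply(seq_len(b), function(g) {
    colMeans(h[starts[g]:ends[g], , drop = FALSE])
  }))
  logits <- sweep(pooled %*% params$w_head, 2, params$b_head, "+")
  if (mode == "train") {
    cache$pooled <- pooled
    cache$ns <- ns
    cache$starts <- starts
    cache$ends <- ends
  }
  list(logits = logits, cache = cache, bn_state = bn_state)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

cross_entropy <- function(logits, y_idx) {
  p <- softmax_rows(logits)
  -mean(log(pmax(p[cbind(seq_len(nrow(p)), y_idx)], 1e-12)))
}

# Backward pass; returns gradients shaped like the parameter list.
gcn_backward <- function(samples, params, config, cache, logits, y_idx) {
  n_layers <- config$n_layers
  b <- length(samples)
  p_soft <- softmax_rows(logits)
  d_logits <- p_soft
  d_logits[cbind(seq_len(b), y_idx)] <- d_logits[cbind(seq_len(b), y_idx)] - 1
  d_logits <- d_logits / b

  grads <- list(w = vector("list", n_layers),
                gamma = vector("list", n_layers),
                beta = vector("list", n_layers))
  grads$w_head <- crossprod(cache$pooled, d_logits)
  grads$b_head <- colSums(d_logits)
  d_pooled <- d_logits %*% t(params$w_head)

  m_total <- sum(cache$ns)
  dh <- matrix(0, m_total, config$hidden)
  for (g in seq_len(b)) {
    idx <- cache$starts[g]:cache$ends[g]
    dh[idx, ] <- matrix(d_pooled[g, ] / cache$ns[g], length(idx),
                        config$hidden, byrow = TRUE)
  }

  for (l in rev(seq_len(n_layers))) {
    lc <- cache$layers[[l]]
    d_act <- if (is.null(lc$mask)) dh else dh * lc$mask
    d_y <- d_act * (lc$y > 0)
    grads$gamma[[l]] <- colSums(d_y * lc$xhat)
    grads$beta[[l]] <- colSums(d_y)
    d_xhat <- sweep(d_y, 2, params$gamma[[l]], "*")
    m <- nrow(d_xhat)
    sum_dxhat <- colSums(d_xhat)
    sum_dxhat_xhat <- colSums(d_xhat * lc$xhat)
    d_z <- sweep(
      m * d_xhat - matrix(sum_dxhat, m, length(sum_dxhat), byrow = TRUE) -
        lc$xhat * matrix(sum_dxhat_xhat, m, length(sum_dxhat_xhat), byrow = TRUE),
      2, lc$istd / m, "*")
    grads$w[[l]] <- crossprod(lc$ph, d_z)
    if (l > 1) {
      d_zw <- d_z %*% t(params$w[[l]])
      dh <- matrix(0, m_total, config$hidden)
      for (g in seq_len(b)) {
        idx <- cache$starts[g]:cache$ends[g]
        dh[idx, ] <- samples[[g]]$p %*% d_zw[idx, , drop = FALSE]
      }
    }
  }
  grads
}

# Adam state/update over the flat list of parameter arrays
adam_init <- function(params) {
  zeros <- function(x) {
    if (is.list(x)) lapply(x, zeros)
    else if (is.matrix(x)) matrix(0, nrow(x), ncol(x))
    else numeric(length(x))
  }
  list(m = zeros(params), v = zeros(params), t = 0)
}

adam_step <- function(params, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p
      out_m <- m
      out_v <- v
      for (i in seq_along(p)) {
        r <- walk(p[[i]], g[[i]], m[[i]], v[[i]])
        out_p[[i]] <- r$p
        out_m[[i]] <- r$m
        out_v[[i]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      g <- g + weight_decay * p
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^state$t)
      vhat <- v / (1 - beta2^state$t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

#' Prepare GCN inputs from graphs and node feature matrices
#'
#' Pairs each graph's renormalized propagation matrix with its node feature
#' matrix.
#'
#' @param graphs list of [brain_graph()] objects (or adjacency matrices).
#' @param features list of N x d node feature matrices, same order.
#' @return list of samples, each `list(p, x)`.
#' @export
prepare_gcn_inputs <- function(graphs, features) {
  if (length(graphs) != length(features)) {
    stop("graphs and features must have the same length")
  }
  d <- unique(vapply(features, ncol, integer(1)))
  if (length(d) != 1) stop("all feature matrices must share the same dimension")
  lapply(seq_along(graphs), function(i) {
    list(p = propagation_matrix(graphs[[i]]), x = as.matrix(features[[i]]))
  })
}

#' Fit the three-layer spectral GCN classifier
#'
#' Trains the graph classifier: stacked simplified spectral convolutions
#' (see [gcn_layer_forward()]), each followed by batch normalization, ReLU
#' and dropout, then global mean pooling and a linear softmax head. Training
#' minimizes cross-entropy with Adam over shuffled mini-batches; the learning
#' rate is multiplied by `plateau_factor` whenever the validation loss fails
#' to improve for `plateau_patience` epochs, and the returned model is the
#' parameter snapshot with the lowest validation loss.
#'
#' @param x training samples from [prepare_gcn_inputs()].
#' @param y training labels (integer or factor), one per sample.
#' @param val_x,val_y validation samples and labels (used for the plateau
#'   schedule and snapshot selection). Defaults to the training set when
#'   absent.
#' @param config a [gcn_config()].
#' @return an object of class `gcn` with the best parameter snapshot, batch
#'   normalization statistics, per-epoch training history, and label levels.
#' @export
fit_gcn <- function(x, y, val_x = NULL, val_y = NULL, config = gcn_config()) {
  if (length(x) == 0) stop("empty training set")
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (is.null(val_x)) {
    val_x <- x
    val_y <- y
  }
  y_f <- factor(y)
  levels_y <- levels(y_f)
  y_idx <- as.integer(y_f)
  vy_idx <- as.integer(factor(val_y, levels = levels_y))
  if (anyNA(vy_idx)) stop("validation labels outside the training label set")
  n_classes <- length(levels_y)
  d_in <- ncol(x[[1]]$x)

  set.seed(config$seed)
  params <- init_gcn_params(d_in, config$hidden, config$n_layers, n_classes)
  bn_state <- init_bn_state(config$hidden, config$n_layers)
  opt <- adam_init(params)
  lr <- config$learning_rate

  best <- list(val_loss = Inf, params = params, bn_state = bn_state, epoch = 0L)
  wait <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), lr = numeric(0))

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(length(x))
    batch_starts <- seq(1, length(x), by = config$batch_size)
    epoch_loss <- 0
    for (bs in batch_starts) {
      idx <- ord[bs:min(bs + config$batch_size - 1L, length(x))]
      fw <- gcn_forward(x[idx], params, bn_state, config, mode = "train")
      bn_state <- fw$bn_state
      loss <- cross_entropy(fw$logits, y_idx[idx])
      if (!is.finite(loss)) {
        stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch))
      }
      grads <- gcn_backward(x[idx], params, config, fw$cache, fw$logits,
                            y_idx[idx])
      st <- adam_step(params, grads, opt, lr, config$weight_decay)
      params <- st$params
      opt <- st$state
      epoch_loss <- epoch_loss + loss * length(idx)
    }
    train_loss <- epoch_loss / length(x)
    val_fw <- gcn_forward(val_x, params, bn_state, config, mode = "eval")
    val_loss <- cross_entropy(val_fw$logits, vy_idx)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = train_loss,
                                         val_loss = val_loss, lr = lr))
    if (val_loss < best$val_loss - 1e-10) {
      best <- list(val_loss = val_loss, params = params, bn_state = bn_state,
                   epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$plateau_patience) {
        lr <- max(lr * config$plateau_factor, config$min_lr)
        wait <- 0L
      }
    }
  }

  structure(list(
    params = best$params, bn_state = best$bn_state, config = config,
    levels = levels_y, d_in = d_in, history = history,
    best_epoch = best$epoch, best_val_loss = best$val_loss
  ), class = "gcn")
}

#' Predict task classes with a fitted GCN
#'
#' @param object a fitted [fit_gcn()] model.
#' @param newdata samples from [prepare_gcn_inputs()].
#' @param type `"class"` (predicted labels), `"prob"` (softmax
#'   probabilities) or `"logits"`.
#' @param ... unused.
#' @return predictions; eval mode (no dropout, running batch-norm
#'   statistics), so repeated calls are identical.
#' @export
predict.gcn <- function(object, newdata,
                        type = c("class", "prob", "logits"), ...) {
  type <- match.arg(type)
  fw <- gcn_forward(newdata, object$params, object$bn_state, object$config,
                    mode = "eval")
  switch(type,
    logits = fw$logits,
    prob = {
      p <- softmax_rows(fw$logits)
      colnames(p) <- object$levels
      p
    },
    class = {
      k <- max.col(fw$logits, ties.method = "first")
      out <- object$levels[k]
      if (!anyNA(suppressWarnings(as.integer(object$levels)))) {
        out <- as.integer(out)
      }
      out
    }
  )
}

#' @export
print.gcn <- function(x, ...) {
  cat(sprintf("gcn: %d conv layers x %d units, %d classes, input dim %d\n",
              x$config$n_layers, x$config$hidden, length(x$levels), x$d_in))
  cat(sprintf("  best epoch %d (validation loss %.4f) of %d\n",
              x$best_epoch, x$best_val_loss, x$config$epochs))
  invisible(x)
}

#' @export
summary.gcn <- function(object, ...) {
  n_par <- sum(vapply(
    unlist(object$params, recursive = TRUE, use.names = FALSE),
    length, integer(1)))
  cat(sprintf("GCN classifier (%d parameters)\n", n_par))
  print(object)
  cat(sprintf("  lr %.4g, dropout %.2f, batch %d, weight decay %.3g\n",
              object$config$learning_rate, object$config$dropout,
              object$config$batch_size, object$config$weight_decay))
  h <- object$history
  cat(sprintf("  final train/val loss: %.4f / %.4f\n",
              h$train_loss[nrow(h)], h$val_loss[nrow(h)]))
  invisible(object)
}

#' @export
coef.gcn <- function(object, ...) object$params

#' Plot the training history of a fitted GCN
#'
#' @param x a fitted [fit_gcn()] model.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.gcn <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "cross-entropy loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Save / load a fitted GCN as versioned JSON
#'
#' Serializes config, parameters, batch-norm state and training history to a
#' single JSON checkpoint.
#'
#' @param object a fitted [fit_gcn()] model.
#' @param path file path.
#' @export
save_gcn <- function(object, path) {
  payload <- list(
    format = "conndecode-gcn", version = 1L,
    config = unclass(object$config), levels = object$levels,
    d_in = object$d_in, best_epoch = object$best_epoch,
    best_val_loss = object$best_val_loss,
    params = object$params, bn_state = object$bn_state,
    history = object$history
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_gcn
#' @export
load_gcn <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(p$format, "conndecode-gcn")) stop("not a conndecode GCN checkpoint")
  num_vec <- function(x) as.numeric(unlist(x, use.names = FALSE))
  num_mat <- function(x) { # serialized row-wise as a list of rows
    matrix(num_vec(x), nrow = length(x), byrow = TRUE)
  }
  params <- list(
    w = lapply(p$params$w, num_mat),
    gamma = lapply(p$params$gamma, num_vec),
    beta = lapply(p$params$beta, num_vec),
    w_head = num_mat(p$params$w_head),
    b_head = num_vec(p$params$b_head)
  )
  bn_state <- list(mean = lapply(p$bn_state$mean, num_vec),
                   var = lapply(p$bn_state$var, num_vec))
  cfg <- lapply(p$config, function(v) if (is.list(v)) unlist(v) else v)
  class(cfg) <- "gcn_config"
  hist <- as.data.frame(lapply(
    c("epoch", "train_loss", "val_loss", "lr"),
    function(nm) num_vec(lapply(p$history, `[[`, nm))
  ))
  names(hist) <- c("epoch", "train_loss", "val_loss", "lr")
  structure(list(
    params = params, bn_state = bn_state, config = cfg,
    levels = unlist(p$levels), d_in = p$d_in, history = hist,
    best_epoch = p$best_epoch, best_val_loss = p$best_val_loss
  ), class = "gcn")
}
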