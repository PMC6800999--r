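# Minimal fully-connected feed-forward regressor: rectified hidden layers,
# sigmoid output, mean-squared-error objective, full-batch Adam with early
# stopping on a validation set. Deliberately small: inputs here are a few
# dozen feature columns and a few hundred rows per dataset.

.mlp_init <- function(p, hidden, seed) {
  set.seed(seed)
  dims <- c(p, hidden, 1L)
  W <- list(); b <- list()
  for (l in seq_len(length(dims) - 1L)) {
    W[[l]] <- matrix(rnorm(dims[l] * dims[l + 1L], sd = sqrt(2 / dims[l])),
                     dims[l], dims[l + 1L])
    b[[l]] <- rep(0, dims[l + 1L])
  }
  list(W = W, b = b, hidden = hidden)
}

.mlp_forward <- function(net, X) {
  A <- list(X)
  Z <- list()
  nl <- length(net$W)
  for (l in seq_len(nl)) {
    Z[[l]] <- sweep(A[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    A[[l + 1L]] <- if (l < nl) pmax(Z[[l]], 0) else 1 / (1 + exp(-Z[[l]]))
  }
  list(A = A, Z = Z, out = as.numeric(A[[nl + 1L]]))
}

#' @keywords internal
mlpPredict <- function(net, X) .mlp_forward(net, as.matrix(X))$out

#' @keywords internal
mlpTrain <- function(X, y, hidden = 16, Xval = NULL, yval = NULL,
                     epochs = 300, patience = 20, lr = 0.02, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  net <- .mlp_init(ncol(X), hidden, seed)
  nl <- length(net$W)
  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mb <- lapply(net$b, function(b) b * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- list(net = net, val = Inf)
  wait <- 0L
  has_val <- !is.null(Xval) && length(yval) > 0
  if (has_val) Xval <- as.matrix(Xval)
  for (ep in seq_len(epochs)) {
    fw <- .mlp_forward(net, X)
    out <- fw$out
    # gradient of mean((out - y)^2) through the sigmoid output
    delta <- matrix(2 * (out - y) / n * out * (1 - out), n, 1)
    for (l in rev(seq_len(nl))) {
      gW <- t(fw$A[[l]]) %*% delta
      gb <- colSums(delta)
      if (l > 1L)
        delta <- (delta %*% t(net$W[[l]])) * (fw$Z[[l - 1L]] > 0)
      mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
      vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
      mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb
      vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb^2
      cm <- 1 - b1^ep; cv <- 1 - b2^ep
      net$W[[l]] <- net$W[[l]] - lr * (mW[[l]] / cm) /
        (sqrt(vW[[l]] / cv) + eps)
      net$b[[l]] <- net$b[[l]] - lr * (mb[[l]] / cm) /
        (sqrt(vb[[l]] / cv) + eps)
    }
    crit <- if (has_val) mean((mlpPredict(net, Xval) - yval)^2)
            else mean((out - y)^2)
    if (crit < best$val - 1e-7) {
      best <- list(net = net, val = crit)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  best$net
}
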