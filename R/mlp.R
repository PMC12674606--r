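# Minimal feed-forward network engine used for both the meta-learner
# (hidden layers 128-64-32-16) and the NN base classifier. Fully connected
# ReLU layers with inverted dropout, softmax output, cross-entropy loss,
# Adam updates, and class-weighted random batch sampling (each example drawn
# with probability inversely proportional to its class frequency; one epoch
# = n draws). Pure matrix arithmetic; deterministic given the seed.

mlp_init <- function(n_in, hidden, n_out, seed) {
  sizes <- c(n_in, hidden, n_out)
  with_seed(seed, {
    W <- vector("list", length(sizes) - 1)
    b <- vector("list", length(sizes) - 1)
    for (l in seq_along(W)) {
      # He initialization, suited to ReLU units
      W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1], 0, sqrt(2 / sizes[l])),
                       sizes[l], sizes[l + 1])
      b[[l]] <- rep(0, sizes[l + 1])
    }
    list(W = W, b = b)
  })
}

mlp_forward <- function(par, x, dropout = 0, training = FALSE) {
  L <- length(par$W)
  a <- x
  cache <- list(a)
  for (l in seq_len(L)) {
    z <- a %*% par$W[[l]] + rep(par$b[[l]], each = nrow(a))
    if (l < L) {
      a <- pmax(z, 0)
      if (training && dropout > 0) {
        keep <- matrix(stats::runif(length(a)) >= dropout, nrow(a), ncol(a))
        a <- a * keep / (1 - dropout)
      }
    } else {
      # softmax, stabilized by row max
      z <- z - apply(z, 1, max)
      e <- exp(z)
      a <- e / rowSums(e)
    }
    cache[[l + 1]] <- a
  }
  list(prob = a, cache = cache)
}

# One Adam step on a batch; returns updated parameters and moments.
mlp_step <- function(par, adam, xb, yb_onehot, dropout, lr, t) {
  L <- length(par$W)
  fw <- mlp_forward(par, xb, dropout = dropout, training = TRUE)
  nb <- nrow(xb)
  delta <- (fw$prob - yb_onehot) / nb  # softmax + cross-entropy gradient
  gW <- vector("list", L)
  gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    a_prev <- fw$cache[[l]]
    gW[[l]] <- crossprod(a_prev, delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(par$W[[l]])) * (fw$cache[[l]] > 0)
    }
  }
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (l in seq_len(L)) {
    adam$mW[[l]] <- b1 * adam$mW[[l]] + (1 - b1) * gW[[l]]
    adam$vW[[l]] <- b2 * adam$vW[[l]] + (1 - b2) * gW[[l]]^2
    adam$mb[[l]] <- b1 * adam$mb[[l]] + (1 - b1) * gb[[l]]
    adam$vb[[l]] <- b2 * adam$vb[[l]] + (1 - b2) * gb[[l]]^2
    mW_hat <- adam$mW[[l]] / (1 - b1^t)
    vW_hat <- adam$vW[[l]] / (1 - b2^t)
    mb_hat <- adam$mb[[l]] / (1 - b1^t)
    vb_hat <- adam$vb[[l]] / (1 - b2^t)
    par$W[[l]] <- par$W[[l]] - lr * mW_hat / (sqrt(vW_hat) + eps)
    par$b[[l]] <- par$b[[l]] - lr * mb_hat / (sqrt(vb_hat) + eps)
  }
  list(par = par, adam = adam)
}

# Fit the network. x: numeric matrix; y: factor. Inputs are z-scored with
# training statistics kept in the model (constant columns get scale 1).
mlp_fit <- function(x, y, hidden = c(128, 64, 32, 16), epochs = 1000,
                    batch_size = 64, lr = 1e-4, dropout = 0.2, seed = 1,
                    class_weighted = TRUE) {
  if (any(!is.finite(x))) stopf("non-finite values in network input")
  y <- droplevels(as.factor(y))
  n <- nrow(x)
  C <- nlevels(y)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  onehot <- diag(C)[as.integer(y), , drop = FALSE]
  freq <- table(y)[as.integer(y)]
  w <- if (class_weighted) as.numeric(1 / freq) else rep(1, n)
  par <- mlp_init(ncol(x), hidden, C, derive_seed(seed, 1))
  adam <- list(mW = lapply(par$W, function(m) m * 0),
               vW = lapply(par$W, function(m) m * 0),
               mb = lapply(par$b, function(v) v * 0),
               vb = lapply(par$b, function(v) v * 0))
  losses <- numeric(epochs)
  t_step <- 0
  with_seed(derive_seed(seed, 2), {
    for (ep in seq_len(epochs)) {
      idx <- sample.int(n, n, replace = TRUE, prob = w)
      starts <- seq(1, n, by = batch_size)
      for (s in starts) {
        bi <- idx[s:min(s + batch_size - 1, n)]
        t_step <- t_step + 1
        st <- mlp_step(par, adam, xs[bi, , drop = FALSE],
                       onehot[bi, , drop = FALSE], dropout, lr, t_step)
        par <- st$par
        adam <- st$adam
      }
      if (ep %% max(1, epochs %/% 100) == 0 || ep == epochs) {
        p <- mlp_forward(par, xs)$prob
        losses[ep] <- -mean(log(pmax(p[cbind(seq_len(n), as.integer(y))], 1e-12)))
      }
    }
  })
  structure(list(par = par, center = center, scale = scale, levels = levels(y),
                 hidden = hidden, dropout = dropout,
                 loss_trace = losses[losses > 0]),
            class = "rps_mlp")
}

# Per-class probability matrix (rows sum to 1), columns = training levels.
mlp_predict <- function(model, x) {
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  p <- mlp_forward(model$par, xs, training = FALSE)$prob
  colnames(p) <- model$levels
  rownames(p) <- rownames(x)
  p
}
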