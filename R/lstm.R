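# Minimal batched LSTM with backpropagation through time, written with plain
# matrix algebra. Gate layout in the packed weight matrix W ((p + H) x 4H)
# is [input, forget, candidate, output]; the forget-gate bias starts at +1.

sigm <- function(x) 1 / (1 + exp(-x))

lstm_init <- function(input_dim, hidden, n_class) {
  p <- input_dim; H <- hidden
  sc_in <- 1 / sqrt(p + H)
  W <- matrix(rnorm((p + H) * 4L * H, sd = sc_in), p + H, 4L * H)
  b <- rep(0, 4L * H)
  b[(H + 1L):(2L * H)] <- 1
  W_out <- matrix(rnorm(H * n_class, sd = 1 / sqrt(H)), H, n_class)
  b_out <- rep(0, n_class)
  list(W = W, b = b, W_out = W_out, b_out = b_out, p = p, H = H, C = n_class)
}

# x: array (N, T, p). The readout feature is the temporal mean of the
# hidden states (mean pooling), so transient cues anywhere in the window
# reach the dense layer without having to survive in the last state.
lstm_forward <- function(par, x, keep_cache = FALSE) {
  N <- dim(x)[1L]; T_ <- dim(x)[2L]; H <- par$H
  h <- matrix(0, N, H); c <- matrix(0, N, H)
  hsum <- matrix(0, N, H)
  cache <- if (keep_cache) vector("list", T_) else NULL
  for (s in seq_len(T_)) {
    xs <- matrix(x[, s, ], N)
    Z <- cbind(xs, h) %*% par$W
    Z <- sweep(Z, 2L, par$b, "+")
    ig <- sigm(Z[, 1:H, drop = FALSE])
    fg <- sigm(Z[, (H + 1L):(2L * H), drop = FALSE])
    gg <- tanh(Z[, (2L * H + 1L):(3L * H), drop = FALSE])
    og <- sigm(Z[, (3L * H + 1L):(4L * H), drop = FALSE])
    c_new <- fg * c + ig * gg
    tc <- tanh(c_new)
    h_new <- og * tc
    if (keep_cache)
      cache[[s]] <- list(xs = xs, h_prev = h, c_prev = c, i = ig, f = fg,
                         g = gg, o = og, tc = tc)
    h <- h_new; c <- c_new
    hsum <- hsum + h
  }
  list(h = hsum / T_, c = c, cache = cache)
}

# dh_pool: gradient wrt the mean-pooled hidden state (N x H); each timestep
# receives dh_pool / T plus the recurrent gradient. Returns packed gradients.
lstm_backward <- function(par, cache, dh_pool) {
  H <- par$H; p <- par$p
  dh_each <- dh_pool / length(cache)
  dh <- dh_each
  dW <- matrix(0, nrow(par$W), ncol(par$W))
  db <- rep(0, length(par$b))
  dc <- matrix(0, nrow(dh), H)
  for (s in rev(seq_along(cache))) {
    cc <- cache[[s]]
    do_ <- dh * cc$tc
    dc <- dc + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    df <- dc * cc$c_prev
    dg <- dc * cc$i
    dZ <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    inp <- cbind(cc$xs, cc$h_prev)
    dW <- dW + crossprod(inp, dZ)
    db <- db + colSums(dZ)
    dinp <- dZ %*% t(par$W)
    dh <- dinp[, (p + 1L):(p + H), drop = FALSE] + dh_each
    dc <- dc * cc$f
  }
  list(dW = dW, db = db)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# one forward + backward pass over a batch; returns loss and gradients
lstm_loss_grad <- function(par, x, y_onehot, drop_mask = NULL) {
  fw <- lstm_forward(par, x, keep_cache = TRUE)
  h <- fw$h
  hd <- if (is.null(drop_mask)) h else h * drop_mask
  logits <- sweep(hd %*% par$W_out, 2L, par$b_out, "+")
  probs <- softmax_rows(logits)
  N <- nrow(h)
  loss <- -mean(log(pmax(probs[y_onehot == 1], 1e-12)))
  dlogits <- (probs - y_onehot) / N
  dW_out <- crossprod(hd, dlogits)
  db_out <- colSums(dlogits)
  dh <- dlogits %*% t(par$W_out)
  if (!is.null(drop_mask)) dh <- dh * drop_mask
  g <- lstm_backward(par, fw$cache, dh)
  list(loss = loss, probs = probs,
       grads = list(W = g$dW, b = g$db, W_out = dW_out, b_out = db_out))
}

adam_state <- function(par) {
  lapply(par[c("W", "b", "W_out", "b_out")],
         function(v) list(m = v * 0, v = v * 0))
}

adam_update <- function(par, grads, st, lr, t, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8, clip = 5) {
  # global gradient-norm clipping stabilises the long-sequence BPTT
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1L))))
  if (gn > clip) grads <- lapply(grads, function(g) g * clip / gn)
  for (nm in names(grads)) {
    st[[nm]]$m <- beta1 * st[[nm]]$m + (1 - beta1) * grads[[nm]]
    st[[nm]]$v <- beta2 * st[[nm]]$v + (1 - beta2) * grads[[nm]]^2
    mhat <- st[[nm]]$m / (1 - beta1^t)
    vhat <- st[[nm]]$v / (1 - beta2^t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, st = st)
}
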