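# Single-time-step LSTM regressor, trained full-batch with Adam.
#
# Each feature vector is presented to the cell as a one-step sequence with
# zero initial state, so the recurrence collapses to a closed-form gated
# map: c = sigmoid(Zi) * tanh(Zg), h = sigmoid(Zo) * tanh(c), with a linear
# read-out on h. The forget gate is computed for completeness but multiplies
# the zero initial cell state, so it cannot influence the output. Gradients
# below are exact (verified against numerical differentiation in the tests).

sigmoid <- function(z) 1 / (1 + exp(-z))

lstm_init <- function(d, hidden, seed) {
  set.seed(seed)
  H <- hidden
  list(
    W = matrix(stats::runif(d * 4 * H, -0.5, 0.5) / sqrt(d), d, 4 * H),
    b = numeric(4 * H),
    wy = stats::runif(H, -0.5, 0.5) / sqrt(H),
    by = 0,
    H = H, d = d
  )
}

lstm_forward <- function(par, x) {
  H <- par$H
  Z <- sweep(x %*% par$W, 2, par$b, "+")
  i <- sigmoid(Z[, 1:H, drop = FALSE])
  o <- sigmoid(Z[, (2 * H + 1):(3 * H), drop = FALSE])
  g <- tanh(Z[, (3 * H + 1):(4 * H), drop = FALSE])
  cc <- i * g
  tc_ <- tanh(cc)
  h <- o * tc_
  yhat <- as.numeric(h %*% par$wy) + par$by
  list(i = i, o = o, g = g, tc_ = tc_, h = h, yhat = yhat)
}

lstm_grad <- function(par, x, y, fw) {
  n <- nrow(x); H <- par$H
  dyhat <- 2 * (fw$yhat - y) / n
  dwy <- as.numeric(crossprod(fw$h, dyhat))
  dby <- sum(dyhat)
  dh <- tcrossprod(dyhat, par$wy)              # n x H
  do_ <- dh * fw$tc_
  dc <- dh * fw$o * (1 - fw$tc_^2)
  di <- dc * fw$g
  dg <- dc * fw$i
  dZ <- matrix(0, n, 4 * H)
  dZ[, 1:H] <- di * fw$i * (1 - fw$i)
  dZ[, (2 * H + 1):(3 * H)] <- do_ * fw$o * (1 - fw$o)
  dZ[, (3 * H + 1):(4 * H)] <- dg * (1 - fw$g^2)
  list(W = crossprod(x, dZ), b = colSums(dZ), wy = dwy, by = dby)
}

lstm_loss <- function(par, x, y) mean((lstm_forward(par, x)$yhat - y)^2)

adam_state <- function(par) {
  lapply(par[c("W", "b", "wy", "by")], function(p) list(m = p * 0, v = p * 0))
}

lstm_train <- function(x, y, hidden = 140L, epochs = 500L, lr = 0.01, seed = 1L) {
  x <- as.matrix(x)
  par <- lstm_init(ncol(x), hidden, seed)
  st <- adam_state(par)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (t in seq_len(epochs)) {
    fw <- lstm_forward(par, x)
    gr <- lstm_grad(par, x, y, fw)
    for (nm in names(st)) {
      st[[nm]]$m <- b1 * st[[nm]]$m + (1 - b1) * gr[[nm]]
      st[[nm]]$v <- b2 * st[[nm]]$v + (1 - b2) * gr[[nm]]^2
      mhat <- st[[nm]]$m / (1 - b1^t)
      vhat <- st[[nm]]$v / (1 - b2^t)
      par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  par
}

lstm_predict <- function(par, x) {
  lstm_forward(par, as.matrix(x))$yhat
}
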