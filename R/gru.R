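# Gated recurrent unit layer with manual backpropagation through time.
# All three networks of the model are built from this one cell, so its
# gradients are verified against finite differences in the test suite.
#
# Cell (n = batch rows, x: n x in, h: n x hidden):
#   r = sigmoid(x Wxr + h Whr + br)          reset gate
#   u = sigmoid(x Wxu + h Whu + bu)          update gate
#   c = tanh(x Wxc + (r * h) Whc + bc)       candidate state
#   h' = (1 - u) * c + u * h
# Padded positions (t > length) carry the hidden state through unchanged.

sigmoid <- function(x) 1 / (1 + exp(-x))

gru_init <- function(input_size, hidden_size, rng_scale = NULL) {
  k <- if (is.null(rng_scale)) 1 / sqrt(hidden_size) else rng_scale
  rmat <- function(nr, nc) matrix(stats::runif(nr * nc, -k, k), nr, nc)
  list(
    Wxr = rmat(input_size, hidden_size), Whr = rmat(hidden_size, hidden_size),
    br = matrix(0, 1, hidden_size),
    Wxu = rmat(input_size, hidden_size), Whu = rmat(hidden_size, hidden_size),
    bu = matrix(0, 1, hidden_size),
    Wxc = rmat(input_size, hidden_size), Whc = rmat(hidden_size, hidden_size),
    bc = matrix(0, 1, hidden_size)
  )
}

gru_cell_forward <- function(p, x, h) {
  r <- sigmoid(add_bias(x %*% p$Wxr + h %*% p$Whr, p$br))
  u <- sigmoid(add_bias(x %*% p$Wxu + h %*% p$Whu, p$bu))
  c <- tanh(add_bias(x %*% p$Wxc + (r * h) %*% p$Whc, p$bc))
  hn <- (1 - u) * c + u * h
  list(h = hn, r = r, u = u, c = c)
}

# X: list of T matrices (n x in); lengths: integer n; h0: n x hidden or NULL.
# Returns final state (n x hidden), per-step states, and the cache needed
# for the backward pass.
gru_forward <- function(p, X, lengths, h0 = NULL) {
  n <- nrow(X[[1]])
  hidden <- ncol(p$Whr)
  h <- if (is.null(h0)) matrix(0, n, hidden) else h0
  Tn <- length(X)
  steps <- vector("list", Tn)
  hs <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    st <- gru_cell_forward(p, X[[t]], h)
    m <- as.numeric(lengths >= t)
    hn <- st$h * m + h * (1 - m)
    steps[[t]] <- list(x = X[[t]], hprev = h, r = st$r, u = st$u, c = st$c,
                       m = m)
    h <- hn
    hs[[t]] <- h
  }
  list(h_final = h, hs = hs, steps = steps, lengths = lengths)
}

gru_grad_zero <- function(p) lapply(p, function(w) w * 0)

# dh_steps: NULL or list of T (n x hidden) gradients applied to the state
# emitted at each step; dh_final: gradient on the final state (n x hidden)
# or NULL. Returns parameter gradients, per-step input gradients dX, and
# the gradient on the initial state dh0.
gru_backward <- function(p, fwd, dh_steps = NULL, dh_final = NULL,
                         need_dx = FALSE) {
  steps <- fwd$steps
  Tn <- length(steps)
  n <- nrow(steps[[1]]$x)
  hidden <- ncol(p$Whr)
  g <- gru_grad_zero(p)
  dX <- if (need_dx) vector("list", Tn) else NULL
  dh <- if (is.null(dh_final)) matrix(0, n, hidden) else dh_final
  for (t in rev(seq_len(Tn))) {
    if (!is.null(dh_steps) && !is.null(dh_steps[[t]])) dh <- dh + dh_steps[[t]]
    s <- steps[[t]]
    dact <- dh * s$m          # gradient entering the cell (active rows)
    dcarry <- dh * (1 - s$m)  # padded rows: state passed through
    du <- dact * (s$hprev - s$c)
    dc <- dact * (1 - s$u)
    dhprev <- dact * s$u
    dc_pre <- dc * (1 - s$c^2)
    g$Wxc <- g$Wxc + crossprod(s$x, dc_pre)
    g$Whc <- g$Whc + crossprod(s$r * s$hprev, dc_pre)
    g$bc <- g$bc + colSums(dc_pre)
    drh <- dc_pre %*% t(p$Whc)
    dr <- drh * s$hprev
    dhprev <- dhprev + drh * s$r
    dr_pre <- dr * s$r * (1 - s$r)
    du_pre <- du * s$u * (1 - s$u)
    g$Wxr <- g$Wxr + crossprod(s$x, dr_pre)
    g$Whr <- g$Whr + crossprod(s$hprev, dr_pre)
    g$br <- g$br + colSums(dr_pre)
    g$Wxu <- g$Wxu + crossprod(s$x, du_pre)
    g$Whu <- g$Whu + crossprod(s$hprev, du_pre)
    g$bu <- g$bu + colSums(du_pre)
    dhprev <- dhprev + dr_pre %*% t(p$Whr) + du_pre %*% t(p$Whu)
    if (need_dx) {
      dX[[t]] <- dc_pre %*% t(p$Wxc) + dr_pre %*% t(p$Wxr) +
        du_pre %*% t(p$Wxu)
    }
    dh <- dhprev + dcarry
  }
  list(grads = g, dX = dX, dh0 = dh)
}

add_bias <- function(m, b) m + rep(b, each = nrow(m))

# Recursive helpers over nested parameter lists (used by Adam and the
# gradient accumulators).
param_map <- function(f, a) {
  if (is.list(a)) {
    out <- lapply(a, function(x) param_map(f, x))
    names(out) <- names(a)
    out
  } else f(a)
}

param_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- mapply(function(x, y) param_map2(f, x, y), a, b, SIMPLIFY = FALSE)
    names(out) <- names(a)
    out
  } else f(a, b)
}

param_flatten <- function(a) {
  if (is.list(a)) unlist(lapply(a, param_flatten), use.names = FALSE)
  else as.numeric(a)
}
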