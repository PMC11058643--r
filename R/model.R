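#' Model configuration
#'
#' Collects the hyperparameters of the predictor-encoder-decoder model.
#' Defaults follow the reference training setup where one is stated
#' (hidden size 250 per GRU, Adam learning rate 0.001, 300 epochs,
#' patience-1 early stopping) and conventional conditional-VAE choices
#' elsewhere.
#'
#' @param hidden_size GRU hidden dimension (each of the three networks).
#' @param latent_dim Dimension of the latent code z.
#' @param properties Character vector of conditioning property names.
#' @param max_len Maximum token count per SMILES (terminator included).
#' @param learning_rate Adam step size.
#' @param max_epochs Training epoch budget.
#' @param batch_size Minibatch size.
#' @param beta Weight of the predictor mean-squared-error term in the loss.
#' @param patience Early stopping patience in epochs (validation loss may
#'   worsen this many consecutive epochs before training halts and the best
#'   parameters are restored). `Inf` disables early stopping.
#' @param val_fraction Fraction of the corpus held out for validation; 0
#'   disables the split (and with it early stopping).
#' @param grad_clip Global gradient-norm clip; `Inf` disables.
#' @param seed Integer seed controlling initialization and training noise.
#' @return A `cvae_config` list.
#' @export
cvae_config <- function(hidden_size = 250L, latent_dim = 100L,
                       properties = c("logP", "MolWt", "QED"),
                       max_len = 120L, learning_rate = 0.001,
                       max_epochs = 300L, batch_size = 64L, beta = 1.0,
                       patience = 1L, val_fraction = 0.05, grad_clip = 5,
                       seed = 1L) {
  stopifnot(hidden_size > 0, latent_dim > 0, length(properties) > 0,
            max_len > 1, learning_rate > 0, max_epochs >= 0, beta >= 0,
            val_fraction >= 0, val_fraction < 1)
  structure(list(
    hidden_size = as.integer(hidden_size), latent_dim = as.integer(latent_dim),
    properties = properties, property_dim = length(properties),
    max_len = as.integer(max_len), learning_rate = learning_rate,
    max_epochs = as.integer(max_epochs), batch_size = as.integer(batch_size),
    beta = beta, patience = patience, val_fraction = val_fraction,
    grad_clip = grad_clip, seed = as.integer(seed)
  ), class = "cvae_config")
}

# Parameter initialization. The predictor and encoder are bidirectional
# (one GRU per direction, final states of both directions concatenated);
# the decoder is unidirectional with its initial state set by a learned
# affine map of [y, z], and [y, z] concatenated onto every step input.
cvae_init <- function(vocab, config, prop_stats) {
  stopifnot(inherits(vocab, "token_vocab"), inherits(config, "cvae_config"),
            inherits(prop_stats, "prop_stats"))
  stopifnot(identical(prop_stats$names, config$properties))
  V <- vocab_size(vocab)
  H <- config$hidden_size
  L <- config$latent_dim
  P <- config$property_dim
  set.seed(config$seed)
  k <- function(fan_in) 1 / sqrt(fan_in)
  rmat <- function(nr, nc) matrix(stats::runif(nr * nc, -k(nr), k(nr)), nr, nc)
  params <- list(
    pred = list(
      fwd = gru_init(V, H), bwd = gru_init(V, H),
      W_mu = rmat(2 * H, P), b_mu = matrix(0, 1, P),
      W_lv = rmat(2 * H, P), b_lv = matrix(0, 1, P)
    ),
    enc = list(
      fwd = gru_init(V, H), bwd = gru_init(V, H),
      W_mu = rmat(2 * H + P, L), b_mu = matrix(0, 1, L),
      W_lv = rmat(2 * H + P, L), b_lv = matrix(0, 1, L)
    ),
    dec = list(
      W_init = rmat(P + L, H), b_init = matrix(0, 1, H),
      gru = gru_init(V + P + L, H),
      W_out = rmat(H, V), b_out = matrix(0, 1, V)
    )
  )
  structure(list(params = params, vocab = vocab, config = config,
                 prop_stats = prop_stats),
            class = "cvae_model")
}

#' @export
print.cvae_model <- function(x, ...) {
  cat(sprintf(paste0(
    "<cvae_model: vocab %d, hidden %d, latent %d, properties [%s], ",
    "%s parameters>\n"),
    vocab_size(x$vocab), x$config$hidden_size, x$config$latent_dim,
    paste(x$config$properties, collapse = ", "),
    format(length(param_flatten(x$params)), big.mark = ",")))
  invisible(x)
}

# One-hot input sequence for a batch id matrix: list of T (n x V) matrices.
onehot_steps <- function(ids, V) {
  n <- nrow(ids)
  lapply(seq_len(ncol(ids)), function(t) {
    m <- matrix(0, n, V)
    m[cbind(seq_len(n), ids[, t])] <- 1
    m
  })
}

# Reverse each row's first `length` entries (pads stay in place) so the
# backward-direction GRU reads the sequence end to start.
reverse_within_length <- function(ids, lengths) {
  out <- ids
  for (i in seq_len(nrow(ids))) {
    len <- lengths[i]
    out[i, seq_len(len)] <- ids[i, rev(seq_len(len))]
  }
  out
}

# Bidirectional read: returns the concatenated final states (n x 2H) and
# both forward objects (needed for backprop).
bidir_forward <- function(p_fwd, p_bwd, ids, lengths, V) {
  fwd <- gru_forward(p_fwd, onehot_steps(ids, V), lengths)
  rev_ids <- reverse_within_length(ids, lengths)
  bwd <- gru_forward(p_bwd, onehot_steps(rev_ids, V), lengths)
  list(state = cbind(fwd$h_final, bwd$h_final), fwd = fwd, bwd = bwd)
}

#' Predict properties from molecules
#'
#' Runs the bidirectional GRU property predictor q(y|x): each molecule maps
#' to a diagonal Gaussian over the standardized properties. The forward
#' pass is deterministic and each batch row depends only on its own
#' sequence.
#'
#' @param model A `cvae_model`.
#' @param smiles Character vector of SMILES (tokenizable under the model's
#'   vocabulary).
#' @return A `gaussian_posterior`: list of `mean` and `var` matrices
#'   (n x property_dim), variances strictly positive, plus the property
#'   names. Values are on the standardized scale; use
#'   [destandardize_properties()] with `model$prop_stats` for natural units.
#' @export
predict_properties <- function(model, smiles) {
  batch <- encode_batch(smiles, model$vocab, model$config$max_len)
  predictor_forward(model, batch)$post
}

predictor_forward <- function(model, batch) {
  p <- model$params$pred
  bi <- bidir_forward(p$fwd, p$bwd, batch$ids, batch$lengths,
                      vocab_size(model$vocab))
  mu <- add_bias(bi$state %*% p$W_mu, p$b_mu)
  lv <- add_bias(bi$state %*% p$W_lv, p$b_lv)
  colnames(mu) <- colnames(lv) <- model$config$properties
  list(post = new_posterior(mu, exp(lv)), bi = bi, logvar = lv)
}

#' Encode molecules (with their properties) to the latent posterior
#'
#' Runs the bidirectional GRU encoder q(z|x, y). Both the posterior mean
#' and variance condition on the molecule and its property values.
#'
#' @param model A `cvae_model`.
#' @param smiles Character vector of SMILES.
#' @param y_std Standardized property matrix (n x property_dim) as produced
#'   by [standardize_properties()]; raw-unit input is refused.
#' @return A `gaussian_posterior` over the latent space (n x latent_dim).
#' @export
encode_latent <- function(model, smiles, y_std) {
  if (!is_standardized(y_std)) {
    stop("y must be standardized with the model's property stats ",
         "(see standardize_properties)")
  }
  batch <- encode_batch(smiles, model$vocab, model$config$max_len)
  encoder_forward(model, batch, y_std)$post
}

encoder_forward <- function(model, batch, y_std) {
  p <- model$params$enc
  bi <- bidir_forward(p$fwd, p$bwd, batch$ids, batch$lengths,
                      vocab_size(model$vocab))
  ctx <- cbind(bi$state, unclass_matrix(y_std))
  mu <- add_bias(ctx %*% p$W_mu, p$b_mu)
  lv <- add_bias(ctx %*% p$W_lv, p$b_lv)
  list(post = new_posterior(mu, exp(lv)), bi = bi, ctx = ctx, logvar = lv)
}

unclass_matrix <- function(y) {
  attr(y, "standardized") <- NULL
  as.matrix(y)
}

new_posterior <- function(mean, var) {
  stopifnot(all(dim(mean) == dim(var)))
  if (any(var <= 0)) stop("posterior variance must be strictly positive")
  structure(list(mean = mean, var = var), class = "gaussian_posterior")
}

#' @export
print.gaussian_posterior <- function(x, ...) {
  cat(sprintf("<gaussian_posterior: %d x %d>\n", nrow(x$mean), ncol(x$mean)))
  invisible(x)
}

#' Reparameterized sample from a diagonal Gaussian posterior
#'
#' Draws `mean + sqrt(var) * eps` with `eps` standard normal, the
#' pathwise (reparameterization-trick) estimator. Seeded draws are
#' reproducible; in the zero-variance limit the sample equals the mean.
#'
#' @param posterior A `gaussian_posterior`.
#' @param seed Optional integer seed.
#' @return Matrix of samples, same shape as `posterior$mean`.
#' @export
reparameterize <- function(posterior, seed = NULL) {
  stopifnot(inherits(posterior, "gaussian_posterior"))
  mu <- posterior$mean
  if (!is.null(seed)) {
    eps <- with_seed(seed, matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu)))
  } else {
    eps <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
  }
  mu + sqrt(posterior$var) * eps
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())),
          add = TRUE)
  set.seed(seed)
  force(expr)
}

# Decoder hidden-state initialization from the conditioning pair (y, z).
decoder_h0 <- function(model, y, z) {
  p <- model$params$dec
  yz <- cbind(unclass_matrix(y), z)
  pre <- add_bias(yz %*% p$W_init, p$b_init)
  list(h0 = tanh(pre), yz = yz)
}

#' Single decoder step
#'
#' Advances the autoregressive GRU decoder one token: consumes the previous
#' token id (one-hot), the conditioning pair (y, z) and the current hidden
#' state, and returns the softmax distribution over the next token together
#' with the new hidden state.
#'
#' @param model A `cvae_model`.
#' @param prev_id Integer vector (length n) of previous-token vocabulary ids.
#' @param y Standardized property matrix (n x property_dim).
#' @param z Latent matrix (n x latent_dim).
#' @param hidden Current hidden state (n x hidden_size).
#' @return List with `probs` (n x vocab, rows summing to 1) and `hidden`.
#' @export
decoder_step <- function(model, prev_id, y, z, hidden) {
  V <- vocab_size(model$vocab)
  prev_id <- as.integer(prev_id)
  if (any(prev_id < 1L | prev_id > V)) stop("invalid previous-token id")
  n <- length(prev_id)
  x <- matrix(0, n, V)
  x[cbind(seq_len(n), prev_id)] <- 1
  x <- cbind(x, unclass_matrix(y), z)
  st <- gru_cell_forward(model$params$dec$gru, x, hidden)
  logits <- add_bias(st$h %*% model$params$dec$W_out, model$params$dec$b_out)
  list(probs = softmax_rows(logits), hidden = st$h)
}

softmax_rows <- function(logits) {
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

log_softmax_rows <- function(logits) {
  m <- apply(logits, 1L, max)
  s <- logits - m
  s - log(rowSums(exp(s)))
}

# Teacher-forced decoder pass over a whole batch. Inputs at step t are the
# one-hot of token t-1 (start token at t = 1) concatenated with (y, z);
# targets are the true tokens through the terminator.
decoder_forward <- function(model, batch, y, z) {
  V <- vocab_size(model$vocab)
  sp <- special_ids(model$vocab)
  Tmax <- max(batch$lengths)
  ids <- batch$ids[, seq_len(Tmax), drop = FALSE]
  n <- nrow(ids)
  init <- decoder_h0(model, y, z)
  dec_in <- cbind(rep.int(sp$start, n), ids[, seq_len(Tmax - 1L), drop = FALSE])
  Xtok <- onehot_steps(dec_in, V)
  yz <- init$yz
  X <- lapply(Xtok, function(xt) cbind(xt, yz))
  fwd <- gru_forward(model$params$dec$gru, X, batch$lengths, h0 = init$h0)
  logits <- lapply(fwd$hs, function(h)
    add_bias(h %*% model$params$dec$W_out, model$params$dec$b_out))
  list(fwd = fwd, logits = logits, targets = ids, init = init, Tmax = Tmax)
}

#' Sequence log-likelihood under the decoder
#'
#' Evaluates log p(x | y, z) by the autoregressive factorization: the sum
#' over positions (through the end token) of the log-probability the
#' decoder assigns to the true next token under teacher forcing. Always
#' <= 0; padding positions contribute nothing.
#'
#' @param model A `cvae_model`.
#' @param smiles Character vector of SMILES.
#' @param y Standardized property matrix (n x property_dim).
#' @param z Latent matrix (n x latent_dim).
#' @return Numeric vector of per-molecule log-likelihoods.
#' @export
sequence_log_likelihood <- function(model, smiles, y, z) {
  batch <- encode_batch(smiles, model$vocab, model$config$max_len)
  dec <- decoder_forward(model, batch, y, z)
  n <- nrow(batch$ids)
  ll <- numeric(n)
  for (t in seq_len(dec$Tmax)) {
    lp <- log_softmax_rows(dec$logits[[t]])
    active <- batch$lengths >= t
    ll[active] <- ll[active] +
      lp[cbind(seq_len(n), dec$targets[, t])][active]
  }
  ll
}
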