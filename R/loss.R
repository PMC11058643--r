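#' Kullback-Leibler divergence of a diagonal Gaussian from the standard normal
#'
#' Closed form `0.5 * sum_i (var_i + mean_i^2 - 1 - log var_i)`, evaluated
#' per row of the posterior. Always >= 0, and 0 exactly when the posterior
#' is the standard normal.
#'
#' @param posterior A `gaussian_posterior` (see [encode_latent()]), or any
#'   list with `mean` and `var` matrices/vectors.
#' @return Numeric vector, one KL value per posterior row.
#' @export
gaussian_kl <- function(posterior) {
  mu <- rbind(posterior$mean)
  v <- rbind(posterior$var)
  if (any(v <= 0)) stop("posterior variance must be strictly positive")
  0.5 * rowSums(v + mu^2 - 1 - log(v))
}

#' Reconstruction negative log-likelihood of a target sequence
#'
#' Negative sum of the log-probabilities the decoder assigned to the true
#' tokens, through the end token; padded positions are excluded by mask.
#'
#' @param logits Numeric matrix (steps x vocab) of unnormalized scores,
#'   row `t` scoring the token at position `t`; at least `target$length`
#'   rows.
#' @param target An `encoded_molecule`.
#' @return Single non-negative number.
#' @export
reconstruction_nll <- function(logits, target) {
  stopifnot(inherits(target, "encoded_molecule"),
            nrow(logits) >= target$length)
  lp <- log_softmax_rows(logits)
  idx <- cbind(seq_len(target$length), target$token_ids[seq_len(target$length)])
  -sum(lp[idx])
}

neg_log_std_normal <- function(y) {
  y <- rbind(unclass_matrix(y))
  0.5 * rowSums(y^2 + log(2 * pi))
}

#' Loss of a labeled batch
#'
#' Single-sample reparameterized estimate of the negative evidence lower
#' bound plus the beta-weighted predictor mean-squared error, averaged over
#' the batch:
#' `total = reconstruction_nll + kl_z + neg_log_prior_y + beta * mse_y`,
#' where the y and z priors are standard normals on the standardized scale.
#' With the same seed the breakdown is bit-reproducible.
#'
#' @param model A `cvae_model`.
#' @param smiles Character vector of SMILES.
#' @param y_std Standardized property matrix.
#' @param seed Integer seed for the latent draw.
#' @return A `loss_breakdown` list: `reconstruction_nll`, `kl_z`,
#'   `neg_log_prior_y`, `mse_y`, `total` (batch means).
#' @export
labeled_loss <- function(model, smiles, y_std, seed = 1L) {
  if (!is_standardized(y_std)) {
    stop("y must be standardized with the model's property stats")
  }
  batch <- encode_batch(smiles, model$vocab, model$config$max_len)
  eps <- with_seed(seed, matrix(stats::rnorm(nrow(batch$ids) *
                                             model$config$latent_dim),
                                nrow(batch$ids)))
  res <- loss_and_grads(model, batch, y_std, eps, want_grads = FALSE)
  res$breakdown
}

# Joint forward/backward over one batch. `eps` is the (n x latent_dim)
# standard-normal draw for the reparameterized latent sample; pass zeros
# for a deterministic (posterior-mean) evaluation. Gradients mirror the
# parameter list structure exactly.
loss_and_grads <- function(model, batch, y_std, eps, want_grads = TRUE) {
  cfg <- model$config
  n <- nrow(batch$ids)
  V <- vocab_size(model$vocab)
  P <- cfg$property_dim
  L <- cfg$latent_dim
  y <- unclass_matrix(y_std)

  pred <- predictor_forward(model, batch)
  mse_i <- rowSums((pred$post$mean - y)^2)

  enc <- encoder_forward(model, batch, y_std)
  mu_z <- enc$post$mean
  var_z <- enc$post$var
  z <- mu_z + sqrt(var_z) * eps

  dec <- decoder_forward(model, batch, y_std, z)
  recon_i <- numeric(n)
  dh_steps <- if (want_grads) vector("list", dec$Tmax) else NULL
  dW_out <- matrix(0, cfg$hidden_size, V)
  db_out <- matrix(0, 1, V)
  for (t in seq_len(dec$Tmax)) {
    lp <- log_softmax_rows(dec$logits[[t]])
    active <- batch$lengths >= t
    tgt <- cbind(seq_len(n), dec$targets[, t])
    recon_i[active] <- recon_i[active] - lp[tgt][active]
    if (want_grads) {
      dlogit <- exp(lp)
      dlogit[tgt] <- dlogit[tgt] - 1
      dlogit <- dlogit * active / n
      h_t <- dec$fwd$hs[[t]]
      dW_out <- dW_out + crossprod(h_t, dlogit)
      db_out <- db_out + colSums(dlogit)
      dh_steps[[t]] <- dlogit %*% t(model$params$dec$W_out)
    }
  }

  kl_i <- 0.5 * rowSums(var_z + mu_z^2 - 1 - log(var_z))
  nlpy_i <- neg_log_std_normal(y)
  breakdown <- structure(list(
    reconstruction_nll = mean(recon_i), kl_z = mean(kl_i),
    neg_log_prior_y = mean(nlpy_i), mse_y = mean(mse_i),
    total = mean(recon_i) + mean(kl_i) + mean(nlpy_i) + cfg$beta * mean(mse_i)
  ), class = "loss_breakdown")
  if (!want_grads) return(list(breakdown = breakdown))

  p <- model$params
  g <- list()

  # --- decoder ---
  bp_dec <- gru_backward(p$dec$gru, dec$fwd, dh_steps = dh_steps,
                         need_dx = TRUE)
  zcols <- (V + P + 1):(V + P + L)
  dz <- Reduce(`+`, lapply(bp_dec$dX, function(dx) dx[, zcols, drop = FALSE]))
  dpre <- bp_dec$dh0 * (1 - dec$init$h0^2)
  dW_init <- crossprod(dec$init$yz, dpre)
  db_init <- colSums(dpre)
  dyz <- dpre %*% t(p$dec$W_init)
  dz <- dz + dyz[, (P + 1):(P + L), drop = FALSE]
  g$dec <- list(W_init = dW_init, b_init = rbind(db_init), gru = bp_dec$grads,
                W_out = dW_out, b_out = db_out)

  # --- encoder: KL + reparameterized sample path ---
  dmu_z <- mu_z / n + dz
  dlv_z <- 0.5 * (var_z - 1) / n + dz * 0.5 * sqrt(var_z) * eps
  dctx <- dmu_z %*% t(p$enc$W_mu) + dlv_z %*% t(p$enc$W_lv)
  H <- cfg$hidden_size
  bp_ef <- gru_backward(p$enc$fwd, enc$bi$fwd,
                        dh_final = dctx[, 1:H, drop = FALSE])
  bp_eb <- gru_backward(p$enc$bwd, enc$bi$bwd,
                        dh_final = dctx[, (H + 1):(2 * H), drop = FALSE])
  g$enc <- list(fwd = bp_ef$grads, bwd = bp_eb$grads,
                W_mu = crossprod(enc$ctx, dmu_z), b_mu = rbind(colSums(dmu_z)),
                W_lv = crossprod(enc$ctx, dlv_z), b_lv = rbind(colSums(dlv_z)))

  # --- predictor: beta-weighted MSE trains the mean head only ---
  dmu_y <- 2 * cfg$beta * (pred$post$mean - y) / n
  dstate <- dmu_y %*% t(p$pred$W_mu)
  bp_pf <- gru_backward(p$pred$fwd, pred$bi$fwd,
                        dh_final = dstate[, 1:H, drop = FALSE])
  bp_pb <- gru_backward(p$pred$bwd, pred$bi$bwd,
                        dh_final = dstate[, (H + 1):(2 * H), drop = FALSE])
  g$pred <- list(fwd = bp_pf$grads, bwd = bp_pb$grads,
                 W_mu = crossprod(pred$bi$state, dmu_y),
                 b_mu = rbind(colSums(dmu_y)),
                 W_lv = p$pred$W_lv * 0, b_lv = p$pred$b_lv * 0)

  # order the gradient tree exactly like the parameter tree
  g <- g[names(p)]
  list(breakdown = breakdown, grads = g)
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(
    "loss total %.4f (recon %.4f, kl_z %.4f, -log p(y) %.4f, mse_y %.4f)\n",
    x$total, x$reconstruction_nll, x$kl_z, x$neg_log_prior_y, x$mse_y))
  invisible(x)
}
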