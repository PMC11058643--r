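# Adam optimizer over the nested parameter list, with global-norm gradient
# clipping.

adam_init <- function(params) {
  list(m = param_map(function(w) w * 0, params),
       v = param_map(function(w) w * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = Inf) {
  if (is.finite(clip)) {
    nrm <- sqrt(sum(param_flatten(grads)^2))
    if (nrm > clip) grads <- param_map(function(gm) gm * (clip / nrm), grads)
  }
  state$t <- state$t + 1L
  state$m <- param_map2(function(m, gm) beta1 * m + (1 - beta1) * gm,
                        state$m, grads)
  state$v <- param_map2(function(v, gm) beta2 * v + (1 - beta2) * gm^2,
                        state$v, grads)
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  upd <- param_map2(function(m, v) (m / corr1) / (sqrt(v / corr2) + eps),
                    state$m, state$v)
  params <- param_map2(function(w, u) w - lr * u, params, upd)
  list(params = params, state = state)
}

#' Early stopping decision rule
#'
#' Training halts once the validation loss has worsened relative to the
#' immediately preceding epoch for `patience` consecutive epochs; the
#' parameters restored are those of the epoch with the lowest validation
#' loss seen so far. Exposed as a pure function of the loss sequence so the
#' rule itself is testable.
#'
#' @param val_losses Numeric vector of per-epoch validation losses so far.
#' @param patience Number of consecutive worsening epochs tolerated.
#' @return List with `stop` (logical) and `restore_epoch` (index of the
#'   epoch whose parameters should be kept).
#' @export
early_stopping_decision <- function(val_losses, patience = 1L) {
  k <- length(val_losses)
  restore <- which.min(val_losses)
  if (k < patience + 1L || !is.finite(patience)) {
    return(list(stop = FALSE, restore_epoch = restore))
  }
  recent <- diff(val_losses)[(k - patience):(k - 1L)]
  list(stop = all(recent > 0), restore_epoch = restore)
}

#' Train the predictor-encoder-decoder model
#'
#' Minimizes the labeled-batch loss (negative evidence lower bound plus the
#' beta-weighted predictor MSE; see [labeled_loss()]) with Adam under
#' teacher forcing. A seeded fraction of the corpus is held out for
#' validation; validation loss is evaluated at the posterior mean (no
#' latent noise) so the early-stopping signal is deterministic. The whole
#' run is reproducible from `config$seed` on one thread.
#'
#' @param smiles Character vector of valid, tokenizable SMILES.
#' @param properties Data frame or matrix of property values in natural
#'   units with columns `config$properties`, or `NULL` to compute them with
#'   [compute_properties()].
#' @param config A [cvae_config()].
#' @param vocab Optional pre-built [build_vocabulary()] vocabulary
#'   (defaults to the corpus vocabulary).
#' @param prop_stats Optional pre-computed [property_stats()] (defaults to
#'   corpus statistics).
#' @param verbose Print one log line per epoch.
#' @return A trained `cvae_model` with a `history` element (data frame of
#'   epoch, train loss, validation loss) and `stopped_epoch`.
#' @export
train_cvae <- function(smiles, properties = NULL, config = cvae_config(),
                      vocab = NULL, prop_stats = NULL, verbose = FALSE) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) stop("empty training corpus")
  if (is.null(properties)) {
    properties <- compute_properties(smiles)
  }
  y_nat <- as.matrix(as.data.frame(properties)[, config$properties,
                                               drop = FALSE])
  if (is.null(vocab)) vocab <- build_vocabulary(smiles)
  if (is.null(prop_stats)) {
    prop_stats <- property_stats(y_nat)
  }
  model <- cvae_init(vocab, config, prop_stats)
  run_training(model, smiles, y_nat, config, verbose)
}

#' Fine-tune a trained model on a new corpus
#'
#' Continues training from a checkpoint on a new (typically
#' bioactivity-filtered) corpus. The vocabulary and the property
#' standardization statistics are retained from pretraining; a corpus token
#' absent from the checkpoint vocabulary is an error naming the missing
#' tokens. Zero epochs returns the model unchanged.
#'
#' @param model A trained `cvae_model`.
#' @param smiles Fine-tuning corpus.
#' @param properties Property values in natural units, or `NULL` to compute.
#' @param epochs,learning_rate,seed Overrides of the checkpoint's training
#'   configuration for the fine-tuning run.
#' @param val_fraction Validation fraction for the fine-tuning run.
#' @param verbose Print per-epoch log lines.
#' @return The fine-tuned `cvae_model`.
#' @export
finetune_cvae <- function(model, smiles, properties = NULL,
                         epochs = model$config$max_epochs,
                         learning_rate = model$config$learning_rate,
                         val_fraction = model$config$val_fraction,
                         seed = model$config$seed + 1L, verbose = FALSE) {
  stopifnot(inherits(model, "cvae_model"))
  missing_tokens <- character(0)
  for (s in smiles) {
    missing_tokens <- union(missing_tokens,
                            setdiff(tokenize_smiles(s), model$vocab$tokens))
  }
  if (length(missing_tokens)) {
    stop("fine-tuning corpus has tokens outside the checkpoint vocabulary: ",
         paste(missing_tokens, collapse = ", "))
  }
  if (is.null(properties)) properties <- compute_properties(smiles)
  y_nat <- as.matrix(as.data.frame(properties)[, model$config$properties,
                                               drop = FALSE])
  cfg <- model$config
  cfg$max_epochs <- as.integer(epochs)
  cfg$learning_rate <- learning_rate
  cfg$val_fraction <- val_fraction
  cfg$seed <- as.integer(seed)
  if (cfg$max_epochs == 0L) {
    model$config <- cfg
    return(model)
  }
  run_training(model, smiles, y_nat, cfg, verbose)
}

run_training <- function(model, smiles, y_nat, config, verbose) {
  if (any(!is.finite(y_nat))) stop("non-finite property values")
  y_std <- standardize_properties(y_nat, model$prop_stats)
  n <- length(smiles)
  set.seed(config$seed * 2L + 1L)
  n_val <- floor(config$val_fraction * n)
  idx <- sample.int(n)
  val_idx <- if (n_val > 0) idx[seq_len(n_val)] else integer(0)
  train_idx <- setdiff(idx, val_idx)
  if (length(train_idx) == 0L) stop("no training examples after split")

  val_batch <- NULL
  if (n_val > 0) {
    val_batch <- encode_batch(smiles[val_idx], model$vocab, config$max_len)
    val_y <- y_std[val_idx, , drop = FALSE]
    attr(val_y, "standardized") <- TRUE
  }

  params <- model$params
  opt <- adam_init(params)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best_params <- params
  val_losses <- numeric(0)
  stopped_epoch <- NA_integer_
  L <- config$latent_dim

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(train_idx)
    batch_starts <- seq(1L, length(ord), by = config$batch_size)
    epoch_loss <- 0
    model$params <- params
    for (b in batch_starts) {
      take <- ord[b:min(b + config$batch_size - 1L, length(ord))]
      batch <- encode_batch(smiles[take], model$vocab, config$max_len)
      yb <- y_std[take, , drop = FALSE]
      attr(yb, "standardized") <- TRUE
      eps <- matrix(stats::rnorm(length(take) * L), length(take), L)
      model$params <- params
      res <- loss_and_grads(model, batch, yb, eps)
      if (!is.finite(res$breakdown$total)) {
        stop(sprintf("non-finite loss at epoch %d", epoch))
      }
      stepped <- adam_step(params, res$grads, opt, config$learning_rate,
                           clip = config$grad_clip)
      params <- stepped$params
      opt <- stepped$state
      epoch_loss <- epoch_loss + res$breakdown$total * length(take)
    }
    train_loss <- epoch_loss / length(ord)

    val_loss <- NA_real_
    if (!is.null(val_batch)) {
      model$params <- params
      vres <- loss_and_grads(model, val_batch, val_y,
                             matrix(0, nrow(val_batch$ids), L),
                             want_grads = FALSE)
      val_loss <- vres$breakdown$total
      val_losses <- c(val_losses, val_loss)
      if (val_loss <= min(val_losses)) best_params <- params
    }
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = train_loss,
                                         val_loss = val_loss))
    if (verbose) {
      message(sprintf("epoch %d  train %.4f  val %s", epoch, train_loss,
                      ifelse(is.na(val_loss), "-", sprintf("%.4f", val_loss))))
    }
    if (!is.null(val_batch)) {
      dec <- early_stopping_decision(val_losses, config$patience)
      if (dec$stop) {
        params <- best_params
        stopped_epoch <- dec$restore_epoch
        break
      }
    }
  }
  model$params <- params
  model$config <- config
  model$history <- history
  model$stopped_epoch <- stopped_epoch
  # standardized labels of the corpus this model was last trained on;
  # generation can resample these as conditioning values (y_source =
  # "training"), which is how a fine-tuned model reproduces its
  # fine-tuning set's property distribution
  model$train_labels <- unclass_matrix(y_std)
  colnames(model$train_labels) <- config$properties
  model
}

#' Save or load a model checkpoint
#'
#' The checkpoint is a single file holding the weights, configuration,
#' vocabulary, property standardization statistics and training history;
#' loading restores bit-identical forward passes.
#'
#' @param model A `cvae_model`.
#' @param path Checkpoint file path.
#' @export
cvae_save <- function(model, path) {
  stopifnot(inherits(model, "cvae_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname cvae_save
#' @export
cvae_load <- function(path) {
  if (!file.exists(path)) stop("no such checkpoint: ", path)
  model <- readRDS(path)
  if (!inherits(model, "cvae_model")) stop("not a cvae_model checkpoint: ", path)
  model
}
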