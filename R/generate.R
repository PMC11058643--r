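#' Draw conditioning values and latent codes for generation
#'
#' The latent code z is drawn from its standard-normal prior. On the
#' standardized property scale, components named in `condition` are fixed
#' at the standardized target values; the remaining components are drawn
#' from the standard-normal prior, matching the training-time prior on
#' standardized properties.
#'
#' @param model A trained `cvae_model`.
#' @param n Number of draws.
#' @param condition Named numeric vector of target property values in
#'   natural units (e.g. `c(MolWt = 350)`); empty or `NULL` for fully
#'   unconditional draws.
#' @param seed Integer seed.
#' @param y_source Where unconditioned property components come from:
#'   `"prior"` (standard normal on the standardized scale, the default) or
#'   `"training"` (rows resampled with replacement from the standardized
#'   labels of the corpus the model was last trained on — the draw that
#'   makes a fine-tuned model reproduce its fine-tuning set's property
#'   distribution).
#' @return List with `y` (standardized n x property_dim matrix) and `z`
#'   (n x latent_dim matrix).
#' @export
sample_latent <- function(model, n, condition = NULL, seed = 1L,
                          y_source = c("prior", "training")) {
  y_source <- match.arg(y_source)
  stopifnot(inherits(model, "cvae_model"), n >= 0)
  props <- model$config$properties
  if (!is.null(condition) && length(condition)) {
    unknown <- setdiff(names(condition), props)
    if (length(unknown)) {
      stop("unknown property name(s): ", paste(unknown, collapse = ", "))
    }
  }
  P <- model$config$property_dim
  L <- model$config$latent_dim
  if (y_source == "training" && is.null(model$train_labels)) {
    stop("model carries no training labels; train or fine-tune first")
  }
  with_seed(seed, {
    z <- matrix(stats::rnorm(n * L), n, L)
    y <- if (y_source == "prior") {
      matrix(stats::rnorm(n * P), n, P, dimnames = list(NULL, props))
    } else {
      model$train_labels[sample.int(nrow(model$train_labels), n,
                                    replace = TRUE), , drop = FALSE]
    }
    for (nm in names(condition)) {
      y[, nm] <- (condition[[nm]] - model$prop_stats$mean[[nm]]) /
        model$prop_stats$sd[[nm]]
    }
    attr(y, "standardized") <- TRUE
    list(y = y, z = z)
  })
}

# Batched autoregressive decoding. All rows advance together; rows that
# have emitted the terminator are frozen. Greedy mode takes the stepwise
# argmax; multinomial mode samples from the softmax sharpened by
# 1/temperature.
decode_batch <- function(model, y, z, mode = "multinomial", temperature = 1.0,
                         max_len = model$config$max_len) {
  stopifnot(mode %in% c("greedy", "multinomial"), temperature > 0)
  sp <- special_ids(model$vocab)
  n <- nrow(z)
  if (n == 0L) {
    return(data.frame(raw_smiles = character(0), terminated = logical(0)))
  }
  init <- decoder_h0(model, y, z)
  hidden <- init$h0
  prev <- rep.int(sp$start, n)
  done <- rep(FALSE, n)
  out_ids <- matrix(sp$pad, n, max_len)
  for (t in seq_len(max_len)) {
    st <- decoder_step(model, prev, y, z, hidden)
    hidden <- st$hidden
    probs <- st$probs
    if (mode == "greedy") {
      nxt <- max.col(probs, ties.method = "first")
    } else {
      lw <- log(probs) / temperature
      w <- exp(lw - apply(lw, 1L, max))  # stable for temperature -> 0
      nxt <- vapply(seq_len(n), function(i)
        sample.int(ncol(w), 1L, prob = w[i, ]), integer(1))
    }
    nxt[done] <- sp$pad
    out_ids[, t] <- nxt
    done <- done | nxt == sp$end
    prev <- nxt
    prev[done] <- sp$end
    if (all(done)) break
  }
  raw <- vapply(seq_len(n), function(i) decode_ids(out_ids[i, ], model$vocab),
                character(1))
  data.frame(raw_smiles = raw, terminated = done, stringsAsFactors = FALSE)
}

#' Decode a single molecule from a conditioning pair
#'
#' Autoregressive decoding from (y, z): greedy mode takes the stepwise
#' argmax of the next-token distribution (deterministic), multinomial mode
#' samples each token from the temperature-sharpened softmax. Decoding
#' stops at the end token or after `max_len` steps; an unterminated
#' sequence is returned truncated and flagged.
#'
#' @param model A trained `cvae_model`.
#' @param y Standardized property row (1 x property_dim).
#' @param z Latent row (1 x latent_dim).
#' @param mode `"greedy"` or `"multinomial"`.
#' @param temperature Softmax temperature for multinomial mode.
#' @param max_len Step budget.
#' @param seed Integer seed (multinomial mode).
#' @return List with `smiles` and `terminated`.
#' @export
decode_molecule <- function(model, y, z, mode = "greedy", temperature = 1.0,
                            max_len = model$config$max_len, seed = 1L) {
  res <- with_seed(seed,
    decode_batch(model, rbind(unclass_matrix(y)), rbind(z), mode, temperature,
                 max_len))
  list(smiles = res$raw_smiles[1], terminated = res$terminated[1])
}

#' Generate a molecule library
#'
#' End-to-end seeded sampling of `n` molecules: draws (y, z) with
#' [sample_latent()], decodes each attempt, and annotates every attempt
#' with its canonical form (or the invalid marker `NA`), termination flag,
#' and computed properties where valid. All `n` attempts are recorded —
#' invalid and unterminated ones included — so downstream metrics use the
#' full attempt count as their denominator.
#'
#' @inheritParams sample_latent
#' @param mode `"multinomial"` (default; temperature 1 reproduces the
#'   model's own distribution) or `"greedy"`.
#' @param temperature Softmax temperature for multinomial mode.
#' @return Data frame with columns `raw_smiles`, `canonical_smiles`,
#'   `valid`, `terminated`, `logP`, `MolWt`, `QED`, `SAScore`.
#' @export
generate_library <- function(model, n, condition = NULL, mode = "multinomial",
                             temperature = 1.0, seed = 1L,
                             y_source = "prior") {
  stopifnot(inherits(model, "cvae_model"), n >= 0)
  empty <- data.frame(raw_smiles = character(0), canonical_smiles = character(0),
                      valid = logical(0), terminated = logical(0),
                      logP = numeric(0), MolWt = numeric(0), QED = numeric(0),
                      SAScore = numeric(0), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  draw <- sample_latent(model, n, condition, seed = seed,
                        y_source = y_source)
  dec <- with_seed(seed + 1L,
    decode_batch(model, draw$y, draw$z, mode, temperature))
  canon <- rep(NA_character_, n)
  nonempty <- nzchar(dec$raw_smiles)
  canon[nonempty] <- canonicalize(dec$raw_smiles[nonempty])
  valid <- !is.na(canon) & dec$terminated
  out <- data.frame(raw_smiles = dec$raw_smiles, canonical_smiles = canon,
                    valid = valid, terminated = dec$terminated,
                    logP = NA_real_, MolWt = NA_real_, QED = NA_real_,
                    SAScore = NA_real_, stringsAsFactors = FALSE)
  if (any(valid)) {
    props <- compute_properties(canon[valid])
    out[valid, c("logP", "MolWt", "QED", "SAScore")] <-
      props[, c("logP", "MolWt", "QED", "SAScore")]
  }
  out
}
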