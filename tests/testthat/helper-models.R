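# Shared tiny fixtures. Chemistry-free helpers are cheap; anything that
# needs the toolkit is built lazily and cached for the session.

tiny_smiles <- c("CCO", "CCN", "CCCO", "c1ccccc1", "CC=CC", "C1CCCC1O",
                 "c1ccc(CO)cc1", "NCCO")

# A small untrained model over the tiny corpus, with hand-set property
# stats so no toolkit call is needed. Used for forward-pass contracts.
tiny_model <- local({
  cache <- NULL
  function(seed = 3L, hidden = 10L, latent = 4L) {
    key <- paste(seed, hidden, latent)
    if (!is.null(cache) && cache$key == key) return(cache$model)
    vocab <- build_vocabulary(tiny_smiles)
    cfg <- cvae_config(hidden_size = hidden, latent_dim = latent,
                      properties = c("logP", "MolWt", "QED"), max_len = 16,
                      seed = seed)
    y_fake <- rbind(c(0.2, 60, 0.40), c(1.1, 95, 0.45), c(0.4, 80, 0.41))
    colnames(y_fake) <- c("logP", "MolWt", "QED")
    stats <- property_stats(y_fake)
    model <- molcvae:::cvae_init(vocab, cfg, stats)
    cache <<- list(key = key, model = model)
    model
  }
})

# Standardized property rows matching a model's stats, tagged.
fake_y <- function(model, n, seed = 1L) {
  y <- molcvae:::with_seed(seed,
    matrix(stats::rnorm(n * model$config$property_dim), n,
           dimnames = list(NULL, model$config$properties)))
  attr(y, "standardized") <- TRUE
  y
}
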