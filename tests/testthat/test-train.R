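# Training-loop behavior at desk scale: the optimizer makes progress on a
# small corpus, the stopping rule follows its trace, runs are reproducible,
# and checkpoints restore bit-identical forward passes.

train_tiny <- function(epochs, seed = 7, val_fraction = 0, smiles = tiny_smiles) {
  y <- matrix(c(seq_along(smiles) / 2,
                30 + 10 * seq_along(smiles),
                0.3 + 0.02 * seq_along(smiles)),
              ncol = 3, dimnames = list(NULL, c("logP", "MolWt", "QED")))
  cfg <- cvae_config(hidden_size = 16, latent_dim = 6,
                    properties = c("logP", "MolWt", "QED"), max_len = 16,
                    learning_rate = 0.01, max_epochs = epochs,
                    batch_size = 8, val_fraction = val_fraction, seed = seed)
  train_cvae(smiles, y, cfg)
}

test_that("early stopping rule traces: worsen-once stops and restores the best epoch", {
  d <- early_stopping_decision(c(5, 4, 4.5), patience = 1)
  expect_true(d$stop)
  expect_identical(d$restore_epoch, 2L)
  expect_false(early_stopping_decision(c(5, 4), patience = 1)$stop)
  expect_false(early_stopping_decision(c(5, 4, 4.5), patience = 2)$stop)
  expect_true(early_stopping_decision(c(5, 4, 4.5, 4.6), patience = 2)$stop)
  expect_false(early_stopping_decision(c(5), patience = 1)$stop)
})

test_that("training loss decreases and identical seeds give identical histories", {
  m1 <- train_tiny(12)
  m2 <- train_tiny(12)
  expect_identical(m1$history, m2$history)
  expect_identical(molcvae:::param_flatten(m1$params),
                   molcvae:::param_flatten(m2$params))
  # optimization makes clear progress on a memorizable corpus
  expect_lt(min(m1$history$train_loss),
            m1$history$train_loss[1])
  expect_lt(mean(tail(m1$history$train_loss, 3)),
            mean(head(m1$history$train_loss, 3)))
  m3 <- train_tiny(12, seed = 8)
  expect_false(identical(m1$history$train_loss, m3$history$train_loss))
})

test_that("the validation split drives early stopping and restores parameters", {
  sm <- rep(tiny_smiles, 3)[1:20]
  m <- train_tiny(30, val_fraction = 0.2, smiles = sm)
  expect_true(all(!is.na(m$history$val_loss)))
  if (!is.na(m$stopped_epoch)) {
    expect_lte(m$stopped_epoch, nrow(m$history))
    expect_equal(m$history$val_loss[m$stopped_epoch], min(m$history$val_loss))
  }
})

test_that("fine-tuning: zero epochs is identity, vocabulary mismatch is named", {
  m <- train_tiny(3)
  same <- finetune_cvae(m, tiny_smiles[1:4],
                       properties = data.frame(logP = 1:4, MolWt = 40 + 1:4,
                                               QED = 0.3 + 0.01 * 1:4),
                       epochs = 0)
  expect_identical(molcvae:::param_flatten(same$params),
                   molcvae:::param_flatten(m$params))
  expect_error(
    finetune_cvae(m, "CCS", properties = data.frame(logP = 1, MolWt = 62,
                                                   QED = 0.3), epochs = 1),
    "outside the checkpoint vocabulary.*S")
})

test_that("checkpoints restore bit-identical forward passes", {
  m <- train_tiny(3)
  path <- withr::local_tempfile(fileext = ".rds")
  cvae_save(m, path)
  back <- cvae_load(path)
  expect_identical(predict_properties(back, tiny_smiles),
                   predict_properties(m, tiny_smiles))
  y <- fake_y(m, 2)
  z <- matrix(0.1, 2, m$config$latent_dim)
  expect_identical(sequence_log_likelihood(back, tiny_smiles[1:2], y, z),
                   sequence_log_likelihood(m, tiny_smiles[1:2], y, z))
  expect_error(cvae_load(withr::local_tempfile(fileext = ".rds")))
})
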