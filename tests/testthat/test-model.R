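test_that("property predictor is deterministic, batch-independent, variance-positive", {
  m <- tiny_model()
  p1 <- predict_properties(m, "CCO")
  p2 <- predict_properties(m, "CCO")
  expect_identical(p1, p2)
  batch <- predict_properties(m, tiny_smiles)
  expect_equal(batch$mean[1, ], p1$mean[1, ], tolerance = 1e-12)
  expect_equal(batch$var[1, ], p1$var[1, ], tolerance = 1e-12)
  expect_true(all(batch$var > 0))
  expect_identical(dim(batch$mean), c(length(tiny_smiles), 3L))
})

test_that("latent encoder requires standardized y and yields a positive-variance posterior", {
  m <- tiny_model()
  y <- fake_y(m, length(tiny_smiles))
  post <- encode_latent(m, tiny_smiles, y)
  expect_true(all(post$var > 0))
  expect_true(all(gaussian_kl(post) >= 0))
  expect_identical(encode_latent(m, tiny_smiles, y), post)
  raw <- unclass(y); attr(raw, "standardized") <- NULL
  expect_error(encode_latent(m, tiny_smiles, raw), "standardized")
})

test_that("reparameterization is seeded, degenerate at zero variance, and matches analytic moments", {
  post <- molcvae:::new_posterior(matrix(c(1.5, -2), 1), matrix(c(4, 0.25), 1))
  s1 <- reparameterize(post, seed = 9)
  s2 <- reparameterize(post, seed = 9)
  expect_identical(s1, s2)
  tiny_var <- molcvae:::new_posterior(matrix(1.5, 1), matrix(1e-24, 1))
  expect_equal(reparameterize(tiny_var, seed = 1)[1, 1], 1.5, tolerance = 1e-9)
  # 10,000 draws: empirical mean within 3 standard errors of the mean
  big <- molcvae:::new_posterior(matrix(rep(1.5, 10000)), matrix(rep(4, 10000)))
  draws <- reparameterize(big, seed = 2)
  se <- 2 / sqrt(10000)
  expect_lt(abs(mean(draws) - 1.5), 3 * se)
  expect_lt(abs(stats::sd(draws) - 2), 3 * se)
})

test_that("decoder step emits a normalized distribution and deterministic state", {
  m <- tiny_model()
  y <- fake_y(m, 2)
  z <- matrix(0.3, 2, m$config$latent_dim)
  h0 <- molcvae:::decoder_h0(m, y, z)$h0
  st <- decoder_step(m, c(2L, 3L), y, z, h0)
  expect_equal(rowSums(st$probs), c(1, 1), tolerance = 1e-6)
  expect_true(all(st$probs >= 0))
  st2 <- decoder_step(m, c(2L, 3L), y, z, h0)
  expect_identical(st$hidden, st2$hidden)
  expect_error(decoder_step(m, 99L, y, z, h0), "invalid previous-token id")
})

test_that("sequence likelihood equals the stepwise chain-rule product", {
  m <- tiny_model(seed = 11)
  for (s in c("CCO", "c1ccc(CO)cc1")) {
    y <- fake_y(m, 1, seed = 4)
    z <- matrix(0.2, 1, m$config$latent_dim)
    batched <- sequence_log_likelihood(m, s, y, z)
    enc <- encode_smiles(s, m$vocab, m$config$max_len)
    h <- molcvae:::decoder_h0(m, y, z)$h0
    prev <- molcvae:::special_ids(m$vocab)$start
    stepwise <- 0
    for (t in seq_len(enc$length)) {
      st <- decoder_step(m, prev, y, z, h)
      stepwise <- stepwise + log(st$probs[1, enc$token_ids[t]])
      h <- st$hidden
      prev <- enc$token_ids[t]
    }
    expect_equal(batched, stepwise, tolerance = 1e-5)
    expect_lte(batched, 0)
  }
})

test_that("cumulative prefix log-probabilities are nonincreasing", {
  m <- tiny_model(seed = 12)
  y <- fake_y(m, 1, seed = 5)
  z <- matrix(0.1, 1, m$config$latent_dim)
  enc <- encode_smiles("CCCO", m$vocab, m$config$max_len)
  h <- molcvae:::decoder_h0(m, y, z)$h0
  prev <- molcvae:::special_ids(m$vocab)$start
  cum <- numeric(enc$length)
  total <- 0
  for (t in seq_len(enc$length)) {
    st <- decoder_step(m, prev, y, z, h)
    total <- total + log(st$probs[1, enc$token_ids[t]])
    cum[t] <- total
    h <- st$hidden
    prev <- enc$token_ids[t]
  }
  expect_true(all(diff(cum) <= 0))
  expect_true(all(cum <= 0))
})

test_that("standardization composed with its inverse is identity", {
  y <- cbind(logP = c(0.5, 2.1, -0.3), MolWt = c(210, 480, 333),
             QED = c(0.9, 0.4, 0.7))
  st <- property_stats(y)
  z <- standardize_properties(y, st)
  back <- destandardize_properties(z, st)
  expect_equal(back, y, tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(molcvae:::is_standardized(z))
  expect_equal(unname(colMeans(z)), c(0, 0, 0), tolerance = 1e-12)
})
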