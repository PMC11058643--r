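test_that("validity equals the valid fraction over all attempts", {
  expect_equal(validity(c("CCO", "CCN", "C(", "CCCO")), 0.75)
  expect_equal(validity(c("CCO", "CCN")), 1.0)
  # an unterminated sequence counts against validity even if parseable
  expect_equal(validity(c("CCO", "CCC"), terminated = c(TRUE, FALSE)), 0.5)
  expect_error(validity(character(0)), "empty")
})

test_that("uniqueness and novelty equal brute-force set arithmetic", {
  expect_equal(uniqueness(c("CCO", "CCO", "CCC")), 2 / 3)
  expect_equal(uniqueness(c("CCO", "CCN", "CCC")), 1.0)
  # permutation invariance
  set.seed(2)
  v <- c("CCO", "CCO", "CCC", "CCN", "CCN", "CCN")
  expect_equal(uniqueness(sample(v)), uniqueness(v))

  expect_equal(novelty(c("a", "b", "b", "c"), "a"), 2 / 3)
  expect_equal(novelty(c("a", "b"), c("a", "b", "c")), 0.0)
  expect_equal(novelty(c("a", "b"), c("x", "y")), 1.0)
  expect_equal(novelty(sample(v), c("CCO")), novelty(v, c("CCO")))
  # printed overlap variant: |set(V) n X| / |V|
  expect_equal(novelty(c("a", "b", "b", "c"), "a", variant = "overlap"), 1 / 4)
  expect_error(novelty(character(0), "a"), "empty")

  # brute-force oracle on a random fixture set
  set.seed(3)
  gen <- sample(letters[1:8], 30, replace = TRUE)
  train <- letters[1:4]
  brute_uni <- length(unique(gen)) / length(gen)
  brute_nov <- sum(!unique(gen) %in% train) / length(unique(gen))
  expect_equal(uniqueness(gen), brute_uni)
  expect_equal(novelty(gen, train), brute_nov)
})

test_that("metrics accept library data frames and stay in [0, 1]", {
  lib <- data.frame(
    raw_smiles = c("CCO", "CCO", "XX", "CCN"),
    canonical_smiles = c("CCO", "CCO", NA, "CCN"),
    valid = c(TRUE, TRUE, FALSE, TRUE),
    terminated = c(TRUE, TRUE, TRUE, TRUE))
  expect_equal(validity(lib), 0.75)
  expect_equal(uniqueness(lib), 2 / 3)
  expect_equal(novelty(lib, "CCO"), 1 / 2)
  rep <- eval_library(lib, training = "CCO")
  expect_identical(rep$n_generated, 4L)
  expect_identical(rep$n_valid, 3L)
  expect_true(all(c(rep$validity, rep$uniqueness, rep$novelty) >= 0))
  expect_true(all(c(rep$validity, rep$uniqueness, rep$novelty) <= 1))
  expect_equal(rep$validity * rep$n_generated, rep$n_valid)
})

test_that("property report: identical sets give zero mean differences; means match brute force", {
  df <- data.frame(logP = c(1, 2, 3), MolWt = c(100, 200, 300),
                   QED = c(0.2, 0.4, 0.6), SAScore = c(2, 3, 4))
  rep0 <- property_report(df, df)
  expect_equal(unname(rep0$mean_diff), rep(0, 4))
  other <- df; other$MolWt <- other$MolWt + 50
  rep1 <- property_report(other, df)
  expect_equal(unname(rep1$mean_diff[["MolWt"]]), 50)
  expect_equal(rep1$summary$mean[rep1$summary$set == "reference" &
                                 rep1$summary$property == "MolWt"],
               mean(df$MolWt))
  expect_identical(property_report(df, df), rep0)
})

test_that("nearest-to-reference ranking equals a brute-force sort with stable ties", {
  lib <- c("CCO", "CCCO", "CCCCO", "c1ccccc1", "CCN")
  hits <- nearest_to_reference(lib, "CCO", k = 3)
  sims <- ecfp4_tanimoto(lib, "CCO")
  ord <- order(-sims, lib, method = "radix")
  expect_identical(hits$smiles, lib[ord][1:3])
  expect_equal(hits$similarity, sims[ord][1:3])
  # the reference itself ranks first with similarity 1
  expect_identical(hits$smiles[1], "CCO")
  expect_equal(hits$similarity[1], 1.0)
  expect_true(all(diff(hits$similarity) <= 0))
  expect_identical(nrow(nearest_to_reference(lib, "CCO", k = 0)), 0L)
  all_of_them <- nearest_to_reference(lib, "CCO", k = 99)
  expect_identical(nrow(all_of_them), length(lib))
  expect_true(isTRUE(attr(all_of_them, "truncated")))
})
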