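# Synthetic corpus generator. Emulates, at desk scale, the statistical
# shape of a drug-like pretraining corpus and a shifted fine-tuning corpus:
# small valid SMILES drawn from three scaffold families (acyclic chains,
# single aliphatic rings, benzene cores with substituents) over a C/N/O
# alphabet, with toolkit-computed property labels. The grammar is
# restricted to molecules the toolkit always sanitizes — no charges,
# radicals or fused systems — so fixtures never flake.

#' Specification of a synthetic SMILES corpus
#'
#' @param n_molecules Corpus size after deduplication.
#' @param families Scaffold families to draw from: `"chain"` (acyclic
#'   heteroatom chains), `"ring"` (single 5-6 membered aliphatic rings with
#'   a tail), `"aromatic"` (benzene with a substituent chain).
#' @param hetero Heteroatom symbols mixed into chains.
#' @param length_range Inclusive range of chain lengths (heavy atoms in the
#'   acyclic part).
#' @param hetero_prob Per-position probability of a heteroatom in a chain.
#' @param seed Integer seed; the corpus is a pure function of the spec.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_molecules = 50L,
                         families = c("chain", "ring", "aromatic"),
                         hetero = c("N", "O"), length_range = c(3L, 9L),
                         hetero_prob = 0.25, seed = 1L) {
  stopifnot(n_molecules > 0, length(families) > 0,
            all(families %in% c("chain", "ring", "aromatic")),
            length_range[1] >= 1, length_range[2] >= length_range[1],
            hetero_prob >= 0, hetero_prob < 1)
  structure(list(n_molecules = as.integer(n_molecules), families = families,
                 hetero = hetero, length_range = as.integer(length_range),
                 hetero_prob = hetero_prob, seed = as.integer(seed)),
            class = "fixture_spec")
}

random_chain <- function(len, hetero, hetero_prob) {
  atoms <- ifelse(stats::runif(len) < hetero_prob,
                  sample(hetero, len, replace = TRUE), "C")
  # an occasional C=C double bond, never at the chain ends
  s <- paste(atoms, collapse = "")
  if (len >= 4 && stats::runif(1) < 0.3) {
    pos <- sample(2:(len - 2), 1L)
    if (substr(s, pos, pos + 1L) == "CC") {
      s <- paste0(substr(s, 1, pos), "=", substr(s, pos + 1L, len))
    }
  }
  s
}

random_fixture_smiles <- function(spec) {
  fam <- sample(spec$families, 1L)
  len <- sample(spec$length_range[1]:spec$length_range[2], 1L)
  if (fam == "chain") {
    random_chain(max(len, 2L), spec$hetero, spec$hetero_prob)
  } else if (fam == "ring") {
    size <- sample(5:6, 1L)
    mid <- ifelse(stats::runif(size - 2L) < spec$hetero_prob / 2,
                  sample(spec$hetero, size - 2L, replace = TRUE), "C")
    tail_len <- max(len - size, 0L)
    tail <- if (tail_len > 0) {
      random_chain(tail_len, spec$hetero, spec$hetero_prob)
    } else ""
    paste0("C1", paste(mid, collapse = ""), "C1", tail)
  } else {
    tail_len <- max(len - 6L, 1L)
    tail <- random_chain(tail_len, spec$hetero, spec$hetero_prob)
    if (stats::runif(1) < 0.5) {
      paste0("c1ccc(", tail, ")cc1")
    } else {
      paste0("c1ccccc1", tail)
    }
  }
}

#' Generate a synthetic labeled corpus
#'
#' Draws candidate SMILES from the spec's scaffold families, canonicalizes
#' them, deduplicates, and refills until exactly `n_molecules` distinct
#' valid molecules are collected; property labels come from
#' [compute_properties()]. Fully reproducible from the spec.
#'
#' @param spec A [fixture_spec()].
#' @return Data frame with columns `smiles` (canonical), `logP`, `MolWt`,
#'   `QED`, `SAScore`.
#' @export
make_corpus <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  canon <- with_seed(spec$seed, {
    got <- character(0)
    stagnant <- 0L
    while (length(got) < spec$n_molecules) {
      want <- spec$n_molecules - length(got)
      cand <- vapply(seq_len(min(max(2L * want, 20L), 2000L)),
                     function(i) random_fixture_smiles(spec), character(1))
      cc <- canonicalize(cand)
      before <- length(got)
      got <- unique(c(got, cc[!is.na(cc)]))
      stagnant <- if (length(got) == before) stagnant + 1L else 0L
      if (stagnant >= 5L) {
        stop(sprintf("cannot reach %d distinct molecules under this spec",
                     spec$n_molecules))
      }
    }
    got[seq_len(spec$n_molecules)]
  })
  props <- compute_properties(canon)
  data.frame(smiles = canon, props[, c("logP", "MolWt", "QED", "SAScore")],
             stringsAsFactors = FALSE)
}

#' Generate a property-shifted corpus
#'
#' Builds a corpus whose named property mean is moved in the direction of
#' `shift` relative to the base spec, by biased enumeration: molecular
#' weight through chain length (one backbone atom is roughly 14 g/mol),
#' logP through the heteroatom fraction. The realized shift is checked and
#' an unreachable request is an error.
#'
#' @param spec Base [fixture_spec()].
#' @param property `"MolWt"` or `"logP"`.
#' @param shift Signed target displacement of the corpus mean, natural
#'   units.
#' @return Data frame as in [make_corpus()].
#' @export
make_shifted_corpus <- function(spec, property = "MolWt", shift = 50) {
  stopifnot(inherits(spec, "fixture_spec"), shift != 0)
  shifted <- spec
  if (property == "MolWt") {
    delta <- as.integer(round(shift / 14))
    if (delta == 0L) delta <- sign(shift)
    shifted$length_range <- pmax(spec$length_range + delta, 1L)
  } else if (property == "logP") {
    shifted$hetero_prob <- min(max(spec$hetero_prob - 0.08 * shift, 0), 0.95)
  } else {
    stop("shift is unreachable for property: ", property)
  }
  shifted$seed <- spec$seed + 7L
  base <- make_corpus(spec)
  out <- make_corpus(shifted)
  realized <- mean(out[[property]]) - mean(base[[property]])
  if (sign(realized) != sign(shift)) {
    stop(sprintf("requested %+g shift of %s, realized %+.3g: unreachable",
                 shift, property, realized))
  }
  out
}
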