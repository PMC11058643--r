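#' SMILES tokenization
#'
#' Splits a SMILES string into the token alphabet used by the sequence
#' models: bracket atoms (`[nH]`, `[N+]`, ...) are single tokens, the
#' two-character halogens `Cl` and `Br` are single tokens, `%nn` ring-bond
#' labels are single tokens, and every other recognized character (organic
#' subset atoms, aromatic atoms, ring digits, bonds, parentheses,
#' stereo marks) is a token of its own. Concatenating the returned tokens
#' always reproduces the input string exactly.
#'
#' @param smiles A single non-empty SMILES string.
#' @return Character vector of tokens.
#' @examples
#' tokenize_smiles("CCO")
#' tokenize_smiles("c1ccc(Cl)cc1")
#' @export
tokenize_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!nzchar(smiles)) stop("cannot tokenize an empty SMILES string")
  single <- .smiles_single_chars
  tokens <- character(0)
  i <- 1L
  n <- nchar(smiles)
  while (i <= n) {
    ch <- substr(smiles, i, i)
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && substr(smiles, j, j) != "]") j <- j + 1L
      if (j > n) {
        stop(sprintf("unterminated bracket atom starting at position %d in '%s'",
                     i, smiles))
      }
      tokens <- c(tokens, substr(smiles, i, j))
      i <- j + 1L
    } else if (ch == "C" && i < n && substr(smiles, i + 1L, i + 1L) == "l") {
      tokens <- c(tokens, "Cl")
      i <- i + 2L
    } else if (ch == "B" && i < n && substr(smiles, i + 1L, i + 1L) == "r") {
      tokens <- c(tokens, "Br")
      i <- i + 2L
    } else if (ch == "%" && i + 2L <= n &&
               grepl("^[0-9]{2}$", substr(smiles, i + 1L, i + 2L))) {
      tokens <- c(tokens, substr(smiles, i, i + 2L))
      i <- i + 3L
    } else if (ch %in% single) {
      tokens <- c(tokens, ch)
      i <- i + 1L
    } else {
      stop(sprintf("unrecognized character '%s' at position %d in '%s'",
                   ch, i, smiles))
    }
  }
  tokens
}

# Organic-subset and aromatic atoms, digits, bonds, branches, stereo.
.smiles_single_chars <- c(
  "B", "C", "N", "O", "P", "S", "F", "I",
  "b", "c", "n", "o", "p", "s",
  as.character(0:9),
  "(", ")", "=", "#", "-", "+", "/", "\\", ".", ":", "@", "*", "$"
)

#' Token vocabulary for SMILES sequence models
#'
#' Builds a deterministic bijective token/index map over all tokens observed
#' in a corpus, with three special tokens (sequence start, the `"\n"` end
#' terminator, and padding) placed first. Index `i` maps to `tokens[i]`
#' (1-based).
#'
#' @param corpus Non-empty character vector of SMILES strings.
#' @return An object of class `token_vocab`: a list with elements `tokens`
#'   (ordered character vector) and `specials` (named list `start`, `end`,
#'   `pad`).
#' @examples
#' v <- build_vocabulary(c("CCO", "CCN"))
#' vocab_size(v)
#' @export
build_vocabulary <- function(corpus) {
  stopifnot(is.character(corpus))
  if (length(corpus) == 0L) stop("corpus is empty")
  specials <- list(pad = "_", start = "^", end = "\n")
  observed <- character(0)
  for (s in corpus) {
    toks <- tryCatch(tokenize_smiles(s), error = function(e) {
      stop(sprintf("untokenizable SMILES '%s': %s", s, conditionMessage(e)))
    })
    observed <- union(observed, toks)
  }
  if (any(unlist(specials) %in% observed)) {
    stop("corpus contains a reserved special token")
  }
  vocab <- list(
    tokens = c(unlist(specials, use.names = FALSE), sort(observed, method = "radix")),
    specials = specials
  )
  class(vocab) <- "token_vocab"
  vocab
}

#' @export
print.token_vocab <- function(x, ...) {
  cat(sprintf("<token_vocab: %d tokens (3 specials + %d observed)>\n",
              length(x$tokens), length(x$tokens) - 3L))
  invisible(x)
}

#' @rdname build_vocabulary
#' @param vocab A `token_vocab`.
#' @export
vocab_size <- function(vocab) length(vocab$tokens)

token_index <- function(vocab, tokens) {
  idx <- match(tokens, vocab$tokens)
  if (anyNA(idx)) {
    stop(sprintf("token(s) not in vocabulary: %s",
                 paste(unique(tokens[is.na(idx)]), collapse = ", ")))
  }
  idx
}

special_ids <- function(vocab) {
  list(pad = match(vocab$specials$pad, vocab$tokens),
       start = match(vocab$specials$start, vocab$tokens),
       end = match(vocab$specials$end, vocab$tokens))
}

#' Encode a SMILES string as a padded token-id sequence
#'
#' Tokenizes `smiles`, appends the end-of-sequence token, and pads with the
#' pad token up to `max_len`. The stored `length` counts real tokens
#' including the terminator; `decode_ids()` inverts the encoding exactly.
#'
#' @param smiles SMILES string.
#' @param vocab A `token_vocab` containing every token of `smiles`.
#' @param max_len Maximum sequence length (tokens plus terminator).
#' @return An object of class `encoded_molecule`: list with `smiles`,
#'   `token_ids` (integer vector of length `max_len`), `length`, `max_len`.
#' @examples
#' v <- build_vocabulary("CCO")
#' enc <- encode_smiles("CCO", v, max_len = 6)
#' decode_ids(enc$token_ids, v)
#' @export
encode_smiles <- function(smiles, vocab, max_len = 120L) {
  toks <- tokenize_smiles(smiles)
  len <- length(toks) + 1L  # incl. end token
  if (len > max_len) {
    stop(sprintf("SMILES needs %d tokens but max_len is %d", len, max_len))
  }
  sp <- special_ids(vocab)
  ids <- c(token_index(vocab, toks), sp$end,
           rep.int(sp$pad, max_len - len))
  structure(
    list(smiles = smiles, token_ids = as.integer(ids),
         length = len, max_len = as.integer(max_len)),
    class = "encoded_molecule"
  )
}

#' Decode token ids back to a SMILES string
#'
#' Concatenates tokens up to (excluding) the first end token; start and pad
#' tokens are dropped.
#'
#' @param token_ids Integer vector of vocabulary indices.
#' @param vocab A `token_vocab`.
#' @return The decoded SMILES string.
#' @export
decode_ids <- function(token_ids, vocab) {
  token_ids <- as.integer(token_ids)
  if (any(token_ids < 1L | token_ids > length(vocab$tokens))) {
    stop("token id out of vocabulary range")
  }
  sp <- special_ids(vocab)
  stop_at <- match(sp$end, token_ids)
  if (!is.na(stop_at)) token_ids <- token_ids[seq_len(stop_at - 1L)]
  token_ids <- token_ids[token_ids != sp$pad & token_ids != sp$start]
  paste(vocab$tokens[token_ids], collapse = "")
}

#' One-hot expansion of an encoded molecule
#'
#' @param enc An `encoded_molecule`.
#' @param vocab The `token_vocab` used to encode it.
#' @return A `max_len` x `vocab_size(vocab)` 0/1 matrix with exactly one 1
#'   per row; rows beyond the sequence length carry the pad token's 1.
#' @export
one_hot <- function(enc, vocab) {
  stopifnot(inherits(enc, "encoded_molecule"))
  m <- matrix(0, nrow = enc$max_len, ncol = vocab_size(vocab))
  m[cbind(seq_len(enc$max_len), enc$token_ids)] <- 1
  m
}

# Stack a list of encoded molecules into an (n x max_len) id matrix plus
# a lengths vector — the batch layout every network forward pass consumes.
encode_batch <- function(smiles, vocab, max_len = 120L) {
  encs <- lapply(smiles, encode_smiles, vocab = vocab, max_len = max_len)
  list(
    ids = do.call(rbind, lapply(encs, `[[`, "token_ids")),
    lengths = vapply(encs, `[[`, integer(1), "length"),
    smiles = vapply(encs, `[[`, character(1), "smiles"),
    max_len = as.integer(max_len)
  )
}
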