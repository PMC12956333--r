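#' Codon tokenizer
#'
#' A fixed vocabulary of 69 tokens: 5 special tokens (`[CLS]` sequence
#' start, `[SEP]` sequence end, `[MASK]`, `[PAD]`, `[UNK]`) followed by the
#' 64 DNA codons in lexicographic order. Token ids are dense `0..68`.
#'
#' @return An object of class `codon_tokenizer` with elements `vocab`
#'   (character, length 69), `token_to_id` (named integer, 0-based),
#'   `special_tokens` (named integer ids for `start`, `end`, `mask`, `pad`,
#'   `unknown`) and `codon_ids` (named integer: codon to id).
#' @examples
#' tok <- codon_tokenizer()
#' length(tok$vocab)
#' tok$special_tokens
#' @export
codon_tokenizer <- function() {
  specials <- c("[CLS]", "[SEP]", "[MASK]", "[PAD]", "[UNK]")
  vocab <- c(specials, ALL_CODONS)
  token_to_id <- stats::setNames(seq_along(vocab) - 1L, vocab)
  structure(
    list(
      vocab = vocab,
      token_to_id = token_to_id,
      special_tokens = stats::setNames(token_to_id[specials],
                                       c("start", "end", "mask", "pad",
                                         "unknown")),
      codon_ids = token_to_id[ALL_CODONS]
    ),
    class = "codon_tokenizer"
  )
}

#' @export
print.codon_tokenizer <- function(x, ...) {
  cat("<codon_tokenizer> ", length(x$vocab),
      " tokens (64 codons + 5 specials)\n", sep = "")
  invisible(x)
}

#' Encode a coding sequence as token ids
#'
#' Validates the sequence at codon level (canonical alphabet, length
#' divisible by three), splits it into codons and returns
#' `[CLS] codon... [SEP]` as 0-based token ids. Sequences longer than
#' `max_positions` total tokens are truncated from the right (trailing
#' codons dropped) before the end token is appended.
#'
#' @param tokenizer A [codon_tokenizer()].
#' @param cds A single DNA string (case-insensitive).
#' @param max_positions Maximum total token positions including the start
#'   and end tokens (default `Inf`, no truncation).
#' @return Integer vector of token ids, length `nchar(cds)/3 + 2` (before
#'   truncation).
#' @examples
#' tok <- codon_tokenizer()
#' encode_cds(tok, "ATGGCT")
#' @export
encode_cds <- function(tokenizer, cds, max_positions = Inf) {
  stopifnot(length(cds) == 1L)
  cds <- toupper(cds)
  if (grepl("[^ACGT]", cds)) {
    stop("invalid CDS: non-canonical nucleotide (alphabet rule)",
         call. = FALSE)
  }
  if (nchar(cds) %% 3L != 0L) {
    stop("invalid CDS: length not divisible by three (length rule)",
         call. = FALSE)
  }
  codons <- split_codons(cds)
  if (length(codons) + 2L > max_positions) {
    codons <- codons[seq_len(max(0L, max_positions - 2L))]
  }
  sp <- tokenizer$special_tokens
  unname(c(sp[["start"]], tokenizer$codon_ids[codons], sp[["end"]]))
}

#' Decode token ids back to a coding sequence
#'
#' Inverse of [encode_cds()]: special tokens are dropped and codon tokens
#' concatenated.
#'
#' @param tokenizer A [codon_tokenizer()].
#' @param ids Integer vector of 0-based token ids.
#' @return A DNA string.
#' @export
decode_ids <- function(tokenizer, ids) {
  stopifnot(all(ids >= 0L), all(ids < length(tokenizer$vocab)))
  tokens <- tokenizer$vocab[ids + 1L]
  paste0(tokens[!startsWith(tokens, "[")], collapse = "")
}

#' Write the tokenizer vocabulary as JSON
#'
#' Serializes the token-to-id map as a single JSON object.
#'
#' @param tokenizer A [codon_tokenizer()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vocab_json <- function(tokenizer, path) {
  jsonlite::write_json(as.list(tokenizer$token_to_id), path,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Build the synonymous-constraint logit mask
#'
#' A `V x V` additive matrix over the tokenizer vocabulary. Entry
#' `[t, v]` is 0 when token `v` is a codon synonymous with codon token `t`
#' (including `t` itself) and `-Inf` otherwise. Rows for special tokens are
#' all `-Inf`: special tokens are never prediction targets. Added to a
#' masked position's logits (row indexed by the true codon), the mask
#' removes every non-synonymous token from the prediction space before
#' softmax — the resulting probabilities outside the family are exactly 0,
#' because `exp(-Inf)` underflows to 0 in double precision.
#'
#' Under the standard code the number of finite entries equals
#' `sum(degeneracy^2 per family) = 244`.
#'
#' @param tokenizer A [codon_tokenizer()].
#' @param code A [genetic_code()] object covering the same 64 codons.
#' @return A numeric `69 x 69` matrix with `dimnames` equal to the
#'   vocabulary.
#' @examples
#' m <- build_synonym_mask(codon_tokenizer(), genetic_code())
#' sum(is.finite(m)) # 244
#' @export
build_synonym_mask <- function(tokenizer, code) {
  if (!setequal(names(code$codon_to_aa), names(tokenizer$codon_ids))) {
    stop("tokenizer and genetic code cover different codon sets",
         call. = FALSE)
  }
  v <- length(tokenizer$vocab)
  mask <- matrix(-Inf, v, v, dimnames = list(tokenizer$vocab,
                                             tokenizer$vocab))
  for (fam in code$families) {
    mask[fam, fam] <- 0
  }
  mask
}
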