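# Amino-acid tokenizer ----------------------------------------------------
#
# Fixed 26-symbol vocabulary: PAD(0), MASK(1), CLS(2), EOS(3), UNK(4), the
# 20 standard residues (5..24, alphabetical) and X (25). PAD must be id 0 so
# a zero-filled batch matrix is valid padding.

#' Amino-acid tokenizer
#'
#' @param max_length Maximum token-sequence length (including CLS and EOS);
#'   longer sequences are truncated by [tokenize()].
#' @return An object of class `aa_tokenizer` with the vocabulary, the
#'   special-token ids and `max_length`.
#' @export
aa_tokenizer <- function(max_length = 1024) {
  stopifnot(max_length >= 3)
  specials <- c(PAD = 0L, MASK = 1L, CLS = 2L, EOS = 3L, UNK = 4L)
  residues <- stats::setNames(seq_along(aa_alphabet()) + 4L, aa_alphabet())
  structure(
    list(vocab = c(specials, residues), specials = specials,
         residue_ids = unname(residues), max_length = as.integer(max_length),
         vocab_size = length(specials) + length(residues)),
    class = "aa_tokenizer"
  )
}

#' Tokenize a residue string
#'
#' Produces `[CLS] residue-ids [EOS]`, truncating to `max_length` (CLS and
#' EOS are always kept) with a warning. Characters outside the 21-letter
#' alphabet map to UNK.
#'
#' @param residues A residue string.
#' @param tok An [aa_tokenizer()].
#' @return An integer vector of token ids.
#' @export
#' @examples
#' tok <- aa_tokenizer()
#' tokenize("ACD", tok)
tokenize <- function(residues, tok) {
  stopifnot(inherits(tok, "aa_tokenizer"), is.character(residues),
            length(residues) == 1)
  ids <- tok$vocab[strsplit(residues, "")[[1]]]
  ids[is.na(ids)] <- tok$specials[["UNK"]]
  if (length(ids) > tok$max_length - 2L) {
    rlang::warn(paste0("sequence of length ", length(ids),
                       " truncated to max_length = ", tok$max_length))
    ids <- ids[seq_len(tok$max_length - 2L)]
  }
  unname(c(tok$specials[["CLS"]], ids, tok$specials[["EOS"]]))
}

#' Invert tokenization
#'
#' @param ids Integer token ids.
#' @param tok An [aa_tokenizer()].
#' @return The residue string, with special tokens dropped.
#' @export
detokenize <- function(ids, tok) {
  stopifnot(inherits(tok, "aa_tokenizer"))
  sym <- names(tok$vocab)[match(ids, tok$vocab)]
  paste(sym[ids >= 5L], collapse = "")
}

#' BERT-style corruption for masked-language-model training
#'
#' Each residue position (special tokens are never touched) is selected
#' independently with probability `rate`. A selected position becomes the
#' MASK token, a uniformly random residue token, or stays unchanged, with
#' probabilities given by `scheme` (default 80/10/10, the standard BERT
#' corruption). Targets record the original ids at the selected positions.
#' Uses the current RNG state.
#'
#' @param ids Integer token ids (at least one non-special token).
#' @param tok An [aa_tokenizer()].
#' @param rate Selection probability in `[0, 1]`.
#' @param scheme Length-3 nonnegative weights (MASK / random / unchanged)
#'   summing to 1.
#' @return A list with `ids` (corrupted), `positions` (selected indices) and
#'   `targets` (original ids at those positions).
#' @export
mask_for_mlm <- function(ids, tok, rate = 0.15, scheme = c(0.8, 0.1, 0.1)) {
  stopifnot(inherits(tok, "aa_tokenizer"))
  if (!is.numeric(rate) || length(rate) != 1 || rate < 0 || rate > 1) {
    rlang::abort("mask rate must be a single number in [0, 1]")
  }
  stopifnot(length(scheme) == 3, all(scheme >= 0),
            abs(sum(scheme) - 1) < 1e-8)
  eligible <- which(ids >= 5L)
  if (!length(eligible)) rlang::abort("no non-special tokens to mask")
  sel <- eligible[stats::runif(length(eligible)) < rate]
  out <- ids
  if (length(sel)) {
    u <- stats::runif(length(sel))
    to_mask <- u < scheme[1]
    to_rand <- !to_mask & u < scheme[1] + scheme[2]
    out[sel[to_mask]] <- tok$specials[["MASK"]]
    if (any(to_rand)) {
      out[sel[to_rand]] <- sample(tok$residue_ids, sum(to_rand),
                                  replace = TRUE)
    }
  }
  list(ids = out, positions = sel, targets = ids[sel])
}
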