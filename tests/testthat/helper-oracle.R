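# Independent exhaustive dynamic-programming oracle for pairwise alignment.
#
# Affine-gap Gotoh DP written directly from the recurrences (a gap of length
# L costs open + L * ext). Because optimal alignments are often non-unique,
# the oracle reports, besides the exact optimal score, the minimum and
# maximum number of identical columns and of aligned columns achievable by
# any optimal alignment (a lexicographic DP on score * K + secondary
# objective). An implementation is consistent with the oracle iff its score
# is exactly optimal and its column counts lie inside those bounds; when
# the bounds collapse, identity is checked exactly.

oracle_score_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}

# one lexicographic DP: primary objective = alignment score, secondary =
# w_nm * (#identical columns) + w_cols * (#aligned columns), each weight in
# {-1, 0, +1}. Returns list(score, secondary).
oracle_dp <- function(a, b, mode, open = 11, ext = 1,
                      w_nm = 0, w_cols = 0, mat = oracle_score_matrix()) {
  K <- 4096  # secondary objective magnitude is < K/2 for desk-scale lengths
  local <- mode == "local"
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  sub <- K * mat[av, bv, drop = FALSE] +
    w_nm * outer(av, bv, "==") + w_cols
  gap_char <- -K * ext + w_cols
  gap_open <- -K * open
  NEG <- -1e15
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  if (local) {
    M[, 1] <- 0
    M[1, ] <- 0
  } else {
    if (n > 0) Ix[2:(n + 1), 1] <- gap_open + seq_len(n) * gap_char
    if (m > 0) Iy[1, 2:(m + 1)] <- gap_open + seq_len(m) * gap_char
  }
  for (i in 2:(n + 1)) {
    prev_best <- pmax(M[i - 1, ], Ix[i - 1, ], Iy[i - 1, ])[1:m]
    if (local) prev_best <- pmax(prev_best, 0)
    M[i, 2:(m + 1)] <- prev_best + sub[i - 1, ]
    Ix[i, ] <- pmax(M[i - 1, ] + gap_open + gap_char,
                    Ix[i - 1, ] + gap_char)
    run <- cummax(M[i, ] - (0:m) * gap_char)[1:m]
    Iy[i, 2:(m + 1)] <- run + gap_open + (1:m) * gap_char
  }
  v <- if (local) {
    max(M, 0)
  } else {
    max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
  }
  # unpack score and secondary from v = K * score + sign * secondary
  sign <- w_nm + w_cols  # one of -1, 0, +1 (only one weight nonzero)
  if (sign >= 0) {
    sec <- v %% K
    score <- (v - sec) / K
  } else {
    sec <- (-v) %% K
    score <- (v + sec) / K
  }
  list(score = score, secondary = sec)
}

# bounds over all optimal alignments
oracle_align <- function(a, b, mode = c("global", "local"),
                         open = 11, ext = 1) {
  mode <- match.arg(mode)
  base <- oracle_dp(a, b, mode, open, ext)
  list(
    score = base$score,
    nm_min = oracle_dp(a, b, mode, open, ext, w_nm = -1)$secondary,
    nm_max = oracle_dp(a, b, mode, open, ext, w_nm = 1)$secondary,
    cols_min = oracle_dp(a, b, mode, open, ext, w_cols = -1)$secondary,
    cols_max = oracle_dp(a, b, mode, open, ext, w_cols = 1)$secondary
  )
}

# TRUE iff an IdentityResult row is consistent with the oracle on (a, b)
oracle_consistent <- function(res, a, b, mode, open = 11, ext = 1) {
  o <- oracle_align(a, b, mode, open, ext)
  nm <- round(res$identity * res$aligned_columns)
  isTRUE(all.equal(res$raw_score, o$score)) &&
    nm >= o$nm_min && nm <= o$nm_max &&
    res$aligned_columns >= o$cols_min &&
    res$aligned_columns <= o$cols_max
}

# random residue string over the 20 standard amino acids
random_protein <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               len, replace = TRUE), collapse = "")
}
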