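# Pairwise identity -------------------------------------------------------
#
# Percent identity from optimal pairwise alignment is the single similarity
# measure used by both filtering steps of the pipeline: the 0.8 cutoff of
# CD-HIT-style redundancy reduction and the 0.40 edge threshold of the SSN.
# Alignments are computed by Biostrings::pairwiseAlignment (affine gaps,
# BLOSUM62 by default); identity = identical columns / aligned columns, where
# the denominator includes gap columns of the optimal alignment (the full
# alignment in global mode, the local footprint in local mode).

the <- new.env(parent = emptyenv())

get_score_matrix <- function(name_or_matrix) {
  if (is.matrix(name_or_matrix)) return(name_or_matrix)
  nm <- as.character(name_or_matrix)
  if (is.null(the[[nm]])) {
    e <- new.env()
    utils::data(list = nm, package = "Biostrings", envir = e)
    the[[nm]] <- get(nm, envir = e)
  }
  the[[nm]]
}

#' Alignment parameters
#'
#' Affine-gap alignment settings used everywhere a pairwise identity is
#' computed. Defaults follow protein BLAST: BLOSUM62 with gap open 11 and gap
#' extend 1 (a gap of length L costs `11 + L`).
#'
#' @param mode `"global"` (Needleman-Wunsch over the full lengths) or
#'   `"local"` (Smith-Waterman footprint).
#' @param substitution_matrix A named 20+ letter score matrix, or the name of
#'   one shipped with Biostrings (e.g. `"BLOSUM62"`, `"PAM250"`).
#' @param gap_open Nonnegative gap-opening penalty.
#' @param gap_extend Nonnegative per-residue gap-extension penalty; must not
#'   exceed `gap_open`.
#' @return An object of class `align_params`.
#' @export
#' @examples
#' align_params(mode = "local")
align_params <- function(mode = c("global", "local"),
                         substitution_matrix = "BLOSUM62",
                         gap_open = 11, gap_extend = 1) {
  mode <- match.arg(mode)
  stopifnot(gap_open >= 0, gap_extend >= 0)
  if (gap_extend > gap_open) rlang::abort("gap_extend must be <= gap_open")
  structure(
    list(mode = mode, substitution_matrix = substitution_matrix,
         gap_open = gap_open, gap_extend = gap_extend),
    class = "align_params"
  )
}

#' Read an NCBI-format substitution matrix
#'
#' Parses the plain-text matrix format distributed by NCBI (comment lines
#' starting with `#`, a header row of residue letters, one labelled row per
#' residue).
#'
#' @param path Path to the matrix file.
#' @return A named integer matrix usable as `substitution_matrix` in
#'   [align_params()].
#' @export
read_score_matrix <- function(path) {
  lines <- grep("^\\s*#", readLines(path), invert = TRUE, value = TRUE)
  lines <- lines[nzchar(trimws(lines))]
  cols <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  m <- t(vapply(rows, function(r) as.integer(r[-1]), integer(length(cols))))
  rownames(m) <- vapply(rows, `[`, "", 1)
  colnames(m) <- cols
  m
}

# vectorised identity of many patterns against one subject;
# returns a tibble(identity, aligned_columns, raw_score)
identity_many <- function(patterns, subject, params) {
  type <- params$mode
  aln <- Biostrings::pairwiseAlignment(
    pattern = patterns, subject = subject, type = type,
    substitutionMatrix = get_score_matrix(params$substitution_matrix),
    gapOpening = params$gap_open, gapExtension = params$gap_extend
  )
  # denominator = every column of the optimal alignment. In global mode
  # that includes terminal gap columns (which Biostrings::nchar excludes):
  # each column consumes a residue of one or both sequences, so
  # columns = len(a) + len(b) - (residue-residue columns).
  paired <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln)
  cols <- if (type == "global") {
    Biostrings::width(patterns) + length(subject) - paired
  } else {
    Biostrings::nchar(aln)
  }
  idents <- ifelse(cols > 0, Biostrings::nmatch(aln) / cols, 0)
  tibble::tibble(
    identity = as.numeric(idents),
    aligned_columns = as.integer(cols),
    raw_score = as.numeric(Biostrings::score(aln))
  )
}

#' Pairwise alignment identity of two sequences
#'
#' Computes the optimal alignment of two residue strings under `params` and
#' returns the fraction of identical columns. Symmetric by construction:
#' the pair is canonically ordered before alignment, so
#' `align_identity(a, b)` and `align_identity(b, a)` are identical.
#'
#' @param a,b Residue strings (or single-row sequence tibbles).
#' @param params An [align_params()] object.
#' @return A one-row tibble with `identity` (in `[0, 1]`), `aligned_columns`
#'   and `raw_score`. An empty optimal local alignment yields identity 0.
#' @export
#' @examples
#' align_identity("ACDEFGHIKL", "ACDEFGHIKV")$identity  # 0.9
align_identity <- function(a, b, params = align_params()) {
  a <- residues_of(a); b <- residues_of(b)
  a <- normalize_residues(a); b <- normalize_residues(b)
  # canonical order: longer first, ties broken lexicographically
  if (nchar(b) > nchar(a) || (nchar(b) == nchar(a) && b < a)) {
    tmp <- a; a <- b; b <- tmp
  }
  identity_many(Biostrings::AAStringSet(a), Biostrings::AAString(b), params)
}

residues_of <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1, "residues" %in% names(x))
    return(x$residues)
  }
  stopifnot(is.character(x), length(x) == 1)
  x
}

# Redundancy reduction -----------------------------------------------------

#' Greedy identity-based redundancy reduction
#'
#' CD-HIT-style incremental clustering: sequences are processed in order of
#' decreasing length (ties broken by input order); each sequence joins the
#' first existing representative it matches at `threshold` identity or
#' better, otherwise it becomes a new representative. Representatives are
#' therefore mutually below the threshold, and every member sits at or above
#' the threshold to its representative.
#'
#' For each candidate/representative pair the alignment mode is chosen from
#' the two lengths: global when they differ by less than 20%, local
#' otherwise (full alignment identity, no k-mer short-circuit heuristics).
#'
#' @param seqs A sequence tibble (non-empty).
#' @param threshold Identity threshold in `(0, 1]`, default 0.80.
#' @param align An [align_params()] object; its `mode` is overridden per pair
#'   as described above.
#' @return A list of class `redundancy_reduction` with elements
#'   `representatives` (sequence tibble, in order of creation) and
#'   `membership` (tibble `id`, `representative_id`, `identity`;
#'   representatives map to themselves with identity 1).
#' @export
reduce_redundancy <- function(seqs, threshold = 0.80, align = align_params()) {
  seqs <- validate_seq_tbl(seqs)
  if (!nrow(seqs)) rlang::abort("reduce_redundancy needs a non-empty sequence set")
  stopifnot(threshold > 0, threshold <= 1)

  ord <- order(-nchar(seqs$residues), seq_len(nrow(seqs)))
  rep_idx <- integer(0)          # indices into seqs, in insertion order
  assigned <- integer(nrow(seqs))  # representative index per sequence
  best_ident <- numeric(nrow(seqs))

  for (i in ord) {
    hit <- 0L; hit_ident <- NA_real_
    if (length(rep_idx)) {
      li <- nchar(seqs$residues[i])
      lr <- nchar(seqs$residues[rep_idx])
      global <- (pmax(li, lr) - pmin(li, lr)) / pmax(li, lr) < 0.2
      ident <- numeric(length(rep_idx))
      for (g in c(TRUE, FALSE)) {
        sel <- which(global == g)
        if (!length(sel)) next
        p <- align
        p$mode <- if (g) "global" else "local"
        res <- identity_many(
          Biostrings::AAStringSet(seqs$residues[rep_idx[sel]]),
          Biostrings::AAString(seqs$residues[i]), p
        )
        ident[sel] <- res$identity
      }
      ok <- which(ident >= threshold)
      if (length(ok)) {
        hit <- rep_idx[ok[1]]
        hit_ident <- ident[ok[1]]
      }
    }
    if (hit == 0L) {
      rep_idx <- c(rep_idx, i)
      assigned[i] <- i
      best_ident[i] <- 1
    } else {
      assigned[i] <- hit
      best_ident[i] <- hit_ident
    }
  }

  structure(
    list(
      representatives = seqs[rep_idx, ],
      membership = tibble::tibble(
        id = seqs$id,
        representative_id = seqs$id[assigned],
        identity = best_ident
      ),
      threshold = threshold
    ),
    class = "redundancy_reduction"
  )
}

#' @export
print.redundancy_reduction <- function(x, ...) {
  cat("Redundancy reduction at identity >=", x$threshold, "\n")
  cat(" ", nrow(x$membership), "sequences ->", nrow(x$representatives),
      "representatives\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.redundancy_reduction <- function(x, ...) x$membership
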