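# Sequence tables ---------------------------------------------------------
#
# Protein sequences travel through the pipeline as plain tibbles with columns
# `id` (unique, non-empty), `description` (full FASTA header, may be NA) and
# `residues` (uppercase string over the 20 standard amino acids plus X).
# Row order is meaningful: greedy redundancy reduction breaks ties by it.

#' Construct a sequence table
#'
#' @param id Character vector of unique, non-empty sequence identifiers.
#' @param residues Character vector of residue strings. Normalised with
#'   [normalize_residues()] before validation.
#' @param description Optional character vector of full headers.
#' @return A tibble with columns `id`, `description`, `residues`.
#' @export
#' @examples
#' seq_tbl(c("a", "b"), c("ACDE", "wyw-y"))
seq_tbl <- function(id, residues, description = NA_character_) {
  out <- tibble::tibble(
    id = as.character(id),
    description = as.character(description),
    residues = normalize_residues(as.character(residues))
  )
  validate_seq_tbl(out)
}

#' Normalise residue strings to the 21-letter alphabet
#'
#' Upper-cases, removes gap characters (`-`, `.`) and maps the ambiguity
#' codes B, Z, J, U and O to X, yielding strings over the closed alphabet
#' required by alignment and tokenisation. Any remaining foreign character
#' raises an error.
#'
#' @param residues Character vector.
#' @return Character vector of normalised residue strings.
#' @export
#' @examples
#' normalize_residues("ac-de")  # "ACDE"
#' normalize_residues("ACBU")   # "ACXX"
normalize_residues <- function(residues) {
  x <- toupper(residues)
  x <- gsub("[-.]", "", x)
  x <- chartr("BZJUO", "XXXXX", x)
  bad <- grepl(paste0("[^", paste(aa_alphabet(), collapse = ""), "]"), x)
  if (any(bad)) {
    ch <- unique(unlist(strsplit(gsub(
      paste0("[", paste(aa_alphabet(), collapse = ""), "]"), "", x[bad]
    ), "")))
    rlang::abort(paste0(
      "residue string contains characters outside the amino-acid alphabet: ",
      paste(ch, collapse = " ")
    ))
  }
  x
}

#' Validate a sequence table
#'
#' Checks the invariants every downstream stage relies on: unique non-empty
#' ids and non-empty residue strings over the 21-letter alphabet.
#'
#' @param seqs A data frame with columns `id` and `residues`.
#' @return The input as a tibble, invisibly unchanged, or an error.
#' @export
validate_seq_tbl <- function(seqs) {
  seqs <- tibble::as_tibble(seqs)
  if (!all(c("id", "residues") %in% names(seqs))) {
    rlang::abort("a sequence table needs `id` and `residues` columns")
  }
  if (!"description" %in% names(seqs)) seqs$description <- NA_character_
  if (any(is.na(seqs$id) | seqs$id == "")) rlang::abort("sequence ids must be non-empty")
  dup <- unique(seqs$id[duplicated(seqs$id)])
  if (length(dup)) {
    rlang::abort(paste0("duplicate sequence id(s): ", paste(dup, collapse = ", ")))
  }
  if (nrow(seqs) && any(is.na(seqs$residues) | seqs$residues == "")) {
    rlang::abort("empty residue string")
  }
  if (nrow(seqs)) normalize_residues(seqs$residues)  # errors on foreign characters
  seqs[, c("id", "description", "residues")]
}

# FASTA --------------------------------------------------------------------

#' Read protein sequences from a FASTA file
#'
#' Headers are parsed as `id` = first whitespace-delimited token, with the
#' full header kept in `description`. Bodies are case-normalised, gap
#' characters are deleted and ambiguity codes B/Z/J/U/O are mapped to X
#' (see [normalize_residues()]). CRLF and LF line endings are both accepted.
#'
#' @param path Path to a FASTA file.
#' @return A sequence tibble (see [seq_tbl()]); empty with a warning for an
#'   empty file.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  keep <- !grepl("^\\s*$", lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    rlang::warn(paste0("empty FASTA file: ", path))
    return(seq_tbl(character(), character()))
  }
  is_header <- startsWith(lines, ">")
  if (!is_header[1]) {
    rlang::abort(paste0(
      "malformed FASTA: sequence line before any header at line ", line_no[1]
    ))
  }
  rec <- cumsum(is_header)
  headers <- sub("^>\\s*", "", lines[is_header])
  ids <- vapply(strsplit(headers, "\\s+"), `[`, "", 1)
  if (any(is.na(ids) | ids == "")) {
    bad <- line_no[is_header][which(is.na(ids) | ids == "")[1]]
    rlang::abort(paste0("malformed FASTA: empty header at line ", bad))
  }
  bodies <- vapply(split(lines[!is_header], rec[!is_header]), paste,
                   "", collapse = "")
  body <- character(length(ids))
  body[as.integer(names(bodies))] <- bodies
  empty <- !nzchar(gsub("[-.]", "", body))
  if (any(empty)) {
    rlang::abort(paste0(
      "FASTA record(s) with empty body: ", paste(ids[empty], collapse = ", ")
    ))
  }
  seq_tbl(ids, body, description = headers)
}

#' Write a sequence table to a FASTA file
#'
#' @param seqs A sequence tibble.
#' @param path Output path.
#' @param width Positive integer line width for wrapping bodies.
#' @return `path`, invisibly. `read_fasta(write_fasta(x, f))` reproduces `x`'s
#'   ids and residues.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  seqs <- validate_seq_tbl(seqs)
  stopifnot(is.numeric(width), width >= 1)
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  for (i in seq_len(nrow(seqs))) {
    desc <- seqs$description[i]
    header <- if (!is.na(desc) && nzchar(desc) && desc != seqs$id[i]) {
      desc
    } else {
      seqs$id[i]
    }
    writeLines(paste0(">", header), con)
    body <- seqs$residues[i]
    starts <- seq(1, nchar(body), by = width)
    writeLines(substring(body, starts, pmin(starts + width - 1, nchar(body))), con)
  }
  invisible(path)
}
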