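`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a stage-specific seed from a global seed
#'
#' Stochastic pipeline stages each draw their own seed deterministically from
#' one global seed plus the stage name, so a single integer reproduces a whole
#' run without coupling the RNG streams of different stages.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name (e.g. `"simulate"`, `"pretrain"`).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' stage_seed(1, "pretrain")
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) + h * 2654435 + 17) %% 2147483646) + 1L
}

# run code with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# residue alphabet: 20 standard amino acids (alphabetical) plus ambiguity X
aa_standard <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

aa_alphabet <- function() c(aa_standard(), "X")

abort_stage <- function(stage, msg) {
  rlang::abort(paste0("[", stage, "] ", msg))
}
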