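# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

DNA_BASES <- c("A", "C", "G", "T")

#' Sample a random DNA string
#'
#' @param n Length in nucleotides.
#' @param base_probs Length-4 probability vector over A, C, G, T.
#' @return A single character string.
#' @keywords internal
#' @noRd
random_dna <- function(n, base_probs = rep(0.25, 4)) {
  stopifnot(n >= 0, length(base_probs) == 4, all(base_probs >= 0))
  if (n == 0) return("")
  paste(sample(DNA_BASES, n, replace = TRUE, prob = base_probs), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Hamming distance of two equal-length strings; N never matches anything.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  sum(av != bv | av == "N" | bv == "N")
}

# evaluate code under a fixed seed, restoring the caller's RNG state
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

check_dna_alphabet <- function(sequence, id) {
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad)) {
    abort(sprintf(
      "non-IUPAC (non-ACGTN) character in sequence of record(s): %s",
      paste(id[bad], collapse = ", ")))
  }
  invisible(TRUE)
}
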