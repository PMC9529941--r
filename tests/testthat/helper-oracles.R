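# Independent oracles used across the suite. These deliberately take a
# different computational route than the package implementation.

# exact DP (Levenshtein) identity via base R adist(); for substitution-only
# pairs of equal length the edit distance equals the substitution count
oracle_identity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  100 * (1 - drop(utils::adist(a, b)) / nchar(a))
}

# aligned fraction oracle for no-indel constructions: 100-nt windows of the
# variant compared to the seed at the same offset; a window is aligned when
# its Hamming identity reaches 80%
oracle_aligned_fraction <- function(seed_seq, variant, window = 100) {
  L <- min(nchar(seed_seq), nchar(variant))
  starts <- seq(1, L - window + 1, by = window)
  ok <- vapply(starts, function(s) {
    a <- substr(seed_seq, s, s + window - 1)
    b <- substr(variant, s, s + window - 1)
    mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]]) >= 0.80
  }, logical(1))
  sum(ok) / length(ok)
}

# exact hypergeometric tail by enumeration: P(shared >= c) for genomes with
# a and b PCs drawn from a universe of M
oracle_hyper_tail <- function(c, a, b, M) {
  i <- c:min(a, b)
  sum(choose(b, i) * choose(M - b, a - i)) / choose(M, a)
}

# deterministic substitution at evenly spaced positions (A->C->G->T->A),
# giving an exactly known identity
flip_positions <- function(sequence, every) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  idx <- seq(1, length(chars), by = every)
  nxt <- c(A = "C", C = "G", G = "T", T = "A", N = "A")
  chars[idx] <- nxt[chars[idx]]
  paste(chars, collapse = "")
}

rand_dna <- function(n, probs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}
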