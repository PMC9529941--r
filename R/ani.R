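# Fragment-based average nucleotide identity and greedy species clustering.
#
# The shorter sequence of a pair is cut into non-overlapping fragments
# (default 500 nt); each fragment is aligned to its best window in the longer
# sequence (global in the fragment, local in the subject). Fragments reaching
# the per-fragment identity floor count as aligned; ANI is the
# length-weighted mean identity over aligned fragments and AF the aligned
# share of the shorter sequence. Fragmenting the shorter sequence makes the
# measure symmetric by construction.

ani_submat <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      bases <- c("A", "C", "G", "T", "N")
      mm <- matrix(-1, 5, 5, dimnames = list(bases, bases))
      diag(mm) <- 1
      mm["N", "N"] <- -1  # N never matches, conservatively
      m <<- mm
    }
    m
  }
})

# identity of one fragment against a window of the subject (global in the
# fragment, local in the window); counts N as mismatch
fragment_identity <- function(fragment, subject_dna) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(fragment), subject = subject_dna,
    type = "global-local", substitutionMatrix = ani_submat(),
    gapOpening = 4, gapExtension = 2)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  matches <- sum(p == s & p != "-" & p != "N")
  100 * matches / nchar(fragment)
}

# seed-and-extend placement: locate the fragment's homologous window in a
# long subject by exact 16-mer seeding against a hash index of the subject,
# then align only against that window. A fragment with no conserved 16-mer
# is treated as unaligned; at the 80% per-fragment identity floor this is
# rare (dozens of overlapping probes per fragment).
SEED_WIDTH <- 16L

subject_seed_index <- function(subject) {
  n <- nchar(subject) - SEED_WIDTH + 1L
  kmers <- substring(subject, seq_len(n), seq_len(n) + SEED_WIDTH - 1L)
  idx <- new.env(parent = emptyenv(), size = n)
  for (i in seq_len(n)) {
    idx[[kmers[i]]] <- c(idx[[kmers[i]]], i)
  }
  idx
}

fragment_identity_seeded <- function(fragment, subject_chr, subject_dna,
                                     seed_index, pad = 60L,
                                     dp_floor = 80) {
  flen <- nchar(fragment)
  offs <- unique(c(seq(1L, flen - SEED_WIDTH + 1L, by = 8L),
                   flen - SEED_WIDTH + 1L))
  probes <- substring(fragment, offs, offs + SEED_WIDTH - 1L)
  starts <- unlist(lapply(seq_along(offs), function(i) {
    hit <- seed_index[[probes[i]]]
    if (is.null(hit)) NULL else hit - offs[i] + 1L
  }))
  if (length(starts) == 0) return(0)
  # most-supported diagonal; a clean diagonal means no indels, where plain
  # per-position comparison is exact (and cheap)
  est <- as.integer(names(sort(table(starts), decreasing = TRUE))[1])
  if (est >= 1L && est + flen - 1L <= nchar(subject_chr)) {
    fv <- strsplit(fragment, "", fixed = TRUE)[[1]]
    sv <- strsplit(substr(subject_chr, est, est + flen - 1L), "",
                   fixed = TRUE)[[1]]
    ham_id <- 100 * sum(fv == sv & fv != "N") / flen
    if (ham_id >= dp_floor) return(ham_id)
  }
  # offset or indel-containing placement: full DP on the padded window
  from <- max(1L, est - pad)
  to <- min(length(subject_dna), max(from + SEED_WIDTH, est + flen - 1L + pad))
  fragment_identity(fragment, Biostrings::subseq(subject_dna, from, to))
}

#' Fragment-based average nucleotide identity between two sequences
#'
#' @param a,b DNA strings.
#' @param fragment Fragment size in nt (default 500). A sequence shorter
#'   than one fragment is aligned in a single full-length pass.
#' @param min_fragment_identity Per-fragment identity floor (percent) below
#'   which a fragment does not count as aligned (default 80).
#' @return A list with `ani` (percent identity over aligned fragments,
#'   `NA` if no fragment aligns) and `af` (aligned fraction of the shorter
#'   sequence).
#' @export
#' @examples
#' s <- strrep("ACGT", 800)
#' pairwise_ani(s, s)
pairwise_ani <- function(a, b, fragment = 500, min_fragment_identity = 80) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }  # a is shorter
  Ls <- nchar(a)
  subject_dna <- Biostrings::DNAString(b)

  starts <- seq(1L, Ls, by = fragment)
  ends <- pmin(starts + fragment - 1L, Ls)
  # fold a trailing sliver (<half fragment) into the previous fragment
  nf <- length(starts)
  if (nf > 1 && (ends[nf] - starts[nf] + 1L) < fragment / 2) {
    ends[nf - 1L] <- ends[nf]
    starts <- starts[-nf]; ends <- ends[-nf]
  }
  frags <- substring(a, starts, ends)
  lens <- ends - starts + 1L

  # against long subjects, place fragments by exact-seed diagonal first so
  # the quadratic alignment runs on a short window only
  if (length(subject_dna) > 6000) {
    seed_index <- subject_seed_index(b)
    ids <- vapply(frags, fragment_identity_seeded, numeric(1),
                  subject_chr = b, subject_dna = subject_dna,
                  seed_index = seed_index, USE.NAMES = FALSE)
  } else {
    ids <- vapply(frags, fragment_identity, numeric(1),
                  subject_dna = subject_dna, USE.NAMES = FALSE)
  }
  aligned <- ids >= min_fragment_identity
  if (!any(aligned)) return(list(ani = NA_real_, af = 0))
  list(
    ani = sum(ids[aligned] * lens[aligned]) / sum(lens[aligned]),
    af = sum(lens[aligned]) / Ls
  )
}

#' Greedy species-level (vOTU) clustering
#'
#' Longest-first greedy clustering: contigs are sorted by length descending
#' (ties by id ascending) and each joins the first existing cluster whose
#' representative it matches at `ani >= ani_min` and `af >= af_min`,
#' otherwise it founds a new cluster. The representative of every cluster is
#' therefore its longest member. Input order never affects the result.
#'
#' @param contigs Contig tibble with `contig_id`, `sequence` (see
#'   [contigs_tbl()]).
#' @param ani_min Minimum average nucleotide identity, percent (default 95).
#' @param af_min Minimum aligned fraction of the shorter contig
#'   (default 0.85).
#' @param fragment Fragment size passed to [pairwise_ani()].
#' @return Tibble with one row per contig: `votu_id`, `contig_id`,
#'   `representative` (logical), `ani`, `af` (identity/fraction to the
#'   representative; 100/1 for representatives themselves).
#' @export
cluster_votus <- function(contigs, ani_min = 95, af_min = 0.85, fragment = 500) {
  assert_columns(contigs, c("contig_id", "sequence"))
  if (nrow(contigs) == 0) abort("no contigs to cluster")
  ord <- contigs %>%
    mutate(length = nchar(.data$sequence)) %>%
    arrange(dplyr::desc(.data$length), .data$contig_id)

  reps <- integer(0)            # row indices of representatives
  rows <- vector("list", nrow(ord))
  for (i in seq_len(nrow(ord))) {
    assigned <- FALSE
    for (j in seq_along(reps)) {
      r <- reps[j]
      hit <- pairwise_ani(ord$sequence[i], ord$sequence[r], fragment = fragment)
      if (!is.na(hit$ani) && hit$ani >= ani_min && hit$af >= af_min) {
        rows[[i]] <- tibble(votu_id = sprintf("vOTU_%04d", j),
                            contig_id = ord$contig_id[i],
                            representative = FALSE,
                            ani = hit$ani, af = hit$af)
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, i)
      rows[[i]] <- tibble(votu_id = sprintf("vOTU_%04d", length(reps)),
                          contig_id = ord$contig_id[i],
                          representative = TRUE, ani = 100, af = 1)
    }
  }
  out <- bind_rows(rows)
  # every member satisfies the thresholds to its representative, by search
  stopifnot(all(out$ani >= ani_min - 1e-9), all(out$af >= af_min - 1e-9))
  arrange(out, .data$votu_id, dplyr::desc(.data$representative), .data$contig_id)
}
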