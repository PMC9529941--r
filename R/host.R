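# Virus-host linkage: four evidence collectors (nucleotide homology, CRISPR
# spacers, shared tRNAs, k-mer composition) and an integrated confidence
# score with the >=3 high-confidence rule.

#' Filter virus-host nucleotide homology matches
#'
#' Keeps alignment rows supporting a shared (prophage-like) segment:
#' alignment length >= `min_length`, identity >= `min_identity`, and total
#' aligned host bases for the pair below `max_host_cov` of the host genome
#' (near-complete coverage of the host sequence indicates a mis-binned viral
#' contig, not an integrated segment).
#'
#' @param alignments Alignment tibble (virus query vs host subject) from
#'   [read_alignment_table()].
#' @param host_lengths Tibble `host_id`, `length` (nt).
#' @param min_length Minimum alignment length, nt (default 2500).
#' @param min_identity Minimum percent identity (default 70).
#' @param max_host_cov Host-coverage ceiling, fraction (default 0.90,
#'   exclusive).
#' @return Evidence tibble `virus_id`, `host_id`, `method` ("homology"),
#'   `aln_length`, `pct_identity`, `host_coverage`.
#' @export
filter_homology_matches <- function(alignments, host_lengths,
                                    min_length = 2500, min_identity = 70,
                                    max_host_cov = 0.90) {
  assert_columns(alignments, c("query_id", "subject_id", "pct_identity",
                               "aln_length", "s_start", "s_end"))
  assert_columns(host_lengths, c("host_id", "length"))
  unknown <- setdiff(alignments$subject_id, host_lengths$host_id)
  if (length(unknown) > 0) {
    abort(sprintf("alignment references unknown host(s): %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  cov <- alignments %>%
    group_by(virus_id = .data$query_id, host_id = .data$subject_id) %>%
    summarise(host_bases = sum(abs(.data$s_end - .data$s_start) + 1),
              .groups = "drop") %>%
    inner_join(host_lengths, by = "host_id") %>%
    mutate(host_coverage = .data$host_bases / .data$length)
  alignments %>%
    filter(.data$aln_length >= min_length,
           .data$pct_identity >= min_identity) %>%
    rename(virus_id = "query_id", host_id = "subject_id") %>%
    inner_join(select(cov, "virus_id", "host_id", "host_coverage"),
               by = c("virus_id", "host_id")) %>%
    filter(.data$host_coverage < max_host_cov) %>%
    group_by(.data$virus_id, .data$host_id) %>%
    slice_max(.data$aln_length, n = 1, with_ties = FALSE) %>%
    ungroup() %>%
    mutate(method = "homology") %>%
    select("virus_id", "host_id", "method", "aln_length", "pct_identity",
           "host_coverage")
}

#' Detect CRISPR arrays on assembled host sequences
#'
#' A minimal repeat-run detector: reports maximal runs of at least
#' `min_copies` exact copies of a repeat of length in `repeat_range`,
#' separated by spacers of length in `spacer_range`; the spacers of an array
#' must be mutually distinct (a tandem repeat is not a CRISPR array).
#'
#' @param host_seq A single host DNA string (>= 200 nt).
#' @param host_id Identifier attached to reported arrays.
#' @param repeat_range Repeat length bounds, nt (default 23-47).
#' @param spacer_range Spacer length bounds, nt (default 26-50).
#' @param min_copies Minimum exact repeat copies (default 3).
#' @return Tibble with one row per array: `host_id`, `start`, `end` (1-based
#'   inclusive), `repeat_seq`, `n_repeats`, `spacers` (list column of
#'   spacer strings).
#' @export
detect_crispr_arrays <- function(host_seq, host_id = "host",
                                 repeat_range = c(23, 47),
                                 spacer_range = c(26, 50),
                                 min_copies = 3) {
  L <- nchar(host_seq)
  if (L < 200) abort("host sequence shorter than 200 nt")
  k <- repeat_range[1]
  step_min <- k + spacer_range[1]
  step_max <- repeat_range[2] + spacer_range[2]

  # seed on k-mers occurring >= min_copies times with plausible spacing
  starts <- seq_len(L - k + 1L)
  kmers <- substring(host_seq, starts, starts + k - 1L)
  idx <- split(starts, kmers)
  idx <- idx[lengths(idx) >= min_copies]

  arrays <- list()
  for (km in names(idx)) {
    pos <- sort(idx[[km]])
    # maximal chains with consecutive start-gaps inside the array geometry
    run_start <- 1L
    for (i in seq_along(pos)) {
      end_of_run <- i == length(pos) ||
        (pos[i + 1] - pos[i] < step_min || pos[i + 1] - pos[i] > step_max)
      if (end_of_run) {
        run <- pos[run_start:i]
        run_start <- i + 1L
        if (length(run) < min_copies) next
        rep_len <- extend_repeat(host_seq, run, k, repeat_range[2],
                                 spacer_range[1])
        spacer_starts <- head(run, -1) + rep_len
        spacer_ends <- tail(run, -1) - 1L
        sp_len <- spacer_ends - spacer_starts + 1L
        if (any(sp_len < spacer_range[1] | sp_len > spacer_range[2])) next
        spacers <- substring(host_seq, spacer_starts, spacer_ends)
        if (anyDuplicated(spacers)) next
        arrays[[length(arrays) + 1L]] <- tibble(
          host_id = host_id,
          start = run[1],
          end = tail(run, 1) + rep_len - 1L,
          repeat_seq = substring(host_seq, run[1], run[1] + rep_len - 1L),
          n_repeats = length(run),
          spacers = list(spacers)
        )
      }
    }
  }
  if (length(arrays) == 0) {
    return(tibble(host_id = character(), start = integer(), end = integer(),
                  repeat_seq = character(), n_repeats = integer(),
                  spacers = list()))
  }
  # seeds shifted within the same repeat rediscover the same array; keep the
  # candidate with the longest repeat (ties: leftmost) per overlapping locus
  cand <- bind_rows(arrays) %>%
    arrange(dplyr::desc(nchar(.data$repeat_seq)), .data$start)
  kept <- list()
  for (i in seq_len(nrow(cand))) {
    overlaps <- any(vapply(kept, function(kp) {
      cand$start[i] <= kp$end && cand$end[i] >= kp$start
    }, logical(1)))
    if (!overlaps) kept[[length(kept) + 1L]] <- cand[i, ]
  }
  bind_rows(kept) %>% arrange(.data$start)
}

# extend a seeded repeat to the right while all copies still agree and the
# shortest spacer keeps its minimum length
extend_repeat <- function(seq, run, k, max_len, min_spacer) {
  gaps <- diff(run)
  cap <- min(max_len, if (length(gaps)) min(gaps) - min_spacer else max_len)
  len <- k
  while (len < cap) {
    nxt <- substring(seq, run + len, run + len)
    if (length(unique(nxt)) != 1 || any(nxt == "")) break
    len <- len + 1L
  }
  len
}

#' Match CRISPR spacers against viral contigs
#'
#' A spacer links its host to a virus when the spacer (or its reverse
#' complement) occurs in the viral contig at full length with at most
#' `max_mismatch` substitutions. Spacers shorter than `min_length` are not
#' consulted.
#'
#' @param arrays Array tibble from [detect_crispr_arrays()] (columns
#'   `host_id`, `spacers`).
#' @param viral_contigs Contig tibble (`contig_id`, `sequence`).
#' @param max_mismatch Mismatch tolerance (default 1).
#' @param min_length Minimum spacer length consulted (default 20).
#' @return Evidence tibble `virus_id`, `host_id`, `method` ("crispr"),
#'   `spacer`, `mismatches`.
#' @export
match_spacers <- function(arrays, viral_contigs, max_mismatch = 1,
                          min_length = 20) {
  assert_columns(viral_contigs, c("contig_id", "sequence"))
  if (nrow(arrays) == 0) {
    return(tibble(virus_id = character(), host_id = character(),
                  method = character(), spacer = character(),
                  mismatches = integer()))
  }
  spacer_tbl <- arrays %>%
    select("host_id", "spacers") %>%
    tidyr::unnest_longer("spacers", values_to = "spacer") %>%
    distinct(.data$host_id, .data$spacer) %>%
    filter(nchar(.data$spacer) >= min_length)

  subjects <- Biostrings::DNAStringSet(viral_contigs$sequence)
  names(subjects) <- viral_contigs$contig_id

  hit_rows <- purrr::pmap(spacer_tbl, function(host_id, spacer) {
    pat_f <- Biostrings::DNAString(spacer)
    pat_r <- Biostrings::reverseComplement(pat_f)
    purrr::map(seq_along(subjects), function(i) {
      mm <- NA_integer_
      for (pat in list(pat_f, pat_r)) {
        m <- Biostrings::matchPattern(pat, subjects[[i]],
                                      max.mismatch = max_mismatch,
                                      with.indels = FALSE, fixed = TRUE)
        if (length(m) > 0) {
          mmv <- Biostrings::neditStartingAt(pat, subjects[[i]],
                                             starting.at = Biostrings::start(m),
                                             with.indels = FALSE)
          mm <- min(mm, min(mmv), na.rm = TRUE)
        }
      }
      if (is.na(mm)) return(NULL)
      tibble(virus_id = names(subjects)[i], host_id = host_id,
             method = "crispr", spacer = spacer, mismatches = as.integer(mm))
    })
  })
  out <- bind_rows(purrr::flatten(hit_rows))
  if (nrow(out) == 0) {
    return(tibble(virus_id = character(), host_id = character(),
                  method = character(), spacer = character(),
                  mismatches = integer()))
  }
  out %>%
    group_by(.data$virus_id, .data$host_id, .data$spacer) %>%
    summarise(method = "crispr", mismatches = min(.data$mismatches),
              .groups = "drop") %>%
    select("virus_id", "host_id", "method", "spacer", "mismatches")
}

#' Match shared tRNA genes
#'
#' A host tRNA links to a virus only when the full tRNA sequence occurs
#' exactly (either strand) in the viral contig.
#'
#' @param trnas Tibble `host_id`, `trna_id`, `sequence` (60-120 nt each).
#' @param viral_contigs Contig tibble (`contig_id`, `sequence`).
#' @return Evidence tibble `virus_id`, `host_id`, `method` ("trna"),
#'   `trna_id`.
#' @export
match_trna <- function(trnas, viral_contigs) {
  assert_columns(trnas, c("host_id", "trna_id", "sequence"))
  assert_columns(viral_contigs, c("contig_id", "sequence"))
  subjects <- Biostrings::DNAStringSet(viral_contigs$sequence)
  names(subjects) <- viral_contigs$contig_id
  rows <- purrr::pmap(trnas, function(host_id, trna_id, sequence, ...) {
    pat_f <- Biostrings::DNAString(sequence)
    pat_r <- Biostrings::reverseComplement(pat_f)
    purrr::map(seq_along(subjects), function(i) {
      hit <- Biostrings::vcountPattern(pat_f, subjects[i], fixed = TRUE) > 0 ||
        Biostrings::vcountPattern(pat_r, subjects[i], fixed = TRUE) > 0
      if (!hit) return(NULL)
      tibble(virus_id = names(subjects)[i], host_id = host_id,
             method = "trna", trna_id = trna_id)
    })
  })
  out <- bind_rows(purrr::flatten(rows))
  if (nrow(out) == 0) {
    return(tibble(virus_id = character(), host_id = character(),
                  method = character(), trna_id = character()))
  }
  distinct(out)
}

#' Train order-k Markov composition models for host genomes
#'
#' Conditional next-base probabilities given the preceding k-mer, estimated
#' from each host genome and its reverse complement with add-one
#' pseudocounts.
#'
#' @param hosts Tibble `host_id`, `sequence`.
#' @param k Markov order (0-7; default 3).
#' @return A named list of models (one per host), each a matrix of
#'   conditional probabilities (4^k contexts x 4 bases), with attribute
#'   `k`.
#' @export
train_markov_models <- function(hosts, k = 3) {
  assert_columns(hosts, c("host_id", "sequence"))
  stopifnot(k >= 0, k <= 7)
  models <- purrr::map(seq_len(nrow(hosts)), function(i) {
    s <- Biostrings::DNAString(hosts$sequence[i])
    both <- Biostrings::DNAStringSet(list(s, Biostrings::reverseComplement(s)))
    counts <- Biostrings::oligonucleotideFrequency(both, width = k + 1)
    counts <- colSums(counts) + 1  # add-one pseudocounts
    if (k == 0) {
      p <- counts / sum(counts)
      m <- matrix(p, nrow = 1, dimnames = list("", names(counts)))
    } else {
      ctx <- substr(names(counts), 1, k)
      nxt <- substr(names(counts), k + 1, k + 1)
      m <- tapply(counts, list(ctx, nxt), sum)
      m <- m / rowSums(m)
    }
    attr(m, "k") <- k
    m
  })
  setNames(models, hosts$host_id)
}

#' Score a viral contig against host composition models
#'
#' Mean log-probability per transition of the contig under each host's
#' order-k Markov model; hosts are ranked descending and the top-ranked
#' host is emitted as k-mer composition evidence.
#'
#' @param viral_seq A single viral contig DNA string (longer than k).
#' @param models Model list from [train_markov_models()].
#' @param virus_id Identifier used in the evidence row.
#' @return A list with `scores` (tibble `host_id`, `loglik_per_nt`, `rank`)
#'   and `evidence` (one-row tibble for the top host, with the score gap to
#'   the runner-up).
#' @export
markov_score <- function(viral_seq, models, virus_id = "virus") {
  k <- attr(models[[1]], "k")
  if (nchar(viral_seq) <= k) abort("contig shorter than k + 1")
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(viral_seq), width = k + 1)
  counts <- counts[counts > 0]
  lls <- purrr::map_dbl(models, function(m) {
    if (k == 0) {
      lp <- log(m[1, names(counts)])
    } else {
      ctx <- substr(names(counts), 1, k)
      nxt <- substr(names(counts), k + 1, k + 1)
      lp <- log(m[cbind(ctx, nxt)])
    }
    unname(sum(lp * counts) / sum(counts))
  })
  scores <- tibble(host_id = names(models), loglik_per_nt = unname(lls)) %>%
    arrange(dplyr::desc(.data$loglik_per_nt)) %>%
    mutate(rank = row_number())
  gap <- if (nrow(scores) > 1) {
    scores$loglik_per_nt[1] - scores$loglik_per_nt[2]
  } else {
    Inf
  }
  list(
    scores = scores,
    evidence = tibble(virus_id = virus_id, host_id = scores$host_id[1],
                      method = "kmer", loglik_per_nt = scores$loglik_per_nt[1],
                      rank_gap = gap)
  )
}

#' Integrate host evidence into scored predictions
#'
#' Point table (a documented surrogate preserving only the published >=3
#' high-confidence decision boundary): exact CRISPR spacer 5, 1-mismatch
#' CRISPR spacer 3, nucleotide homology 3, shared tRNA 2, top-ranked k-mer
#' composition 1. A (virus, host) pair scores the maximum base value of its
#' evidence plus 0.5 per additional distinct supporting method, capped at 5.
#'
#' @param evidence Evidence tibble with columns `virus_id`, `host_id`,
#'   `method` and method details (`mismatches` for CRISPR rows).
#' @param points Named list of base points (see [virome_config()]
#'   `host_points`).
#' @param score_min High-confidence threshold (default 3).
#' @return Tibble `virus_id`, `host_id`, `score`, `high_confidence`,
#'   `methods` (semicolon-joined), `n_methods`.
#' @export
integrate_host_evidence <- function(evidence,
                                    points = list(crispr0 = 5, crispr1 = 3,
                                                  homology = 3, trna = 2,
                                                  kmer = 1),
                                    score_min = 3) {
  assert_columns(evidence, c("virus_id", "host_id", "method"))
  if (nrow(evidence) == 0) {
    return(tibble(virus_id = character(), host_id = character(),
                  score = double(), high_confidence = logical(),
                  methods = character(), n_methods = integer()))
  }
  if (!"mismatches" %in% names(evidence)) {
    evidence <- mutate(evidence, mismatches = NA_integer_)
  }
  ev <- evidence %>%
    mutate(base = dplyr::case_when(
      .data$method == "crispr" &
        tidyr::replace_na(.data$mismatches, 0L) == 0L ~ points$crispr0,
      .data$method == "crispr" ~ points$crispr1,
      .data$method == "homology" ~ points$homology,
      .data$method == "trna" ~ points$trna,
      .data$method == "kmer" ~ points$kmer,
      TRUE ~ NA_real_
    ))
  if (any(is.na(ev$base))) abort("evidence row with unknown method")
  ev %>%
    group_by(.data$virus_id, .data$host_id) %>%
    summarise(
      score = pmin(max(.data$base) + 0.5 * (n_distinct(.data$method) - 1), 5),
      methods = paste(sort(unique(.data$method)), collapse = ";"),
      n_methods = n_distinct(.data$method),
      .groups = "drop"
    ) %>%
    mutate(high_confidence = .data$score >= score_min) %>%
    select("virus_id", "host_id", "score", "high_confidence", "methods",
           "n_methods") %>%
    arrange(dplyr::desc(.data$score), .data$virus_id, .data$host_id)
}
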