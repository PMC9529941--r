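aln_row <- function(virus, host, len, id, s_start = 1000) {
  tibble::tibble(query_id = virus, subject_id = host, pct_identity = id,
                 aln_length = len, mismatches = 0L, gaps = 0L,
                 q_start = 1L, q_end = len, s_start = s_start,
                 s_end = s_start + len - 1L, evalue = 0, bitscore = 2 * len)
}

test_that("homology matches pass the length/identity/host-coverage gates", {
  hosts <- tibble::tibble(host_id = c("h1", "h2"), length = c(30000L, 3200L))
  alns <- dplyr::bind_rows(
    aln_row("v1", "h1", 3000L, 85),     # kept: coverage 10%
    aln_row("v2", "h1", 2000L, 99),     # dropped: below 2500
    aln_row("v3", "h2", 3000L, 85)      # dropped: 94% of the host covered
  )
  got <- filter_homology_matches(alns, hosts)
  expect_equal(got$virus_id, "v1")
  expect_equal(got$method, "homology")
  expect_lt(got$host_coverage, 0.90)

  # identity below 70 is dropped too
  low <- aln_row("v4", "h1", 5000L, 65)
  expect_equal(nrow(filter_homology_matches(low, hosts)), 0)
  expect_error(filter_homology_matches(aln_row("v", "nope", 3000L, 80), hosts),
               "unknown host")

  # idempotent: re-filtering the kept evidence keeps it
  again <- filter_homology_matches(
    dplyr::filter(alns, .data$query_id == "v1"), hosts)
  expect_equal(again, got)
})

test_that("CRISPR array detector finds planted arrays and nothing in noise", {
  set.seed(41)
  rep30 <- rand_dna(30)
  spacers <- replicate(3, rand_dna(32))
  array <- paste0(rep30, paste0(spacers, rep30, collapse = ""))
  host <- paste0(rand_dna(4000), array, rand_dna(4000))
  got <- detect_crispr_arrays(host, host_id = "hA")
  expect_equal(nrow(got), 1)
  expect_equal(got$n_repeats, 4)
  expect_equal(got$repeat_seq, rep30)
  expect_equal(got$spacers[[1]], spacers)

  # two repeat copies only: below the minimum, not reported
  two <- paste0(rand_dna(2000), rep30, rand_dna(32), rep30, rand_dna(2000))
  expect_equal(nrow(detect_crispr_arrays(two)), 0)

  # random sequence: no arrays
  expect_equal(nrow(detect_crispr_arrays(rand_dna(10000))), 0)
  expect_error(detect_crispr_arrays(rand_dna(100)), "200")
})

test_that("spacer matching tolerates one substitution and is strand-symmetric", {
  set.seed(42)
  virus <- rand_dna(8000)
  spacer <- substr(virus, 3001, 3032)
  spacer1 <- flip_positions(spacer, every = 32)   # 1 substitution
  spacer2 <- flip_positions(spacer1, every = 17)  # 2-3 substitutions
  arrays <- tibble::tibble(host_id = c("h0", "h1", "h2"),
                           spacers = list(spacer, spacer1, spacer2))
  contigs <- contigs_tbl("v1", virus)
  got <- match_spacers(arrays, contigs)
  expect_setequal(got$host_id, c("h0", "h1"))
  expect_equal(got$mismatches[got$host_id == "h0"], 0L)
  expect_equal(got$mismatches[got$host_id == "h1"], 1L)

  # reverse-complementing the viral contig changes nothing
  rc <- contigs_tbl("v1", as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(virus))))
  got_rc <- match_spacers(arrays, rc)
  expect_equal(got_rc[, c("host_id", "mismatches")],
               got[, c("host_id", "mismatches")])
})

test_that("tRNA links require full-length exact matches on either strand", {
  set.seed(43)
  trna <- rand_dna(75)
  virus_with <- paste0(rand_dna(2000), trna, rand_dna(2000))
  virus_rc <- paste0(rand_dna(2000),
                     as.character(Biostrings::reverseComplement(
                       Biostrings::DNAString(trna))), rand_dna(2000))
  virus_near <- paste0(rand_dna(2000), flip_positions(trna, 75),
                       rand_dna(2000))
  trnas <- tibble::tibble(host_id = "hA", trna_id = "tRNA-Met", sequence = trna)
  contigs <- contigs_tbl(c("vf", "vr", "vn"),
                         c(virus_with, virus_rc, virus_near))
  got <- match_trna(trnas, contigs)
  expect_setequal(got$virus_id, c("vf", "vr"))  # 1 mismatch: no evidence
})

test_that("Markov scoring has the closed-form order-0 value and ranks by composition", {
  # order-0 model on a perfectly uniform genome: score is exactly ln(1/4)
  uniform <- paste(rep("ACGT", 5000), collapse = "")
  m0 <- train_markov_models(tibble::tibble(host_id = "u", sequence = uniform),
                            k = 0)
  got <- markov_score(rand_dna(2000), m0)
  expect_equal(got$scores$loglik_per_nt, log(0.25), tolerance = 1e-6)

  # composition-distinct hosts: the contig's source ranks first
  set.seed(44)
  hosts <- tibble::tibble(
    host_id = c("gc70", "gc30"),
    sequence = c(rand_dna(40000, c(.15, .35, .35, .15)),
                 rand_dna(40000, c(.35, .15, .15, .35))))
  models <- train_markov_models(hosts, k = 3)
  res <- markov_score(rand_dna(5000, c(.15, .35, .35, .15)), models,
                      virus_id = "vx")
  expect_equal(res$evidence$host_id, "gc70")
  expect_true(all(res$scores$loglik_per_nt <= 0))

  # each host's own genome scores best under its own model
  for (i in 1:2) {
    own <- markov_score(substr(hosts$sequence[i], 1, 10000), models)
    expect_equal(own$scores$host_id[1], hosts$host_id[i])
  }
  expect_error(markov_score("ACG", models), "shorter")
})

test_that("evidence integration scores pairs and applies the >=3 rule", {
  ev <- function(method, mismatches = NA_integer_) {
    tibble::tibble(virus_id = "v", host_id = "h", method = method,
                   mismatches = mismatches)
  }
  score_of <- function(e) integrate_host_evidence(e)$score
  expect_equal(score_of(ev("crispr", 0L)), 5)
  expect_equal(score_of(ev("crispr", 1L)), 3)
  expect_equal(score_of(ev("kmer")), 1)
  expect_equal(score_of(dplyr::bind_rows(ev("homology"), ev("trna"))), 3.5)
  # cap at 5: exact CRISPR plus three more methods
  all4 <- dplyr::bind_rows(ev("crispr", 0L), ev("homology"), ev("trna"),
                           ev("kmer"))
  expect_equal(score_of(all4), 5)

  got <- integrate_host_evidence(dplyr::bind_rows(ev("kmer"), ev("trna")))
  expect_equal(got$score, 2.5)
  expect_false(got$high_confidence)
  expect_true(integrate_host_evidence(ev("crispr", 1L))$high_confidence)
  expect_equal(nrow(integrate_host_evidence(ev("kmer")[0, ])), 0)
})

test_that("planted CRISPR links are recovered with precision and recall 1", {
  gs <- sim_genomes(n_viral = 8, n_host = 4, n_nonviral = 0,
                    crispr_fraction = 1, trna_fraction = 0,
                    homology_fraction = 0, seed = 77)
  hosts <- dplyr::filter(gs$contigs, .data$source_set == "host_mag")
  viruses <- dplyr::filter(gs$contigs, .data$source_set == "assembly")
  arrays <- dplyr::bind_rows(purrr::map2(
    hosts$sequence, hosts$contig_id,
    ~ detect_crispr_arrays(.x, host_id = .y)))
  found <- match_spacers(arrays, viruses) |>
    dplyr::distinct(.data$virus_id, .data$host_id)
  planted <- gs$host_links |>
    dplyr::filter(.data$method == "crispr") |>
    dplyr::distinct(.data$virus_id, .data$host_id)
  expect_setequal(paste(found$virus_id, found$host_id),
                  paste(planted$virus_id, planted$host_id))
})
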