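test_that("gene products classify by keyword, with correct precedence", {
  expect_equal(
    classify_gene_product(c("phage terminase large subunit",
                            "hypothetical protein",
                            "30S ribosomal protein S3",
                            "major capsid protein",
                            "tail fiber protein",
                            "protein of unknown function",
                            "Viruses",
                            "ATP synthase")),
    c("viral_specific", "unknown", "prokaryote_specific", "viral_specific",
      "viral_specific", "unknown", "unknown", "other"))
  # word-boundary matching: "head" must not fire inside "overhead"
  expect_equal(classify_gene_product("overhead crane operator"), "other")
  expect_equal(classify_gene_product("head-tail connector"), "viral_specific")
  # phrases and case-insensitivity
  expect_equal(classify_gene_product("DNA PACKAGING protein"), "viral_specific")
  # prokaryote marker outranks a viral keyword in the same string
  expect_equal(classify_gene_product("phage-type 50S ribosomal protein"),
               "prokaryote_specific")
  expect_equal(classify_gene_product(""), "other")
})

make_gene_tbl <- function(contig, products) {
  tibble::tibble(
    gene_id = sprintf("%s_g%d", contig, seq_along(products)),
    contig_id = contig,
    start = (seq_along(products) - 1L) * 1000L,
    end = (seq_along(products) - 1L) * 1000L + 900L,
    strand = "+",
    product = products
  )
}

test_that("triage retain/reject rules fire as specified", {
  calls <- tibble::tibble(contig_id = c("q", "u", "p", "w"),
                          tool = "VIBRANT", call = TRUE)
  comp <- tibble::tibble(contig_id = c("q", "u", "p", "w"),
                         completeness = c(80, 60, 90, NA))
  genes <- dplyr::bind_rows(
    # quorum: 2 viral-specific among 10
    make_gene_tbl("q", c("major capsid protein", "portal protein",
                         rep("glycosyltransferase", 8))),
    # 1 viral gene and only 60% unknown: fails both routes
    make_gene_tbl("u", c("major capsid protein", rep("hypothetical protein", 6),
                         rep("glycosyltransferase", 3))),
    # quorum met but a ribosomal gene kills it
    make_gene_tbl("p", c("major capsid protein", "portal protein",
                         "terminase small subunit",
                         "50S ribosomal protein L2",
                         rep("hypothetical protein", 6))),
    # unknown-majority route: 70% unknown + predictor call
    make_gene_tbl("w", c(rep("hypothetical protein", 7),
                         rep("glycosyltransferase", 3)))
  )
  dec <- triage_contigs(genes, calls, comp)
  dec <- dec[match(c("q", "u", "p", "w"), dec$contig_id), ]
  expect_equal(dec$retained, c(TRUE, FALSE, FALSE, TRUE))
  expect_match(dec$reasons[1], "VIRAL_GENE_QUORUM")
  expect_match(dec$reasons[3], "PROKARYOTE_GENE")
  expect_match(dec$reasons[4], "UNKNOWN_MAJORITY")
  expect_equal(dec$n_viral_specific[3], 3L)
  expect_equal(dec$n_prokaryote[3], 1L)
})

test_that("unknown-majority route needs predictor support and the
           conservative-signal rule needs one of its three outs", {
  genes <- make_gene_tbl("x", c(rep("hypothetical protein", 8),
                                rep("glycosyltransferase", 2)))
  no_call <- tibble::tibble(contig_id = "x", tool = "VIBRANT", call = FALSE)
  dec <- triage_contigs(genes, no_call,
                        tibble::tibble(contig_id = "x", completeness = 50))
  expect_false(dec$retained)

  # with a call but from a non-conservative tool and no completeness, the
  # conservative signal is missing
  soft_call <- tibble::tibble(contig_id = "x", tool = "Seeker", call = TRUE)
  dec2 <- triage_contigs(genes, soft_call)
  expect_false(dec2$retained)
  expect_match(dec2$reasons, "CONSERVATIVE_SIGNAL_MISSING")

  # same contig with a VirSorter2 call is retained
  hard_call <- tibble::tibble(contig_id = "x", tool = "VirSorter2", call = TRUE)
  dec3 <- triage_contigs(genes, hard_call)
  expect_true(dec3$retained)

  # a contig with predictor calls but no gene rows: NO_EVIDENCE
  dec4 <- triage_contigs(genes, tibble::tibble(contig_id = c("x", "ghost"),
                                               tool = "VirSorter2",
                                               call = TRUE))
  expect_false(dec4$retained[dec4$contig_id == "ghost"])
  expect_equal(dec4$reasons[dec4$contig_id == "ghost"], "NO_EVIDENCE")
})

test_that("triage recovers generator truth on perfectly annotated contigs", {
  gs <- sim_genomes(n_viral = 30, n_host = 0, n_nonviral = 30,
                    sensitivity = 1, specificity = 1, seed = 42)
  comp <- tibble::tibble(contig_id = gs$truth$contig_id, completeness = 50)
  dec <- triage_contigs(gs$genes, gs$predictor_calls, comp,
                        contig_ids = gs$truth$contig_id)
  joined <- dplyr::inner_join(dec, gs$truth, by = "contig_id")
  # sensitivity 1 on viral contigs with the keyword quorum
  pos <- joined[joined$is_viral & joined$n_keyword_genes >= 2 &
                  joined$n_ribosomal == 0, ]
  expect_gt(nrow(pos), 10)
  expect_true(all(pos$retained))
  # specificity 1 on contigs carrying a ribosomal marker
  neg <- joined[joined$n_ribosomal > 0, ]
  expect_gt(nrow(neg), 10)
  expect_false(any(neg$retained))
})

test_that("DTR detection finds exact terminal overlaps and only those", {
  set.seed(7)
  core <- rand_dna(5000)
  rep25 <- rand_dna(25)
  got <- detect_dtr(paste0(rep25, core, rep25))
  expect_true(got$dtr)
  expect_gte(got$repeat_length, 25)

  expect_false(detect_dtr(rand_dna(10000))$dtr)

  rep19 <- rand_dna(19)
  expect_false(detect_dtr(paste0(rep19, core, rep19), min_repeat = 20)$dtr)
  expect_error(detect_dtr("ACGTACGT", min_repeat = 20), "too short")
})

test_that("quality tiers partition the (completeness, dtr) space", {
  expect_equal(
    assign_quality_tier(c(100, 100, 95, 91, 90, 50, 49.9, NA),
                        dtr = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE,
                                FALSE, TRUE)),
    c("complete", "high", "high", "high", "medium", "medium", "low",
      "undetermined"))
  expect_error(assign_quality_tier(101), "out of")
  # exactly one tier for every grid point
  grid <- expand.grid(comp = c(NA, 0, 25, 49.99, 50, 75, 90, 90.01, 99, 100),
                      dtr = c(TRUE, FALSE))
  tiers <- assign_quality_tier(grid$comp, grid$dtr)
  expect_true(all(tiers %in% c("complete", "high", "medium", "low",
                               "undetermined")))
  expect_equal(length(tiers), nrow(grid))
})

test_that("blank-control decontamination removes >=1-read contigs, monotonically", {
  retained <- c("a", "b", "c", "d")
  hits <- tibble::tibble(contig_id = c("a", "b"), blank_reads = c(1L, 0L))
  got <- decontaminate(retained, hits)
  expect_equal(got$removed, "a")
  expect_setequal(got$kept, c("b", "c", "d"))

  empty <- tibble::tibble(contig_id = character(), blank_reads = integer())
  expect_setequal(decontaminate(retained, empty)$kept, retained)

  expect_warning(
    decontaminate(retained, tibble::tibble(contig_id = "zz", blank_reads = 3L)),
    "not in the retained set")

  # monotone: adding blank hits never grows the kept set
  bigger <- dplyr::bind_rows(hits, tibble::tibble(contig_id = "c",
                                                  blank_reads = 2L))
  expect_true(all(decontaminate(retained, bigger)$kept %in% got$kept))
})
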