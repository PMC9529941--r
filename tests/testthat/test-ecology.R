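test_that("depth computation filters reads and zeroes low-covered contigs", {
  lens <- tibble::tibble(contig_id = "c1", length = 1000L)
  reads <- tibble::tibble(contig_id = "c1", sample_id = "s1",
                          identity = rep(0.98, 100), aln_length = 100L)
  cov <- tibble::tibble(contig_id = "c1", sample_id = "s1",
                        covered_fraction = 0.95)
  got <- compute_depth(reads, lens, cov)
  expect_equal(got$depth, 10)

  # a 90%-identity read contributes nothing
  reads90 <- dplyr::bind_rows(reads,
                              tibble::tibble(contig_id = "c1", sample_id = "s1",
                                             identity = 0.90,
                                             aln_length = 10000L))
  expect_equal(compute_depth(reads90, lens, cov)$depth, 10)
  # short alignments are dropped too
  reads49 <- dplyr::mutate(reads, aln_length = 49L)
  expect_equal(compute_depth(reads49, lens, cov)$depth, 0)

  # the <10% covered-fraction rule zeroes the mean depth
  cov09 <- dplyr::mutate(cov, covered_fraction = 0.09)
  expect_equal(compute_depth(reads, lens, cov09)$depth, 0)
})

test_that("the zeroing rule toggles exactly at the 10% boundary", {
  base <- tibble::tibble(contig_id = "c", sample_id = "s", depth = 4.2)
  expect_equal(zero_low_coverage(dplyr::mutate(base, covered_fraction = 0.10))$depth,
               4.2)  # boundary: 10% is not "<10%"
  expect_equal(zero_low_coverage(dplyr::mutate(base, covered_fraction = 0.0999))$depth,
               0)
  expect_error(zero_low_coverage(dplyr::mutate(base, depth = -1,
                                               covered_fraction = 1)),
               "negative")
})

test_that("per-base depth supports mean and trimmed mean", {
  lens <- tibble::tibble(contig_id = "c", length = 100L)
  pb <- tibble::tibble(contig_id = "c", sample_id = "s",
                       pos = 1:100, depth = c(rep(10, 99), 1000))
  m <- depth_from_basedepth(pb, lens, method = "mean")
  expect_equal(m$depth, (99 * 10 + 1000) / 100)
  tm <- depth_from_basedepth(pb, lens, method = "trimmed_mean", trim = 0.05)
  expect_equal(tm$depth, 10)  # the outlier base is trimmed
  expect_equal(m$covered_fraction, 1)
})

test_that("normalization divides by gigabases and pseudo-counts are ceiled", {
  depths <- tibble::tibble(contig_id = c("v1", "v2"), sample_id = "s1",
                           depth = c(10, 0.115))
  gb <- tibble::tibble(sample_id = "s1", gb = 5)
  got <- normalize_abundance(depths, gb)
  expect_equal(got$normalized, c(2, 0.023))
  expect_equal(got$pseudo_count, c(20L, 1L))
  expect_equal(sum(got$relative), 1)

  # worked pseudo-count example: 0.23 per Gb -> ceil(2.3) = 3
  one <- normalize_abundance(
    tibble::tibble(contig_id = "v", sample_id = "s", depth = 0.23),
    tibble::tibble(sample_id = "s", gb = 1))
  expect_equal(one$pseudo_count, 3L)

  expect_error(normalize_abundance(depths,
                                   tibble::tibble(sample_id = "s9", gb = 1)),
               "missing gigabase")
  expect_error(normalize_abundance(depths,
                                   dplyr::mutate(gb, gb = 0)), "> 0")
})

test_that("alpha diversity matches closed forms and the vegan cross-check", {
  uni <- alpha_diversity(rep(5, 10))
  expect_equal(uni$observed, 10)
  expect_equal(uni$shannon, log(10))
  expect_equal(uni$inv_simpson, 10)
  expect_equal(uni$chao1, 10)
  expect_equal(uni$ace, 10)

  expect_equal(alpha_diversity(c(1, 1, 2))$chao1, 3.5)

  # no singletons, nothing rare: all estimators collapse to observed
  none_rare <- alpha_diversity(c(12, 15, 20))
  expect_equal(none_rare$chao1, 3)
  expect_equal(none_rare$ace, 3)

  expect_error(alpha_diversity(c(0, 0)), "all-zero")

  set.seed(51)
  for (i in 1:20) {
    counts <- stats::rpois(50, lambda = sample(c(1, 3, 8), 1))
    if (all(counts == 0)) next
    got <- alpha_diversity(counts)
    # independent route: vegan's estimators and diversity indices
    est <- vegan::estimateR(counts)
    expect_equal(got$chao1, unname(est["S.chao1"]), tolerance = 1e-8)
    if (is.finite(est["S.ACE"])) {
      expect_equal(got$ace, unname(est["S.ACE"]), tolerance = 1e-8)
    }
    pos <- counts[counts > 0]
    expect_equal(got$shannon, unname(vegan::diversity(pos)))
    expect_equal(got$inv_simpson, unname(vegan::diversity(pos, "invsimpson")))
    # order relations among the indices
    expect_lte(got$shannon, log(got$observed) + 1e-12)
    expect_gte(got$chao1, got$observed)
    expect_gte(got$inv_simpson, 1)
    expect_lte(got$inv_simpson, got$observed + 1e-12)
  }
})

abund_from_matrix <- function(m) {
  tibble::tibble(
    votu_id = rep(sprintf("v%d", seq_len(ncol(m))), each = nrow(m)),
    sample_id = rep(rownames(m), times = ncol(m)),
    depth = as.vector(m),
    normalized = as.vector(m),
    relative = as.vector(m / rowSums(m)),
    pseudo_count = as.integer(ceiling(10 * as.vector(m)))
  )
}

test_that("Bray-Curtis distances and PCoA behave on worked examples", {
  m <- rbind(a = c(2, 2), b = c(1, 3), c = c(2, 2))
  ab <- abund_from_matrix(m)
  ord <- beta_ordination(ab)
  d <- as.matrix(ord$distances)
  # relative-abundance view: a and c identical, a vs b = BC of [.5,.5],[.25,.75]
  expect_equal(d["a", "c"], 0)
  expect_equal(d["a", "b"], 0.25)

  # disjoint supports: distance 1
  m2 <- rbind(a = c(1, 1, 0, 0), b = c(0, 0, 1, 1), c = c(1, 0, 1, 0))
  d2 <- as.matrix(beta_ordination(abund_from_matrix(m2))$distances)
  expect_equal(d2["a", "b"], 1)

  zero_s <- dplyr::mutate(ab, relative = ifelse(sample_id == "b", 0, relative))
  expect_error(beta_ordination(zero_s), "zero total.*b")
})

test_that("PCoA reconstructs Euclidean-embeddable distances exactly", {
  # two-taxon compositions (p, 1-p) give BC(i, j) = |p_i - p_j| exactly: a
  # line metric, hence Euclidean-embeddable with one positive axis
  p <- c(0.05, 0.2, 0.35, 0.55, 0.7, 0.9)
  m <- cbind(p, 1 - p)
  rownames(m) <- sprintf("s%d", 1:6)
  ord <- beta_ordination(abund_from_matrix(m))
  expect_true(all(ord$eigenvalues > -1e-10))
  expect_equal(as.vector(ord$distances), as.vector(dist(p)), tolerance = 1e-12)
  coords <- as.matrix(ord$coordinates[, -1])
  expect_equal(as.vector(stats::dist(coords)), as.vector(ord$distances),
               tolerance = 1e-8)
  # independent eigensolver route: same leading coordinate up to sign
  cmd <- suppressWarnings(stats::cmdscale(ord$distances, k = 1, eig = FALSE))
  expect_equal(abs(coords[, 1]), abs(unname(cmd[, 1])), tolerance = 1e-8)
})

test_that("group tests: exhaustive tiny-case p equals the enumeration oracle", {
  # 4 + 2 samples with disjoint compositions: only the true labeling
  # reaches the observed pseudo-F, so p = 1 / choose(6, 2)
  m <- rbind(a1 = c(5, 4, 0, 0), a2 = c(4, 5, 0, 0), a3 = c(5, 5, 0, 0),
             a4 = c(4, 4, 0, 0), b1 = c(0, 0, 5, 4), b2 = c(0, 0, 4, 5))
  ab <- abund_from_matrix(m)
  groups <- tibble::tibble(sample_id = rownames(m),
                           group = c(rep("slope", 4), rep("axis", 2)))
  got <- group_tests(ab, groups, exhaustive = TRUE)
  expect_equal(got$permanova$p_value, 1 / choose(6, 2))
  expect_equal(got$permanova$n_labelings, choose(6, 2))

  # the in-package pseudo-F agrees with the vegan implementation
  set.seed(53)
  m2 <- matrix(stats::runif(8 * 10, 0, 3), nrow = 8,
               dimnames = list(sprintf("s%d", 1:8), NULL))
  ab2 <- abund_from_matrix(m2)
  g2 <- tibble::tibble(sample_id = rownames(m2),
                       group = rep(c("x", "y"), each = 4))
  fit <- group_tests(ab2, g2, n_perm = 99, seed = 4)
  d2 <- fit$ordination$distances
  f_own <- hadalvirome:::permanova_pseudo_f(
    d2, g2$group[match(attr(d2, "Labels"), g2$sample_id)])
  expect_equal(fit$permanova$statistic, f_own, tolerance = 1e-10)
})

test_that("group tests surface t and Wilcoxon p-values per index", {
  cm <- sim_communities(n_votus = 60, n_slope = 5, n_bottom = 5,
                        group_effect = 0.5, group_factor = 10, seed = 61)
  ab <- normalize_abundance(zero_low_coverage(cm$depths), cm$sample_gb)
  got <- group_tests(ab, cm$groups, n_perm = 199, seed = 6)
  expect_equal(nrow(got$alpha_tests), 5)

  # the reported t-test equals a direct t.test on the alpha values
  alpha <- sample_alpha_diversity(ab) |>
    dplyr::left_join(cm$groups, by = "sample_id")
  ref <- stats::t.test(shannon ~ group, data = alpha, var.equal = TRUE)
  expect_equal(got$alpha_tests$t_p[got$alpha_tests$index == "shannon"],
               ref$p.value)

  td <- tidy(got)
  expect_true(all(c("permanova", "t", "wilcoxon") %in% td$test))
  gl <- glance(got)
  expect_equal(gl$permanova_p, got$permanova$p_value)

  expect_error(group_tests(ab, dplyr::mutate(cm$groups, group = "one")),
               "two groups")
})

test_that("transcriptional activity applies the >1-read and 20% rules", {
  gc <- tibble::tibble(gene_id = sprintf("g%d", 1:10), votu_id = "v",
                       reads = c(2, 2, rep(0, 8)))
  got <- transcribed_activity(gc)
  expect_equal(got$expressed_fraction, 0.2)
  expect_true(got$active)

  # exactly 1 read is not expression
  one <- dplyr::mutate(gc, reads = c(1, rep(0, 9)))
  expect_equal(transcribed_activity(one)$n_expressed, 0)

  # 1 of 5 genes at 3 reads: boundary 20% inclusive
  five <- tibble::tibble(gene_id = sprintf("g%d", 1:5), votu_id = "v",
                         reads = c(3, 0, 0, 0, 0))
  expect_true(transcribed_activity(five)$active)
  expect_error(transcribed_activity(gc[0, ]), "empty")
})
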